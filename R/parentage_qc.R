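# Parentage assignment by Mendelian-error minimisation, sibling-based
# inference of informative SNPs, colony consensus differences, the
# sample-swap diagnostic, and small reporting arithmetic.

#' Classify a mother/father/child genotype triple
#'
#' A triple is a Mendelian `"error"` when no pair of gametes (one allele
#' from each parent) can produce the child genotype, `"uninformative"` when
#' any call is missing, and `"consistent"` otherwise. Vectorised over sites:
#' each argument is a 2-column matrix (or length-2 vector) of allele
#' indices.
#'
#' @param mother,father,child diploid calls: length-2 integer vectors or
#'   n x 2 matrices of allele indices (0/1, `NA` = missing).
#' @return character vector in `{"consistent", "error", "uninformative"}`.
#' @export
mendelian_error_rate <- function(mother, father, child) {
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 2)
  m <- as_mat(mother); f <- as_mat(father); k <- as_mat(child)
  n <- nrow(m)
  stopifnot(nrow(f) == n, nrow(k) == n)
  out <- rep("consistent", n)
  unknown <- is.na(m[, 1]) | is.na(m[, 2]) | is.na(f[, 1]) | is.na(f[, 2]) |
    is.na(k[, 1]) | is.na(k[, 2])
  # child {c1,c2} is producible iff one allele can come from the mother and
  # the other from the father, under either assignment
  ok1 <- (k[, 1] == m[, 1] | k[, 1] == m[, 2]) &
         (k[, 2] == f[, 1] | k[, 2] == f[, 2])
  ok2 <- (k[, 2] == m[, 1] | k[, 2] == m[, 2]) &
         (k[, 1] == f[, 1] | k[, 1] == f[, 2])
  out[!(ok1 | ok2)] <- "error"
  out[unknown] <- "uninformative"
  out
}

# Per-progeny Mendelian error rate for one candidate father:
# errors / informative sites, sites with any missing call excluded.
progeny_error_rates <- function(mother_gm, father_gm, progeny_gm) {
  m <- cbind(mother_gm$a1[, 1], mother_gm$a2[, 1])
  f <- cbind(father_gm$a1[, 1], father_gm$a2[, 1])
  vapply(progeny_gm$individuals, function(p) {
    k <- cbind(progeny_gm$a1[, p], progeny_gm$a2[, p])
    cls <- mendelian_error_rate(m, f, k)
    informative <- cls != "uninformative"
    if (!any(informative)) return(NA_real_)
    sum(cls == "error") / sum(informative)
  }, numeric(1))
}

#' Assign a father by minimising the median Mendelian error rate
#'
#' For each candidate father the per-progeny Mendelian error rate
#' (errors / informative sites) is computed against the mother, and the
#' median across progeny taken (mid-mean for even counts). The candidate
#' with the smallest median is assigned, unless that minimum exceeds
#' `max_error`, in which case no father is assigned (the study observed
#' crosses where no sequenced putative father was a good match).
#'
#' @param mother_gm single-individual [genotype_matrix()] for the mother.
#' @param candidates_gm [genotype_matrix()] of candidate fathers (same
#'   sites as the mother).
#' @param progeny_gm [genotype_matrix()] of progeny (same sites).
#' @param max_error maximum acceptable median error rate (default 0.05).
#' @return list with `father` (id or `NA` for no-match) and `summary`, a
#'   data.frame of candidate, median error and informative-progeny count.
#' @export
match_father <- function(mother_gm, candidates_gm, progeny_gm,
                         max_error = 0.05) {
  stopifnot(length(mother_gm$individuals) == 1L,
            length(candidates_gm$individuals) >= 1L,
            length(progeny_gm$individuals) >= 1L)
  summ <- do.call(rbind, lapply(candidates_gm$individuals, function(cand) {
    rates <- progeny_error_rates(mother_gm,
                                 gm_subset(candidates_gm, individuals = cand),
                                 progeny_gm)
    usable <- !is.na(rates)
    if (!any(usable)) {
      warning("candidate ", cand, " has no informative sites; excluded")
      return(data.frame(candidate = cand, median_error = NA_real_,
                        n_progeny = 0L))
    }
    data.frame(candidate = cand,
               median_error = stats::median(rates[usable]),
               n_progeny = sum(usable))
  }))
  ok <- !is.na(summ$median_error)
  father <- NA_character_
  if (any(ok)) {
    best <- summ$candidate[ok][which.min(summ$median_error[ok])]
    if (min(summ$median_error[ok]) <= max_error) father <- best
  }
  list(father = father, summary = summ)
}

#' Infer informative SNPs from male-sibling genotypes
#'
#' When parental genotypes are unavailable (e.g. pooled F1 RNA with a
#' failed-QC mother), sites where the parents were homozygous for different
#' alleles can be recognised in the siblings: every sibling must be
#' heterozygous there. Returns autosomal sites at which all non-missing
#' sibling calls are heterozygous, with at least `min_calls` non-missing
#' calls (limits leakage from het x het parental sites). Sites are
#' phase-unknown: the maternal allele cannot be identified.
#'
#' @param sib_gm [genotype_matrix()] of 2+ siblings.
#' @param min_calls minimum non-missing sibling calls per site.
#' @return data.frame of retained sites (`site`, `chrom`, `pos`,
#'   `phase_known = FALSE`).
#' @export
infer_sibling_snps <- function(sib_gm, min_calls = 2L) {
  if (length(sib_gm$individuals) < 2L) stop("need at least 2 siblings")
  autosomal <- as.character(arm_of(sib_gm$sites$chrom)) %in% AUTOSOMES
  het <- sib_gm$a1 != sib_gm$a2
  n_called <- rowSums(!is.na(het))
  all_het <- rowSums(het, na.rm = TRUE) == n_called & n_called > 0
  keep <- autosomal & all_het & n_called >= min_calls
  data.frame(site = which(keep),
             chrom = sib_gm$sites$chrom[keep],
             pos = sib_gm$sites$pos[keep],
             phase_known = FALSE)
}

# A site is homozygous-consensus in a colony if every non-missing call is
# homozygous for the same allele (and at least one call is present).
colony_consensus_allele <- function(gm) {
  hom <- !is.na(gm$a1) & gm$a1 == gm$a2
  any_called <- rowSums(hom) > 0
  all_hom <- rowSums(!is.na(gm$a1)) == rowSums(hom)
  allele <- rep(NA_integer_, nrow(gm$sites))
  first <- apply(gm$a1, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) x[1] else NA_integer_
  })
  same <- vapply(seq_len(nrow(gm$a1)), function(i) {
    x <- gm$a1[i, ]; x <- x[!is.na(x)]
    length(x) > 0 && all(x == x[1])
  }, logical(1))
  ok <- any_called & all_hom & same
  allele[ok] <- first[ok]
  allele
}

#' Count fixed consensus differences between two colonies, per arm
#'
#' A site counts when it is homozygous for one allele in every genotyped
#' individual of colony A, homozygous in every individual of colony B, and
#' the two alleles differ. Counts are tabulated by chromosome arm
#' (2L, 2R, 3L, 3R, X, other) plus a total.
#'
#' @param colony_a_gm,colony_b_gm [genotype_matrix()] objects sharing the
#'   same site universe.
#' @return named integer vector with one entry per arm plus `total`.
#' @export
consensus_diff_counts <- function(colony_a_gm, colony_b_gm) {
  stopifnot(nrow(colony_a_gm$sites) == nrow(colony_b_gm$sites))
  ca <- colony_consensus_allele(colony_a_gm)
  cb <- colony_consensus_allele(colony_b_gm)
  diff <- !is.na(ca) & !is.na(cb) & ca != cb
  arms <- arm_of(colony_a_gm$sites$chrom)
  counts <- table(arms[diff])
  out <- stats::setNames(as.integer(counts[ARM_LEVELS]), ARM_LEVELS)
  out[is.na(out)] <- 0L
  c(out, total = sum(out))
}

#' Sample-swap diagnostic from SNP-level allelic fractions
#'
#' Summarises per-SNP allelic imbalance: with the matched parental SNP set
#' the mean fraction sits near 0.5 and the mean absolute deviation is small;
#' scoring a cross with SNPs from non-matching parents inflates apparent
#' imbalance (informative sites in the wrong cross are frequently
#' homozygous, pushing fractions toward 0 or 1).
#'
#' @param counts count table (columns `count_a`, `count_b`), already
#'   depth-filtered or filtered here via `min_total`.
#' @param min_total per-SNP total-count filter applied before summarising.
#' @return list with `mean_deviation` (mean |fraction - 0.5|),
#'   `mean_fraction` and `n_snps`.
#' @export
mismatch_diagnostic <- function(counts, min_total = 10L) {
  counts <- filter_snps(counts, min_total)
  if (nrow(counts) == 0L) stop("no SNPs pass the depth filter")
  f <- counts$count_a / (counts$count_a + counts$count_b)
  list(mean_deviation = mean(abs(f - 0.5)),
       mean_fraction = mean(f),
       n_snps = nrow(counts))
}

#' Mean and sample standard deviation of mapping rates
#'
#' @param rates numeric vector (percentages), length 2+.
#' @return list with `mean` and `sd` (n - 1 denominator).
#' @export
summarize_mapping <- function(rates) {
  if (length(rates) < 2L) stop("need at least 2 values for a sample sd")
  list(mean = mean(rates), sd = stats::sd(rates))
}

#' Total reads required for a target per-gene depth
#'
#' Multiplies the number of annotated genes by the recommended reads per
#' gene (500 reads/gene gives roughly 60% power to detect 1.5-fold ASE).
#'
#' @param n_genes number of annotated genes.
#' @param reads_per_gene recommended reads per gene.
#' @return total read count (report at 2 significant figures).
#' @export
reads_for_power <- function(n_genes, reads_per_gene) {
  if (n_genes < 0 || reads_per_gene < 0) stop("inputs must be non-negative")
  n_genes * reads_per_gene
}

#' Percent increase of a quantity relative to a baseline
#'
#' @param baseline positive baseline value.
#' @param new new value.
#' @return `100 * (new - baseline) / baseline`.
#' @export
percent_relative_increase <- function(baseline, new) {
  if (baseline <= 0) stop("'baseline' must be positive")
  100 * (new - baseline) / baseline
}
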