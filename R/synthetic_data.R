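# Synthetic crosses with known ground truth. The generator emulates the
# statistical structure of the real experiment: two partially inbred
# colonies with a high density of fixed homozygous differences and residual
# within-colony heterozygosity, Mendelian F1 segregation, beta-binomial
# allelic counts (overdispersion 0.038) at SNPs informative within each
# cross, a planted fraction of cis-regulated genes with shifted allelic
# fractions, copy-number confounders, and per-gene age classes on a small
# species tree. It does not model read-level artefacts (mapping bias,
# linkage structure, FASTQ-level noise).

#' Configuration for the synthetic cohort generator
#'
#' Defaults are the study conditions the generator emulates: six crosses
#' (two with unphased, sibling-inferred SNP sets), six male siblings per
#' cross, an exonic SNP density yielding a handful of informative
#' (parent-homozygous-different) sites per gene per cross, mean per-SNP
#' coverage 100, overdispersion 0.038, 20% of genes cis-regulated with
#' true major-allele fraction 0.7.
#'
#' @param seed integer; fixes the whole bundle byte-for-byte.
#' @param n_genes number of genes.
#' @param snps_per_gene_lambda Poisson mean of exonic SNPs per gene
#'   (genes may draw 0 and are then undetectable).
#' @param coverage_mean,coverage_size negative-binomial mean and size of the
#'   per-SNP total read count.
#' @param rho_true beta-binomial overdispersion of allelic counts.
#' @param frac_ase fraction of genes with planted cis-regulation.
#' @param ase_maf true major-allele fraction of ASE genes (scalar in
#'   (0.5, 1], or a `function(n)` drawing n values).
#' @param n_sibs male siblings genotyped per cross.
#' @param n_crosses number of crosses (half each direction).
#' @param n_extra_candidates extra unrelated candidate fathers per colony.
#' @param colony_div probability that a SNP site is a fixed homozygous
#'   difference between the colonies. The default keeps fixed differences a
#'   minority of each cross's informative sites, mirroring the real design
#'   where per-cross SNP sets far exceed the colony consensus differences.
#' @param het_rate probability that a non-fixed site segregates within the
#'   colonies.
#' @param het_freq allele frequency of segregating sites (both colonies).
#' @param frac_cnv fraction of genes with a planted copy-number != 2 in at
#'   least one parent.
#' @param missing_rate per-call genotype missingness in emitted matrices.
#' @param phased logical vector, one per cross: `TRUE` when parental
#'   genotypes identify the maternal allele. Default: the first two crosses
#'   are unphased (their mothers failed sequencing QC in the emulated
#'   design).
#' @param young_ase_boost relative enrichment of the youngest gene-age
#'   class among planted ASE genes.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 1000L, snps_per_gene_lambda = 25,
                       coverage_mean = 100, coverage_size = 10,
                       rho_true = 0.038, frac_ase = 0.2, ase_maf = 0.7,
                       n_sibs = 6L, n_crosses = 6L, n_extra_candidates = 2L,
                       colony_div = 0.08, het_rate = 0.9, het_freq = 0.5,
                       frac_cnv = 0.1, missing_rate = 0.02,
                       phased = NULL, young_ase_boost = 2) {
  if (n_genes < 1 || n_crosses < 1 || n_sibs < 1)
    stop("degenerate configuration: counts must be positive")
  stopifnot_scalar_prob(frac_ase, "frac_ase")
  stopifnot_scalar_prob(colony_div, "colony_div")
  stopifnot_scalar_prob(het_rate, "het_rate")
  stopifnot_scalar_prob(het_freq, "het_freq")
  stopifnot_scalar_prob(frac_cnv, "frac_cnv")
  stopifnot_scalar_prob(missing_rate, "missing_rate")
  if (rho_true < 0 || rho_true >= 1) stop("'rho_true' must be in [0, 1)")
  if (is.numeric(ase_maf) && (ase_maf <= 0.5 || ase_maf > 1))
    stop("'ase_maf' must lie in (0.5, 1]")
  if (is.null(phased))
    phased <- c(rep(FALSE, min(2L, n_crosses)),
                rep(TRUE, max(0L, n_crosses - 2L)))
  if (length(phased) != n_crosses)
    stop("'phased' must have one flag per cross")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 snps_per_gene_lambda = snps_per_gene_lambda,
                 coverage_mean = coverage_mean, coverage_size = coverage_size,
                 rho_true = rho_true, frac_ase = frac_ase, ase_maf = ase_maf,
                 n_sibs = as.integer(n_sibs), n_crosses = as.integer(n_crosses),
                 n_extra_candidates = as.integer(n_extra_candidates),
                 colony_div = colony_div, het_rate = het_rate,
                 het_freq = het_freq,
                 frac_cnv = frac_cnv, missing_rate = missing_rate,
                 phased = phased, young_ase_boost = young_ase_boost),
            class = "sim_config")
}

# Genes laid out along the five arms with roughly genome-proportional
# weights; 2 kb genes spaced 10 kb apart, SNP positions uniform within the
# gene body.
sim_gene_layout <- function(config) {
  with_seed(substream_seed(config$seed, "layout"), {
    arms <- sample(c("2L", "2R", "3L", "3R", "X"), config$n_genes,
                   replace = TRUE, prob = c(0.20, 0.26, 0.18, 0.22, 0.14))
    idx <- stats::ave(seq_along(arms), arms, FUN = seq_along)
    start <- (idx - 1L) * 10000L + 1000L        # 0-based
    genes <- data.frame(chrom = arms, start = start, end = start + 2000L,
                        gene_id = sprintf("GENE%04d", seq_len(config$n_genes)),
                        arm = arms, stringsAsFactors = FALSE)
    n_snps <- stats::rpois(config$n_genes, config$snps_per_gene_lambda)
    snps <- data.frame(
      gene_id = rep(genes$gene_id, n_snps),
      chrom = rep(genes$chrom, n_snps),
      pos = unlist(lapply(seq_len(config$n_genes), function(i) {
        if (n_snps[i] == 0) return(integer())
        sort(sample((genes$start[i] + 1L):genes$end[i], n_snps[i]))
      })),
      stringsAsFactors = FALSE)
    list(genes = genes, snps = snps)
  })
}

#' Simulate the parental colonies
#'
#' Two colonies of diploid individuals over a shared SNP-site universe:
#' a configured density of sites fixed homozygous-different between the
#' colonies (the planting list is returned as ground truth) and residual
#' within-colony heterozygosity at the remaining segregating sites.
#'
#' @param config a [sim_config()].
#' @param sites optional site table (`chrom`, `pos`); defaults to the SNP
#'   layout implied by the config.
#' @return list with `gm` (the emitted [genotype_matrix()] including
#'   missingness), `gm_true` (fully observed truth), `colony` (named
#'   character vector of colony assignment), `fixed_diff` (logical planting
#'   list per site) and `roles` (data.frame of individual roles).
#' @export
simulate_parents <- function(config, sites = NULL) {
  if (is.null(sites)) sites <- sim_gene_layout(config)$snps[, c("chrom", "pos")]
  n_half <- ceiling(config$n_crosses / 2)
  # colony N supplies mothers of B crosses and fathers of K crosses
  n_per_colony <- n_half + (config$n_crosses - n_half) +
    config$n_extra_candidates
  ids_n <- sprintf("N_%02d", seq_len(n_per_colony))
  ids_k <- sprintf("K_%02d", seq_len(n_per_colony))
  ids <- c(ids_n, ids_k)
  colony <- stats::setNames(rep(c("N", "K"), each = n_per_colony), ids)
  S <- nrow(sites)
  with_seed(substream_seed(config$seed, "parents"), {
    type <- sample(c("fixed", "seg", "mono"), S, replace = TRUE,
                   prob = c(config$colony_div,
                            (1 - config$colony_div) * config$het_rate,
                            (1 - config$colony_div) * (1 - config$het_rate)))
    alt_in_n <- stats::runif(S) < 0.5     # which colony carries ALT at fixed sites
    a1 <- matrix(0L, S, length(ids), dimnames = list(NULL, ids))
    a2 <- a1
    fixed <- type == "fixed"
    for (id in ids) {
      is_n <- colony[id] == "N"
      hom_alt <- fixed & (alt_in_n == is_n)
      a1[hom_alt, id] <- 1L; a2[hom_alt, id] <- 1L
    }
    seg <- which(type == "seg")
    if (length(seg)) {
      g1 <- matrix(stats::rbinom(length(seg) * length(ids), 1L, config$het_freq),
                   nrow = length(seg))
      g2 <- matrix(stats::rbinom(length(seg) * length(ids), 1L, config$het_freq),
                   nrow = length(seg))
      a1[seg, ] <- pmin(g1, g2)
      a2[seg, ] <- pmax(g1, g2)
    }
    site_tab <- data.frame(chrom = sites$chrom, pos = sites$pos,
                           ref = "A", alt = "T", stringsAsFactors = FALSE)
    gm_true <- genotype_matrix(site_tab, a1, a2)
    drop <- matrix(stats::runif(S * length(ids)) < config$missing_rate,
                   S, length(ids))
    a1m <- a1; a2m <- a2
    a1m[drop] <- NA_integer_; a2m[drop] <- NA_integer_
    gm <- genotype_matrix(site_tab, a1m, a2m)
    roles <- data.frame(individual = ids, colony = unname(colony),
                        stringsAsFactors = FALSE)
    list(gm = gm, gm_true = gm_true, colony = colony,
         fixed_diff = fixed, roles = roles)
  })
}

#' Simulate F1 sibling genotypes by Mendelian segregation
#'
#' Each sibling inherits one allele from each parent, drawn uniformly and
#' independently across sites.
#'
#' @param mother_gm,father_gm single-individual [genotype_matrix()] objects
#'   over the same sites (fully observed).
#' @param n_sibs number of siblings.
#' @param seed integer seed.
#' @return [genotype_matrix()] of the siblings.
#' @export
simulate_f1 <- function(mother_gm, father_gm, n_sibs, seed) {
  stopifnot(length(mother_gm$individuals) == 1L,
            length(father_gm$individuals) == 1L,
            nrow(mother_gm$sites) == nrow(father_gm$sites))
  S <- nrow(mother_gm$sites)
  ids <- sprintf("sib_%02d", seq_len(n_sibs))
  with_seed(seed, {
    pick <- function(g1, g2) ifelse(stats::runif(S) < 0.5, g1, g2)
    a1 <- vapply(ids, function(i) pick(mother_gm$a1[, 1], mother_gm$a2[, 1]),
                 integer(S))
    a2 <- vapply(ids, function(i) pick(father_gm$a1[, 1], father_gm$a2[, 1]),
                 integer(S))
    if (S == 1L) { a1 <- matrix(a1, 1L, dimnames = list(NULL, ids))
                   a2 <- matrix(a2, 1L, dimnames = list(NULL, ids)) }
    genotype_matrix(mother_gm$sites, a1, a2)
  })
}

#' Simulate per-SNP allelic read counts
#'
#' At each informative SNP the total read count is drawn from a negative
#' binomial and the maternal count from a beta-binomial with mean equal to
#' the SNP's true maternal fraction and intraclass overdispersion
#' `rho_true`. For phased output `count_a` is the maternal count; for
#' unphased output it is the reference-allele count.
#'
#' @param snps data.frame with columns `gene_id`, `chrom`, `pos`,
#'   `mat_frac` (true maternal fraction) and `maternal_is_ref` (logical).
#' @param config a [sim_config()] (supplies coverage and overdispersion).
#' @param sample_id cross/sample identifier for the emitted rows.
#' @param phased emit maternal-oriented (`TRUE`) or reference-oriented
#'   counts.
#' @param seed integer seed.
#' @return count-table data.frame (see [read_count_table()]).
#' @export
simulate_allelic_counts <- function(snps, config, sample_id, phased, seed) {
  n <- nrow(snps)
  with_seed(seed, {
    total <- stats::rnbinom(n, mu = config$coverage_mean,
                            size = config$coverage_size)
    count_m <- rbetabinom(n, total, snps$mat_frac, config$rho_true)
    count_a <- if (phased) count_m
               else ifelse(snps$maternal_is_ref, count_m, total - count_m)
    data.frame(sample_id = sample_id, chrom = snps$chrom, pos = snps$pos,
               gene_id = snps$gene_id,
               count_a = as.integer(count_a),
               count_b = as.integer(total - count_a),
               phase_known = phased, stringsAsFactors = FALSE)
  })
}

# Fixed 8-taxon ladder species tree; tip t1 is the focal taxon. Age class 1
# is the root (oldest), classes 2..7 the successively younger ancestors of
# t1, class 8 the focal tip itself (species-specific gene).
SIM_TREE_NEWICK <- "(((((((t1,t2),t3),t4),t5),t6),t7),t8);"
SIM_N_AGE_CLASSES <- 8L

sim_presence_from_age <- function(age_class) {
  tips <- paste0("t", 1:8)
  m <- matrix(0L, length(age_class), 8L,
              dimnames = list(names(age_class), tips))
  for (i in seq_along(age_class)) {
    c_i <- age_class[i]
    n_tips <- if (c_i == 8L) 1L else 9L - c_i
    m[i, seq_len(n_tips)] <- 1L
  }
  m
}

sim_truth <- function(config, genes) {
  with_seed(substream_seed(config$seed, "truth"), {
    n <- config$n_genes
    # class 2 (absent only in the root's sister tip) is indistinguishable
    # from a root origin under the older-origin tie rule, so it is never
    # planted: its mass goes to the root class
    age_class <- sample(seq_len(SIM_N_AGE_CLASSES), n, replace = TRUE,
                        prob = c(0.52, 0, 0.10, 0.08, 0.08, 0.07, 0.06, 0.09))
    n_ase <- round(config$frac_ase * n)
    w <- ifelse(age_class == SIM_N_AGE_CLASSES, config$young_ase_boost, 1)
    is_ase <- rep(FALSE, n)
    if (n_ase > 0)
      is_ase[sample.int(n, n_ase, prob = w)] <- TRUE
    true_maf <- rep(0.5, n)
    if (any(is_ase))
      true_maf[is_ase] <- if (is.function(config$ase_maf))
        config$ase_maf(sum(is_ase)) else config$ase_maf
    direction <- rep("none", n)
    direction[is_ase] <- sample(c("maternal", "paternal"), sum(is_ase),
                                replace = TRUE)
    has_cnv <- stats::runif(n) < config$frac_cnv
    data.frame(gene_id = genes$gene_id, is_ase = is_ase, true_maf = true_maf,
               direction = direction, has_cnv = has_cnv,
               age_class = age_class, stringsAsFactors = FALSE)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Generates parents, crosses, F1 sibling genotypes, per-cross allelic
#' count tables, gene annotation, a copy-number table, a species tree with
#' a gene presence/absence matrix, sweep and CRM interval sets, and the
#' ground truth behind all of it. Identical configs (including seed) yield
#' byte-identical bundles.
#'
#' @param config a [sim_config()].
#' @param dir optional directory: when given, every component is written
#'   in the file dialects the package readers consume.
#' @return list of class `sim_cohort` with elements `config`, `genes`,
#'   `snps`, `parents` (see [simulate_parents()]), `crosses` (data.frame
#'   with `cross_id`, `mother`, `father`, `phased`), `sib_gms` (list of
#'   sibling [genotype_matrix()] per cross), `counts` (list of count
#'   tables), `cn_table`, `tree_newick`, `presence`, `sweeps`, `crms`,
#'   `truth`, and `paths` when written.
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL) {
  layout <- sim_gene_layout(config)
  genes <- layout$genes
  snps <- layout$snps
  parents <- simulate_parents(config, sites = snps[, c("chrom", "pos")])
  truth <- sim_truth(config, genes)

  n_half <- ceiling(config$n_crosses / 2)
  ids_n <- parents$roles$individual[parents$roles$colony == "N"]
  ids_k <- parents$roles$individual[parents$roles$colony == "K"]
  crosses <- data.frame(
    cross_id = c(sprintf("B%d", seq_len(n_half)),
                 sprintf("K%d", seq_len(config$n_crosses - n_half))),
    mother = c(ids_n[seq_len(n_half)],
               ids_k[seq_len(config$n_crosses - n_half)]),
    father = c(ids_k[n_half + seq_len(n_half)],
               ids_n[n_half + seq_len(config$n_crosses - n_half)]),
    phased = config$phased, stringsAsFactors = FALSE)

  # copy-number table: parents (and siblings, below) default 2 copies;
  # planted CNV genes put 3 copies in one random parent in a cross
  cnv_carrier <- stats::setNames(rep(NA_character_, config$n_genes),
                                 genes$gene_id)
  with_seed(substream_seed(config$seed, "cnv"), {
    cross_parents <- unique(c(crosses$mother, crosses$father))
    for (g in truth$gene_id[truth$has_cnv])
      cnv_carrier[g] <- sample(cross_parents, 1L)
  })

  truth_map <- truth; rownames(truth_map) <- truth_map$gene_id
  gene_mat_frac <- function(cross) {
    base <- ifelse(truth_map$direction == "maternal", truth_map$true_maf,
                   ifelse(truth_map$direction == "paternal",
                          1 - truth_map$true_maf, 0.5))
    cm <- rep(1, config$n_genes); cp <- rep(1, config$n_genes)
    carrier <- cnv_carrier[truth_map$gene_id]
    cm[!is.na(carrier) & carrier == cross$mother] <- 2   # 2:1 copy ratio in F1
    cp[!is.na(carrier) & carrier == cross$father] <- 2
    stats::setNames(cm * base / (cm * base + cp * (1 - base)),
                    truth_map$gene_id)
  }

  sib_gms <- list(); counts <- list()
  true_gm <- parents$gm_true
  for (i in seq_len(config$n_crosses)) {
    cr <- crosses[i, ]
    mother_gm <- gm_subset(true_gm, individuals = cr$mother)
    father_gm <- gm_subset(true_gm, individuals = cr$father)
    sib_true <- simulate_f1(mother_gm, father_gm, config$n_sibs,
                            substream_seed(config$seed, paste0("f1_", cr$cross_id)))
    # emitted sibling matrix carries missingness
    with_seed(substream_seed(config$seed, paste0("miss_", cr$cross_id)), {
      drop <- matrix(stats::runif(prod(dim(sib_true))) < config$missing_rate,
                     nrow = nrow(sib_true$sites))
      a1 <- sib_true$a1; a2 <- sib_true$a2
      a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
      sib_gms[[cr$cross_id]] <- genotype_matrix(sib_true$sites, a1, a2)
    })
    # informative SNPs: parents homozygous for different alleles; unphased
    # crosses can only use sibling-inferable autosomal sites
    m_hom <- mother_gm$a1[, 1] == mother_gm$a2[, 1]
    f_hom <- father_gm$a1[, 1] == father_gm$a2[, 1]
    informative <- m_hom & f_hom & (mother_gm$a1[, 1] != father_gm$a1[, 1])
    if (!cr$phased)
      informative <- informative &
        as.character(arm_of(true_gm$sites$chrom)) %in% AUTOSOMES
    inf_snps <- snps[informative, , drop = FALSE]
    mf <- gene_mat_frac(cr)
    inf_snps$mat_frac <- unname(mf[inf_snps$gene_id])
    inf_snps$maternal_is_ref <- mother_gm$a1[informative, 1] == 0L
    counts[[cr$cross_id]] <- simulate_allelic_counts(
      inf_snps, config, cr$cross_id, cr$phased,
      substream_seed(config$seed, paste0("counts_", cr$cross_id)))
  }

  # copy-number long table over cross parents and siblings
  all_inds <- c(unique(c(crosses$mother, crosses$father)),
                unlist(lapply(names(sib_gms), function(cid)
                  paste0(cid, ".", sib_gms[[cid]]$individuals))))
  cn_table <- expand.grid(gene_id = genes$gene_id, individual = all_inds,
                          stringsAsFactors = FALSE)
  cn_table$copy_number <- 2L
  with_seed(substream_seed(config$seed, "cnv_sibs"), {
    for (g in names(cnv_carrier)[!is.na(cnv_carrier)]) {
      cn_table$copy_number[cn_table$gene_id == g &
                             cn_table$individual == cnv_carrier[g]] <- 3L
      # siblings of crosses involving the carrier inherit the extra copy
      # with probability 1/2
      hit <- crosses$mother == cnv_carrier[g] | crosses$father == cnv_carrier[g]
      for (cid in crosses$cross_id[hit]) {
        sibs <- paste0(cid, ".", sib_gms[[cid]]$individuals)
        inherit <- sibs[stats::runif(length(sibs)) < 0.5]
        cn_table$copy_number[cn_table$gene_id == g &
                               cn_table$individual %in% inherit] <- 3L
      }
    }
  })

  presence <- sim_presence_from_age(
    stats::setNames(truth$age_class, truth$gene_id))

  # sweep and CRM intervals: random layouts (no planted association)
  with_seed(substream_seed(config$seed, "intervals"), {
    mk_intervals <- function(n_per_arm, width, prefix) {
      do.call(rbind, lapply(unique(genes$chrom), function(a) {
        hi <- max(genes$end[genes$chrom == a])
        w <- max(1L, min(width, hi %/% 2L))
        st <- sort(sample.int(max(hi - w, n_per_arm), n_per_arm))
        data.frame(chrom = a, start = st, end = st + w,
                   label = sprintf("%s_%s_%d", prefix, a, seq_len(n_per_arm)),
                   stringsAsFactors = FALSE)
      }))
    }
    sweeps <- mk_intervals(2L, 60000L, "sweep")
    crms <- mk_intervals(20L, 800L, "crm")
  })

  cohort <- structure(list(config = config, genes = genes, snps = snps,
                           parents = parents, crosses = crosses,
                           sib_gms = sib_gms, counts = counts,
                           cn_table = cn_table,
                           tree_newick = SIM_TREE_NEWICK,
                           presence = presence, sweeps = sweeps, crms = crms,
                           truth = truth),
                      class = "sim_cohort")
  if (!is.null(dir)) cohort$paths <- write_cohort(cohort, dir)
  cohort
}

#' Simulate allelic counts scored with another cross's SNP set
#'
#' Emulates the sample-swap scenario: RNA from one cross's F1 pool is
#' scored at the SNPs informative for a different cross's parents. At such
#' a site the true reference-allele fraction of the pool is determined by
#' the RNA cross's own parental genotypes (`(dosage_m + dosage_f) / 4`
#' reference alleles), which is frequently 0 or 1 — inflating apparent
#' allelic imbalance relative to the matched SNP set.
#'
#' @param cohort a `sim_cohort`.
#' @param rna_cross cross id whose F1 pool supplies the reads.
#' @param snp_cross cross id whose parents define the SNP set.
#' @param seed integer seed.
#' @return count-table data.frame (reference-oriented, `phase_known = FALSE`).
#' @export
simulate_swapped_counts <- function(cohort, rna_cross, snp_cross, seed) {
  config <- cohort$config
  gm <- cohort$parents$gm_true
  cr_snp <- cohort$crosses[cohort$crosses$cross_id == snp_cross, ]
  cr_rna <- cohort$crosses[cohort$crosses$cross_id == rna_cross, ]
  if (!nrow(cr_snp) || !nrow(cr_rna)) stop("unknown cross id")
  gt <- function(ind) cbind(gm$a1[, ind], gm$a2[, ind])
  m_s <- gt(cr_snp$mother); f_s <- gt(cr_snp$father)
  informative <- m_s[, 1] == m_s[, 2] & f_s[, 1] == f_s[, 2] &
    m_s[, 1] != f_s[, 1]
  m_r <- gt(cr_rna$mother); f_r <- gt(cr_rna$father)
  ref_dosage <- function(g) rowSums(g == 0L)
  p_ref <- (ref_dosage(m_r) + ref_dosage(f_r))[informative] / 4
  snps <- cohort$snps[informative, , drop = FALSE]
  n <- nrow(snps)
  with_seed(seed, {
    total <- stats::rnbinom(n, mu = config$coverage_mean,
                            size = config$coverage_size)
    count_a <- integer(n)
    mid <- p_ref > 0 & p_ref < 1
    count_a[mid] <- rbetabinom(sum(mid), total[mid], p_ref[mid],
                               config$rho_true)
    count_a[p_ref == 1] <- total[p_ref == 1]
    data.frame(sample_id = rna_cross, chrom = snps$chrom, pos = snps$pos,
               gene_id = snps$gene_id, count_a = as.integer(count_a),
               count_b = as.integer(total - count_a),
               phase_known = FALSE, stringsAsFactors = FALSE)
  })
}

#' Write a simulated cohort to disk
#'
#' Emits the bundle in the dialects the package readers consume:
#' `parents.vcf`, `sibs_<cross>.vcf`, `counts_<cross>.tsv`,
#' `annotation.bed`, `copy_number.tsv`, `tree.nwk`, `presence.tsv`,
#' `sweeps.bed`, `crms.bed`, `crosses.tsv` and `truth.tsv`.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return named list of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list()
  p$parents <- file.path(dir, "parents.vcf")
  write_vcf_subset(cohort$parents$gm, p$parents)
  for (cid in names(cohort$sib_gms)) {
    p[[paste0("sibs_", cid)]] <- file.path(dir, sprintf("sibs_%s.vcf", cid))
    write_vcf_subset(cohort$sib_gms[[cid]], p[[paste0("sibs_", cid)]])
    p[[paste0("counts_", cid)]] <- file.path(dir, sprintf("counts_%s.tsv", cid))
    write_count_table(cohort$counts[[cid]], p[[paste0("counts_", cid)]])
  }
  p$annotation <- file.path(dir, "annotation.bed")
  write_gene_annotation(cohort$genes, p$annotation)
  p$copy_number <- file.path(dir, "copy_number.tsv")
  write_copy_number(cohort$cn_table, p$copy_number)
  p$tree <- file.path(dir, "tree.nwk")
  writeLines(cohort$tree_newick, p$tree)
  p$presence <- file.path(dir, "presence.tsv")
  write_presence_matrix(cohort$presence, p$presence)
  p$sweeps <- file.path(dir, "sweeps.bed")
  write_intervals(cohort$sweeps, p$sweeps)
  p$crms <- file.path(dir, "crms.bed")
  write_intervals(cohort$crms, p$crms)
  p$crosses <- file.path(dir, "crosses.tsv")
  utils::write.table(cohort$crosses, p$crosses, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p$truth <- file.path(dir, "truth.tsv")
  utils::write.table(cohort$truth, p$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p
}
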