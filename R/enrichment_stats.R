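# Confounder and enrichment analyses: exact 2x2 tests (copy-number
# variants, selective sweeps, gene-age classes), Wagner-parsimony gene
# ages on a species tree, the chromosome-arm two-way ANOVA, and generic
# interval operations (overlap counting, flanking-gene assignment).

#' Two-sided Fisher's exact test with the sample odds ratio
#'
#' Rows are ASE / non-ASE, columns feature-present / feature-absent. The
#' reported odds ratio is the sample (cross-product) estimate
#' `(a d) / (b c)` — `Inf` when `b c = 0` with `a d > 0` — not the
#' conditional MLE. The two-sided p-value sums the hypergeometric
#' probabilities of all tables with the same margins whose probability does
#' not exceed that of the observed table.
#'
#' @param a,b,c,d non-negative integer cell counts, or `a` may be a 2x2
#'   matrix.
#' @return list of class `fisher2x2`: `odds_ratio`, `p_value`, `table`.
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), c(2L, 2L)))
    tab <- a
  } else {
    tab <- matrix(c(a, c, b, d), 2L, 2L)
  }
  if (any(tab < 0)) stop("cell counts must be non-negative")
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- min(1, stats::fisher.test(tab, alternative = "two.sided")$p.value)
  structure(list(odds_ratio = or, p_value = p, table = tab),
            class = "fisher2x2")
}

#' @export
print.fisher2x2 <- function(x, ...) {
  cat(sprintf("Fisher exact 2x2: OR = %.3g, two-sided p = %.3g\n",
              x$odds_ratio, x$p_value))
  invisible(x)
}

# Sankoff up/down dynamic programme for a binary character on a rooted
# tree with unit change cost. Returns, for every node, the minimum total
# tree cost conditional on that node's state.
sankoff_node_costs <- function(tree, tip_states) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  up <- matrix(Inf, n_node, 2L)            # columns: state 0 (absent), 1 (present)
  up[(n_tip + 1L):n_node, ] <- 0           # internal nodes accumulate
  up[cbind(seq_len(n_tip), tip_states[tree$tip.label] + 1L)] <- 0
  edges <- stats::reorder(tree, "postorder")$edge
  children <- split(edges[, 2], edges[, 1])
  # postorder: every edge below v precedes the edge (p, v), so v's subtree
  # cost is complete when it is folded into p
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, 1]; v <- edges[i, 2]
    for (s in 1:2)
      up[p, s] <- up[p, s] + min(up[v, s], up[v, 3 - s] + 1)
  }
  root <- n_tip + 1L
  down <- matrix(NA_real_, n_node, 2L)
  down[root, ] <- 0
  # preorder: reverse postorder edge list
  for (i in rev(seq_len(nrow(edges)))) {
    p <- edges[i, 1]; v <- edges[i, 2]
    sibs <- setdiff(children[[as.character(p)]], v)
    sib_cost <- function(s) sum(vapply(sibs, function(cn)
      min(up[cn, s], up[cn, 3 - s] + 1), numeric(1)))
    for (s in 1:2)
      down[v, s] <- min(down[p, 1] + (s != 1) + sib_cost(1),
                        down[p, 2] + (s != 2) + sib_cost(2))
  }
  list(up = up, down = down, total = up + down,
       min_cost = min(up[root, ]))
}

#' Wagner-parsimony gene ages on a rooted species tree
#'
#' For each gene (a binary presence/absence character over the tips),
#' ancestral presence states are reconstructed by minimum-change (Wagner)
#' parsimony, and the gene's age is the deepest ancestor of the focal tip
#' that is reconstructed as present in at least one minimum-change
#' labelling — ambiguity is thereby resolved toward the older origin. Age
#' classes are indexed from the root: 1 = root (oldest), increasing toward
#' the focal tip, whose own class (`n_ancestors + 1`) means
#' species-specific.
#'
#' @param presence integer matrix (genes x tips, 0/1) with gene ids as row
#'   names and tip labels as column names.
#' @param tree a rooted `ape::phylo` tree (or a Newick string).
#' @param focal focal tip label.
#' @return data.frame: `gene_id`, `age_class`, `min_changes`; attribute
#'   `n_classes` gives the number of age classes.
#' @export
age_assign <- function(presence, tree, focal) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!(focal %in% tree$tip.label)) stop("focal taxon must be a tip")
  tips <- tree$tip.label
  if (!all(tips %in% colnames(presence)))
    stop("presence matrix missing tip(s): ",
         paste(setdiff(tips, colnames(presence)), collapse = ", "))
  n_tip <- length(tips)
  root <- n_tip + 1L
  focal_idx <- match(focal, tips)
  path <- ape::nodepath(tree, from = root, to = focal_idx)  # root ... tip
  n_classes <- length(path)
  out <- data.frame(gene_id = rownames(presence),
                    age_class = NA_integer_, min_changes = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(presence))) {
    st <- stats::setNames(as.integer(presence[i, tips]), tips)
    if (st[focal] != 1L)
      stop("gene ", rownames(presence)[i], " absent from focal taxon")
    sk <- sankoff_node_costs(tree, st)
    present_optimal <- sk$total[, 2] <= sk$min_cost
    out$age_class[i] <- match(TRUE, present_optimal[path])
    out$min_changes[i] <- as.integer(sk$min_cost)
  }
  attr(out, "n_classes") <- n_classes
  out
}

#' Per-age-class enrichment of ASE genes
#'
#' For each age class, tests the 2x2 table (ASE in-class / ASE out-of-class
#' vs non-ASE in-class / out-of-class) with [fisher_exact_2x2()].
#' Significance stars follow the convention `*` for 0.001 < p < 0.05 and
#' `***` for p <= 0.001.
#'
#' @param ase_genes,non_ase_genes character vectors of gene ids.
#' @param ages data.frame from [age_assign()] (or a named vector of age
#'   classes).
#' @return data.frame per class: `age_class`, `n_ase`, `n_non_ase`,
#'   `odds_ratio`, `p_value`, `stars`, `note`.
#' @export
age_enrichment <- function(ase_genes, non_ase_genes, ages) {
  if (is.data.frame(ages))
    ages <- stats::setNames(ages$age_class, ages$gene_id)
  missing_age <- setdiff(c(ase_genes, non_ase_genes), names(ages))
  if (length(missing_age))
    stop("gene(s) without an age class: ",
         paste(utils::head(missing_age, 3), collapse = ", "))
  classes <- sort(unique(ages[c(ase_genes, non_ase_genes)]))
  rows <- lapply(classes, function(cl) {
    a <- sum(ages[ase_genes] == cl)
    b <- length(ase_genes) - a
    c_ <- sum(ages[non_ase_genes] == cl)
    d <- length(non_ase_genes) - c_
    if (a + c_ == 0L)
      return(data.frame(age_class = cl, n_ase = 0L, n_non_ase = 0L,
                        odds_ratio = NA_real_, p_value = NA_real_,
                        stars = "", note = "empty class"))
    ft <- fisher_exact_2x2(a, b, c_, d)
    stars <- if (ft$p_value <= 0.001) "***"
             else if (ft$p_value < 0.05) "*" else ""
    data.frame(age_class = cl, n_ase = a, n_non_ase = c_,
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               stars = stars, note = "")
  })
  do.call(rbind, rows)
}

#' Two-way main-effects ANOVA on per-arm ASE proportions
#'
#' Tests whether chromosome arm and cross explain variance in the
#' proportion of ASE genes among detectable genes, on a complete
#' arm x cross grid of proportions (main effects only; residual
#' df = (A-1)(C-1)). Sums of squares are computed from marginal means;
#' for a balanced complete grid this matches [stats::aov()].
#'
#' @param arm_table data.frame with columns `arm`, `cross`, `proportion`
#'   (one row per cell).
#' @return data.frame with rows `arm`, `cross`, `residual`: `df`,
#'   `sum_sq`, `F`, `p`; attribute `ss_total`.
#' @export
arm_anova <- function(arm_table) {
  arms <- unique(arm_table$arm); crosses <- unique(arm_table$cross)
  if (nrow(arm_table) != length(arms) * length(crosses) ||
      anyDuplicated(arm_table[, c("arm", "cross")]))
    stop("need a complete arm x cross grid with one proportion per cell")
  y <- arm_table$proportion
  grand <- mean(y)
  m_arm <- tapply(y, arm_table$arm, mean)
  m_cross <- tapply(y, arm_table$cross, mean)
  A <- length(arms); C <- length(crosses)
  ss_arm <- C * sum((m_arm - grand)^2)
  ss_cross <- A * sum((m_cross - grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_res <- ss_total - ss_arm - ss_cross
  df_arm <- A - 1L; df_cross <- C - 1L; df_res <- (A - 1L) * (C - 1L)
  ms_res <- ss_res / df_res
  f_stat <- function(ss, df) {
    if (ms_res <= .Machine$double.eps * max(1, ss_total)) {
      if (ss / df <= .Machine$double.eps * max(1, ss_total)) 0 else Inf
    } else (ss / df) / ms_res
  }
  f_arm <- f_stat(ss_arm, df_arm)
  f_cross <- f_stat(ss_cross, df_cross)
  p_of <- function(f, df1) {
    if (f == 0) 1 else if (is.infinite(f)) 0
    else stats::pf(f, df1, df_res, lower.tail = FALSE)
  }
  out <- data.frame(term = c("arm", "cross", "residual"),
                    df = c(df_arm, df_cross, df_res),
                    sum_sq = c(ss_arm, ss_cross, ss_res),
                    F = c(f_arm, f_cross, NA_real_),
                    p = c(p_of(f_arm, df_arm), p_of(f_cross, df_cross),
                          NA_real_))
  attr(out, "ss_total") <- ss_total
  out
}

# Half-open [start, end) intervals -> IRanges (1-based closed) per chrom.
as_iranges <- function(d) IRanges::IRanges(start = d$start + 1L, end = d$end)

#' Count intervals of one set overlapping another
#'
#' Intervals are 0-based half-open; overlap requires intersection length
#' > 0. Each interval of `set_a` is counted at most once.
#'
#' @param set_a,set_b data.frames with columns `chrom`, `start`, `end`.
#' @return integer: number of `set_a` intervals overlapping any `set_b`
#'   interval.
#' @export
overlap_count <- function(set_a, set_b) {
  total <- 0L
  for (chr in unique(set_a$chrom)) {
    a <- set_a[set_a$chrom == chr, , drop = FALSE]
    b <- set_b[set_b$chrom == chr, , drop = FALSE]
    if (nrow(b) == 0L) next
    total <- total +
      sum(IRanges::countOverlaps(as_iranges(a), as_iranges(b)) > 0L)
  }
  total
}

#' Assign flanking genes to intervals
#'
#' Each interval maps to every gene it overlaps, plus the nearest
#' non-overlapping gene on each side on the same chromosome (a regulatory
#' element between two genes is assigned to both neighbours). Neighbours
#' tied at the same distance are all reported.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`,
#'   `label` (0-based half-open).
#' @param genes gene annotation data.frame (`chrom`, `start`, `end`,
#'   `gene_id`).
#' @return data.frame: `label`, `gene_id`, `relation` in
#'   `{"overlap", "upstream", "downstream"}`.
#' @export
flank_assign <- function(intervals, genes) {
  rows <- list()
  for (chr in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == chr, , drop = FALSE]
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(g) == 0L) next
    ir_iv <- as_iranges(iv); ir_g <- as_iranges(g)
    ov <- IRanges::findOverlaps(ir_iv, ir_g)
    if (length(ov))
      rows[[length(rows) + 1L]] <- data.frame(
        label = iv$label[S4Vectors::queryHits(ov)],
        gene_id = g$gene_id[S4Vectors::subjectHits(ov)],
        relation = "overlap", stringsAsFactors = FALSE)
    # nearest non-overlapping neighbour on each side; genes tied at the
    # same distance are all reported
    for (i in seq_len(nrow(iv))) {
      up <- which(g$end <= iv$start[i])
      if (length(up)) {
        best <- up[g$end[up] == max(g$end[up])]
        rows[[length(rows) + 1L]] <- data.frame(
          label = iv$label[i], gene_id = g$gene_id[best],
          relation = "upstream", stringsAsFactors = FALSE)
      }
      down <- which(g$start >= iv$end[i])
      if (length(down)) {
        best <- down[g$start[down] == min(g$start[down])]
        rows[[length(rows) + 1L]] <- data.frame(
          label = iv$label[i], gene_id = g$gene_id[best],
          relation = "downstream", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(label = character(), gene_id = character(),
                      relation = character()))
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$label, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag genes with a possible copy-number variant
#'
#' A gene is flagged when any relevant individual carries a copy number
#' different from 2.
#'
#' @param cn_table long-format data.frame (`gene_id`, `individual`,
#'   `copy_number`).
#' @param individuals optional subset of individuals to consider.
#' @return data.frame: `gene_id`, `has_cnv`.
#' @export
cnv_flag <- function(cn_table, individuals = NULL) {
  if (!is.null(individuals))
    cn_table <- cn_table[cn_table$individual %in% individuals, , drop = FALSE]
  flag <- tapply(cn_table$copy_number, cn_table$gene_id,
                 function(x) any(x != 2L))
  data.frame(gene_id = names(flag), has_cnv = unname(flag),
             stringsAsFactors = FALSE)
}

#' Flag genes overlapping swept regions
#'
#' A gene counts as swept when its interval overlaps any swept interval by
#' at least one base.
#'
#' @param genes gene annotation data.frame.
#' @param sweeps interval data.frame (`chrom`, `start`, `end`).
#' @return data.frame: `gene_id`, `in_sweep`.
#' @export
sweep_flag <- function(genes, sweeps) {
  flags <- logical(nrow(genes))
  for (chr in unique(genes$chrom)) {
    gi <- which(genes$chrom == chr)
    b <- sweeps[sweeps$chrom == chr, , drop = FALSE]
    if (nrow(b) == 0L) next
    flags[gi] <- IRanges::countOverlaps(as_iranges(genes[gi, , drop = FALSE]),
                                        as_iranges(b)) > 0L
  }
  data.frame(gene_id = genes$gene_id, in_sweep = flags,
             stringsAsFactors = FALSE)
}
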