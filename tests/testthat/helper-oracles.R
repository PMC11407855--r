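# Independent oracles and shared fixtures, deliberately kept naive: brute
# force, enumeration or closed form, never the code paths they check.

# Two-sided Fisher p by direct hypergeometric enumeration: sum the
# probabilities of all tables with the observed margins whose probability
# does not exceed that of the observed table (relative tolerance 1e-7).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact upper tail of the gene-level MAF statistic for a single phased SNP:
# P(max(X, n - X)/n >= maf_obs) under beta-binomial(n, 1/2, rho).
oracle_single_snp_tail <- function(k, n, rho) {
  m <- max(k, n - k)
  ks <- 0:n
  keep <- pmax(ks, n - ks) >= m
  sum(crossASE::dbetabinom(ks[keep], n, 0.5, rho))
}

# Minimum-change parsimony by exhaustive enumeration over all internal
# labelings; returns the minimal change count and the oldest (root-most)
# age class achievable by any minimum-change labelling.
oracle_parsimony_age <- function(tree, tip_states, focal) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  root <- n_tip + 1L
  path <- ape::nodepath(tree, root, match(focal, tree$tip.label))
  states <- c(tip_states[tree$tip.label], rep(NA_integer_, n_int))
  best_cost <- Inf; best_age <- NA_integer_
  for (code in 0:(2^n_int - 1)) {
    lab <- as.integer(intToBits(code))[seq_len(n_int)]
    states[(n_tip + 1L):(n_tip + n_int)] <- lab
    cost <- sum(states[tree$edge[, 1]] != states[tree$edge[, 2]])
    age <- match(1L, states[path])
    if (cost < best_cost || (cost == best_cost && age < best_age)) {
      best_cost <- cost; best_age <- age
    }
  }
  list(min_changes = best_cost, age_class = best_age)
}

# Quadratic brute-force interval scans over 0-based half-open intervals.
oracle_overlap_count <- function(set_a, set_b) {
  hit <- logical(nrow(set_a))
  for (i in seq_len(nrow(set_a))) for (j in seq_len(nrow(set_b))) {
    if (set_a$chrom[i] == set_b$chrom[j] &&
        min(set_a$end[i], set_b$end[j]) >
        max(set_a$start[i], set_b$start[j])) hit[i] <- TRUE
  }
  sum(hit)
}

oracle_flank_assign <- function(intervals, genes) {
  rows <- list()
  for (i in seq_len(nrow(intervals))) {
    iv <- intervals[i, ]
    g <- genes[genes$chrom == iv$chrom, , drop = FALSE]
    if (!nrow(g)) next
    ovl <- pmin(iv$end, g$end) - pmax(iv$start, g$start) > 0
    for (gid in g$gene_id[ovl])
      rows[[length(rows) + 1L]] <- data.frame(label = iv$label, gene_id = gid,
                                              relation = "overlap")
    left <- g[!ovl & g$end <= iv$start, , drop = FALSE]
    if (nrow(left)) {
      for (best in left$gene_id[left$end == max(left$end)])
        rows[[length(rows) + 1L]] <- data.frame(label = iv$label,
                                                gene_id = best,
                                                relation = "upstream")
    }
    right <- g[!ovl & g$start >= iv$end, , drop = FALSE]
    if (nrow(right)) {
      for (best in right$gene_id[right$start == min(right$start)])
        rows[[length(rows) + 1L]] <- data.frame(label = iv$label,
                                                gene_id = best,
                                                relation = "downstream")
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

# Small shared cohort, built once per test run.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(
        simulate_cohort(sim_config(seed = 424, n_genes = 150)))
    cache
  }
})

make_gm <- function(chrom, pos, calls) {
  # calls: list individual -> integer vector coded 0 = hom ref, 1 = het,
  # 2 = hom alt, NA = missing
  a1 <- sapply(calls, function(x) ifelse(is.na(x), NA_integer_,
                                         ifelse(x == 2L, 1L, 0L)))
  a2 <- sapply(calls, function(x) ifelse(is.na(x), NA_integer_,
                                         ifelse(x >= 1L, 1L, 0L)))
  if (length(pos) == 1L) {
    a1 <- matrix(a1, 1L, dimnames = list(NULL, names(calls)))
    a2 <- matrix(a2, 1L, dimnames = list(NULL, names(calls)))
  }
  genotype_matrix(data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                             stringsAsFactors = FALSE), a1, a2)
}
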