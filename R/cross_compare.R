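# Combining gene-level ASE results across crosses: set intersections
# (UpSet-style), a permutation null for the all-cross overlap, direction
# tallies, and the "significant in >= k crosses" consistency list.

#' Bundle one cross's gene-level results into a result set
#'
#' @param results data.frame from [ase_gene_table()] (or [read_results()]).
#' @param alpha nominal FDR for calling a gene significant.
#' @return list of class `cross_result_set` with `cross_id`, `detectable`
#'   (genes with SNPs and sufficient counts), `significant`
#'   (`q_ase <= alpha`), `direction` (named, significant genes only) and
#'   the full `results` table.
#' @export
cross_result_set <- function(results, alpha = 0.05) {
  sig <- results$gene_id[!is.na(results$q_ase) & results$q_ase <= alpha]
  structure(list(cross_id = results$cross_id[1],
                 detectable = results$gene_id,
                 significant = sig,
                 direction = stats::setNames(
                   results$direction[match(sig, results$gene_id)], sig),
                 alpha = alpha,
                 results = results),
            class = "cross_result_set")
}

#' Exclusive intersection counts of ASE gene sets (UpSet-style)
#'
#' Counts, for every non-empty combination of crosses, the genes significant
#' in exactly that combination. The plain all-cross intersection is attached
#' as the attribute `all_cross` (and returned by [consistency_table()] at
#' `k` = number of crosses).
#'
#' @param result_sets list of [cross_result_set()] objects (2+).
#' @return data.frame with columns `combination` (cross ids joined by
#'   `"+"`), `n_crosses`, `count`, ordered by decreasing count; attribute
#'   `all_cross` holds the genes significant in every cross.
#' @export
intersect_ase <- function(result_sets) {
  if (length(result_sets) < 2L) stop("need at least 2 crosses")
  ids <- vapply(result_sets, function(s) s$cross_id, character(1))
  sigs <- lapply(result_sets, function(s) s$significant)
  genes <- unique(unlist(sigs))
  member <- vapply(sigs, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1L) member <- matrix(member, nrow = 1L)
  colnames(member) <- ids
  pattern <- apply(member, 1L, function(r) paste(ids[r], collapse = "+"))
  tab <- table(pattern)
  out <- data.frame(combination = names(tab),
                    n_crosses = lengths(strsplit(names(tab), "+", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$combination), ]
  rownames(out) <- NULL
  attr(out, "all_cross") <- Reduce(intersect, sigs)
  out
}

#' Permutation null for the all-cross ASE overlap
#'
#' Each permutation draws, for every cross, a uniform random subset of the
#' shared detectable-gene universe of the same size as that cross's
#' significant set (by default restricted to the universe), and records the
#' size of the all-cross overlap. The permutation p-value uses the add-one
#' estimator `(1 + #{null >= observed}) / (n_perm + 1)`, which can never be
#' zero. Under independent draws the expected overlap is
#' `N * prod(k_i / N)`.
#'
#' @param result_sets list of [cross_result_set()] objects, or a list of
#'   character vectors of significant genes.
#' @param universe character vector: genes detectable in all crosses.
#' @param n_perm number of permutations (study configuration: 100000).
#' @param seed integer seed.
#' @param restrict_to_universe if `TRUE` (default) draw sizes are the
#'   per-cross significant counts intersected with the universe; otherwise
#'   the full significant counts.
#' @return list of class `intersection_summary`: `observed`, `null`
#'   (integer vector of null overlaps), `null_max`, `p`, `expected`
#'   (closed-form expectation), `draw_sizes`, `mode`.
#' @export
permute_intersection <- function(result_sets, universe, n_perm = 100000L,
                                 seed = 1L, restrict_to_universe = TRUE) {
  sigs <- lapply(result_sets, function(s)
    if (inherits(s, "cross_result_set")) s$significant else s)
  N <- length(universe)
  k <- vapply(sigs, function(s)
    if (restrict_to_universe) sum(s %in% universe) else length(s), integer(1))
  if (any(k > N)) stop("draw size exceeds universe size")
  observed <- length(Reduce(intersect, c(sigs, list(universe))))
  n_cross <- length(sigs)
  null <- integer(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      hits <- integer(N)
      for (j in seq_len(n_cross)) {
        idx <- sample.int(N, k[j])
        hits[idx] <- hits[idx] + 1L
      }
      null[b] <- sum(hits == n_cross)
    }
  })
  structure(list(observed = observed, null = null, null_max = max(null),
                 p = (1 + sum(null >= observed)) / (n_perm + 1),
                 expected = N * prod(k / N), draw_sizes = k,
                 mode = if (restrict_to_universe) "universe-restricted"
                        else "full-set"),
            class = "intersection_summary")
}

#' @export
print.intersection_summary <- function(x, ...) {
  cat(sprintf(paste0("all-cross overlap: observed %d, null max %d, ",
                     "expected %.3f, p = %.3g (%s draws)\n"),
              x$observed, x$null_max, x$expected, x$p, x$mode))
  invisible(x)
}

#' Genes significant in at least k crosses
#'
#' @param result_sets list of [cross_result_set()] objects.
#' @param k minimum number of crosses a gene must be significant in
#'   (study configuration: 4 of 6).
#' @param alpha nominal FDR for the per-cross heterogeneity flag.
#' @return data.frame per retained gene: `gene_id`, `n_significant`,
#'   `n_detectable`, `n_maternal`, `n_paternal` (direction calls among
#'   significant phased crosses) and `any_het` (significant heterogeneity
#'   in any cross where the gene is significant).
#' @export
consistency_table <- function(result_sets, k = 4L, alpha = 0.05) {
  if (k > length(result_sets)) stop("'k' exceeds the number of crosses")
  all_res <- do.call(rbind, lapply(result_sets, function(s) {
    r <- s$results
    r$significant <- r$gene_id %in% s$significant
    r
  }))
  by_gene <- split(all_res, all_res$gene_id)
  rows <- lapply(by_gene, function(d) {
    sig <- d[d$significant, , drop = FALSE]
    data.frame(gene_id = d$gene_id[1],
               n_significant = nrow(sig),
               n_detectable = nrow(d),
               n_maternal = sum(sig$direction == "maternal"),
               n_paternal = sum(sig$direction == "paternal"),
               any_het = any(!is.na(sig$q_het) & sig$q_het <= alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_significant >= k, , drop = FALSE]
  out <- out[order(-out$n_significant, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene maternal/paternal direction tallies across phased crosses
#'
#' Unphased crosses carry no direction information and contribute nothing.
#'
#' @param result_sets list of [cross_result_set()] objects.
#' @return data.frame: `gene_id`, `n_maternal`, `n_paternal` over crosses
#'   where the gene is significant and phase is known.
#' @export
direction_summary <- function(result_sets) {
  rows <- do.call(rbind, lapply(result_sets, function(s) {
    d <- s$direction[s$direction %in% c("maternal", "paternal")]
    if (!length(d)) return(NULL)
    data.frame(gene_id = names(d), direction = unname(d),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    return(data.frame(gene_id = character(), n_maternal = integer(),
                      n_paternal = integer()))
  by_gene <- split(rows$direction, rows$gene_id)
  out <- data.frame(gene_id = names(by_gene),
                    n_maternal = vapply(by_gene, function(d)
                      sum(d == "maternal"), integer(1)),
                    n_paternal = vapply(by_gene, function(d)
                      sum(d == "paternal"), integer(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
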