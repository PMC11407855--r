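fake_set <- function(id, detectable, significant,
                     direction = rep("maternal", length(significant))) {
  res <- data.frame(cross_id = id, gene_id = detectable,
                    n_snps = 1L, maf = 0.6, maternal_fraction = 0.6,
                    p_ase = ifelse(detectable %in% significant, 0.001, 0.9),
                    p_het = NA_real_,
                    q_ase = ifelse(detectable %in% significant, 0.01, 0.9),
                    q_het = NA_real_, direction = "unknown",
                    stringsAsFactors = FALSE)
  res$direction[match(significant, res$gene_id)] <- direction
  cross_result_set(res)
}

genes <- sprintf("g%02d", 1:40)

test_that("exclusive intersection counts match brute-force set algebra", {
  withr::with_seed(14, {
    for (rep in 1:5) {
      sets <- lapply(1:4, function(i)
        fake_set(paste0("c", i), genes, sample(genes, sample(3:12, 1))))
      out <- intersect_ase(sets)
      sigs <- lapply(sets, function(s) s$significant)
      names(sigs) <- vapply(sets, function(s) s$cross_id, "")
      # brute force: every gene's membership pattern
      pat <- vapply(unique(unlist(sigs)), function(g)
        paste(names(sigs)[vapply(sigs, function(s) g %in% s, TRUE)],
              collapse = "+"), "")
      brute <- table(pat)
      expect_equal(sum(out$count), length(unique(unlist(sigs))))
      for (cmb in out$combination)
        expect_equal(out$count[out$combination == cmb],
                     as.integer(brute[cmb]))
      expect_setequal(attr(out, "all_cross"), Reduce(intersect, sigs))
      # invariance to cross ordering
      out2 <- intersect_ase(rev(sets))
      expect_equal(sum(out2$count), sum(out$count))
      expect_setequal(attr(out2, "all_cross"), attr(out, "all_cross"))
    }
  })
  # disjoint sets: no multi-cross combinations
  dis <- list(fake_set("a", genes, genes[1:3]), fake_set("b", genes, genes[4:6]))
  od <- intersect_ase(dis)
  expect_true(all(od$n_crosses == 1L))
  expect_length(attr(od, "all_cross"), 0L)
  # identical sets of size s: all-cross overlap s
  idn <- list(fake_set("a", genes, genes[1:7]), fake_set("b", genes, genes[1:7]))
  expect_length(attr(intersect_ase(idn), "all_cross"), 7L)
})

test_that("permutation null matches its closed-form expectation", {
  sets <- list(fake_set("a", genes, genes[1:5]),
               fake_set("b", genes, genes[3:9]))
  universe <- sprintf("u%03d", 1:100)
  ps <- permute_intersection(list(sprintf("u%03d", 1:50),
                                  sprintf("u%03d", 26:75)),
                             universe, n_perm = 3000L, seed = 6)
  # E[overlap] = N * (k1/N)(k2/N) = 100 * 0.25 = 25
  expect_equal(ps$expected, 25)
  null_se <- stats::sd(ps$null) / sqrt(length(ps$null))
  expect_lt(abs(mean(ps$null) - 25), 3 * null_se)
  # degenerate draws: whole universe every time -> p = 1
  full <- permute_intersection(list(universe, universe), universe,
                               n_perm = 50L, seed = 1)
  expect_true(all(full$null == 100L))
  expect_equal(full$p, 1)
  expect_error(permute_intersection(list(universe), universe[1:10],
                                    n_perm = 10L, seed = 1,
                                    restrict_to_universe = FALSE),
               "exceeds")
  # add-one estimator can never be zero
  expect_gt(ps$p, 0)
})

test_that("consistency table thresholds and direction tallies work", {
  sets <- lapply(1:6, function(i)
    fake_set(paste0("c", i), genes,
             if (i <= 4) c("g01", "g02") else "g02",
             direction = if (i <= 4) c("maternal", "paternal")
                         else "paternal"))
  k4 <- consistency_table(sets, k = 4)
  expect_setequal(k4$gene_id, c("g01", "g02"))
  k5 <- consistency_table(sets, k = 5)
  expect_equal(k5$gene_id, "g02")
  expect_error(consistency_table(sets, k = 7), "exceeds")
  # k = 1 is the union; k = n equals the all-cross intersection
  k1 <- consistency_table(sets, k = 1)
  expect_setequal(k1$gene_id, c("g01", "g02"))
  k6 <- consistency_table(sets, k = 6)
  expect_setequal(k6$gene_id, attr(intersect_ase(sets), "all_cross"))
  ds <- direction_summary(sets)
  expect_equal(ds$n_maternal[ds$gene_id == "g01"], 4L)
  expect_equal(ds$n_paternal[ds$gene_id == "g02"], 6L)
  # unphased crosses (direction unknown) contribute nothing
  unph <- fake_set("u", genes, "g03", direction = "unknown")
  expect_false("g03" %in% direction_summary(list(unph))$gene_id)
})

test_that("planted ASE genes dominate the consistency list", {
  co <- small_cohort()
  nm <- null_model(n_sims = 2000, seed = 10)
  sets <- lapply(seq_len(nrow(co$crosses)), function(i)
    cross_result_set(suppressMessages(ase_gene_table(
      co$counts[[i]], nm, phased = co$crosses$phased[i]))))
  consist <- consistency_table(sets, k = 4)
  truth <- co$truth
  planted <- truth$gene_id[truth$is_ase]
  precision <- mean(consist$gene_id %in% planted)
  expect_gt(precision, 0.8)
  expect_gt(nrow(consist), 0)
  # maternal-planted genes tally maternal in phased crosses
  ds <- direction_summary(sets)
  mat_genes <- truth$gene_id[truth$is_ase & truth$direction == "maternal"]
  sub <- ds[ds$gene_id %in% intersect(mat_genes, consist$gene_id), ]
  if (nrow(sub) > 0)
    expect_gt(sum(sub$n_maternal), sum(sub$n_paternal))
})
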