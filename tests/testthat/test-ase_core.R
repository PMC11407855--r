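test_that("beta-binomial pmf normalises, is symmetric, and has the binomial limit", {
  # normalisation at the study overdispersion
  expect_equal(sum(dbetabinom(0:50, 50, 0.5, 0.038)), 1, tolerance = 1e-12)
  # symmetry around n/2 when mu = 1/2
  expect_equal(dbetabinom(0:20, 20, 0.5, 0.1),
               dbetabinom(20:0, 20, 0.5, 0.1), tolerance = 1e-12)
  # rho -> 0 converges to the binomial
  expect_lt(max(abs(dbetabinom(0:20, 20, 0.5, 1e-9) -
                    dbinom(0:20, 20, 0.5))), 1e-6)
  expect_equal(dbetabinom(3, 10, 0.3, 0), dbinom(3, 10, 0.3))
  expect_error(dbetabinom(5, 10, 1.2, 0.1), "mu")
  expect_error(dbetabinom(11, 10, 0.5, 0.1), "k")
})

test_that("SNP depth filter retains >= 10 total reads", {
  counts <- data.frame(count_a = c(6, 5, 0), count_b = c(3, 5, 0))
  expect_message(out <- filter_snps(counts), "2 SNP")
  expect_equal(nrow(out), 1L)
  expect_equal(out$count_a, 5)       # (6,3) removed at 9 reads, (5,5) kept
  expect_equal(nrow(filter_snps(counts[0, ])), 0L)
})

test_that("pseudo-phasing combines the higher-count alleles", {
  pp <- pseudo_phase(c(8, 3), c(2, 7))
  expect_equal(pp$major, c(8, 7))
  expect_equal(pp$maf, 15 / 20)
  expect_equal(pseudo_phase(5, 5)$maf, 0.5)
  withr::with_seed(21, {
    for (i in 1:20) {
      a <- rpois(4, 6) + 1L; b <- rpois(4, 6) + 1L
      expect_gte(pseudo_phase(a, b)$maf, 0.5)
    }
  })
  expect_error(pseudo_phase(c(0), c(0)), "zero-total")
})

test_that("single-SNP Monte-Carlo p-values match the closed-form beta-binomial tail", {
  nm <- function(rho) null_model(rho = rho, n_sims = 2e4, seed = 42)
  for (case in list(c(9, 10), c(40, 50), c(100, 100))) {
    k <- case[1]; n <- case[2]
    for (rho in c(0, 0.038)) {
      res <- gene_ase_test(data.frame(count_a = k, count_b = n - k),
                           nm(rho), phased = TRUE)
      exact <- oracle_single_snp_tail(k, n, rho)
      mc_se <- sqrt(exact * (1 - exact) / 2e4)
      expect_lt(abs(res$p_ase - exact), 3 * mc_se + 1e-9)
    }
  }
})

test_that("a balanced single SNP gives MAF 0.5 and p = 1", {
  res <- gene_ase_test(data.frame(count_a = 5, count_b = 5),
                       null_model(n_sims = 500, seed = 1), phased = TRUE)
  expect_equal(res$maf, 0.5)
  expect_equal(res$p_ase, 1)
  expect_true(is.na(res$p_het))
  expect_equal(res$direction, "unknown")
})

test_that("p_ase decreases as the observed MAF grows at fixed totals", {
  nm <- null_model(n_sims = 5e3, seed = 7)
  ks <- c(55, 65, 75, 90)
  ps <- vapply(ks, function(k)
    gene_ase_test(data.frame(count_a = k, count_b = 100 - k), nm,
                  phased = TRUE, seed = 7)$p_ase, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("heterogeneity p-value flags inconsistent per-SNP imbalance", {
  nm <- null_model(rho = 0.038, n_sims = 1e4, seed = 5)
  # identical fractions -> Q = 0 -> p_het = 1
  res <- gene_ase_test(data.frame(count_a = c(30, 30), count_b = c(10, 10)),
                       nm, phased = TRUE)
  expect_equal(res$p_het, 1)
  # opposite extreme SNPs -> enormous Q
  res2 <- gene_ase_test(data.frame(count_a = c(50, 0), count_b = c(0, 50)),
                        nm, phased = TRUE)
  expect_lt(res2$p_het, 0.01)
  # always a probability
  withr::with_seed(9, {
    for (i in 1:5) {
      d <- data.frame(count_a = rpois(3, 20) + 1, count_b = rpois(3, 20) + 1)
      r <- gene_ase_test(d, null_model(n_sims = 300, seed = i))
      expect_true(r$p_het >= 0 && r$p_het <= 1)
    }
  })
})

test_that("BH correction matches the step-up formula", {
  out <- bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05))
  expect_equal(out$q, rep(0.05, 5))          # min_{j>=i} p_(j) m / j
  expect_true(all(out$significant))
  expect_equal(bh_fdr(0.73)$q, 0.73)
  all1 <- bh_fdr(rep(1, 4))
  expect_true(all(all1$q == 1) && !any(all1$significant))
  expect_equal(nrow(bh_fdr(numeric())), 0L)
  # q-values are monotone in p-rank
  withr::with_seed(2, {
    p <- runif(50)
    q <- bh_fdr(p)$q
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  })
})

test_that("overdispersion estimation recovers the simulating rho", {
  withr::with_seed(31, {
    n <- pmax(10L, rnbinom(5000, mu = 100, size = 10))
    k <- rbetabinom(5000, n, 0.5, 0.1)
    fit <- estimate_overdispersion(data.frame(count_a = k, count_b = n - k))
    expect_true(fit$rho_hat > 0.08 && fit$rho_hat < 0.12)
    expect_gte(fit$loglik_betabinom, fit$loglik_binom)
    # binomial data: rho_hat collapses toward zero
    k0 <- rbinom(5000, n, 0.5)
    fit0 <- estimate_overdispersion(data.frame(count_a = k0, count_b = n - k0))
    expect_lt(fit0$rho_hat, 0.005)
  })
})

test_that("a default null model carries the study configuration", {
  nm <- null_model()
  expect_equal(nm$rho, 0.038)
  expect_equal(nm$n_sims, 1000000L)
  expect_error(null_model(rho = 1.2), "rho")
})

test_that("gene tables are reproducible and independent of gene order", {
  co <- small_cohort()
  counts <- co$counts[[4]]
  nm <- null_model(n_sims = 500, seed = 17)
  r1 <- suppressMessages(ase_gene_table(counts, nm, phased = TRUE))
  r2 <- suppressMessages(ase_gene_table(counts, nm, phased = TRUE))
  expect_identical(r1, r2)
  shuffled <- counts[rev(seq_len(nrow(counts))), ]
  r3 <- suppressMessages(ase_gene_table(shuffled, nm, phased = TRUE))
  r3 <- r3[match(r1$gene_id, r3$gene_id), ]
  expect_equal(r1$p_ase, r3$p_ase)
  expect_equal(r1$maf, r3$maf)
})
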