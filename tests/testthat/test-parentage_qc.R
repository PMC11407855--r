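# Brute-force gamete enumeration for a single genotype triple, coded as
# 0/1/2 alt dosage.
enumerate_triple <- function(m, f, k) {
  alleles <- function(g) switch(g + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
  for (gm in alleles(m)) for (gf in alleles(f))
    if (identical(sort(c(gm, gf)), sort(alleles(k)))) return("consistent")
  "error"
}

test_that("Mendelian triple classification matches gamete enumeration on all 27 triples", {
  to_call <- function(g) switch(g + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
  for (m in 0:2) for (f in 0:2) for (k in 0:2) {
    got <- mendelian_error_rate(to_call(m), to_call(f), to_call(k))
    expect_equal(got, enumerate_triple(m, f, k),
                 info = sprintf("m=%d f=%d k=%d", m, f, k))
  }
  # forced cases: hom x hom parents
  expect_equal(mendelian_error_rate(c(0L, 0L), c(0L, 0L), c(0L, 1L)), "error")
  expect_equal(mendelian_error_rate(c(0L, 0L), c(1L, 1L), c(0L, 1L)),
               "consistent")
  # any missing call is uninformative
  expect_equal(mendelian_error_rate(c(0L, 0L), c(NA, NA), c(0L, 1L)),
               "uninformative")
})

test_that("father matching recovers the planted father and rejects strangers", {
  co <- small_cohort()
  cr <- co$crosses[3, ]  # phased cross with genotyped parents
  mother <- gm_subset(co$parents$gm, individuals = cr$mother)
  candidates <- gm_subset(co$parents$gm,
                          individuals = co$parents$roles$individual[
                            co$parents$roles$colony ==
                              co$parents$roles$colony[
                                co$parents$roles$individual == cr$father]])
  progeny <- co$sib_gms[[cr$cross_id]]
  fit <- match_father(mother, candidates, progeny)
  expect_equal(fit$father, cr$father)
  best <- fit$summary$median_error[fit$summary$candidate == cr$father]
  expect_lt(best, 0.01)
  # candidates unrelated to the cross (the mother's own colony) at a strict
  # threshold: no match
  unrelated <- gm_subset(co$parents$gm,
                         individuals = setdiff(
                           co$parents$roles$individual[
                             co$parents$roles$colony != co$parents$roles$colony[
                               co$parents$roles$individual == cr$father]],
                           cr$mother))
  fit2 <- match_father(mother, unrelated, progeny, max_error = 0.02)
  expect_true(is.na(fit2$father))
  # a single candidate who is the true father is returned
  solo <- match_father(mother, gm_subset(co$parents$gm,
                                         individuals = cr$father), progeny)
  expect_equal(solo$father, cr$father)
})

test_that("sibling-inferred SNPs are the autosomal parental homozygous differences", {
  all_ab <- make_gm(c("2L", "2L", "X"), c(10L, 20L, 30L),
                    list(s1 = c(1L, 1L, 1L), s2 = c(1L, 0L, 1L)))
  inf <- infer_sibling_snps(all_ab)
  # site 1: all sibs het -> informative; site 2: one hom sib -> excluded;
  # site 3: X -> excluded
  expect_equal(inf$site, 1L)
  expect_false(any(inf$phase_known))

  co <- small_cohort()
  cr <- co$crosses[1, ]  # unphased cross
  inf2 <- infer_sibling_snps(co$sib_gms[[cr$cross_id]], min_calls = 2L)
  gm <- co$parents$gm_true
  m <- gm$a1[, cr$mother]; m2 <- gm$a2[, cr$mother]
  f <- gm$a1[, cr$father]; f2 <- gm$a2[, cr$father]
  autosomal <- gm$sites$chrom %in% c("2L", "2R", "3L", "3R")
  hom_diff <- which(m == m2 & f == f2 & m != f & autosomal)
  # every informative call must come from a true homozygous difference, up
  # to leakage from parent pairs that can produce an all-het sibship
  # (het x het and hom x het), each passing the screen with probability
  # (1/2)^n_called; the expected leaked fraction follows from the
  # generator densities
  cfg <- co$config
  q <- cfg$het_freq
  p_het <- 2 * q * (1 - q)
  p_hom <- q^2 + (1 - q)^2
  d_seg <- (1 - cfg$colony_div) * cfg$het_rate
  d_leaky <- d_seg * (p_het^2 + 2 * p_hom * p_het)
  d_inf <- cfg$colony_div + d_seg * 2 * q^2 * (1 - q)^2
  pass <- ((1 + cfg$missing_rate) / 2)^cfg$n_sibs
  exp_leak <- d_leaky * pass / (d_inf + d_leaky * pass)
  leak <- setdiff(inf2$site, hom_diff)
  expect_lt(length(leak) / max(1L, length(inf2$site)), 2 * exp_leak)
  # recall is bounded only by missingness-induced dropout
  expect_gt(length(intersect(inf2$site, hom_diff)) / length(hom_diff), 0.95)
})

test_that("het x het leakage rate matches its binomial expectation", {
  # parents both het: each sib is het with probability 1/2, so a site
  # passes the all-het screen with probability (1/2)^n_sibs
  withr::with_seed(77, {
    n_sites <- 4000L; n_sibs <- 6L
    sib_calls <- lapply(seq_len(n_sibs), function(i)
      rbinom(n_sites, 2L, 0.5))
    names(sib_calls) <- paste0("s", seq_len(n_sibs))
    gm <- make_gm(rep("2L", n_sites), seq_len(n_sites), sib_calls)
    inf <- infer_sibling_snps(gm)
    expected <- n_sites * 0.5^n_sibs
    se <- sqrt(n_sites * 0.5^n_sibs * (1 - 0.5^n_sibs))
    expect_lt(abs(nrow(inf) - expected), 3 * se + 1e-9)
  })
})

test_that("colony consensus difference counts recover planted fixed differences", {
  # identical colonies: zero everywhere
  a <- make_gm(c("2L", "3R"), c(5L, 6L), list(i1 = c(0L, 2L), i2 = c(0L, 2L)))
  expect_equal(unname(consensus_diff_counts(a, a)["total"]), 0L)
  # one planted difference on 2L
  b <- make_gm(c("2L", "3R"), c(5L, 6L), list(j1 = c(2L, 2L), j2 = c(2L, 2L)))
  cd <- consensus_diff_counts(a, b)
  expect_equal(unname(cd["2L"]), 1L)
  expect_equal(unname(cd["total"]), 1L)
  # synthetic colonies: exact recovery of the planting list, and the total
  # equals the per-arm sum
  co <- small_cohort()
  roles <- co$parents$roles
  gm_n <- gm_subset(co$parents$gm,
                    individuals = roles$individual[roles$colony == "N"])
  gm_k <- gm_subset(co$parents$gm,
                    individuals = roles$individual[roles$colony == "K"])
  cd2 <- consensus_diff_counts(gm_n, gm_k)
  expect_equal(unname(cd2["total"]), sum(co$parents$fixed_diff))
  expect_equal(unname(cd2["total"]),
               sum(cd2[c("2L", "2R", "3L", "3R", "X", "other")]))
})

test_that("colony_div = 0 yields no fixed differences", {
  cfg <- sim_config(seed = 5, n_genes = 60, colony_div = 0)
  p <- simulate_parents(cfg)
  expect_equal(sum(p$fixed_diff), 0L)
  roles <- p$roles
  cd <- consensus_diff_counts(
    gm_subset(p$gm, individuals = roles$individual[roles$colony == "N"]),
    gm_subset(p$gm, individuals = roles$individual[roles$colony == "K"]))
  expect_equal(unname(cd["total"]), 0L)
})

test_that("swap diagnostic summarises per-SNP imbalance", {
  even <- data.frame(count_a = rep(5, 4), count_b = rep(5, 4))
  d <- mismatch_diagnostic(even)
  expect_equal(d$mean_fraction, 0.5)
  expect_equal(d$mean_deviation, 0)
  one <- mismatch_diagnostic(data.frame(count_a = 9, count_b = 1))
  expect_equal(one$mean_fraction, 0.9)
  suppressMessages(
    expect_error(mismatch_diagnostic(data.frame(count_a = 1, count_b = 1)),
                 "no SNPs"))
})

test_that("mapping-rate and power arithmetic behave", {
  s <- summarize_mapping(c(4.5, 5.5))
  expect_equal(s$mean, 5)
  expect_equal(summarize_mapping(c(3, 3, 3))$sd, 0)
  expect_error(summarize_mapping(5), "at least 2")
  expect_equal(reads_for_power(0, 500), 0)
  expect_equal(reads_for_power(1, 500), 500)
  expect_equal(percent_relative_increase(50, 75), 50)
  expect_equal(percent_relative_increase(4, 4), 0)
  expect_error(percent_relative_increase(0, 5), "positive")
})
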