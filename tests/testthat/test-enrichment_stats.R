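test_that("Fisher test reports the sample odds ratio on the study tables", {
  cnv <- fisher_exact_2x2(60, 54, 481, 852)
  expect_equal(round(cnv$odds_ratio, 1), 2.0)
  sweep <- fisher_exact_2x2(13, 102, 103, 1230)
  expect_equal(round(sweep$odds_ratio, 1), 1.5)
  small <- fisher_exact_2x2(2, 1, 1, 2)
  expect_equal(small$odds_ratio, 4)
  expect_equal(small$p_value, 1)
  expect_equal(fisher_exact_2x2(3, 0, 1, 5)$odds_ratio, Inf)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher p matches hypergeometric enumeration; transposition invariance", {
  withr::with_seed(8, {
    for (i in 1:200) {
      tab <- rpois(4, sample(1:8, 1))
      got <- fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4])
      expect_equal(got$p_value,
                   oracle_fisher_p(tab[1], tab[2], tab[3], tab[4]),
                   tolerance = 1e-7)
      tr <- fisher_exact_2x2(tab[1], tab[3], tab[2], tab[4])
      expect_equal(tr$p_value, got$p_value, tolerance = 1e-12)
      if (is.finite(got$odds_ratio) && got$odds_ratio > 0)
        expect_equal(tr$odds_ratio, got$odds_ratio, tolerance = 1e-12)
      expect_true(got$p_value > 0 && got$p_value <= 1)
    }
  })
})

test_that("Wagner parsimony ages match brute-force enumeration", {
  trees <- list(
    ape::read.tree(text = "(((((((t1,t2),t3),t4),t5),t6),t7),t8);"),
    ape::read.tree(text = "(((t1,t2),(t3,t4)),((t5,t6),(t7,t8)));"),
    ape::read.tree(text = "((((t1,t2),t3),(t4,t5)),t6);"))
  withr::with_seed(19, {
    for (tree in trees) {
      tips <- tree$tip.label
      # focal tip present; sweep random patterns plus the two extremes
      pats <- rbind(matrix(rbinom(40 * length(tips), 1, 0.5), ncol = length(tips)),
                    rep(1L, length(tips)),
                    c(1L, rep(0L, length(tips) - 1L)))
      pats[, 1] <- 1L
      colnames(pats) <- tips
      rownames(pats) <- sprintf("gene%02d", seq_len(nrow(pats)))
      got <- age_assign(pats, tree, focal = "t1")
      for (i in seq_len(nrow(pats))) {
        oracle <- oracle_parsimony_age(tree, pats[i, ], "t1")
        expect_equal(got$min_changes[i], oracle$min_changes,
                     info = paste(tree$Nnode, i))
        expect_equal(got$age_class[i], oracle$age_class,
                     info = paste(tree$Nnode, i))
      }
    }
  })
  # extremes: focal-only gene is youngest; ubiquitous gene is root class
  tree <- trees[[1]]
  only <- matrix(c(1L, rep(0L, 7)), 1, dimnames = list("g", tree$tip.label))
  expect_equal(age_assign(only, tree, "t1")$age_class, 8L)
  all8 <- matrix(1L, 1, 8, dimnames = list("g", tree$tip.label))
  expect_equal(age_assign(all8, tree, "t1")$age_class, 1L)
  absent <- matrix(c(0L, rep(1L, 7)), 1, dimnames = list("g", tree$tip.label))
  expect_error(age_assign(absent, tree, "t1"), "absent from focal")
})

test_that("age assignment agrees with phangorn's parsimony score", {
  skip_if_not_installed("phangorn")
  tree <- ape::read.tree(text = "(((t1,t2),(t3,t4)),(t5,t6));")
  withr::with_seed(3, {
    pats <- matrix(rbinom(20 * 6, 1, 0.5), ncol = 6,
                   dimnames = list(sprintf("g%02d", 1:20), tree$tip.label))
    pats[, 1] <- 1L
    got <- age_assign(pats, tree, "t1")
    scores <- vapply(seq_len(nrow(pats)), function(i) {
      pd <- phangorn::phyDat(t(pats[i, , drop = FALSE]) + 1L, type = "USER",
                             levels = 1:2)
      as.integer(phangorn::parsimony(tree, pd))
    }, integer(1))
    expect_equal(got$min_changes, scores)
  })
})

test_that("age-class enrichment finds a planted young-gene excess", {
  cfg <- sim_config(seed = 60, n_genes = 800, young_ase_boost = 6)
  co <- suppressMessages(simulate_cohort(cfg))
  ages <- age_assign(co$presence, co$tree_newick, "t1")
  ase <- co$truth$gene_id[co$truth$is_ase]
  non <- co$truth$gene_id[!co$truth$is_ase]
  enr <- age_enrichment(ase, non, ages)
  young <- enr[enr$age_class == max(enr$age_class), ]
  expect_lt(young$p_value, 0.05)
  expect_gt(young$odds_ratio, 1)
  # identical distributions: p near 1 everywhere
  both <- sample(co$truth$gene_id, 400)
  null_enr <- age_enrichment(both[1:200], both[1:200], ages)
  expect_true(all(null_enr$p_value[!is.na(null_enr$p_value)] > 0.9))
  # ages recovered by parsimony equal the planted classes
  expect_equal(stats::setNames(ages$age_class, ages$gene_id)[co$truth$gene_id],
               stats::setNames(co$truth$age_class, co$truth$gene_id))
})

test_that("arm ANOVA decomposes variance and detects a planted arm effect", {
  grid <- expand.grid(arm = c("2L", "2R", "3L", "3R"),
                      cross = paste0("c", 1:6), stringsAsFactors = FALSE)
  # flat table: F = 0, p = 1
  grid$proportion <- 0.1
  flat <- arm_anova(grid)
  expect_equal(flat$F[1:2], c(0, 0))
  expect_equal(flat$p[1:2], c(1, 1))
  # planted arm effect
  withr::with_seed(4, {
    grid$proportion <- 0.1 + 0.2 * (grid$arm == "2R") + rnorm(24, 0, 0.01)
  })
  fit <- arm_anova(grid)
  expect_lt(fit$p[fit$term == "arm"], 0.01)
  # decomposition identity
  expect_equal(sum(fit$sum_sq), attr(fit, "ss_total"), tolerance = 1e-9)
  # agreement with aov on the balanced grid
  av <- summary(stats::aov(proportion ~ arm + cross, data = grid))[[1]]
  expect_equal(fit$F[1], av["arm", "F value"], tolerance = 1e-8)
  expect_equal(fit$p[2], av["cross", "Pr(>F)"], tolerance = 1e-8)
  expect_error(arm_anova(grid[-1, ]), "complete")
})

test_that("interval operations agree with quadratic brute force", {
  withr::with_seed(33, {
    for (rep in 1:8) {
      n_a <- sample(5:30, 1); n_g <- sample(5:40, 1)
      mk <- function(n, w, prefix) {
        st <- sample.int(5000, n)
        data.frame(chrom = sample(c("2L", "3R"), n, TRUE), start = st,
                   end = st + sample.int(w, n),
                   label = sprintf("%s%02d", prefix, 1:n),
                   stringsAsFactors = FALSE)
      }
      a <- mk(n_a, 300, "iv")
      g <- mk(n_g, 400, "g"); names(g)[4] <- "gene_id"
      expect_equal(overlap_count(a, g[, c("chrom", "start", "end")]),
                   oracle_overlap_count(a, g))
      expect_equal(flank_assign(a, g), oracle_flank_assign(a, g))
    }
  })
  # trivial geometry
  one_gene <- data.frame(chrom = "2L", start = 100L, end = 500L,
                         gene_id = "g1", stringsAsFactors = FALSE)
  inside <- data.frame(chrom = "2L", start = 200L, end = 250L, label = "iv1",
                       stringsAsFactors = FALSE)
  fa <- flank_assign(inside, one_gene)
  expect_true(any(fa$gene_id == "g1" & fa$relation == "overlap"))
  disjoint <- data.frame(chrom = "3L", start = 1L, end = 10L, label = "x",
                         stringsAsFactors = FALSE)
  expect_equal(overlap_count(disjoint, one_gene), 0L)
  expect_equal(overlap_count(one_gene[, 1:3], one_gene[, 1:3]), 1L)
})

test_that("CNV and sweep flags behave on planted data", {
  cn <- data.frame(gene_id = rep(c("g1", "g2"), each = 3),
                   individual = rep(c("i1", "i2", "i3"), 2),
                   copy_number = c(2L, 2L, 2L, 2L, 3L, 2L))
  fl <- cnv_flag(cn)
  expect_false(fl$has_cnv[fl$gene_id == "g1"])
  expect_true(fl$has_cnv[fl$gene_id == "g2"])
  # restricting to individuals without the variant clears the flag
  fl2 <- cnv_flag(cn, individuals = c("i1", "i3"))
  expect_false(fl2$has_cnv[fl2$gene_id == "g2"])
  genes <- data.frame(chrom = c("2L", "2L"), start = c(0L, 1000L),
                      end = c(500L, 1500L), gene_id = c("g1", "g2"),
                      stringsAsFactors = FALSE)
  sweeps <- data.frame(chrom = "2L", start = 400L, end = 600L, label = "s1",
                       stringsAsFactors = FALSE)
  sf <- sweep_flag(genes, sweeps)
  expect_equal(sf$in_sweep, c(TRUE, FALSE))
})

test_that("copy-number confounding inflates apparent ASE per cross", {
  # cohort with no true cis-regulation: only CNVs shift allelic fractions
  hits <- 0L
  for (seed in c(101, 202, 303)) {
    cfg <- sim_config(seed = seed, n_genes = 400, frac_ase = 0,
                      frac_cnv = 0.25)
    co <- suppressMessages(simulate_cohort(cfg))
    nm <- null_model(n_sims = 1000, seed = seed)
    has_cnv <- stats::setNames(cnv_flag(co$cn_table)$has_cnv,
                               cnv_flag(co$cn_table)$gene_id)
    a <- b <- c_ <- d <- 0L
    for (i in seq_len(nrow(co$crosses))) {
      res <- suppressMessages(ase_gene_table(co$counts[[i]], nm,
                                             phased = co$crosses$phased[i]))
      sig <- !is.na(res$q_ase) & res$q_ase <= 0.05
      cn <- has_cnv[res$gene_id]
      a <- a + sum(sig & cn); b <- b + sum(sig & !cn)
      c_ <- c_ + sum(!sig & cn); d <- d + sum(!sig & !cn)
    }
    or <- fisher_exact_2x2(a, b, c_, d)$odds_ratio  # Inf counts as > 1
    if (!is.nan(or) && or > 1) hits <- hits + 1L
  }
  expect_equal(hits, 3L)
})
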