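# Diet assignment, group summaries, non-parametric tests, phylo ANOVA.

test_that("diet assignment applies the leaf/hard-object/fruit rule", {
  expect_equal(assign_diet(55, "fruit", FALSE), "folivore")
  expect_equal(assign_diet(20, "fruit", TRUE), "hard_object")
  expect_equal(assign_diet(20, "fruit", FALSE), "frugivore")
  expect_error(assign_diet(20, "insects", FALSE), "unclassifiable")
  expect_error(assign_diet(120, "fruit", FALSE), "0, 100")

  # the reference sample's categories are reproduced from its components
  ref <- reference_sample()
  got <- assign_diet(ifelse(ref$primary_component == "leaves", 60, 20),
                     ref$primary_component, ref$hard_object)
  expect_equal(got, ref$diet_category)
})

test_that("weighted group means reconstruct the published group summaries", {
  rec <- reconstruct_group_means()
  ref <- reference_group_means()
  merged <- merge(rec, ref, by = c("group", "variable"))
  expect_equal(nrow(merged), 15L)
  # cells arithmetically consistent in the published table: reconstruction
  # agrees to the printed precision (half a printed unit)
  consistent <- list(
    c("folivore", "or_lower", 0.05), c("frugivore", "or_lower", 0.05),
    c("hard_object", "or_lower", 0.05),
    c("folivore", "rfi_upper", 0.005), c("frugivore", "rfi_upper", 0.005),
    c("hard_object", "rfi_upper", 0.005),
    c("folivore", "rfi_lower", 0.005), c("frugivore", "rfi_lower", 0.005),
    c("folivore", "sq_upper", 0.005), c("hard_object", "sq_upper", 0.005),
    c("hard_object", "sq_lower", 0.005))
  for (cell in consistent) {
    row <- merged[merged$group == cell[1] & merged$variable == cell[2], ]
    expect_lt(abs(row$weighted_mean - row$mean), as.numeric(cell[3]) + 1e-9)
  }
  # the four known-inconsistent published cells really are inconsistent
  inconsistent <- list(c("frugivore", "sq_upper"), c("folivore", "sq_lower"),
                       c("frugivore", "sq_lower"),
                       c("hard_object", "rfi_lower"))
  for (cell in inconsistent) {
    row <- merged[merged$group == cell[1] & merged$variable == cell[2], ]
    expect_gt(abs(row$weighted_mean - row$mean), 0.005)
  }
})

test_that("specific published weighted means are matched", {
  rec <- reconstruct_group_means()
  pick <- function(g, v) rec$weighted_mean[rec$group == g & rec$variable == v]
  expect_equal(pick("folivore", "sq_upper"), 34.54, tolerance = 0.005)
  expect_equal(pick("hard_object", "sq_lower"), -13.25, tolerance = 0.005)
  expect_equal(pick("hard_object", "sq_upper"), -12.25, tolerance = 0.005)
})

test_that("group summaries give t-based CIs and weighted means", {
  set.seed(5)
  x <- rnorm(30); g <- rep(c("a", "b", "c"), 10)
  gs <- group_summary(x, g)
  for (i in seq_len(nrow(gs))) {
    xi <- x[g == gs$group[i]]
    ci <- t.test(xi)$conf.int
    expect_equal(c(gs$ci_low[i], gs$ci_high[i]), as.numeric(ci),
                 tolerance = 1e-10)
    expect_true(gs$ci_low[i] <= gs$mean[i] && gs$mean[i] <= gs$ci_high[i])
  }
  one <- group_summary(5, "solo")
  expect_true(one$degenerate)
  expect_equal(one$mean, 5)

  w <- group_summary(c(1, 2, 4), c("a", "a", "b"), weights = c(1, 3, 2))
  expect_equal(w$mean[w$group == "a"], (1 + 6) / 4)
  expect_error(group_summary(1:3, c("a", "a", "b"), weights = c(1, -1, 2)),
               "positive integers")
})

test_that("Kruskal-Wallis H matches rank arithmetic and is rank-invariant", {
  r <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$statistic, 27 / 7, tolerance = 1e-6)   # 3.857 by hand
  expect_equal(r$p_value, pchisq(27 / 7, 1, lower.tail = FALSE),
               tolerance = 1e-9)

  set.seed(2)
  x <- rnorm(30); g <- rep(c("a", "b", "c"), each = 10)
  h1 <- kruskal_wallis(x, g)$statistic
  h2 <- kruskal_wallis(exp(2 * x) + 7, g)$statistic   # strictly monotone map
  expect_equal(h1, h2, tolerance = 1e-12)

  const <- kruskal_wallis(rep(1, 9), rep(c("a", "b", "c"), 3))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)
})

test_that("Kruskal-Wallis p-values are calibrated under the null", {
  set.seed(99)
  ps <- replicate(500, {
    kruskal_wallis(rnorm(30), sample(rep(c("a", "b", "c"), 10)))$p_value
  })
  # rank-based p-values are mildly discrete; the KS check is approximate
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pairwise Wilcoxon applies the Bonferroni criterion", {
  expect_equal(bonferroni_criterion(0.05, 3), 0.05 / 3)
  expect_equal(round(bonferroni_criterion(0.05, 3), 4), 0.0167)

  set.seed(11)
  x <- c(rnorm(8), rnorm(8, 4), rnorm(8, 8))
  g <- rep(c("a", "b", "c"), each = 8)
  pw <- pairwise_wilcoxon(x, g)
  expect_equal(nrow(pw), 3L)
  expect_equal(attr(pw, "criterion"), 0.05 / 3)
  expect_true(all(pw$exact))

  same <- pairwise_wilcoxon(c(1, 2, 3, 1.5, 2.5, 3.5),
                            rep(c("a", "b"), each = 3))
  expect_gt(same$p_value, 0.5)
})

test_that("small-sample Wilcoxon p equals exhaustive permutation", {
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(7, 0.5)
    pw <- pairwise_wilcoxon(c(x, y), rep(c("a", "b"), c(6, 7)))
    expect_true(pw$exact)
    expect_equal(pw$p_value, wilcox_perm_p(x, y), tolerance = 1e-10)
  }
})

test_that("phylogenetic ANOVA is calibrated and powered appropriately", {
  tr <- make_tree(15, seed = 4)
  null_ok <- 0L; power_ok <- 0L
  groups <- rep(c("a", "b", "c"), c(5, 5, 5))
  for (rep in 1:50) {
    y <- simulate_bm(tr, 1, seed = 5000 + rep)
    g <- with_seed_test(5100 + rep, sample(groups))
    names(g) <- names(y)
    p_null <- phylo_anova(y, g, tr, n_sim = 200, seed = 5200 + rep)$p_value
    if (p_null > 0.05) null_ok <- null_ok + 1L
    # strong group offsets: 5 within-group SDs
    ysd <- stats::sd(y)
    y_eff <- y + (as.numeric(factor(g)) - 2) * 5 * ysd
    p_eff <- phylo_anova(y_eff, g, tr, n_sim = 200, seed = 5300 + rep)$p_value
    if (p_eff <= 0.01) power_ok <- power_ok + 1L
  }
  expect_gte(null_ok, 45L)
  expect_gte(power_ok, 45L)

  # determinism under a fixed seed
  y <- simulate_bm(tr, 1, seed = 61)
  g <- setNames(rep(c("a", "b", "c"), 5), names(y))
  p1 <- phylo_anova(y, g, tr, n_sim = 300, seed = 7)$p_value
  p2 <- phylo_anova(y, g, tr, n_sim = 300, seed = 7)$p_value
  expect_identical(p1, p2)

  expect_error(phylo_anova(setNames(rep(1, 15), tr$tip.label), g, tr,
                           n_sim = 200, seed = 1), "constant")
})

test_that("phylogenetic ANOVA agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- make_tree(12, seed = 19)
  y <- simulate_bm(tr, 1, seed = 20)
  g <- setNames(rep(c("a", "b", "c"), each = 4), names(y))
  mine <- phylo_anova(y, g, tr, n_sim = 1000, seed = 3)
  theirs <- phytools::phylANOVA(tr, factor(g), y, nsim = 1000,
                                posthoc = FALSE)
  expect_equal(mine$statistic, theirs$F, tolerance = 1e-8)
  expect_lt(abs(mine$p_value - theirs$Pf), 0.1)
})
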