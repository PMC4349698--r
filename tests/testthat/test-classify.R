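# Equal-prior LDA, leave-one-out cross-validation, canonical scores.

# three 2-D Gaussian clouds with controllable separation
make_clouds <- function(n_per = 12, sep = 5, seed = 1, sd = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  X <- do.call(rbind, lapply(1:3, function(g) {
    cbind(rnorm(n_per, centers[g, 1], sd), rnorm(n_per, centers[g, 2], sd))
  }))
  colnames(X) <- c("f1", "f2")
  list(X = X, labels = rep(c("folivore", "frugivore", "hard_object"),
                           each = n_per))
}

test_that("two-cloud LDA boundary is the perpendicular bisector", {
  set.seed(3)
  X <- rbind(cbind(rnorm(20, -3), rnorm(20, 0)),
             cbind(rnorm(20, 3), rnorm(20, 0)))
  colnames(X) <- c("f1", "f2")
  labels <- rep(c("a", "b"), each = 20)
  m <- fit_lda(X, labels)
  # symmetric spherical case: the rule is sign of the bisector between the
  # two estimated means
  grid <- as.matrix(expand.grid(f1 = seq(-5, 5, 0.5), f2 = seq(-4, 4, 0.5)))
  pred <- predict(m, grid)$class
  mu_a <- m$group_means["a", ]; mu_b <- m$group_means["b", ]
  Sinv <- solve(m$pooled_cov)
  lhs <- grid %*% Sinv %*% (mu_b - mu_a)
  rhs <- drop(0.5 * (mu_a + mu_b) %*% Sinv %*% (mu_b - mu_a))
  expect_equal(pred, ifelse(drop(lhs) > rhs, "b", "a"))
})

test_that("classification matches the Gaussian discriminant formula", {
  cl <- make_clouds(n_per = 10, sep = 3, seed = 7)
  m <- fit_lda(cl$X, cl$labels)
  pred <- predict(m, cl$X)$class
  # independent evaluation of delta_g per point
  groups <- m$group_labels
  Sinv <- solve(m$pooled_cov)
  oracle <- apply(cl$X, 1, function(x) {
    delta <- vapply(groups, function(g) {
      mu <- m$group_means[g, ]
      drop(x %*% Sinv %*% mu - 0.5 * t(mu) %*% Sinv %*% mu + log(1 / 3))
    }, numeric(1))
    groups[which.max(delta)]
  })
  expect_equal(pred, unname(oracle))

  # explicit equal priors and the default give the identical rule
  m2 <- fit_lda(cl$X, cl$labels, priors = rep(1 / 3, 3))
  expect_equal(predict(m2, cl$X)$class, pred)
})

test_that("LDA agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  cl <- make_clouds(n_per = 15, sep = 2.5, seed = 9)
  m <- fit_lda(cl$X, cl$labels)
  ref <- MASS::lda(cl$X, grouping = cl$labels,
                   prior = rep(1 / 3, 3))
  ref_pred <- predict(ref, cl$X)
  mine <- predict(m, cl$X)
  expect_equal(mine$class, as.character(ref_pred$class))
  expect_equal(unname(mine$posterior), unname(ref_pred$posterior),
               tolerance = 1e-8)
})

test_that("LOO classification is exact against a brute-force oracle", {
  set.seed(5)                                        # n = 6 toy set
  X6 <- rbind(cbind(rnorm(3, 0), rnorm(3, 0)), cbind(rnorm(3, 4), rnorm(3, 2)))
  colnames(X6) <- c("f1", "f2")
  lab6 <- rep(c("a", "b"), each = 3)
  rep6 <- loo_classify(X6, lab6)
  expect_equal(rep6$predicted, brute_loo(X6, lab6, priors = c(0.5, 0.5)))

  cl2 <- make_clouds(n_per = 8, sep = 2, seed = 13)
  rep2 <- loo_classify(cl2$X, cl2$labels)
  expect_equal(rep2$predicted, brute_loo(cl2$X, cl2$labels))
  expect_equal(sum(rep2$confusion), rep2$n)
  expect_equal(rep2$rate_percent,
               100 * sum(diag(rep2$confusion)) / rep2$n)
})

test_that("separable groups reach 100% and permuted labels hit chance", {
  cl <- make_clouds(n_per = 10, sep = 20, seed = 2)  # 10+ within-SD separation
  expect_equal(loo_classify(cl$X, cl$labels)$rate_percent, 100)

  rates <- numeric(20)
  conf_sum <- matrix(0, 3, 3)
  for (rep in 1:20) {
    cl <- make_clouds(n_per = 20, sep = 8, seed = 100 + rep)
    perm <- with_seed_test(200 + rep, sample(cl$labels))
    r <- loo_classify(cl$X, perm)
    rates[rep] <- r$rate_percent
    conf_sum <- conf_sum + r$confusion
  }
  expect_lt(abs(mean(rates) - 100 / 3), 6)
  # permuted labels: pooled off-diagonal counts are uniform (chi-squared)
  off <- conf_sum[row(conf_sum) != col(conf_sum)]
  expect_gt(stats::chisq.test(off)$p.value, 0.01)
})

test_that("LOO does not exceed resubstitution on average", {
  diffs <- vapply(1:15, function(rep) {
    cl <- make_clouds(n_per = 10, sep = 2, seed = 300 + rep)
    resub_classify(cl$X, cl$labels)$rate_percent -
      loo_classify(cl$X, cl$labels)$rate_percent
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})

test_that("classification is invariant to affine feature rescaling", {
  cl <- make_clouds(n_per = 12, sep = 2.5, seed = 17)
  base <- loo_classify(cl$X, cl$labels)$predicted
  X2 <- cl$X
  X2[, 1] <- 1000 * X2[, 1] - 77
  X2[, 2] <- 0.001 * X2[, 2] + 3
  expect_equal(loo_classify(X2, cl$labels)$predicted, base)

  m <- fit_lda(cl$X, cl$labels); m2 <- fit_lda(X2, cl$labels)
  expect_equal(predict(m, cl$X)$posterior, predict(m2, X2)$posterior,
               tolerance = 1e-8)
})

test_that("canonical scores decompose between-group variance", {
  # k = 2: exactly one function carrying 100%
  set.seed(23)
  X <- rbind(cbind(rnorm(10), rnorm(10)), cbind(rnorm(10, 3), rnorm(10, 1)))
  colnames(X) <- c("f1", "f2")
  lab2 <- rep(c("a", "b"), each = 10)
  cs2 <- canonical_scores(fit_lda(X, lab2), X)
  expect_equal(ncol(cs2$scores), 1L)
  expect_equal(cs2$pct_variance, 100)

  # k = 3, p = 2: two functions summing to 100%
  cl <- make_clouds(n_per = 10, sep = 3, seed = 29)
  m <- fit_lda(cl$X, cl$labels)
  cs3 <- canonical_scores(m, cl$X)
  expect_equal(ncol(cs3$scores), 2L)
  expect_equal(sum(cs3$pct_variance), 100)
  expect_true(all(diff(cs3$pct_variance) <= 0))

  # eigenvalues match a direct generalized-eigenproblem solve
  groups <- m$group_labels
  ng <- m$sizes
  gm <- colSums(m$group_means * ng) / sum(ng)
  Bc <- t(m$group_means) - gm
  B <- Bc %*% (ng * t(Bc))
  vals <- sort(Re(eigen(solve(m$pooled_cov) %*% B)$values),
               decreasing = TRUE)[1:2]
  expect_equal(cs3$eigenvalues, vals, tolerance = 1e-8)
})

test_that("subset reports behave sensibly with noise and separating features", {
  set.seed(41)
  n <- 60
  labels <- rep(c("folivore", "frugivore", "hard_object"), each = n / 3)
  f_sep <- as.numeric(factor(labels)) * 10 + rnorm(n, 0, 0.3)
  f_noise <- rnorm(n)
  X <- cbind(sep = f_sep, noise = f_noise)
  reps <- variable_subset_report(X, labels,
                                 list(sep_only = "sep",
                                      both = c("sep", "noise"),
                                      noise_only = "noise"))
  rates <- attr(reps, "rates")
  expect_equal(unname(rates["sep_only"]), 100)
  expect_equal(unname(rates["both"]), 100)   # separating feature dominates
  expect_lt(rates["noise_only"], 60)
  expect_warning(variable_subset_report(X, labels, list(bad = "zzz")),
                 "unknown feature")
  expect_warning(variable_subset_report(X, labels, list(none = character(0))),
                 "empty subset")
})

test_that("degenerate inputs are rejected with clear errors", {
  cl <- make_clouds(n_per = 6, seed = 3)
  expect_error(fit_lda(cl$X, rep("one", nrow(cl$X))), ">= 2 groups")
  expect_error(fit_lda(cl$X[1:7, ], c(rep("a", 6), "b")), ">= 2 members")
  Xs <- cbind(cl$X[, 1], cl$X[, 1])      # collinear features
  expect_error(fit_lda(Xs, cl$labels), "singular")
})
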