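# Diet-category assignment, group summaries, Kruskal-Wallis, pairwise
# Wilcoxon with Bonferroni correction, and simulation-based phylogenetic
# ANOVA with Brownian-motion nulls.

#' Assign a diet category from feeding records
#'
#' Rule: species with more than 50% of recorded feeding time on leaves are
#' folivores; otherwise species flagged as substantial hard-seed/nut
#' consumers are hard-object feeders; otherwise species whose primary
#' ingested component is fruit are frugivores. Anything else is
#' unclassifiable.
#'
#' @param pct_leaves Percent of feeding time on leaves, in `[0, 100]`;
#'   vectorized.
#' @param primary_component Primary ingested component (e.g. `"fruit"`,
#'   `"leaves"`); vectorized.
#' @param hard_object_flag Logical: substantial hard seed/nut consumption.
#' @return Character vector of [diet_levels()] values.
#' @export
assign_diet <- function(pct_leaves, primary_component, hard_object_flag) {
  n <- max(length(pct_leaves), length(primary_component),
           length(hard_object_flag))
  pct_leaves <- rep_len(pct_leaves, n)
  primary_component <- rep_len(tolower(primary_component), n)
  hard_object_flag <- rep_len(as.logical(hard_object_flag), n)
  if (any(is.na(pct_leaves)) || any(pct_leaves < 0 | pct_leaves > 100)) {
    stop_domain("pct_leaves must be in [0, 100]")
  }
  out <- ifelse(pct_leaves > 50, "folivore",
                ifelse(hard_object_flag, "hard_object",
                       ifelse(primary_component == "fruit", "frugivore",
                              NA_character_)))
  if (anyNA(out)) {
    bad <- which(is.na(out))
    stop_input("unclassifiable record(s) at position(s) ",
               paste(bad, collapse = ", "),
               ": <=50% leaves, no hard-object flag, primary not fruit")
  }
  out
}

#' Group means with 95% confidence intervals
#'
#' Unweighted mode: per-group mean and two-sided t-based 95% CI over
#' individuals. Weighted mode (integer `weights`, e.g. per-species sample
#' sizes applied to species means): the weighted mean
#' `sum(w * x) / sum(w)`; no CI is attached since the within-unit spread is
#' not available.
#'
#' @param values Numeric vector.
#' @param groups Group label per value.
#' @param weights Optional positive integer weights per value.
#' @param conf Confidence level for the unweighted CI.
#' @return Data frame: `group`, `n`, `mean`, `ci_low`, `ci_high`,
#'   `degenerate` (TRUE when a CI could not be formed).
#' @export
group_summary <- function(values, groups, weights = NULL, conf = 0.95) {
  stopifnot(length(values) == length(groups))
  if (!is.null(weights)) {
    if (length(weights) != length(values) || any(weights <= 0) ||
        any(weights != round(weights))) {
      stop_input("weights must be positive integers aligned with values")
    }
  }
  keep <- !is.na(values)
  if (any(!keep)) warning("dropping ", sum(!keep), " NA value(s)", call. = FALSE)
  values <- values[keep]; groups <- groups[keep]
  if (!is.null(weights)) weights <- weights[keep]
  idx <- split(seq_along(values), groups)
  empty <- vapply(idx, length, integer(1)) == 0L
  if (any(empty)) {
    warning("empty group(s) omitted: ", paste(names(idx)[empty], collapse = ", "),
            call. = FALSE)
    idx <- idx[!empty]
  }
  rows <- lapply(names(idx), function(g) {
    i <- idx[[g]]
    x <- values[i]
    if (is.null(weights)) {
      m <- mean(x)
      n <- length(x)
      if (n >= 2L && stats::sd(x) > 0) {
        half <- stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(x) / sqrt(n)
        data.frame(group = g, n = n, mean = m, ci_low = m - half,
                   ci_high = m + half, degenerate = FALSE)
      } else {
        data.frame(group = g, n = n, mean = m, ci_low = m, ci_high = m,
                   degenerate = TRUE)
      }
    } else {
      w <- weights[i]
      data.frame(group = g, n = sum(w), mean = sum(w * x) / sum(w),
                 ci_low = NA_real_, ci_high = NA_real_, degenerate = NA)
    }
  })
  do.call(rbind, rows)
}

#' Kruskal-Wallis test across diet groups
#'
#' Tie-corrected H statistic with a chi-squared (k-1 df) approximation,
#' via [stats::kruskal.test()]. Constant data returns H = 0, p = 1 instead
#' of an error.
#'
#' @param values Numeric vector.
#' @param groups Group label per value.
#' @return A list of class `diet_test`: `statistic` (H), `p_value`, `df`,
#'   `method`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop_input("need >= 2 non-empty groups")
  if (length(values) < 3L) stop_input("need >= 3 observations")
  if (stats::sd(values) == 0) {
    return(structure(list(statistic = 0, p_value = 1,
                          df = nlevels(droplevels(groups)) - 1L,
                          method = "Kruskal-Wallis (constant data)"),
                     class = "diet_test"))
  }
  kt <- stats::kruskal.test(values, droplevels(groups))
  structure(list(statistic = unname(kt$statistic), p_value = kt$p.value,
                 df = unname(kt$parameter), method = "Kruskal-Wallis"),
            class = "diet_test")
}

#' @export
print.diet_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 5),
      ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni correction
#'
#' One two-sided rank-sum test per unordered group pair. The exact
#' distribution is used when both groups have at most `exact_max`
#' observations and the pooled data are tie-free; otherwise the normal
#' approximation with tie and continuity correction. The family-wise
#' criterion is `alpha / n_pairs` (0.05/3 = 0.0167 for three groups).
#'
#' @param values Numeric vector.
#' @param groups Group label per value.
#' @param alpha Family-wise significance level.
#' @param exact_max Largest group size for which the exact test is used.
#' @return Data frame: `group1`, `group2`, `n1`, `n2`, `statistic` (W),
#'   `p_value`, `exact`, `significant`, plus attributes `criterion` and
#'   `n_pairs`.
#' @export
pairwise_wilcoxon <- function(values, groups, alpha = 0.05, exact_max = 10L) {
  groups <- as.character(groups)
  levs <- sort(unique(groups))
  if (length(levs) < 2L) stop_input("need >= 2 groups")
  pairs <- utils::combn(levs, 2)
  usable <- logical(ncol(pairs))
  rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    x <- values[groups == g1]; y <- values[groups == g2]
    if (length(x) < 2L || length(y) < 2L) {
      warning("pair ", g1, " vs ", g2, " skipped: group of size < 2",
              call. = FALSE)
      next
    }
    usable[j] <- TRUE
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                         alternative = "two.sided")
    )
    rows[[j]] <- data.frame(group1 = g1, group2 = g2,
                            n1 = length(x), n2 = length(y),
                            statistic = unname(wt$statistic),
                            p_value = wt$p.value, exact = exact)
  }
  out <- do.call(rbind, rows[usable])
  if (is.null(out)) stop_input("no testable pair")
  n_pairs <- nrow(out)
  criterion <- alpha / n_pairs
  out$significant <- out$p_value < criterion
  attr(out, "criterion") <- criterion
  attr(out, "n_pairs") <- n_pairs
  out
}

#' Bonferroni per-comparison criterion
#'
#' @param alpha Family-wise level.
#' @param k Number of comparisons.
#' @return `alpha / k`.
#' @export
bonferroni_criterion <- function(alpha = 0.05, k = 3L) {
  stopifnot(alpha > 0, alpha < 1, k >= 1)
  alpha / k
}

#' Phylogenetic ANOVA by Brownian-motion simulation
#'
#' The observed F statistic (between-group over within-group mean squares
#' on species means) is compared with a null distribution of F statistics
#' from traits simulated under Brownian motion on the tree, with the rate
#' estimated from the data by maximum likelihood. The p-value is
#' `(1 + #(F_sim >= F_obs)) / (1 + n_sim)`.
#'
#' @param species_means Named numeric vector of per-species trait means.
#' @param groups Diet category per species (aligned with `species_means`).
#' @param tree A `phylo` object containing all species.
#' @param n_sim Number of Brownian simulations (>= 100).
#' @param seed Integer seed (the null distribution is deterministic under
#'   it).
#' @return A list of class `diet_test`: `statistic` (F), `p_value`,
#'   `method`, `n_sim`, `seed`, `sigma2_hat`.
#' @export
phylo_anova <- function(species_means, groups, tree, n_sim = 1000L,
                        seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(names(species_means))) {
    stop_input("species_means must be named by species")
  }
  if (length(groups) != length(species_means)) {
    stop_input("groups must align with species_means")
  }
  if (n_sim < 100L) stop_input("n_sim must be >= 100")
  missing <- setdiff(names(species_means), tree$tip.label)
  if (length(missing)) {
    stop_lookup("species not in tree: ", paste(missing, collapse = ", "))
  }
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop_input("need >= 2 groups")
  if (stats::sd(species_means) == 0) {
    stop_input("trait is constant across species; F undefined")
  }
  small <- names(which(table(droplevels(groups)) == 1L))
  if (length(small)) {
    warning("group(s) with a single species: ", paste(small, collapse = ", "),
            call. = FALSE)
  }
  f_stat <- function(y) {
    m <- tapply(y, groups, mean)
    ng <- tapply(y, groups, length)
    gm <- mean(y)
    k <- length(m)
    ss_b <- sum(ng * (m - gm)^2)
    ss_w <- sum((y - m[groups])^2)
    df_w <- length(y) - k
    if (ss_w == 0) return(Inf)
    (ss_b / (k - 1)) / (ss_w / df_w)
  }
  f_obs <- f_stat(species_means)
  # ML Brownian rate on the pooled species-mean vector
  C <- bm_covariance(tree, names(species_means))
  fit <- gls_profile(species_means, matrix(1, length(species_means), 1), C, 1)
  sims <- simulate_bm(tree, fit$sigma2, root_state = fit$beta[1],
                      n = n_sim, seed = seed)
  sims <- sims[names(species_means), , drop = FALSE]
  f_sim <- apply(sims, 2, f_stat)
  p <- (1 + sum(f_sim >= f_obs)) / (1 + n_sim)
  structure(list(statistic = f_obs, p_value = p,
                 method = "phylogenetic ANOVA (BM simulation null)",
                 n_sim = n_sim, seed = seed, sigma2_hat = fit$sigma2),
            class = "diet_test")
}
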