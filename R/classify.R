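# Equal-prior linear discriminant analysis of diet categories with
# leave-one-out cross-validation and canonical variate scores.

#' Fit a linear discriminant model
#'
#' Classic pooled-covariance LDA: per-group feature means and the pooled
#' within-group covariance (divisor n - k) define the linear discriminant
#' score `delta_g(x) = x' S^-1 mu_g - 0.5 mu_g' S^-1 mu_g + log pi_g`.
#' Priors are equal by default, mirroring classification under unequal
#' group sizes. Posterior ties are broken by group label order
#' (alphabetical), deterministically.
#'
#' @param X Numeric n-by-p feature matrix (column names = feature names).
#' @param labels Group label per row.
#' @param priors `"equal"` or a named numeric vector of prior
#'   probabilities summing to 1.
#' @param ridge Optional non-negative ridge added to the pooled-covariance
#'   diagonal (times its mean diagonal) for near-singular inputs; 0 (off)
#'   by default.
#' @return An object of class `lda_model`.
#' @export
fit_lda <- function(X, labels, priors = "equal", ridge = 0) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (anyNA(X)) stop_input("missing feature values")
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stop_input("labels must align with rows of X")
  groups <- sort(unique(labels))
  k <- length(groups)
  n <- nrow(X); p <- ncol(X)
  if (k < 2L) stop_input("need >= 2 groups")
  sizes <- table(factor(labels, levels = groups))
  if (any(sizes < 2L)) {
    stop_input("every group needs >= 2 members; too small: ",
               paste(groups[sizes < 2L], collapse = ", "))
  }
  if (n <= p + k) {
    stop_input("need n > p + k (n = ", n, ", p = ", p, ", k = ", k, ")")
  }
  if (identical(priors, "equal")) {
    pri <- stats::setNames(rep(1 / k, k), groups)
  } else {
    if (!is.numeric(priors) || length(priors) != k ||
        abs(sum(priors) - 1) > 1e-8) {
      stop_input("priors must be 'equal' or k probabilities summing to 1")
    }
    pri <- if (is.null(names(priors))) stats::setNames(priors, groups)
           else priors[groups]
  }
  means <- do.call(rbind, lapply(groups, function(g) {
    colMeans(X[labels == g, , drop = FALSE])
  }))
  dimnames(means) <- list(groups, colnames(X))
  centered <- X - means[labels, , drop = FALSE]
  pooled <- crossprod(centered) / (n - k)
  if (ridge > 0) {
    diag(pooled) <- diag(pooled) + ridge * mean(diag(pooled))
  }
  Sinv <- tryCatch(solve(pooled), error = function(e) NULL)
  if (is.null(Sinv)) {
    stop("pooled within-group covariance is singular (condition number ~ ",
         format(kappa(pooled), digits = 3),
         "); remove collinear features or set ridge > 0")
  }
  structure(list(group_labels = groups, group_means = means,
                 pooled_cov = pooled, pooled_inv = Sinv, priors = pri,
                 feature_names = colnames(X), n = n, sizes = c(sizes)),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("LDA model:", length(x$group_labels), "groups,",
      length(x$feature_names), "features, n =", x$n, "\n")
  cat("  priors:", paste(sprintf("%s=%.3f", x$group_labels, x$priors),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Classify specimens with a fitted LDA model
#'
#' @param object An `lda_model`.
#' @param newdata Feature matrix with the model's features.
#' @param ... Ignored.
#' @return A list: `class` (predicted labels) and `posterior` (n-by-k
#'   matrix).
#' @export
predict.lda_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X <- X[, object$feature_names, drop = FALSE]
  M <- object$group_means
  Sinv <- object$pooled_inv
  # delta_g(x) = x' Sinv mu_g - 0.5 mu_g' Sinv mu_g + log pi_g
  W <- Sinv %*% t(M)                               # p x k
  const <- -0.5 * colSums(t(M) * W) + log(object$priors)
  scores <- X %*% W + matrix(const, nrow(X), ncol(W), byrow = TRUE)
  colnames(scores) <- object$group_labels
  # ties broken toward the first (alphabetical) group by which.max
  cls <- object$group_labels[apply(scores, 1, which.max)]
  post <- exp(scores - apply(scores, 1, max))
  post <- post / rowSums(post)
  list(class = cls, posterior = post, scores = scores)
}

confusion_report <- function(true, pred, groups, mode) {
  confusion <- table(factor(true, levels = groups),
                     factor(pred, levels = groups))
  n <- sum(confusion)
  per_group <- 100 * diag(confusion) / rowSums(confusion)
  structure(list(confusion = unclass(confusion),
                 rate_percent = 100 * sum(diag(confusion)) / n,
                 per_group_rates = per_group, n = n, mode = mode),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Classification report (", x$mode, "), n = ", x$n, "\n", sep = "")
  cat(sprintf("  overall correct: %.1f%%\n", x$rate_percent))
  print(x$confusion)
  invisible(x)
}

#' Leave-one-out cross-validated classification
#'
#' Each specimen is classified by a model fitted to the other n - 1; the
#' confusion matrix is tabulated over true labels and the rate is
#' `100 * correct / n`.
#'
#' @inheritParams fit_lda
#' @return A `classification_report`: `confusion`, `rate_percent`,
#'   `per_group_rates`, `n`, `mode = "leave_one_out"`, and `predicted`.
#' @export
loo_classify <- function(X, labels, priors = "equal", ridge = 0) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    if (min(table(labels[rest])) < 1L || length(unique(labels[rest])) <
        length(unique(labels))) {
      stop_input("leaving out row ", i, " empties a group")
    }
    m <- fit_lda(X[rest, , drop = FALSE], labels[rest], priors, ridge)
    pred[i] <- predict(m, X[i, , drop = FALSE])$class
  }
  rep <- confusion_report(labels, pred, sort(unique(labels)), "leave_one_out")
  rep$predicted <- pred
  rep
}

#' Resubstitution classification
#'
#' Classifies the training specimens with the model fitted to all of them
#' (an optimistic upper reference for the LOO rate).
#'
#' @inheritParams fit_lda
#' @return A `classification_report` with `mode = "resubstitution"`.
#' @export
resub_classify <- function(X, labels, priors = "equal", ridge = 0) {
  m <- fit_lda(X, labels, priors, ridge)
  pred <- predict(m, X)$class
  confusion_report(as.character(labels), pred, m$group_labels,
                   "resubstitution")
}

#' Canonical variate scores
#'
#' Eigen-decomposition of the pooled-within-inverse times between-group
#' scatter; specimens are projected onto the eigenvectors (discriminant
#' functions) ordered by eigenvalue, and each function's share of
#' between-group variance is reported.
#'
#' @param model An `lda_model`.
#' @param X Feature matrix conformable with the model.
#' @return A list of class `canonical_scores`: `scores` (n-by-d),
#'   `pct_variance` (length d, sums to 100), `directions` (p-by-d).
#' @export
canonical_scores <- function(model, X) {
  stopifnot(inherits(model, "lda_model"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X <- X[, model$feature_names, drop = FALSE]
  groups <- model$group_labels
  k <- length(groups)
  if (k < 2L) stop_input("no discriminant function with a single group")
  p <- length(model$feature_names)
  M <- model$group_means
  ng <- model$sizes
  gm <- colSums(M * ng) / sum(ng)
  Bc <- t(M) - gm
  B <- Bc %*% (ng * t(Bc))                        # between-group scatter
  W <- model$pooled_cov
  # whiten: W = U'U, solve symmetric eigenproblem in whitened space
  U <- chol(W)
  A <- forwardsolve(t(U), t(forwardsolve(t(U), B)))
  eig <- eigen((A + t(A)) / 2, symmetric = TRUE)
  d <- min(k - 1, p)
  vals <- pmax(eig$values[seq_len(d)], 0)
  dirs <- backsolve(U, eig$vectors[, seq_len(d), drop = FALSE])
  # normalize so pooled within-group variance of each score is 1
  scale <- sqrt(colSums(dirs * (W %*% dirs)))
  dirs <- sweep(dirs, 2, scale, "/")
  scores <- sweep(X, 2, gm) %*% dirs
  colnames(scores) <- paste0("DF", seq_len(d))
  structure(list(scores = scores,
                 pct_variance = 100 * vals / sum(vals),
                 eigenvalues = vals, directions = dirs),
            class = "canonical_scores")
}

#' @export
print.canonical_scores <- function(x, ...) {
  cat("Canonical scores:", ncol(x$scores), "function(s);",
      paste(sprintf("%.1f%%", x$pct_variance), collapse = ", "),
      "of between-group variance\n")
  invisible(x)
}

#' LOO classification over named feature subsets
#'
#' One leave-one-out report per named subset of the feature columns — the
#' grid of classification rates by variable combination.
#'
#' @param X Feature matrix.
#' @param labels Group label per row.
#' @param subsets Named list of character vectors of feature names.
#' @param priors,ridge Passed to [loo_classify()].
#' @return Named list of `classification_report`s (empty or unknown-name
#'   subsets are skipped with a warning); also a `rates` attribute with the
#'   per-subset percent-correct.
#' @export
variable_subset_report <- function(X, labels, subsets, priors = "equal",
                                   ridge = 0) {
  X <- as.matrix(X)
  out <- list()
  for (nm in names(subsets)) {
    sub <- subsets[[nm]]
    if (!length(sub)) {
      warning("empty subset '", nm, "' skipped", call. = FALSE)
      next
    }
    unknown <- setdiff(sub, colnames(X))
    if (length(unknown)) {
      warning("subset '", nm, "' skipped; unknown feature(s): ",
              paste(unknown, collapse = ", "), call. = FALSE)
      next
    }
    out[[nm]] <- loo_classify(X[, sub, drop = FALSE], labels, priors, ridge)
  }
  attr(out, "rates") <- vapply(out, function(r) r$rate_percent, numeric(1))
  out
}
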