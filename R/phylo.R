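# Phylogenetic machinery: Newick ingestion, Brownian-motion covariance,
# Pagel's lambda transform and ML estimation, phylogenetic GLS, and
# Brownian trait simulation.

#' Read a rooted Newick tree
#'
#' Parses a Newick string (or a file containing one) into an [ape::phylo]
#' object and validates the invariants the downstream comparative methods
#' rely on: unique non-empty leaf labels, branch lengths present and
#' non-negative.
#'
#' @param text A Newick string, or the path of a file holding one.
#' @return An object of class `phylo`.
#' @seealso [write_newick()], [bm_covariance()]
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  is_file <- !grepl("\\(", text) && file.exists(text)
  if (is_file) text <- paste(readLines(text, warn = FALSE), collapse = "")
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  n_open <- lengths(regmatches(text, gregexpr("\\(", text)))
  n_close <- lengths(regmatches(text, gregexpr("\\)", text)))
  if (n_open != n_close) {
    stop_input("unbalanced parentheses in Newick string (", n_open, " '(' vs ",
               n_close, "')')")
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop_input("Newick string failed to parse: ", text)
  if (is.null(tree$edge.length)) {
    stop_input("Newick string has no branch lengths")
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stop_input("Newick string has missing or negative branch lengths")
  }
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop_input("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(tree$tip.label))) stop_input("empty leaf label")
  tree
}

#' Write a tree as a Newick string
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when given the string is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Brownian-motion covariance matrix of a tree
#'
#' Builds the matrix `C` with `C[i, j]` equal to the summed branch length
#' from the root to the most recent common ancestor of leaves `i` and `j`
#' (so `C[i, i]` is the root-to-tip depth). Under Brownian motion with rate
#' `sigma2`, tip values are multivariate normal with covariance
#' `sigma2 * C`.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param taxa Optional character vector: restrict to (and order by) these
#'   leaves.
#' @return A symmetric positive semi-definite matrix with dimnames set to
#'   the taxa.
#' @export
bm_covariance <- function(tree, taxa = NULL) {
  stopifnot(inherits(tree, "phylo"))
  C <- ape::vcv.phylo(tree)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, rownames(C))
    if (length(missing)) {
      stop_lookup("taxa not in tree: ", paste(missing, collapse = ", "))
    }
    C <- C[taxa, taxa, drop = FALSE]
  }
  C
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries of `C` by `lambda`, leaving the
#' diagonal untouched. `lambda = 1` is pure Brownian motion; `lambda = 0`
#' removes all shared history (a star phylogeny).
#'
#' @param C A phylogenetic covariance matrix (see [bm_covariance()]).
#' @param lambda A value in `[0, 1]`.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop_domain("lambda must be a single value in [0, 1], got ",
                format(lambda))
  }
  d <- diag(C)
  C2 <- C * lambda
  diag(C2) <- d
  C2
}

# Profile log-likelihood of a GLS model y ~ X under covariance
# sigma2 * lambda_transform(C, lambda), with sigma2 and beta at their ML
# values. Returns the fit pieces needed by fit_lambda_ml and pgls_fit.
gls_profile <- function(y, X, C, lambda) {
  V <- lambda_transform(C, lambda)
  L <- tryCatch(t(chol(V)), error = function(e) NULL)
  if (is.null(L)) {
    stop("lambda-transformed covariance is numerically singular ",
         "(condition number ~ ", format(kappa(V), digits = 3), ")")
  }
  n <- length(y)
  z <- forwardsolve(L, y)
  Zx <- forwardsolve(L, X)
  qr_fit <- qr(Zx)
  beta <- qr.coef(qr_fit, z)
  resid_w <- z - Zx %*% beta
  rss <- sum(resid_w^2)
  sigma2 <- rss / n                       # ML estimate
  logdetV <- 2 * sum(log(diag(L)))
  ll <- -n / 2 * log(2 * pi * sigma2) - logdetV / 2 - n / 2
  list(loglik = ll, beta = drop(beta), sigma2 = sigma2,
       resid = drop(y - X %*% beta), resid_w = drop(resid_w),
       rss_w = rss, L = L, z = z)
}

# Maximize f over [lo, hi] by golden-section search; ties broken toward hi.
golden_max <- function(f, lo, hi, tol = 1e-8) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 <= f2) {            # <= : prefer the upper interval on ties
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  x <- (a + b) / 2
  list(maximum = x, objective = f(x))
}

# Shared lambda optimizer: 21-point grid seed then golden-section refine,
# ties toward larger lambda.
optimize_lambda <- function(ll_fun) {
  grid <- seq(0, 1, length.out = 21)
  ll_grid <- vapply(grid, ll_fun, numeric(1))
  best <- max(which(ll_grid == max(ll_grid)))   # tie -> larger lambda
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  opt <- golden_max(ll_fun, lo, hi)
  if (opt$objective >= ll_grid[best]) {
    list(lambda = opt$maximum, loglik = opt$objective)
  } else {
    list(lambda = grid[best], loglik = ll_grid[best])
  }
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Fits the single-trait model: tip values multivariate normal with mean
#' `mu`, covariance `sigma2 * lambda_transform(C, lambda)`, maximizing over
#' `lambda` in `[0, 1]` with `mu` and `sigma2` profiled out. A
#' likelihood-ratio test against `lambda = 0` (chi-squared, 1 df) gives
#' `p_vs_zero`, the evidence for phylogenetic signal.
#'
#' @param trait Named numeric vector of per-species trait values; names must
#'   match tree leaves.
#' @param tree A `phylo` object.
#' @return An object of class `lambda_fit`: `lambda_hat`, `log_likelihood`,
#'   `p_vs_zero`, `sigma2_hat`, `mu_hat`, `n_species`.
#' @export
fit_lambda_ml <- function(trait, tree) {
  stopifnot(inherits(tree, "phylo"), is.numeric(trait))
  if (is.null(names(trait))) stop_input("trait vector must be named by species")
  missing <- setdiff(names(trait), tree$tip.label)
  if (length(missing)) {
    stop_lookup("trait species not in tree: ", paste(missing, collapse = ", "))
  }
  if (length(trait) < 4L) stop_input("need at least 4 species, got ",
                                     length(trait))
  if (stats::sd(trait) == 0) stop_input("trait is constant; lambda undefined")
  C <- bm_covariance(tree, names(trait))
  X <- matrix(1, length(trait), 1)
  ll_fun <- function(lam) gls_profile(trait, X, C, lam)$loglik
  opt <- optimize_lambda(ll_fun)
  fit <- gls_profile(trait, X, C, opt$lambda)
  ll0 <- ll_fun(0)
  lrt <- max(0, 2 * (opt$loglik - ll0))
  structure(list(
    lambda_hat = opt$lambda,
    log_likelihood = opt$loglik,
    p_vs_zero = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
    sigma2_hat = fit$sigma2,
    mu_hat = unname(fit$beta[1]),
    n_species = length(trait)
  ), class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat("Pagel's lambda (ML), n =", x$n_species, "species\n")
  cat(sprintf("  lambda = %.4f  logLik = %.3f  sigma2 = %.5g  p(vs lambda=0) = %.4g\n",
              x$lambda_hat, x$log_likelihood, x$sigma2_hat, x$p_vs_zero))
  invisible(x)
}

#' Phylogenetic generalized least-squares regression
#'
#' Fits `y ~ x` by GLS with error covariance proportional to
#' `lambda_transform(bm_covariance(tree), lambda)`. With `lambda = 0` this
#' reduces to ordinary least squares; `lambda = 1` (the default) is pure
#' Brownian motion; `lambda = "ml"` profiles lambda by maximum likelihood
#' jointly with the regression.
#'
#' R-squared is computed in the GLS metric: `1 - RSS/TSS` on
#' Cholesky-whitened variables, with TSS taken about the GLS
#' (intercept-only) mean. Residuals are returned on the original (log10)
#' scale of `y`.
#'
#' @param x,y Named numeric vectors of per-species values (names matching
#'   tree leaves and each other).
#' @param tree A `phylo` object.
#' @param lambda A fixed value in `[0, 1]`, or `"ml"`.
#' @return An object of class `pgls_fit`: `intercept`, `slope`,
#'   `lambda`, `r_squared`, `n_species`, `residuals` (named, response
#'   scale), `sigma2`, `log_likelihood`.
#' @export
pgls_fit <- function(x, y, tree, lambda = 1) {
  stopifnot(inherits(tree, "phylo"), is.numeric(x), is.numeric(y))
  if (is.null(names(x)) || is.null(names(y))) {
    stop_input("x and y must be named by species")
  }
  if (!setequal(names(x), names(y))) stop_input("x and y species differ")
  y <- y[names(x)]
  n <- length(x)
  if (n < 3L) stop_input("need at least 3 species, got ", n)
  missing <- setdiff(names(x), tree$tip.label)
  if (length(missing)) {
    stop_lookup("species not in tree: ", paste(missing, collapse = ", "))
  }
  C <- bm_covariance(tree, names(x))
  X <- cbind(1, x)
  if (identical(lambda, "ml")) {
    opt <- optimize_lambda(function(l) gls_profile(y, X, C, l)$loglik)
    lam <- opt$lambda
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      stop_domain("lambda must be in [0, 1] or \"ml\"")
    }
    lam <- lambda
  }
  fit <- gls_profile(y, X, C, lam)
  # TSS in the same whitened metric, about the GLS mean
  null <- gls_profile(y, matrix(1, n, 1), C, lam)
  tss <- null$rss_w
  r2 <- if (tss > 0) 1 - fit$rss_w / tss else 1
  structure(list(
    intercept = unname(fit$beta[1]),
    slope = unname(fit$beta[2]),
    lambda = lam,
    r_squared = max(0, min(1, r2)),
    n_species = n,
    residuals = stats::setNames(fit$resid, names(x)),
    sigma2 = fit$sigma2,
    log_likelihood = fit$loglik
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit, n =", x$n_species, "species\n")
  cat(sprintf("  y = %.5f + %.5f x   (lambda = %s, R^2 = %.3f)\n",
              x$intercept, x$slope, format(x$lambda, digits = 4),
              x$r_squared))
  invisible(x)
}

#' Simulate Brownian-motion traits on a tree
#'
#' Each edge adds an independent normal increment with variance
#' `sigma2 * branch_length`; tips accumulate the increments on their
#' root-to-tip path. Multifurcations are handled directly (each child edge
#' draws its own increment).
#'
#' @param tree A `phylo` object with branch lengths.
#' @param sigma2 Brownian rate (variance per unit branch length), `>= 0`.
#' @param root_state Trait value at the root.
#' @param n Number of independent replicate trait sets.
#' @param seed Optional integer seed; the caller's RNG stream is untouched.
#' @return If `n == 1`, a named vector of tip values; otherwise a
#'   tips-by-`n` matrix.
#' @export
simulate_bm <- function(tree, sigma2, root_state = 0, n = 1, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(sigma2) || length(sigma2) != 1L || is.na(sigma2) ||
      sigma2 < 0) {
    stop_domain("sigma2 must be a single non-negative number")
  }
  with_seed(seed, {
    tree <- stats::reorder(tree, "cladewise")  # parents precede children
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    vals <- matrix(0, nnode, n)
    root <- ntip + 1L
    vals[root, ] <- root_state
    inc_sd <- sqrt(sigma2 * tree$edge.length)
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]
      child <- tree$edge[e, 2L]
      vals[child, ] <- vals[par, ] +
        if (inc_sd[e] > 0) stats::rnorm(n, 0, inc_sd[e]) else 0
    }
    tips <- vals[seq_len(ntip), , drop = FALSE]
    rownames(tips) <- tree$tip.label
    if (n == 1L) drop(tips) else tips
  })
}
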