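# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantity they check.

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# Brute-force Brownian covariance: C[i, j] = summed branch lengths from the
# root to the MRCA of i and j, by explicit path enumeration.
brute_bm_cov <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  # root-to-node path (node sequence) for every tip
  paths <- lapply(seq_len(ntip), function(i) ape::nodepath(tree, root, i))
  edge_len <- function(a, b) {
    tree$edge.length[tree$edge[, 1] == a & tree$edge[, 2] == b]
  }
  C <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) {
    for (j in seq_len(ntip)) {
      pi_ <- paths[[i]]; pj <- paths[[j]]
      shared <- pi_[seq_len(min(length(pi_), length(pj)))]
      k <- max(which(shared == pj[seq_along(shared)]))
      # sum of edges along the shared prefix
      s <- 0
      if (k >= 2) for (e in 2:k) s <- s + edge_len(pi_[e - 1L], pi_[e])
      C[i, j] <- s
    }
  }
  C
}

# GLS regression by explicit Cholesky whitening followed by OLS.
gls_whiten_fit <- function(x, y, V) {
  L <- t(chol(V))
  z <- forwardsolve(L, y)
  Z <- forwardsolve(L, cbind(1, x))
  fit <- stats::lm.fit(Z, z)
  unname(fit$coefficients)
}

# Exhaustive-permutation two-sided p-value of the Wilcoxon rank-sum
# statistic (small n only).
wilcox_perm_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2    # W as in wilcox.test
  combs <- utils::combn(n, nx)
  ws <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * (length(y)) / 2
  mean(abs(ws - mu) >= abs(obs - mu) - 1e-9)
}

# Brute-force leave-one-out LDA classification by direct evaluation of the
# Gaussian discriminant formula (independent of fit_lda/predict).
brute_loo <- function(X, labels, priors = NULL) {
  X <- as.matrix(X)
  groups <- sort(unique(labels))
  if (is.null(priors)) priors <- rep(1 / length(groups), length(groups))
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; li <- labels[-i]
    mus <- lapply(groups, function(g) colMeans(Xi[li == g, , drop = FALSE]))
    k <- length(groups)
    S <- Reduce(`+`, lapply(seq_along(groups), function(gi) {
      Z <- sweep(Xi[li == groups[gi], , drop = FALSE], 2, mus[[gi]])
      crossprod(Z)
    })) / (nrow(Xi) - k)
    Sinv <- solve(S)
    delta <- vapply(seq_len(k), function(gi) {
      mu <- mus[[gi]]
      drop(X[i, ] %*% Sinv %*% mu - 0.5 * t(mu) %*% Sinv %*% mu +
             log(priors[gi]))
    }, numeric(1))
    pred[i] <- groups[which.max(delta)]
  }
  pred
}

# Sutherland-Hodgman clip of a 3D triangle against half-space z >= h
# (clipping on the up coordinate given by up_col), returning total area of
# the clipped polygon. Independent of the package's case-analysis clipper.
sh_clip_area <- function(tri, h, up_col = 3) {
  poly <- tri
  out <- matrix(numeric(0), 0, 3)
  np <- nrow(poly)
  for (i in seq_len(np)) {
    a <- poly[i, ]; b <- poly[if (i == np) 1 else i + 1, ]
    ain <- a[up_col] >= h; bin <- b[up_col] >= h
    if (ain) out <- rbind(out, a)
    if (xor(ain, bin)) {
      t <- (h - a[up_col]) / (b[up_col] - a[up_col])
      out <- rbind(out, a + t * (b - a))
    }
  }
  if (nrow(out) < 3) return(0)
  # fan area of the (convex) clipped polygon
  s <- 0
  for (i in 2:(nrow(out) - 1)) {
    u <- out[i, ] - out[1, ]; w <- out[i + 1, ] - out[1, ]
    cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    s <- s + 0.5 * sqrt(sum(cr^2))
  }
  s
}
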