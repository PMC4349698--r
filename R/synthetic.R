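# Synthetic study generator: pure-birth trees, species trait means under
# Brownian motion with diet-group offsets, specimen tables with
# within-species noise, and parametric cusp-on-base tooth meshes.

#' Simulated pure-birth phylogeny
#'
#' A pure-birth (Yule) tree rescaled to unit root-to-tip depth, with leaves
#' labelled `S01, S02, ...`. Deterministic under `seed`.
#'
#' @param n_species Number of leaves (>= 2).
#' @param seed Integer seed.
#' @return A `phylo` object.
#' @export
make_tree <- function(n_species, seed) {
  if (n_species < 2L) stop_input("need at least 2 species")
  with_seed(seed, {
    tree <- ape::rphylo(n_species, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth
    tree$tip.label <- sprintf("S%02d", seq_len(n_species))
    tree
  })
}

#' Configuration of a synthetic study
#'
#' Defaults emulate the statistical structure of the real thirteen-species
#' platyrrhine sample: 13 species with diet multiset {3 folivores,
#' 7 frugivores, 3 hard-object feeders}; diet-group offsets per variable
#' patterned on the observed diet-group means; within-species SDs patterned
#' on the medians of the observed per-species SDs; about 7 specimens per
#' species; and a true frugivore shearing line with the observed
#' negative-allometry shape.
#'
#' @param n_species Number of species.
#' @param diet_assignment Character vector of per-species diets (length
#'   `n_species`), or `NULL` to assign the default multiset at random
#'   (seeded).
#' @param n_per_species Specimens per species (scalar or per-species).
#' @param bm_sd Named per-variable Brownian SDs at unit tree depth
#'   (between-species, within-diet scatter).
#' @param diet_offsets Named list: per-variable named vector of diet-group
#'   offsets.
#' @param within_sd Named per-variable within-species specimen SDs.
#' @param shear_line Named list with `lower = c(a, b)` and `upper = c(a, b)`:
#'   true log10 shear ~ log10 length frugivore lines.
#' @param log10_length_mean,log10_length_bm_sd Species mean log10 lower-molar
#'   length distribution (BM on the tree around this mean).
#' @param length_diet_offset Per-diet offset of species mean log10 length,
#'   emulating folivores being the larger-bodied species in the sample.
#' @param within_sd_log10_length Within-species SD of log10 length.
#' @param seed Integer seed (mandatory).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_species = 13L,
    diet_assignment = NULL,
    n_per_species = 7L,
    bm_sd = c(sq_upper = 8, sq_lower = 4.5, or_lower = 0.08,
              rfi_upper = 0.015, rfi_lower = 0.015),
    diet_offsets = list(
      sq_upper = c(folivore = 34.5, frugivore = 2.3, hard_object = -12.3),
      sq_lower = c(folivore = 20.1, frugivore = 0, hard_object = -13.3),
      or_lower = c(folivore = 1.80, frugivore = 1.70, hard_object = 1.50),
      rfi_upper = c(folivore = 0.47, frugivore = 0.47, hard_object = 0.49),
      rfi_lower = c(folivore = 0.54, frugivore = 0.53, hard_object = 0.50)),
    within_sd = c(sq_upper = 6.28, sq_lower = 5.43, or_lower = 0.09,
                  rfi_upper = 0.02, rfi_lower = 0.02),
    shear_line = list(lower = c(0.30, 0.91), upper = c(0.45, 0.74)),
    log10_length_mean = 0.65,
    log10_length_bm_sd = 0.12,
    length_diet_offset = c(folivore = 0.08, frugivore = 0,
                           hard_object = -0.04),
    within_sd_log10_length = 0.015,
    seed) {
  if (missing(seed) || is.null(seed)) stop_input("seed is mandatory")
  vars <- c("sq_upper", "sq_lower", "or_lower", "rfi_upper", "rfi_lower")
  if (!all(vars %in% names(diet_offsets)) || !all(vars %in% names(within_sd)) ||
      !all(vars %in% names(bm_sd))) {
    stop_input("bm_sd, diet_offsets and within_sd must cover variables: ",
               paste(vars, collapse = ", "))
  }
  for (v in vars) {
    if (!all(diet_levels() %in% names(diet_offsets[[v]]))) {
      stop_input("diet_offsets$", v, " must name all diet levels")
    }
  }
  if (!is.null(diet_assignment)) {
    if (length(diet_assignment) != n_species ||
        !all(diet_assignment %in% diet_levels())) {
      stop_input("diet_assignment must give a diet level per species")
    }
  }
  n_per_species <- rep_len(as.integer(n_per_species), n_species)
  if (any(n_per_species < 1L)) stop_input("n_per_species must be >= 1")
  structure(list(n_species = as.integer(n_species),
                 diet_assignment = diet_assignment,
                 n_per_species = n_per_species, bm_sd = bm_sd,
                 diet_offsets = diet_offsets, within_sd = within_sd,
                 shear_line = shear_line,
                 log10_length_mean = log10_length_mean,
                 log10_length_bm_sd = log10_length_bm_sd,
                 length_diet_offset = length_diet_offset,
                 within_sd_log10_length = within_sd_log10_length,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Default diet multiset mirroring the real sample's 3/7/3 composition,
# scaled to n species.
default_diet_multiset <- function(n) {
  base <- c(folivore = 3, frugivore = 7, hard_object = 3)
  counts <- pmax(round(base / sum(base) * n), 1L)
  while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) < n) counts[which.max(base)] <- counts[which.max(base)] + 1L
  rep(names(counts), counts)
}

#' Simulate a complete synthetic study
#'
#' Species trait means are Brownian motion on a simulated pure-birth tree
#' plus a per-diet offset; specimens add independent normal within-species
#' noise. Molar lengths are generated log-normally and total shear follows
#' the true frugivore line `log10 S = a + b log10 L` shifted by each
#' species' SQ deviation, so the shearing calibration has a known true
#' intercept/slope and diet-group SQ structure. Crest lengths split total
#' shear in fixed proportions.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_study`: `specimens` (schema of
#'   [specimen_schema()], both teeth), `features` (per-specimen wide table
#'   of true topographic/size features), `species_truth` (per-species true
#'   means and diets), `tree`, `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n_sp <- config$n_species
    tree <- make_tree(n_sp, seed = NULL)
    species <- tree$tip.label
    diets <- config$diet_assignment
    if (is.null(diets)) diets <- sample(default_diet_multiset(n_sp))
    names(diets) <- species
    vars <- c("sq_upper", "sq_lower", "or_lower", "rfi_upper", "rfi_lower")
    # species means: BM deviation + diet offset
    sp_means <- sapply(vars, function(v) {
      dev <- simulate_bm(tree, config$bm_sd[[v]]^2)
      dev[species] + config$diet_offsets[[v]][diets[species]]
    })
    rownames(sp_means) <- species
    # species mean log10 lower-molar length; upper length tracks it closely
    loglen_lower <- config$log10_length_mean +
      simulate_bm(tree, config$log10_length_bm_sd^2)[species] +
      config$length_diet_offset[diets[species]]
    names(loglen_lower) <- species
    loglen_upper <- loglen_lower + stats::rnorm(n_sp, 0, 0.01)
    names(loglen_upper) <- species
    crest_w <- c(0.22, 0.20, 0.18, 0.16, 0.13, 0.11)
    spec_rows <- list()
    feat_rows <- list()
    for (si in seq_len(n_sp)) {
      sp <- species[si]
      n_i <- config$n_per_species[si]
      ids <- sprintf("%s_%02d", sp, seq_len(n_i))
      for (tooth in c("M1_lower", "M1_upper")) {
        line <- config$shear_line[[if (tooth == "M1_lower") "lower" else "upper"]]
        sqvar <- if (tooth == "M1_lower") "sq_lower" else "sq_upper"
        loglen_sp <- if (tooth == "M1_lower") loglen_lower[si] else loglen_upper[si]
        loglen_ij <- loglen_sp +
          stats::rnorm(n_i, 0, config$within_sd_log10_length)
        L <- 10^loglen_ij
        sq_ij <- sp_means[sp, sqvar] +
          stats::rnorm(n_i, 0, config$within_sd[[sqvar]])
        S <- 10^(line[1] + line[2] * loglen_ij) * (1 + sq_ij / 100)
        crests <- outer(S, crest_w)
        colnames(crests) <- crest_cols
        spec_rows[[length(spec_rows) + 1L]] <- data.frame(
          specimen_id = ids, species = sp, tooth = tooth, crests,
          length_md_mm = L, diet = unname(diets[sp]),
          stringsAsFactors = FALSE)
      }
      # per-specimen topographic features (direct trait noise)
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        specimen_id = ids, species = sp, diet = unname(diets[sp]),
        rfi_upper = sp_means[sp, "rfi_upper"] +
          stats::rnorm(n_i, 0, config$within_sd[["rfi_upper"]]),
        rfi_lower = sp_means[sp, "rfi_lower"] +
          stats::rnorm(n_i, 0, config$within_sd[["rfi_lower"]]),
        or_lower = sp_means[sp, "or_lower"] +
          stats::rnorm(n_i, 0, config$within_sd[["or_lower"]]),
        stringsAsFactors = FALSE)
    }
    specimens <- do.call(rbind, spec_rows)
    rownames(specimens) <- NULL
    features <- do.call(rbind, feat_rows)
    rownames(features) <- NULL
    # attach specimen lengths per tooth to the feature table
    for (tooth in c("M1_lower", "M1_upper")) {
      sub <- specimens[specimens$tooth == tooth, c("specimen_id", "length_md_mm")]
      col <- if (tooth == "M1_lower") "length_lower_mm" else "length_upper_mm"
      features[[col]] <- sub$length_md_mm[match(features$specimen_id,
                                                sub$specimen_id)]
    }
    species_truth <- data.frame(species = species, diet = unname(diets[species]),
                                sp_means, log10_length_lower = unname(loglen_lower),
                                log10_length_upper = unname(loglen_upper),
                                stringsAsFactors = FALSE)
    structure(list(specimens = validate_specimens(specimens),
                   features = features, species_truth = species_truth,
                   tree = tree, config = config),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study:", x$config$n_species, "species,",
      nrow(x$features), "specimens, seed", x$config$seed, "\n")
  invisible(x)
}

#' Write a synthetic study bundle to disk
#'
#' Emits `specimens.csv` (specimen schema), `tree.nwk`, and `truth.json`
#' (all generator parameters plus the true species means) under `dir`.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$specimens, file.path(dir, "specimens.csv"),
                   row.names = FALSE)
  utils::write.csv(study$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  write_newick(study$tree, file.path(dir, "tree.nwk"))
  truth <- list(config = unclass(study$config),
                species_truth = study$species_truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

# --- parametric tooth meshes ---------------------------------------------

#' Height function of a parametric cusp-on-base crown
#'
#' Returns a vectorized closure `h(x, y)` giving crown height above the
#' base plane: a sum of Gaussian cusps at seeded positions over an
#' elliptical base. The closure is the analytic ground truth the mesh
#' discretizes, usable for independent quadrature of the surface area.
#'
#' @param n_cusps Number of cusps.
#' @param cusp_height Peak height of each cusp, mm.
#' @param base_radius Semi-major base radius, mm.
#' @param base_ecc Ratio of semi-minor to semi-major axis.
#' @param cusp_width Gaussian SD of each cusp, mm.
#' @param cusp_positions Optional n-by-2 matrix of cusp centers; default
#'   places one cusp at the center, two at `(+-0.45 r, 0)`, and more
#'   evenly on a `0.45 r` circle (seeded rotation).
#' @param seed Integer seed for the default cusp layout.
#' @return A function `h(x, y)` with attributes `params`.
#' @export
tooth_height_fun <- function(n_cusps = 4, cusp_height = 1.5, base_radius = 3,
                             base_ecc = 0.85, cusp_width = NULL,
                             cusp_positions = NULL, seed = 1L) {
  if (is.null(cusp_width)) cusp_width <- 0.35 * base_radius
  if (is.null(cusp_positions)) {
    cusp_positions <- with_seed(seed, {
      if (n_cusps == 0) {
        matrix(numeric(0), 0, 2)
      } else if (n_cusps == 1) {
        matrix(0, 1, 2)
      } else {
        phase <- stats::runif(1, 0, 2 * pi)
        ang <- phase + 2 * pi * (seq_len(n_cusps) - 1) / n_cusps
        0.45 * base_radius * cbind(cos(ang), sin(ang) * base_ecc)
      }
    })
  }
  h <- function(x, y) {
    z <- numeric(length(x))
    if (nrow(cusp_positions)) {
      for (j in seq_len(nrow(cusp_positions))) {
        d2 <- (x - cusp_positions[j, 1])^2 + (y - cusp_positions[j, 2])^2
        z <- z + cusp_height * exp(-d2 / (2 * cusp_width^2))
      }
    }
    z
  }
  attr(h, "params") <- list(n_cusps = n_cusps, cusp_height = cusp_height,
                            base_radius = base_radius, base_ecc = base_ecc,
                            cusp_width = cusp_width,
                            cusp_positions = cusp_positions)
  h
}

#' Parametric tooth mesh
#'
#' Triangulates the crown height field of [tooth_height_fun()] over a
#' polar grid on the elliptical base. The mesh is a single-valued height
#' field, so its true projected area is the base ellipse and TSA >= PSA by
#' construction.
#'
#' @inheritParams tooth_height_fun
#' @param resolution Angular resolution (>= 16); the radial resolution is
#'   half of it.
#' @return A [tooth_mesh()] with up axis `"z"`; the height closure is kept
#'   in attribute `height_fun`.
#' @export
make_tooth_mesh <- function(n_cusps = 4, cusp_height = 1.5, base_radius = 3,
                            base_ecc = 0.85, cusp_width = NULL,
                            cusp_positions = NULL, resolution = 48L,
                            seed = 1L) {
  if (resolution < 16L) stop_input("resolution must be >= 16")
  if (base_radius <= 0) stop_input("base radius must be > 0")
  if (cusp_height < 0) stop_input("cusp_height must be >= 0")
  hfun <- tooth_height_fun(n_cusps, cusp_height, base_radius, base_ecc,
                           cusp_width, cusp_positions, seed)
  n_theta <- as.integer(resolution)
  n_r <- max(8L, as.integer(resolution) %/% 2L)
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  rfrac <- seq_len(n_r) / n_r
  # center vertex + concentric rings
  ring_x <- as.vector(t(outer(rfrac * base_radius, cos(theta))))
  ring_y <- as.vector(t(outer(rfrac * base_radius * base_ecc, sin(theta))))
  xy <- rbind(c(0, 0), cbind(ring_x, ring_y))
  z <- hfun(xy[, 1], xy[, 2])
  V <- cbind(xy, z)
  colnames(V) <- c("x", "y", "z")
  ring_id <- function(i, j) 1L + (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  faces <- vector("list", n_r)
  j <- seq_len(n_theta)
  faces[[1]] <- cbind(1L, ring_id(1L, j), ring_id(1L, j + 1L))
  if (n_r > 1L) {
    for (i in seq_len(n_r - 1L)) {
      a <- ring_id(i, j); b <- ring_id(i, j + 1L)
      c_ <- ring_id(i + 1L, j); d <- ring_id(i + 1L, j + 1L)
      faces[[i + 1L]] <- rbind(cbind(a, c_, d), cbind(a, d, b))
    }
  }
  m <- tooth_mesh(V, do.call(rbind, faces), up_axis = "z")
  attr(m, "height_fun") <- hfun
  m
}

#' Analytic surface area of a parametric crown
#'
#' Independent quadrature of `sqrt(1 + hx^2 + hy^2)` over the elliptical
#' base by a fine polar midpoint rule with numerical gradients — the
#' oracle a mesh-based TSA is checked against.
#'
#' @param hfun A [tooth_height_fun()] closure.
#' @param n Quadrature resolution.
#' @return Surface area, mm^2.
#' @export
tooth_analytic_area <- function(hfun, n = 400L) {
  p <- attr(hfun, "params")
  a <- p$base_radius; b <- p$base_radius * p$base_ecc
  rf <- (seq_len(n) - 0.5) / n
  th <- 2 * pi * (seq_len(n) - 0.5) / n
  R <- matrix(rf, n, n)
  TH <- matrix(th, n, n, byrow = TRUE)
  X <- a * R * cos(TH); Y <- b * R * sin(TH)
  eps <- 1e-5 * a
  hx <- (hfun(X + eps, Y) - hfun(X - eps, Y)) / (2 * eps)
  hy <- (hfun(X, Y + eps) - hfun(X, Y - eps)) / (2 * eps)
  integrand <- sqrt(1 + hx^2 + hy^2)
  # polar midpoint rule with elliptical Jacobian a*b*r
  sum(integrand * a * b * R) * (1 / n) * (2 * pi / n)
}
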