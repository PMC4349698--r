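# Shearing-quotient computation: total shear from the six measured crest
# lengths, frugivore-only PGLS calibration of log10 shear on log10 molar
# length, and per-specimen SQ percentages.

crest_cols <- paste0("c", 1:6, "_mm")

#' Columns of the specimen table schema
#'
#' Header of the specimen CSV: one row per measured first molar with the
#' six shearing-crest lengths, mesiodistal molar length and diet label.
#'
#' @return Character vector of required column names.
#' @export
specimen_schema <- function() {
  c("specimen_id", "species", "tooth", crest_cols, "length_md_mm", "diet")
}

#' Read a specimen measurement table
#'
#' @param path CSV path following [specimen_schema()]; `tooth` must be
#'   `M1_upper` or `M1_lower`, `diet` one of the [diet_levels()] or
#'   `unknown`.
#' @return A validated data frame.
#' @export
read_specimens <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_specimens(df)
}

#' Validate a specimen table against the schema
#'
#' @param df Data frame with the columns of [specimen_schema()].
#' @return The data frame, invisibly unchanged, or an error naming the
#'   offending column/row.
#' @export
validate_specimens <- function(df) {
  missing <- setdiff(specimen_schema(), names(df))
  if (length(missing)) {
    stop_input("specimen table lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad_tooth <- setdiff(unique(df$tooth), c("M1_upper", "M1_lower"))
  if (length(bad_tooth)) {
    stop_input("unknown tooth value(s): ", paste(bad_tooth, collapse = ", "))
  }
  bad_diet <- setdiff(unique(df$diet), c(diet_levels(), "unknown"))
  if (length(bad_diet)) {
    stop_input("unknown diet value(s): ", paste(bad_diet, collapse = ", "))
  }
  for (cc in crest_cols) {
    if (anyNA(df[[cc]])) {
      stop_input("missing crest length in column ", cc, " (row ",
                 which(is.na(df[[cc]]))[1], ")")
    }
    if (any(df[[cc]] < 0)) stop_input("negative crest length in ", cc)
  }
  if (anyNA(df$length_md_mm) || any(df$length_md_mm <= 0)) {
    stop_input("length_md_mm must be present and > 0")
  }
  df
}

#' Total shear of a specimen
#'
#' The sum of the six measured shearing-crest lengths, in mm.
#'
#' @param crests A numeric vector of six crest lengths, or a specimen data
#'   frame holding the `c1_mm..c6_mm` columns (then one value per row).
#' @return Total shear S (mm).
#' @export
total_shear <- function(crests) {
  if (is.data.frame(crests)) {
    missing <- setdiff(crest_cols, names(crests))
    if (length(missing)) {
      stop_input("missing crest column(s): ", paste(missing, collapse = ", "))
    }
    m <- as.matrix(crests[crest_cols])
    if (anyNA(m)) {
      bad <- crest_cols[apply(is.na(m), 2, any)]
      stop_input("missing crest value(s) in: ", paste(bad, collapse = ", "))
    }
    return(rowSums(m))
  }
  crests <- as.numeric(crests)
  if (length(crests) != 6L || anyNA(crests)) {
    stop_input("need exactly six crest lengths; missing/extra: got ",
               length(crests), " with ", sum(is.na(crests)), " NA")
  }
  sum(crests)
}

#' Per-species means of log10 molar length and log10 total shear
#'
#' Arithmetic means of log10-transformed per-specimen values, for one
#' tooth position. Species with no record for that tooth are omitted with
#' a warning.
#'
#' @param specimens Specimen data frame ([specimen_schema()]).
#' @param tooth `"M1_upper"` or `"M1_lower"`.
#' @return Data frame: `species`, `n`, `mean_log10_length`,
#'   `mean_log10_shear`, `diet` (the species' modal diet label).
#' @export
species_log_means <- function(specimens, tooth = c("M1_lower", "M1_upper")) {
  tooth <- match.arg(tooth)
  validate_specimens(specimens)
  sub <- specimens[specimens$tooth == tooth, , drop = FALSE]
  dropped <- setdiff(unique(specimens$species), unique(sub$species))
  if (length(dropped)) {
    warning("species with no ", tooth, " records omitted: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (!nrow(sub)) stop_input("no records for tooth ", tooth)
  s <- total_shear(sub)
  if (any(s <= 0)) stop_input("total shear must be > 0 to take log10")
  sp <- split(seq_len(nrow(sub)), sub$species)
  out <- data.frame(
    species = names(sp),
    n = vapply(sp, length, integer(1)),
    mean_log10_length = vapply(sp, function(i) mean(log10(sub$length_md_mm[i])),
                               numeric(1)),
    mean_log10_shear = vapply(sp, function(i) mean(log10(s[i])), numeric(1)),
    diet = vapply(sp, function(i) names(which.max(table(sub$diet[i]))),
                  character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Calibrate the shearing regression on frugivores
#'
#' Fits the PGLS line `mean log10 shear ~ mean log10 length` across the
#' frugivorous species only — so SQ measures deviation from a typical
#' frugivore of the same molar length.
#'
#' @param specimens Specimen data frame.
#' @param tooth `"M1_upper"` or `"M1_lower"`.
#' @param tree A `phylo` object containing the frugivore species (possibly
#'   via `aliases`).
#' @param lambda Fixed lambda in `[0, 1]` (default 1, pure Brownian) or
#'   `"ml"`.
#' @param aliases Optional alias map (data frame `table_name`, `tree_name`)
#'   translating table species names to tree leaf names.
#' @return An object of class `shear_calibration`: the `pgls_fit` plus
#'   `tooth` and the species means used.
#' @export
calibrate_shear <- function(specimens, tooth = c("M1_lower", "M1_upper"),
                            tree, lambda = 1, aliases = NULL) {
  tooth <- match.arg(tooth)
  means <- species_log_means(specimens, tooth)
  fr <- means[means$diet == "frugivore", , drop = FALSE]
  if (nrow(fr) < 3L) {
    stop_input("need >= 3 frugivore species for calibration, got ", nrow(fr))
  }
  tree_names <- apply_aliases(fr$species, aliases)
  missing <- setdiff(tree_names, tree$tip.label)
  if (length(missing)) {
    stop_lookup("frugivore species not in tree: ",
                paste(missing, collapse = ", "))
  }
  x <- stats::setNames(fr$mean_log10_length, tree_names)
  y <- stats::setNames(fr$mean_log10_shear, tree_names)
  fit <- pgls_fit(x, y, tree, lambda = lambda)
  structure(list(fit = fit, tooth = tooth, species_means = fr),
            class = "shear_calibration")
}

#' @export
print.shear_calibration <- function(x, ...) {
  cat("Frugivore shearing calibration (", x$tooth, "), ",
      nrow(x$species_means), " species\n", sep = "")
  print(x$fit)
  invisible(x)
}

# Translate species names through an optional alias map.
apply_aliases <- function(species, aliases) {
  if (is.null(aliases)) return(species)
  stopifnot(all(c("table_name", "tree_name") %in% names(aliases)))
  idx <- match(species, aliases$table_name)
  ifelse(is.na(idx), species, aliases$tree_name[idx])
}

#' Shearing quotient
#'
#' Expected total shear for a molar of length L under the calibration line
#' is `E = 10^(a + b * log10(L))` (back-transformed to real space); SQ is
#' the percentage deviation of observed shear from it:
#' `SQ = 100 * (S - E) / E`.
#'
#' @param shear Observed total shear S (mm); vectorized.
#' @param length Mesiodistal molar length L (mm); vectorized.
#' @param calibration A `shear_calibration`, **or** a numeric
#'   `c(intercept, slope)` pair on the log10 scale.
#' @return SQ in percent.
#' @export
shearing_quotient <- function(shear, length, calibration) {
  if (inherits(calibration, "shear_calibration")) {
    a <- calibration$fit$intercept
    b <- calibration$fit$slope
  } else if (is.numeric(calibration) && length(calibration) == 2L) {
    a <- calibration[1]; b <- calibration[2]
  } else {
    stop_input("calibration must be a shear_calibration or c(intercept, slope)")
  }
  if (any(length <= 0)) stop_input("molar length must be > 0")
  expected <- 10^(a + b * log10(length))
  100 * (shear - expected) / expected
}

#' Per-specimen (or per-species) SQ table
#'
#' Adds `total_shear_mm`, `expected_shear_mm` and `sq_percent` to the rows
#' of one tooth position. `expected_from = "individual"` (default)
#' evaluates the calibration line at each specimen's own molar length;
#' `"species"` evaluates it at the species-mean length (log10-mean
#' back-transformed), as when only species means are available.
#'
#' @param specimens Specimen data frame.
#' @param calibration A `shear_calibration` for the same tooth.
#' @param expected_from `"individual"` or `"species"`.
#' @return The tooth-subset data frame with the three added columns.
#' @export
compute_sq <- function(specimens, calibration,
                       expected_from = c("individual", "species")) {
  expected_from <- match.arg(expected_from)
  stopifnot(inherits(calibration, "shear_calibration"))
  validate_specimens(specimens)
  sub <- specimens[specimens$tooth == calibration$tooth, , drop = FALSE]
  if (!nrow(sub)) {
    stop_input("no specimens for calibrated tooth ", calibration$tooth)
  }
  s <- total_shear(sub)
  len <- if (expected_from == "individual") {
    sub$length_md_mm
  } else {
    means <- species_log_means(sub, calibration$tooth)
    10^means$mean_log10_length[match(sub$species, means$species)]
  }
  a <- calibration$fit$intercept; b <- calibration$fit$slope
  expected <- 10^(a + b * log10(len))
  sub$total_shear_mm <- s
  sub$expected_shear_mm <- expected
  sub$sq_percent <- 100 * (s - expected) / expected
  attr(sub, "expected_from") <- expected_from
  sub
}
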