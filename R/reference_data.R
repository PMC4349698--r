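# Published reference tables for the thirteen-species platyrrhine sample:
# sample composition, per-species index means/SDs, and diet-group
# summaries. Shipped as plain CSV under inst/extdata and used to
# reconstruct the group-level summaries and to pattern the synthetic
# generator's defaults.

ref_path <- function(name) {
  system.file("extdata", name, package = "molardiet", mustWork = TRUE)
}

#' Platyrrhine study sample
#'
#' The thirteen medium- to large-bodied platyrrhine species of the
#' reference sample: per-species specimen counts, mean body mass, primary
#' ingested dietary component, hard-object-feeding flag, and assigned diet
#' category.
#'
#' @return Data frame with columns `species`, `n`, `body_mass_g`,
#'   `primary_component`, `hard_object`, `diet_category`.
#' @export
reference_sample <- function() {
  utils::read.csv(ref_path("platyrrhine_sample.csv"), stringsAsFactors = FALSE)
}

#' Per-species molar index means and SDs
#'
#' Species means and standard deviations of the five occlusal indices
#' (lower-molar OR, upper/lower RFI, upper/lower SQ) for the reference
#' sample. Species naming differs slightly from [reference_sample()] for
#' three species; [species_aliases()] resolves the mismatch. One printed
#' SD (Saimiri boliviensis, lower SQ) is negative in the source table and
#' is kept as printed; take `abs()` before using it as a dispersion.
#'
#' @return Data frame keyed by `species` with `<index>_mean` / `<index>_sd`
#'   columns.
#' @export
reference_index_means <- function() {
  utils::read.csv(ref_path("platyrrhine_index_means.csv"),
                  stringsAsFactors = FALSE)
}

#' Species alias map
#'
#' Exact-string alias table (`table_name`, `tree_name`) absorbing the
#' naming mismatches between the measurement tables and the sample/tree
#' naming.
#'
#' @return Data frame with columns `table_name`, `tree_name`.
#' @export
species_aliases <- function() {
  utils::read.csv(ref_path("species_aliases.csv"), stringsAsFactors = FALSE)
}

#' Published diet-group means with confidence intervals
#'
#' The published group-level summaries (mean and 95% CI bounds) of the
#' five indices by diet category — the reference the reconstructed
#' weighted group means are compared against.
#'
#' @return Data frame: `group`, `variable`, `mean`, `ci_high`, `ci_low`.
#' @export
reference_group_means <- function() {
  utils::read.csv(ref_path("platyrrhine_group_means.csv"),
                  stringsAsFactors = FALSE)
}

#' Reconstruct diet-group means from species means and sample sizes
#'
#' Joins the per-species index means to the sample table (through the
#' alias map), then computes the sample-size-weighted group mean of each
#' index by diet category — the arithmetic behind the published group
#' summaries.
#'
#' @return Data frame: `group`, `variable`, `weighted_mean`, `n`.
#' @export
reconstruct_group_means <- function() {
  sample_tab <- reference_sample()
  means <- reference_index_means()
  means$species_key <- apply_aliases(means$species, species_aliases())
  idx <- match(means$species_key, sample_tab$species)
  if (anyNA(idx)) {
    stop_lookup("unmatched species after aliasing: ",
                paste(means$species[is.na(idx)], collapse = ", "))
  }
  means$n <- sample_tab$n[idx]
  means$group <- sample_tab$diet_category[idx]
  vars <- c("or_lower", "rfi_upper", "rfi_lower", "sq_upper", "sq_lower")
  rows <- lapply(vars, function(v) {
    gs <- group_summary(means[[paste0(v, "_mean")]], means$group,
                        weights = means$n)
    data.frame(group = gs$group, variable = v, weighted_mean = gs$mean,
               n = gs$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
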