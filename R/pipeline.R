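# End-to-end orchestration: configuration, logging, and report generation
# reproducing the study's table structures (species means, diet-group
# summaries, group tests, classification-rate grid, canonical scores).

#' Read a run configuration from YAML
#'
#' @param path YAML file. Recognized keys: `seed` (required when any
#'   stochastic stage runs), `simulate` (generator overrides, or `true`),
#'   `paths` (`specimens`, `features`, `tree`, `aliases`), `lambda_mode`
#'   (number in `[0,1]` or `"ml"`), `n_sim`, `expected_from`, `subsets`,
#'   `out_dir`.
#' @return A config list for [run_full()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$paths)) {
    for (p in unlist(cfg$paths)) {
      if (!file.exists(p)) stop_input("configured path does not exist: ", p)
    }
  }
  cfg
}

default_subsets <- function(features) {
  subs <- list(
    length_lower = "length_lower_mm",
    sq_lower = "sq_lower",
    sq_lower_length = c("sq_lower", "length_lower_mm"),
    or_lower = "or_lower",
    or_lower_length = c("or_lower", "length_lower_mm"),
    rfi_lower = "rfi_lower",
    rfi_lower_length = c("rfi_lower", "length_lower_mm"),
    all_lower = c("sq_lower", "or_lower", "rfi_lower", "length_lower_mm"),
    sq_upper = "sq_upper",
    rfi_upper = "rfi_upper",
    all_upper = c("sq_upper", "rfi_upper", "length_upper_mm"),
    sq_both = c("sq_upper", "sq_lower"),
    all_combined = c("sq_upper", "sq_lower", "rfi_upper", "rfi_lower",
                     "or_lower", "length_upper_mm", "length_lower_mm"))
  subs[vapply(subs, function(s) all(s %in% names(features)), logical(1))]
}

#' Run the full dietary-inference pipeline
#'
#' Orchestrates shearing calibration, per-specimen SQ, phylogenetic-signal
#' estimation, group summaries and tests, the phylogenetic ANOVA, the LOO
#' classification-rate grid over feature subsets, and canonical scores.
#' Writes `table2.csv` (species means and SDs), `table3.csv` (diet-group
#' means and CIs), `table4.csv` (group tests), `table5.csv` (LOO rates),
#' `scores.csv`, and `run.log` under `config$out_dir` (when given), and
#' returns everything invisibly.
#'
#' @param config A list (see [read_run_config()]); the default simulates a
#'   synthetic study. A `seed` is required.
#' @return A list of class `diet_run` with elements `table2`, `table3`,
#'   `table4`, `table5`, `scores`, `lambda`, `calibrations`, `features`,
#'   `log`.
#' @export
run_full <- function(config = list(simulate = TRUE, seed = 1L)) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$seed)) stop_input("config$seed is required")
  seed <- as.integer(config$seed)
  lambda_mode <- if (is.null(config$lambda_mode)) 1 else config$lambda_mode
  n_sim <- if (is.null(config$n_sim)) 1000L else as.integer(config$n_sim)
  expected_from <- if (is.null(config$expected_from)) "individual"
                   else config$expected_from
  logln <- character(0)
  say <- function(...) logln <<- c(logln, paste0(...))
  say("molardiet run, package version ",
      as.character(utils::packageVersion("molardiet")))
  say("seed = ", seed, "; lambda_mode = ", format(lambda_mode),
      "; n_sim = ", n_sim, "; expected_from = ", expected_from)

  aliases <- NULL
  if (!is.null(config$paths)) {
    specimens <- read_specimens(config$paths$specimens)
    features <- utils::read.csv(config$paths$features,
                                stringsAsFactors = FALSE)
    tree <- read_newick(config$paths$tree)
    if (!is.null(config$paths$aliases)) {
      aliases <- utils::read.csv(config$paths$aliases,
                                 stringsAsFactors = FALSE)
    }
    say("inputs: ", config$paths$specimens)
  } else {
    sim_args <- if (isTRUE(config$simulate)) list() else
      config$simulate[setdiff(names(config$simulate), "seed")]
    cfg <- do.call(synthetic_config, c(sim_args, list(seed = seed)))
    study <- simulate_study(cfg)
    specimens <- study$specimens
    features <- study$features
    tree <- study$tree
    say("inputs: synthetic study (", cfg$n_species, " species, seed ",
        seed, ")")
  }

  # shearing calibration (frugivores only) and per-specimen SQ
  calibrations <- list()
  for (tooth in c("M1_lower", "M1_upper")) {
    cal <- calibrate_shear(specimens, tooth, tree, lambda = lambda_mode,
                           aliases = aliases)
    calibrations[[tooth]] <- cal
    sq <- compute_sq(specimens, cal, expected_from = expected_from)
    col <- if (tooth == "M1_lower") "sq_lower" else "sq_upper"
    features[[col]] <- sq$sq_percent[match(features$specimen_id,
                                           sq$specimen_id)]
    say(sprintf("%s calibration: a = %.5f, b = %.5f, lambda = %s, R2 = %.3f",
                tooth, cal$fit$intercept, cal$fit$slope,
                format(cal$fit$lambda, digits = 4), cal$fit$r_squared))
  }

  vars <- intersect(c("sq_upper", "sq_lower", "or_lower", "rfi_upper",
                      "rfi_lower"), names(features))

  # table 2 analog: species means and SDs
  sp <- split(seq_len(nrow(features)), features$species)
  table2 <- data.frame(species = names(sp),
                       n = vapply(sp, length, integer(1)),
                       row.names = NULL)
  for (v in vars) {
    table2[[paste0(v, "_mean")]] <-
      vapply(sp, function(i) mean(features[[v]][i]), numeric(1))
    table2[[paste0(v, "_sd")]] <-
      vapply(sp, function(i) stats::sd(features[[v]][i]), numeric(1))
  }
  table2$diet <- vapply(sp, function(i) features$diet[i][1], character(1))

  # phylogenetic signal per variable on species means
  tree_key <- apply_aliases(table2$species, aliases)
  lambda_fits <- list()
  for (v in vars) {
    trait <- stats::setNames(table2[[paste0(v, "_mean")]], tree_key)
    lambda_fits[[v]] <- fit_lambda_ml(trait, tree)
    say(sprintf("lambda(%s) = %.3f (p vs 0: %.4g)", v,
                lambda_fits[[v]]$lambda_hat, lambda_fits[[v]]$p_vs_zero))
  }

  # table 3 analog: diet-group means with t-based CIs over individuals
  table3 <- do.call(rbind, lapply(vars, function(v) {
    gs <- group_summary(features[[v]], features$diet)
    gs$variable <- v
    gs
  }))

  # table 4 analog: Kruskal-Wallis + pairwise Wilcoxon + phylo ANOVA
  t4 <- list()
  for (v in vars) {
    kw <- kruskal_wallis(features[[v]], features$diet)
    pw <- pairwise_wilcoxon(features[[v]], features$diet)
    pa <- phylo_anova(stats::setNames(table2[[paste0(v, "_mean")]], tree_key),
                      table2$diet, tree, n_sim = n_sim, seed = seed)
    say(sprintf("%s: KW H = %.3f (p = %.4g); phyloANOVA F = %.3f (p = %.4g); %s",
                v, kw$statistic, kw$p_value, pa$statistic, pa$p_value,
                if (all(pw$exact)) "Wilcoxon exact" else
                  "Wilcoxon normal approximation"))
    t4[[v]] <- data.frame(variable = v, pw,
                          kw_H = kw$statistic, kw_p = kw$p_value,
                          panova_F = pa$statistic, panova_p = pa$p_value)
  }
  table4 <- do.call(rbind, t4)
  rownames(table4) <- NULL
  say("Bonferroni per-pair criterion: ",
      format(bonferroni_criterion(0.05, 3), digits = 4))

  # table 5 analog: LOO rates by feature subset
  subsets <- if (!is.null(config$subsets)) config$subsets
             else default_subsets(features)
  complete <- stats::complete.cases(features[unique(unlist(subsets))])
  Xall <- features[complete, , drop = FALSE]
  reports <- variable_subset_report(as.matrix(Xall[unique(unlist(subsets))]),
                                    Xall$diet, subsets)
  table5 <- data.frame(subset = names(reports),
                       features = vapply(subsets[names(reports)], paste,
                                         character(1), collapse = "+"),
                       n = vapply(reports, function(r) r$n, numeric(1)),
                       loo_rate_percent = vapply(reports, function(r)
                         r$rate_percent, numeric(1)),
                       row.names = NULL)

  # canonical scores on the full feature set
  full <- unique(unlist(subsets[length(subsets)]))
  model <- fit_lda(as.matrix(Xall[full]), Xall$diet)
  cs <- canonical_scores(model, as.matrix(Xall[full]))
  scores <- data.frame(specimen_id = Xall$specimen_id, species = Xall$species,
                       diet = Xall$diet, cs$scores)
  say("canonical functions: ",
      paste(sprintf("%.1f%%", cs$pct_variance), collapse = ", "),
      " of between-group variance")

  out <- structure(list(table2 = table2, table3 = table3, table4 = table4,
                        table5 = table5, scores = scores,
                        lambda = lambda_fits, calibrations = calibrations,
                        features = features, pct_variance = cs$pct_variance,
                        log = logln),
                   class = "diet_run")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("table2", "table3", "table4", "table5", "scores")) {
      utils::write.csv(out[[nm]], file.path(config$out_dir,
                                            paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    writeLines(logln, file.path(config$out_dir, "run.log"))
  }
  invisible(out)
}

#' @export
print.diet_run <- function(x, ...) {
  cat("Dietary-inference run\n")
  cat(paste0("  ", x$log), sep = "\n")
  invisible(x)
}
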