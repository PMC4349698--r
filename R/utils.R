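# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. seed = NULL runs the code with the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

stop_input <- function(...) {
  stop(structure(class = c("molardiet_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_domain <- function(...) {
  stop(structure(class = c("molardiet_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_lookup <- function(...) {
  stop(structure(class = c("molardiet_lookup_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Diet category levels
#'
#' The closed set of diet-category labels used throughout the package, in
#' their canonical (alphabetical) order.
#'
#' @return Character vector `c("folivore", "frugivore", "hard_object")`.
#' @export
diet_levels <- function() c("folivore", "frugivore", "hard_object")
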