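# Internal helpers shared across modules.

#' Derive a reproducible per-stage seed from a global seed
#'
#' Hashes a stage name onto the integer line so pipeline stages can be rerun
#' in isolation with the same stream they would receive inside
#' [run_pipeline()]. Always returns a non-negative integer below 2^31 - 1.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return A single integer seed.
#' @export
#' @examples
#' stage_seed(1, "connectivity")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% (2^31 - 1))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "ctcnet_config_error")
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", name), class = "ctcnet_config_error")
  }
  x
}

# Lexicographic order of unordered region pairs (i < j by label order as given).
# Used everywhere a deterministic tie-break over edges is needed.
region_pairs <- function(regions) {
  n <- length(regions)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  tibble::tibble(
    i = idx[, 1L], j = idx[, 2L],
    region_a = regions[idx[, 1L]], region_b = regions[idx[, 2L]]
  )
}
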