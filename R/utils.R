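#' @keywords internal
#' @import stats
#' @importFrom utils str
"_PACKAGE"

## Run an expression under a fixed RNG seed without disturbing the caller's
## RNG state. All generators route their randomness through this so that
## identical (seed, params) give identical output.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}

## GroundTruth record attached to every synthetic dataset.
ground_truth <- function(modality, params, seed) {
  structure(
    list(modality = modality, params = params, seed = seed),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth [", x$modality, "], seed ", x$seed, "\n", sep = "")
  str(x$params, max.level = 1, give.attr = FALSE)
  invisible(x)
}
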