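#' @keywords internal
#' @aliases kglink-package
#' @importFrom rlang .data
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict
#' @useDynLib kglink, .registration = TRUE
"_PACKAGE"

# Run the calling function's remaining body under a given RNG seed and
# restore the caller-of-caller's RNG state when that function exits.
local_seed <- function(seed, env = parent.frame()) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  restore <- function() {
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
  do.call(base::on.exit, list(bquote((.(restore))()), add = TRUE), envir = env)
  set.seed(seed)
  invisible(seed)
}
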