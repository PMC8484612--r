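#' @useDynLib crmbiofilm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rpois runif median quantile cov complete.cases sd
#' @importFrom utils read.csv write.csv packageVersion modifyList
"_PACKAGE"

# Named substreams derived from one user seed, so scene geometry, detector
# noise and SBR patch sampling can be re-seeded independently.
.stream_ids <- c(scene = 101L, noise = 211L, sbr = 307L)

derive_seed <- function(seed, stream = names(.stream_ids)) {
  stream <- match.arg(stream)
  seed <- as.integer(seed)
  as.integer((abs(seed) * 2149 + .stream_ids[[stream]] * 7919) %% 2147483647)
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
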