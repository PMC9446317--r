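#' @useDynLib lesionshape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rlnorm rbinom runif qlogis plogis glm binomial
#'   coef vcov quantile median wilcox.test chisq.test prcomp sd qnorm pnorm
#' @importFrom utils write.csv read.csv
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators never perturb the global stream.
with_rng_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
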