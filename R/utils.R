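#' @importFrom stats rpois runif rnorm sd var setNames
NULL

# Evaluate expr under a temporary RNG seed, restoring global RNG state.
# seed = NULL leaves the RNG stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic per-stream child seeds: the first n draws are unchanged when
# n grows, so adding loci never perturbs earlier loci.
childSeeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  withSeed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

# generations <-> years helper, generation time in years per generation
#' Convert between years and generations
#'
#' Demographic models in this package keep time in generations; dated
#' divergence estimates (e.g. Ma-scale molecular dating) are converted with a
#' user-supplied generation time.
#'
#' @param years,generations numeric times to convert.
#' @param generationTime years per generation.
#' @return numeric vector of converted times.
#' @export
yearsToGenerations <- function(years, generationTime) {
  stopifnot(generationTime > 0)
  years / generationTime
}

#' @rdname yearsToGenerations
#' @export
generationsToYears <- function(generations, generationTime) {
  stopifnot(generationTime > 0)
  generations * generationTime
}

# assert helper with caller-friendly message
abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
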