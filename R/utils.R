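#' @useDynLib biomepred, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rchisq runif rmultinom rgamma sd var lm coef
#'   predict model.matrix cor anova aov as.formula contr.sum qt setNames
#'   complete.cases
#' @importFrom utils write.table read.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a master seed
#'
#' Each random stage of the pipeline draws its seed from the master seed and
#' the stage name, so toggling one stage never shifts the randomness of
#' another. The derivation is a small deterministic hash kept below 2^31.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return an integer seed.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- as.numeric(master) %% 2147483647
  for (cp in utf8ToInt(stage)) h <- (h * 131 + cp) %% 2147483647
  as.integer(h)
}

# scaled-inverse-chi-square draw, sum-of-squares parameterisation:
# density proportional to (x)^-(df/2 + 1) exp(-S / (2 x))
rinvchisq <- function(n, df, S) S / stats::rchisq(n, df = df)

# evaluate a function under a temporary RNG state, restoring the caller's
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
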