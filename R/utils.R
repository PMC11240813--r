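#' @importFrom stats median optimize p.adjust plogis pchisq pt quantile
#'   rbinom rgamma rlnorm rnorm rpois runif sd setNames var complete.cases
#'   as.formula coef cov lm model.matrix terms wilcox.test relevel
#' @importFrom utils write.csv read.csv head
#' @importFrom data.table data.table as.data.table setDF setnames rbindlist
#'   dcast .N .SD
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a global seed
#'
#' Stages of the pipeline draw their own seeds from a single global seed with
#' a fixed counter scheme, so any stage can be re-run in isolation and
#' reproduce its output. The scheme is `(seed + 7919 * counter) mod (2^31-1)`
#' (7919 is the 1000th prime; the modulus keeps seeds in integer range).
#'
#' @param seed integer global seed.
#' @param counter non-negative integer stage counter.
#' @return an integer seed.
#' @export
child_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), is.numeric(counter), counter >= 0)
  as.integer((as.double(seed) + 7919 * as.double(counter)) %% 2147483647)
}

# run code under a fixed seed without disturbing the caller's RNG stream
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_config <- function(...) stop(..., call. = FALSE)

assert_has_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_config(sprintf("%s is missing required columns: %s",
                        what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

# median with the midpoint convention for even-sized sets (stats::median
# already does this for type-7 on numeric input; wrapper makes intent explicit)
midpoint_median <- function(x) stats::median(x, na.rm = TRUE)
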