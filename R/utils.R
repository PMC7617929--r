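#' @useDynLib rhizotrack, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom median sd var coef lm vcov predict residuals
#' @importFrom utils read.csv write.csv
NULL

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
# seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number or NULL")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %s (got %s)", name, lower, x), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %s (got %s)", name, lower, x), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %s (got %s)", name, upper, x), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer (got %s)", name, x), call. = FALSE)
  x
}

check_columns <- function(df, cols, name) {
  if (!is.data.frame(df))
    stop(sprintf("'%s' must be a data.frame", name), call. = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("'%s' is missing column(s): %s", name,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}
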