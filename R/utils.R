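#' @importFrom stats sd var quantile rnorm runif cor.test pt pnorm dnorm qnorm
#'   integrate uniroot aggregate complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG stream.  All stochastic operations in the package go through this so
## that results are reproducible per seed.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (is.null(old)) {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    } else {
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

## Derive a child seed from a base seed, staying inside 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7907 * as.numeric(k)) %% 2147483629L)
}

#' Undefined-score marker
#'
#' Several statistics in the package (kappa with degenerate marginals, a
#' t statistic with zero variance, a metric with a zero denominator) are
#' mathematically undefined for some inputs.  Rather than silently return
#' `NaN` or 0, such cases return an `NA` carrying a human-readable reason.
#'
#' @param reason Single string stating why the value is undefined.
#' @return For `undefinedValue()`, an `NA` of class `undefinedValue` with a
#'   `reason` attribute.  `isUndefined()` returns `TRUE` for such markers,
#'   `undefinedReason()` retrieves the reason (or `NA`).
#' @examples
#' x <- undefinedValue("zero between-subject variance")
#' isUndefined(x)
#' undefinedReason(x)
#' @export
undefinedValue <- function(reason) {
  stopifnot(is.character(reason), length(reason) == 1L)
  structure(NA_real_, reason = reason, class = c("undefinedValue", "numeric"))
}

#' @rdname undefinedValue
#' @param x Object to test / query.
#' @export
isUndefined <- function(x) inherits(x, "undefinedValue")

#' @rdname undefinedValue
#' @export
undefinedReason <- function(x) {
  r <- attr(x, "reason", exact = TRUE)
  if (is.null(r)) NA_character_ else r
}

#' @export
print.undefinedValue <- function(x, ...) {
  cat("<undefined>", attr(x, "reason", exact = TRUE), "\n")
  invisible(x)
}

## assertions --------------------------------------------------------------

assertFinite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(what, " must be finite numeric", call. = FALSE)
  invisible(x)
}

assertCount <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != round(x))
    stop(what, " must be a single non-negative integer", call. = FALSE)
  invisible(x)
}

## Short stable hash of an R object (used for run manifests / log lines).
configHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE, version = 2)
  unname(tools::md5sum(f))
}
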