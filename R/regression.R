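# Linear regression with Pearson correlation statistics, the analysis
# used to relate conformational spread to torsion counts and ligand
# efficiency to scaffold similarity.

#' Pearson regression
#'
#' Ordinary least-squares fit of \code{y} on \code{x} with the Pearson
#' correlation coefficient and its two-tailed significance from
#' t = r sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
#' Incomplete pairs (NA in either variable) are dropped pairwise before
#' fitting; at least 3 complete pairs and non-zero variance in both
#' variables are required.
#'
#' @param x,y numeric vectors of equal length.
#' @return a \linkS4class{RegressionResult}.
#' @examples
#' fit <- pearsonRegression(1:6, c(1.1, 2.2, 2.9, 4.1, 5.2, 5.8))
#' fit
#' @export
pearsonRegression <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3)
    stop("need at least 3 complete observation pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("degenerate regression: zero variance in x or y", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  new("RegressionResult", n = as.integer(n),
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r = r, r2 = r^2, p = min(max(ct$p.value, 0), 1))
}

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf(
    "RegressionResult: n = %d\n  y = %.4g x + %.4g\n  r = %.4f, r2 = %.4f, p = %.4g\n",
    object@n, object@slope, object@intercept, object@r, object@r2,
    object@p))
})

#' @rdname RegressionResult-class
#' @param x a \code{RegressionResult}.
#' @param ... ignored.
#' @export
setMethod("as.list", "RegressionResult", function(x, ...) {
  list(n = x@n, slope = x@slope, intercept = x@intercept, r = x@r,
       r2 = x@r2, p = x@p)
})
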