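# Internal helpers shared across modules.

#' Fast simple linear regression
#'
#' Minimal least-squares fit used in the hot loops of the efficiency
#' estimators, where calling [stats::lm()] thousands of times per curve
#' would dominate runtime.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return list with `slope`, `intercept`, `r2`. When `y` has (numerically)
#'   zero variance the fit is a perfect horizontal line and `r2` is 1.
#' @keywords internal
#' @noRd
lsfit1 <- function(x, y) {
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  dx <- x - mx
  dy <- y - my
  sxx <- sum(dx * dx)
  sxy <- sum(dx * dy)
  syy <- sum(dy * dy)
  if (sxx <= 0) {
    return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_))
  }
  slope <- sxy / sxx
  intercept <- my - slope * mx
  if (syy <= .Machine$double.eps * n * max(1, my^2)) {
    r2 <- 1
  } else {
    r2 <- (sxy * sxy) / (sxx * syy)
  }
  list(slope = slope, intercept = intercept, r2 = r2)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a formatted message
#' @noRd
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Check that a value is a single finite number
#' @noRd
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    fail("'%s' must be a single finite number", name)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    fail("'%s' = %g is outside the allowed range %s%g, %g%s", name, x,
         if (strict_lower) "(" else "[", lower, upper,
         if (strict_upper) ")" else "]")
  }
  invisible(x)
}

#' Sample standard deviation that returns 0 (not NA) for n = 1
#' @noRd
sd0 <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x)
}

#' Evaluate code under a temporary RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}
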