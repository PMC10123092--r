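#' One-breakpoint step fit of a footprint ratio profile
#'
#' Fits a piecewise-constant function with a single breakpoint to a numeric
#' profile by exhaustive least squares: every interior position is tried as
#' a breakpoint, the mean of the data on each side is taken, and the
#' breakpoint with the smallest total sum of squared residuals wins (ties
#' go to the smallest breakpoint, for determinism). The difference between
#' the right and left means is the *co-translational assembly score*: on a
#' selective/total 80S footprint ratio profile along a CDS, a large
#' positive score marks a sudden increase in factor-bound ribosomes, the
#' signature of the factor engaging the nascent chain once its binding
#' site has emerged.
#'
#' `fit_step()` is the direct O(n^2) reference implementation;
#' `fit_step_fast()` computes identical results in O(n) from running sums
#' of x and x^2. Both return the same class of object.
#'
#' The reported `breakpoint` is the number of bins in the left segment, so
#' with 0-based bin indices the left segment is `[0, b)` and the right
#' `[b, n)`; both segments are always non-empty (`1 <= b <= n-1`).
#'
#' @param x numeric profile (a [ratio_profile] or plain vector), length
#'   >= 2, all values finite.
#' @return An object of class `step_fit` with components `breakpoint`,
#'   `mean_left`, `mean_right`, `sse`, `score` (`mean_right - mean_left`),
#'   `profile` and `n`.
#' @examples
#' fit <- fit_step(c(0, 0, 0, 4, 4, 4))
#' fit$breakpoint  # 3
#' coef(fit)
#' @seealso [compute_ratio_profile()], [score_genes()]
#' @export
fit_step <- function(x) {
  x <- as_profile_values(x)
  n <- length(x)
  best <- NULL
  tol <- step_fit_tol(x)
  for (b in 1:(n - 1)) {
    ml <- mean(x[1:b])
    mr <- mean(x[(b + 1):n])
    sse <- sum((x[1:b] - ml)^2) + sum((x[(b + 1):n] - mr)^2)
    # ascending b + strict improvement beyond tol => smallest-b tie-break
    if (is.null(best) || sse < best$sse - tol)
      best <- list(b = b, ml = ml, mr = mr, sse = sse)
  }
  new_step_fit(best$b, best$ml, best$mr, best$sse, x, "exhaustive")
}

#' @rdname fit_step
#' @export
fit_step_fast <- function(x) {
  x <- as_profile_values(x)
  n <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  b <- 1:(n - 1)
  sl <- cs[b]; sr <- cs[n] - sl
  nl <- b; nr <- n - b
  sse <- pmax(cs2[b] - sl^2 / nl, 0) + pmax(cs2[n] - cs2[b] - sr^2 / nr, 0)
  bi <- which(sse <= min(sse) + step_fit_tol(x))[1]  # smallest-b tie-break
  new_step_fit(bi, sl[bi] / bi, sr[bi] / (n - bi), sse[bi], x, "prefix")
}

# absolute tolerance used to resolve floating-point SSE ties; scales with
# the profile's energy so exact ties (constant or perfect-step profiles)
# resolve to the smallest breakpoint in both implementations
step_fit_tol <- function(x) 1e-10 * (1 + sum(x^2))

as_profile_values <- function(x) {
  if (inherits(x, "ratio_profile")) x <- x$values
  x <- as.numeric(x)
  if (length(x) < 2) abort("profile must have at least 2 values")
  if (any(!is.finite(x))) abort("profile contains non-finite values")
  x
}

new_step_fit <- function(b, ml, mr, sse, profile, method) {
  structure(list(breakpoint = as.integer(b), mean_left = ml, mean_right = mr,
                 sse = sse, score = mr - ml, profile = profile,
                 n = length(profile), method = method),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, digits = 4, ...) {
  cat("One-breakpoint step fit\n")
  cat(sprintf("  breakpoint: %d of %d bins (left [0,%d), right [%d,%d))\n",
              x$breakpoint, x$n, x$breakpoint, x$breakpoint, x$n))
  cat(sprintf("  means: left %s, right %s\n",
              format(x$mean_left, digits = digits),
              format(x$mean_right, digits = digits)))
  cat(sprintf("  assembly score (right - left): %s   SSE: %s\n",
              format(x$score, digits = digits),
              format(x$sse, digits = digits)))
  invisible(x)
}

#' @export
summary.step_fit <- function(object, ...) {
  f <- fitted(object)
  r <- object$profile - f
  out <- list(fit = object,
              sd_left = sd(object$profile[1:object$breakpoint]),
              sd_right = sd(object$profile[(object$breakpoint + 1):object$n]),
              rmse = sqrt(mean(r^2)),
              breakpoint_frac = object$breakpoint / object$n)
  class(out) <- "summary.step_fit"
  out
}

#' @export
print.summary.step_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  breakpoint at %.1f%% of profile; segment sd %s / %s; RMSE %s\n",
              100 * x$breakpoint_frac, format(x$sd_left, digits = digits),
              format(x$sd_right, digits = digits),
              format(x$rmse, digits = digits)))
  invisible(x)
}

#' @export
coef.step_fit <- function(object, ...) {
  c(mean_left = object$mean_left, mean_right = object$mean_right,
    score = object$score)
}

#' Predicted step level at given bin indices
#' @param object a [fit_step()] result.
#' @param newbins 0-based bin indices (default: all bins of the profile).
#' @param ... unused.
#' @export
predict.step_fit <- function(object, newbins = NULL, ...) {
  newbins <- newbins %||% (seq_len(object$n) - 1L)
  ifelse(newbins < object$breakpoint, object$mean_left, object$mean_right)
}

#' @export
fitted.step_fit <- function(object, ...) predict(object)

#' @export
residuals.step_fit <- function(object, ...) object$profile - fitted(object)

#' Simulate profiles from a fitted step
#'
#' Draws Gaussian noise around the fitted step, with the residual standard
#' deviation estimated from the fit (`sqrt(sse / (n - 2))`).
#' @param object a [fit_step()] result.
#' @param nsim number of profiles.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of numeric profiles.
#' @export
simulate.step_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(object$sse / max(object$n - 2, 1))
  mu <- fitted(object)
  lapply(seq_len(nsim), function(i) mu + rnorm(object$n, 0, sigma))
}

#' @export
plot.step_fit <- function(x, xlab = "bin", ylab = "ratio", ...) {
  plot(seq_len(x$n) - 1L, x$profile, xlab = xlab, ylab = ylab,
       pch = 16, col = "grey40", ...)
  segments(0, x$mean_left, x$breakpoint - 0.5, x$mean_left,
           col = "firebrick", lwd = 2)
  segments(x$breakpoint - 0.5, x$mean_right, x$n - 1, x$mean_right,
           col = "firebrick", lwd = 2)
  abline(v = x$breakpoint - 0.5, lty = 2, col = "firebrick")
  invisible(x)
}
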