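#' Evaluate a sum-of-four-Gaussians curve
#'
#' `f(t) = sum_i a_i * exp(-((t - b_i)/c_i)^2)` with `i = 1..4`. Used as the
#' smooth, analytically evaluable forcing function for the ODE model, so the
#' solver never sees interpolation kinks.
#'
#' @param fit a `gaussian_sum_fit` (or any list with `a`, `b`, `c`).
#' @param t numeric vector of times (minutes).
#' @return numeric vector of curve values.
#' @export
eval_gaussian_sum <- function(fit, t) {
  out <- numeric(length(t))
  for (i in seq_along(fit$a)) {
    out <- out + fit$a[i] * exp(-((t - fit$b[i]) / fit$c[i])^2)
  }
  out
}

gaussian_sum_residuals <- function(par, times, counts, w) {
  a <- par[1:4]; b <- par[5:8]; cc <- par[9:12]
  pred <- numeric(length(times))
  for (i in 1:4) pred <- pred + a[i] * exp(-((times - b[i]) / cc[i])^2)
  sqrt(w) * (pred - counts)
}

#' Fit a CI trajectory to a sum of four Gaussians
#'
#' Least-squares fit of the four-Gaussian curve to puncta counts, with the
#' residual at t = 0 up-weighted so the fitted curve starts at (near) zero
#' -- the model requires no receptor complexes before stimulation.
#' Amplitudes are constrained nonnegative and widths bounded below, so the
#' fitted curve is nonnegative within tolerance. The parameterization is
#' intentionally redundant (sums of Gaussians are non-identifiable); only
#' the fitted curve, not the individual components, is meaningful.
#'
#' @param ci a [ci_trajectory()].
#' @param zero_anchor_weight multiplicative weight on the t = 0 residual
#'   (default 1000).
#' @param max_restarts deterministic restarts from perturbed initializations
#'   when the optimizer fails to reduce the residual adequately.
#' @return object of class `gaussian_sum_fit` with fields `a`, `b`, `c`
#'   (length 4 each), `sse` (unweighted), `zero_anchor_weight`, `times`,
#'   `counts`.
#' @export
fit_gaussian_sum <- function(ci, zero_anchor_weight = 1000, max_restarts = 3) {
  times <- ci$times; counts <- ci$counts
  if (length(times) < 12) stop("need at least 12 timepoints to fit 12 parameters")
  if (all(counts <= 1e-12)) {
    fit <- structure(list(a = rep(0, 4), b = c(20, 60, 100, 140),
                          c = rep(20, 4), sse = 0,
                          zero_anchor_weight = zero_anchor_weight,
                          times = times, counts = counts),
                     class = "gaussian_sum_fit")
    return(fit)
  }
  w <- rep(1, length(times))
  w[1] <- zero_anchor_weight
  peak <- max(counts)
  support <- range(times[counts > 0.05 * peak])
  span <- max(diff(support), 4 * mean(diff(times)))

  init_for <- function(r) {
    # r = restart index; deterministic spread perturbations
    centers <- support[1] + span * (c(0.15, 0.4, 0.65, 0.9) + 0.05 * (r - 1))
    c(rep(peak * 0.5 / (1 + 0.2 * (r - 1)), 4), centers,
      rep(span / (3 + r - 1), 4))
  }
  lower <- c(rep(0, 4), rep(min(times) - span, 4), rep(1, 4))
  upper <- c(rep(5 * peak, 4), rep(max(times) + span, 4), rep(2 * diff(range(times)), 4))

  best <- NULL
  for (r in seq_len(max_restarts)) {
    res <- try(minpack.lm::nls.lm(
      par = init_for(r), lower = lower, upper = upper,
      fn = gaussian_sum_residuals, times = times, counts = counts, w = w,
      control = minpack.lm::nls.lm.control(maxiter = 400)), silent = TRUE)
    if (inherits(res, "try-error")) next
    sse_w <- sum(res$fvec^2)
    if (is.null(best) || sse_w < best$sse_w) best <- list(par = res$par, sse_w = sse_w)
    # good enough: weighted SSE below 1% of signal energy
    if (sse_w < 0.01 * sum(counts^2)) break
  }
  if (is.null(best))
    stop("Gaussian-sum fit failed to converge after ", max_restarts, " restarts")
  par <- best$par
  fit <- structure(list(a = par[1:4], b = par[5:8], c = par[9:12],
                        sse = NA_real_, zero_anchor_weight = zero_anchor_weight,
                        times = times, counts = counts),
                   class = "gaussian_sum_fit")
  fit$sse <- sum((eval_gaussian_sum(fit, times) - counts)^2)
  fit
}

#' @export
print.gaussian_sum_fit <- function(x, ...) {
  cat(sprintf("<gaussian_sum_fit> SSE %.4g over %d points; f(0) = %.4g\n",
              x$sse, length(x$times), eval_gaussian_sum(x, 0)))
  invisible(x)
}
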