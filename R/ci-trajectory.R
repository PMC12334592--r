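#' Receptor-complex (CI) count trajectory
#'
#' A CI trajectory holds time-stamped counts of receptor-proximal signaling
#' complexes (visualized experimentally as EGFP-NEMO puncta) for one cell or
#' one condition average. CI trajectories are the forcing input of the
#' NF-kB model: counts drive the activation of neutral IKK.
#'
#' @param times numeric vector of times in minutes, strictly increasing on a
#'   uniform grid.
#' @param counts numeric vector of puncta counts, nonnegative, same length as
#'   `times`.
#' @param cell_id character label for the cell (or `"mean"` for averages).
#' @param condition character label for the stimulation condition.
#' @param meta optional list of provenance notes (e.g. grid snapping).
#'
#' @return An object of class `ci_trajectory`: a list with elements `times`,
#'   `counts`, `cell_id`, `condition`, `meta`.
#' @export
ci_trajectory <- function(times, counts, cell_id = "cell", condition = "na",
                          meta = list()) {
  times <- as.numeric(times)
  counts <- as.numeric(counts)
  if (length(times) != length(counts))
    stop("`times` and `counts` must have the same length")
  if (length(times) >= 2) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("`times` must be strictly increasing")
    if (max(dt) - min(dt) > 1e-8 * max(dt))
      stop("`times` must lie on a uniform grid")
  }
  if (any(counts < -1e-12)) stop("`counts` must be nonnegative")
  counts[counts < 0] <- 0
  structure(list(times = times, counts = counts, cell_id = cell_id,
                 condition = condition, meta = meta),
            class = "ci_trajectory")
}

#' @export
print.ci_trajectory <- function(x, ...) {
  cat(sprintf("<ci_trajectory> cell %s / condition %s: %d points, %.0f-%.0f min, peak %.1f\n",
              x$cell_id, x$condition, length(x$times),
              min(x$times), max(x$times), max(x$counts)))
  invisible(x)
}

#' Nuclear NF-kB fold-change trajectory
#'
#' Nuclear reporter intensity divided by its value at t = 0, so the first
#' sample is 1 by construction. This is both the experimental observable
#' (nuclear mCh-RelA fold change) and the model output channel.
#'
#' @param times numeric, minutes.
#' @param fold_change numeric, dimensionless, nonnegative; first element must
#'   equal 1 within tolerance.
#' @param cell_id,condition labels.
#' @param meta optional list.
#' @return An object of class `nfkb_trajectory`.
#' @export
nfkb_trajectory <- function(times, fold_change, cell_id = "cell",
                            condition = "na", meta = list()) {
  times <- as.numeric(times)
  fold_change <- as.numeric(fold_change)
  if (length(times) != length(fold_change))
    stop("`times` and `fold_change` must have the same length")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (abs(fold_change[1] - 1) > 1e-6)
    stop("fold_change must equal 1 at t = 0 (normalize first)")
  if (any(fold_change < 0)) stop("fold_change must be nonnegative")
  structure(list(times = times, fold_change = fold_change, cell_id = cell_id,
                 condition = condition, meta = meta),
            class = "nfkb_trajectory")
}

#' @export
print.nfkb_trajectory <- function(x, ...) {
  cat(sprintf("<nfkb_trajectory> cell %s / condition %s: %d points, peak FC %.2f\n",
              x$cell_id, x$condition, length(x$times), max(x$fold_change)))
  invisible(x)
}

# Centered rolling mean whose window shrinks symmetrically at the edges
# (half-width limited by the distance to the nearest boundary), so the first
# and last samples keep their raw values -- in particular t = 0 stays at
# zero, which anchors the downstream Gaussian fits.
rolling_mean_shrink <- function(x, window) {
  if (window < 1 || window != round(window)) stop("window must be a positive integer")
  if (window == 1) return(x)
  n <- length(x)
  h <- floor((window - 1) / 2)
  vapply(seq_len(n), function(i) {
    hi <- min(h, i - 1L, n - i)
    mean(x[(i - hi):(i + hi)])
  }, numeric(1))
}

#' Generate a triangular CI pulse trajectory
#'
#' Builds a synthetic receptor-complex count trajectory with a triangular
#' shape: counts rise linearly from 0 at t = 0 to `peak_height` at
#' `peak_time`, fall linearly back to 0 at `adaptation_time`, and stay 0
#' afterwards. A centered rolling mean (window shrinking at the edges) is
#' then applied to ease downstream fitting to a sum of Gaussians. Peak
#' height, peak time and adaptation time are thereby controlled exactly.
#'
#' @param peak_height peak puncta count, > 0.
#' @param adaptation_time minutes at which counts return to 0; must exceed
#'   `peak_time` and not exceed the last grid time.
#' @param peak_time minutes of the peak; snapped to the nearest grid index
#'   (recorded in `meta$peak_time_snapped` when it moves). Default 28 min,
#'   index position 7 on the default grid.
#' @param n_points number of grid points (default 46).
#' @param dt grid spacing in minutes (default 4, i.e. 0--180 min).
#' @param smooth_window rolling-mean window width (default 3; 1 = no
#'   smoothing).
#' @param cell_id,condition labels passed to [ci_trajectory()].
#'
#' @return A [ci_trajectory()] whose `meta` records the requested and
#'   realized peak/adaptation parameters.
#' @export
make_triangular_ci <- function(peak_height, adaptation_time, peak_time = 28,
                               n_points = 46, dt = 4, smooth_window = 3,
                               cell_id = "synthetic", condition = "synthetic") {
  if (peak_height <= 0) stop("peak_height must be > 0")
  times <- (seq_len(n_points) - 1) * dt
  if (adaptation_time <= peak_time)
    stop("invalid geometry: adaptation_time must exceed peak_time")
  if (adaptation_time > max(times))
    stop("adaptation_time beyond the last grid time")
  if (peak_time <= 0) stop("peak_time must be > 0")
  peak_idx <- which.min(abs(times - peak_time))
  tp <- times[peak_idx]
  meta <- list(peak_height = peak_height, peak_time = tp,
               adaptation_time = adaptation_time,
               smooth_window = smooth_window)
  if (abs(tp - peak_time) > 1e-9) meta$peak_time_snapped <- c(from = peak_time, to = tp)
  if (adaptation_time <= tp)
    stop("invalid geometry: adaptation_time must exceed the snapped peak_time")
  raw <- ifelse(times <= tp,
                peak_height * times / tp,
                pmax(0, peak_height * (adaptation_time - times) / (adaptation_time - tp)))
  counts <- rolling_mean_shrink(raw, smooth_window)
  ci_trajectory(times, counts, cell_id = cell_id, condition = condition,
                meta = c(meta, list(raw_counts = raw)))
}

#' Named library of pulse-condition CI templates
#'
#' Templates mirroring the stimulation conditions used throughout the
#' workflow: a single 6-minute pulse and its split versions (2 x 3, 3 x 2,
#' 4 x 1.5 minutes -- equal total cytokine exposure, hence comparable CI
#' area, but progressively longer adaptation times), longer single pulses
#' (1 x 15, 1 x 30), and an unstimulated control (all-zero counts). Peak
#' heights are in the tens-to-hundreds of puncta range typical of
#' IL-1-stimulated cells; the peak sits at 28 min on the default 46-point,
#' 4-min grid.
#'
#' The split-pulse templates are constructed so that peak_height *
#' adaptation_time / 2 (the triangle area) is constant across the
#' 6-minute-total group: splitting the same dose into more pulses trades
#' peak height for persistence.
#'
#' @param smooth_window rolling-mean window (default 3).
#' @return Named list of [ci_trajectory()] templates with conditions
#'   `control`, `1x6`, `2x3`, `3x2`, `4x1.5`, `1x15`, `1x30`.
#' @export
make_pulse_condition_library <- function(smooth_window = 3) {
  specs <- list(
    `1x6`   = c(peak = 135, auc = 3600),
    `2x3`   = c(peak = 105, auc = 3600),
    `3x2`   = c(peak = 88,  auc = 3600),
    `4x1.5` = c(peak = 70,  auc = 3600),
    `1x15`  = c(peak = 180, auc = 7200),
    `1x30`  = c(peak = 250, auc = 14375)
  )
  out <- lapply(names(specs), function(cond) {
    s <- specs[[cond]]
    make_triangular_ci(peak_height = s[["peak"]],
                       adaptation_time = 2 * s[["auc"]] / s[["peak"]],
                       smooth_window = smooth_window,
                       cell_id = "mean", condition = cond)
  })
  names(out) <- names(specs)
  times <- (0:45) * 4
  out$control <- ci_trajectory(times, rep(0, 46), cell_id = "mean",
                               condition = "control",
                               meta = list(peak_height = 0))
  out
}

#' Convert a list of trajectories to a long-format data frame
#'
#' @param ci_list list of [ci_trajectory()] objects.
#' @param nfkb_list optional list of paired [nfkb_trajectory()] objects (by
#'   position).
#' @return data.frame with columns `cell_id, condition, time_min, ci_count`
#'   and, when `nfkb_list` is given, `nfkb_fc`.
#' @export
trajectories_to_df <- function(ci_list, nfkb_list = NULL) {
  rows <- lapply(seq_along(ci_list), function(i) {
    ci <- ci_list[[i]]
    d <- data.frame(cell_id = ci$cell_id, condition = ci$condition,
                    time_min = ci$times, ci_count = ci$counts,
                    stringsAsFactors = FALSE)
    if (!is.null(nfkb_list)) {
      nf <- nfkb_list[[i]]
      stopifnot(identical(nf$cell_id, ci$cell_id))
      d$nfkb_fc <- nf$fold_change
    }
    d
  })
  do.call(rbind, rows)
}
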