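#' Area under the fold-change curve
#'
#' Trapezoidal integral of `max(fold_change - 1, 0)` over time: the baseline
#' of 1 is subtracted and negative excursions are clipped to zero before
#' integration, so only activation above baseline contributes.
#'
#' @param traj an [nfkb_trajectory()], or a list with `times` and
#'   `fold_change`.
#' @return AUC in dimensionless fold-change x minutes.
#' @export
auc_fold_change <- function(traj) {
  times <- traj$times
  fc <- traj$fold_change
  if (length(times) < 2) stop("need at least 2 timepoints")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  pracma::trapz(times, pmax(fc - 1, 0))
}

#' Scalar features of a CI trajectory
#'
#' Extracts the time to maximum (`t_max`), the adaptation time (`t_adapt`)
#' and the trapezoidal area under the counts. `t_adapt` is operationalized
#' as the first time after the peak at which counts fall to or below
#' `adapt_fraction * peak` and remain there for the rest of the trace; if
#' counts never do, `t_adapt` is the last timepoint and the result is
#' flagged right-censored.
#'
#' @param ci a [ci_trajectory()].
#' @param adapt_fraction fraction of the peak defining return-to-baseline
#'   (default 0.1).
#' @return list with `t_max`, `t_adapt`, `auc`, and logical flags
#'   `undefined` (all-zero trace) and `right_censored`.
#' @export
ci_features <- function(ci, adapt_fraction = 0.1) {
  times <- ci$times
  counts <- ci$counts
  auc <- if (length(times) >= 2) pracma::trapz(times, counts) else 0
  if (all(counts <= 0)) {
    return(list(t_max = NA_real_, t_adapt = NA_real_, auc = 0,
                undefined = TRUE, right_censored = FALSE))
  }
  peak_idx <- which.max(counts)            # first occurrence on ties
  peak <- counts[peak_idx]
  thr <- adapt_fraction * peak
  below <- counts <= thr
  # first index after the peak from which the trace stays at/below threshold
  idx <- NA_integer_
  if (peak_idx < length(counts)) {
    for (i in seq(peak_idx + 1L, length(counts))) {
      if (all(below[i:length(counts)])) { idx <- i; break }
    }
  }
  censored <- is.na(idx)
  t_adapt <- if (censored) times[length(times)] else times[idx]
  list(t_max = times[peak_idx], t_adapt = t_adapt, auc = auc,
       undefined = FALSE, right_censored = censored)
}

#' Locate the onset of nuclear NF-kB decay
#'
#' The decay onset is the global maximum of the fold-change trace (first
#' index on ties). Trajectories whose maximum never exceeds 1 are
#' non-responders: no decay phase exists and the export score is undefined.
#'
#' @param traj an [nfkb_trajectory()].
#' @param min_rise numeric tolerance: a maximum below `1 + min_rise` counts
#'   as never responding (default 1e-6, guarding solver-level jitter around
#'   baseline).
#' @return integer index of the onset, or `NA` with attribute
#'   `non_responder = TRUE` when the trace never rises above 1.
#' @export
find_decay_onset <- function(traj, min_rise = 1e-6) {
  fc <- traj$fold_change
  if (max(fc) <= 1 + min_rise) {
    return(structure(NA_integer_, non_responder = TRUE))
  }
  which.max(fc)
}

#' Zero- versus first-order nuclear export score
#'
#' Fits two decay models to the fold-change trace from its decay onset (the
#' global maximum) to the last sample, with time measured from the onset:
#' a zero-order (linear) model `y = m t + b` by unconstrained least squares,
#' and a first-order (exponential) model `y = N0 exp(-k t)` with `N0` fixed
#' to the fold change at onset and `k` optimized subject to a floor of
#' 0.0167 per minute. The floor corresponds to ~95% nuclear exit within
#' 180 min; slower-than-floor decays cannot be represented by the
#' exponential model and are thereby classified as pseudo-zero-order. The
#' score is the signed difference of the two model misfits, oriented so
#' that positive values mean the zero-order (linear) model fits better --
#' zero-order export kinetics -- and negative values mean the first-order
#' (exponential) model fits better.
#'
#' @param traj an [nfkb_trajectory()].
#' @param k_min,k_max bounds on the exponential rate (per minute). Only the
#'   floor is biologically prescribed; the ceiling is a generous numerical
#'   bound.
#' @return list of class `export_score` with `score`, `m`, `b`, `N0`, `k`,
#'   `sse_zero`, `sse_first`, `onset_index`, `order_class` (`"zero"` or
#'   `"first"`), and `undefined` flag (non-responders or < 4 post-onset
#'   points).
#' @export
export_order_score <- function(traj, k_min = 0.0167, k_max = 10) {
  undefined <- list(score = NA_real_, m = NA_real_, b = NA_real_,
                    N0 = NA_real_, k = NA_real_, sse_zero = NA_real_,
                    sse_first = NA_real_, onset_index = NA_integer_,
                    order_class = NA_character_, undefined = TRUE)
  onset <- find_decay_onset(traj)
  if (is.na(onset)) return(structure(undefined, class = "export_score"))
  idx <- seq(onset, length(traj$times))
  if (length(idx) < 4) return(structure(undefined, class = "export_score"))
  t_rel <- traj$times[idx] - traj$times[onset]
  y <- traj$fold_change[idx]

  lin <- stats::lm.fit(cbind(1, t_rel), y)
  b <- lin$coefficients[1]; m <- lin$coefficients[2]
  sse_zero <- sum(lin$residuals^2)

  N0 <- y[1]
  sse_exp <- function(k) sum((y - N0 * exp(-k * t_rel))^2)
  opt <- stats::optimize(sse_exp, lower = k_min, upper = k_max, tol = 1e-10)
  # optimize() never evaluates the boundary exactly; the floor is a hard
  # constraint, so compare against it explicitly
  k <- opt$minimum; sse_first <- opt$objective
  if (sse_exp(k_min) <= sse_first) { k <- k_min; sse_first <- sse_exp(k_min) }
  score <- sse_first - sse_zero
  structure(list(score = score, m = unname(m), b = unname(b), N0 = N0,
                 k = k, sse_zero = sse_zero, sse_first = sse_first,
                 onset_index = onset,
                 order_class = if (score > 0) "zero" else "first",
                 undefined = FALSE),
            class = "export_score")
}

#' Elbow threshold of a set of per-cell SSE values
#'
#' Builds the curve of candidate threshold versus number of cells whose SSE
#' exceeds the threshold (candidates swept over the sorted unique SSEs),
#' connects its first and last points with a straight line, and returns the
#' candidate at maximum perpendicular distance from that line. Both axes are
#' min--max normalized to \[0, 1\] before measuring distances so the elbow
#' is invariant to the units of SSE. Ties break toward the smaller
#' threshold.
#'
#' @param sse_values numeric vector of per-cell SSEs (>= 3 distinct values).
#' @return the elbow SSE threshold; attribute `degenerate = TRUE` when all
#'   points fall on the connecting line (the smallest candidate is returned
#'   with a warning).
#' @export
elbow_threshold <- function(sse_values) {
  s <- sort(unique(sse_values[is.finite(sse_values)]))
  if (length(s) < 3) stop("need at least 3 distinct SSE values")
  n_above <- vapply(s, function(th) sum(sse_values > th), numeric(1))
  x <- (s - s[1]) / (s[length(s)] - s[1])
  y <- if (max(n_above) == min(n_above)) rep(0, length(s)) else
    (n_above - min(n_above)) / (max(n_above) - min(n_above))
  # distance from (x, y) to the line through the first and last points
  x0 <- x[1]; y0 <- y[1]; x1 <- x[length(x)]; y1 <- y[length(y)]
  dx <- x1 - x0; dy <- y1 - y0
  len <- sqrt(dx^2 + dy^2)
  d <- abs(dy * (x - x0) - dx * (y - y0)) / len
  if (max(d) < 1e-12) {
    warning("degenerate elbow: all points collinear; returning smallest candidate")
    return(structure(s[1], degenerate = TRUE))
  }
  s[which.max(d)]                          # which.max takes the first = smaller
}

#' Classify per-cell prediction quality against an elbow threshold
#'
#' Cells with SSE at or below half the elbow are `excellent`, between half
#' the elbow and the elbow `high`, above the elbow `low` (boundaries
#' inclusive toward the better class).
#'
#' @param sse_per_cell named numeric vector of per-cell SSEs.
#' @param elbow elbow SSE threshold (> 0), e.g. from [elbow_threshold()].
#' @return list of class `fit_quality_report` with `sse_per_cell`,
#'   `elbow_threshold`, `excellent_threshold` (= elbow/2), `labels` (named
#'   character), and `counts`.
#' @export
classify_fits <- function(sse_per_cell, elbow) {
  if (elbow <= 0) stop("elbow threshold must be > 0")
  exc <- elbow / 2
  labels <- ifelse(sse_per_cell <= exc, "excellent",
                   ifelse(sse_per_cell <= elbow, "high", "low"))
  names(labels) <- names(sse_per_cell)
  counts <- c(excellent = sum(labels == "excellent"),
              high = sum(labels == "high"),
              low = sum(labels == "low"))
  structure(list(sse_per_cell = sse_per_cell, elbow_threshold = elbow,
                 excellent_threshold = exc, labels = labels, counts = counts),
            class = "fit_quality_report")
}

#' Feature table for a cohort of paired trajectories
#'
#' Convenience wrapper computing, per cell: NF-kB fold-change AUC, CI AUC,
#' `t_max`, `t_adapt`, the export-order score and its class.
#'
#' @param ci_list list of [ci_trajectory()].
#' @param nfkb_list list of paired [nfkb_trajectory()] (same order).
#' @param adapt_fraction passed to [ci_features()].
#' @return data.frame with one row per cell.
#' @export
feature_table <- function(ci_list, nfkb_list, adapt_fraction = 0.1) {
  stopifnot(length(ci_list) == length(nfkb_list))
  rows <- lapply(seq_along(ci_list), function(i) {
    ci <- ci_list[[i]]; nf <- nfkb_list[[i]]
    cf <- ci_features(ci, adapt_fraction)
    es <- export_order_score(nf)
    data.frame(cell_id = ci$cell_id, condition = ci$condition,
               auc_nfkb = auc_fold_change(nf), auc_ci = cf$auc,
               t_max = cf$t_max, t_adapt = cf$t_adapt,
               export_score = es$score,
               order_class = if (es$undefined) NA_character_ else es$order_class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
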