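#' Generate a synthetic dual-reporter cohort
#'
#' Builds paired single-cell CI (receptor-complex count) and nuclear NF-kB
#' fold-change trajectories from a known ground-truth parameter set, as a
#' stand-in for dual-reporter live-cell data. Per cell, the condition
#' template's peak height and adaptation time are jittered multiplicatively
#' (lognormal with log-sd `ci_jitter`), the jittered triangle is fitted to
#' a Gaussian sum and fed through the model, and additive Gaussian
#' measurement noise (sd `noise_sd`, floored at 0) is applied to the fold
#' change. The t = 0 sample is the normalization reference of a
#' fold-change trace and is therefore exactly 1 by construction, as in the
#' experimental quantification.
#'
#' One master seed fully determines the cohort; each cell consumes its own
#' derived substream (`seed + 1000003 * cell counter`), so any subset of
#' cells is reproducible in isolation.
#'
#' @param ground_truth `nfkb_params` used as the data-generating truth.
#' @param templates named list of [ci_trajectory()] condition templates,
#'   e.g. from [make_pulse_condition_library()].
#' @param n_cells_per_condition cells per condition (default 20).
#' @param ci_jitter lognormal log-sd of the per-cell peak/adaptation jitter
#'   (default 0.1; 0 disables).
#' @param noise_sd additive Gaussian noise sd on fold change (default
#'   0.05; 0 disables).
#' @param seed integer master seed.
#' @return object of class `synthetic_cohort`: lists `ci_trajectories` and
#'   `nfkb_trajectories` paired by position and `cell_id`, plus
#'   `ground_truth`, `noise_spec`, `seed`, and `dropped` (cells whose
#'   simulation failed; never silently imputed).
#' @export
generate_cohort <- function(ground_truth, templates, n_cells_per_condition = 20,
                            ci_jitter = 0.1, noise_sd = 0.05, seed = 1) {
  model <- build_model("d2fc2", params = ground_truth)
  steady <- run_to_steady_state(model)
  if (steady$R <= 0.01 || steady$R >= 0.3)
    stop("ground truth fails the basal nuclear/cytoplasmic heuristic band")
  ci_out <- list(); nf_out <- list(); dropped <- character()
  counter <- 0L
  for (cond in names(templates)) {
    tpl <- templates[[cond]]
    horizon <- max(tpl$times)
    dt <- tpl$times[2] - tpl$times[1]
    for (j in seq_len(n_cells_per_condition)) {
      counter <- counter + 1L
      cell_id <- sprintf("%s_c%02d", cond, j)
      set.seed((seed + 1000003 * counter) %% .Machine$integer.max)
      ci <- if (all(tpl$counts == 0)) {
        ci_trajectory(tpl$times, tpl$counts, cell_id = cell_id, condition = cond)
      } else {
        pk <- tpl$meta$peak_height * exp(stats::rnorm(1, 0, ci_jitter))
        ad <- tpl$meta$adaptation_time * exp(stats::rnorm(1, 0, ci_jitter))
        ad <- min(max(ad, tpl$meta$peak_time + 2 * dt), horizon)
        make_triangular_ci(pk, ad, peak_time = tpl$meta$peak_time,
                           n_points = length(tpl$times), dt = dt,
                           smooth_window = tpl$meta$smooth_window,
                           cell_id = cell_id, condition = cond)
      }
      sim <- try(simulate_response(model, ci_input = ci, steady = steady,
                                   horizon_min = horizon, dt_out_min = dt),
                 silent = TRUE)
      if (inherits(sim, "try-error")) {
        warning("simulation failed for cell ", cell_id, "; cell dropped")
        dropped <- c(dropped, cell_id)
        next
      }
      fc <- sim$fold_change
      if (noise_sd > 0) {
        fc[-1] <- pmax(fc[-1] + stats::rnorm(length(fc) - 1, 0, noise_sd), 0)
      }
      fc[1] <- 1
      ci_out[[length(ci_out) + 1L]] <- ci
      nf_out[[length(nf_out) + 1L]] <-
        nfkb_trajectory(sim$times, fc, cell_id = cell_id, condition = cond)
    }
  }
  structure(list(ci_trajectories = ci_out, nfkb_trajectories = nf_out,
                 ground_truth = ground_truth,
                 noise_spec = list(ci_jitter = ci_jitter, noise_sd = noise_sd),
                 seed = seed, dropped = dropped),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  conds <- table(vapply(x$ci_trajectories, function(ci) ci$condition, ""))
  cat(sprintf("<synthetic_cohort> %d cells (%s); seed %d; jitter %.2f, noise sd %.3f\n",
              length(x$ci_trajectories),
              paste(names(conds), conds, sep = ":", collapse = ", "),
              x$seed, x$noise_spec$ci_jitter, x$noise_spec$noise_sd))
  invisible(x)
}

#' Split a cohort by condition
#'
#' @param cohort a `synthetic_cohort`.
#' @return named list: per condition, a list with `ci` and `nfkb`
#'   trajectory lists.
#' @export
split_cohort <- function(cohort) {
  conds <- vapply(cohort$ci_trajectories, function(ci) ci$condition, "")
  out <- list()
  for (cond in unique(conds)) {
    idx <- which(conds == cond)
    out[[cond]] <- list(ci = cohort$ci_trajectories[idx],
                        nfkb = cohort$nfkb_trajectories[idx])
  }
  out
}

#' Write a cohort to long-format CSV with a JSON sidecar
#'
#' The CSV has columns `cell_id, condition, time_min, ci_count, nfkb_fc`;
#' the sidecar (same path with extension `.json`) stores the ground-truth
#' parameters, noise specification and master seed for full
#' reproducibility.
#'
#' @param cohort a `synthetic_cohort`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- trajectories_to_df(cohort$ci_trajectories, cohort$nfkb_trajectories)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(ground_truth = unclass(cohort$ground_truth),
         noise_spec = cohort$noise_spec, seed = cohort$seed,
         dropped = cohort$dropped),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort from long-format CSV (+ optional JSON sidecar)
#'
#' @param path CSV path as written by [write_cohort_csv()].
#' @return a `synthetic_cohort` (with `ground_truth` of class
#'   `nfkb_params` when the sidecar is present, else `NULL`).
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "condition", "time_min", "ci_count", "nfkb_fc")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  ci_out <- list(); nf_out <- list()
  for (id in unique(df$cell_id)) {
    d <- df[df$cell_id == id, ]
    d <- d[order(d$time_min), ]
    ci_out[[length(ci_out) + 1L]] <-
      ci_trajectory(d$time_min, d$ci_count, cell_id = id,
                    condition = d$condition[1])
    nf_out[[length(nf_out) + 1L]] <-
      nfkb_trajectory(d$time_min, d$nfkb_fc, cell_id = id,
                      condition = d$condition[1])
  }
  gt <- NULL; noise <- NULL; seed <- NA_integer_; dropped <- character()
  sidecar <- sub("\\.csv$", ".json", path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    gt <- structure(as.list(meta$ground_truth), class = "nfkb_params")
    noise <- meta$noise_spec; seed <- meta$seed
    dropped <- as.character(meta$dropped)
  }
  structure(list(ci_trajectories = ci_out, nfkb_trajectories = nf_out,
                 ground_truth = gt, noise_spec = noise, seed = seed,
                 dropped = dropped),
            class = "synthetic_cohort")
}

#' Read CI trajectories from a spreadsheet of fitted Gaussian parameters
#'
#' Reads sheets shaped like published modeled-IKK-trajectory
#' workbooks: one row per trajectory, identified by condition and cell
#' columns, carrying either the 12 Gaussian-sum parameters or sampled
#' counts in per-timepoint columns. The exact column layout is
#' configurable because such workbooks are not standardized.
#'
#' @param path `.xlsx` (requires the readxl package) or `.csv` file.
#' @param layout list describing the sheet: `condition_col`, `cell_col`,
#'   and either `gaussian_cols` (12 column names, order a1..a4, b1..b4,
#'   c1..c4, minutes) or `count_cols` (per-timepoint column names);
#'   `times` (minutes) required with `count_cols`, defaults to the
#'   46-point 4-min grid.
#' @param sheet sheet index or name for Excel input.
#' @return list of [ci_trajectory()] (for `count_cols`) or
#'   `gaussian_sum_fit`-like forcing objects (for `gaussian_cols`), each
#'   tagged with cell and condition.
#' @export
read_ikk_trajectory_table <- function(path, layout, sheet = 1) {
  df <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx requires the readxl package")
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  }
  stopifnot(is.list(layout), !is.null(layout$condition_col),
            !is.null(layout$cell_col))
  out <- list()
  if (!is.null(layout$gaussian_cols)) {
    stopifnot(length(layout$gaussian_cols) == 12)
    for (i in seq_len(nrow(df))) {
      g <- as.numeric(df[i, layout$gaussian_cols])
      out[[i]] <- structure(
        list(a = g[1:4], b = g[5:8], c = g[9:12], sse = NA_real_,
             zero_anchor_weight = NA_real_,
             cell_id = as.character(df[i, layout$cell_col]),
             condition = as.character(df[i, layout$condition_col])),
        class = "gaussian_sum_fit")
    }
  } else if (!is.null(layout$count_cols)) {
    times <- layout$times
    if (is.null(times)) times <- (seq_along(layout$count_cols) - 1) * 4
    for (i in seq_len(nrow(df))) {
      out[[i]] <- ci_trajectory(
        times, as.numeric(df[i, layout$count_cols]),
        cell_id = as.character(df[i, layout$cell_col]),
        condition = as.character(df[i, layout$condition_col]))
    }
  } else {
    stop("layout must supply gaussian_cols or count_cols")
  }
  out
}
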