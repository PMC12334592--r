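#' Basal-localization heuristic penalty
#'
#' Soft constraint on the pre-stimulus nuclear/cytoplasmic NF-kB ratio `R`
#' added to the calibration objective: 0 inside the accepted band
#' `0.01 < R < 0.3`; a flat 100 when `R <= 0.01` (essentially no nuclear
#' NF-kB -- strongly penalized); `5 * R` when `R >= 0.3` (penalty
#' proportional to the excess). Boundary points belong to the penalized
#' branches.
#'
#' @param R nuclear/cytoplasmic NF-kB ratio, >= 0.
#' @return penalty value.
#' @export
nfkb_heuristic <- function(R) {
  stopifnot(R >= 0)
  if (R > 0.01 && R < 0.3) 0 else if (R <= 0.01) 100 else 5 * R
}

#' Condition-average training/validation entries from a cohort
#'
#' Averages CI counts and NF-kB fold change across the cells of each
#' condition, producing the mean-trajectory pairs used for calibration.
#'
#' @param cohort a `synthetic_cohort` (or compatible list).
#' @param conditions which conditions to include (default: all present).
#' @return named list; per condition, `ci` (mean [ci_trajectory()]),
#'   `target` (mean [nfkb_trajectory()]), and `ci_fit` (Gaussian-sum fit
#'   of the mean CI, ready to use as model forcing).
#' @export
condition_averages <- function(cohort, conditions = NULL) {
  parts <- split_cohort(cohort)
  if (is.null(conditions)) conditions <- names(parts)
  out <- list()
  for (cond in conditions) {
    p <- parts[[cond]]
    if (is.null(p)) stop("condition not in cohort: ", cond)
    times <- p$ci[[1]]$times
    ci_mean <- rowMeans(vapply(p$ci, function(x) x$counts,
                               numeric(length(times))))
    fc_mean <- rowMeans(vapply(p$nfkb, function(x) x$fold_change,
                               numeric(length(times))))
    fc_mean[1] <- 1
    ci <- ci_trajectory(times, ci_mean, cell_id = "mean", condition = cond)
    out[[cond]] <- list(
      ci = ci,
      target = nfkb_trajectory(times, fc_mean, cell_id = "mean",
                               condition = cond),
      ci_fit = fit_gaussian_sum(ci))
  }
  out
}

# Large finite sentinel returned when a proposed parameter set crashes the
# solver, so the swarm keeps moving instead of aborting.
.J_SENTINEL <- 1e8

#' Calibration objective
#'
#' The composite least-squares objective minimized during calibration:
#' the model is equilibrated, each training condition is simulated from
#' its average CI input, and squared fold-change residuals are summed over
#' all timepoints and conditions; the basal-localization heuristic
#' ([nfkb_heuristic()]) evaluated at the pre-stimulus ratio is added.
#' Simulation failures yield a large finite sentinel (1e8).
#'
#' @param params `nfkb_params` to evaluate.
#' @param train named list as returned by [condition_averages()].
#' @param variant model variant string.
#' @return scalar objective J >= 0.
#' @export
objective <- function(params, train, variant = "d2fc2") {
  model <- build_model(variant, params = params)
  out <- try({
    steady <- run_to_steady_state(model)
    J <- nfkb_heuristic(steady$R)
    for (cond in names(train)) {
      entry <- train[[cond]]
      sim <- simulate_response(model, ci_input = entry$ci_fit, steady = steady,
                               horizon_min = max(entry$target$times),
                               dt_out_min = diff(entry$target$times[1:2]))
      J <- J + sum((entry$target$fold_change - sim$fold_change)^2)
    }
    J
  }, silent = TRUE)
  if (inherits(out, "try-error") || !is.finite(out)) .J_SENTINEL else out
}

#' Build a log10-space objective over selected free parameters
#'
#' Returns a closure mapping a vector of log10 parameter values (in the
#' order of `free_names`) to the calibration objective, with all other
#' parameters fixed at `base_params`. This is the function handed to the
#' particle swarm.
#'
#' @param train [condition_averages()] output.
#' @param base_params full `nfkb_params` supplying the fixed parameters.
#' @param free_names character names of the optimized parameters.
#' @param variant model variant.
#' @return function(log10 values) -> J.
#' @export
make_objective <- function(train, base_params, free_names,
                           variant = "d2fc2") {
  force(train); force(base_params); force(free_names); force(variant)
  function(x) {
    p <- base_params
    for (j in seq_along(free_names)) p[[free_names[j]]] <- 10^x[j]
    objective(p, train, variant = variant)
  }
}

#' Default log10 bounds for calibration
#'
#' Prior search ranges for the optimized parameters: a symmetric window of
#' `half_width` decades around the reference values, mirroring a
#' biophysically-plausible-range prior. Hill exponents, fixed constants
#' and totals are not included by default.
#'
#' @param params reference `nfkb_params` (centers).
#' @param free_names parameters to bound (default: the DNA-binding module
#'   plus the CI-coupling rate, the set the chromatin-pioneering extension
#'   introduces).
#' @param half_width decades on each side (default 1).
#' @return matrix with rows `lower`, `upper` and one column per free
#'   parameter (log10 units).
#' @export
default_bounds <- function(params,
                           free_names = c("ka", "ka1d", "kdNFKB", "Ps",
                                          "KDNA", "ka2a", "kd1d"),
                           half_width = 1) {
  ctr <- log10(unlist(params[free_names]))
  rbind(lower = ctr - half_width, upper = ctr + half_width)
}

#' Global-best particle swarm optimization
#'
#' Standard global-best PSO with inertia and cognitive/social
#' acceleration, reflecting the common default coefficients (inertia
#' 0.729, c1 = c2 = 1.49445). Particles are clamped to the bounds
#' (clamp-and-log policy: the velocity component is zeroed on contact).
#' The run stops when the global best has failed to improve by more than
#' `fun_tol` (relative) for `stall_iterations` consecutive iterations, or
#' at `max_iter`. Fully reproducible via `seed`.
#'
#' @param fn objective function of a numeric vector.
#' @param bounds 2 x k matrix (rows lower/upper), e.g. from
#'   [default_bounds()].
#' @param swarm_size particles (default 100).
#' @param stall_iterations stop after this many non-improving iterations
#'   (default 20).
#' @param max_iter hard cap (default 1000).
#' @param inertia,c1,c2 PSO coefficients.
#' @param fun_tol relative improvement below which an iteration counts as
#'   stalled (default 1e-6).
#' @param seed integer seed.
#' @return list with `par` (best position), `value`, `history` (global
#'   best per iteration), `n_iter`, `n_evals`.
#' @export
run_pso <- function(fn, bounds, swarm_size = 100, stall_iterations = 20,
                    max_iter = 1000, inertia = 0.729, c1 = 1.49445,
                    c2 = 1.49445, fun_tol = 1e-6, seed = 1) {
  stopifnot(nrow(bounds) == 2, all(is.finite(bounds)))
  lower <- bounds[1, ]; upper <- bounds[2, ]
  k <- length(lower)
  rng <- upper - lower
  set.seed(seed)
  X <- matrix(stats::runif(swarm_size * k), swarm_size, k)
  X <- sweep(sweep(X, 2, rng, "*"), 2, lower, "+")
  V <- matrix(stats::runif(swarm_size * k, -1, 1), swarm_size, k)
  V <- sweep(V, 2, 0.25 * rng, "*")
  fvals <- apply(X, 1, fn)
  Pbest <- X; pbest_f <- fvals
  g <- which.min(fvals)
  gbest <- X[g, ]; gbest_f <- fvals[g]
  history <- gbest_f
  n_evals <- swarm_size
  stall <- 0L; iter <- 0L
  while (iter < max_iter && stall < stall_iterations) {
    iter <- iter + 1L
    r1 <- matrix(stats::runif(swarm_size * k), swarm_size, k)
    r2 <- matrix(stats::runif(swarm_size * k), swarm_size, k)
    V <- inertia * V +
      c1 * r1 * (Pbest - X) +
      c2 * r2 * (matrix(gbest, swarm_size, k, byrow = TRUE) - X)
    vmax <- matrix(rng, swarm_size, k, byrow = TRUE)
    V <- pmin(pmax(V, -vmax), vmax)
    X <- X + V
    for (j in seq_len(k)) {
      lo <- X[, j] < lower[j]; hi <- X[, j] > upper[j]
      X[lo, j] <- lower[j]; X[hi, j] <- upper[j]
      V[lo | hi, j] <- 0
    }
    fvals <- apply(X, 1, fn)
    n_evals <- n_evals + swarm_size
    imp <- fvals < pbest_f
    Pbest[imp, ] <- X[imp, ]; pbest_f[imp] <- fvals[imp]
    g <- which.min(pbest_f)
    new_best <- pbest_f[g]
    rel_gain <- (gbest_f - new_best) / max(abs(gbest_f), 1e-12)
    if (new_best < gbest_f) { gbest <- Pbest[g, ]; }
    stall <- if (rel_gain > fun_tol) 0L else stall + 1L
    gbest_f <- min(gbest_f, new_best)
    history <- c(history, gbest_f)
  }
  list(par = stats::setNames(gbest, colnames(bounds)), value = gbest_f,
       history = history, n_iter = iter, n_evals = n_evals)
}

#' Calibrate model parameters by repeated particle-swarm runs
#'
#' Runs `n_replicates` independent PSO replicates of the calibration
#' objective (each with its own derived seed) and collects the
#' best-found parameter set and objective per replicate, ranked by
#' objective.
#'
#' @param train [condition_averages()] output (training conditions).
#' @param base_params full `nfkb_params` for the fixed parameters.
#' @param free_names optimized parameter names (log10 space).
#' @param bounds 2 x k log10 bounds; default [default_bounds()] around
#'   `base_params`.
#' @param variant model variant.
#' @param n_replicates PSO repeats (default 10; increase for production
#'   fits).
#' @param seed master seed; replicate r uses `seed + 7919 * r`.
#' @param ... passed to [run_pso()] (`swarm_size`, `stall_iterations`,
#'   ...).
#' @return object of class `calibration_result`: `replicates` (list of
#'   `par` in log10, `params` as `nfkb_params`, `value`, `n_iter`),
#'   `ranking` (by objective), `free_names`, `bounds`, `seed`.
#' @export
calibrate <- function(train, base_params, free_names = NULL, bounds = NULL,
                      variant = "d2fc2", n_replicates = 10, seed = 1, ...) {
  if (is.null(free_names))
    free_names <- c("ka", "ka1d", "kdNFKB", "Ps", "KDNA", "ka2a", "kd1d")
  if (is.null(bounds)) bounds <- default_bounds(base_params, free_names)
  colnames(bounds) <- free_names
  fn <- make_objective(train, base_params, free_names, variant)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    res <- run_pso(fn, bounds, seed = (seed + 7919 * r) %% .Machine$integer.max, ...)
    p <- base_params
    for (j in seq_along(free_names)) p[[free_names[j]]] <- 10^res$par[j]
    reps[[r]] <- list(par = res$par, params = p, value = res$value,
                      n_iter = res$n_iter)
  }
  vals <- vapply(reps, `[[`, numeric(1), "value")
  structure(list(replicates = reps, ranking = order(vals),
                 free_names = free_names, bounds = bounds, seed = seed,
                 variant = variant),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  vals <- vapply(x$replicates, `[[`, numeric(1), "value")
  cat(sprintf("<calibration_result> %s, %d replicates; J best %.4g, median %.4g\n",
              x$variant, length(vals), min(vals), stats::median(vals)))
  invisible(x)
}

#' Emergent-property score
#'
#' Discrepancy between experimental and simulated median-AUC ratios across
#' the pulse-train and long-pulse conditions, relative to the single
#' 6-minute pulse:
#' `|med(AUC_4x1.5)/med(AUC_1x6) - med(sim 4x1.5)/med(sim 1x6)| +
#'  |med(AUC_1x15)/med(AUC_1x6) - med(sim 1x15)/med(sim 1x6)|`.
#' Experimental medians are over single cells; simulated medians over
#' per-cell predictions. The score is invariant to common rescaling of
#' all simulated (or all experimental) AUCs.
#'
#' @param sim_aucs named list of numeric AUC vectors with elements
#'   `"1x6"`, `"1x15"`, `"4x1.5"` (per-cell simulated predictions).
#' @param exp_aucs same shape, experimental per-cell AUCs.
#' @return nonnegative score; 0 when the ratios agree exactly.
#' @export
emergent_property_score <- function(sim_aucs, exp_aucs) {
  need <- c("1x6", "1x15", "4x1.5")
  if (!all(need %in% names(sim_aucs)) || !all(need %in% names(exp_aucs)))
    stop("AUC lists must contain conditions ", paste(need, collapse = ", "))
  m_exp <- vapply(exp_aucs[need], stats::median, numeric(1))
  m_sim <- vapply(sim_aucs[need], stats::median, numeric(1))
  if (m_exp[["1x6"]] == 0 || m_sim[["1x6"]] == 0)
    stop("zero median AUC for the reference 1x6 condition")
  abs(m_exp[["4x1.5"]] / m_exp[["1x6"]] - m_sim[["4x1.5"]] / m_sim[["1x6"]]) +
    abs(m_exp[["1x15"]] / m_exp[["1x6"]] - m_sim[["1x15"]] / m_sim[["1x6"]])
}

#' Simulate per-cell predictions and their fold-change AUCs
#'
#' @param params `nfkb_params`.
#' @param ci_list list of per-cell [ci_trajectory()] inputs.
#' @param variant model variant.
#' @param steady optional precomputed steady state.
#' @return list with `sims` (per-cell `simulation_result` or `NULL` on
#'   failure) and `aucs` (named per-cell AUC vector, `NA` for failures).
#' @export
simulate_cells <- function(params, ci_list, variant = "d2fc2", steady = NULL) {
  model <- build_model(variant, params = params)
  if (is.null(steady)) steady <- run_to_steady_state(model)
  sims <- vector("list", length(ci_list))
  aucs <- rep(NA_real_, length(ci_list))
  names(aucs) <- vapply(ci_list, function(ci) ci$cell_id, "")
  for (i in seq_along(ci_list)) {
    ci <- ci_list[[i]]
    sim <- try(simulate_response(model, ci_input = ci, steady = steady,
                                 horizon_min = max(ci$times),
                                 dt_out_min = diff(ci$times[1:2])),
               silent = TRUE)
    if (inherits(sim, "try-error")) next
    sims[[i]] <- sim
    aucs[i] <- auc_fold_change(sim_to_nfkb_trajectory(sim))
  }
  list(sims = sims, aucs = aucs)
}

#' Evaluate the three post-hoc error criteria for a parameter set
#'
#' Computes (i) the emergent-property score from per-cell simulations of
#' the 1x6, 1x15 and 4x1.5 condition inputs, (ii) the mean per-condition
#' SSE against the training conditions, and (iii) the total SSE against
#' the validation conditions.
#'
#' @param params `nfkb_params` to score.
#' @param train,validation [condition_averages()]-shaped lists.
#' @param single_cells named list (conditions `1x6`, `1x15`, `4x1.5`),
#'   each with `ci` (list of per-cell CI inputs) and `nfkb` (paired
#'   experimental trajectories), e.g. from [split_cohort()].
#' @param variant model variant.
#' @return list with `ep_score`, `mean_train_sse`, `validation_sse`.
#' @export
evaluate_criteria <- function(params, train, validation, single_cells,
                              variant = "d2fc2") {
  model <- build_model(variant, params = params)
  steady <- try(run_to_steady_state(model), silent = TRUE)
  if (inherits(steady, "try-error"))
    return(list(ep_score = NA_real_, mean_train_sse = .J_SENTINEL,
                validation_sse = .J_SENTINEL))
  cond_sse <- function(entries) {
    vapply(entries, function(entry) {
      sim <- try(simulate_response(model, ci_input = entry$ci_fit,
                                   steady = steady,
                                   horizon_min = max(entry$target$times),
                                   dt_out_min = diff(entry$target$times[1:2])),
                 silent = TRUE)
      if (inherits(sim, "try-error")) return(.J_SENTINEL)
      sum((entry$target$fold_change - sim$fold_change)^2)
    }, numeric(1))
  }
  sim_aucs <- list(); exp_aucs <- list()
  for (cond in c("1x6", "1x15", "4x1.5")) {
    sc <- single_cells[[cond]]
    if (is.null(sc)) stop("single_cells must include condition ", cond)
    res <- simulate_cells(params, sc$ci, variant = variant, steady = steady)
    sim_aucs[[cond]] <- res$aucs[is.finite(res$aucs)]
    exp_aucs[[cond]] <- vapply(sc$nfkb, auc_fold_change, numeric(1))
  }
  list(ep_score = emergent_property_score(sim_aucs, exp_aucs),
       mean_train_sse = mean(cond_sse(train)),
       validation_sse = sum(cond_sse(validation)))
}

#' Predict single cells and classify prediction quality
#'
#' For each cell, the CI input is fitted to a Gaussian sum, the model is
#' simulated, and the SSE against the observed fold change is recorded.
#' The pooled SSEs are thresholded with [elbow_threshold()] and
#' [classify_fits()] into excellent / high / low classes; cells whose
#' simulation fails are labeled `"failed"` and excluded from the elbow.
#'
#' @param params `nfkb_params`.
#' @param ci_list per-cell [ci_trajectory()] inputs.
#' @param nfkb_list paired observed [nfkb_trajectory()] targets.
#' @param variant model variant.
#' @return list with `report` (a `fit_quality_report`), `sse` (named, NA
#'   for failures), `failed` (cell ids), `sims` (per-cell simulations).
#' @export
predict_single_cells <- function(params, ci_list, nfkb_list,
                                 variant = "d2fc2") {
  stopifnot(length(ci_list) == length(nfkb_list))
  res <- simulate_cells(params, ci_list, variant = variant)
  ids <- vapply(ci_list, function(ci) ci$cell_id, "")
  sse <- rep(NA_real_, length(ci_list)); names(sse) <- ids
  for (i in seq_along(ci_list)) {
    if (is.null(res$sims[[i]])) next
    sse[i] <- sum((nfkb_list[[i]]$fold_change - res$sims[[i]]$fold_change)^2)
  }
  failed <- ids[!is.finite(sse)]
  ok <- sse[is.finite(sse)]
  elbow <- elbow_threshold(ok)
  report <- classify_fits(ok, elbow)
  list(report = report, sse = sse, failed = failed, sims = res$sims)
}
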