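#' Scan the CI-encoding feature space
#'
#' Maps downstream signaling features over a grid of CI-trajectory
#' encodings: for each (peak height, adaptation time) pair a triangular
#' CI input is generated (peak fixed at 28 min), Gaussian-fitted and
#' simulated, and four summaries are extracted -- peak nuclear fold
#' change, the export-order score of the simulated trajectory, relative
#' chromatin permissiveness, and (on a separate total x permissiveness
#' grid) the free-NF-kB fraction from the equilibrium sub-model.
#'
#' Relative permissiveness is the time average of
#' `(NPio(t) - Ps0) / Ps` over the simulation horizon (in \[0, 1\]); the
#' final-value alternative is available via `permissiveness = "final"`.
#' Failed grid cells propagate as `NA`, never interpolated.
#'
#' @param params `nfkb_params`.
#' @param peak_grid vector of peak puncta counts.
#' @param t_adapt_grid vector of adaptation times (minutes).
#' @param variant model variant (default `"d2fc2"`).
#' @param permissiveness `"mean"` (default) or `"final"` summary.
#' @param npio_grid,total_grid axes for the free-fraction sub-model
#'   surface (defaults span basal-to-open permissiveness and the
#'   plausible total nuclear NF-kB range).
#' @return object of class `scan_result`: the grids and matrices
#'   `peak_fold_change`, `export_order_score`, `relative_permissiveness`
#'   (each peak x t_adapt) and `free_fraction` (total x npio).
#' @export
scan_feature_space <- function(params, peak_grid, t_adapt_grid,
                               variant = "d2fc2",
                               permissiveness = c("mean", "final"),
                               npio_grid = NULL, total_grid = NULL) {
  permissiveness <- match.arg(permissiveness)
  stopifnot(length(peak_grid) >= 1, length(t_adapt_grid) >= 1)
  model <- build_model(variant, params = params)
  steady <- run_to_steady_state(model)
  np <- length(peak_grid); na <- length(t_adapt_grid)
  dimn <- list(peak = signif(peak_grid, 4), t_adapt = signif(t_adapt_grid, 4))
  pk_fc <- matrix(NA_real_, np, na, dimnames = dimn)
  exp_sc <- matrix(NA_real_, np, na, dimnames = dimn)
  rel_pio <- matrix(NA_real_, np, na, dimnames = dimn)
  for (i in seq_len(np)) {
    for (j in seq_len(na)) {
      cell <- try({
        if (peak_grid[i] <= 0) {
          times <- (0:45) * 4
          ci <- ci_trajectory(times, rep(0, 46))
        } else {
          ci <- make_triangular_ci(peak_grid[i], t_adapt_grid[j])
        }
        sim <- simulate_response(model, ci_input = ci, steady = steady)
        pk_fc[i, j] <- max(sim$fold_change)
        npio_rel <- (sim$npio - params$Ps0) / params$Ps
        rel_pio[i, j] <- if (permissiveness == "mean") mean(npio_rel) else
          npio_rel[length(npio_rel)]
        es <- export_order_score(sim_to_nfkb_trajectory(sim))
        if (!es$undefined) exp_sc[i, j] <- es$score
        NULL
      }, silent = TRUE)
      if (inherits(cell, "try-error")) next
    }
  }
  if (is.null(npio_grid))
    npio_grid <- seq(0, params$Ps0 + params$Ps, length.out = max(na, 2))
  if (is.null(total_grid))
    total_grid <- seq(1e-3, params$NFkBtot / params$vol_ratio,
                      length.out = max(np, 2))
  ikba_ss <- unname(steady$state["IkBan"])
  free_frac <- free_fraction_surface(total_grid, npio_grid, params,
                                     ikba_ss = ikba_ss)
  structure(list(peak_grid = peak_grid, t_adapt_grid = t_adapt_grid,
                 peak_fold_change = pk_fc, export_order_score = exp_sc,
                 relative_permissiveness = rel_pio,
                 free_fraction = free_frac, npio_grid = npio_grid,
                 total_grid = total_grid, variant = variant,
                 permissiveness = permissiveness),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %d x %d (peak x t_adapt) grid, variant %s; %d NA cells\n",
              length(x$peak_grid), length(x$t_adapt_grid), x$variant,
              sum(is.na(x$peak_fold_change))))
  invisible(x)
}

#' Write scan matrices as CSV files
#'
#' One file per matrix (`<prefix>_<name>.csv`), rows labeled by the first
#' grid axis and columns by the second.
#'
#' @param scan a `scan_result`.
#' @param prefix path prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_scan_csv <- function(scan, prefix) {
  mats <- list(peak_fold_change = scan$peak_fold_change,
               export_order_score = scan$export_order_score,
               relative_permissiveness = scan$relative_permissiveness,
               free_fraction = scan$free_fraction)
  paths <- character()
  for (nm in names(mats)) {
    p <- paste0(prefix, "_", nm, ".csv")
    utils::write.csv(mats[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
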