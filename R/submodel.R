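#' Free nuclear NF-kB fraction at fixed chromatin permissiveness
#'
#' Chromatin-opening equilibrium sub-model: only the binding and unbinding
#' of NF-kB to DNA are dynamic, every other species -- in particular
#' nuclear IkBa -- is frozen at its pre-stimulus resting value. Binding
#' follows `ka1d * DCoop(free) * NPio_const * free` with permissiveness
#' held constant (it is the scanned axis), and unbinding is
#' `kd1d * bound + ka2a * IkBa_ss * bound`. The function solves the flux
#' balance for the partition of a fixed total nuclear NF-kB between free
#' and DNA-bound form and returns the free fraction.
#'
#' @param total_nuclear_nfkb total nuclear NF-kB (free + bound), >= 0.
#' @param npio_const constant permissiveness (scanned axis; >= 0).
#' @param p `nfkb_params` (uses `ka1d`, `kdNFKB`, `h2`, `ka2a`, `kd1d`).
#' @param ikba_ss nuclear IkBa held at its resting value. Default taken
#'   from equilibrating the model with `p` when not supplied.
#' @return free fraction in \[0, 1\].
#' @export
free_nfkb_fraction <- function(total_nuclear_nfkb, npio_const, p,
                               ikba_ss = NULL) {
  stopifnot(total_nuclear_nfkb >= 0, npio_const >= 0)
  if (total_nuclear_nfkb == 0) return(1)
  if (npio_const == 0) return(1)
  if (is.null(ikba_ss)) {
    ss <- run_to_steady_state(build_model("d2fc2", params = p))
    ikba_ss <- unname(ss$state["IkBan"])
  }
  koff <- p$kd1d + p$ka2a * ikba_ss
  flux_gap <- function(free) {
    r2 <- (free / p$kdNFKB)^p$h2
    dcoop <- r2 / (1 + r2)
    bind <- p$ka1d * dcoop * npio_const * free
    bind - koff * (total_nuclear_nfkb - free)
  }
  # flux_gap is monotone increasing: <= 0 at free = 0, >= 0 at free = total
  root <- stats::uniroot(flux_gap, c(0, total_nuclear_nfkb),
                         tol = 1e-12 * max(total_nuclear_nfkb, 1))
  root$root / total_nuclear_nfkb
}

#' Free-fraction surface over total NF-kB and permissiveness
#'
#' Evaluates [free_nfkb_fraction()] on a grid, the quantity mapped in the
#' encoding-space scan: even at high total nuclear NF-kB, permissive
#' chromatin can deplete the free pool.
#'
#' @param totals vector of total nuclear NF-kB values.
#' @param npio_values vector of constant permissiveness values.
#' @param p `nfkb_params`.
#' @param ikba_ss nuclear IkBa resting value (computed once if missing).
#' @return matrix `length(totals) x length(npio_values)` of free fractions.
#' @export
free_fraction_surface <- function(totals, npio_values, p, ikba_ss = NULL) {
  if (is.null(ikba_ss)) {
    ss <- run_to_steady_state(build_model("d2fc2", params = p))
    ikba_ss <- unname(ss$state["IkBan"])
  }
  out <- matrix(NA_real_, length(totals), length(npio_values),
                dimnames = list(signif(totals, 4), signif(npio_values, 4)))
  for (i in seq_along(totals)) {
    for (j in seq_along(npio_values)) {
      out[i, j] <- free_nfkb_fraction(totals[i], npio_values[j], p, ikba_ss)
    }
  }
  out
}
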