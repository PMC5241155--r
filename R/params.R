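#' Parameter set for the two-compartment label-propagation model
#'
#' Bundles the kinetic parameters governing the propagation of a pulse of
#' thymine-analog label along a one-dimensional crypt-villus epithelial unit
#' (CVEU). Labeled cells in the crypt grow exponentially at the specific
#' proliferation rate `delta` until they reach the transfer threshold
#' `l_c_star`; from then on the crypt content is constant and labeled cells
#' are transferred to the villus at rate `delta * l_c_star`. Once the villus
#' content reaches `l_v_star`, labeled cells are additionally shed from the
#' villus tip at specific rate `gamma`.
#'
#' The two thresholds are determined by the phase-change times: `l_c_star =
#' l_c0 * exp(delta * (t1 - t0))` and `l_v_star = l_v0 + delta * l_c_star *
#' (t2 - t1)` (see [thresholds_from_times()]); they are computed on
#' construction and stored alongside the primary parameters.
#'
#' @param delta Specific cell proliferation rate within the crypt, per hour;
#'   equal to the specific rate of cell transfer to the villus.
#' @param n_crypt Crypt compartment size in cells; also the position of the
#'   crypt-villus boundary along the CVEU.
#' @param l_c0 Labeled cells in the crypt at `t0`.
#' @param l_v0 Labeled cells on the villus at `t0` (default 0).
#' @param t0 Initial time, hours (default 0).
#' @param t1 Time at which crypt-to-villus transfer of labeled cells begins,
#'   hours. Must satisfy `t1 >= t0`.
#' @param t2 Time at which shedding of labeled cells from the villus tip
#'   begins, hours, or `NULL` when shedding lies beyond the observation
#'   window.
#' @param gamma Specific shedding rate from the villus tip, per hour, or
#'   `NULL` when only the pre-shedding phase is modeled.
#'
#' @return An object of class `"cveu_params"`: a named list with components
#'   `delta`, `gamma`, `n_crypt`, `l_c0`, `l_v0`, `t0`, `t1`, `t2`,
#'   `l_c_star`, `l_v_star`.
#'
#' @examples
#' p <- cveu_params(delta = 0.0760, n_crypt = 20, l_c0 = 8.2, t1 = 10)
#' p$l_c_star
#' @seealso [pre_shedding_solution()], [explicit_solution()], [label_rates()]
#' @export
cveu_params <- function(delta, n_crypt, l_c0, l_v0 = 0, t0 = 0, t1 = t0,
                        t2 = NULL, gamma = NULL) {
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta),
            is.numeric(n_crypt), length(n_crypt) == 1L, n_crypt >= 1,
            is.numeric(l_c0), l_c0 >= 0, is.numeric(l_v0), l_v0 >= 0,
            is.numeric(t0), t0 >= 0, is.numeric(t1))
  if (delta < 0)
    stop("'delta' must be non-negative", call. = FALSE)
  if (t1 < t0)
    stop("'t1' must be >= 't0'", call. = FALSE)
  if (!is.null(t2) && t2 < t1)
    stop("'t2' must be >= 't1'", call. = FALSE)
  if (!is.null(gamma) && gamma < 0)
    stop("'gamma' must be non-negative", call. = FALSE)
  th <- thresholds_from_times(delta, l_c0, l_v0, t0, t1,
                              if (is.null(t2)) t1 else t2)
  if (th[["l_c_star"]] > n_crypt * (1 + 1e-9))
    stop("transfer threshold l_c_star exceeds the crypt size n_crypt; ",
         "check delta, t1 - t0 and l_c0", call. = FALSE)
  structure(list(delta = delta, gamma = gamma, n_crypt = n_crypt,
                 l_c0 = l_c0, l_v0 = l_v0, t0 = t0, t1 = t1, t2 = t2,
                 l_c_star = th[["l_c_star"]],
                 l_v_star = if (is.null(t2)) NULL else th[["l_v_star"]]),
            class = "cveu_params")
}

#' @export
print.cveu_params <- function(x, digits = 4, ...) {
  cat("Two-compartment CVEU label-propagation parameters\n")
  cat(sprintf("  delta   = %.*g /h   n_crypt = %g cells\n",
              digits, x$delta, x$n_crypt))
  cat(sprintf("  L_C0    = %.*g      L_V0    = %.*g cells\n",
              digits, x$l_c0, digits, x$l_v0))
  cat(sprintf("  t0 = %g h, t1 = %g h%s\n", x$t0, x$t1,
              if (is.null(x$t2)) " (no shedding phase)"
              else sprintf(", t2 = %g h, gamma = %.*g /h",
                           x$t2, digits, x$gamma)))
  cat(sprintf("  thresholds: L_C* = %.*g%s\n", digits, x$l_c_star,
              if (is.null(x$l_v_star)) ""
              else sprintf(", L_V* = %.*g", digits, x$l_v_star)))
  invisible(x)
}

#' Transfer and shedding thresholds from the phase-change times
#'
#' The threshold formulation and the time formulation of the model are
#' equivalent: evaluating the pre-shedding solution at `t1` and `t2` gives
#' the labeled-cell counts at which transfer and shedding switch on.
#'
#' @param delta Specific proliferation rate, per hour.
#' @param l_c0,l_v0 Initial labeled cells in crypt and on villus.
#' @param t0,t1,t2 Initial, transfer-onset and shedding-onset times, hours,
#'   with `t2 >= t1 >= t0`.
#'
#' @return Named numeric vector with components `l_c_star` and `l_v_star`.
#' @examples
#' thresholds_from_times(0.076, 8.2, 0, 0, 10, 40)
#' @export
thresholds_from_times <- function(delta, l_c0, l_v0, t0, t1, t2) {
  if (any(c(delta, l_c0, l_v0, t0, t1, t2) < 0))
    stop("all arguments must be non-negative", call. = FALSE)
  if (t1 < t0 || t2 < t1)
    stop("times must satisfy t2 >= t1 >= t0", call. = FALSE)
  l_c_star <- l_c0 * exp(delta * (t1 - t0))
  l_v_star <- l_v0 + delta * l_c_star * (t2 - t1)
  c(l_c_star = l_c_star, l_v_star = l_v_star)
}
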