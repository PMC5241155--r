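#' Instantaneous rates of the two-compartment label model
#'
#' Right-hand side of the threshold-gated ODE system for labeled cells in
#' the crypt (`L_C`) and on the villus (`L_V`):
#'
#' \deqn{dL_C/dt = \delta L_C [1 - H(L_C - L_C^*)]}
#' \deqn{dL_V/dt = \delta L_C H(L_C - L_C^*) - \gamma L_V H(L_V - L_V^*)}
#'
#' where `H` is the Heaviside step function with `H(0) = 1`, so a process is
#' active exactly at its threshold. Below the transfer threshold labeled
#' crypt cells grow exponentially; at the threshold the crypt content is
#' held constant and all production is transferred to the villus; once the
#' villus content reaches its threshold, shedding at specific rate `gamma`
#' also acts.
#'
#' @param params A [cveu_params()] object.
#' @param l_crypt,l_villus Current labeled-cell counts (real-valued; counts
#'   are sums of labeled proportions over CVEUs, not integers).
#'
#' @return Named numeric vector `c(dl_crypt, dl_villus)` in cells/hour.
#' @examples
#' p <- cveu_params(delta = 0.08, n_crypt = 20, l_c0 = 5, t1 = 10)
#' label_rates(p, l_crypt = 5, l_villus = 0)
#' @export
label_rates <- function(params, l_crypt, l_villus) {
  stopifnot(inherits(params, "cveu_params"))
  if (!is.finite(l_crypt) || !is.finite(l_villus))
    stop("labeled-cell state must be finite", call. = FALSE)
  if (l_crypt < 0 || l_villus < 0)
    stop("labeled-cell counts must be non-negative", call. = FALSE)
  h_transfer <- as.numeric(l_crypt >= params$l_c_star)
  h_shed <- if (is.null(params$l_v_star)) 0
            else as.numeric(l_villus >= params$l_v_star)
  gam <- if (is.null(params$gamma)) 0 else params$gamma
  c(dl_crypt = params$delta * l_crypt * (1 - h_transfer),
    dl_villus = params$delta * l_crypt * h_transfer -
      gam * l_villus * h_shed)
}

# unvalidated piecewise evaluation; tolerates any real delta (needed when
# fitting arrest-phase data where delta may be estimated below zero, in
# which case t1 = t0 and only the linear phase exists)
.pre_shedding <- function(delta, l_c0, l_v0, t0, t1, times) {
  l_c_star <- l_c0 * exp(delta * (t1 - t0))
  growth <- times < t1
  data.frame(
    time_h = times,
    l_crypt = ifelse(growth, l_c0 * exp(delta * (times - t0)), l_c_star),
    l_villus = ifelse(growth, l_v0,
                      l_v0 + delta * l_c_star * (times - t1)))
}

#' Pre-shedding solution of the label-propagation model
#'
#' Closed-form labeled-cell counts for times before shedding begins
#' (`t < t2`). For `t0 <= t < t1` the crypt content grows exponentially at
#' rate `delta` and the villus content is constant at `l_v0`; for `t >= t1`
#' the crypt content is held at the transfer threshold `l_c_star` and the
#' villus content grows linearly at rate `delta * l_c_star`. This is the
#' form fitted to pulse-chase compartment counts, all of which are collected
#' before the labeled front reaches the villus tip.
#'
#' @param params A [cveu_params()] object.
#' @param times Ascending numeric vector of times, hours; all must lie in
#'   `[t0, t2)` (or `>= t0` when `t2` is absent).
#'
#' @return Data frame with columns `time_h`, `l_crypt`, `l_villus`.
#' @examples
#' p <- cveu_params(delta = 0.076, n_crypt = 20, l_c0 = 8.2, t1 = 10)
#' pre_shedding_solution(p, times = c(0, 5, 10, 20, 30))
#' @export
pre_shedding_solution <- function(params, times) {
  stopifnot(inherits(params, "cveu_params"), is.numeric(times))
  if (is.unsorted(times)) stop("'times' must be ascending", call. = FALSE)
  if (any(times < params$t0))
    stop("all times must be >= t0", call. = FALSE)
  if (!is.null(params$t2) && any(times >= params$t2))
    stop("times at or beyond the shedding onset t2; ",
         "use explicit_solution()", call. = FALSE)
  .pre_shedding(params$delta, params$l_c0, params$l_v0, params$t0,
                params$t1, times)
}

#' Full three-phase solution of the label-propagation model
#'
#' Extends [pre_shedding_solution()] beyond the shedding onset `t2`: for
#' `t >= t2` the crypt content stays at `l_c_star` while the villus content
#' relaxes exponentially at rate `gamma` from `l_v_star` toward the balance
#' level `delta * l_c_star / gamma`, where transfer from the crypt balances
#' shedding from the tip:
#' \deqn{L_V(t) = \frac{\delta L_C^*}{\gamma} +
#'   \left(L_V^* - \frac{\delta L_C^*}{\gamma}\right) e^{-\gamma (t - t_2)}}
#'
#' The closed form solves the threshold-gated system only when the balance
#' level is at or above the shedding threshold (`delta * l_c_star >=
#' gamma * l_v_star`), i.e. when the villus keeps gaining labeled cells
#' after shedding starts. Otherwise the gated dynamics would hold `L_V` at
#' the threshold (shedding switching off as soon as the count dips below
#' it) and the closed form extrapolates the shedding phase instead; a
#' warning is issued.
#'
#' @inheritParams pre_shedding_solution
#' @return Data frame with columns `time_h`, `l_crypt`, `l_villus`.
#' @examples
#' p <- cveu_params(delta = 0.076, n_crypt = 20, l_c0 = 8.2, t1 = 10,
#'                  t2 = 40, gamma = 0.05)
#' explicit_solution(p, times = seq(0, 120, by = 10))
#' @export
explicit_solution <- function(params, times) {
  stopifnot(inherits(params, "cveu_params"), is.numeric(times))
  if (is.unsorted(times)) stop("'times' must be ascending", call. = FALSE)
  if (any(times < params$t0))
    stop("all times must be >= t0", call. = FALSE)
  if (is.null(params$t2))
    return(pre_shedding_solution(params, times))
  shed <- times >= params$t2
  if (any(shed) && (is.null(params$gamma) || params$gamma <= 0))
    stop("'gamma' must be positive to evaluate the shedding phase",
         call. = FALSE)
  out <- data.frame(time_h = times, l_crypt = NA_real_, l_villus = NA_real_)
  if (any(!shed)) {
    pre <- pre_shedding_solution(
      cveu_params(params$delta, params$n_crypt, params$l_c0, params$l_v0,
                  params$t0, params$t1),
      times[!shed])
    out$l_crypt[!shed] <- pre$l_crypt
    out$l_villus[!shed] <- pre$l_villus
  }
  if (any(shed)) {
    balance <- params$delta * params$l_c_star / params$gamma
    if (balance < params$l_v_star)
      warning("shedding balance level below the threshold l_v_star; the ",
              "gated system would hold L_V at the threshold, the closed ",
              "form extrapolates the shedding phase", call. = FALSE)
    out$l_crypt[shed] <- params$l_c_star
    out$l_villus[shed] <- balance + (params$l_v_star - balance) *
      exp(-params$gamma * (times[shed] - params$t2))
  }
  out
}
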