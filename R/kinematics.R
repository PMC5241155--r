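#' Labeled-front velocity along the villus by linear regression
#'
#' The labeled front (highest labeled cell on the CVEU) advances along the
#' villus at constant velocity, so its position in micrometers is regressed
#' on time: `X_LF(t) = V_LF * t + K`.
#'
#' @param track Data frame with columns `time_h` and `front_position_um`
#'   (e.g. stacked rows of [front_position()] over sampling times).
#' @return An object of class `"cveu_frontfit"`: list with `v_lf` (slope,
#'   um/h), `intercept` (K, um), `se` (slope standard error), `r_squared`,
#'   `n`, and the underlying `lm` fit.
#' @examples
#' track <- data.frame(time_h = c(0, 10), front_position_um = c(100, 190))
#' fit_front_velocity(track)$v_lf  # 9 um/h
#' @export
fit_front_velocity <- function(track) {
  stopifnot(is.data.frame(track),
            all(c("time_h", "front_position_um") %in% names(track)))
  if (length(unique(track$time_h)) < 2L)
    stop("need at least 2 distinct times to estimate a velocity",
         call. = FALSE)
  fit <- stats::lm(front_position_um ~ time_h, data = track)
  cf <- stats::coef(fit)
  n <- nrow(track)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((track$front_position_um - mean(track$front_position_um))^2)
  sxx <- sum((track$time_h - mean(track$time_h))^2)
  se <- if (n > 2L) sqrt(rss / (n - 2L) / sxx) else NA_real_
  structure(list(v_lf = unname(cf["time_h"]),
                 intercept = unname(cf["(Intercept)"]), se = se,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 n = n, lm = fit),
            class = "cveu_frontfit")
}

#' @export
print.cveu_frontfit <- function(x, digits = 4, ...) {
  cat(sprintf("Labeled-front velocity: V_LF = %.*g um/h (se %.*g), K = %.*g um, n = %d\n",
              digits, x$v_lf, digits, x$se, digits, x$intercept, x$n))
  invisible(x)
}

#' Mitotic-pressure velocities and crypt-to-tip transit times
#'
#' Under the assumption that crypt proliferation drives all migration, a
#' cell at crypt position `x` moves at `V_x = delta * x` (cells/h), so the
#' velocity at the crypt-villus boundary — equal to the crypt cell
#' production rate — is `V_CV = delta * N_C`. Transit time from crypt base
#' to boundary is the integral of `dx / (delta x)` from position 1 to
#' `N_C`, i.e. `ln(N_C) / delta`; from boundary to villus tip it is the
#' number of villus cells divided by `V_CV`.
#'
#' @param fit A `"cveu_fit"` object, a [cveu_params()] object, or a named
#'   list/vector with elements `delta` and `n_crypt`.
#' @param cveu_length_cells Total CVEU length (crypt base to villus tip) in
#'   cells; must be at least `n_crypt`.
#' @param density_cells_per_10um Optional cell density used to express the
#'   boundary velocity in um/h as well.
#' @return An object of class `"cveu_kinematics"`: list with `delta`,
#'   `n_crypt`, `v_cv` (cells/h), `v_cv_um` (um/h or `NA`),
#'   `crypt_transit_h`, `villus_transit_h`, `total_transit_h`, and the
#'   velocity function `v_x`.
#' @examples
#' k <- derive_kinematics(list(delta = 0.0760, n_crypt = 20),
#'                        cveu_length_cells = 99.7)
#' round(k$total_transit_h)  # 92 h
#' @export
derive_kinematics <- function(fit, cveu_length_cells,
                              density_cells_per_10um = NULL) {
  p <- if (inherits(fit, "cveu_fit")) fit$params else fit
  delta <- p[["delta"]]
  n_crypt <- p[["n_crypt"]]
  stopifnot(is.numeric(delta), is.numeric(n_crypt),
            is.numeric(cveu_length_cells))
  if (cveu_length_cells < n_crypt)
    stop("CVEU length must be at least the crypt size", call. = FALSE)
  if (delta <= 0)
    stop("transit times are undefined for delta <= 0", call. = FALSE)
  v_cv <- delta * n_crypt
  crypt_t <- log(n_crypt) / delta        # integral of dx/(delta x), x = 1..N_C
  villus_t <- (cveu_length_cells - n_crypt) / v_cv
  structure(list(delta = delta, n_crypt = n_crypt,
                 cveu_length_cells = cveu_length_cells,
                 v_cv = v_cv,
                 v_cv_um = if (is.null(density_cells_per_10um)) NA_real_
                           else v_cv * 10 / density_cells_per_10um,
                 crypt_transit_h = crypt_t, villus_transit_h = villus_t,
                 total_transit_h = crypt_t + villus_t,
                 v_x = function(x) {
                   stopifnot(all(x >= 1), all(x <= n_crypt))
                   delta * x
                 }),
            class = "cveu_kinematics")
}

#' @export
print.cveu_kinematics <- function(x, digits = 3, ...) {
  cat("CVEU kinematics (mitotic pressure)\n")
  cat(sprintf("  V_CV = delta * N_C = %.*g cells/h%s\n", digits, x$v_cv,
              if (is.na(x$v_cv_um)) ""
              else sprintf(" = %.*g um/h", digits, x$v_cv_um)))
  cat(sprintf("  transit: crypt %.*g h + villus %.*g h = %.*g h total\n",
              digits, x$crypt_transit_h, digits, x$villus_transit_h,
              digits, x$total_transit_h))
  invisible(x)
}

#' Time for a halted labeled front to reach a later position
#'
#' Back-calculates how long the labeled front needs to migrate between two
#' observed positions at a given constant villus velocity; used to infer
#' when proliferation (and hence migration) resumed after a transient
#' arrest.
#'
#' @param held_position_um Front position while migration was halted, um.
#' @param resumed_position_um Front position observed after resumption, um.
#' @param v_lf_um_per_h Villus front velocity, um/h; must be positive.
#' @return Migration time in hours.
#' @examples
#' front_recovery_time(178, 234, 6.09)  # ~9.2 h
#' @export
front_recovery_time <- function(held_position_um, resumed_position_um,
                                v_lf_um_per_h) {
  if (v_lf_um_per_h <= 0)
    stop("front velocity must be positive", call. = FALSE)
  if (resumed_position_um < held_position_um)
    stop("resumed position must be at or beyond the held position",
         call. = FALSE)
  (resumed_position_um - held_position_um) / v_lf_um_per_h
}

#' Sensitivity of the fit to the crypt-villus boundary position
#'
#' Refits the pre-shedding model with the compartment counts recomputed for
#' each candidate boundary position. If the criterion boundary really lies
#' above all proliferative cells, the absolute production rate
#' `delta * N_C` is stable for boundaries at or above it (larger crypts are
#' compensated by smaller fitted `delta`), whereas boundaries cutting into
#' the proliferative zone distort it.
#'
#' @param profiles_by_time List of [position_profile()] objects, one per
#'   sampling time (any order; times are read from the profiles).
#' @param boundaries Integer vector of candidate boundary positions
#'   (at least one).
#' @param cv_cutoff Coefficient-of-variation cutoff defining the stable
#'   plateau of `delta * N_C` among boundaries at or above the criterion;
#'   default 0.10.
#' @param criterion Optional criterion boundary; defaults to the smallest
#'   candidate for plateau flagging purposes.
#' @param ... Passed to [fit_cveu()] (e.g. `scheme`, `f`).
#' @return A `"cveu_sensitivity"` data frame with columns `boundary`,
#'   `delta`, `delta_se`, `production_rate` (`delta * boundary`), `rmse`,
#'   `converged`, plus attributes `plateau_cv` and `plateau_stable`.
#' @examples \donttest{
#' cfg <- cveu_preset("control_ileum")
#' sim <- simulate_cveu(cfg, seed = 1)
#' profs <- lapply(sim$scores, position_profile)
#' boundary_sensitivity(profs, boundaries = c(17, 19, 21))
#' }
#' @export
boundary_sensitivity <- function(profiles_by_time, boundaries,
                                 cv_cutoff = 0.10, criterion = NULL, ...) {
  stopifnot(length(boundaries) >= 1L, all(boundaries >= 1))
  if (is.null(criterion)) criterion <- min(boundaries)
  rows <- lapply(boundaries, function(b) {
    cts <- do.call(rbind, lapply(profiles_by_time, compartment_counts,
                                 boundary = b))
    fit <- tryCatch(fit_cveu(cts, boundary = b, ...), error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(boundary = b, delta = NA_real_,
                        delta_se = NA_real_, production_rate = NA_real_,
                        rmse = NA_real_, converged = FALSE))
    data.frame(boundary = b, delta = fit$params$delta,
               delta_se = unname(fit$se["delta"]),
               production_rate = fit$params$delta * b,
               rmse = fit$rmse, converged = TRUE)
  })
  out <- do.call(rbind, rows)
  hi <- out$converged & out$boundary >= criterion
  cv <- if (sum(hi) >= 2L) {
    stats::sd(out$production_rate[hi]) / mean(out$production_rate[hi])
  } else NA_real_
  structure(out, plateau_cv = cv,
            plateau_stable = isTRUE(cv < cv_cutoff),
            criterion = criterion,
            class = c("cveu_sensitivity", "data.frame"))
}
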