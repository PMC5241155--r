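# Fixed/free parameter schemes per experimental regime. In control and
# reduced-proliferation (Omomyc) animals, t0 and L_V0 are fixed at 0 and
# delta, t1, L_C0 are free. In proliferation-arrest (Ara-C) experiments the
# labeled front is already on the villus at t0, so t1 = t0 (fixed at 15 h
# for the arrest phase, 25 h after resumption) and delta, L_C0, L_V0 are
# free; delta may be fitted arbitrarily close to (or below) zero.
cveu_scheme <- function(scheme = c("control", "omomyc", "arac_early",
                                   "arac_late", "custom"),
                        t0 = NULL, fixed = NULL, free = NULL) {
  scheme <- match.arg(scheme)
  out <- switch(scheme,
    control = ,
    omomyc = list(fixed = c(t0 = 0, l_v0 = 0),
                  free = c("delta", "t1", "l_c0")),
    arac_early = list(fixed = c(t0 = 15, t1 = 15),
                      free = c("delta", "l_c0", "l_v0")),
    arac_late = list(fixed = c(t0 = 25, t1 = 25),
                     free = c("delta", "l_c0", "l_v0")),
    custom = {
      if (is.null(fixed) || is.null(free))
        stop("custom scheme needs 'fixed' and 'free'", call. = FALSE)
      list(fixed = fixed, free = free)
    })
  if (!is.null(t0)) {
    out$fixed["t0"] <- t0
    if ("t1" %in% names(out$fixed)) out$fixed["t1"] <- t0
  }
  if (length(intersect(names(out$fixed), out$free)))
    stop("a parameter cannot be both fixed and free", call. = FALSE)
  need <- c("delta", "t0", "t1", "l_c0", "l_v0")
  if (!all(need %in% c(names(out$fixed), out$free)))
    stop("scheme must fix or free each of: ",
         paste(need, collapse = ", "), call. = FALSE)
  out$name <- scheme
  out
}

#' Flag and remove label-diluted and shedding-affected counts
#'
#' The two-compartment model accounts for neither dilution of the analog
#' below the detection limit (which makes crypt counts decline after ~4-5
#' generations) nor shedding from the villus tip (which makes villus counts
#' plateau). Points showing these effects are excluded before fitting.
#'
#' Crypt rule: all points from the first observed time at which the crypt
#' count has dropped below `f` times its running maximum and never recovers
#' above it. Villus rule: all points strictly after the first interval from
#' which every subsequent per-interval slope stays below `(1 - f)` times
#' the series' maximum slope.
#'
#' Exclusion is per compartment: a time point dropped from the crypt
#' series can still contribute its villus count, and vice versa.
#'
#' @param counts Data frame of compartment counts with columns `time_h`,
#'   `l_crypt_obs`, `l_villus_obs` (rows in ascending time).
#' @param f Running-maximum factor in (0, 1]; default 0.9.
#' @param manual Optional integer vector of row indices to exclude (both
#'   compartments) instead of the automatic rules.
#' @return List with elements `counts` (unchanged, for reference),
#'   `crypt_keep` and `villus_keep` (logical masks over rows), and
#'   `excluded` (data frame of row index and compartment for each
#'   excluded observation, with a `reason` column).
#' @examples
#' cts <- data.frame(time_h = c(0, 10, 20, 30, 40),
#'                   l_crypt_obs = c(8, 12, 16, 15, 9),
#'                   l_villus_obs = c(0, 2, 10, 18, 26))
#' exclude_diluted(cts)$excluded
#' @export
exclude_diluted <- function(counts, f = 0.9, manual = NULL) {
  stopifnot(is.data.frame(counts),
            all(c("time_h", "l_crypt_obs", "l_villus_obs") %in%
                  names(counts)))
  n <- nrow(counts)
  crypt_keep <- villus_keep <- rep(TRUE, n)
  if (!is.null(manual)) {
    manual <- sort(unique(as.integer(manual)))
    crypt_keep[manual] <- villus_keep[manual] <- FALSE
    return(list(counts = counts, crypt_keep = crypt_keep,
                villus_keep = villus_keep,
                excluded = data.frame(index = rep(manual, 2L),
                                      compartment = rep(c("crypt", "villus"),
                                                        each = length(manual)),
                                      reason = "manual")))
  }
  stopifnot(f > 0, f <= 1)
  villus_reason <- rep(NA_character_, n)
  # crypt: sustained decline below f * running max (label dilution)
  cmax <- cummax(counts$l_crypt_obs)
  below <- counts$l_crypt_obs < f * cmax
  onset <- which(vapply(seq_len(n), function(i) all(below[i:n]), logical(1)))
  if (length(onset)) {
    crypt_keep[seq.int(min(onset), n)] <- FALSE
    # the villus integrates transfer that happened earlier, so dilution
    # reaches it one sampling interval after the crypt's decline onset:
    # drop villus points from there on
    v_onset <- min(min(onset) + 1L, n + 1L)
    if (v_onset <= n) {
      villus_keep[seq.int(v_onset, n)] <- FALSE
      villus_reason[seq.int(v_onset, n)] <- "dilution"
    }
  }
  # villus: sustained plateau — all later slopes small relative to the
  # series' maximum slope (shedding from the tip)
  if (n >= 3L) {
    sl <- diff(counts$l_villus_obs) / diff(counts$time_h)
    thr <- (1 - f) * max(sl)
    if (max(sl) > 0) {
      flat <- which(vapply(seq_along(sl), function(i)
        all(sl[i:length(sl)] < thr), logical(1)))
      if (length(flat)) {
        idx <- seq.int(min(flat) + 1L, n)
        villus_keep[idx] <- FALSE
        villus_reason[idx] <- ifelse(is.na(villus_reason[idx]),
                                     "villus_plateau", "both")
      }
    }
  }
  excl <- rbind(
    if (any(!crypt_keep))
      data.frame(index = which(!crypt_keep), compartment = "crypt",
                 reason = "crypt_dilution"),
    if (any(!villus_keep))
      data.frame(index = which(!villus_keep), compartment = "villus",
                 reason = villus_reason[!villus_keep]))
  if (is.null(excl))
    excl <- data.frame(index = integer(), compartment = character(),
                       reason = character())
  list(counts = counts, crypt_keep = crypt_keep, villus_keep = villus_keep,
       excluded = excl)
}

# residuals on the log(L+1) scale for a candidate free-parameter vector;
# per-compartment keep masks select the observations entering the fit
cveu_fit_residuals <- function(par, fixed, counts, crypt_keep,
                               villus_keep) {
  full <- c(as.list(par), as.list(fixed))
  pred <- .pre_shedding(full$delta, full$l_c0, full$l_v0, full$t0,
                        full$t1, counts$time_h)
  bad <- !is.finite(pred$l_crypt) | !is.finite(pred$l_villus) |
    pred$l_crypt < 0 | pred$l_villus < 0
  pred$l_crypt[bad] <- 0
  pred$l_villus[bad] <- 1e6
  c((log1p(pred$l_crypt) - log1p(counts$l_crypt_obs))[crypt_keep],
    (log1p(pred$l_villus) - log1p(counts$l_villus_obs))[villus_keep])
}

#' Fit the pre-shedding label-propagation model to compartment counts
#'
#' Jointly fits the crypt and villus labeled-cell time series to the
#' piecewise pre-shedding solution by nonlinear least squares on the
#' variance-homogenizing `log(L + 1)` scale, using Levenberg-Marquardt with
#' bounds and five deterministic restarts spanning plausible proliferation
#' rates and transfer-onset times. Which parameters are fixed and which are
#' estimated depends on the experimental regime (`scheme`); see Details.
#'
#' @details
#' Schemes:
#' \describe{
#'   \item{`"control"`, `"omomyc"`}{`t0 = 0`, `l_v0 = 0` fixed; `delta`,
#'     `t1`, `l_c0` free. `delta` is bounded below by a small positive
#'     value and `t1` by `t0`.}
#'   \item{`"arac_early"`}{`t0 = t1 = 15` h fixed (first sampling after
#'     label activation); `delta`, `l_c0`, `l_v0` free, with `delta`
#'     allowed to go negative so that "no proliferation" is an interior
#'     hypothesis, testable against its standard error.}
#'   \item{`"arac_late"`}{as `arac_early` with `t0 = t1 = 25` h (10 h of
#'     arrest added).}
#'   \item{`"custom"`}{supply `fixed` (named numeric) and `free`
#'     (character) covering `delta`, `t0`, `t1`, `l_c0`, `l_v0`.}
#' }
#' Standard errors are the conventional Gauss-Newton asymptotic errors,
#' `sigma^2 (J'J)^{-1}` at the optimum with `sigma^2 = RSS / (n - p)`.
#'
#' @param counts Data frame of observed compartment counts (columns
#'   `time_h`, `l_crypt_obs`, `l_villus_obs`), e.g. rows of
#'   [compartment_counts()] over time.
#' @param boundary Crypt compartment size `N_C` used to form the counts;
#'   fixes the upper bound of `l_c0` and the crypt capacity.
#' @param scheme Experimental regime; see Details.
#' @param exclude One of `"auto"` (apply [exclude_diluted()]), `"none"`, or
#'   an integer vector of row indices to drop.
#' @param f Running-maximum factor passed to [exclude_diluted()].
#' @param t0 Optional override of the scheme's fixed `t0` (Ara-C schemes
#'   also move `t1` with it).
#' @param fixed,free Custom scheme specification (see Details).
#' @param start Optional named list/vector of starting values overriding
#'   the deterministic restart grid.
#' @return An object of class `"cveu_fit"` with components `params` (a
#'   [cveu_params()] object at the optimum), `coefficients`, `se`, `vcov`,
#'   `rmse`, `rss`, `df_residual`, `n_used`, `n_excluded`, `excluded`,
#'   `scheme`, `boundary`, `counts` (rows used), `counts_all`,
#'   `convergence`.
#' @examples
#' p <- cveu_params(delta = 0.076, n_crypt = 20, l_c0 = 8.2, t1 = 10)
#' cts <- pre_shedding_solution(p, seq(0, 35, by = 5))
#' names(cts) <- c("time_h", "l_crypt_obs", "l_villus_obs")
#' fit <- fit_cveu(cts, boundary = 20)
#' coef(fit)
#' @seealso [derive_kinematics()], [fit_front_velocity()],
#'   [boundary_sensitivity()]
#' @export
fit_cveu <- function(counts, boundary, scheme = "control",
                     exclude = "auto", f = 0.9, t0 = NULL,
                     fixed = NULL, free = NULL, start = NULL) {
  sch <- cveu_scheme(scheme, t0 = t0, fixed = fixed, free = free)
  counts_all <- counts[order(counts$time_h), , drop = FALSE]
  rownames(counts_all) <- NULL
  n <- nrow(counts_all)
  if (identical(exclude, "auto")) {
    # the rule must leave a fittable dataset: relax the running-max factor
    # stepwise when fewer than 3 time points survive (heavily diluted
    # series, e.g. label several generations old at the window start)
    for (ff in unique(c(f, 0.8, 0.6, 0.4, 0.2))) {
      ex <- exclude_diluted(counts_all, f = ff)
      n_t <- length(unique(
        counts_all$time_h[ex$crypt_keep | ex$villus_keep]))
      if (n_t >= 3L) break
    }
  } else if (identical(exclude, "none")) {
    ex <- list(counts = counts_all, crypt_keep = rep(TRUE, n),
               villus_keep = rep(TRUE, n),
               excluded = data.frame(index = integer(),
                                     compartment = character(),
                                     reason = character()))
  } else {
    ex <- exclude_diluted(counts_all, manual = exclude)
  }
  n_res <- sum(ex$crypt_keep) + sum(ex$villus_keep)
  t_used <- counts_all$time_h[ex$crypt_keep | ex$villus_keep]
  if (length(unique(t_used)) < 3L)
    stop("need at least 3 time points after exclusions", call. = FALSE)
  if (n_res <= length(sch$free))
    stop("under-determined fit: more free parameters than residuals",
         call. = FALSE)

  t0_fix <- if ("t0" %in% names(sch$fixed)) sch$fixed[["t0"]] else 0
  t_max <- max(t_used)
  lower <- c(delta = if (startsWith(sch$name, "arac")) -0.5 else 1e-4,
             t1 = t0_fix, l_c0 = 1e-6, l_v0 = 0, t0 = 0)
  upper <- c(delta = 1, t1 = max(t_max, t0_fix), l_c0 = boundary,
             l_v0 = Inf, t0 = t_max)

  starts <- if (!is.null(start)) {
    list(unlist(start)[sch$free])
  } else {
    # deterministic restart grid spanning delta in [0.01, 0.2], t1 in [2, 30]
    dg <- seq(0.01, 0.2, length.out = 5)
    tg <- seq(2, 30, length.out = 5)
    lapply(seq_len(5), function(i) {
      s <- c(delta = dg[i],
             t1 = max(t0_fix, tg[i]),
             l_c0 = max(counts_all$l_crypt_obs[1L], 0.5),
             l_v0 = max(counts_all$l_villus_obs[1L], 0.1))
      s[sch$free]
    })
  }

  best <- NULL
  for (s0 in starts) {
    s0 <- pmin(pmax(s0, lower[names(s0)]), upper[names(s0)])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s0, lower = lower[names(s0)],
                         upper = upper[names(s0)],
                         fn = cveu_fit_residuals, fixed = sch$fixed,
                         counts = counts_all, crypt_keep = ex$crypt_keep,
                         villus_keep = ex$villus_keep,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best))
    stop("optimizer failed to converge from every starting point",
         call. = FALSE)

  est <- best$par
  rss <- best$deviance
  df_res <- n_res - length(est)
  sigma2 <- rss / df_res
  vc <- tryCatch(sigma2 * solve(best$hessian), error = function(e) {
    matrix(NA_real_, length(est), length(est),
           dimnames = list(names(est), names(est)))
  })
  se <- sqrt(pmax(diag(vc), 0))
  names(se) <- names(est)

  full <- c(as.list(est), as.list(sch$fixed))
  params <- tryCatch(
    cveu_params(delta = full$delta, n_crypt = boundary, l_c0 = full$l_c0,
                l_v0 = full$l_v0, t0 = full$t0, t1 = full$t1),
    error = function(e) {
      # a fitted delta below zero (arrest regimes) has no threshold
      # interpretation; keep the raw values so predict() still works
      structure(list(delta = full$delta, gamma = NULL, n_crypt = boundary,
                     l_c0 = full$l_c0, l_v0 = full$l_v0, t0 = full$t0,
                     t1 = full$t1, t2 = NULL,
                     l_c_star = full$l_c0 *
                       exp(full$delta * (full$t1 - full$t0)),
                     l_v_star = NULL),
                class = "cveu_params")
    })
  structure(list(params = params, coefficients = est, se = se, vcov = vc,
                 rmse = sqrt(rss / n_res), rss = rss, df_residual = df_res,
                 n_used = n_res, n_excluded = nrow(ex$excluded),
                 excluded = ex$excluded, crypt_keep = ex$crypt_keep,
                 villus_keep = ex$villus_keep,
                 scheme = sch, boundary = boundary, counts = counts_all,
                 counts_all = counts_all,
                 convergence = best$info, message = best$message),
            class = "cveu_fit")
}

#' @export
coef.cveu_fit <- function(object, ...) object$coefficients

#' @export
vcov.cveu_fit <- function(object, ...) object$vcov

#' @export
print.cveu_fit <- function(x, digits = 4, ...) {
  cat("Two-compartment CVEU label model fit (scheme:", x$scheme$name, ")\n")
  cat("Free parameters:\n")
  print(signif(rbind(estimate = x$coefficients, se = x$se), digits))
  cat("Fixed:", paste(sprintf("%s = %g", names(x$scheme$fixed),
                              x$scheme$fixed), collapse = ", "), "\n")
  cat(sprintf("Boundary N_C = %d; RMSE (log(L+1) scale) = %.*g; %d points used, %d excluded\n",
              x$boundary, digits, x$rmse, x$n_used, x$n_excluded))
  invisible(x)
}

#' @export
summary.cveu_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, scheme = object$scheme,
              rmse = object$rmse, boundary = object$boundary,
              n_used = object$n_used, n_excluded = object$n_excluded,
              production_rate = object$params$delta * object$boundary)
  class(out) <- "summary.cveu_fit"
  out
}

#' @export
print.summary.cveu_fit <- function(x, digits = 4, ...) {
  cat("Two-compartment CVEU label model fit (scheme:", x$scheme$name, ")\n\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat(sprintf("\nRMSE (log(L+1) scale): %.*g on %d points (%d excluded)\n",
              digits, x$rmse, x$n_used, x$n_excluded))
  cat(sprintf("Crypt cell production rate delta * N_C = %.*g cells/h\n",
              digits, x$production_rate))
  invisible(x)
}

#' @export
predict.cveu_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$counts$time_h
  pre_shedding_solution(object$params, sort(times))
}

#' @export
fitted.cveu_fit <- function(object, ...) {
  pre_shedding_solution(object$params, object$counts$time_h)
}

#' @export
residuals.cveu_fit <- function(object,
                               scale = c("transformed", "natural"), ...) {
  scale <- match.arg(scale)
  pred <- fitted(object)
  if (scale == "transformed") {
    data.frame(time_h = object$counts$time_h,
               crypt = log1p(object$counts$l_crypt_obs) - log1p(pred$l_crypt),
               villus = log1p(object$counts$l_villus_obs) -
                 log1p(pred$l_villus))
  } else {
    data.frame(time_h = object$counts$time_h,
               crypt = object$counts$l_crypt_obs - pred$l_crypt,
               villus = object$counts$l_villus_obs - pred$l_villus)
  }
}

#' @export
plot.cveu_fit <- function(x, ...) {
  cts <- x$counts_all
  tt <- seq(min(cts$time_h), max(cts$time_h), length.out = 200)
  tt <- tt[if (is.null(x$params$t2)) TRUE else tt < x$params$t2]
  pred <- pre_shedding_solution(x$params, tt)
  ylim <- range(0, cts$l_crypt_obs, cts$l_villus_obs,
                pred$l_crypt, pred$l_villus)
  graphics::plot(cts$time_h, cts$l_crypt_obs, ylim = ylim, pch = 1,
                 xlab = "time (h)", ylab = "labeled cells",
                 main = "Labeled cells per compartment", ...)
  graphics::points(cts$time_h[x$crypt_keep], cts$l_crypt_obs[x$crypt_keep],
                   pch = 16)
  graphics::points(cts$time_h, cts$l_villus_obs, pch = 2)
  graphics::points(cts$time_h[x$villus_keep],
                   cts$l_villus_obs[x$villus_keep], pch = 17)
  graphics::lines(pred$time_h, pred$l_crypt, lty = 1)
  graphics::lines(pred$time_h, pred$l_villus, lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = c("crypt", "villus", "excluded point"),
                   pch = c(16, 17, 1), lty = c(1, 2, NA))
  invisible(x)
}
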