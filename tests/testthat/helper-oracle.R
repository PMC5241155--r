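# Numerical oracle: integrate the gated ODE right-hand side (label_rates)
# with the solver restarted at the phase-change times, the standard
# event-handling treatment of a discontinuous right-hand side.
integrate_gated <- function(p, times) {
  rhs <- function(t, y, parms) list(label_rates(p, y[1], y[2]))
  t2 <- if (is.null(p$t2)) max(times) else p$t2
  brk <- sort(unique(c(p$t0, p$t1, t2, times)))
  segs <- list(brk[brk <= p$t1], brk[brk >= p$t1 & brk <= t2],
               brk[brk >= t2])
  y <- c(p$l_c0, p$l_v0)
  out <- NULL
  for (si in seq_along(segs)) {
    sg <- segs[[si]]
    if (length(sg) < 2L) next
    # event handling: at a phase change, snap the state onto the
    # threshold manifold so the gate does not chatter at round-off scale
    if (si >= 2L && abs(y[1] - p$l_c_star) < 1e-7 * p$l_c_star)
      y[1] <- p$l_c_star
    if (si == 3L && !is.null(p$l_v_star) &&
        abs(y[2] - p$l_v_star) < 1e-7 * max(p$l_v_star, 1))
      y[2] <- p$l_v_star
    sol <- deSolve::ode(y, sg, rhs, NULL, method = "lsoda",
                        rtol = 1e-11, atol = 1e-11)
    out <- rbind(out, sol)
    y <- sol[nrow(sol), 2:3]
  }
  out <- out[!duplicated(out[, 1]), , drop = FALSE]
  out[match(times, out[, 1]), 2:3, drop = FALSE]
}

# random parameter set in the regime where the explicit shedding-phase
# form solves the gated system (balance level >= shedding threshold)
random_params <- function(with_shedding = TRUE) {
  repeat {
    delta <- runif(1, 0.02, 0.15)
    nc <- sample(10:30, 1)
    l_c0 <- runif(1, 1, 6)
    t0 <- runif(1, 0, 2)
    t1 <- t0 + runif(1, 2, 15)
    if (l_c0 * exp(delta * (t1 - t0)) <= nc) break
  }
  if (!with_shedding)
    return(cveu_params(delta, nc, l_c0, l_v0 = runif(1, 0, 2), t0, t1))
  t2 <- t1 + runif(1, 5, 20)
  l_v0 <- runif(1, 0, 2)
  l_c_star <- l_c0 * exp(delta * (t1 - t0))
  l_v_star <- l_v0 + delta * l_c_star * (t2 - t1)
  gamma <- runif(1, 0.1, 0.95) * delta * l_c_star / l_v_star
  cveu_params(delta, nc, l_c0, l_v0, t0, t1, t2, gamma)
}

# noiseless compartment counts generated straight from the pre-shedding
# closed form (zero-noise inverse problem for the fitter)
noiseless_counts <- function(p, times) {
  sol <- pre_shedding_solution(p, times)
  data.frame(time_h = sol$time_h, l_crypt_obs = sol$l_crypt,
             l_villus_obs = sol$l_villus)
}

sim_counts <- function(sim, boundary) {
  profs <- lapply(sim$scores, position_profile)
  cts <- do.call(rbind, lapply(profs, compartment_counts,
                               boundary = boundary))
  rownames(cts) <- NULL
  cts
}
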