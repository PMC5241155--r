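#' Configuration for the agent-based CVEU simulator
#'
#' Describes one pulse-labeling experiment on a 1-D column of cells (the
#' CVEU): all cells at crypt positions `1..n_crypt` divide as independent
#' Poisson processes at rate `delta`; a division at position `x` inserts a
#' daughter at `x + 1` and pushes every higher cell up one position
#' (mitotic pressure), shedding the cell that leaves the villus tip. Label
#' and generation counters are inherited at division; label diluted over
#' `detection_limit` or more generations is no longer detectable. Arrest
#' windows set the division rate to zero (cytostatic treatment).
#'
#' @param delta Division rate per crypt cell, per hour.
#' @param n_crypt Crypt compartment size, cells.
#' @param cveu_length Mean CVEU length (crypt base to villus tip), cells.
#' @param cveu_length_sd Between-CVEU standard deviation of length, cells;
#'   lengths are drawn normal and truncated below at `n_crypt + 1`.
#' @param sample_times Ascending times (h) at which CVEUs are scored.
#' @param label_profile Optional numeric vector of per-position labeling
#'   probabilities at the pulse; must be zero at and above `n_crypt`. When
#'   `NULL`, a mid-crypt-peaked trapezoid is used, scaled so the expected
#'   number of initially labeled cells equals `target_labeled`.
#' @param target_labeled Expected initially labeled cells per CVEU used to
#'   scale the default trapezoid profile.
#' @param detection_limit_generations Divisions after which inherited label
#'   is no longer detected (default 5).
#' @param arrest_windows List of `c(start, end)` time pairs (h) during
#'   which the division rate is zero.
#' @param n_cveu CVEUs scored per sample time (default 30).
#' @param density Cell density in cells per 10 um, used to convert cell
#'   positions to micrometers (cell length = `10 / density`).
#' @param tissue,group Metadata labels attached to the generated score
#'   matrices.
#' @return A `"cveu_sim_config"` list.
#' @seealso [cveu_preset()], [simulate_cveu()]
#' @export
sim_config <- function(delta, n_crypt, cveu_length, cveu_length_sd = 0,
                       sample_times, label_profile = NULL,
                       target_labeled = NULL,
                       detection_limit_generations = 5,
                       arrest_windows = list(), n_cveu = 30,
                       density = 1.0, tissue = NA_character_,
                       group = NA_character_) {
  stopifnot(delta >= 0, n_crypt >= 1, cveu_length >= n_crypt,
            cveu_length_sd >= 0, detection_limit_generations >= 1,
            n_cveu >= 1, density > 0, length(sample_times) >= 1,
            !is.unsorted(sample_times))
  if (is.null(label_profile)) {
    if (is.null(target_labeled))
      stop("supply either 'label_profile' or 'target_labeled'",
           call. = FALSE)
    label_profile <- trapezoid_profile(n_crypt, target_labeled)
  }
  if (any(label_profile < 0) || any(label_profile > 1))
    stop("labeling probabilities must lie in [0, 1]", call. = FALSE)
  if (length(label_profile) >= n_crypt &&
      any(label_profile[n_crypt:length(label_profile)] > 0))
    stop("labeling probability must be zero at and above the boundary ",
         "position n_crypt (the pulse hits proliferative cells only)",
         call. = FALSE)
  for (w in arrest_windows)
    stopifnot(length(w) == 2L, w[2] > w[1], w[1] >= 0)
  structure(list(delta = delta, n_crypt = as.integer(n_crypt),
                 cveu_length = cveu_length,
                 cveu_length_sd = cveu_length_sd,
                 sample_times = as.numeric(sample_times),
                 label_profile = label_profile,
                 detection_limit = as.integer(detection_limit_generations),
                 arrest_windows = arrest_windows,
                 n_cveu = as.integer(n_cveu), density = density,
                 cell_length_um = 10 / density, tissue = tissue,
                 group = group),
            class = "cveu_sim_config")
}

# mid-crypt-peaked pulse profile over positions 1..(n_crypt - 1), zero at
# and above n_crypt: rises from a partially labeled base (label decreases
# toward the crypt mouth and base but proliferative cells near the base do
# take up the pulse) to a plateau over the intermediate positions, then
# falls to a low foot just below the boundary. The low bulk keeps early
# crypt-to-villus transfer negligible (so crypt counts first grow roughly
# exponentially and villus counts accumulate linearly only later), while
# the shallow foot keeps every pre-boundary position above the 0.01
# boundary-detection criterion; position n_crypt itself is unlabeled, so
# the criterion lands at the boundary. Scaled so the expected initially
# labeled count equals `target`.
trapezoid_profile <- function(n_crypt, target, base = 0.5, foot = 0.08) {
  x2 <- max(2, round(0.25 * n_crypt))
  x3 <- max(x2, round(0.55 * n_crypt))
  x4 <- n_crypt
  x <- seq_len(n_crypt)
  shape <- numeric(n_crypt)
  shape[x <= x2] <- base + (1 - base) * x[x <= x2] / x2
  shape[x > x2 & x <= x3] <- 1
  fall <- x > x3 & x < x4
  shape[fall] <- 1 - (1 - foot) * (x[fall] - x3) / (x4 - 1 - x3)
  p <- target / sum(shape)
  if (p > 0.98)
    stop("target labeled count too large for a trapezoid profile on this ",
         "crypt", call. = FALSE)
  shape * p
}

#' Initial labeled cells of one simulated CVEU
#'
#' Independent Bernoulli draws per crypt position with the configured
#' labeling probabilities; positions above the crypt are never labeled
#' (the analog pulse is taken up by proliferative cells only).
#'
#' @param config A [sim_config()].
#' @param cveu_length Length of this CVEU in cells; defaults to the
#'   configured mean length (rounded).
#' @return Logical vector of length `cveu_length`; `TRUE` where labeled.
#' @examples
#' cfg <- cveu_preset("control_duodenum")
#' set.seed(1); mean(replicate(200, sum(make_initial_label(cfg))))
#' @export
make_initial_label <- function(config, cveu_length = NULL) {
  stopifnot(inherits(config, "cveu_sim_config"))
  if (is.null(cveu_length)) cveu_length <- round(config$cveu_length)
  p <- numeric(cveu_length)
  k <- min(length(config$label_profile), cveu_length)
  p[seq_len(k)] <- config$label_profile[seq_len(k)]
  stats::runif(cveu_length) < p
}

#' Simulator presets calibrated to the studied experimental regimes
#'
#' Returns a [sim_config()] for one of the six studied (group, tissue)
#' combinations, with proliferation rate, crypt size, CVEU length
#' distribution, cell density and two-hour labeled-cell totals set to the
#' fitted/measured values of the corresponding mouse experiment. The Ara-C
#' presets place the label pulse 17 h before the cytostatic injection and
#' include the ensuing 10-h proliferation-arrest window (17-27 h on the
#' label clock), with samples spanning 1-57 h after the injection.
#'
#' @param name One of `"control_duodenum"`, `"control_ileum"`,
#'   `"omomyc_duodenum"`, `"omomyc_ileum"`, `"arac_duodenum"`,
#'   `"arac_ileum"`.
#' @return A `"cveu_sim_config"`.
#' @examples
#' cveu_preset("control_ileum")$delta
#' @export
cveu_preset <- function(name) {
  presets <- list(
    control_duodenum = list(delta = 0.0760, n_crypt = 20,
                            cveu_length = 99.7, cveu_length_sd = 8.30,
                            density = 1.25, target_labeled = 8.2,
                            sample_times = seq(0, 40, length.out = 8),
                            tissue = "duodenum", group = "control"),
    control_ileum = list(delta = 0.0544, n_crypt = 19,
                         cveu_length = 61.5, cveu_length_sd = 7.18,
                         density = 1.00, target_labeled = 7.4,
                         sample_times = seq(0, 40, length.out = 8),
                         tissue = "ileum", group = "control"),
    omomyc_duodenum = list(delta = 0.0547, n_crypt = 18,
                           cveu_length = 98.8, cveu_length_sd = 7.32,
                           density = 1.01, target_labeled = 6.1,
                           sample_times = seq(0, 40, length.out = 8),
                           tissue = "duodenum", group = "omomyc"),
    omomyc_ileum = list(delta = 0.0509, n_crypt = 16,
                        cveu_length = 52.1, cveu_length_sd = 7.36,
                        density = 0.865, target_labeled = 4.3,
                        sample_times = seq(0, 40, length.out = 8),
                        tissue = "ileum", group = "omomyc"),
    arac_duodenum = list(delta = 0.0864, n_crypt = 20,
                         cveu_length = 101, cveu_length_sd = 11.9,
                         density = 1.12, target_labeled = 8,
                         arrest_windows = list(c(17, 27)),
                         sample_times = c(18, 20, 22, 25, 27,
                                          28, 32, 38, 44, 50, 56, 64, 74),
                         tissue = "duodenum", group = "arac"),
    arac_ileum = list(delta = 0.0466, n_crypt = 20,
                      cveu_length = 59.2, cveu_length_sd = 9.25,
                      density = 0.778, target_labeled = 6.8,
                      arrest_windows = list(c(17, 27)),
                      sample_times = c(18, 20, 22, 25, 27,
                                       28, 32, 38, 44, 50, 56, 64, 74),
                      tissue = "ileum", group = "arac"))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  do.call(sim_config, presets[[name]])
}

# time of the next division, skipping arrest windows; waiting time on the
# active clock is exponential with the total crypt rate
next_division <- function(t, rate, windows) {
  if (rate <= 0) return(Inf)
  w <- stats::rexp(1L, rate)
  for (win in windows) {
    if (t >= win[2]) next
    if (t >= win[1]) t <- win[2]
    gap <- win[1] - t
    if (gap >= 0 && w <= gap) return(t + w)
    if (gap >= 0) {
      w <- w - gap
      t <- win[2]
    }
  }
  t + w
}

#' Simulate pulse-labeled CVEUs
#'
#' Runs the agent-based 1-D CVEU model (see [sim_config()]) for
#' `n_cveu` independent CVEUs and scores each at every sample time: a
#' position scores 1 if its cell carries label that has undergone fewer
#' than `detection_limit_generations` divisions. The crypt occupies a fixed
#' `n_crypt` positions throughout; each division displaces the column
#' upward and sheds one cell from the tip.
#'
#' @param config A [sim_config()] or preset name for [cveu_preset()].
#' @param seed Optional integer seed.
#' @return List with components:
#' \describe{
#'   \item{`scores`}{named list of [cveu_scores()] matrices, one per
#'     sample time (`NA`-padded to the longest CVEU).}
#'   \item{`front`}{data frame (`time_h`, `front_position_um`, `n_cveu`) of
#'     mean detectable-front positions.}
#'   \item{`truth`}{per-time ground truth: mean detectable and total label
#'     counts per compartment, true boundary, mean front position, total
#'     division events — the oracle channel for testing.}
#'   \item{`config`}{the configuration used.}
#' }
#' @examples
#' sim <- simulate_cveu(cveu_preset("control_ileum"), seed = 1)
#' sapply(sim$scores, nrow)
#' @export
simulate_cveu <- function(config, seed = NULL) {
  if (is.character(config)) config <- cveu_preset(config)
  stopifnot(inherits(config, "cveu_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  nc <- config$n_crypt
  rate <- config$delta * nc
  st <- config$sample_times
  n_t <- length(st)

  # cross-sectional design: every sample time gets its own independent
  # CVEU realizations, as each experimental time point comes from a
  # different animal
  lens <- matrix(pmax(nc + 1L,
                      round(stats::rnorm(config$n_cveu * n_t,
                                         config$cveu_length,
                                         config$cveu_length_sd))),
                 config$n_cveu, n_t)
  max_len <- max(lens)

  det_mat <- array(NA_real_, c(config$n_cveu, max_len, n_t))
  crypt_det <- crypt_tot <- villus_det <- villus_tot <-
    front_idx <- matrix(NA_real_, config$n_cveu, n_t)
  n_events <- 0L

  for (k in seq_len(n_t)) {
    for (i in seq_len(config$n_cveu)) {
      L <- lens[i, k]
      gen <- rep(-1L, L)                     # -1 = unlabeled
      gen[make_initial_label(config, L)] <- 0L
      t_ev <- next_division(0, rate, config$arrest_windows)
      while (t_ev <= st[k]) {
        x <- sample.int(nc, 1L)
        g <- gen[x]
        newg <- if (g >= 0L) g + 1L else -1L
        gen[x] <- newg
        gen <- c(gen[seq_len(x)], newg,
                 if (x < L) gen[seq.int(x + 1L, L)])[seq_len(L)]
        n_events <- n_events + 1L
        t_ev <- next_division(t_ev, rate, config$arrest_windows)
      }
      det <- as.numeric(gen >= 0L & gen < config$detection_limit)
      tot <- gen >= 0L
      det_mat[i, seq_len(L), k] <- det
      crypt_det[i, k] <- sum(det[seq_len(nc)])
      villus_det[i, k] <- sum(det[-seq_len(nc)])
      crypt_tot[i, k] <- sum(tot[seq_len(nc)])
      villus_tot[i, k] <- sum(tot[-seq_len(nc)])
      front_idx[i, k] <- if (any(det > 0)) max(which(det > 0)) else NA
    }
  }

  scores <- lapply(seq_len(n_t), function(k)
    cveu_scores(matrix(det_mat[, seq_len(max(lens[, k])), k],
                       nrow = config$n_cveu),
                time_h = st[k],
                tissue = config$tissue, group = config$group))
  names(scores) <- sprintf("t%g", st)

  front <- data.frame(
    time_h = st,
    front_position_um = colMeans(front_idx, na.rm = TRUE) *
      config$cell_length_um,
    n_cveu = colSums(!is.na(front_idx)))

  truth <- data.frame(
    time_h = st,
    l_crypt_detectable = colMeans(crypt_det),
    l_villus_detectable = colMeans(villus_det),
    l_crypt_total = colMeans(crypt_tot),
    l_villus_total = colMeans(villus_tot),
    front_position_um = front$front_position_um,
    boundary = nc)

  list(scores = scores, front = front, truth = truth, config = config,
       n_events = n_events)
}
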