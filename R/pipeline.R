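#' Run the full CVEU labeling analysis
#'
#' Composes the analysis stages in order: per-position labeling profiles
#' from the score matrices, crypt-villus boundary from the time-zero
#' profile, compartment counts per time, dilution/shedding exclusion,
#' pre-shedding model fit, labeled-front velocity, and kinematics
#' (production rate, velocities, transit times).
#'
#' @param scores List of [cveu_scores()] matrices, one per sample time
#'   (e.g. the `scores` element of [simulate_cveu()], or matrices read with
#'   [read_scores()]).
#' @param scheme Fitting scheme passed to [fit_cveu()].
#' @param boundary Optional crypt-villus boundary override; when `NULL` it
#'   is estimated from the earliest profile with [estimate_boundary()].
#' @param threshold Boundary threshold (default 0.01).
#' @param density Cell density (cells/10 um) used to convert front
#'   positions to micrometers and the boundary velocity to um/h.
#' @param front Optional pre-computed front track (`time_h`,
#'   `front_position_um`); when `NULL` it is measured from the score
#'   matrices.
#' @param cveu_length_cells CVEU length in cells for transit times; when
#'   `NULL`, the mean scored CVEU length is used.
#' @param exclude,f Exclusion rule controls passed to [fit_cveu()].
#' @return A `"cveu_analysis"` list with elements `profiles`, `boundary`,
#'   `counts`, `fit`, `front_fit`, `kinematics` (or `NULL` when the fitted
#'   rate is not positive), and `density`.
#' @examples
#' sim <- simulate_cveu(cveu_preset("control_ileum"), seed = 1)
#' res <- run_pipeline(sim$scores, density = sim$config$density)
#' coef(res$fit)
#' @export
run_pipeline <- function(scores, scheme = "control", boundary = NULL,
                         threshold = 0.01, density = 1.0, front = NULL,
                         cveu_length_cells = NULL, exclude = "auto",
                         f = 0.9) {
  if (!length(scores)) stop("no score matrices supplied", call. = FALSE)
  times <- vapply(scores, attr, numeric(1), "time_h")
  scores <- scores[order(times)]
  profiles <- lapply(scores, position_profile)
  if (is.null(boundary))
    boundary <- estimate_boundary(profiles[[1L]], threshold = threshold)
  counts <- do.call(rbind, lapply(profiles, compartment_counts,
                                  boundary = boundary))
  rownames(counts) <- NULL
  fit <- fit_cveu(counts, boundary = boundary, scheme = scheme,
                  exclude = exclude, f = f)
  cell_len <- 10 / density
  if (is.null(front))
    front <- do.call(rbind, lapply(scores, function(m)
      tryCatch(front_position(m, cell_length_um = cell_len),
               error = function(e) NULL)))
  front_fit <- if (!is.null(front) && length(unique(front$time_h)) >= 2L)
    fit_front_velocity(front) else NULL
  if (is.null(cveu_length_cells))
    cveu_length_cells <- mean(unlist(lapply(scores, function(m)
      rowSums(!is.na(m)))))
  kin <- if (fit$params$delta > 0)
    derive_kinematics(fit, cveu_length_cells = cveu_length_cells,
                      density_cells_per_10um = density) else NULL
  structure(list(profiles = profiles, boundary = boundary,
                 counts = counts, fit = fit, front_fit = front_fit,
                 kinematics = kin, density = density),
            class = "cveu_analysis")
}

#' @export
print.cveu_analysis <- function(x, digits = 4, ...) {
  cat("CVEU labeling analysis\n")
  cat(sprintf("  boundary N_C = %d cells; %d sample times\n",
              x$boundary, nrow(x$counts)))
  print(x$fit, digits = digits)
  if (!is.null(x$front_fit)) print(x$front_fit, digits = digits)
  if (!is.null(x$kinematics)) print(x$kinematics, digits = digits)
  invisible(x)
}
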