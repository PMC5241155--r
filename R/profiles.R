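#' Construct a per-CVEU binary score matrix
#'
#' One row per scored crypt-villus epithelial unit (CVEU), one column per
#' cell position counted from the crypt base (position 1). Entry 1 means
#' the cell at that position carried detectable label, 0 means unlabeled.
#' CVEUs shorter than the longest one are padded with `NA` and excluded
#' per-position from averaging.
#'
#' @param scores Numeric or logical matrix of 0/1 (and `NA`) values.
#' @param time_h Sampling time in hours after experimental time zero.
#' @param tissue,group,analog Optional metadata labels (e.g. `"duodenum"`,
#'   `"control"`, `"BrdU"`).
#' @return A `"cveu_scores"` matrix with metadata attributes.
#' @examples
#' m <- cveu_scores(rbind(c(1, 0, 1), c(0, 0, 1)), time_h = 0)
#' @export
cveu_scores <- function(scores, time_h, tissue = NA_character_,
                        group = NA_character_, analog = NA_character_) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (nrow(scores) < 1L)
    stop("score matrix needs at least one CVEU row", call. = FALSE)
  vals <- scores[!is.na(scores)]
  if (!all(vals %in% c(0, 1)))
    stop("scores must be 0, 1 or NA", call. = FALSE)
  structure(scores, time_h = as.numeric(time_h), tissue = tissue,
            group = group, analog = analog,
            class = c("cveu_scores", class(scores)))
}

#' Labeled-cell proportion at each CVEU position
#'
#' Averages the binary scores column-wise across CVEUs, ignoring `NA`
#' padding, to give the proportion of labeled cells at each position from
#' the crypt base, together with the number of CVEUs scored per position.
#'
#' @param m A [cveu_scores()] matrix.
#' @return A `"cveu_profile"` data frame with columns `position`,
#'   `proportion`, `n_obs` and the metadata of `m` as attributes.
#' @examples
#' m <- cveu_scores(rbind(c(1, 0), c(0, 0), c(1, 0)), time_h = 0)
#' position_profile(m)
#' @export
position_profile <- function(m) {
  stopifnot(inherits(m, "cveu_scores"))
  n_obs <- colSums(!is.na(m))
  if (any(n_obs == 0L))
    stop("every position must be scored in at least one CVEU",
         call. = FALSE)
  prop <- colSums(m, na.rm = TRUE) / n_obs
  structure(data.frame(position = seq_len(ncol(m)), proportion = prop,
                       n_obs = as.integer(n_obs), row.names = NULL),
            time_h = attr(m, "time_h"), tissue = attr(m, "tissue"),
            group = attr(m, "group"), analog = attr(m, "analog"),
            class = c("cveu_profile", "data.frame"))
}

#' Estimate the crypt-villus boundary from a two-hour labeling profile
#'
#' The boundary (equivalently the crypt compartment size, `N_C`) is the
#' lowest position in the upper part of the crypt at which the proportion
#' of labeled cells two hours after analog injection falls below
#' `threshold`. Because the two-hour profile is also low near the crypt
#' base, the scan starts strictly above the profile's peak position.
#'
#' @param profile A [position_profile()] taken at the experiment's time
#'   zero (two hours after injection).
#' @param threshold Proportion below which a position is considered
#'   unlabeled; default 0.01.
#' @return Integer boundary position (= crypt compartment size, cells).
#' @examples
#' m <- cveu_scores(matrix(rep(c(0.0, 1, 1, 1, 0, 0), each = 1), 1),
#'                  time_h = 0)
#' estimate_boundary(position_profile(m))
#' @export
estimate_boundary <- function(profile, threshold = 0.01) {
  stopifnot(inherits(profile, "cveu_profile"),
            is.numeric(threshold), threshold > 0, threshold <= 1)
  p <- profile$proportion
  if (all(p == 0))
    stop("profile has no labeled region", call. = FALSE)
  peak <- which.max(p)
  if (peak >= length(p))
    stop("profile peak is at the last position; no crypt-villus boundary ",
         "found", call. = FALSE)
  above <- seq.int(peak + 1L, length(p))
  if (!any(p[above] < threshold))
    stop("no position above the peak falls below the threshold; ",
         "no crypt-villus boundary found", call. = FALSE)
  above[which(p[above] < threshold)[1L]]
}

#' Labeled-cell counts in the crypt and villus compartments
#'
#' Sums labeled proportions at positions `1..boundary` (crypt) and
#' `boundary+1..L` (villus). These per-time sums are the data to which the
#' pre-shedding model solution is fitted.
#'
#' @param profile A [position_profile()].
#' @param boundary Crypt-villus boundary position (crypt size `N_C`).
#' @return One-row data frame with columns `time_h`, `l_crypt_obs`,
#'   `l_villus_obs`, `boundary_used`.
#' @examples
#' m <- cveu_scores(matrix(1, 2, 30), time_h = 0)
#' compartment_counts(position_profile(m), boundary = 20)
#' @export
compartment_counts <- function(profile, boundary) {
  stopifnot(inherits(profile, "cveu_profile"))
  boundary <- as.integer(boundary)
  if (boundary < 1L || boundary > nrow(profile))
    stop("boundary outside the profile's position range", call. = FALSE)
  crypt <- sum(profile$proportion[seq_len(boundary)])
  villus <- sum(profile$proportion[-seq_len(boundary)])
  data.frame(time_h = attr(profile, "time_h"), l_crypt_obs = crypt,
             l_villus_obs = villus, boundary_used = boundary)
}

#' Position of the labeled front
#'
#' The labeled front of a CVEU is its highest (most villus-tip-ward)
#' labeled cell. Its position is converted from a cell index to micrometers
#' from the crypt base and averaged over CVEUs; CVEUs without any labeled
#' cell do not contribute.
#'
#' @param m A [cveu_scores()] matrix.
#' @param cell_length_um Cell length in micrometers (e.g. `10 / density`
#'   with density in cells per 10 um).
#' @return One-row data frame with columns `time_h`, `front_position_um`,
#'   `n_cveu`.
#' @examples
#' m <- cveu_scores(rbind(c(1, 1, 0, 0), c(1, 1, 1, 0)), time_h = 2)
#' front_position(m, cell_length_um = 10)
#' @export
front_position <- function(m, cell_length_um) {
  stopifnot(inherits(m, "cveu_scores"),
            is.numeric(cell_length_um), cell_length_um > 0)
  idx <- apply(m, 1L, function(r) {
    lab <- which(!is.na(r) & r == 1)
    if (length(lab)) max(lab) else NA_integer_
  })
  if (all(is.na(idx)))
    stop("no labeled cell in the score matrix", call. = FALSE)
  data.frame(time_h = attr(m, "time_h"),
             front_position_um = mean(idx * cell_length_um, na.rm = TRUE),
             n_cveu = sum(!is.na(idx)))
}

#' Cell density of a labeled strip
#'
#' Number of cells in a labeled strip divided by the strip length, scaled
#' to cells per 10 micrometers — the unit in which epithelial densities are
#' conventionally reported.
#'
#' @param strip_cell_count Number of cells in the strip.
#' @param strip_length_um Strip length in micrometers; must be positive.
#' @return Density in cells per 10 um.
#' @examples
#' cell_density(30, 240)  # 1.25 cells/10 um
#' @export
cell_density <- function(strip_cell_count, strip_length_um) {
  stopifnot(is.numeric(strip_cell_count), is.numeric(strip_length_um))
  if (any(strip_length_um <= 0))
    stop("strip length must be positive", call. = FALSE)
  10 * strip_cell_count / strip_length_um
}
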