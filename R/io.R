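#' Read and write CVEU score matrices and derived tables
#'
#' Score matrices are stored as delimited text (comma or tab), one file per
#' (group, tissue, time point, analog): a header row of cell positions,
#' then one row of 0/1 scores per CVEU, with empty fields or `NA` marking
#' positions beyond the end of shorter CVEUs. Metadata travel in commented
#' header lines (`# key: value`).
#'
#' @param file Path to the file.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @return `read_scores()` returns a [cveu_scores()] matrix;
#'   `write_scores()` returns `file` invisibly.
#' @examples
#' m <- cveu_scores(rbind(c(1, 0, NA), c(0, 1, 1)), time_h = 2,
#'                  tissue = "ileum", group = "control", analog = "BrdU")
#' f <- tempfile(fileext = ".csv")
#' write_scores(m, f)
#' all.equal(unclass(read_scores(f)), unclass(m), check.attributes = FALSE)
#' @name scores_io
NULL

#' @rdname scores_io
#' @param m A [cveu_scores()] matrix to write.
#' @export
write_scores <- function(m, file, sep = ",") {
  stopifnot(inherits(m, "cveu_scores"))
  meta <- sprintf("# %s: %s", c("time_h", "tissue", "group", "analog"),
                  c(attr(m, "time_h"), attr(m, "tissue"),
                    attr(m, "group"), attr(m, "analog")))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(seq_len(ncol(m)), collapse = sep), con)
  utils::write.table(unclass(m), con, sep = sep, na = "",
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname scores_io
#' @export
read_scores <- function(file, sep = ",") {
  lines <- readLines(file)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(time_h = NA, tissue = NA_character_, group = NA_character_,
               analog = NA_character_)
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    if (key %in% names(meta)) meta[[key]] <- val
  }
  body <- lines[!grepl("^#", lines)]
  dat <- utils::read.table(text = body, sep = sep, header = TRUE,
                           na.strings = c("", "NA"))
  cveu_scores(as.matrix(dat), time_h = as.numeric(meta$time_h),
              tissue = meta$tissue, group = meta$group,
              analog = meta$analog)
}

#' Write profiles and compartment counts as tidy tables
#'
#' Long-format delimited tables with one value per row: profiles carry
#' columns `group`, `tissue`, `analog`, `time_h`, `position`, `proportion`,
#' `n_obs`; compartment counts carry `time_h`, `compartment`, `value`,
#' `boundary_used`.
#'
#' @param profile A [position_profile()].
#' @param counts A data frame of compartment counts.
#' @param file Output path.
#' @param sep Field separator (default `","`).
#' @return The path, invisibly.
#' @name tidy_io
NULL

#' @rdname tidy_io
#' @export
write_profile <- function(profile, file, sep = ",") {
  stopifnot(inherits(profile, "cveu_profile"))
  df <- data.frame(group = attr(profile, "group"),
                   tissue = attr(profile, "tissue"),
                   analog = attr(profile, "analog"),
                   time_h = attr(profile, "time_h"),
                   position = profile$position,
                   proportion = profile$proportion,
                   n_obs = profile$n_obs)
  utils::write.table(df, file, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname tidy_io
#' @export
write_counts <- function(counts, file, sep = ",") {
  long <- rbind(
    data.frame(time_h = counts$time_h, compartment = "crypt",
               value = counts$l_crypt_obs,
               boundary_used = counts$boundary_used),
    data.frame(time_h = counts$time_h, compartment = "villus",
               value = counts$l_villus_obs,
               boundary_used = counts$boundary_used))
  utils::write.table(long[order(long$time_h), ], file, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname tidy_io
#' @export
read_counts <- function(file, sep = ",") {
  long <- utils::read.table(file, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE)
  wide <- merge(
    stats::setNames(long[long$compartment == "crypt",
                         c("time_h", "value", "boundary_used")],
                    c("time_h", "l_crypt_obs", "boundary_used")),
    stats::setNames(long[long$compartment == "villus",
                         c("time_h", "value")],
                    c("time_h", "l_villus_obs")),
    by = "time_h")
  wide[order(wide$time_h),
       c("time_h", "l_crypt_obs", "l_villus_obs", "boundary_used")]
}
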