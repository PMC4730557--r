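#' Read and write the pipeline's standard file formats
#'
#' NIfTI for volumetric data (via RNifti), tab-delimited text for tables,
#' waveforms and sensor arrays.
#'
#' @param run a [bold_run()].
#' @param path file or directory path.
#' @param prefix filename prefix for the run's files.
#' @return `write_bold_run` invisibly returns the written paths;
#'   `read_bold_run` returns a [bold_run()].
#' @name rsfa-io
NULL

#' @rdname rsfa-io
#' @export
write_bold_run <- function(run, path, prefix = "run") {
  stopifnot(inherits(run, "bold_run"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(path, paste0(prefix, "_", x))
  RNifti::writeNifti(RNifti::asNifti(run$data, pixdim = c(3, 3, 3, run$tr)),
                     f("bold.nii.gz"))
  for (mm in c("gm", "wm", "csf")) {
    RNifti::writeNifti(RNifti::asNifti(run[[paste0(mm, "_mask")]] * 1),
                       f(paste0(mm, "_mask.nii.gz")))
  }
  motion <- as.data.frame(run$motion)
  names(motion) <- c(paste0("trans_", c("x", "y", "z")),
                     paste0("rot_", c("x", "y", "z")))
  utils::write.table(motion, f("motion.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("tr_s\t%g", run$tr), f("meta.tsv"))
  invisible(path)
}

#' @rdname rsfa-io
#' @export
read_bold_run <- function(path, prefix = "run") {
  f <- function(x) file.path(path, paste0(prefix, "_", x))
  dat <- array(as.numeric(RNifti::readNifti(f("bold.nii.gz"))),
               dim = dim(RNifti::readNifti(f("bold.nii.gz"))))
  masks <- lapply(c("gm", "wm", "csf"), function(mm) {
    m <- RNifti::readNifti(f(paste0(mm, "_mask.nii.gz")))
    array(as.numeric(m) > 0.5, dim = dim(m))
  })
  motion <- utils::read.delim(f("motion.tsv"))
  meta <- utils::read.delim(f("meta.tsv"), header = FALSE)
  tr <- as.numeric(meta[meta[[1]] == "tr_s", 2])
  bold_run(dat, tr, masks[[1]], masks[[2]], masks[[3]], motion)
}

#' @rdname rsfa-io
#' @param map an `rsfa_map`.
#' @export
write_rsfa_map <- function(map, path) {
  stopifnot(inherits(map, "rsfa_map"))
  RNifti::writeNifti(RNifti::asNifti(map$values), path)
  invisible(path)
}

#' Read / write delimited event, waveform, cohort and sensor files
#'
#' Events use columns `onset_s`, `duration_s`, `condition`; waveforms use
#' `time_s`, `value`; sensor runs are written as a channels x samples TSV
#' whose first line records the sampling rate.
#'
#' @param events an [event_table()].
#' @param path file path.
#' @name rsfa-io-text
NULL

#' @rdname rsfa-io-text
#' @export
write_events <- function(events, path) {
  utils::write.table(
    data.frame(onset_s = events$onset, duration_s = events$duration,
               condition = events$condition),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname rsfa-io-text
#' @export
read_events <- function(path) {
  d <- utils::read.delim(path)
  event_table(d$onset_s, d$duration_s, d$condition)
}

#' @rdname rsfa-io-text
#' @param w a [waveform()].
#' @param modality stored modality label when reading.
#' @export
write_waveform <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  tt <- (seq_along(w$values) - 1L) / w$fs
  utils::write.table(data.frame(time_s = tt, value = w$values), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname rsfa-io-text
#' @export
read_waveform <- function(path, modality = "pulseox") {
  d <- utils::read.delim(path)
  fs <- 1 / stats::median(diff(d$time_s))
  waveform(d$value, fs, modality)
}

#' @rdname rsfa-io-text
#' @param cohort a [generate_cohort()] table.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname rsfa-io-text
#' @export
read_cohort <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' @rdname rsfa-io-text
#' @param run a [sensor_run()].
#' @export
write_sensor_tsv <- function(run, path) {
  stopifnot(inherits(run, "sensor_run"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%g", run$fs), con)
  utils::write.table(data.frame(channel = run$channel_ids, run$data),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname rsfa-io-text
#' @export
read_sensor_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  fs <- as.numeric(sub("# fs_hz=", "", header, fixed = TRUE))
  d <- utils::read.delim(path, skip = 1L)
  sensor_run(as.matrix(d[, -1, drop = FALSE]), fs, channel_ids = d$channel)
}
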