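## Delimited-text export/import of raw acquisition channels. One file per
## channel plus a YAML manifest; units are stated in the column headers.

#' Export a recording as delimited-text channel tables
#'
#' Writes `frames.tsv` (long format: `time_s`, `depth_mm`, `amplitude`),
#' `force.tsv` (`time_s`, `force_N`) and `manifest.yaml` (acquisition
#' configuration and protocol) into `dir`.
#'
#' @param recording an `indentation_recording`.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fr <- recording$frames
  frames_long <- data.frame(
    time_s = rep(fr$times, each = length(fr$depth_mm)),
    depth_mm = rep(fr$depth_mm, times = length(fr$times)),
    amplitude = as.vector(fr$amplitude))
  utils::write.table(frames_long, file.path(dir, "frames.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(time_s = recording$force$times,
               force_N = recording$force$force_N),
    file.path(dir, "force.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  yaml::write_yaml(list(config = unclass(recording$config),
                        protocol = unclass(recording$protocol),
                        overlap_flagged = recording$overlap_flagged),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Import a recording from delimited-text channel tables
#'
#' Reads the layout written by [write_recording()]; also accepts externally
#' produced tables with the same columns.
#'
#' @param dir directory containing `frames.tsv`, `force.tsv` and
#'   `manifest.yaml`.
#' @return an `indentation_recording`.
#' @export
read_recording <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  frames_long <- utils::read.table(file.path(dir, "frames.tsv"),
                                   header = TRUE, sep = "\t")
  force <- utils::read.table(file.path(dir, "force.tsv"),
                             header = TRUE, sep = "\t")
  times <- unique(frames_long$time_s)
  depth <- unique(frames_long$depth_mm)
  amp <- matrix(frames_long$amplitude, nrow = length(depth),
                ncol = length(times))
  structure(list(frames = list(times = times, depth_mm = depth,
                               amplitude = amp),
                 force = list(times = force$time_s,
                              force_N = force$force_N),
                 protocol = do.call(loading_protocol, man$protocol),
                 config = do.call(acquisition_config,
                                  man$config[setdiff(names(man$config),
                                                     character(0))]),
                 overlap_flagged = isTRUE(man$overlap_flagged)),
            class = "indentation_recording")
}

#' Write per-subject modulus results as a delimited-text table
#'
#' @param records the per-subject results data frame of a pipeline run.
#' @param path output file (CSV).
#' @return invisibly, `path`.
#' @export
write_subject_results <- function(records, path) {
  utils::write.csv(format_table_fixed(records), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Read a per-subject results table written by [write_subject_results()]
#'
#' @param path CSV file path.
#' @return data frame.
#' @export
read_subject_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
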