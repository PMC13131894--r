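#' Read / write EMG traces as two-column CSV
#'
#' Columns: `time_s`, `mv`.  Pulse onsets, when present, travel in a
#' `# pulse_onsets:` comment line so a single file round-trips a record.
#'
#' @param rec An `emg_record`.
#' @param path File path.
#' @return `write_emg_csv` returns `path` invisibly; `read_emg_csv`
#'   returns an `emg_record`.
#' @export
write_emg_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pulse_onsets: %s",
                     paste(rec$pulse_onsets, collapse = " ")), con)
  writeLines("time_s,mv", con)
  t <- (seq_along(rec$samples) - 1) / rec$fs
  writeLines(paste(format(t, trim = TRUE), rec$samples, sep = ","), con)
  invisible(path)
}

#' @rdname write_emg_csv
#' @export
read_emg_csv <- function(path) {
  first <- readLines(path, n = 1)
  onsets <- numeric(0)
  skip <- 0
  if (startsWith(first, "# pulse_onsets:")) {
    onsets <- as.numeric(strsplit(trimws(sub("# pulse_onsets:", "", first)),
                                  "\\s+")[[1]])
    onsets <- onsets[!is.na(onsets)]
    skip <- 1
  }
  df <- read.csv(path, skip = skip)
  fs <- 1 / median(diff(df$time_s))
  structure(list(samples = df$mv, fs = fs, pulse_onsets = onsets,
                 meta = list(), truth = NULL), class = "emg_record")
}

#' Read / write DeepLabCut-style keypoint CSV
#'
#' The on-disk format uses the pose-estimation convention of a three-row
#' header (scorer / bodyparts / coords) above a frame-index column and
#' x, y, likelihood triplets per tracked point; in R the table is a plain
#' data.frame with `<bodypart>_x`, `<bodypart>_y`,
#' `<bodypart>_likelihood` columns.
#'
#' @param table Keypoint data.frame (see [synth_tracks()]).
#' @param path File path.
#' @param fps Frame rate stored on the returned table, Hz.
#' @return `write_dlc_csv` returns `path` invisibly; `read_dlc_csv`
#'   returns the data.frame with an `fps` attribute.
#' @export
write_dlc_csv <- function(table, path) {
  cols <- setdiff(names(table), "frame")
  part <- sub("_(x|y|likelihood)$", "", cols)
  coord <- sub("^.*_(x|y|likelihood)$", "\\1", cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("scorer", rep("dgfus", length(cols))), collapse = ","),
             con)
  writeLines(paste(c("bodyparts", part), collapse = ","), con)
  writeLines(paste(c("coords", coord), collapse = ","), con)
  mat <- cbind(table$frame, as.matrix(table[cols]))
  utils::write.table(mat, con, sep = ",", col.names = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dlc_csv
#' @export
read_dlc_csv <- function(path, fps = NULL) {
  hdr <- readLines(path, n = 3)
  part <- strsplit(hdr[2], ",")[[1]][-1]
  coord <- strsplit(hdr[3], ",")[[1]][-1]
  df <- read.csv(path, skip = 3, header = FALSE)
  names(df) <- c("frame", paste0(part, "_", coord))
  attr(df, "fps") <- fps
  df
}

#' Write a pixel map (displacement, correlation, power Doppler) as CSV
#'
#' Plain matrix CSV, axial rows by lateral columns, no header — a
#' text-format exchange for downstream plotting.
#'
#' @param map A map object with a `values` or `r` matrix, or a matrix.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  m <- if (is.matrix(map)) map else
    if (!is.null(map$values)) map$values else map$r
  utils::write.table(m, path, sep = ",", col.names = FALSE,
                     row.names = FALSE)
  invisible(path)
}
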