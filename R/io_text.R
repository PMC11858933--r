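# Text-format I/O: TRC marker trajectories, per-camera 2D track CSV, and
# joint-angle CSV export.

#' Write a 3D track to a TRC file
#'
#' Tab-separated marker trajectory format as consumed by musculoskeletal
#' modeling tools. Invisible samples are written as blank fields.
#'
#' @param track a [track3d()].
#' @param path output path.
#' @param units coordinate units to declare (always written as mm values).
#' @return `path`, invisibly.
#' @export
write_trc <- function(track, path, units = "mm") {
  TT <- n_frames(track); L <- length(track$landmark_names)
  t <- track_times(track)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units", "OrigDataRate", "OrigDataStartFrame",
                   "OrigNumFrames", sep = "\t"), con)
  writeLines(paste(format(track$fs), format(track$fs), TT, L, units,
                   format(track$fs), 1, TT, sep = "\t"), con)
  writeLines(paste0("Frame#\tTime\t",
                    paste(track$landmark_names, collapse = "\t\t\t"), "\t\t"),
             con)
  writeLines(paste0("\t\t", paste(paste0(c("X", "Y", "Z"),
                                         rep(seq_len(L), each = 3)),
                                  collapse = "\t")), con)
  writeLines("", con)
  fmt <- function(x) ifelse(is.finite(x), sprintf("%.8g", x), "")
  for (f in seq_len(TT)) {
    row <- as.numeric(t(matrix(track$data[f, , ], ncol = 3)))
    writeLines(paste(c(f, sprintf("%.8g", t[f]), fmt(row)), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read a TRC file into a 3D track
#'
#' @param path path to a TRC file.
#' @return a [track3d()] (blank/NaN samples marked invisible).
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (!grepl("^PathFileType", lines[1])) stop("not a TRC file: ", path)
  meta <- strsplit(lines[3], "\t")[[1]]
  fs <- as.numeric(meta[1]); L <- as.integer(meta[4])
  units <- meta[5]
  scale <- if (identical(units, "m")) 1000 else 1
  markers <- strsplit(lines[4], "\t")[[1]]
  markers <- markers[-(1:2)]
  markers <- markers[nzchar(markers)]
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  TT <- length(data_lines)
  data <- array(NaN, c(TT, L, 3))
  t0 <- 0
  for (f in seq_len(TT)) {
    fields <- strsplit(data_lines[f], "\t")[[1]]
    if (f == 1) t0 <- as.numeric(fields[2])
    vals <- suppressWarnings(as.numeric(fields[-(1:2)]))
    vals <- c(vals, rep(NA_real_, 3 * L - length(vals)))
    data[f, , ] <- matrix(vals[seq_len(3 * L)], ncol = 3, byrow = TRUE) * scale
  }
  track3d(data, landmark_names = markers[seq_len(L)], fs = fs, t0 = t0)
}

#' Write a 2D landmark track to CSV
#'
#' Long format, one row per (frame, landmark): columns `frame`, `time_s`,
#' `landmark`, `x_px`, `y_px`, `confidence`.
#'
#' @param track a [track2d()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track2d_csv <- function(track, path) {
  TT <- dim(track$data)[1]; L <- dim(track$data)[2]
  t <- track$t0 + (seq_len(TT) - 1) / track$fs
  df <- data.frame(
    frame = rep(seq_len(TT), L),
    time_s = rep(t, L),
    landmark = rep(track$landmark_names, each = TT),
    x_px = as.vector(track$data[, , 1]),
    y_px = as.vector(track$data[, , 2]),
    confidence = as.vector(track$confidence))
  df <- df[order(df$frame, match(df$landmark, track$landmark_names)), ]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a 2D landmark track from CSV
#'
#' @param path CSV with columns `frame`, `time_s`, `landmark`, `x_px`,
#'   `y_px`, `confidence`.
#' @param camera_name camera identifier; default the file name without
#'   extension.
#' @return a [track2d()].
#' @export
read_track2d_csv <- function(path, camera_name = NULL) {
  if (is.null(camera_name))
    camera_name <- sub("_2d$", "", sub("\\.[^.]*$", "", basename(path)))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "landmark", "x_px", "y_px", "confidence")
  if (!all(need %in% names(df)))
    stop("2D track CSV must have columns: ", paste(need, collapse = ", "))
  frames <- sort(unique(df$frame))
  lms <- unique(df$landmark)
  canonical <- hand_landmarks()
  if (all(canonical %in% lms)) lms <- canonical
  TT <- length(frames); L <- length(lms)
  data <- array(NaN, c(TT, L, 2))
  conf <- matrix(0, TT, L)
  fi <- match(df$frame, frames)
  li <- match(df$landmark, lms)
  data[cbind(fi, li, 1L)] <- df$x_px
  data[cbind(fi, li, 2L)] <- df$y_px
  conf[cbind(fi, li)] <- ifelse(is.na(df$confidence), 0, df$confidence)
  tt <- df$time_s[match(frames, df$frame)]
  fs <- if (TT > 1) 1 / stats::median(diff(tt)) else 30
  track2d(camera_name, data, conf, landmark_names = lms,
          fs = fs, t0 = tt[1])
}

#' Write a joint-angle series to CSV
#'
#' Wide format: `time_s` then one column per joint (degrees, NA where
#' invalid), in canonical joint order.
#'
#' @param series a [joint_angle_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_angles_csv <- function(series, path) {
  t <- series$t0 + (seq_len(nrow(series$angles)) - 1) / series$fs
  df <- data.frame(time_s = t, series$angles, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a joint-angle series from CSV
#'
#' @param path CSV as written by [write_angles_csv()].
#' @return a [joint_angle_series()].
#' @export
read_angles_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("angle CSV must have a time_s column")
  t <- df$time_s
  ang <- as.matrix(df[setdiff(names(df), "time_s")])
  fs <- if (length(t) > 1) 1 / stats::median(diff(t)) else 30
  joint_angle_series(ang, joint_names = colnames(ang), fs = fs, t0 = t[1])
}
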