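# Minimal C3D reader/writer for labeled 3D point data.
#
# Implements the subset of the public C3D specification this pipeline
# needs: Intel (little-endian) processor type, 3D point data stored either
# as floats (negative POINT:SCALE) or scaled integers, residual-based
# validity flags, POINT:LABELS/UNITS/RATE parameters, no analog channels.
# Coordinates are float32 on disk, so round-trips are exact to single
# precision.

C3D_BLOCK <- 512L

#' Write a 3D track to a C3D file
#'
#' Standard C3D (Intel processor type, float point data) with POINT labels
#' set to the landmark names and the point rate to the track's sampling
#' rate. Invisible samples are written with residual -1 (invalid), not as
#' zeros.
#'
#' @param track a nonempty [track3d()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_c3d <- function(track, path) {
  TT <- n_frames(track); L <- length(track$landmark_names)
  if (TT < 1 || L < 1) stop("track must be nonempty")

  params <- c3d_param_bytes(track)
  n_param_blocks <- ceiling((length(params) + 4) / C3D_BLOCK)
  data_start <- 2L + n_param_blocks

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")

  # --- header block ---
  writeBin(as.raw(c(2, 0x50)), con)        # first parameter block, magic
  w16(L)                                   # number of 3D points
  w16(0)                                   # analog samples per frame
  w16(1)                                   # first frame
  w16(min(TT, 65535))                      # last frame
  w16(10)                                  # max interpolation gap
  wf(-1)                                   # 3D scale factor (negative: float)
  w16(data_start)                          # data start block
  w16(0)                                   # analog frames per video frame
  wf(track$fs)                             # point frame rate
  writeBin(raw(C3D_BLOCK - 24L), con)

  # --- parameter section ---
  hdr <- as.raw(c(1, 0x50, n_param_blocks, 84))  # 84 = Intel
  writeBin(hdr, con)
  writeBin(params, con)
  writeBin(raw(n_param_blocks * C3D_BLOCK - 4L - length(params)), con)

  # --- point data ---
  frame <- numeric(4 * L)
  out <- numeric(4L * L * TT)
  k <- 0L
  for (f in seq_len(TT)) {
    pts <- matrix(track$data[f, , ], ncol = 3)
    resid <- ifelse(track$visible[f, ], 0, -1)
    pts[!track$visible[f, ], ] <- 0
    block <- cbind(pts, resid)
    out[k + seq_len(4L * L)] <- as.numeric(t(block))
    k <- k + 4L * L
  }
  wf(out)
  invisible(path)
}

# Serialize the parameter section (groups POINT and ANALOG) to raw bytes,
# excluding the 4-byte section header.
c3d_param_bytes <- function(track) {
  TT <- n_frames(track); L <- length(track$landmark_names)
  buf <- raw(0)
  put <- function(...) buf <<- c(buf, ...)
  chr <- function(s) as.raw(utf8ToInt(s))
  i8 <- function(x) as.raw(bitwAnd(as.integer(x), 255L))
  i16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  f32 <- function(x) writeBin(as.numeric(x), raw(), size = 4, endian = "little")

  group <- function(id, name) {
    put(i8(nchar(name)), i8(-id), chr(name), i16(3L), i8(0))
  }
  param <- function(gid, name, type, dims, data_raw, last = FALSE) {
    body <- c(as.raw(type_byte(type)), i8(length(dims)),
              do.call(c, c(list(raw(0)), lapply(dims, i8))), data_raw, i8(0))
    off <- if (last) 0L else length(body) + 2L
    put(i8(nchar(name)), i8(gid), chr(name), i16(off), body)
  }
  type_byte <- function(type)
    switch(type, char = 255L, int = 2L, float = 4L)  # 255 = -1 signed

  group(1L, "POINT")
  param(1L, "USED", "int", integer(0), i16(L))
  param(1L, "FRAMES", "int", integer(0), i16(min(TT, 65535L)))
  param(1L, "SCALE", "float", integer(0), f32(-1))
  param(1L, "RATE", "float", integer(0), f32(track$fs))
  width <- max(4L, max(nchar(track$landmark_names)))
  labs <- formatC(track$landmark_names, width = width, flag = "-")
  param(1L, "LABELS", "char", c(width, L),
        do.call(c, lapply(labs, chr)))
  param(1L, "UNITS", "char", 2L, chr("mm"))
  group(2L, "ANALOG")
  param(2L, "USED", "int", integer(0), i16(0L), last = TRUE)
  buf
}

#' Read a C3D file into a 3D track
#'
#' Point coordinates are converted to mm (from POINT:UNITS), samples with a
#' negative residual are marked invisible, label order is preserved and the
#' frame rate comes from POINT:RATE (falling back to the header).
#'
#' @param path path to a C3D file (Intel processor type).
#' @return a [track3d()].
#' @export
read_c3d <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 2 * C3D_BLOCK || raw_all[2] != as.raw(0x50))
    stop("not a C3D file: ", path)
  r16 <- function(off) readBin(raw_all[off + 1:2], "integer", size = 2,
                               endian = "little", signed = FALSE)
  rf <- function(off) readBin(raw_all[off + 1:4], "numeric", size = 4,
                              endian = "little")
  param_block <- as.integer(raw_all[1])
  n_points <- r16(2)
  first_frame <- r16(6)
  last_frame <- r16(8)
  hdr_scale <- rf(12)
  data_start_hdr <- r16(16)
  hdr_rate <- rf(20)

  poff <- (param_block - 1L) * C3D_BLOCK
  proc <- as.integer(raw_all[poff + 4])
  if (proc != 84) stop("unsupported C3D processor type ", proc,
                       " (only Intel/84 is supported)")
  pars <- parse_c3d_params(raw_all, poff)
  getp <- function(name, default = NULL) {
    if (!is.null(pars[[name]])) pars[[name]] else default
  }
  L <- getp("POINT:USED", n_points)
  if (is.null(L) || L < 1) stop("C3D file has zero labeled points")
  TT <- getp("POINT:FRAMES", last_frame - first_frame + 1L)
  scale <- getp("POINT:SCALE", hdr_scale)
  rate <- getp("POINT:RATE", hdr_rate)
  data_start <- getp("POINT:DATA_START", data_start_hdr)
  labels <- getp("POINT:LABELS", paste0("P", seq_len(L)))
  labels <- trimws(labels)[seq_len(L)]
  blank <- !nzchar(labels)
  labels[blank] <- paste0("P", which(blank))
  units <- trimws(getp("POINT:UNITS", "mm"))
  unit_scale <- if (identical(units, "m")) 1000 else 1

  doff <- (data_start - 1L) * C3D_BLOCK
  n_vals <- 4L * L * TT
  if (scale < 0) {
    vals <- readBin(raw_all[(doff + 1):(doff + 4L * n_vals)], "numeric",
                    n = n_vals, size = 4, endian = "little")
  } else {
    ints <- readBin(raw_all[(doff + 1):(doff + 2L * n_vals)], "integer",
                    n = n_vals, size = 2, endian = "little", signed = TRUE)
    vals <- ints * scale
    # residual words are not scaled for the validity test
    vals[seq(4, n_vals, by = 4)] <- ints[seq(4, n_vals, by = 4)]
  }
  m <- matrix(vals, ncol = 4, byrow = TRUE)  # (T*L) x (x,y,z,residual)
  data <- array(NaN, c(TT, L, 3))
  visible <- matrix(FALSE, TT, L)
  for (l in seq_len(L)) {
    rows <- seq(l, nrow(m), by = L)
    vis <- m[rows, 4] >= 0
    visible[, l] <- vis
    for (k in 1:3) data[, l, k] <- ifelse(vis, m[rows, k] * unit_scale, NaN)
  }
  track3d(data, visible = visible, landmark_names = labels, fs = rate)
}

# Parse the parameter section into a named list "GROUP:PARAM" -> value.
parse_c3d_params <- function(raw_all, poff) {
  i <- poff + 5L  # first group/parameter record (1-based)
  groups <- character(0)
  out <- list()
  rd16 <- function(at, signed = TRUE)
    readBin(raw_all[at + 0:1], "integer", size = 2, endian = "little",
            signed = signed)
  repeat {
    if (i + 1 > length(raw_all)) break
    nlen <- readBin(raw_all[i], "integer", size = 1, signed = TRUE)
    gid <- readBin(raw_all[i + 1], "integer", size = 1, signed = TRUE)
    if (nlen == 0) break
    nlen_a <- abs(nlen)
    name <- rawToChar(raw_all[(i + 2):(i + 1 + nlen_a)])
    off_at <- i + 2L + nlen_a
    offset <- rd16(off_at)
    nxt <- off_at + offset
    if (gid < 0) {
      groups[as.character(-gid)] <- name
    } else {
      type <- readBin(raw_all[off_at + 2], "integer", size = 1, signed = TRUE)
      nd <- as.integer(raw_all[off_at + 3])
      dims <- if (nd > 0) as.integer(raw_all[(off_at + 4):(off_at + 3 + nd)])
              else integer(0)
      n_el <- prod(c(1L, dims))
      dat_at <- off_at + 4L + nd
      val <- NULL
      if (type == -1) {
        s <- rawToChar(raw_all[dat_at + seq_len(n_el) - 1L])
        if (length(dims) >= 2) {
          w <- dims[1]
          val <- substring(s, seq(1, nchar(s), by = w),
                           seq(w, nchar(s), by = w))
        } else val <- s
      } else if (type == 1) {
        val <- as.integer(raw_all[dat_at + seq_len(n_el) - 1L])
      } else if (type == 2) {
        val <- readBin(raw_all[dat_at + seq_len(2L * n_el) - 1L], "integer",
                       n = n_el, size = 2, endian = "little", signed = TRUE)
        val <- ifelse(val < 0, val + 65536L, val)
      } else if (type == 4) {
        val <- readBin(raw_all[dat_at + seq_len(4L * n_el) - 1L], "numeric",
                       n = n_el, size = 4, endian = "little")
      }
      gname <- groups[as.character(gid)]
      if (!is.na(gname) && !is.null(val))
        out[[paste0(gname, ":", name)]] <- val
    }
    if (offset == 0) break
    i <- nxt
  }
  out
}
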