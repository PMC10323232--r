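# ImageJ/Fiji point-ROI interchange.
#
# The binary .roi layout follows the published ImageJ ROI format (RoiDecoder/
# RoiEncoder): a 64-byte big-endian header, packed signed-short coordinates,
# and a second 64-byte header carrying the stack position and the ROI name
# (UTF-16BE). Only point ROIs are supported; the event class is encoded as a
# name prefix ("extrusion_", "sop_", "division_") because the format has no
# class field. The frame index is stored 1-based in both the legacy
# `position` field and the header2 T-position, and converted to 0-based in
# memory.

ROI_MAGIC <- charToRaw("Iout")
ROI_VERSION <- 228L
ROI_TYPE_POINT <- 10L

write_i16 <- function(con, v) writeBin(as.integer(v), con, size = 2, endian = "big")
write_i32 <- function(con, v) writeBin(as.integer(v), con, size = 4, endian = "big")

#' Write one event as an ImageJ point ROI file
#'
#' @param x,y 0-based pixel coordinates of the point.
#' @param t 0-based frame index (stored 1-based on disk, Fiji convention).
#' @param class event class, used as the ROI name prefix.
#' @param path output `.roi` path (or an open binary connection).
#' @param name optional explicit ROI name.
#' @return the ROI name used, invisibly.
#' @export
write_imagej_roi <- function(x, y, t, class = "none", path, name = NULL) {
  if (is.null(name))
    name <- sprintf("%s_%04d-%04d-%04d", class, t + 1L, round(y), round(x))
  con <- if (inherits(path, "connection")) path else {
    cc <- file(path, "wb"); on.exit(close(cc)); cc
  }
  xi <- as.integer(round(x)); yi <- as.integer(round(y))
  n <- 1L
  hdr2_offset <- 64L + 4L * n
  writeBin(ROI_MAGIC, con)
  write_i16(con, ROI_VERSION)
  writeBin(as.raw(c(ROI_TYPE_POINT, 0L)), con)
  write_i16(con, c(yi, xi, yi + 1L, xi + 1L))        # top, left, bottom, right
  write_i16(con, n)                                   # nCoordinates
  writeBin(numeric(4), con, size = 4, endian = "big") # x1..y2 floats, unused
  write_i16(con, 0L)                                  # stroke width
  write_i32(con, c(0L, 0L, 0L))                       # shapeRoiSize, colours
  write_i16(con, c(0L, 0L))                           # subtype, options
  writeBin(as.raw(c(0L, 0L)), con)                    # point type, head size
  write_i16(con, 0L)                                  # arc size
  write_i32(con, t + 1L)                              # position (1-based)
  write_i32(con, hdr2_offset)
  write_i16(con, 0L)                                  # x coord rel. to left
  write_i16(con, 0L)                                  # y coord rel. to top
  # header2: 64 bytes; offsets within are relative to hdr2_offset
  write_i32(con, 0L)                                  # unused
  write_i32(con, c(0L, 0L, t + 1L))                   # C, Z, T positions
  write_i32(con, hdr2_offset + 64L)                   # name offset
  write_i32(con, nchar(name))                         # name length
  write_i32(con, c(0L, 0L))                           # overlay colour/font
  write_i32(con, rep(0L, 8L))                         # remaining header2
  writeBin(as.integer(utf8ToInt(name)), con, size = 2, endian = "big")
  invisible(name)
}

read_i16 <- function(r, off) {  # off is 0-based byte offset into raw vector
  v <- as.integer(r[off + 1L]) * 256L + as.integer(r[off + 2L])
  if (v >= 32768L) v - 65536L else v
}
read_i32 <- function(r, off) {
  sum(as.integer(r[off + 1:4]) * c(2^24, 2^16, 2^8, 1))
}

parse_roi_bytes <- function(r) {
  if (length(r) < 64L || !identical(r[1:4], ROI_MAGIC))
    stop_format("not an ImageJ ROI file")
  type <- as.integer(r[7])
  if (type != ROI_TYPE_POINT) return(NULL)  # caller warns and skips
  top <- read_i16(r, 8L); left <- read_i16(r, 10L)
  n <- read_i16(r, 16L)
  pos <- read_i32(r, 56L)
  h2 <- read_i32(r, 60L)
  tpos <- 0L; zpos <- 0L; name <- ""
  if (h2 > 0L && h2 + 64L <= length(r)) {
    zpos <- read_i32(r, h2 + 8L)
    tpos <- read_i32(r, h2 + 12L)
    noff <- read_i32(r, h2 + 16L); nlen <- read_i32(r, h2 + 20L)
    if (noff > 0L && nlen > 0L && noff + 2L * nlen <= length(r)) {
      codes <- vapply(seq_len(nlen), function(i) read_i16(r, noff + 2L * (i - 1L)), 0L)
      name <- intToUtf8(codes)
    }
  }
  # frame index: prefer the T position, then Z (older Fiji), then the legacy
  # position field; all are 1-based on disk, 0 meaning "not set"
  t1 <- if (tpos > 0L) tpos else if (zpos > 0L) zpos else pos
  xs <- vapply(seq_len(max(n, 1L)), function(i) read_i16(r, 64L + 2L * (i - 1L)), 0L)
  ys <- vapply(seq_len(max(n, 1L)), function(i) read_i16(r, 64L + 2L * n + 2L * (i - 1L)), 0L)
  list(x = left + xs[1], y = top + ys[1], t1 = t1, name = name)
}

roi_class_from_name <- function(name) {
  for (cl in c("extrusion", "division", "sop"))
    if (startsWith(name, paste0(cl, "_")) || identical(name, cl)) return(cl)
  "none"
}

#' Read ImageJ point ROIs as an annotation set
#'
#' Accepts a single `.roi` file, a `.zip` ROI set (as saved by the Fiji ROI
#' manager) or a directory of `.roi` files. Non-point ROIs are skipped with a
#' warning; a missing position field yields `t = 0` with a warning.
#'
#' @param path `.roi` file, `.zip` ROI set, or directory.
#' @param default_class class assigned when the ROI name has no class prefix.
#' @return an [event_set()].
#' @export
read_imagej_rois <- function(path, default_class = "none") {
  if (!file.exists(path)) stop_format("file not found: ", path)
  files <- NULL; tmp <- NULL
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.roi$", full.names = TRUE)
  } else if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    tmp <- tempfile("roiset"); dir.create(tmp)
    utils::unzip(path, exdir = tmp)
    on.exit(unlink(tmp, recursive = TRUE))
    files <- list.files(tmp, pattern = "\\.roi$", full.names = TRUE,
                        recursive = TRUE)
  } else {
    files <- path
  }
  xs <- ys <- ts <- numeric(0); cls <- character(0)
  skipped <- 0L; missing_pos <- 0L
  for (f in sort(files)) {
    p <- parse_roi_bytes(readBin(f, "raw", file.info(f)$size))
    if (is.null(p)) { skipped <- skipped + 1L; next }
    t1 <- p$t1
    if (t1 <= 0L) { missing_pos <- missing_pos + 1L; t1 <- 1L }
    xs <- c(xs, p$x); ys <- c(ys, p$y); ts <- c(ts, t1 - 1L)
    cl <- roi_class_from_name(p$name)
    cls <- c(cls, if (cl == "none" && default_class != "none") default_class else cl)
  }
  if (skipped > 0L) warning(skipped, " non-point ROI(s) skipped")
  if (missing_pos > 0L)
    warning(missing_pos, " ROI(s) had no position field; t set to 0")
  event_set(xs, ys, ts, cls)
}

#' Write an annotation set as an ImageJ ROI set
#'
#' Writes one `.roi` per event. With a `.zip` path the files are bundled into
#' a stored (uncompressed) ZIP archive readable by the Fiji ROI manager; with
#' a directory path they are written individually. The inverse of
#' [read_imagej_rois()] up to the detection probability, which the ROI format
#' cannot carry (use [write_events_csv()] to preserve it).
#'
#' @param events an [event_set()].
#' @param path output `.zip` file or directory.
#' @return `path`, invisibly.
#' @export
write_imagej_rois <- function(events, path) {
  n <- nrow(events)
  if (n == 0L) {   # valid empty archive / directory
    if (grepl("\\.zip$", path, ignore.case = TRUE))
      write_stored_zip(stats::setNames(list(), character(0)), path)
    else if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    return(invisible(path))
  }
  names <- sprintf("%s_%04d-%04d-%04d", events$class, events$t + 1L,
                   round(events$y), round(events$x))
  names <- make.unique(names, sep = "-")
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    entries <- lapply(seq_len(n), function(i) {
      con <- rawConnection(raw(0), "wb")
      write_imagej_roi(events$x[i], events$y[i], events$t[i], events$class[i],
                       con, name = names[i])
      b <- rawConnectionValue(con); close(con); b
    })
    write_stored_zip(stats::setNames(entries, paste0(names, ".roi")), path)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (i in seq_len(n))
      write_imagej_roi(events$x[i], events$y[i], events$t[i], events$class[i],
                       file.path(path, paste0(names[i], ".roi")),
                       name = names[i])
  }
  invisible(path)
}

# ---- minimal stored-ZIP writer -------------------------------------------
# Entries are stored uncompressed; CRC-32 is computed with the standard
# reflected polynomial via a lookup table. Sufficient for ROI sets, which
# are tiny, and keeps the package free of system zip dependencies.

crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(-306674912L, bitwShiftR(c, 1L))
           else bitwShiftR(c, 1L)
    }
    tab[i + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    c <- bitwXor(crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L],
                 bitwShiftR(c, 8L))
  }
  bitwXor(c, -1L)
}

u32le <- function(v) {
  v <- as.numeric(v) %% 2^32
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
           (v %/% 16777216) %% 256))
}
u16le <- function(v) as.raw(c(v %% 256, (v %/% 256) %% 256))

write_stored_zip <- function(entries, path) {
  con <- file(path, "wb"); on.exit(close(con))
  offsets <- integer(length(entries)); pos <- 0L
  crcs <- numeric(length(entries))
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i]); data <- entries[[i]]
    crcs[i] <- as.numeric(crc32(data)) %% 2^32
    offsets[i] <- pos
    hdr <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), u16le(20), u16le(0), u16le(0),
             u16le(0), u16le(0x21), u32le(crcs[i]), u32le(length(data)),
             u32le(length(data)), u16le(length(name)), u16le(0))
    writeBin(c(hdr, name, data), con)
    pos <- pos + length(hdr) + length(name) + length(data)
  }
  cd_start <- pos; cd_size <- 0L
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i]); data <- entries[[i]]
    cd <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)), u16le(20), u16le(20), u16le(0),
            u16le(0), u16le(0), u16le(0x21), u32le(crcs[i]),
            u32le(length(data)), u32le(length(data)), u16le(length(name)),
            u16le(0), u16le(0), u16le(0), u16le(0), u32le(0),
            u32le(offsets[i]))
    writeBin(c(cd, name), con)
    cd_size <- cd_size + length(cd) + length(name)
  }
  writeBin(c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), u16le(0), u16le(0),
             u16le(length(entries)), u16le(length(entries)), u32le(cd_size),
             u32le(cd_start), u16le(0)), con)
  invisible(path)
}
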