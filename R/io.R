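# File formats: CSV tables with '#' provenance comments, JSON parameter
# files, and a minimal grayscale TIFF reader/writer (single strip,
# uncompressed, uint8/uint16/float32) for image frames and velocity fields.
# Numbers are written with 6 significant digits; write -> read -> write is
# byte-identical.

fmt_num <- function(x) {
  out <- sprintf("%.6g", x)
  out[is.na(x)] <- "NA"
  out
}

provenance_lines <- function(meta) {
  meta <- c(list(package = paste0("rachis ",
                                  as.character(utils::packageVersion("rachis")))),
            meta)
  vapply(names(meta), function(k) sprintf("# %s: %s", k,
                                          as.character(meta[[k]])), "")
}

write_table_csv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(provenance_lines(meta), con)
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  for (j in which(num)) out[[j]] <- fmt_num(df[[j]])
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(out), sep = ",")), con)
  invisible(path)
}

read_table_csv <- function(path, required, numeric_cols) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("format error in %s: missing column `%s`", basename(path),
                 missing[1]), call. = FALSE)
  for (cn in intersect(numeric_cols, names(df))) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (any(is.na(vn) & !(v %in% c("NA", ""))))
        stop(sprintf("format error in %s: column `%s` is not numeric",
                     basename(path), cn), call. = FALSE)
      df[[cn]] <- vn
    }
  }
  df
}

#' Read and write cell tables, axial profiles and event streams
#'
#' Plain CSV with a mandatory header, dot decimal separator, 6 significant
#' digits, and `#` comment lines carrying provenance (package version, seed,
#' configuration hash) that are ignored on read.
#'
#' @param cells,profile,events the object to write.
#' @param path file path.
#' @param meta named list written as provenance comments.
#' @return the read object, or (for writers) the path, invisibly.
#' @name rachis_io
#' @export
write_cell_table <- function(cells, path, meta = list()) {
  write_table_csv(cells[, c("gonad_id", "x", "volume_fl",
                            intersect("alive", names(cells)))],
                  path, meta)
}

#' @rdname rachis_io
#' @export
read_cell_table <- function(path) {
  df <- read_table_csv(path, c("gonad_id", "x", "volume_fl"),
                       c("x", "volume_fl"))
  if (any(df$volume_fl <= 0, na.rm = TRUE) ||
      any(df$x < 0 | df$x > 1, na.rm = TRUE))
    stop("cell table violates its invariants (volume > 0, x in [0, 1])",
         call. = FALSE)
  class(df) <- c("cell_table", "data.frame")
  df
}

#' @rdname rachis_io
#' @export
write_axial_profile <- function(profile, path, meta = list()) {
  write_table_csv(as.data.frame(profile), path, meta)
}

#' @rdname rachis_io
#' @export
read_axial_profile <- function(path) {
  df <- read_table_csv(path, "x", c("x", "Qr", "Qc", "J", "S", "Pc", "Pr"))
  do.call(axial_profile, c(list(x = df$x), as.list(df[setdiff(names(df), "x")])))
}

#' @rdname rachis_io
#' @export
write_events <- function(events, path, meta = list()) {
  write_table_csv(events, path, meta)
}

#' @rdname rachis_io
#' @export
read_events <- function(path) {
  df <- read_table_csv(path, c("x", "t_h", "type"), c("x", "t_h"))
  class(df) <- c("event_stream", "data.frame")
  df
}

#' Minimal grayscale TIFF input and output
#'
#' Baseline little-endian TIFF, one image, one strip, no compression.
#' `write_tiff` stores a numeric matrix as 32-bit float (default) or uint16
#' / uint8; `read_tiff` reads those layouts back as a numeric matrix
#' (rows = y). Intended for synthetic frames and velocity-field channels,
#' not as a general TIFF library.
#'
#' @param m numeric matrix (rows = image rows).
#' @param path file path.
#' @param type `"float"`, `"uint16"`, or `"uint8"`.
#' @return `read_tiff`: numeric matrix; `write_tiff`: the path, invisibly.
#' @export
write_tiff <- function(m, path, type = c("float", "uint16", "uint8")) {
  type <- match.arg(type)
  h <- nrow(m); w <- ncol(m)
  bits <- switch(type, float = 32L, uint16 = 16L, uint8 = 8L)
  sfmt <- switch(type, float = 3L, 1L)
  bytes_px <- bits / 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(c(42L), con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")            # IFD offset
  tags <- list( # tag, type (3 short, 4 long), count, value
    c(256L, 4L, 1L, w), c(257L, 4L, 1L, h), c(258L, 3L, 1L, bits),
    c(259L, 3L, 1L, 1L), c(262L, 3L, 1L, 1L),
    c(273L, 4L, 1L, 0L),                                    # strip offset, fixed below
    c(277L, 3L, 1L, 1L), c(278L, 4L, 1L, h),
    c(279L, 4L, 1L, w * h * bytes_px), c(339L, 3L, 1L, sfmt))
  n_tags <- length(tags)
  data_offset <- 8L + 2L + n_tags * 12L + 4L
  tags[[6]][4] <- data_offset
  writeBin(as.integer(n_tags), con, size = 2, endian = "little")
  for (tg in tags) {
    tg <- as.integer(tg)
    writeBin(tg[1], con, size = 2, endian = "little")
    writeBin(tg[2], con, size = 2, endian = "little")
    writeBin(tg[3], con, size = 4, endian = "little")
    if (tg[2] == 3L) { # SHORT packed into 4-byte value field
      writeBin(tg[4], con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(tg[4], con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")            # no next IFD
  v <- as.vector(t(m))                                      # row-major
  if (type == "float") writeBin(v, con, size = 4, endian = "little")
  else writeBin(as.integer(round(v)), con, size = bytes_px,
                endian = "little")
  invisible(path)
}

#' @rdname write_tiff
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (!(raw[1] == charToRaw("I") && raw[2] == charToRaw("I")))
    stop("format error: only little-endian TIFF is supported", call. = FALSE)
  u16 <- function(off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * 256^(0:3))
  ifd <- u32(4)
  n <- u16(ifd)
  fields <- list()
  for (i in seq_len(n)) {
    off <- ifd + 2 + (i - 1) * 12
    tag <- u16(off); typ <- u16(off + 2)
    val <- if (typ == 3L) u16(off + 8) else u32(off + 8)
    fields[[as.character(tag)]] <- val
  }
  w <- fields[["256"]]; h <- fields[["257"]]
  bits <- fields[["258"]] %||% 8L
  comp <- fields[["259"]] %||% 1L
  sfmt <- fields[["339"]] %||% 1L
  soff <- fields[["273"]]
  if (comp != 1L) stop("format error: compressed TIFF is not supported",
                       call. = FALSE)
  npx <- w * h
  con <- rawConnection(raw[(soff + 1):length(raw)])
  on.exit(close(con))
  v <- if (sfmt == 3L && bits == 32L)
    readBin(con, "double", npx, size = 4, endian = "little")
  else readBin(con, "integer", npx, size = bits / 8, signed = FALSE,
               endian = "little")
  matrix(v, nrow = h, byrow = TRUE)
}

#' Write and read a velocity field (two TIFF channels plus CSVs)
#'
#' The axial and transverse velocity components are stored as float TIFFs,
#' the centreline and grid/mask metadata as CSV/JSON next to them.
#'
#' @param field a `velocity_field`.
#' @param basename_path path prefix (without extension).
#' @return `read_velocity_field`: the field; writer: the prefix, invisibly.
#' @export
write_velocity_field <- function(field, basename_path) {
  write_tiff(field$vx, paste0(basename_path, "_vx.tif"))
  write_tiff(field$vy, paste0(basename_path, "_vy.tif"))
  write_tiff((field$mask * 1), paste0(basename_path, "_mask.tif"),
             type = "uint8")
  write_table_csv(field$centreline, paste0(basename_path, "_centreline.csv"))
  jsonlite::write_json(list(x_um = field$x_um, y_um = field$y_um,
                            pixel_size_um = field$pixel_size_um,
                            a_um = field$a_um),
                       paste0(basename_path, "_meta.json"), digits = NA)
  invisible(basename_path)
}

#' @rdname write_velocity_field
#' @export
read_velocity_field <- function(basename_path) {
  meta <- jsonlite::read_json(paste0(basename_path, "_meta.json"),
                              simplifyVector = TRUE)
  structure(list(x_um = meta$x_um, y_um = meta$y_um,
                 vx = read_tiff(paste0(basename_path, "_vx.tif")),
                 vy = read_tiff(paste0(basename_path, "_vy.tif")),
                 mask = read_tiff(paste0(basename_path, "_mask.tif")) > 0,
                 centreline = read_table_csv(
                   paste0(basename_path, "_centreline.csv"),
                   c("x_um", "y_um"), c("x_um", "y_um")),
                 pixel_size_um = meta$pixel_size_um, a_um = meta$a_um),
            class = "velocity_field")
}

#' Read and write parameter lists as JSON
#' @param params named list (e.g. [model_params] or [doublet_params]).
#' @param path file path.
#' @return the list, or the path invisibly.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(unclass(params)[!vapply(unclass(params), is.function,
                                               TRUE)],
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
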