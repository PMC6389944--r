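## Tractogram file I/O.
##
## Two standard on-disk formats are supported:
##   * TCK (MRtrix): text header terminated by "END\n", then little- or
##     big-endian float32 triplets; streamlines separated by a NaN triplet and
##     the stream terminated by an Inf triplet. Coordinates are world mm.
##   * TRK (TrackVis): fixed 1000-byte binary header (version 2 carries a
##     4x4 voxel-to-RAS affine), then per-streamline point counts and float32
##     triplets stored in "voxmm" coordinates: world = A %*% (p / voxel_size
##     - 0.5). Scalars/properties are read past but not retained.
## No installed R package reads these formats, so the parsers live here.

#' Read a tractogram from a TCK or TRK file
#'
#' @param path Path to an existing file.
#' @param format `"auto"` (by extension), `"tck"` or `"trk"`.
#' @return A [tractogram()]. Coordinates are returned in world mm; for TRK
#'   the header affine has already been applied.
#' @export
read_tractogram <- function(path, format = c("auto", "tck", "trk")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tck = "tck", trk = "trk",
                     stop("cannot infer tractogram format from extension: ", path))
  }
  switch(format, tck = read_tck(path), trk = read_trk(path))
}

#' Write a tractogram to a TCK or TRK file
#'
#' @param x A [tractogram()] (coordinates in world mm).
#' @param path Output path.
#' @param format `"auto"` (by extension), `"tck"` or `"trk"`.
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(x, path, format = c("auto", "tck", "trk")) {
  stopifnot(inherits(x, "tractogram"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tck = "tck", trk = "trk",
                     stop("cannot infer tractogram format from extension: ", path))
  }
  switch(format, tck = write_tck(x, path), trk = write_trk(x, path))
  invisible(path)
}

## ---- TCK --------------------------------------------------------------------

read_tck <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  head_limit <- min(length(raw), 4096L)
  pat <- charToRaw("END\n")
  end_at <- NA_integer_
  for (i in which(raw[seq_len(head_limit)] == pat[1])) {
    if (i + 3L <= length(raw) && identical(raw[i:(i + 3L)], pat)) {
      end_at <- i
      break
    }
  }
  if (is.na(end_at)) stop("malformed TCK header: no END marker within first ",
                          head_limit, " bytes (byte offset 0)")
  header <- strsplit(rawToChar(raw[seq_len(end_at - 1L)]), "\n", fixed = TRUE)[[1]]
  if (length(header) == 0 || header[1] != "mrtrix tracks") {
    stop("malformed TCK header at byte offset 0: missing 'mrtrix tracks' magic")
  }
  fields <- header[-1]
  kv <- regmatches(fields, regexec("^([^:]+): *(.*)$", fields))
  keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else NA_character_, "")
  vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else NA_character_, "")
  datatype <- vals[match("datatype", keys)]
  if (is.na(datatype)) datatype <- "Float32LE"
  endian <- if (grepl("BE$", datatype)) "big" else "little"
  if (!grepl("^Float32", datatype)) {
    stop("unsupported TCK datatype: ", datatype)
  }
  filefield <- vals[match("file", keys)]
  if (is.na(filefield)) stop("malformed TCK header: missing 'file' field")
  offset <- as.integer(sub("^\\. +", "", filefield))
  if (is.na(offset) || offset > length(raw)) {
    stop("malformed TCK header: bad data offset '", filefield, "'")
  }
  nbytes <- length(raw) - offset
  if (nbytes %% 4L != 0L) {
    stop("truncated TCK stream at byte offset ", length(raw),
         ": trailing ", nbytes %% 4L, " bytes")
  }
  vals32 <- readBin(raw[(offset + 1L):length(raw)], "numeric",
                    n = nbytes %/% 4L, size = 4L, endian = endian)
  if (length(vals32) %% 3L != 0L) {
    stop("truncated TCK stream at byte offset ", length(raw),
         ": float count not a multiple of 3")
  }
  pts <- matrix(vals32, ncol = 3L, byrow = TRUE)
  is_sep <- is.nan(pts[, 1])
  is_end <- is.infinite(pts[, 1])
  term <- which(is_end)
  if (length(term) == 0) {
    stop("truncated TCK stream at byte offset ", length(raw),
         ": missing Inf terminator")
  }
  pts <- pts[seq_len(term[1] - 1L), , drop = FALSE]
  is_sep <- is_sep[seq_len(term[1] - 1L)]
  grp <- cumsum(c(TRUE, is_sep[-length(is_sep)]))[!is_sep]
  body <- pts[!is_sep, , drop = FALSE]
  streamlines <- if (nrow(body)) {
    unname(lapply(split.data.frame(body, grp), function(m) {
      dimnames(m) <- NULL
      m
    }))
  } else {
    list()
  }
  tractogram(streamlines, affine = diag(4))
}

write_tck <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x$streamlines)
  body <- c("mrtrix tracks",
            "datatype: Float32LE",
            sprintf("count: %d", n))
  ## fixed-point offset: header length depends on the printed offset itself
  offset <- 0L
  repeat {
    lines <- c(body, sprintf("file: . %d", offset), "END")
    new_offset <- sum(nchar(lines, type = "bytes")) + length(lines)  # + newlines
    if (new_offset == offset) break
    offset <- new_offset
  }
  writeChar(paste0(paste(c(body, sprintf("file: . %d", offset), "END"),
                         collapse = "\n"), "\n"), con, eos = NULL)
  for (s in x$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, size = 4L, endian = "little")
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, size = 4L, endian = "little")
  invisible(path)
}

## ---- TRK --------------------------------------------------------------------

trk_pad <- function(s, width) {
  r <- charToRaw(s)
  c(r[seq_len(min(length(r), width))], rep(as.raw(0), max(0L, width - length(r))))
}

write_trk <- function(x, path, dim = c(128L, 128L, 128L)) {
  A <- x$affine
  check_affine(A)
  voxel_size <- affine_voxel_size(A)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(trk_pad("TRACK", 6L), con)                          # id_string
  writeBin(as.integer(dim), con, size = 2L, endian = "little") # dim
  writeBin(as.numeric(voxel_size), con, size = 4L, endian = "little")
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4L, endian = "little") # origin
  writeBin(0L, con, size = 2L, endian = "little")              # n_scalars
  writeBin(rep(as.raw(0), 200L), con)                          # scalar names
  writeBin(0L, con, size = 2L, endian = "little")              # n_properties
  writeBin(rep(as.raw(0), 200L), con)                          # property names
  writeBin(as.numeric(t(A)), con, size = 4L, endian = "little")# vox_to_ras
  writeBin(rep(as.raw(0), 444L), con)                          # reserved
  writeBin(trk_pad("RAS", 4L), con)                            # voxel_order
  writeBin(rep(as.raw(0), 4L), con)                            # pad2
  writeBin(as.numeric(rep(0, 6)), con, size = 4L, endian = "little") # img orient
  writeBin(rep(as.raw(0), 2L), con)                            # pad1
  writeBin(rep(as.raw(0), 6L), con)                            # invert/swap
  writeBin(length(x$streamlines), con, size = 4L, endian = "little") # n_count
  writeBin(2L, con, size = 4L, endian = "little")              # version
  writeBin(1000L, con, size = 4L, endian = "little")           # hdr_size
  Ainv <- solve(A)
  for (s in x$streamlines) {
    vox <- transform_points(Ainv, s)                  # continuous voxel idx
    voxmm <- sweep(vox + 0.5, 2L, voxel_size, "*")
    writeBin(nrow(s), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

read_trk <- function(path) {
  sz <- file.size(path)
  if (sz < 1000) stop("malformed TRK header at byte offset 0: file shorter than 1000 bytes")
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readBin(con, "raw", n = 6L)
  if (rawToChar(id[1:5]) != "TRACK") {
    stop("malformed TRK header at byte offset 0: bad id_string")
  }
  invisible(readBin(con, "integer", n = 3L, size = 2L, endian = "little")) # dim
  voxel_size <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  invisible(readBin(con, "numeric", n = 3L, size = 4L, endian = "little")) # origin
  n_scalars <- readBin(con, "integer", n = 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", n = 200L))
  n_properties <- readBin(con, "integer", n = 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", n = 200L))
  A <- matrix(readBin(con, "numeric", n = 16L, size = 4L, endian = "little"),
              nrow = 4L, byrow = TRUE)
  invisible(readBin(con, "raw", n = 444L + 4L + 4L))           # reserved, order, pad2
  invisible(readBin(con, "numeric", n = 6L, size = 4L, endian = "little"))
  invisible(readBin(con, "raw", n = 2L + 6L))
  n_count <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (hdr_size != 1000L) {
    stop("malformed TRK header at byte offset 996: hdr_size = ", hdr_size)
  }
  if (version < 2L || all(A == 0)) {
    warning("TRK file lacks a vox_to_ras affine; assuming identity")
    A <- diag(4)
    A[cbind(1:3, 1:3)] <- voxel_size
  }
  if (any(voxel_size <= 0)) {
    stop("malformed TRK header at byte offset 12: non-positive voxel size")
  }
  streamlines <- vector("list", max(n_count, 0L))
  i <- 0L
  offset <- 1000L
  repeat {
    np <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(np) == 0L) break
    if (np < 0L) stop("malformed TRK stream at byte offset ", offset,
                      ": negative point count")
    need <- np * (3L + n_scalars)
    vals <- readBin(con, "numeric", n = need, size = 4L, endian = "little")
    if (length(vals) < need) {
      stop("truncated TRK stream at byte offset ", offset + 4L,
           ": expected ", need, " floats")
    }
    if (n_properties > 0L) {
      invisible(readBin(con, "numeric", n = n_properties, size = 4L,
                        endian = "little"))
    }
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(m, 2L, voxel_size, "/") - 0.5
    i <- i + 1L
    if (i > length(streamlines)) streamlines <- c(streamlines, vector("list", 16L))
    streamlines[[i]] <- transform_points(A, vox)
    offset <- offset + 4L + 4L * (need + n_properties)
  }
  tractogram(streamlines[seq_len(i)], affine = A)
}
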