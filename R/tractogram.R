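#' Tractogram container
#'
#' Ordered 3D polylines ("streamlines") in world RAS millimetres with
#' optional nonnegative per-streamline weights (e.g. SIFT2-style multipliers
#' making tractogram density proportional to fiber density).
#'
#' @param streamlines List of numeric matrices, one per streamline, each
#'   n_points x 3 with n_points >= 2.
#' @param weights Optional numeric vector, one nonnegative weight per
#'   streamline.
#' @return An object of class `cc_tractogram`.
#' @export
cc_tractogram <- function(streamlines, weights = NULL) {
  if (!is.list(streamlines))
    stop("streamlines must be a list of point matrices")
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    if (ncol(s) != 3L) stop("streamline points must be n x 3")
    storage.mode(s) <- "double"
    s
  })
  npts <- vapply(streamlines, nrow, integer(1))
  if (any(npts < 2L))
    stop("every streamline must have at least 2 points")
  if (!is.null(weights)) {
    if (length(weights) != length(streamlines))
      stop(sprintf("weight count (%d) does not match streamline count (%d)",
                   length(weights), length(streamlines)))
    if (any(!is.finite(weights)) || any(weights < 0))
      stop("weights must be finite and >= 0")
    weights <- as.double(weights)
  }
  structure(list(streamlines = streamlines, weights = weights),
            class = "cc_tractogram")
}

#' @export
print.cc_tractogram <- function(x, ...) {
  cat(sprintf("<cc_tractogram> %d streamlines%s\n", length(x$streamlines),
              if (is.null(x$weights)) "" else ", weighted"))
  invisible(x)
}

#' @export
length.cc_tractogram <- function(x) length(x$streamlines)

#' Read streamline weights
#'
#' Whitespace/newline-separated ASCII floats, one weight per streamline.
#'
#' @param path Text file of weights.
#' @return Numeric vector.
#' @export
read_weights <- function(path) {
  w <- scan(path, what = double(), quiet = TRUE)
  if (any(!is.finite(w)) || any(w < 0))
    stop("weights must be finite and >= 0")
  w
}

#' Read a tractogram (TCK or TRK)
#'
#' Dispatches on file extension. TCK streamlines are native world mm; TRK
#' voxel-space coordinates are converted to world mm through the header's
#' `vox_to_ras` matrix. Single-point streamlines are dropped (their count is
#' attached as attribute `dropped`) and their weights discarded with them.
#'
#' @param path `.tck` or `.trk` file.
#' @param weights_path Optional text file with one weight per streamline
#'   (counted before dropping single-point streamlines).
#' @return A [cc_tractogram()].
#' @export
read_tractogram <- function(path, weights_path = NULL) {
  ext <- tolower(tools::file_ext(path))
  sl <- switch(ext,
               tck = read_tck_streamlines(path),
               trk = read_trk_streamlines(path),
               stop("unsupported tractogram format: .", ext))
  weights <- if (!is.null(weights_path)) read_weights(weights_path)
  if (!is.null(weights) && length(weights) != length(sl))
    stop(sprintf("weight count (%d) does not match streamline count (%d)",
                 length(weights), length(sl)))
  npts <- vapply(sl, nrow, integer(1))
  dropped <- sum(npts < 2L)
  if (dropped > 0L) {
    message(sprintf("dropped %d single-point streamline(s)", dropped))
    keep <- npts >= 2L
    sl <- sl[keep]
    weights <- weights[keep]
  }
  tract <- cc_tractogram(sl, weights)
  attr(tract, "dropped") <- dropped
  tract
}

## ---- TCK (MRtrix) ----------------------------------------------------------

read_tck_streamlines <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!identical(first, "mrtrix tracks"))
    stop("not a TCK file (missing 'mrtrix tracks' signature)")
  datatype <- "Float32LE"
  offset <- NA_integer_
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed TCK header: no END")
    if (identical(line, "END")) break
    kv <- regmatches(line, regexpr(":", line), invert = TRUE)[[1]]
    if (length(kv) != 2L) next
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (key == "datatype") datatype <- val
    if (key == "file") {
      parts <- strsplit(val, "[[:space:]]+")[[1]]
      if (parts[1] != ".") stop("external TCK data files are not supported")
      offset <- as.integer(parts[2])
    }
  }
  if (is.na(offset)) stop("malformed TCK header: missing 'file' field")
  endian <- if (grepl("BE$", datatype)) "big" else "little"
  size <- if (grepl("64", datatype)) 8L else 4L
  seek(con, offset)
  vals <- readBin(con, "double", n = file.size(path), size = size,
                  endian = endian)
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  is_nan <- rowSums(is.na(pts) & !is.infinite(pts)) > 0L
  is_inf <- rowSums(is.infinite(pts)) > 0L
  breaks <- which(is_nan | is_inf)
  sl <- list(); start <- 1L
  for (b in breaks) {
    if (b > start) sl[[length(sl) + 1L]] <- pts[start:(b - 1L), , drop = FALSE]
    start <- b + 1L
    if (is_inf[b]) break
  }
  sl
}

#' Write a TCK tractogram
#'
#' @param tract A [cc_tractogram()].
#' @param path Output `.tck` path.
#' @param weights_path Optional path for an accompanying ASCII weights file.
#' @return `path`, invisibly.
#' @export
write_tck <- function(tract, path, weights_path = NULL) {
  stopifnot(inherits(tract, "cc_tractogram"))
  hdr_for <- function(off) {
    paste0("mrtrix tracks\n",
           "datatype: Float32LE\n",
           sprintf("count: %d\n", length(tract$streamlines)),
           sprintf("file: . %d\n", off),
           "END\n")
  }
  off <- nchar(hdr_for(0L))
  while (nchar(hdr_for(off)) != off)  # stabilize width of the offset field
    off <- nchar(hdr_for(off))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr_for(off), con, eos = NULL)
  for (s in tract$streamlines) {
    writeBin(as.double(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  if (!is.null(weights_path)) {
    w <- tract$weights
    if (is.null(w)) w <- rep(1, length(tract$streamlines))
    writeLines(format(w, digits = 17, scientific = FALSE, trim = TRUE),
               weights_path)
  }
  invisible(path)
}

## ---- TRK (TrackVis) --------------------------------------------------------
## TRK stores points in "voxmm": voxel indices scaled by voxel_size, with the
## origin at the corner of voxel (0,0,0). Conversion to world RAS mm follows
## the nibabel convention: world = vox_to_ras %*% (p / voxel_size - 0.5).

read_trk_streamlines <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1000L)
  if (length(hdr) < 1000L) stop("malformed TRK header")
  if (rawToChar(hdr[1:5]) != "TRACK") stop("not a TRK file")
  endian <- "little"
  hdr_size <- readBin(hdr[997:1000], "integer", size = 4L, endian = endian)
  if (hdr_size != 1000L) {
    endian <- "big"
    hdr_size <- readBin(hdr[997:1000], "integer", size = 4L, endian = endian)
    if (hdr_size != 1000L) stop("malformed TRK header: hdr_size != 1000")
  }
  voxel_size <- readBin(hdr[13:24], "double", n = 3L, size = 4L,
                        endian = endian)
  n_scalars <- readBin(hdr[37:38], "integer", size = 2L, endian = endian)
  n_properties <- readBin(hdr[239:240], "integer", size = 2L, endian = endian)
  M <- matrix(readBin(hdr[441:504], "double", n = 16L, size = 4L,
                      endian = endian), 4L, 4L, byrow = TRUE)
  if (all(M == 0))
    stop("TRK header has no vox_to_ras transform; cannot map to world mm")
  if (any(voxel_size <= 0))
    stop("TRK header has non-positive voxel_size")
  n_count <- readBin(hdr[989:992], "integer", size = 4L, endian = endian)
  sl <- list()
  repeat {
    np <- readBin(con, "integer", n = 1L, size = 4L, endian = endian)
    if (length(np) == 0L) break
    vals <- readBin(con, "double", n = np * (3L + n_scalars), size = 4L,
                    endian = endian)
    if (n_properties > 0L)
      readBin(con, "double", n = n_properties, size = 4L, endian = endian)
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(m, 2L, voxel_size, "/") - 0.5
    sl[[length(sl) + 1L]] <- t(M[1:3, 1:3] %*% t(vox) + M[1:3, 4])
    if (n_count > 0L && length(sl) >= n_count) break
  }
  sl
}

#' Write a TRK tractogram
#'
#' Stores world-mm streamlines in TrackVis voxmm convention on a reference
#' grid (default: 1 mm isotropic, identity orientation).
#'
#' @param tract A [cc_tractogram()].
#' @param path Output `.trk` path.
#' @param affine Reference voxel-to-world affine (default identity / 1 mm).
#' @param dim Reference grid dimensions.
#' @return `path`, invisibly.
#' @export
write_trk <- function(tract, path, affine = diag(4), dim = c(1L, 1L, 1L)) {
  stopifnot(inherits(tract, "cc_tractogram"))
  vs <- voxel_sizes(affine)
  inv <- solve(affine)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  writeBin(c(charToRaw("TRACK"), as.raw(0L)), con)     # id_string
  wi(dim, 2L)                                          # dim
  wf(vs)                                               # voxel_size
  wf(c(0, 0, 0))                                       # origin
  wi(0L, 2L); writeBin(raw(200L), con)                 # n_scalars + names
  wi(0L, 2L); writeBin(raw(200L), con)                 # n_properties + names
  wf(as.vector(t(affine)))                             # vox_to_ras (row-major)
  writeBin(raw(444L), con)                             # reserved
  writeBin(c(charToRaw("RAS"), as.raw(0L)), con)       # voxel_order
  writeBin(raw(4L), con)                               # pad2
  wf(c(1, 0, 0, 0, 1, 0))                              # image_orientation
  writeBin(raw(2L), con)                               # pad1
  writeBin(raw(6L), con)                               # invert/swap flags
  wi(length(tract$streamlines), 4L)                    # n_count
  wi(2L, 4L)                                           # version
  wi(1000L, 4L)                                        # hdr_size
  for (s in tract$streamlines) {
    vox <- t(inv[1:3, 1:3] %*% t(s) + inv[1:3, 4]) + 0.5
    wi(nrow(s), 4L)
    wf(as.vector(t(sweep(vox, 2L, vs, "*"))))
  }
  invisible(path)
}
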