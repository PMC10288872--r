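#' Midsagittal plane specification
#'
#' A plane in world mm given by an origin point and a unit normal. The left
#' hemisphere is the negative signed side. The common case, the
#' interhemispheric plane `x = x0` in RAS coordinates, can be given as
#' `plane_spec(x = x0)` (normal points right, so left is negative).
#'
#' @param origin Point on the plane (mm).
#' @param normal Plane normal (mm); normalised internally.
#' @param x Shorthand for the plane `x = x0`.
#' @return An object of class `cc_plane`.
#' @export
plane_spec <- function(origin = NULL, normal = NULL, x = NULL) {
  if (!is.null(x)) {
    origin <- c(x, 0, 0)
    normal <- c(1, 0, 0)
  }
  if (is.null(origin) || is.null(normal))
    stop("give either x= or both origin and normal")
  normal <- as.double(normal)
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("plane normal must be non-zero")
  structure(list(origin = as.double(origin), normal = normal / nn),
            class = "cc_plane")
}

#' Parse a command-line plane argument
#'
#' Accepts `"x=<mm>"` or a JSON object `{"origin": [...], "normal": [...]}`.
#'
#' @param text Argument string.
#' @return A [plane_spec()].
#' @export
parse_plane <- function(text) {
  if (grepl("^x\\s*=", text))
    return(plane_spec(x = as.numeric(sub("^x\\s*=", "", text))))
  spec <- jsonlite::fromJSON(text)
  plane_spec(origin = spec$origin, normal = spec$normal)
}

#' Signed distance from points to a plane
#'
#' @param plane A [plane_spec()].
#' @param pts n x 3 matrix (or length-3 vector) of world-mm points.
#' @return Numeric vector of signed distances (negative = left).
#' @export
signed_distance <- function(plane, pts) {
  pts <- matrix(pts, ncol = 3)
  as.vector(sweep(pts, 2L, plane$origin) %*% plane$normal)
}

## nearest-neighbour subdivision of a volume by an integer factor: sub-voxel
## u along an axis has original index floor(u / f) and centre
## (u + 0.5) / f - 0.5 in original index coordinates.
oversample_volume <- function(vol, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor == 1L) return(vol)
  d <- dim(vol$data)
  idx <- lapply(d, function(n) rep(seq_len(n), each = factor))
  data_os <- vol$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  S <- diag(c(rep(1 / factor, 3), 1))
  S[1:3, 4] <- 0.5 / factor - 0.5
  cc_volume(data_os, vol$affine %*% S)
}

#' Extract the midsagittal section of the corpus callosum
#'
#' Oversamples a binary white-matter mask by nearest-neighbour subdivision
#' (default factor 2, i.e. 1 mm native -> 0.5 mm) and intersects it with the
#' midsagittal plane: the section contains exactly the oversampled voxels
#' whose centres lie inside the mask and within half an (oversampled) voxel
#' of the plane, a one-voxel-thick slab. The plane normal must align with a
#' voxel axis; in-plane geometry of oblique planes is not supported.
#'
#' @param wm_mask Binary [cc_volume()] (white-matter or ready-made CC mask).
#' @param plane A [plane_spec()].
#' @param oversample Integer subdivision factor >= 1, default 2.
#' @return An object of class `cc_section`: the in-plane voxel grid with
#'   fields `coords` (n x 2 0-based in-plane indices), `voxel_area` (mm^2),
#'   `voxel_size` (mm per in-plane axis), plus the mapping back to 3D
#'   (`affine`, `shape`, `normal_axis`, `plane_axes`, `slice`, `plane`).
#' @export
extract_section <- function(wm_mask, plane, oversample = 2L) {
  validate_mask(wm_mask)
  stopifnot(inherits(plane, "cc_plane"))
  os <- oversample_volume(wm_mask, oversample)
  dirs <- sweep(os$affine[1:3, 1:3], 2L, voxel_sizes(os$affine), "/")
  align <- abs(as.vector(plane$normal %*% dirs))
  axis <- which.max(align)
  if (align[axis] < 0.999)
    stop("plane normal must align with a voxel axis (oblique planes are not supported)")
  h <- voxel_sizes(os$affine)[axis]
  on_idx <- which(os$data != 0, arr.ind = TRUE) - 1L  # 0-based
  if (nrow(on_idx) == 0L) stop("no callosal section found")
  d <- signed_distance(plane, voxel_to_world(os$affine, on_idx))
  keep <- d >= -h / 2 & d < h / 2
  if (!any(keep)) stop("no callosal section found")
  sel <- on_idx[keep, , drop = FALSE]
  slice <- unique(sel[, axis])
  if (length(slice) != 1L)
    stop("section slab spans multiple voxel layers; check plane and affine")
  plane_axes <- setdiff(1:3, axis)
  coords <- sel[, plane_axes, drop = FALSE]
  if (anyDuplicated(coords)) stop("duplicate in-plane voxels in section")
  vs <- voxel_sizes(os$affine)[plane_axes]
  structure(list(coords = coords,
                 voxel_size = vs,
                 voxel_area = prod(vs),
                 affine = os$affine,
                 shape = dim(os$data),
                 normal_axis = axis,
                 plane_axes = plane_axes,
                 slice = slice,
                 plane = plane),
            class = "cc_section")
}

#' Build a section grid from a ready-made CC section mask
#'
#' Bypasses extraction when a one-voxel-thick midsagittal CC mask is already
#' available (e.g. from an upstream morphological pipeline).
#'
#' @param mask Binary [cc_volume()] whose nonzero voxels form a single
#'   one-voxel-thick slab.
#' @param plane A [plane_spec()] (used downstream for hemisphere sides).
#' @return A `cc_section`.
#' @export
section_from_mask <- function(mask, plane) {
  validate_mask(mask)
  on_idx <- which(mask$data != 0, arr.ind = TRUE) - 1L
  if (nrow(on_idx) == 0L) stop("no callosal section found")
  dirs <- sweep(mask$affine[1:3, 1:3], 2L, voxel_sizes(mask$affine), "/")
  align <- abs(as.vector(plane$normal %*% dirs))
  axis <- which.max(align)
  slice <- unique(on_idx[, axis])
  if (length(slice) != 1L)
    stop("section mask is not a one-voxel-thick slab along the plane normal")
  plane_axes <- setdiff(1:3, axis)
  vs <- voxel_sizes(mask$affine)[plane_axes]
  structure(list(coords = on_idx[, plane_axes, drop = FALSE],
                 voxel_size = vs,
                 voxel_area = prod(vs),
                 affine = mask$affine,
                 shape = dim(mask$data),
                 normal_axis = axis,
                 plane_axes = plane_axes,
                 slice = slice,
                 plane = plane),
            class = "cc_section")
}

#' @export
print.cc_section <- function(x, ...) {
  cat(sprintf("<cc_section> %d voxels x %.4g mm^2 = %.4g mm^2\n",
              nrow(x$coords), x$voxel_area, nrow(x$coords) * x$voxel_area))
  invisible(x)
}

## number of voxels
section_size <- function(section) nrow(section$coords)

## world-mm centres of the section voxels (n x 3)
section_centers <- function(section) {
  idx <- matrix(0, nrow(section$coords), 3)
  idx[, section$plane_axes] <- section$coords
  idx[, section$normal_axis] <- section$slice
  voxel_to_world(section$affine, idx)
}

## anterior-posterior world coordinate of voxel centres (RAS: +y = anterior)
section_ap <- function(section) section_centers(section)[, 2]

## lookup matrix over the in-plane bounding box: entry = voxel row or NA
section_index_map <- function(section) {
  co <- section$coords
  off <- c(min(co[, 1]), min(co[, 2]))
  m <- matrix(NA_integer_, max(co[, 1]) - off[1] + 1L,
              max(co[, 2]) - off[2] + 1L)
  m[cbind(co[, 1] - off[1] + 1L, co[, 2] - off[2] + 1L)] <- seq_len(nrow(co))
  list(map = m, offset = off)
}

## row index in the section for in-plane integer coords (n x 2); NA if absent
section_lookup <- function(imap, ij) {
  ij <- matrix(ij, ncol = 2)
  r <- ij[, 1] - imap$offset[1] + 1L
  c_ <- ij[, 2] - imap$offset[2] + 1L
  ok <- r >= 1L & r <= nrow(imap$map) & c_ >= 1L & c_ <= ncol(imap$map)
  out <- rep(NA_integer_, nrow(ij))
  out[ok] <- imap$map[cbind(r[ok], c_[ok])]
  out
}

N8_OFFSETS <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1),
                    c(-1, 0, 1, -1, 1, -1, 0, 1))

## per-voxel list of 8-neighbour row indices, as an edge list (from, to)
section_neighbors <- function(section) {
  imap <- section_index_map(section)
  co <- section$coords
  n <- nrow(co)
  from <- rep(seq_len(n), each = 8L)
  nb <- co[from, , drop = FALSE] + N8_OFFSETS[rep(1:8, times = n), ]
  to <- section_lookup(imap, nb)
  ok <- !is.na(to)
  list(from = from[ok], to = to[ok])
}

## 8-connected component id per voxel (1-based, arbitrary order)
section_components <- function(section, subset = NULL) {
  n <- section_size(section)
  if (is.null(subset)) subset <- rep(TRUE, n)
  edges <- section_neighbors(section)
  keep <- subset[edges$from] & subset[edges$to]
  adj <- split(edges$to[keep], factor(edges$from[keep], levels = seq_len(n)))
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in which(subset)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.na(comp[w])) {
          comp[w] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

#' Keep the largest connected component of a section
#'
#' Automated surrogate for manual clean-up of obvious segmentation errors:
#' retains the largest 8-connected in-plane component. Ties are broken
#' deterministically: the component reaching furthest anterior wins, then
#' the one with the larger anterior-posterior extent, then the first in
#' scan order. The number of removed voxels is attached as attribute
#' `removed`.
#'
#' @param section A `cc_section`.
#' @return A `cc_section` restricted to one component.
#' @export
clean_section <- function(section) {
  stopifnot(inherits(section, "cc_section"))
  comp <- section_components(section)
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    ap <- section_ap(section)
    ap_max <- vapply(best, function(k) max(ap[comp == k]), double(1))
    best <- best[ap_max == max(ap_max)]
    if (length(best) > 1L) {
      ext <- vapply(best, function(k) diff(range(ap[comp == k])), double(1))
      best <- best[ext == max(ext)]
    }
    best <- best[1L]
  }
  keep <- comp == best
  out <- section
  out$coords <- section$coords[keep, , drop = FALSE]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Paint a section label map back into a 3D volume
#'
#' @param section A `cc_section`.
#' @param values Integer per-voxel values (e.g. parcel labels), length
#'   `nrow(section$coords)`.
#' @return A [cc_volume()] on the (oversampled) section grid with `values`
#'   painted into the slab and 0 elsewhere.
#' @export
section_to_volume <- function(section, values) {
  stopifnot(length(values) == section_size(section))
  arr <- array(0, dim = section$shape)
  idx <- matrix(0L, section_size(section), 3)
  idx[, section$plane_axes] <- section$coords
  idx[, section$normal_axis] <- section$slice
  arr[idx + 1L] <- values
  cc_volume(arr, section$affine)
}
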