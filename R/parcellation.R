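#' Vote kernel configuration
#'
#' Weights of the regularized majority vote: the voxel's own density counts
#' half, each of its eight in-plane neighbours a twelfth. The kernel is left
#' unnormalised (sum 7/6); the per-voxel argmax is scale-free.
#'
#' @param self_weight Weight of the voxel itself (default 1/2).
#' @param neighbor_weight Weight of each 8-neighbour (default 1/12).
#' @return A list of class `cc_vote_config`.
#' @export
vote_config <- function(self_weight = 1 / 2, neighbor_weight = 1 / 12) {
  stopifnot(self_weight > 0, neighbor_weight > 0)
  structure(list(self_weight = self_weight, neighbor_weight = neighbor_weight),
            class = "cc_vote_config")
}

## ---- streamline selection --------------------------------------------------

## crossing points of one streamline with the plane (world mm, k x 3).
## A point exactly on the plane counts as a crossing point itself; otherwise
## crossings are linearly interpolated where the signed distance changes sign.
streamline_crossings <- function(points, d) {
  out <- points[d == 0, , drop = FALSE]
  s <- sign(d)
  i <- which(s[-length(s)] * s[-1] < 0)
  if (length(i) > 0L) {
    t <- d[i] / (d[i] - d[i + 1L])
    out <- rbind(out, points[i, , drop = FALSE] +
                   t * (points[i + 1L, , drop = FALSE] -
                          points[i, , drop = FALSE]))
  }
  out
}

## world points -> section voxel rows (NA when outside). Crossing points lie
## exactly on the plane, i.e. on the boundary of the one-voxel slab, so
## membership is decided by the in-plane coordinates only (check_slab =
## FALSE); for general 3D points the slab index is enforced too.
points_to_section_rows <- function(pts, section, imap, check_slab = TRUE) {
  vox <- world_to_voxel(section$affine, pts)
  idx <- floor(vox + 0.5)  # voxel containing the point (half-open boxes)
  rows <- section_lookup(imap, idx[, section$plane_axes, drop = FALSE])
  if (check_slab)
    rows[idx[, section$normal_axis] != section$slice] <- NA_integer_
  rows
}

#' Select streamlines crossing the midsagittal CC section
#'
#' Positive selection criterion for the corpus callosum bundle: a streamline
#' is retained iff a consecutive point pair changes the sign of the signed
#' plane distance and the linearly interpolated crossing point falls inside
#' a section voxel. All in-section crossing voxels of a retained streamline
#' are recorded (a streamline crossing several times is retained once).
#'
#' @param tract A [cc_tractogram()] in world mm.
#' @param section A `cc_section` (see [extract_section()]).
#' @return A list of class `cc_selection` with `indices` (positions of the
#'   retained streamlines in `tract`), `crossing` (per retained streamline,
#'   the distinct section-voxel row indices crossed), `weights`, and `n_input`.
#' @export
select_cc_streamlines <- function(tract, section) {
  stopifnot(inherits(tract, "cc_tractogram"), inherits(section, "cc_section"))
  plane <- section$plane
  imap <- section_index_map(section)
  crossing <- vector("list", length(tract$streamlines))
  hit <- logical(length(tract$streamlines))
  for (k in seq_along(tract$streamlines)) {
    pts <- tract$streamlines[[k]]
    d <- signed_distance(plane, pts)
    if (all(d > 0) || all(d < 0)) next
    cr <- streamline_crossings(pts, d)
    if (nrow(cr) == 0L) next
    rows <- points_to_section_rows(cr, section, imap, check_slab = FALSE)
    rows <- unique(rows[!is.na(rows)])
    if (length(rows) > 0L) {
      hit[k] <- TRUE
      crossing[[k]] <- rows
    }
  }
  idx <- which(hit)
  structure(list(indices = idx,
                 crossing = crossing[idx],
                 weights = if (!is.null(tract$weights)) tract$weights[idx],
                 n_input = length(tract$streamlines)),
            class = "cc_selection")
}

## ---- endpoint labelling ----------------------------------------------------

## precompute labelled sites (world centres + labels) from a cortex object
prepare_cortex <- function(cortex) {
  if (inherits(cortex, "cc_prepared_cortex")) return(cortex)
  if (inherits(cortex, "cc_volume")) {
    validate_labels(cortex)
    idx <- which(cortex$data > 0, arr.ind = TRUE) - 1L
    structure(list(kind = "volume",
                   sites = voxel_to_world(cortex$affine, idx),
                   labels = as.integer(cortex$data[idx + 1L]),
                   affine = cortex$affine,
                   shape = dim(cortex$data),
                   volume = cortex),
              class = "cc_prepared_cortex")
  } else if (inherits(cortex, "cc_mesh")) {
    lab <- cortex$labels > 0L
    structure(list(kind = "mesh",
                   sites = cortex$vertices[lab, , drop = FALSE],
                   labels = cortex$labels[lab]),
              class = "cc_prepared_cortex")
  } else {
    stop("cortex must be a cc_volume label volume or a cc_mesh")
  }
}

#' Map a streamline endpoint to a cortical parcel
#'
#' For a label volume: the label of the labelled voxel containing the point,
#' else the label of the nearest labelled voxel centre within `radius`
#' (tractography endpoints stop at the grey-matter interface, not inside
#' labelled voxels). For a mesh: the nearest labelled vertex within `radius`.
#' The hemisphere is the sign of the signed plane distance.
#'
#' @param point Length-3 world-mm point.
#' @param cortex Label [cc_volume()], [cc_mesh()], or a prepared cortex.
#' @param plane A [plane_spec()].
#' @param radius Search radius in mm (default 3).
#' @return List with `label` (integer or NA) and `side` (`"L"`, `"R"`, or NA
#'   when the point lies exactly on the plane).
#' @export
endpoint_parcel <- function(point, cortex, plane, radius = 3) {
  stopifnot(radius >= 0)
  cx <- prepare_cortex(cortex)
  d <- signed_distance(plane, point)
  side <- if (d < 0) "L" else if (d > 0) "R" else NA_character_
  label <- NA_integer_
  if (cx$kind == "volume") {
    idx <- floor(world_to_voxel(cx$affine, point) + 0.5)
    if (all(idx >= 0) && all(idx < cx$shape)) {
      v <- cx$volume$data[idx + 1L]
      if (v > 0) label <- as.integer(v)
    }
  }
  if (is.na(label) && nrow(cx$sites) > 0L) {
    d2 <- colSums((t(cx$sites) - as.double(point))^2)
    j <- which.min(d2)
    if (d2[j] <= radius^2) label <- cx$labels[j]
  }
  list(label = label, side = side)
}

#' Assemble the seven homotopic sub-bundles
#'
#' A selected streamline joins the bundle of label l iff its two endpoints
#' lie in opposite hemispheres and both map to cortical parcel l. All other
#' streamlines are discarded and tallied by reason (`on_plane`, `unlabeled`,
#' `same_hemisphere`, `heterotopic`).
#'
#' @param tract The full [cc_tractogram()].
#' @param selection A `cc_selection` from [select_cc_streamlines()].
#' @param cortex Label [cc_volume()] or [cc_mesh()].
#' @param plane A [plane_spec()].
#' @param radius Endpoint search radius in mm (default 3).
#' @return A list of class `cc_bundles`: per parcel, `members` (streamline
#'   positions in `tract`), `weights` and `crossing` (section-voxel rows per
#'   member); plus a `qc` list of discard counts.
#' @export
build_bundles <- function(tract, selection, cortex, plane, radius = 3) {
  stopifnot(inherits(selection, "cc_selection"))
  cx <- prepare_cortex(cortex)
  n <- length(selection$indices)
  lab <- rep(NA_integer_, n)
  reason <- character(n)
  for (k in seq_len(n)) {
    pts <- tract$streamlines[[selection$indices[k]]]
    e1 <- endpoint_parcel(pts[1L, ], cx, plane, radius)
    e2 <- endpoint_parcel(pts[nrow(pts), ], cx, plane, radius)
    if (is.na(e1$side) || is.na(e2$side)) {
      reason[k] <- "on_plane"
    } else if (e1$side == e2$side) {
      reason[k] <- "same_hemisphere"
    } else if (is.na(e1$label) || is.na(e2$label)) {
      reason[k] <- "unlabeled"
    } else if (e1$label != e2$label) {
      reason[k] <- "heterotopic"
    } else {
      lab[k] <- e1$label
      reason[k] <- "kept"
    }
  }
  w <- selection$weights
  bundles <- lapply(1:7, function(l) {
    m <- which(!is.na(lab) & lab == l)
    list(members = selection$indices[m],
         weights = if (!is.null(w)) w[m] else rep(1, length(m)),
         crossing = selection$crossing[m])
  })
  names(bundles) <- parcel_names()
  qc <- as.list(table(factor(reason, levels = c("kept", "on_plane",
                                                "same_hemisphere",
                                                "unlabeled", "heterotopic"))))
  qc <- lapply(qc, as.integer)
  structure(list(bundles = bundles, qc = qc), class = "cc_bundles")
}

## ---- density maps and vote -------------------------------------------------

#' Per-bundle fiber density maps on the section
#'
#' d_l(v) is the sum of streamline weights over the streamlines of bundle l
#' whose crossing voxels include v; each streamline contributes at most once
#' per voxel (a loop through the same voxel does not double-count).
#' Unweighted tractograms use weight 1.
#'
#' @param bundles A `cc_bundles`.
#' @param section A `cc_section`.
#' @return A 7 x n_voxels numeric matrix (rows in parcel order), class
#'   `cc_density`.
#' @export
density_maps <- function(bundles, section) {
  stopifnot(inherits(bundles, "cc_bundles"))
  n <- section_size(section)
  d <- matrix(0, nrow = 7L, ncol = n,
              dimnames = list(parcel_names(), NULL))
  for (l in 1:7) {
    b <- bundles$bundles[[l]]
    for (k in seq_along(b$crossing)) {
      v <- unique(b$crossing[[k]])
      d[l, v] <- d[l, v] + b$weights[k]
    }
  }
  structure(d, class = c("cc_density", "matrix", "array"))
}

#' Regularized majority vote on density maps
#'
#' Each section voxel gets the label whose smoothed density score is largest:
#' `score_l(v) = 1/2 d_l(v) + 1/12 sum of d_l over the in-grid 8-neighbours`.
#' Ties go to the label with the larger whole-section bundle mass, then the
#' lower (more anterior) label index. Voxels whose scores are all zero are
#' left unassigned for [fill_gaps()].
#'
#' @param d A `cc_density` matrix from [density_maps()].
#' @param section A `cc_section`.
#' @param cfg A [vote_config()].
#' @return A list of class `cc_labelmap`: `labels` (integer, NA =
#'   unassigned) and `provenance` (`"voted"` or NA) per section voxel.
#' @export
regularized_vote <- function(d, section, cfg = vote_config()) {
  n <- section_size(section)
  stopifnot(ncol(d) == n)
  d <- unclass(d)  # plain matrix: keeps Matrix's %*% dispatch happy
  if (all(d == 0)) stop("no callosal fibers")
  edges <- section_neighbors(section)
  A <- Matrix::sparseMatrix(i = edges$from, j = edges$to, x = 1,
                            dims = c(n, n))
  score <- cfg$self_weight * d +
    cfg$neighbor_weight * as.matrix(d %*% A)
  mass <- rowSums(d)
  ## label priority for ties: larger mass first, then lower index
  prio <- order(-mass, seq_len(7L))
  labels <- prio[max.col(t(score[prio, , drop = FALSE]),
                         ties.method = "first")]
  labels[apply(score, 2L, max) <= 0] <- NA_integer_
  structure(list(labels = as.integer(labels),
                 provenance = ifelse(is.na(labels), NA_character_, "voted")),
            class = "cc_labelmap")
}

#' Fill unassigned voxels of a label map
#'
#' Zero-density voxels are assigned iteratively: in each pass every
#' unassigned voxel with at least one assigned 8-neighbour takes the modal
#' neighbour label (ties to the lower label index), until stable. Voxels
#' still unassigned (no assigned voxel in their connected surroundings) take
#' the label of the nearest assigned voxel by in-plane Euclidean distance
#' (ties to the lower label index). Filled voxels carry provenance
#' `"filled"`.
#'
#' @param labelmap A `cc_labelmap` from [regularized_vote()].
#' @param section A `cc_section`.
#' @return A total `cc_labelmap` (no NA labels).
#' @export
fill_gaps <- function(labelmap, section) {
  labels <- labelmap$labels
  prov <- labelmap$provenance
  if (!any(!is.na(labels))) stop("cannot fill a fully unassigned label map")
  n <- section_size(section)
  edges <- section_neighbors(section)
  nb <- split(edges$to, factor(edges$from, levels = seq_len(n)))
  repeat {
    todo <- which(is.na(labels))
    if (length(todo) == 0L) break
    newlab <- rep(NA_integer_, length(todo))
    for (i in seq_along(todo)) {
      nl <- labels[nb[[todo[i]]]]
      nl <- nl[!is.na(nl)]
      if (length(nl) > 0L) {
        counts <- tabulate(nl, nbins = 7L)
        newlab[i] <- which.max(counts)  # ties -> lower label index
      }
    }
    if (all(is.na(newlab))) break
    labels[todo] <- newlab
    prov[todo[!is.na(newlab)]] <- "filled"
  }
  todo <- which(is.na(labels))
  if (length(todo) > 0L) {
    co <- sweep(section$coords, 2L, section$voxel_size, "*")  # in-plane mm
    has <- which(!is.na(labels))
    for (v in todo) {
      d2 <- colSums((t(co[has, , drop = FALSE]) - co[v, ])^2)
      best <- has[d2 == min(d2)]
      labels[v] <- min(labels[best])  # equidistant ties -> lower label
      prov[v] <- "filled"
    }
  }
  structure(list(labels = labels, provenance = prov), class = "cc_labelmap")
}

#' @export
print.cc_labelmap <- function(x, ...) {
  cat(sprintf("<cc_labelmap> %d voxels, %d unassigned, %d filled\n",
              length(x$labels), sum(is.na(x$labels)),
              sum(x$provenance == "filled", na.rm = TRUE)))
  invisible(x)
}

## ---- morphometry -----------------------------------------------------------

#' Callosal parcel areas (CcPS)
#'
#' @param labelmap A total `cc_labelmap`.
#' @param section A `cc_section`.
#' @return List with `ccps` (named mm^2 vector over the 7 parcels; absent
#'   parcels report 0) and `cc_total` (mm^2, = sum of `ccps` exactly).
#' @export
parcel_areas <- function(labelmap, section) {
  if (any(is.na(labelmap$labels)))
    stop("label map is not total; run fill_gaps() first")
  counts <- tabulate(labelmap$labels, nbins = 7L)
  ccps <- counts * section$voxel_area
  names(ccps) <- parcel_names()
  list(ccps = ccps, cc_total = sum(ccps))
}

#' Cortical parcel areas (CxPS) and total cortical surface (TCxS)
#'
#' Each triangle contributes a third of its area to the label of each of its
#' vertices; both hemispheres are summed. Unlabelled (label 0) area is by
#' default excluded from both CxPS and TCxS; set `include_unlabeled` to
#' count it in TCxS. Degenerate zero-area triangles are ignored (their count
#' is attached as attribute `degenerate`).
#'
#' @param mesh A [cc_mesh()] in mm.
#' @param include_unlabeled Count label-0 area in TCxS? Default `FALSE`.
#' @return List with `cxps` (named cm^2 vector) and `tcxs` (cm^2).
#' @export
cortical_areas <- function(mesh, include_unlabeled = FALSE) {
  stopifnot(inherits(mesh, "cc_mesh"))
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  area <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)  # mm^2
  degenerate <- sum(area == 0)
  share <- rep(area / 3, 3L)
  lab <- mesh$labels[as.vector(tr)]
  per_label <- vapply(0:7, function(l) sum(share[lab == l]), double(1))
  cxps <- per_label[2:8] / 100  # mm^2 -> cm^2
  names(cxps) <- parcel_names()
  tcxs <- sum(cxps) + if (include_unlabeled) per_label[1] / 100 else 0
  out <- list(cxps = cxps, tcxs = tcxs)
  attr(out, "degenerate") <- degenerate
  out
}

#' Geometric baseline parcellation (Witelson-style)
#'
#' Purely geometric comparator: bins section voxels by the
#' anterior-posterior position of their centres relative to the section's AP
#' extent, cut at the given fractions (measured from the anterior end).
#' The defaults are the classical geometric cuts at 1/3, 1/2, 2/3 and 4/5.
#'
#' @param section A `cc_section`.
#' @param fractions Strictly increasing cut fractions in (0, 1); an empty
#'   vector yields a single parcel.
#' @return A `cc_labelmap` with labels 1..(length(fractions) + 1), anterior
#'   first.
#' @export
witelson_baseline <- function(section, fractions = c(1 / 3, 1 / 2, 2 / 3,
                                                     4 / 5)) {
  if (length(fractions) > 0) {
    if (any(fractions <= 0) || any(fractions >= 1) ||
        any(diff(fractions) <= 0))
      stop("fractions must be strictly increasing within (0, 1)")
  }
  ap <- section_ap(section)
  h <- section$voxel_size[match(2L, section$plane_axes)]
  if (is.na(h)) h <- mean(section$voxel_size)  # AP axis not in-plane: degenerate
  ant_edge <- max(ap) + h / 2
  extent <- ant_edge - (min(ap) - h / 2)
  s <- (ant_edge - ap) / extent  # 0 at anterior edge, 1 at posterior edge
  labels <- findInterval(s, fractions) + 1L
  structure(list(labels = as.integer(labels),
                 provenance = rep("voted", length(labels))),
            class = "cc_labelmap")
}

#' Quality-control report for a parcellation
#'
#' Checks the qualitative expectations for a successful run: one-piece
#' parcels with areas in a plausible band of the total callosal surface.
#'
#' @param labelmap A total `cc_labelmap`.
#' @param section A `cc_section`.
#' @param band Warning band for parcel area fractions (default 0.10-0.25,
#'   the range observed for healthy parcellations).
#' @return A list of class `cc_qc`: per-label component counts, area
#'   fractions, filled-voxel fraction, and character vector `warnings`.
#' @export
qc_report <- function(labelmap, section, band = c(0.10, 0.25)) {
  if (any(is.na(labelmap$labels)))
    stop("label map is not total; run fill_gaps() first")
  labels <- labelmap$labels
  comps <- vapply(1:7, function(l) {
    sub <- labels == l
    if (!any(sub)) return(0L)
    max(section_components(section, subset = sub), na.rm = TRUE)
  }, integer(1))
  counts <- tabulate(labels, nbins = 7L)
  frac <- counts / length(labels)
  warnings <- character(0)
  for (l in which(comps > 1L))
    warnings <- c(warnings, sprintf("parcel '%s' has %d components",
                                    parcel_names()[l], comps[l]))
  tol <- 1e-9
  for (l in which(counts > 0L & (frac < band[1] - tol | frac > band[2] + tol)))
    warnings <- c(warnings,
                  sprintf("parcel '%s' area fraction %.3f outside [%.2f, %.2f]",
                          parcel_names()[l], frac[l], band[1], band[2]))
  structure(list(components = stats::setNames(comps, parcel_names()),
                 area_fraction = stats::setNames(frac, parcel_names()),
                 filled_fraction = mean(labelmap$provenance == "filled",
                                        na.rm = FALSE),
                 n_voxels = length(labels),
                 warnings = warnings),
            class = "cc_qc")
}
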