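#' Labelled triangle mesh
#'
#' Inner cortical surface as a triangle mesh with one parcel label (0 =
#' unlabelled, 1-7 = anterior-posterior cortical parcels) and a hemisphere
#' tag per vertex.
#'
#' @param vertices n x 3 numeric matrix, world mm.
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param labels Integer vector of per-vertex labels in 0..7.
#' @param hemisphere Character vector of `"L"`/`"R"` per vertex.
#' @return An object of class `cc_mesh`.
#' @export
cc_mesh <- function(vertices, triangles, labels, hemisphere) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  labels <- as.integer(labels)
  if (ncol(vertices) != 3L) stop("vertices must be n x 3")
  n <- nrow(vertices)
  if (length(labels) != n || length(hemisphere) != n)
    stop("labels and hemisphere must have one entry per vertex")
  if (any(labels < 0L) || any(labels > 7L))
    stop("vertex labels must lie in 0..7")
  if (any(triangles < 1L) || any(triangles > n))
    stop("triangle indices out of range")
  if (!all(hemisphere %in% c("L", "R")))
    stop("hemisphere tags must be 'L' or 'R'")
  structure(list(vertices = vertices, triangles = triangles,
                 labels = labels, hemisphere = as.character(hemisphere)),
            class = "cc_mesh")
}

#' @export
print.cc_mesh <- function(x, ...) {
  cat(sprintf("<cc_mesh> %d vertices, %d triangles, %d labelled\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$labels > 0L)))
  invisible(x)
}

#' Read a labelled mesh (ASCII)
#'
#' Plain-text format: a `ccmesh 1` signature line, `vertices N` followed by
#' N lines `x y z label hemi`, then `triangles M` followed by M lines of
#' three 0-based vertex indices.
#'
#' @param path Path to the mesh file.
#' @return A [cc_mesh()].
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !grepl("^ccmesh\\s+1$", lines[1]))
    stop("not a ccmesh file")
  vhead <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (vhead[1] != "vertices") stop("malformed ccmesh: expected 'vertices N'")
  n <- as.integer(vhead[2])
  vrows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  vm <- do.call(rbind, lapply(vrows, function(r) as.numeric(r[1:4])))
  hemi <- vapply(vrows, `[`, character(1), 5L)
  thead <- strsplit(trimws(lines[3 + n]), "\\s+")[[1]]
  if (thead[1] != "triangles") stop("malformed ccmesh: expected 'triangles M'")
  m <- as.integer(thead[2])
  tm <- do.call(rbind, lapply(strsplit(trimws(lines[(4 + n):(3 + n + m)]),
                                       "\\s+"),
                              function(r) as.integer(r[1:3])))
  cc_mesh(vm[, 1:3, drop = FALSE], tm + 1L, vm[, 4], hemi)
}

#' Write a labelled mesh (ASCII)
#'
#' @param mesh A [cc_mesh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "cc_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("ccmesh 1", con)
  writeLines(sprintf("vertices %d", nrow(mesh$vertices)), con)
  writeLines(sprintf("%.9g %.9g %.9g %d %s",
                     mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3], mesh$labels, mesh$hemisphere), con)
  writeLines(sprintf("triangles %d", nrow(mesh$triangles)), con)
  writeLines(sprintf("%d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  invisible(path)
}
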