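## GEPOL-style tessellation: every atomic (or auxiliary) sphere carries the
## same triangular mesh, a pentakisdodecahedron (60 faces) optionally
## midpoint-subdivided once (240) or twice (960). Face areas are exact
## spherical-triangle areas so they partition 4*pi*R^2 exactly.

#' Tessellation level
#'
#' The three supported per-sphere tessellation densities: `coarse` (60
#' triangles), `fine` (240, the default elsewhere in the package) and
#' `xfine` (960). Each refinement level splits every triangle in four.
#'
#' @param label `"coarse"`, `"fine"` or `"xfine"`, or an existing
#'   `tess_level` object (returned unchanged).
#' @return A `tess_level` object with fields `label`, `faces_per_sphere`
#'   and `subdivisions` (`faces_per_sphere == 60 * 4^subdivisions`).
#' @export
#' @examples
#' tess_level("fine")$faces_per_sphere  # 240
tess_level <- function(label = c("coarse", "fine", "xfine")) {
  if (inherits(label, "tess_level")) return(label)
  label <- match.arg(label)
  subdivisions <- c(coarse = 0L, fine = 1L, xfine = 2L)[[label]]
  structure(list(label = label,
                 faces_per_sphere = 60L * 4L^subdivisions,
                 subdivisions = subdivisions),
            class = "tess_level")
}

## ---- mesh construction ----------------------------------------------------

## Spherical triangle area (l'Huilier) for unit-sphere vertex triples.
## v1, v2, v3: n x 3 matrices of unit vectors. Returns steradians.
spherical_triangle_areas <- function(v1, v2, v3) {
  ang <- function(a, b) {
    ## robust angle between unit vectors
    2 * asin(pmin(1, 0.5 * sqrt(rowSums((a - b)^2))))
  }
  a <- ang(v2, v3); b <- ang(v1, v3); c <- ang(v1, v2)
  s <- (a + b + c) / 2
  t <- tan(s / 2) * tan((s - a) / 2) * tan((s - b) / 2) * tan((s - c) / 2)
  4 * atan(sqrt(pmax(t, 0)))
}

normalize_rows <- function(m) m / sqrt(rowSums(m^2))

## face centers (radially projected centroids) and spherical areas
mesh_finalize <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  centers <- normalize_rows((v1 + v2 + v3) / 3)
  areas <- spherical_triangle_areas(v1, v2, v3)
  structure(list(vertices = vertices, faces = faces,
                 face_centers = centers, face_areas = areas),
            class = "triangle_mesh")
}

#' Pentakisdodecahedron base mesh
#'
#' Builds the 60-face triangular mesh that seeds the GEPOL tessellation:
#' the regular dodecahedron with each pentagonal face apexed at its
#' radially projected center, all vertices on the unit sphere. The
#' dodecahedron is obtained as the dual of a regular icosahedron, so the
#' connectivity satisfies the Euler relation V - E + F = 2 with V = 32,
#' E = 90, F = 60.
#'
#' @return A `triangle_mesh`: `vertices` (32 x 3 unit vectors), `faces`
#'   (60 x 3 vertex indices, outward-oriented), `face_centers` (radially
#'   projected centroids) and `face_areas` (spherical areas, summing to
#'   4*pi).
#' @export
pentakisdodecahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  ## regular icosahedron: cyclic permutations of (0, +/-1, +/-phi)
  ico <- rbind(
    cbind(0, c(1, 1, -1, -1), c(phi, -phi, phi, -phi)),
    cbind(c(1, 1, -1, -1), c(phi, -phi, phi, -phi), 0),
    cbind(c(phi, -phi, phi, -phi), 0, c(1, 1, -1, -1)))
  ico <- normalize_rows(ico)
  ## icosahedron faces = triples of mutually adjacent vertices
  d <- as.matrix(stats::dist(ico))
  edge_len <- min(d[d > 1e-9])
  adj <- d < edge_len + 1e-9 & d > 1e-9
  faces <- list()
  for (i in 1:10) for (j in (i + 1):11) for (k in (j + 1):12)
    if (adj[i, j] && adj[j, k] && adj[i, k]) faces[[length(faces) + 1L]] <- c(i, j, k)
  ico_faces <- do.call(rbind, faces)   # 20 faces
  ## dual: dodecahedron vertices are projected icosahedron face centroids
  dod <- normalize_rows(t(vapply(seq_len(nrow(ico_faces)), function(f)
    colMeans(ico[ico_faces[f, ], ]), numeric(3))))
  vertices <- rbind(dod, ico)          # 20 pentagon corners + 12 apexes
  tri <- matrix(0L, 60, 3)
  row <- 0L
  for (v in 1:12) {
    ## pentagon around icosahedron vertex v: its 5 incident faces
    inc <- which(apply(ico_faces, 1, function(f) v %in% f))
    apex <- ico[v, ]
    ## order corners cyclically around the apex direction
    ref <- dod[inc[1], ] - sum(dod[inc[1], ] * apex) * apex
    ref <- ref / sqrt(sum(ref^2))
    perp <- c(apex[2] * ref[3] - apex[3] * ref[2],
              apex[3] * ref[1] - apex[1] * ref[3],
              apex[1] * ref[2] - apex[2] * ref[1])
    angs <- vapply(inc, function(f) {
      u <- dod[f, ] - sum(dod[f, ] * apex) * apex
      atan2(sum(u * perp), sum(u * ref))
    }, numeric(1))
    inc <- inc[order(angs)]
    for (e in 1:5) {
      row <- row + 1L
      tri[row, ] <- c(20L + v, inc[e], inc[e %% 5 + 1L])
    }
  }
  ## orient all faces outward (positive triple product)
  for (f in 1:60) {
    vv <- vertices[tri[f, ], ]
    if (det(vv) < 0) tri[f, ] <- tri[f, c(1, 3, 2)]
  }
  mesh_finalize(vertices, tri)
}

#' Subdivide a spherical triangular mesh
#'
#' Midpoint 4-split: each triangle is split into four by its edge
#' midpoints, which are radially projected back to the unit sphere.
#' Children of face `f` occupy rows `4*(f-1)+1 .. 4*f` of the refined
#' face list, so refinement nesting is index-addressable.
#'
#' @param mesh A `triangle_mesh`.
#' @param k Number of 4-splits (k >= 0); face count is multiplied by `4^k`.
#' @return A `triangle_mesh`.
#' @export
subdivide_mesh <- function(mesh, k = 1L) {
  stopifnot(inherits(mesh, "triangle_mesh"), k >= 0)
  if (k == 0) return(mesh)
  for (iter in seq_len(k)) {
    verts <- mesh$vertices
    faces <- mesh$faces
    midkey <- new.env(hash = TRUE, parent = emptyenv())
    nv <- nrow(verts)
    extra <- list()
    midpoint <- function(i, j) {
      key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
      idx <- midkey[[key]]
      if (!is.null(idx)) return(idx)
      m <- verts[i, ] + verts[j, ]
      m <- m / sqrt(sum(m^2))
      extra[[length(extra) + 1L]] <<- m
      idx <- nv + length(extra)
      midkey[[key]] <- idx
      idx
    }
    newf <- matrix(0L, 4L * nrow(faces), 3)
    for (f in seq_len(nrow(faces))) {
      i <- faces[f, 1]; j <- faces[f, 2]; l <- faces[f, 3]
      a <- midpoint(i, j); b <- midpoint(j, l); c <- midpoint(l, i)
      base <- 4L * (f - 1L)
      newf[base + 1L, ] <- c(i, a, c)
      newf[base + 2L, ] <- c(a, j, b)
      newf[base + 3L, ] <- c(c, b, l)
      newf[base + 4L, ] <- c(a, b, c)
    }
    verts <- rbind(verts, do.call(rbind, extra))
    mesh <- mesh_finalize(verts, newf)
  }
  mesh
}

## per-level mesh cache (meshes are deterministic, build once)
.mesh_cache <- new.env(parent = emptyenv())

sphere_mesh <- function(level) {
  level <- tess_level(level)
  key <- level$label
  if (is.null(.mesh_cache[[key]]))
    .mesh_cache[[key]] <- subdivide_mesh(pentakisdodecahedron(),
                                         level$subdivisions)
  .mesh_cache[[key]]
}

## ---- segment containers ---------------------------------------------------

#' Surface segment container
#'
#' Column-major container for cavity surface segments (tesserae, possibly
#' merged): centers and unit outward normals as n x 3 matrices, areas in
#' Angstrom^2, the parent sphere index, and the number of original
#' tesserae each segment has absorbed.
#'
#' @param centers n x 3 matrix of segment centers, Angstrom.
#' @param areas Segment areas, Angstrom^2.
#' @param normals n x 3 matrix of unit outward normals.
#' @param sphere Integer parent-sphere index per segment.
#' @param merged Count of absorbed tesserae per segment (default 1).
#' @return A `cosmo_segments` object.
#' @export
make_segments <- function(centers, areas, normals, sphere, merged = NULL) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  normals <- matrix(as.numeric(normals), ncol = 3)
  if (is.null(merged)) merged <- rep(1L, length(areas))
  structure(list(centers = centers, areas = as.numeric(areas),
                 normals = normals, sphere = as.integer(sphere),
                 merged = as.integer(merged)),
            class = "cosmo_segments")
}

#' Number of surface segments
#' @param segments A `cosmo_segments` object.
#' @return Integer count.
#' @export
n_segments <- function(segments) length(segments$areas)

#' @export
print.cosmo_segments <- function(x, ...) {
  cat(sprintf("<cosmo_segments> %d segments, total area %.4f A^2\n",
              n_segments(x), sum(x$areas)))
  invisible(x)
}

subset_segments <- function(segments, idx) {
  make_segments(segments$centers[idx, , drop = FALSE], segments$areas[idx],
                segments$normals[idx, , drop = FALSE], segments$sphere[idx],
                segments$merged[idx])
}

bind_segments <- function(a, b) {
  if (n_segments(a) == 0) return(b)
  if (n_segments(b) == 0) return(a)
  make_segments(rbind(a$centers, b$centers), c(a$areas, b$areas),
                rbind(a$normals, b$normals), c(a$sphere, b$sphere),
                c(a$merged, b$merged))
}

#' Tessellate a single sphere
#'
#' Places the per-level mesh on a sphere: tessera centers are the radially
#' projected face centroids scaled to the sphere surface, areas scale as
#' `radius^2` and normals point away from the sphere center.
#'
#' @param center Numeric length-3 sphere center (Angstrom).
#' @param radius Sphere radius in Angstrom (> 0).
#' @param level A [tess_level()] or its label.
#' @param sphere_id Integer id recorded on each tessera.
#' @return A `cosmo_segments` object with `level$faces_per_sphere` tesserae.
#' @export
#' @examples
#' s <- tessellate_sphere(c(0, 0, 0), 1.0, "coarse")
#' n_segments(s)          # 60
#' sum(s$areas) / (4 * pi) # ~1
tessellate_sphere <- function(center, radius, level, sphere_id = 1L) {
  if (radius <= 0) stop("sphere radius must be positive, got ", radius)
  level <- tess_level(level)
  mesh <- sphere_mesh(level)
  centers <- sweep(mesh$face_centers * radius, 2, center, "+")
  make_segments(centers, mesh$face_areas * radius^2, mesh$face_centers,
                rep(sphere_id, nrow(centers)))
}
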