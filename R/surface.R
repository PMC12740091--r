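#' Triangulated surface mesh
#'
#' Light container for hippocampal-style surfaces: vertices in world mm,
#' faces with consistent outward winding, optional per-vertex subfield
#' labels (subiculum, CA1-CA4, DG) and named per-vertex scalar arrays.
#'
#' @param vertices n x 3 numeric matrix of coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param labels optional per-vertex label vector (factor or character).
#' @param scalars optional named list of per-vertex numeric vectors.
#' @return Object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, labels = NULL, scalars = list()) {
  vertices <- as.matrix(vertices); faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL; dimnames(faces) <- NULL
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            max(faces) <= nrow(vertices), min(faces) >= 1)
  if (!is.null(labels)) stopifnot(length(labels) == nrow(vertices))
  a <- face_areas(vertices, faces)
  if (any(a <= 0)) stop("mesh contains degenerate (zero-area) faces")
  structure(list(vertices = vertices, faces = faces, labels = labels,
                 scalars = scalars),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces", if (!is.null(x$labels)) paste0(", labels: ",
        paste(unique(as.character(x$labels)), collapse = ", ")), "\n",
      sep = "")
  invisible(x)
}

face_areas <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

face_normals <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  cr / pmax(sqrt(rowSums(cr^2)), 1e-300)
}

#' Per-vertex barycentric areas
#'
#' One third of the area of each incident triangle, a partition of unity of
#' the total mesh area.
#'
#' @param mesh a [surface_mesh()].
#' @return Numeric vector of per-vertex areas (mm^2).
#' @export
vertex_areas <- function(mesh) {
  fa <- face_areas(mesh$vertices, mesh$faces) / 3
  va <- numeric(nrow(mesh$vertices))
  for (j in 1:3) {
    acc <- tapply(fa, mesh$faces[, j], sum)
    idx <- as.integer(names(acc))
    va[idx] <- va[idx] + as.numeric(acc)
  }
  va
}

#' Boundary vertices of an open mesh
#'
#' Vertices incident to an edge that belongs to a single face (incomplete
#' one-ring).
#'
#' @param mesh a [surface_mesh()].
#' @return Logical vector.
#' @export
boundary_vertices <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  open_edges <- e[key %in% names(cnt)[cnt == 1], , drop = FALSE]
  out <- logical(nrow(mesh$vertices))
  out[unique(as.vector(open_edges))] <- TRUE
  out
}

#' Discrete mean curvature
#'
#' Cotangent Laplace-Beltrami estimate with mixed Voronoi vertex areas
#' (Voronoi area for non-obtuse triangles; area/2 at the obtuse corner and
#' area/4 at the others otherwise). The magnitude is half the norm of the
#' mean-curvature normal; the sign is taken from its projection on the
#' outward vertex normal, so locally convex regions are positive. Boundary
#' vertices (incomplete one-ring) are returned as NA rather than silently
#' computed.
#'
#' @param mesh a [surface_mesh()] with consistent outward winding.
#' @return Per-vertex mean curvature H in 1/mm; NA at boundary vertices.
#' @export
mean_curvature <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  nv <- nrow(v)
  hvec <- matrix(0, nv, 3)
  amix <- numeric(nv)
  # accumulate cotangent weights and mixed areas face by face (vectorised
  # over all faces, one pass per corner)
  p1 <- v[f[, 1], , drop = FALSE]; p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  cot_at <- function(a, b, c) {       # cot of angle at a, spanned to b, c
    u <- b - a; w <- c - a
    num <- rowSums(u * w)
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    num / pmax(sqrt(rowSums(cr^2)), 1e-300)
  }
  ct1 <- cot_at(p1, p2, p3); ct2 <- cot_at(p2, p3, p1); ct3 <- cot_at(p3, p1, p2)
  areas <- face_areas(v, f)
  add_vec <- function(idx, val) {
    for (k in 1:3) {
      acc <- tapply(val[, k], idx, sum)
      ii <- as.integer(names(acc))
      hvec[ii, k] <<- hvec[ii, k] + as.numeric(acc)
    }
  }
  # cot formula: sum over edges (i,j): (cot alpha + cot beta) (v_i - v_j);
  # accumulate each face's three edge contributions at both endpoints
  add_vec(f[, 1], ct3 * (p1 - p2) + ct2 * (p1 - p3))
  add_vec(f[, 2], ct3 * (p2 - p1) + ct1 * (p2 - p3))
  add_vec(f[, 3], ct2 * (p3 - p1) + ct1 * (p3 - p2))
  # mixed Voronoi areas
  obtuse1 <- ct1 < 0; obtuse2 <- ct2 < 0; obtuse3 <- ct3 < 0
  any_obtuse <- obtuse1 | obtuse2 | obtuse3
  l23 <- rowSums((p2 - p3)^2); l13 <- rowSums((p1 - p3)^2)
  l12 <- rowSums((p1 - p2)^2)
  a1 <- ifelse(any_obtuse, ifelse(obtuse1, areas / 2, areas / 4),
               (l12 * ct3 + l13 * ct2) / 8)
  a2 <- ifelse(any_obtuse, ifelse(obtuse2, areas / 2, areas / 4),
               (l12 * ct3 + l23 * ct1) / 8)
  a3 <- ifelse(any_obtuse, ifelse(obtuse3, areas / 2, areas / 4),
               (l13 * ct2 + l23 * ct1) / 8)
  for (j in 1:3) {
    acc <- tapply(list(a1, a2, a3)[[j]], f[, j], sum)
    ii <- as.integer(names(acc))
    amix[ii] <- amix[ii] + as.numeric(acc)
  }
  # outward vertex normals: area-weighted face normals
  fn <- face_normals(v, f) * areas
  vn <- matrix(0, nv, 3)
  for (j in 1:3) {
    for (k in 1:3) {
      acc <- tapply(fn[, k], f[, j], sum)
      ii <- as.integer(names(acc))
      vn[ii, k] <- vn[ii, k] + as.numeric(acc)
    }
  }
  kvec <- hvec / (2 * pmax(amix, 1e-300))   # mean-curvature normal, |K| = 2H
  h <- sqrt(rowSums(kvec^2)) / 2
  sgn <- sign(rowSums(kvec * vn))
  h <- h * ifelse(sgn == 0, 1, sgn)
  h[boundary_vertices(mesh)] <- NA_real_
  h
}

#' Per-vertex gyrification
#'
#' Ratio of the vertex's barycentric area on the native (folded) surface to
#' its area on the unfolded surface; the two meshes must share vertex
#' indexing and face connectivity.
#'
#' @param native,unfolded [surface_mesh()] objects in correspondence.
#' @return Per-vertex positive ratio.
#' @export
gyrification <- function(native, unfolded) {
  check_correspondence(native, unfolded)
  a_n <- vertex_areas(native)
  a_u <- vertex_areas(unfolded)
  if (any(a_u <= 0)) stop("unfolded surface has zero-area vertices")
  a_n / a_u
}

#' Per-vertex thickness
#'
#' Euclidean distance between corresponding vertices of the inner and outer
#' gray-matter surfaces. Undefined (NA) for dentate-gyrus-labelled vertices,
#' which lack a two-layer structure.
#'
#' @param inner,outer [surface_mesh()] objects in correspondence.
#' @param dg_label label value marking the dentate gyrus (default "DG").
#' @return Per-vertex distance in mm; NA for DG vertices.
#' @export
thickness <- function(inner, outer, dg_label = "DG") {
  check_correspondence(inner, outer)
  if (!is.null(inner$labels) && !is.null(outer$labels) &&
      !identical(as.character(inner$labels), as.character(outer$labels)))
    stop("label mismatch between inner and outer surfaces")
  th <- sqrt(rowSums((inner$vertices - outer$vertices)^2))
  lab <- if (!is.null(inner$labels)) inner$labels else outer$labels
  if (!is.null(lab)) th[as.character(lab) == dg_label] <- NA_real_
  th
}

check_correspondence <- function(a, b) {
  if (nrow(a$vertices) != nrow(b$vertices) ||
      !identical(a$faces, b$faces))
    stop("meshes are not in vertex correspondence ",
         "(vertex counts or face connectivity differ)")
  invisible(TRUE)
}

# trilinear interpolation at 0-based voxel coordinates
interp_trilinear <- function(vol, pts, clamp = FALSE) {
  d <- dim(vol)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  if (clamp) {
    x <- pmin(pmax(x, 0), d[1] - 1)
    y <- pmin(pmax(y, 0), d[2] - 1)
    z <- pmin(pmax(z, 0), d[3] - 1)
  }
  ok <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    z >= 0 & z <= d[3] - 1 & is.finite(x) & is.finite(y) & is.finite(z)
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 2); y0 <- pmin(floor(y), d[2] - 2)
  z0 <- pmin(floor(z), d[3] - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0); z0 <- pmax(z0, 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) vol[cbind(i + 1, j + 1, k + 1)]
  v <- at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    at(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    at(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    at(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    at(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    at(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    at(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  out[ok] <- v
  out
}

#' Sample a volumetric map at mesh vertices
#'
#' Trilinear interpolation of a 3D volume at each vertex (typically the
#' mid-thickness surface, to avoid partial-volume effects). Vertices outside
#' the volume return NA.
#'
#' @param volume 3D array.
#' @param mesh a [surface_mesh()] with vertices in world mm.
#' @param affine 4 x 4 voxel-to-world matrix (0-based voxel indices);
#'   default identity (vertices already in voxel units).
#' @return Per-vertex sampled values.
#' @export
sample_at_vertices <- function(volume, mesh, affine = diag(4)) {
  vw <- cbind(mesh$vertices, 1)
  vox <- t(solve(affine) %*% t(vw))[, 1:3, drop = FALSE]
  interp_trilinear(volume, vox)
}
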