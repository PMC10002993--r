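#' Closed triangulated structure mesh
#'
#' Container for a subcortical structure surface (STN, STN subregion, red
#' nucleus): an n x 3 vertex matrix (AC-PC mm), an m x 3 face index matrix
#' (1-based, counter-clockwise seen from outside so normals point outward), a
#' structure label and a hemisphere tag.
#'
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param label one of `"STN"`, `"RN"`, `"STN_dorsolateral"`, `"STN_other"`.
#' @param side `"left"` or `"right"`.
#' @param validate run [validate_mesh()] (closedness, orientation,
#'   degenerate triangles) and fail on violations.
#' @return a `structure_mesh` object.
#' @export
structure_mesh <- function(vertices, faces, label = "STN", side = "right",
                           validate = TRUE) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have 3 columns", call. = FALSE)
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates", call. = FALSE)
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  label <- match.arg(label, c("STN", "RN", "STN_dorsolateral", "STN_other"))
  check_side(side)
  mesh <- structure(list(vertices = vertices, faces = faces,
                         label = label, side = side),
                    class = "structure_mesh")
  if (validate) {
    rep <- validate_mesh(mesh)
    if (!rep$valid)
      stop("invalid structure mesh: ", paste(rep$problems, collapse = "; "),
           call. = FALSE)
  }
  mesh
}

#' @export
print.structure_mesh <- function(x, ...) {
  cat(sprintf("structure_mesh %s (%s): %d vertices, %d faces, volume %.2f mm^3\n",
              x$label, x$side, nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

#' Validate a structure mesh
#'
#' Checks that the surface is closed and consistently oriented (every
#' undirected edge is shared by exactly two faces, traversed once in each
#' direction) and that no triangle is degenerate (area > 1e-12 mm^2).
#'
#' @param mesh a `structure_mesh` or a bare list with `vertices`/`faces`.
#' @return list with `valid` (logical), `problems` (character), and
#'   `boundary_edges` (k x 2 matrix of unmatched edges, possibly empty).
#' @export
validate_mesh <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  problems <- character(); boundary <- matrix(integer(), 0L, 2L)
  if (nrow(F) == 0L) {
    return(list(valid = FALSE, problems = "mesh has no faces",
                boundary_edges = boundary))
  }
  # directed edges i->j from each face
  e_from <- c(F[, 1L], F[, 2L], F[, 3L])
  e_to   <- c(F[, 2L], F[, 3L], F[, 1L])
  dir_key <- paste(e_from, e_to)
  und_key <- paste(pmin(e_from, e_to), pmax(e_from, e_to))
  if (anyDuplicated(dir_key)) {
    problems <- c(problems, "inconsistent orientation (repeated directed edge)")
  }
  cnt <- table(und_key)
  if (any(cnt != 2L)) {
    bad <- names(cnt)[cnt != 2L]
    idx <- match(bad, und_key)
    boundary <- cbind(e_from[idx], e_to[idx])
    problems <- c(problems,
                  sprintf("not watertight: %d edge(s) not shared by exactly 2 faces",
                          length(bad)))
  }
  a <- V[F[, 2L], , drop = FALSE] - V[F[, 1L], , drop = FALSE]
  b <- V[F[, 3L], , drop = FALSE] - V[F[, 1L], , drop = FALSE]
  nx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  ny <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  nz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  areas <- sqrt(nx^2 + ny^2 + nz^2) / 2
  if (any(areas <= 1e-12))
    problems <- c(problems, sprintf("%d degenerate triangle(s)", sum(areas <= 1e-12)))
  list(valid = length(problems) == 0L, problems = problems,
       boundary_edges = boundary)
}

face_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 2L], , drop = FALSE] - V[F[, 1L], , drop = FALSE]
  b <- V[F[, 3L], , drop = FALSE] - V[F[, 1L], , drop = FALSE]
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' Enclosed volume and centroid of a closed mesh
#'
#' Signed-tetrahedron (divergence theorem) formulas; positive volume for
#' outward-oriented faces.
#'
#' @param mesh a `structure_mesh`.
#' @return `mesh_volume`: volume in mm^3. `mesh_centroid`: length-3 centroid
#'   of the enclosed solid (mm).
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  p1 <- V[F[, 1L], , drop = FALSE]
  p2 <- V[F[, 2L], , drop = FALSE]
  p3 <- V[F[, 3L], , drop = FALSE]
  det6 <- p1[, 1L] * (p2[, 2L] * p3[, 3L] - p2[, 3L] * p3[, 2L]) -
          p1[, 2L] * (p2[, 1L] * p3[, 3L] - p2[, 3L] * p3[, 1L]) +
          p1[, 3L] * (p2[, 1L] * p3[, 2L] - p2[, 2L] * p3[, 1L])
  sum(det6) / 6
}

#' @rdname mesh_volume
#' @export
mesh_centroid <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  p1 <- V[F[, 1L], , drop = FALSE]
  p2 <- V[F[, 2L], , drop = FALSE]
  p3 <- V[F[, 3L], , drop = FALSE]
  det6 <- p1[, 1L] * (p2[, 2L] * p3[, 3L] - p2[, 3L] * p3[, 2L]) -
          p1[, 2L] * (p2[, 1L] * p3[, 3L] - p2[, 3L] * p3[, 1L]) +
          p1[, 3L] * (p2[, 1L] * p3[, 2L] - p2[, 2L] * p3[, 1L])
  vol <- sum(det6) / 6
  if (abs(vol) < 1e-12) stop("mesh encloses no volume", call. = FALSE)
  # tetrahedron centroid = (0 + p1 + p2 + p3)/4, weight = signed volume
  cx <- sum(det6 * (p1[, 1L] + p2[, 1L] + p3[, 1L])) / 24
  cy <- sum(det6 * (p1[, 2L] + p2[, 2L] + p3[, 2L])) / 24
  cz <- sum(det6 * (p1[, 3L] + p2[, 3L] + p3[, 3L])) / 24
  c(cx, cy, cz) / vol
}

# ---- primitive mesh generators ------------------------------------------

# base icosahedron on the unit sphere
icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c( t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  V <- V / sqrt(1 + t^2)
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = V, faces = F)
}

subdivide_sphere <- function(V, F) {
  midcache <- new.env(hash = TRUE, parent = emptyenv())
  verts <- lapply(seq_len(nrow(V)), function(i) V[i, ])
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    hit <- midcache[[key]]
    if (!is.null(hit)) return(hit)
    m <- normalize(verts[[i]] + verts[[j]])
    verts[[length(verts) + 1L]] <<- m
    idx <- length(verts)
    midcache[[key]] <- idx
    idx
  }
  newF <- matrix(0L, 4L * nrow(F), 3L)
  for (k in seq_len(nrow(F))) {
    i1 <- F[k, 1L]; i2 <- F[k, 2L]; i3 <- F[k, 3L]
    a <- midpoint(i1, i2); b <- midpoint(i2, i3); cc <- midpoint(i3, i1)
    newF[4L * k - 3L, ] <- c(i1, a, cc)
    newF[4L * k - 2L, ] <- c(i2, b, a)
    newF[4L * k - 1L, ] <- c(i3, cc, b)
    newF[4L * k, ]      <- c(a, b, cc)
  }
  list(vertices = do.call(rbind, verts), faces = newF)
}

#' Icosphere and ellipsoid meshes
#'
#' Geodesic sphere from a subdivided icosahedron; the ellipsoid scales the
#' unit sphere by `radii` and applies an optional rotation. Faces are
#' outward-oriented; the mesh is watertight by construction.
#'
#' @param center length-3 center (mm).
#' @param radius,radii sphere radius / ellipsoid semi-axes (mm).
#' @param rotation 3x3 rotation applied to the scaled sphere (ellipsoid
#'   semi-axis i ends up along `rotation[, i]`).
#' @param subdiv number of subdivision rounds (3 gives 1280 faces).
#' @param label,side passed to [structure_mesh()].
#' @return a `structure_mesh`.
#' @export
icosphere <- function(center = c(0, 0, 0), radius = 1, subdiv = 3L,
                      label = "RN", side = "right") {
  ellipsoid_mesh(center, c(radius, radius, radius), diag(3), subdiv,
                 label = label, side = side)
}

#' @rdname icosphere
#' @export
ellipsoid_mesh <- function(center = c(0, 0, 0), radii = c(1, 1, 1),
                           rotation = diag(3), subdiv = 3L,
                           label = "STN", side = "right") {
  center <- as_point3(center, "center")
  radii <- as.numeric(radii)
  if (length(radii) != 3L || any(radii <= 0)) stop("radii must be 3 positive values",
                                                   call. = FALSE)
  s <- icosahedron()
  for (i in seq_len(subdiv)) s <- subdivide_sphere(s$vertices, s$faces)
  V <- sweep(s$vertices, 2L, radii, `*`) %*% t(rotation)
  V <- sweep(V, 2L, center, `+`)
  structure_mesh(V, s$faces, label = label, side = side)
}

#' Mirror a mesh across the midsagittal plane
#'
#' Negates x and reverses face winding so outward orientation is preserved;
#' the hemisphere tag is flipped.
#'
#' @param mesh a `structure_mesh`.
#' @return the mirrored `structure_mesh`.
#' @export
mirror_mesh <- function(mesh) {
  V <- mesh$vertices
  V[, 1L] <- -V[, 1L]
  F <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  structure_mesh(V, F, label = mesh$label,
                 side = if (mesh$side == "left") "right" else "left")
}

# ---- point / ray queries -------------------------------------------------

#' Point-in-mesh test by generalized winding number
#'
#' Sums the signed solid angle subtended by every face (van Oosterom &
#' Strackee) and normalizes by 4*pi. Points within `surface_tol` of the
#' surface count as inside (contacts touching the structure border count as
#' overlapping).
#'
#' @param mesh a closed `structure_mesh`.
#' @param p query point (length 3, mm).
#' @param surface_tol on-surface tolerance (mm).
#' @return logical.
#' @export
point_in_mesh <- function(mesh, p, surface_tol = 1e-9) {
  p <- as_point3(p, "p")
  V <- mesh$vertices; F <- mesh$faces
  A <- sweep(V[F[, 1L], , drop = FALSE], 2L, p)
  B <- sweep(V[F[, 2L], , drop = FALSE], 2L, p)
  C <- sweep(V[F[, 3L], , drop = FALSE], 2L, p)
  la <- sqrt(rowSums(A^2)); lb <- sqrt(rowSums(B^2)); lc <- sqrt(rowSums(C^2))
  if (min(la, lb, lc) < surface_tol) return(TRUE)  # sits on a vertex
  num <- A[, 1L] * (B[, 2L] * C[, 3L] - B[, 3L] * C[, 2L]) -
         A[, 2L] * (B[, 1L] * C[, 3L] - B[, 3L] * C[, 1L]) +
         A[, 3L] * (B[, 1L] * C[, 2L] - B[, 2L] * C[, 1L])
  den <- la * lb * lc + rowSums(A * B) * lc + rowSums(B * C) * la +
         rowSums(C * A) * lb
  w <- sum(2 * atan2(num, den)) / (4 * pi)
  if (abs(w) >= 0.5 - 1e-6) return(TRUE)
  # near-surface query: the winding number is unreliable, fall back to distance
  if (abs(w) > 1e-3 || surface_tol > 1e-9) {
    d <- min_distance_to_mesh(mesh, p)
    if (d <= surface_tol) return(TRUE)
  }
  FALSE
}

# exact point-triangle distance, vectorized over faces
min_distance_to_mesh <- function(mesh, p) {
  V <- mesh$vertices; F <- mesh$faces
  p1 <- V[F[, 1L], , drop = FALSE]
  e0 <- V[F[, 2L], , drop = FALSE] - p1
  e1 <- V[F[, 3L], , drop = FALSE] - p1
  dp <- sweep(-p1, 2L, p, `+`)     # p - p1
  a <- rowSums(e0 * e0); b <- rowSums(e0 * e1); c <- rowSums(e1 * e1)
  d <- rowSums(e0 * dp); e <- rowSums(e1 * dp)
  det <- pmax(a * c - b * b, 1e-300)
  s <- (c * d - b * e) / det
  t <- (a * e - b * d) / det
  s <- pmin(pmax(s, 0), 1)
  t <- pmin(pmax(t, 0), 1)
  over <- s + t > 1
  if (any(over)) {
    sc <- s[over] / (s[over] + t[over])
    s[over] <- sc; t[over] <- 1 - sc
  }
  # clamped (s, t) is approximate on edges; refine by projecting per edge
  q <- p1 + s * e0 + t * e1
  d2 <- rowSums(sweep(q, 2L, p)^2)
  # edge projections (covers clamping bias)
  edge_d2 <- function(av, bv) {
    ab <- bv - av
    tt <- pmin(pmax(rowSums(sweep(-av, 2L, p, `+`) * ab) / pmax(rowSums(ab^2), 1e-300), 0), 1)
    qq <- av + tt * ab
    rowSums(sweep(qq, 2L, p)^2)
  }
  d2 <- pmin(d2,
             edge_d2(V[F[, 1L], , drop = FALSE], V[F[, 2L], , drop = FALSE]),
             edge_d2(V[F[, 2L], , drop = FALSE], V[F[, 3L], , drop = FALSE]),
             edge_d2(V[F[, 3L], , drop = FALSE], V[F[, 1L], , drop = FALSE]))
  sqrt(min(d2))
}

#' Ray-mesh intersections (Moller-Trumbore)
#'
#' All intersections of the ray `origin + t * direction`, `t >= 0`, with the
#' mesh triangles.
#'
#' @param mesh a `structure_mesh`.
#' @param origin,direction ray origin and direction (direction need not be
#'   unit; `t` is in units of `|direction|`).
#' @return data.frame with columns `t`, `x`, `y`, `z`, `exit` (TRUE where the
#'   ray leaves the solid, i.e. outward normal . direction > 0), sorted by `t`.
#' @export
ray_mesh_intersections <- function(mesh, origin, direction) {
  o <- as_point3(origin, "origin"); d <- as_point3(direction, "direction")
  V <- mesh$vertices; F <- mesh$faces
  p1 <- V[F[, 1L], , drop = FALSE]
  e1 <- V[F[, 2L], , drop = FALSE] - p1
  e2 <- V[F[, 3L], , drop = FALSE] - p1
  # h = d x e2
  hx <- d[2L] * e2[, 3L] - d[3L] * e2[, 2L]
  hy <- d[3L] * e2[, 1L] - d[1L] * e2[, 3L]
  hz <- d[1L] * e2[, 2L] - d[2L] * e2[, 1L]
  a <- e1[, 1L] * hx + e1[, 2L] * hy + e1[, 3L] * hz
  eps <- 1e-12
  ok <- abs(a) > eps
  s <- sweep(-p1, 2L, o, `+`)      # o - p1
  u <- (s[, 1L] * hx + s[, 2L] * hy + s[, 3L] * hz) / ifelse(ok, a, 1)
  # q = s x e1
  qx <- s[, 2L] * e1[, 3L] - s[, 3L] * e1[, 2L]
  qy <- s[, 3L] * e1[, 1L] - s[, 1L] * e1[, 3L]
  qz <- s[, 1L] * e1[, 2L] - s[, 2L] * e1[, 1L]
  v <- (d[1L] * qx + d[2L] * qy + d[3L] * qz) / ifelse(ok, a, 1)
  t <- (e2[, 1L] * qx + e2[, 2L] * qy + e2[, 3L] * qz) / ifelse(ok, a, 1)
  tol <- 1e-9
  hit <- ok & u >= -tol & v >= -tol & (u + v) <= 1 + tol & t >= -tol
  if (!any(hit)) {
    return(data.frame(t = numeric(), x = numeric(), y = numeric(),
                      z = numeric(), exit = logical()))
  }
  N <- face_normals(mesh)[hit, , drop = FALSE]
  tt <- pmax(t[hit], 0)
  pts <- matrix(o, sum(hit), 3L, byrow = TRUE) + tt %o% d
  out <- data.frame(t = tt, x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
                    exit = as.vector(N %*% d) > 0)
  # de-duplicate hits on shared edges/vertices
  out <- out[order(out$t), , drop = FALSE]
  if (nrow(out) > 1L) {
    keep <- c(TRUE, diff(out$t) > 1e-9 * max(1, max(out$t)))
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
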