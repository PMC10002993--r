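# Exact mesh-plane cross sections (axial planes z = const) and convex plane
# clipping. Cross sections are polygons, not voxel masks, so analytic area /
# centroid oracles apply. Plane crossings are computed once per undirected
# mesh edge and chained by edge identity, so loop closure is exact and free
# of floating-point endpoint-matching artifacts.

#' Axial cross-section of a closed mesh
#'
#' Intersects the mesh with the plane `z = z_level` exactly: every triangle
#' crossing the plane contributes one segment between its two crossed edges;
#' segments are chained into closed polygons through the shared edges.
#' Vertices lying numerically on the plane are perturbed by an infinitesimal
#' deterministic epsilon so the section is always generic.
#'
#' @param mesh a `structure_mesh`.
#' @param z_level axial level (mm, +Z inferior).
#' @return list with `polygons` (list of k x 2 matrices of (x, y) loops),
#'   `area` (total, mm^2) and `centroid` (area-weighted, length-3 with
#'   z = z_level), or `NULL` when the plane misses the mesh.
#' @export
cross_section <- function(mesh, z_level) {
  V <- mesh$vertices; F <- mesh$faces
  s <- V[, 3L] - z_level
  s[abs(s) < 1e-12] <- 1e-12          # nudge on-plane vertices
  neg <- s < 0
  tri_neg <- matrix(neg[F], nrow(F), 3L)
  nb <- rowSums(tri_neg)
  crossing <- which(nb == 1L | nb == 2L)
  if (!length(crossing)) return(NULL)

  # crossing point per undirected edge, cached by edge key
  pt_cache <- new.env(hash = TRUE, parent = emptyenv())
  edge_point <- function(i, j) {
    a <- min(i, j); b <- max(i, j)
    kk <- paste(a, b)
    hit <- pt_cache[[kk]]
    if (!is.null(hit)) return(hit)
    tt <- s[a] / (s[a] - s[b])
    p <- V[a, 1:2] + tt * (V[b, 1:2] - V[a, 1:2])
    val <- list(key = kk, p = p)
    pt_cache[[kk]] <- val
    val
  }

  seg_a <- character(length(crossing)); seg_b <- character(length(crossing))
  pts <- new.env(hash = TRUE, parent = emptyenv())
  for (m in seq_along(crossing)) {
    tri <- F[crossing[m], ]
    got <- character(0)
    for (e in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
      i <- tri[e[1L]]; j <- tri[e[2L]]
      if (neg[i] != neg[j]) {
        ep <- edge_point(i, j)
        pts[[ep$key]] <- ep$p
        got <- c(got, ep$key)
      }
    }
    seg_a[m] <- got[1L]; seg_b[m] <- got[2L]
  }

  # chain segments through shared edge keys
  n <- length(seg_a)
  adj <- new.env(hash = TRUE, parent = emptyenv())
  for (m in seq_len(n)) {
    adj[[seg_a[m]]] <- c(adj[[seg_a[m]]], m)
    adj[[seg_b[m]]] <- c(adj[[seg_b[m]]], m)
  }
  used <- logical(n)
  polys <- list()
  for (start in seq_len(n)) {
    if (used[start]) next
    used[start] <- TRUE
    first <- seg_a[start]
    cur <- seg_b[start]
    keys <- c(first)
    closed <- FALSE
    repeat {
      if (cur == first) { closed <- TRUE; break }
      keys <- c(keys, cur)
      cand <- adj[[cur]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break      # open chain (shouldn't happen on closed meshes)
      nxt <- cand[1L]
      used[nxt] <- TRUE
      cur <- if (seg_a[nxt] == cur) seg_b[nxt] else seg_a[nxt]
    }
    if (closed && length(keys) >= 3L) {
      poly <- t(vapply(keys, function(k) pts[[k]], numeric(2)))
      rownames(poly) <- NULL
      polys[[length(polys) + 1L]] <- poly
    }
  }
  if (!length(polys)) return(NULL)
  areas <- vapply(polys, polygon_area, numeric(1))
  cents <- t(vapply(polys, polygon_centroid, numeric(2)))
  total <- sum(abs(areas))
  if (total < 1e-12) return(NULL)
  w <- abs(areas) / total
  list(polygons = polys, area = total,
       centroid = c(colSums(cents * matrix(w, length(w), 2L)), z_level))
}

polygon_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# even-odd point-in-polygon (2D ray casting)
point_in_polygon <- function(p, poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((y[i] > p[2L]) != (y[j] > p[2L]) &&
        p[1L] < (x[j] - x[i]) * (p[2L] - y[i]) / (y[j] - y[i]) + x[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

#' Clip a convex closed mesh by a plane
#'
#' Keeps the half-space `dot(v - point, normal) >= 0`, retriangulating cut
#' faces and capping the (convex) cut polygon with a triangle fan so the
#' result is again closed and outward-oriented. Intended for convex input
#' meshes (ellipsoids/spheres), which is all the synthetic anatomy needs.
#'
#' @param mesh a convex `structure_mesh`.
#' @param point a point on the clipping plane.
#' @param normal plane normal; the kept side is the one `normal` points into.
#' @param label label for the clipped mesh.
#' @return a `structure_mesh`.
#' @export
clip_mesh_plane <- function(mesh, point, normal, label = mesh$label) {
  p0 <- as_point3(point, "point"); nrm <- normalize(as_point3(normal, "normal"))
  V <- mesh$vertices; F <- mesh$faces
  sd <- as.vector(sweep(V, 2L, p0) %*% nrm)
  sd[abs(sd) < 1e-12] <- 1e-12

  verts <- list()
  vkey <- new.env(hash = TRUE, parent = emptyenv())
  add_orig <- function(i) {
    kk <- paste0("v", i)
    hit <- vkey[[kk]]
    if (!is.null(hit)) return(hit)
    verts[[length(verts) + 1L]] <<- V[i, ]
    vkey[[kk]] <- length(verts)
    length(verts)
  }
  add_cut <- function(i, j) {          # crossing point on undirected edge (i, j)
    a <- min(i, j); b <- max(i, j)
    kk <- paste0("e", a, "_", b)
    hit <- vkey[[kk]]
    if (!is.null(hit)) return(hit)
    tt <- sd[a] / (sd[a] - sd[b])
    verts[[length(verts) + 1L]] <<- V[a, ] + tt * (V[b, ] - V[a, ])
    vkey[[kk]] <- length(verts)
    length(verts)
  }

  faces <- list()
  cut_ids <- integer(0)
  for (k in seq_len(nrow(F))) {
    tri <- F[k, ]
    keep <- sd[tri] > 0
    if (!any(keep)) next
    if (all(keep)) {
      faces[[length(faces) + 1L]] <- vapply(tri, add_orig, integer(1))
      next
    }
    # Sutherland-Hodgman on the triangle against the plane
    idx <- integer(0)
    for (e in 1:3) {
      i <- tri[e]; j <- tri[if (e == 3L) 1L else e + 1L]
      if (sd[i] > 0) idx <- c(idx, add_orig(i))
      if (sign(sd[i]) != sign(sd[j])) {
        ci <- add_cut(i, j)
        idx <- c(idx, ci)
        cut_ids <- c(cut_ids, ci)
      }
    }
    for (m in seq_len(length(idx) - 2L)) {
      faces[[length(faces) + 1L]] <- c(idx[1L], idx[m + 1L], idx[m + 2L])
    }
  }
  cut_ids <- unique(cut_ids)
  if (!length(cut_ids)) {
    return(structure_mesh(do.call(rbind, verts), do.call(rbind, faces),
                          label = label, side = mesh$side))
  }
  # cap: order the (convex) cut ring by angle around its centroid in-plane
  cp <- do.call(rbind, verts[cut_ids])
  cen <- colMeans(cp)
  u <- normalize(cp[1L, ] - cen)
  v <- cross3(nrm, u)
  ang <- atan2(as.vector(sweep(cp, 2L, cen) %*% v),
               as.vector(sweep(cp, 2L, cen) %*% u))
  ring <- cut_ids[order(ang)]
  verts[[length(verts) + 1L]] <- cen
  ci <- length(verts)
  nR <- length(ring)
  for (i in seq_len(nR)) {
    j <- if (i == nR) 1L else i + 1L
    tri <- c(ci, ring[i], ring[j])
    e1 <- verts[[tri[2L]]] - verts[[tri[1L]]]
    e2 <- verts[[tri[3L]]] - verts[[tri[1L]]]
    if (sum(cross3(e1, e2) * nrm) > 0) tri <- tri[c(1L, 3L, 2L)]  # cap faces point along -normal
    faces[[length(faces) + 1L]] <- tri
  }
  weld_mesh(do.call(rbind, verts), do.call(rbind, faces),
            label = label, side = mesh$side)
}

# merge vertices within `tol` and drop collapsed faces; keeps a clipped mesh
# watertight when cut points coincide with original vertices
weld_mesh <- function(V, F, label, side, tol = 1e-9) {
  key <- apply(round(V / tol), 1L, paste, collapse = " ")
  first <- match(key, key)
  keep <- sort(unique(first))
  remap <- match(first, keep)
  V2 <- V[keep, , drop = FALSE]
  F2 <- matrix(remap[F], nrow(F), 3L)
  ok <- F2[, 1L] != F2[, 2L] & F2[, 2L] != F2[, 3L] & F2[, 3L] != F2[, 1L]
  structure_mesh(V2, F2[ok, , drop = FALSE], label = label, side = side)
}
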