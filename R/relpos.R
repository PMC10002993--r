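# Relative position of the electrode and the STN at the maximum red-nucleus
# level: the axial level where the RN cross-section is largest anchors the
# analysis; a ray from the RN center through the electrode at that level is
# intersected with the ventral border of the STN, and the electrode-to-border
# Euclidean distance plus a positional category are recorded per electrode
# and method.

#' Axial level of maximal red-nucleus cross-section
#'
#' Scans the z-extent of the mesh at `slice_step` resolution and returns the
#' level whose cross-sectional area is maximal (first such level on ties;
#' deterministic for a fixed step). The default step of 0.1 mm is an order of
#' magnitude below the ~1 mm effects of interest.
#'
#' @param rn the red-nucleus `structure_mesh`.
#' @param slice_step scan resolution (mm).
#' @return the z level (mm).
#' @export
max_rn_level <- function(rn, slice_step = 0.1) {
  stopifnot(inherits(rn, "structure_mesh"))
  if (!is.numeric(slice_step) || slice_step <= 0)
    stop("slice_step must be > 0", call. = FALSE)
  zr <- range(rn$vertices[, 3L])
  if (diff(zr) < 1e-9) stop("mesh has zero z-extent", call. = FALSE)
  zs <- seq(zr[1L], zr[2L], by = slice_step)
  areas <- vapply(zs, function(z) {
    cs <- cross_section(rn, z)
    if (is.null(cs)) 0 else cs$area
  }, numeric(1))
  if (all(areas == 0)) stop("no non-empty cross-section found", call. = FALSE)
  zs[which.max(areas)]
}

#' Centroid of an axial cross-section
#'
#' Area-weighted centroid of the planar polygon(s) cut by `z = z_level`;
#' errors when the plane misses the mesh.
#'
#' @param mesh a `structure_mesh`.
#' @param z_level axial level (mm).
#' @return length-3 centroid with z = `z_level`.
#' @export
cross_section_centroid <- function(mesh, z_level) {
  cs <- cross_section(mesh, z_level)
  if (is.null(cs))
    stop(sprintf("plane z = %g does not intersect the %s mesh", z_level, mesh$label),
         call. = FALSE)
  cs$centroid
}

#' Electrode center point at an axial level
#'
#' Intersects the electrode's contact span (the segment from the ventral-most
#' to the dorsal-most contact center) with the plane `z = z_level`. When the
#' span does not reach the plane the electrode is flagged `above_rn_level`,
#' mirroring how electrodes whose contacts end short of the maximum RN level
#' are excluded from the relative-position analysis.
#'
#' @param cs a `contact_set`.
#' @param z_level axial level (mm).
#' @return list with `point` (length-3 or `NULL`) and `above_level` (logical).
#' @export
electrode_point_at_level <- function(cs, z_level) {
  stopifnot(inherits(cs, "contact_set"))
  p0 <- unname(cs$contacts[1L, ])
  p1 <- unname(cs$contacts[nrow(cs$contacts), ])
  dz <- p1[3L] - p0[3L]
  if (abs(dz) < 1e-12) {
    if (abs(p0[3L] - z_level) < 1e-9)
      return(list(point = p0, above_level = FALSE))   # lies in the plane
    return(list(point = NULL, above_level = TRUE))    # parallel, off-plane
  }
  t <- (z_level - p0[3L]) / dz
  if (t < -1e-9 || t > 1 + 1e-9)
    return(list(point = NULL, above_level = TRUE))
  list(point = p0 + min(max(t, 0), 1) * (p1 - p0), above_level = FALSE)
}

#' Ray intersection with the ventral STN border
#'
#' Casts the ray from the red-nucleus center through the electrode point (both
#' at the same axial level) and returns the intersection with the ventral
#' border of the STN, operationalized as the exit intersection (where the ray
#' leaves the structure) with the largest +Z (most inferior) coordinate;
#' further ties resolve to the largest ray parameter. Errors with class
#' `dbsreco_no_intersection` when the ray misses the STN.
#'
#' @param stn the STN `structure_mesh`.
#' @param rn_center red-nucleus center at the working level.
#' @param electrode_point electrode center point at the same level.
#' @return length-3 intersection point (mm).
#' @export
stn_ventral_intersection <- function(stn, rn_center, electrode_point) {
  rn_center <- as_point3(rn_center, "rn_center")
  electrode_point <- as_point3(electrode_point, "electrode_point")
  if (abs(rn_center[3L] - electrode_point[3L]) > 1e-6)
    stop("rn_center and electrode_point must lie at the same axial level",
         call. = FALSE)
  d <- electrode_point - rn_center
  if (vnorm(d) < 1e-9)
    stop("electrode point coincides with the RN center", call. = FALSE)
  d <- d / vnorm(d)
  hits <- ray_mesh_intersections(stn, rn_center, d)
  exits <- hits[hits$exit, , drop = FALSE]
  if (nrow(exits) == 0L) {
    stop(structure(class = c("dbsreco_no_intersection", "error", "condition"),
                   list(message = "ray from RN center misses the STN",
                        call = NULL)))
  }
  best <- order(-exits$z, -exits$t)[1L]
  c(exits$x[best], exits$y[best], exits$z[best])
}

#' Relative distance between electrode and ventral STN border
#'
#' Plain Euclidean distance between the electrode point at the working level
#' and the STN border intersection.
#'
#' @param electrode_point,stn_intersection length-3 points (mm).
#' @return non-negative distance (mm).
#' @export
relative_distance <- function(electrode_point, stn_intersection) {
  point_distance(electrode_point, stn_intersection)
}

#' Positional category of the electrode relative to the STN cross-section
#'
#' `"within"` when the electrode point falls inside the STN cross-section at
#' the working level; otherwise the dominant axis-wise offset from the
#' cross-section centroid: medial/lateral by X (hemisphere-aware: lateral is
#' away from the midline), anterior/posterior by Y. Equal offsets tie-break
#' to the X axis (lateral before anterior).
#'
#' @param stn the STN `structure_mesh` (its `side` resolves laterality).
#' @param electrode_point electrode center point at `z_level`.
#' @param z_level working axial level (mm).
#' @return one of `"within"`, `"medial"`, `"lateral"`, `"anterior"`,
#'   `"posterior"`.
#' @export
position_category <- function(stn, electrode_point, z_level) {
  p <- as_point3(electrode_point, "electrode_point")
  cs <- cross_section(stn, z_level)
  if (is.null(cs))
    stop(sprintf("no STN cross-section at z = %g", z_level), call. = FALSE)
  inside <- any(vapply(cs$polygons, function(poly) point_in_polygon(p[1:2], poly),
                       logical(1)))
  if (inside) return("within")
  dx <- p[1L] - cs$centroid[1L]
  dy <- p[2L] - cs$centroid[2L]
  lateral_sign <- if (stn$side == "left") -1 else 1
  if (abs(dx) >= abs(dy)) {
    if (dx * lateral_sign >= 0) "lateral" else "medial"
  } else {
    if (dy > 0) "anterior" else "posterior"
  }
}

#' Subregion membership of a contact
#'
#' Point-in-mesh test of a contact center against the dorsolateral
#' (sensorimotor) STN subregion first, then the whole STN; points on a
#' surface count as inside (a contact touching the border overlaps it).
#'
#' @param stn,dorsolateral `structure_mesh`es, `dorsolateral` contained in
#'   `stn`.
#' @param contact contact center (length-3, mm).
#' @param surface_tol on-surface tolerance (mm).
#' @return one of `"dorsolateral"`, `"other_stn"`, `"outside"`.
#' @export
contact_subregion <- function(stn, dorsolateral, contact, surface_tol = 1e-9) {
  p <- as_point3(contact, "contact")
  if (point_in_mesh(dorsolateral, p, surface_tol)) return("dorsolateral")
  if (point_in_mesh(stn, p, surface_tol)) return("other_stn")
  "outside"
}

#' Relative-position records for a set of electrodes
#'
#' Runs the full maximum-RN-level construction for each electrode: RN level
#' and center per hemisphere, electrode point at the level, ventral STN
#' border intersection, relative distance, and category. Electrodes whose
#' contact span does not reach the level are flagged `above_rn_level` with
#' `NA` distance.
#'
#' @param anatomy a per-side anatomy list as returned by [generate_anatomy()]
#'   (elements `right`/`left`, each with `stn` and `rn` meshes).
#' @param contact_sets named list of `contact_set`s; names are used as
#'   electrode ids.
#' @param slice_step passed to [max_rn_level()].
#' @return data.frame with one row per electrode: `id`, `side`, `rn_level_z`,
#'   `electrode_x/y/z`, `relative_distance_mm`, `category`.
#' @export
relative_position_table <- function(anatomy, contact_sets, slice_step = 0.1) {
  sides <- vapply(contact_sets, function(cs) cs$side, character(1))
  per_side <- lapply(c(right = "right", left = "left"), function(sd) {
    if (!sd %in% sides) return(NULL)
    lvl <- max_rn_level(anatomy[[sd]]$rn, slice_step)
    list(level = lvl, center = cross_section_centroid(anatomy[[sd]]$rn, lvl))
  })
  rows <- lapply(seq_along(contact_sets), function(i) {
    cs <- contact_sets[[i]]
    ps <- per_side[[cs$side]]
    ep <- electrode_point_at_level(cs, ps$level)
    if (ep$above_level) {
      return(data.frame(id = names(contact_sets)[i] %||% as.character(i),
                        side = cs$side, rn_level_z = ps$level,
                        electrode_x = NA_real_, electrode_y = NA_real_,
                        electrode_z = NA_real_,
                        relative_distance_mm = NA_real_,
                        category = "above_rn_level"))
    }
    inter <- tryCatch(
      stn_ventral_intersection(anatomy[[cs$side]]$stn, ps$center, ep$point),
      dbsreco_no_intersection = function(e) NULL)
    dist <- if (is.null(inter)) NA_real_ else relative_distance(ep$point, inter)
    cat <- position_category(anatomy[[cs$side]]$stn, ep$point, ps$level)
    data.frame(id = names(contact_sets)[i] %||% as.character(i),
               side = cs$side, rn_level_z = ps$level,
               electrode_x = ep$point[1L], electrode_y = ep$point[2L],
               electrode_z = ep$point[3L],
               relative_distance_mm = dist, category = cat)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
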