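#' AC-PC stereotactic coordinate frame
#'
#' Builds the AC-PC coordinate frame used for all stereotactic coordinates in
#' this package: origin at the posterior commissure (PC), +Y along PC->AC
#' (anterior), +Z inferior, +X toward the patient's right, all axes unit and
#' mutually orthogonal. The frame is right-handed once the inferior-pointing
#' +Z convention is accounted for (x = y cross -z).
#'
#' @param ac,pc anterior / posterior commissure in world (scanner) mm.
#' @param midsagittal any midsagittal-plane point strictly superior to the
#'   AC-PC line (used only to fix the sagittal plane; +Z points away from it,
#'   i.e. inferior).
#' @return an object of class `acpc_frame` with elements `origin` (the PC) and
#'   `rotation`, a 3x3 matrix whose rows are `axis_x`, `axis_y`, `axis_z`.
#' @examples
#' fr <- acpc_frame(ac = c(0, 25, 0), pc = c(0, 0, 0), midsagittal = c(0, 10, 50))
#' to_acpc(fr, c(1, 0, 0))   # one step right-lateral
#' @export
acpc_frame <- function(ac, pc, midsagittal) {
  ac <- as_point3(ac, "ac"); pc <- as_point3(pc, "pc")
  mid <- as_point3(midsagittal, "midsagittal")
  ab <- ac - pc
  if (vnorm(ab) < 1e-9) stop("invalid input: AC and PC coincide", call. = FALSE)
  axis_y <- ab / vnorm(ab)
  m <- mid - pc
  perp <- m - sum(m * axis_y) * axis_y
  # collinearity tolerance: sin(angle between mid-pc and the AC-PC line)
  if (vnorm(m) < 1e-9 || vnorm(perp) / vnorm(m) < 1e-6) {
    stop("degenerate frame: midsagittal point is collinear with the AC-PC line",
         call. = FALSE)
  }
  axis_z <- -perp / vnorm(perp)          # midsagittal point is superior; +Z inferior
  axis_x <- cross3(axis_y, -axis_z)      # completes a right-handed (x, y, -z) triple
  rotation <- rbind(axis_x = axis_x, axis_y = axis_y, axis_z = axis_z)
  colnames(rotation) <- c("x", "y", "z")
  structure(list(origin = pc, rotation = rotation), class = "acpc_frame")
}

#' @export
print.acpc_frame <- function(x, ...) {
  cat("AC-PC frame (origin = PC, +X right, +Y anterior, +Z inferior)\n")
  cat("  origin:", paste(format(x$origin, digits = 6), collapse = ", "), "\n")
  print(round(x$rotation, 6))
  invisible(x)
}

check_frame <- function(frame) {
  if (!inherits(frame, "acpc_frame")) stop("not an acpc_frame", call. = FALSE)
  R <- frame$rotation
  if (max(abs(R %*% t(R) - diag(3))) > 1e-9)
    stop("invalid frame: axes are not orthonormal", call. = FALSE)
  invisible(frame)
}

#' Transform points between world and AC-PC coordinates
#'
#' Rigid transforms (rotation + translation only); `from_acpc` is the exact
#' inverse of `to_acpc`.
#'
#' @param frame an [acpc_frame()].
#' @param p a length-3 point or an n x 3 matrix of points.
#' @return point(s) in the target coordinate system, same shape as `p`.
#' @export
to_acpc <- function(frame, p) {
  check_frame(frame)
  if (is.matrix(p)) {
    sweep(p, 2L, frame$origin) %*% t(frame$rotation)
  } else {
    as.numeric(frame$rotation %*% (as_point3(p, "p") - frame$origin))
  }
}

#' @rdname to_acpc
#' @export
from_acpc <- function(frame, p) {
  check_frame(frame)
  if (is.matrix(p)) {
    sweep(p %*% frame$rotation, 2L, frame$origin, `+`)
  } else {
    as.numeric(t(frame$rotation) %*% as_point3(p, "p") + frame$origin)
  }
}

check_side <- function(side) {
  if (length(side) != 1L || !side %in% c("left", "right"))
    stop("side must be \"left\" or \"right\"", call. = FALSE)
  side
}

#' Hemisphere display convention
#'
#' Coordinates are stored signed in the single physical AC-PC frame (+X
#' right-lateral, +Y anterior, +Z inferior for both hemispheres). Published
#' coordinate tables conventionally report left-hemisphere rows mirrored so
#' that every axis of a left electrode prints negative; that display transform
#' is (x, -y, -z) of the stored point for the left side and the identity for
#' the right. It is applied at reporting/pooling time only, never to stored
#' geometry.
#'
#' @param p stored physical point (length 3) or an n x 3 matrix.
#' @param side `"left"` or `"right"` (recycled over rows when `p` is a matrix).
#' @return the display-convention coordinates, same shape as `p`.
#' @export
display_coords <- function(p, side) {
  if (is.matrix(p)) {
    side <- rep_len(side, nrow(p))
    out <- p
    flip <- side == "left"
    out[flip, 2L] <- -out[flip, 2L]
    out[flip, 3L] <- -out[flip, 3L]
    return(out)
  }
  check_side(side)
  p <- as_point3(p, "p")
  if (side == "left") c(p[1L], -p[2L], -p[3L]) else p
}

#' Pool per-electrode coordinates across hemispheres by magnitude
#'
#' Bilateral cohorts are pooled per axis using the absolute value of the
#' coordinate, so that right (+X) and left (-X) lateral offsets, and the
#' mirrored display signs of the other axes, combine into a single
#' "All electrodes" sample.
#'
#' @param coords an n x 3 matrix (or single point) of stored AC-PC coordinates.
#' @param side hemisphere per row, `"left"`/`"right"` (unused by the magnitude
#'   itself, accepted for interface symmetry and validated).
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return numeric vector of non-negative per-electrode magnitudes (mm).
#' @export
pool_magnitude <- function(coords, side, axis = c("x", "y", "z")) {
  axis <- match.arg(tolower(axis), c("x", "y", "z"))
  if (!is.matrix(coords)) coords <- matrix(as_point3(coords, "coords"), nrow = 1L)
  if (nrow(coords) == 0L) stop("empty coordinate list", call. = FALSE)
  vapply(side, check_side, character(1))
  if (length(side) != nrow(coords))
    stop("side must have one entry per coordinate row", call. = FALSE)
  abs(coords[, match(axis, c("x", "y", "z"))])
}
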