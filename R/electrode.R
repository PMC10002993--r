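#' Quadripolar DBS lead geometry
#'
#' Hardware constants of a DBS lead: the distance from the physical electrode
#' tip to the proximal edge of the ventral-most contact, the contact length,
#' the center-to-center spacing of adjacent contacts, and the number of
#' contacts. The Medtronic 3389 and PINS 301 leads implanted in STN surgery
#' share identical constants: a 1.5 mm tip-to-contact gap, 1.5 mm contacts
#' spaced 2 mm center-to-center, four contacts.
#'
#' @param model_name lead model label, or one of the built-ins
#'   `"medtronic_3389"` / `"pins_301"` to get the stock constants.
#' @param tip_to_contact_mm gap between the tip and the ventral-most contact's
#'   proximal edge (mm).
#' @param contact_length_mm length of each stimulating contact (mm).
#' @param center_spacing_mm center-to-center distance of adjacent contacts (mm).
#' @param n_contacts number of contacts.
#' @return an `electrode_spec` object.
#' @examples
#' electrode_spec("medtronic_3389")
#' @export
electrode_spec <- function(model_name = "medtronic_3389",
                           tip_to_contact_mm = 1.5,
                           contact_length_mm = 1.5,
                           center_spacing_mm = 2,
                           n_contacts = 4L) {
  stopifnot(length(model_name) == 1L, is.character(model_name))
  spec <- list(model_name = model_name,
               tip_to_contact_mm = as.numeric(tip_to_contact_mm),
               contact_length_mm = as.numeric(contact_length_mm),
               center_spacing_mm = as.numeric(center_spacing_mm),
               n_contacts = as.integer(n_contacts))
  with(spec, {
    if (tip_to_contact_mm < 0 || contact_length_mm < 0)
      stop("lead lengths must be non-negative", call. = FALSE)
    if (n_contacts < 1L) stop("n_contacts must be >= 1", call. = FALSE)
    if (n_contacts > 1L && center_spacing_mm < contact_length_mm)
      stop("center spacing cannot be smaller than the contact length",
           call. = FALSE)
  })
  structure(spec, class = "electrode_spec")
}

#' Read an electrode spec from JSON
#'
#' Expects an object with fields `model_name`, `tip_to_contact_mm`,
#' `contact_length_mm`, `center_spacing_mm`, `n_contacts`.
#'
#' @param path JSON file path.
#' @return an [electrode_spec()].
#' @export
read_electrode_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("model_name", "tip_to_contact_mm", "contact_length_mm",
            "center_spacing_mm", "n_contacts")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("electrode spec JSON is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  do.call(electrode_spec, x[need])
}

#' @export
print.electrode_spec <- function(x, ...) {
  cat(sprintf("electrode_spec %s: %d contacts, %.2f mm long, %.2f mm spacing, tip gap %.2f mm\n",
              x$model_name, x$n_contacts, x$contact_length_mm,
              x$center_spacing_mm, x$tip_to_contact_mm))
  invisible(x)
}

#' Fit an electrode trajectory from two points
#'
#' The lead is modeled as a straight line through the center of the
#' ventral-most (deepest) contact and a second point chosen on the cranial,
#' bend-free part of the trajectory. The stored direction is the unit vector
#' from the ventral contact toward the cranial point, i.e. pointing dorsally
#' along the lead.
#'
#' @param ventral_contact center of the ventral-most contact (AC-PC mm).
#' @param cranial_point any other point up the electrode trajectory.
#' @return an `electrode_trajectory` with fields `ventral_contact`,
#'   `direction` (unit).
#' @export
fit_trajectory <- function(ventral_contact, cranial_point) {
  v <- as_point3(ventral_contact, "ventral_contact")
  cpt <- as_point3(cranial_point, "cranial_point")
  d <- cpt - v
  if (vnorm(d) <= 1e-6)
    stop("degenerate trajectory: the two points coincide", call. = FALSE)
  structure(list(ventral_contact = v, direction = d / vnorm(d)),
            class = "electrode_trajectory")
}

#' Interpolate contact centers along a trajectory
#'
#' Contact i (counting from the ventral-most contact as 0) sits at
#' `ventral_contact + i * center_spacing * direction`: for the stock
#' quadripolar leads the dorsal contacts are 2, 4 and 6 mm up the trajectory
#' from the ventral-most contact. This parametric form is the consistent
#' solution of the per-coordinate distance equations
#' `x_i = x_1 +/- sqrt(l_i^2 - (y_1 - y_i)^2 - (z_1 - z_i)^2)` (and cyclic),
#' with the sign branch resolved dorsally, toward the cranial point.
#'
#' @param traj an [fit_trajectory()] result.
#' @param spec an [electrode_spec()].
#' @param side hemisphere tag, `"left"` or `"right"`.
#' @return a `contact_set`: list with `contacts` (n_contacts x 3 matrix,
#'   ventral-most first), `side`, `spec`.
#' @export
interpolate_contacts <- function(traj, spec = electrode_spec(), side = "right") {
  stopifnot(inherits(traj, "electrode_trajectory"), inherits(spec, "electrode_spec"))
  check_side(side)
  i <- seq_len(spec$n_contacts) - 1L
  contacts <- outer(i * spec$center_spacing_mm, traj$direction) +
    matrix(traj$ventral_contact, spec$n_contacts, 3L, byrow = TRUE)
  colnames(contacts) <- c("x", "y", "z")
  structure(list(contacts = contacts, side = side, spec = spec),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("contact_set (%s hemisphere, %s):\n", x$side, x$spec$model_name))
  print(round(x$contacts, 4))
  invisible(x)
}

#' Physical tip position of the lead
#'
#' The stored trajectory reference is the *center* of the ventral-most
#' contact; the physical tip lies `tip_to_contact_mm + contact_length_mm / 2`
#' further ventral along the trajectory (2.25 mm for the stock leads: the
#' manufacturer's 1.5 mm tip gap plus the 0.75 mm half-contact).
#'
#' @inheritParams interpolate_contacts
#' @return length-3 tip coordinate (mm).
#' @export
tip_position <- function(traj, spec = electrode_spec()) {
  stopifnot(inherits(traj, "electrode_trajectory"), inherits(spec, "electrode_spec"))
  offset <- spec$tip_to_contact_mm + spec$contact_length_mm / 2
  traj$ventral_contact - offset * traj$direction
}

#' Average the contact centers of one electrode
#'
#' The per-hemisphere summary coordinate used for all method comparisons is
#' the arithmetic mean of the four contact centers (per axis).
#'
#' @param cs a `contact_set` (or bare n x 3 matrix of contacts).
#' @return length-3 mean contact coordinate (mm).
#' @export
average_contacts <- function(cs) {
  contacts <- if (inherits(cs, "contact_set")) cs$contacts else cs
  if (!is.matrix(contacts) || nrow(contacts) < 1L)
    stop("contact set is empty", call. = FALSE)
  colMeans(contacts)
}
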