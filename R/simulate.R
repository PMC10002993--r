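# Seeded synthetic cohort generator: analytic subcortical anatomy (ellipsoid
# STN with a carved dorsolateral subregion, spherical RN), bilateral
# ground-truth implants aimed at the dorsolateral STN, and two noisy
# "reconstruction methods" observing the same electrodes — method A
# (Lead-DBS-like) unbiased, method B (planning-system-like) with a systematic
# per-axis bias. Every random draw lives in a documented per-patient
# substream, so enlarging the cohort never perturbs earlier patients.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions the pipeline is designed around:
#' 26 bilaterally implanted patients (52 electrodes), method-B bias
#' (-0.13, -1.16, +0.59) mm in hemisphere-symmetric (lateral, anterior,
#' inferior) terms, and 1 mm per-axis landmark noise for both methods.
#' All coordinates are stored physical AC-PC mm (+X right, +Y anterior,
#' +Z inferior, PC origin); right-hemisphere values are given and the left
#' side is mirrored.
#'
#' @param n_patients number of bilaterally implanted patients.
#' @param seed base RNG seed for the whole generator chain.
#' @param stn_center,stn_radii,stn_axis right STN ellipsoid center (mm),
#'   semi-axes (mm), and long-axis direction (toward the
#'   posterior-lateral-dorsal pole).
#' @param rn_center,rn_radius right red-nucleus sphere (mm).
#' @param target_offset planned target relative to the dorsolateral centroid,
#'   hemisphere-symmetric mm; the default places the target ~5.25 mm deeper
#'   along the approach so the four contacts straddle the dorsolateral region.
#' @param bias_b method-B systematic bias, hemisphere-symmetric mm.
#' @param sigma_a,sigma_b per-axis landmark noise SD of methods A and B (mm).
#' @param mer_sigma SD of the MER depth-reading noise (mm).
#' @param entry_cone_deg half-angle of the entry-direction cone about the
#'   canonical double-oblique approach (degrees).
#' @param placement_sigma SD of the isotropic tip placement deviation from
#'   plan (mm).
#' @param approach_dir canonical unit approach direction from the ventral
#'   contact toward the cranial entry (right side).
#' @param cranial_offset_mm distance up the trajectory at which the cranial
#'   reference point is read (mm).
#' @param mesh_subdiv icosphere subdivision rounds for the anatomy meshes.
#' @param slice_step axial scan step for [max_rn_level()] (mm).
#' @param dorsolateral_quantile principal-axis quantile beyond which the STN
#'   counts as dorsolateral.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 26L,
                              seed = 20230101L,
                              stn_center = c(10.5, 12.5, 3.5),
                              stn_radii = c(5, 3, 2),
                              stn_axis = c(0.7, -0.5, -0.5),
                              rn_center = c(5.5, 7, 3.5),
                              rn_radius = 3,
                              target_offset = NULL,
                              bias_b = c(-0.13, -1.16, 0.59),
                              sigma_a = c(1, 1, 1),
                              sigma_b = c(1, 1, 1),
                              mer_sigma = 0.3,
                              entry_cone_deg = 5,
                              placement_sigma = 0.5,
                              approach_dir = c(0.17, 0.34, -0.92),
                              cranial_offset_mm = 40,
                              mesh_subdiv = 3L,
                              slice_step = 0.1,
                              dorsolateral_quantile = 0.6) {
  approach_dir <- normalize(as_point3(approach_dir, "approach_dir"))
  if (is.null(target_offset)) target_offset <- -5.25 * approach_dir
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              stn_center = as_point3(stn_center, "stn_center"),
              stn_radii = as.numeric(stn_radii),
              stn_axis = normalize(as_point3(stn_axis, "stn_axis")),
              rn_center = as_point3(rn_center, "rn_center"),
              rn_radius = as.numeric(rn_radius),
              target_offset = as_point3(target_offset, "target_offset"),
              bias_b = as_point3(bias_b, "bias_b"),
              sigma_a = rep_len(as.numeric(sigma_a), 3L),
              sigma_b = rep_len(as.numeric(sigma_b), 3L),
              mer_sigma = as.numeric(mer_sigma),
              entry_cone_deg = as.numeric(entry_cone_deg),
              placement_sigma = as.numeric(placement_sigma),
              approach_dir = approach_dir,
              cranial_offset_mm = as.numeric(cranial_offset_mm),
              mesh_subdiv = as.integer(mesh_subdiv),
              slice_step = as.numeric(slice_step),
              dorsolateral_quantile = as.numeric(dorsolateral_quantile))
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  if (any(c(cfg$sigma_a, cfg$sigma_b, cfg$mer_sigma, cfg$placement_sigma) < 0))
    stop("noise SDs must be >= 0", call. = FALSE)
  if (any(cfg$stn_radii <= 0) || cfg$rn_radius <= 0)
    stop("structure radii must be > 0", call. = FALSE)
  if (vnorm(cfg$stn_center - cfg$rn_center) <= cfg$rn_radius)
    stop("config error: RN sphere engulfs the STN center", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

mirror_point <- function(p, side) {
  if (side == "left") c(-p[1L], p[2L], p[3L]) else p
}

# rotation taking e1 to the unit vector a (used to orient the STN long axis)
rotation_to <- function(a) {
  a <- normalize(a)
  helper <- if (abs(a[3L]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  b <- normalize(cross3(helper, a))
  cc <- cross3(a, b)
  cbind(a, b, cc, deparse.level = 0)
}

#' Generate synthetic subcortical anatomy
#'
#' One obliquely oriented ellipsoidal STN and one spherical RN per
#' hemisphere; the dorsolateral (sensorimotor) subregion is carved from the
#' STN beyond the configured quantile of the vertex projections onto the
#' structure's first principal axis, oriented toward the
#' posterior-lateral-dorsal pole. Left structures are exact mirror images of
#' the right ones. Deterministic (no RNG involved). A sampled overlap check
#' rejects configurations where the RN sphere intrudes into the STN.
#'
#' @param config a [simulation_config()].
#' @return a `dbs_anatomy` list with elements `right` and `left`, each
#'   holding `stn`, `dorsolateral` and `rn` meshes plus the dorsolateral
#'   centroid.
#' @export
generate_anatomy <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  rot <- rotation_to(config$stn_axis)
  stn_r <- ellipsoid_mesh(config$stn_center, config$stn_radii, rot,
                          subdiv = config$mesh_subdiv, label = "STN",
                          side = "right")
  rn_r <- icosphere(config$rn_center, config$rn_radius,
                    subdiv = config$mesh_subdiv, label = "RN", side = "right")
  if (min(sqrt(rowSums(sweep(stn_r$vertices, 2L, config$rn_center)^2))) <=
      config$rn_radius)
    stop("config error: STN and RN volumes overlap", call. = FALSE)
  dl_r <- carve_dorsolateral(stn_r, config$dorsolateral_quantile)
  right <- list(stn = stn_r, dorsolateral = dl_r, rn = rn_r,
                dorsolateral_centroid = mesh_centroid(dl_r))
  left <- list(stn = mirror_mesh(stn_r), dorsolateral = mirror_mesh(dl_r),
               rn = mirror_mesh(rn_r))
  left$dorsolateral_centroid <- mirror_point(right$dorsolateral_centroid, "left")
  structure(list(right = right, left = left), class = "dbs_anatomy")
}

# dorsolateral carve: clip beyond the given quantile of vertex projections
# onto the first principal axis, oriented toward posterior-lateral-dorsal
carve_dorsolateral <- function(stn, quantile = 0.6) {
  V <- stn$vertices
  pc1 <- stats::prcomp(V, center = TRUE, scale. = FALSE)$rotation[, 1L]
  lateral_sign <- if (stn$side == "left") -1 else 1
  pole <- normalize(c(lateral_sign, -1, -1))   # lateral, posterior, dorsal (-Z)
  if (sum(pc1 * pole) < 0) pc1 <- -pc1
  proj <- as.vector(V %*% pc1)
  thr <- stats::quantile(proj, quantile, names = FALSE)
  # snap the plane to a midpoint between distinct projection values so it
  # never passes through a vertex (tessellation symmetry makes exact hits
  # common), which would create degenerate cut triangles
  uproj <- sort(unique(round(proj, 9L)))
  if (min(abs(uproj - thr)) < 1e-6) {
    k <- which.min(abs(uproj - thr))
    nb <- if (k < length(uproj)) uproj[k + 1L] else uproj[k - 1L]
    thr <- (uproj[k] + nb) / 2
  }
  center <- colMeans(V)
  plane_pt <- center + (thr - sum(center * pc1)) * pc1
  clip_mesh_plane(stn, plane_pt, pc1, label = "STN_dorsolateral")
}

# uniform draw in a spherical cap of half-angle `deg` about axis `d`
draw_in_cone <- function(d, deg) {
  if (deg <= 0) return(d)
  cosmax <- cos(deg * pi / 180)
  ct <- 1 - stats::runif(1) * (1 - cosmax)
  st <- sqrt(max(0, 1 - ct^2))
  phi <- stats::runif(1, 0, 2 * pi)
  R <- rotation_to(d)   # columns: d and two orthogonal completions
  as.vector(R %*% c(ct, st * cos(phi), st * sin(phi)))
}

#' Generate ground-truth implants
#'
#' Per patient and hemisphere: the planned target is the dorsolateral STN
#' centroid plus the configured hemisphere-symmetric offset; the trajectory
#' direction is drawn uniformly within the entry cone about the canonical
#' approach; the true tip is the planned target plus an isotropic Gaussian
#' placement deviation; the MER-recorded depth is the tip-to-target distance
#' plus Gaussian reading noise, clipped at zero.
#'
#' @param config a [simulation_config()].
#' @param anatomy a [generate_anatomy()] result.
#' @param seed optional seed override (defaults to `config$seed`).
#' @return data.frame of implants, one row per electrode, with the planned
#'   target, trajectory direction, true tip, true ventral-contact center and
#'   MER distance.
#' @export
generate_implants <- function(config, anatomy, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"), inherits(anatomy, "dbs_anatomy"))
  spec <- electrode_spec()
  tip_off <- spec$tip_to_contact_mm + spec$contact_length_mm / 2
  n <- 2L * config$n_patients
  target <- dir <- tip <- ventral <- matrix(NA_real_, n, 3L)
  mer <- numeric(n)
  pat_id <- character(n); side_col <- character(n)
  r <- 0L
  for (pat in seq_len(config$n_patients)) {
    for (side in c("right", "left")) {
      r <- r + 1L
      side_id <- if (side == "right") 1L else 2L
      tg <- anatomy[[side]]$dorsolateral_centroid +
        mirror_point(config$target_offset, side)
      draws <- with_substream(seed, 1L, pat, side_id, expr = {
        d <- draw_in_cone(mirror_point(config$approach_dir, side),
                          config$entry_cone_deg)
        dev <- stats::rnorm(3L, 0, config$placement_sigma)
        mer_noise <- stats::rnorm(1L, 0, config$mer_sigma)
        list(dir = d, dev = dev, mer_noise = mer_noise)
      })
      tp <- tg + draws$dev
      target[r, ] <- tg; dir[r, ] <- draws$dir; tip[r, ] <- tp
      ventral[r, ] <- tp + tip_off * draws$dir
      mer[r] <- max(0, vnorm(tp - tg) + draws$mer_noise)
      pat_id[r] <- sprintf("P%02d", pat); side_col[r] <- side
    }
  }
  data.frame(patient_id = pat_id, side = side_col,
             target_x = target[, 1L], target_y = target[, 2L], target_z = target[, 3L],
             dir_x = dir[, 1L], dir_y = dir[, 2L], dir_z = dir[, 3L],
             tip_x = tip[, 1L], tip_y = tip[, 2L], tip_z = tip[, 3L],
             ventral_x = ventral[, 1L], ventral_y = ventral[, 2L],
             ventral_z = ventral[, 3L], mer_mm = mer)
}

#' Simulate the two reconstruction methods
#'
#' Both methods observe each electrode's two landmark points — the
#' ventral-most contact center and a cranial trajectory point — with
#' independent per-axis Gaussian noise; method B additionally carries the
#' configured hemisphere-symmetric systematic bias. Contacts are then derived
#' through the same trajectory-fit + interpolation path the real methods use,
#' so landmark error propagates through the interpolation.
#'
#' @param config a [simulation_config()].
#' @param implants a [generate_implants()] data.frame.
#' @param seed optional seed override.
#' @param methods labels for methods A and B.
#' @return list with `table` (a [paired_coordinate_table()] of per-electrode
#'   mean contacts), `contact_sets` (named list of `contact_set`s, names
#'   `patient/side/method`), `distances` (per-electrode Euclidean
#'   tip-to-target distances of both methods plus the MER distance), and
#'   `optimal` (per-electrode optimal-contact index and method-A coordinate).
#' @export
generate_measurements <- function(config, implants, seed = config$seed,
                                  methods = c("leaddbs", "surgiplan")) {
  stopifnot(inherits(config, "simulation_config"))
  spec <- electrode_spec()
  n <- nrow(implants)
  mc_xyz <- matrix(NA_real_, 2L * n, 3L)
  tab_method <- character(2L * n)
  euclid <- matrix(NA_real_, n, 2L)
  csets <- vector("list", 2L * n)
  cname <- character(2L * n)
  opt_idx <- integer(n)
  opt_xyz <- matrix(NA_real_, n, 3L)
  steps <- (seq_len(spec$n_contacts) - 1L) * spec$center_spacing_mm
  for (r in seq_len(n)) {
    side <- implants$side[r]
    side_id <- if (side == "right") 1L else 2L
    pat <- as.integer(sub("^P", "", implants$patient_id[r]))
    ventral <- c(implants$ventral_x[r], implants$ventral_y[r], implants$ventral_z[r])
    dir <- c(implants$dir_x[r], implants$dir_y[r], implants$dir_z[r])
    cranial <- ventral + config$cranial_offset_mm * dir
    target <- c(implants$target_x[r], implants$target_y[r], implants$target_z[r])
    noise <- with_substream(seed, 2L, pat, side_id, expr = {
      list(va = stats::rnorm(3L, 0, config$sigma_a),
           ca = stats::rnorm(3L, 0, config$sigma_a),
           vb = stats::rnorm(3L, 0, config$sigma_b),
           cb = stats::rnorm(3L, 0, config$sigma_b))
    })
    bias <- mirror_point(config$bias_b, side)
    obs_v <- list(ventral + noise$va, ventral + bias + noise$vb)
    obs_c <- list(cranial + noise$ca, cranial + bias + noise$cb)
    for (j in 1:2) {
      d <- obs_c[[j]] - obs_v[[j]]
      d <- d / vnorm(d)
      contacts <- outer(steps, d) + matrix(obs_v[[j]], spec$n_contacts, 3L,
                                           byrow = TRUE)
      colnames(contacts) <- c("x", "y", "z")
      idx <- 2L * (r - 1L) + j
      csets[[idx]] <- structure(list(contacts = contacts, side = side,
                                     spec = spec), class = "contact_set")
      cname[idx] <- paste(implants$patient_id[r], side, methods[j], sep = "/")
      tab_method[idx] <- methods[j]
      mc_xyz[idx, ] <- colMeans(contacts)
      tip <- obs_v[[j]] -
        (spec$tip_to_contact_mm + spec$contact_length_mm / 2) * d
      euclid[r, j] <- vnorm(tip - target)
    }
    # optimal contact: the true contact closest to the dorsolateral centroid
    # (clinical selection favors the sensorimotor region); recorded with its
    # method-A coordinate, as mapping onto the semi-automated reconstruction
    true_contacts <- outer(steps, dir) + matrix(ventral, spec$n_contacts, 3L,
                                                byrow = TRUE)
    dlc <- target - mirror_point(config$target_offset, side)
    k <- which.min(rowSums(sweep(true_contacts, 2L, dlc)^2))
    opt_idx[r] <- k - 1L
    opt_xyz[r, ] <- csets[[2L * (r - 1L) + 1L]]$contacts[k, ]
  }
  names(csets) <- cname
  tab <- data.frame(patient_id = rep(implants$patient_id, each = 2L),
                    side = rep(implants$side, each = 2L),
                    method = tab_method,
                    x = mc_xyz[, 1L], y = mc_xyz[, 2L], z = mc_xyz[, 3L])
  list(table = paired_coordinate_table(tab),
       contact_sets = csets,
       distances = data.frame(patient_id = implants$patient_id,
                              side = implants$side,
                              euclid_a_mm = euclid[, 1L],
                              euclid_b_mm = euclid[, 2L],
                              mer_mm = implants$mer_mm),
       optimal = data.frame(patient_id = implants$patient_id,
                            side = implants$side, contact_index = opt_idx,
                            x = opt_xyz[, 1L], y = opt_xyz[, 2L],
                            z = opt_xyz[, 3L]))
}

#' Simulate a full cohort
#'
#' Convenience wrapper: anatomy, implants and measurements under one seed.
#'
#' @param config a [simulation_config()].
#' @param seed optional override of `config$seed`.
#' @param anatomy optionally reuse a precomputed [generate_anatomy()] result
#'   (the anatomy is deterministic given the config).
#' @return list with `config`, `anatomy`, `implants` and the
#'   [generate_measurements()] elements.
#' @export
simulate_cohort <- function(config = simulation_config(), seed = config$seed,
                            anatomy = NULL) {
  anatomy <- anatomy %||% generate_anatomy(config)
  implants <- generate_implants(config, anatomy, seed = seed)
  meas <- generate_measurements(config, implants, seed = seed)
  c(list(config = config, anatomy = anatomy, implants = implants), meas)
}
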