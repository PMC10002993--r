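# Independent oracles and fixture builders used across the suite. These stay
# deliberately separate from the implementation paths they check: closed-form
# sphere intersections, a Cramer-solve ray-triangle oracle, shoelace hand
# values, and an exact within-block permutation oracle for the paired
# three-condition post hocs.

normalize_vec <- function(v) v / sqrt(sum(v * v))

# closed-form exit (far-root) intersection of a ray with a sphere
line_sphere_exit <- function(origin, dir, center, radius) {
  dir <- dir / sqrt(sum(dir^2))
  oc <- origin - center
  b <- sum(oc * dir)
  disc <- b^2 - (sum(oc^2) - radius^2)
  if (disc < 0) return(NULL)
  t2 <- -b + sqrt(disc)
  if (t2 < 0) return(NULL)
  origin + t2 * dir
}

# brute-force ray-triangle oracle: solve u*e1 + v*e2 - t*d = o - p1 per face
brute_ray_mesh <- function(mesh, origin, dir) {
  V <- mesh$vertices; F <- mesh$faces
  hits <- list()
  for (k in seq_len(nrow(F))) {
    p1 <- V[F[k, 1L], ]; e1 <- V[F[k, 2L], ] - p1; e2 <- V[F[k, 3L], ] - p1
    A <- cbind(e1, e2, -dir)
    if (abs(det(A)) < 1e-12) next
    uvt <- solve(A, origin - p1)
    if (uvt[1L] >= -1e-9 && uvt[2L] >= -1e-9 &&
        uvt[1L] + uvt[2L] <= 1 + 1e-9 && uvt[3L] >= -1e-9) {
      hits[[length(hits) + 1L]] <- c(t = max(uvt[3L], 0))
    }
  }
  if (!length(hits)) return(numeric(0))
  sort(unique(round(vapply(hits, `[[`, numeric(1), "t"), 9L)))
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
rand_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# L-shaped prism: L polygon in the xy plane extruded along z.
# Polygon (0,0)-(2,0)-(2,1)-(1,1)-(1,2)-(0,2): area 3, centroid (5/6, 5/6)
# (hand value: rects [0,2]x[0,1] + [0,1]x[1,2], ((2*1 + 1*0.5)/3, (2*0.5 + 1*1.5)/3)).
l_prism_mesh <- function(z0 = 0, z1 = 2) {
  poly <- rbind(c(0, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 2), c(0, 2))
  np <- nrow(poly)
  V <- rbind(cbind(poly, z0), cbind(poly, z1))
  # fan triangulation from the reflex corner (1,1) (index 4): covers the L
  tris <- rbind(c(4, 1, 2), c(4, 2, 3), c(4, 5, 6), c(4, 6, 1))
  F <- rbind(tris[, c(1L, 3L, 2L)],                 # bottom
             tris + np)                             # top
  for (i in seq_len(np)) {                          # side quads
    j <- if (i == np) 1L else i + 1L
    F <- rbind(F, c(i, j, j + np), c(i, j + np, i + np))
  }
  mesh <- structure_mesh(V, F, label = "RN", side = "right", validate = FALSE)
  if (mesh_volume(mesh) < 0)
    mesh <- structure_mesh(V, F[, c(1L, 3L, 2L)], label = "RN", side = "right",
                           validate = FALSE)
  stopifnot(validate_mesh(mesh)$valid)
  mesh
}

# two disjoint spheres as one (two-component) closed mesh
two_sphere_mesh <- function(c1, r1, c2, r2, subdiv = 2L) {
  s1 <- icosphere(c1, r1, subdiv)
  s2 <- icosphere(c2, r2, subdiv)
  structure_mesh(rbind(s1$vertices, s2$vertices),
                 rbind(s1$faces, s2$faces + nrow(s1$vertices)),
                 label = "RN", side = "right")
}

# ---- exact permutation oracle for paired three-condition post hocs ------

perms3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

# pairwise Dunn z statistics (B-A, C-A, C-B) from within-block rank means
oracle_dunn_z <- function(M) {
  ranks <- t(apply(M, 1L, rank))
  rbar <- colMeans(ranks)
  se <- sqrt(ncol(M) * (ncol(M) + 1) / (6 * nrow(M)))
  c(rbar[2L] - rbar[1L], rbar[3L] - rbar[1L], rbar[3L] - rbar[2L]) / se
}

# pairwise studentized statistics from the within-subject MSE
oracle_tukey_q <- function(M) {
  n <- nrow(M); k <- ncol(M)
  gm <- colMeans(M); sm <- rowMeans(M); mu <- mean(M)
  res <- M - outer(sm, gm, `+`) + mu
  mse <- sum(res^2) / ((n - 1) * (k - 1))
  c(gm[2L] - gm[1L], gm[3L] - gm[1L], gm[3L] - gm[2L]) / sqrt(mse / n)
}

# exact enumeration of all 3!^n within-block label permutations (n <= 7).
# adjust = "maxstat": single-step max-|statistic| familywise p (the
# permutation analogue of Tukey's single-step adjustment);
# adjust = "bonferroni": per-pair permutation p times the number of pairs
# (the analogue of Dunn's Bonferroni adjustment).
perm_posthoc_oracle <- function(M, statfun, adjust = c("maxstat", "bonferroni")) {
  adjust <- match.arg(adjust)
  n <- nrow(M)
  stopifnot(n <= 7L)
  A <- as.matrix(expand.grid(rep(list(1:6), n)))
  obs <- abs(statfun(M))
  stats <- matrix(NA_real_, nrow(A), 3L)
  Mp <- M
  for (r in seq_len(nrow(A))) {
    for (i in seq_len(n)) Mp[i, ] <- M[i, perms3[A[r, i], ]]
    stats[r, ] <- abs(statfun(Mp))
  }
  if (adjust == "maxstat") {
    mx <- apply(stats, 1L, max)
    vapply(1:3, function(j) mean(mx >= obs[j] - 1e-9), numeric(1))
  } else {
    pmin(1, 3 * vapply(1:3, function(j) mean(stats[, j] >= obs[j] - 1e-9),
                       numeric(1)))
  }
}

# small paired coordinate table built from explicit per-electrode values
make_paired_table <- function(a_vals, b_vals, side = "right",
                              axis = "y", base = c(12, 11, 2)) {
  n <- length(a_vals)
  stopifnot(length(b_vals) == n)
  mk <- function(vals, method) {
    df <- data.frame(patient_id = sprintf("P%02d", seq_len(n)),
                     side = rep(side, n), method = method,
                     x = base[1L], y = base[2L], z = base[3L])
    df[[axis]] <- vals
    df
  }
  paired_coordinate_table(rbind(mk(a_vals, "leaddbs"), mk(b_vals, "surgiplan")))
}

fast_cfg <- function(...) {
  simulation_config(n_patients = 6L, mesh_subdiv = 2L, ...)
}
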