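test_that("generated anatomy is valid, mirrored and analytically sized", {
  cfg <- fast_cfg()
  an <- generate_anatomy(cfg)
  for (side in c("right", "left")) {
    for (st in c("stn", "dorsolateral", "rn")) {
      expect_true(validate_mesh(an[[side]][[st]])$valid)
    }
  }
  # mirror symmetry to 1e-9
  expect_equal(an$left$stn$vertices[, 1], -an$right$stn$vertices[, 1])
  expect_equal(an$left$rn$vertices[, 2:3], an$right$rn$vertices[, 2:3])
  expect_equal(an$left$dorsolateral_centroid[1],
               -an$right$dorsolateral_centroid[1], tolerance = 1e-9)

  # analytic volume oracles (subdiv 3 for the 1% tessellation bound)
  cfg3 <- simulation_config(mesh_subdiv = 3L)
  an3 <- generate_anatomy(cfg3)
  expect_equal(mesh_volume(an3$right$rn), 4 / 3 * pi * cfg3$rn_radius^3,
               tolerance = 0.01)
  expect_equal(mesh_volume(an3$right$stn), 4 / 3 * pi * prod(cfg3$stn_radii),
               tolerance = 0.01)
  vol_dl <- mesh_volume(an3$right$dorsolateral)
  expect_gt(vol_dl, 0)
  expect_lt(vol_dl, 0.5 * mesh_volume(an3$right$stn))
  # the dorsolateral region sits at the posterior-lateral-dorsal pole
  dlc <- an3$right$dorsolateral_centroid
  stc <- mesh_centroid(an3$right$stn)
  expect_gt(dlc[1], stc[1])    # more lateral
  expect_lt(dlc[2], stc[2])    # more posterior
  expect_lt(dlc[3], stc[3])    # more dorsal (+Z inferior)
})

test_that("overlapping structure configurations are rejected", {
  # RN engulfing the STN center fails at config validation
  expect_error(simulation_config(rn_center = c(9, 11, 3), mesh_subdiv = 2L),
               "engulfs")
  # RN intruding into the STN surface fails the sampled mesh check
  expect_error(generate_anatomy(simulation_config(rn_center = c(6.2, 9, 3.5),
                                                  rn_radius = 4,
                                                  mesh_subdiv = 2L)),
               "overlap")
})

test_that("implants are deterministic, cone-bounded and target-centered", {
  cfg <- fast_cfg()
  an <- generate_anatomy(cfg)
  im1 <- generate_implants(cfg, an, seed = 7)
  im2 <- generate_implants(cfg, an, seed = 7)
  expect_identical(im1, im2)
  expect_false(identical(im1, generate_implants(cfg, an, seed = 8)))

  # zero cone + zero deviation: tip = planned target, mer = |noise|
  cfg0 <- fast_cfg(entry_cone_deg = 0, placement_sigma = 0)
  im0 <- generate_implants(cfg0, an, seed = 7)
  expect_equal(im0$tip_x, im0$target_x, tolerance = 1e-12)
  expect_equal(im0$tip_z, im0$target_z, tolerance = 1e-12)
  expect_true(all(im0$mer_mm >= 0))
  dirs <- as.matrix(im0[, c("dir_x", "dir_y", "dir_z")])
  expect_equal(rowSums(dirs^2), rep(1, nrow(dirs)), tolerance = 1e-9)
  ref <- rbind(cfg0$approach_dir, c(-1, 1, 1) * cfg0$approach_dir)
  expect_equal(unname(dirs[1, ]), ref[1, ], tolerance = 1e-12)
  expect_equal(unname(dirs[2, ]), ref[2, ], tolerance = 1e-12)

  # cone bound holds for every drawn direction
  cfgc <- fast_cfg(entry_cone_deg = 5)
  imc <- generate_implants(cfgc, an, seed = 11)
  dirs <- as.matrix(imc[, c("dir_x", "dir_y", "dir_z")])
  for (r in seq_len(nrow(dirs))) {
    axis <- if (imc$side[r] == "left") c(-1, 1, 1) * cfgc$approach_dir else cfgc$approach_dir
    ang <- acos(sum(dirs[r, ] * axis)) * 180 / pi
    expect_lte(ang, 5 + 1e-6)
  }
})

test_that("mean placement deviation matches the Monte-Carlo chi oracle", {
  cfg <- simulation_config(n_patients = 400L, mesh_subdiv = 2L,
                           placement_sigma = 0.5)
  an <- generate_anatomy(cfg)
  im <- generate_implants(cfg, an, seed = 3)
  dev <- sqrt((im$tip_x - im$target_x)^2 + (im$tip_y - im$target_y)^2 +
              (im$tip_z - im$target_z)^2)
  # E||N3(0, sigma I)|| = 2 sigma sqrt(2/pi)
  expect_equal(mean(dev), 2 * 0.5 * sqrt(2 / pi),
               tolerance = 3 * sd(dev) / sqrt(length(dev)) / (2 * 0.5 * sqrt(2 / pi)))
})

test_that("zero noise and zero bias reproduce ground truth exactly", {
  cfg <- fast_cfg(sigma_a = 0, sigma_b = 0, bias_b = c(0, 0, 0))
  co <- simulate_cohort(cfg, seed = 5)
  wide_a <- co$table[co$table$method == "leaddbs", ]
  wide_b <- co$table[co$table$method == "surgiplan", ]
  expect_equal(wide_a[, c("x", "y", "z")], wide_b[, c("x", "y", "z")],
               ignore_attr = TRUE)
  # mean contact = ventral + 3 * direction for the 4-contact lead
  im <- co$implants
  expect_equal(wide_a$x, im$ventral_x + 3 * im$dir_x, tolerance = 1e-9)
  expect_equal(wide_a$z, im$ventral_z + 3 * im$dir_z, tolerance = 1e-9)
  expect_equal(co$distances$euclid_a_mm, co$distances$euclid_b_mm)
})

test_that("measurement generation is seed-stable under cohort growth", {
  an6 <- generate_anatomy(fast_cfg())
  cfg6 <- fast_cfg(); cfg9 <- simulation_config(n_patients = 9L, mesh_subdiv = 2L)
  co6 <- simulate_cohort(cfg6, seed = 13, anatomy = an6)
  co9 <- simulate_cohort(cfg9, seed = 13, anatomy = an6)
  first <- co9$table[co9$table$patient_id %in% sprintf("P%02d", 1:6), ]
  expect_equal(as.data.frame(co6$table), as.data.frame(first),
               ignore_attr = TRUE)
})

test_that("injected bias is recovered and label swap negates it", {
  cfg <- simulation_config(n_patients = 40L, mesh_subdiv = 2L)
  an <- generate_anatomy(cfg)
  im <- generate_implants(cfg, an, seed = 19)
  me <- generate_measurements(cfg, im, seed = 19)
  bias <- cfg$bias_b
  for (j in 1:3) {
    ax <- c("x", "y", "z")[j]
    cmp <- paired_axis_test(me$table, ax)
    se <- sqrt(2) * 1 / sqrt(80)
    expect_lt(abs(cmp$mean_discrepancy - bias[j]), 4 * se)
    swapped <- paired_axis_test(me$table, ax, method_a = "surgiplan",
                                method_b = "leaddbs")
    expect_equal(swapped$mean_discrepancy, -cmp$mean_discrepancy,
                 tolerance = 1e-12)
  }
})

test_that("generated tables always satisfy the paired-table invariants", {
  co <- simulate_cohort(fast_cfg(), seed = 23)
  expect_s3_class(co$table, "paired_coordinate_table")
  key <- with(co$table, table(patient_id, side))
  expect_true(all(key == 2))   # one row per method per electrode
  expect_equal(sort(unique(co$table$method)), c("leaddbs", "surgiplan"))
  expect_true(all(co$optimal$contact_index %in% 0:3))
})
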