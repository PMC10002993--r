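test_that("Lilliefors gate separates normal from exponential samples", {
  set.seed(100)
  expect_true(ks_normality(rnorm(2000))$normal)
  expect_false(ks_normality(rexp(2000))$normal)
  expect_error(ks_normality(rep(1.5, 50)), "constant")
  expect_error(ks_normality(c(1, 2, 3)), "insufficient")
})

test_that("discrepancies from printed method means are exact arithmetic", {
  expect_equal(discrepancy_from_means(12.36, 12.23), -0.13)
  expect_equal(discrepancy_from_means(11.19, 10.03), -1.16)
  expect_equal(discrepancy_from_means(2.05, 2.64), 0.59)
  # left rows are printed signed; magnitudes are compared
  expect_equal(discrepancy_from_means(-12.11, -11.82), -0.29)
})

test_that("paired axis test handles identity, shift and the textbook t", {
  a <- c(10.5, 11.2, 12.0, 10.8, 11.5)
  ident <- make_paired_table(a, a)
  r0 <- paired_axis_test(ident, "y")
  expect_equal(r0$mean_discrepancy, 0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  shift <- paired_axis_test(make_paired_table(a, a + 1), "y")
  expect_equal(shift$mean_discrepancy, 1)
  expect_equal(shift$p_value, 0)     # constant non-zero shift is certain

  # textbook paired t: differences {0.5, 1.0, 1.5, 2.0},
  # t = mean / (sd / sqrt(n)) = 1.25 / 0.32275 = 3.8730
  b <- c(10, 11, 12, 13)
  r <- paired_axis_test(make_paired_table(b, b + c(0.5, 1, 1.5, 2)), "y",
                        test = "t")
  expect_equal(r$statistic, 1.25 / (sd(c(0.5, 1, 1.5, 2)) / 2),
               tolerance = 1e-9)
  expect_equal(r$statistic, 3.873, tolerance = 1e-3)
  expect_equal(r$n, 4)
})

test_that("paired axis test is antisymmetric in its methods", {
  set.seed(17)
  for (i in 1:5) {
    a <- rnorm(12, 11, 1); b <- a + rnorm(12, 0.4, 0.6)
    tab <- make_paired_table(a, b)
    fwd <- paired_axis_test(tab, "y", method_a = "leaddbs", method_b = "surgiplan")
    rev <- paired_axis_test(tab, "y", method_a = "surgiplan", method_b = "leaddbs")
    expect_equal(fwd$mean_discrepancy, -rev$mean_discrepancy, tolerance = 1e-12)
    expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
    expect_gte(fwd$p_value, 0); expect_lte(fwd$p_value, 1)
  }
})

test_that("left-scope comparisons work on magnitudes of stored signed data", {
  # stored physical left coordinates: x negative, y/z positive
  n <- 8
  set.seed(23)
  base <- data.frame(patient_id = sprintf("P%02d", 1:n), side = "left",
                     method = "leaddbs", x = -rnorm(n, 12, 1),
                     y = rnorm(n, 11, 1), z = rnorm(n, 2, 1))
  other <- base
  other$method <- "surgiplan"
  other$x <- base$x + 0.29          # less lateral: |x| smaller by 0.29
  tab <- paired_coordinate_table(rbind(base, other))
  cmp <- paired_axis_test(tab, "x", scope = "left")
  expect_equal(cmp$mean_discrepancy, -0.29, tolerance = 1e-9)
  # display means print negative for left rows
  expect_lt(cmp$display_mean_a, 0)
})

test_that("three-condition post hoc recognizes identity and strong shifts", {
  M <- cbind(A = c(10, 11, 12, 10.5, 11.5, 12.5))
  M <- cbind(M, B = M[, 1], C = M[, 1])
  r <- three_method_posthoc(M)
  expect_equal(r$route, "degenerate")
  expect_true(all(vapply(r$pairs, `[[`, numeric(1), "p_value") == 1))

  set.seed(41)
  A <- rnorm(10, 10, 1)
  M2 <- cbind(A = A, B = A, C = A + 5)
  r2 <- three_method_posthoc(M2)
  p <- vapply(r2$pairs, `[[`, numeric(1), "p_value")
  names(p) <- vapply(r2$pairs, function(x) paste(x$a, x$b), character(1))
  expect_lt(p[["A C"]], 0.05)
  expect_lt(p[["B C"]], 0.05)
  expect_gt(p[["A B"]], 0.9)

  expect_error(three_method_posthoc(M2[1:2, ]), "fewer than 3")
  expect_message(three_method_posthoc(rbind(M2, c(NA, 1, 2))), "dropped")
})

test_that("both post hoc routes match the exact permutation oracle", {
  # frozen n = 6 fixture: three paired conditions, one real shift (B)
  M <- cbind(A = c(10.00, 10.99, 10.84, 10.71, 11.31, 8.61),
             B = c(11.44, 11.88, 12.02, 11.81, 11.62, 9.27),
             C = c(9.66, 11.45, 11.00, 10.77, 11.20, 8.43))

  tk <- three_method_posthoc(M, route = "tukey")
  p_tk <- vapply(tk$pairs, `[[`, numeric(1), "p_value")
  o_tk <- perm_posthoc_oracle(M, oracle_tukey_q, "maxstat")
  # parametric Tukey vs exact max-statistic permutation: the studentized
  # range approximation tracks the exact null closely even at n = 6
  expect_lt(max(abs(p_tk - o_tk)), 0.02)

  dn <- three_method_posthoc(M, route = "dunn")
  p_dn <- vapply(dn$pairs, `[[`, numeric(1), "p_value")
  o_dn <- perm_posthoc_oracle(M, oracle_dunn_z, "bonferroni")
  # Dunn's normal approximation of the discrete rank statistic: tight in the
  # decision-relevant range; same significance classification throughout
  sig <- o_dn <= 0.2
  expect_lt(max(abs(p_dn[sig] - o_dn[sig])), 0.03)
  expect_equal(p_dn < 0.05, o_dn < 0.05)
})

test_that("distance validation treats MER depth as a third paired condition", {
  set.seed(53)
  d0 <- runif(12, 2, 6)
  same <- data.frame(euclid_a_mm = d0, euclid_b_mm = d0, mer_mm = d0)
  r <- distance_validation(same)
  expect_true(all(vapply(r$pairs, `[[`, numeric(1), "p_value") == 1))

  # tips at the true tip + small noise, true distances dominating: no pair
  # significant in most runs (checked with a fixed seed)
  noisy <- data.frame(euclid_a_mm = d0 + rnorm(12, 0, 0.2),
                      euclid_b_mm = d0 + rnorm(12, 0, 0.2),
                      mer_mm = d0 + rnorm(12, 0, 0.2))
  r2 <- distance_validation(noisy)
  expect_true(all(vapply(r2$pairs, `[[`, numeric(1), "p_value") > 0.05))

  # a 5 mm bias in one method must be flagged
  biased <- data.frame(euclid_a_mm = d0 + rnorm(12, 0, 0.2),
                       euclid_b_mm = d0 + 5 + rnorm(12, 0, 0.2),
                       mer_mm = d0 + rnorm(12, 0, 0.2))
  r3 <- distance_validation(biased)
  p3 <- vapply(r3$pairs, `[[`, numeric(1), "p_value")
  names(p3) <- vapply(r3$pairs, function(x) paste(x$a, x$b), character(1))
  expect_lt(p3[["euclid_a euclid_b"]], 0.05)
  expect_lt(p3[["euclid_b mer"]], 0.05)
  expect_error(distance_validation(data.frame(euclid_a_mm = 1)), "missing")
  expect_error(distance_validation(same[0, ]), "fewer|missing|3")
})

test_that("consistency and subregion rates reproduce printed-count arithmetic", {
  a <- c(rep("within", 29), rep("lateral", 11))
  b <- c(rep("within", 29), rep("posterior", 11))
  r <- consistency_rate(a, b)
  expect_equal(r$matches, 29); expect_equal(r$n, 40)
  expect_equal(r$percent, 72.5)
  expect_equal(consistency_rate(a, a)$percent, 100)
  expect_equal(consistency_rate(a, rev(b))$fraction,
               mean(a == rev(b)))
  expect_error(consistency_rate(a, b[-1]), "length")
  expect_error(consistency_rate(character(), character()), "empty")

  expect_equal(subregion_rate(c(rep("dorsolateral", 31), rep("other_stn", 11)))$percent,
               73.8)
  expect_equal(subregion_rate(c(rep("dorsolateral", 7), rep("outside", 3)))$percent,
               70)
  expect_equal(subregion_rate(rep("other_stn", 5))$percent, 0)
  expect_error(subregion_rate(character()), "empty")
})

test_that("paired table validation rejects malformed input", {
  df <- data.frame(patient_id = "P01", side = "right", method = "a",
                   x = 1, y = 2, z = 3)
  expect_s3_class(paired_coordinate_table(df), "paired_coordinate_table")
  expect_error(paired_coordinate_table(df[, -4]), "missing column")
  expect_error(paired_coordinate_table(rbind(df, df)), "duplicate")
  df2 <- df; df2$x <- NA
  expect_error(paired_coordinate_table(df2), "finite")
})
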