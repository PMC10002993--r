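# End-to-end pipeline driver: simulate (or load) a cohort, derive contacts,
# run the relative-position construction, compare methods, and write the CSV
# + markdown report with a reproducibility manifest. Logging goes to stderr
# with stage-scoped prefixes; results only ever go to files / return values.

#' Per-axis comparison table in the published layout
#'
#' Rows X/Y/Z by All/Right/Left with each method's mean +/- SD (signed
#' display convention), the mean discrepancy (method B minus method A, on
#' pooled magnitudes, 2 decimals) and the gated paired-test p-value.
#'
#' @param table a [paired_coordinate_table()].
#' @param method_a,method_b the two method labels.
#' @return data.frame with columns `axis`, `scope`, `n`, `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `mean_discrepancy`, `test`, `p_value`.
#' @export
comparison_table <- function(table, method_a = "leaddbs", method_b = "surgiplan") {
  rows <- list()
  for (axis in c("x", "y", "z")) {
    for (scope in c("all", "right", "left")) {
      cmp <- paired_axis_test(table, axis, scope, method_a, method_b)
      # "All" rows print the magnitude-pooled sample, single-hemisphere rows
      # the signed display convention
      pooled <- scope == "all"
      rows[[length(rows) + 1L]] <- data.frame(
        axis = toupper(axis), scope = scope, n = cmp$n,
        mean_a = if (pooled) cmp$mean_a else cmp$display_mean_a,
        sd_a = if (pooled) cmp$sd_a else cmp$display_sd_a,
        mean_b = if (pooled) cmp$mean_b else cmp$display_mean_b,
        sd_b = if (pooled) cmp$sd_b else cmp$display_sd_b,
        mean_discrepancy = round(cmp$mean_discrepancy, 2L),
        test = cmp$test_name, p_value = cmp$p_value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort under `config` (or consumes a precomputed one),
#' derives contacts and per-electrode summaries, runs the relative-position
#' construction for both methods, the per-axis comparisons, the MER distance
#' validation and the overlap rates, and writes everything under `out_dir`:
#' `coordinates.csv`, `distances.csv`, `relative_position.csv`,
#' `comparison.csv`, `report.md`, `manifest.json`, plus the anatomy as OBJ.
#' CSV outputs are byte-identical across reruns with the same config and
#' seed.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @param seed optional override of `config$seed`.
#' @param cohort optionally a precomputed [simulate_cohort()] result.
#' @return (invisibly) a list with the in-memory results: `comparison`,
#'   `relpos`, `consistency`, `distance_validation`, `subregion`, `paths`.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir, seed = config$seed,
                         cohort = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_log("simulate", "cohort of %d patients, seed %d", config$n_patients, seed)
  cohort <- cohort %||% simulate_cohort(config, seed = seed)

  stage_log("contacts", "writing per-contact coordinates")
  coord_rows <- do.call(rbind, lapply(names(cohort$contact_sets), function(nm) {
    parts <- strsplit(nm, "/", fixed = TRUE)[[1L]]
    cs <- cohort$contact_sets[[nm]]
    data.frame(patient_id = parts[1L], side = parts[2L], method = parts[3L],
               point_role = paste0("contact_", seq_len(nrow(cs$contacts)) - 1L),
               x_mm = cs$contacts[, 1L], y_mm = cs$contacts[, 2L],
               z_mm = cs$contacts[, 3L])
  }))
  mean_rows <- data.frame(patient_id = cohort$table$patient_id,
                          side = cohort$table$side, method = cohort$table$method,
                          point_role = "mean_contact",
                          x_mm = cohort$table$x, y_mm = cohort$table$y,
                          z_mm = cohort$table$z)
  paths <- list(coordinates = file.path(out_dir, "coordinates.csv"),
                distances = file.path(out_dir, "distances.csv"),
                relpos = file.path(out_dir, "relative_position.csv"),
                comparison = file.path(out_dir, "comparison.csv"),
                report = file.path(out_dir, "report.md"),
                manifest = file.path(out_dir, "manifest.json"))
  write_coordinate_csv(rbind(coord_rows, mean_rows), paths$coordinates)
  write_csv_plain(cohort$distances, paths$distances)

  stage_log("relpos", "relative position at the maximum RN level")
  relpos <- relative_position_table(cohort$anatomy, cohort$contact_sets,
                                    slice_step = config$slice_step)
  relpos$patient_id <- vapply(strsplit(relpos$id, "/"), `[[`, character(1), 1L)
  relpos$method <- vapply(strsplit(relpos$id, "/"), `[[`, character(1), 3L)
  write_csv_plain(relpos[, c("patient_id", "side", "method", "rn_level_z",
                             "relative_distance_mm", "category")], paths$relpos)

  stage_log("compare", "per-axis method comparison")
  comparison <- comparison_table(cohort$table)
  write_csv_plain(comparison, paths$comparison)

  # categorical consistency between methods, excluding electrodes flagged
  # above the RN level in either method (listwise, as in the source analysis)
  key <- paste(relpos$patient_id, relpos$side)
  meths <- unique(relpos$method)
  ca <- relpos[relpos$method == meths[1L], ]
  cb <- relpos[relpos$method == meths[2L], ]
  cb <- cb[match(paste(ca$patient_id, ca$side), paste(cb$patient_id, cb$side)), ]
  usable <- ca$category != "above_rn_level" & cb$category != "above_rn_level"
  consistency <- consistency_rate(ca$category[usable], cb$category[usable])
  n_above <- sum(!usable)

  reldist <- lapply(c(right = "right", left = "left"), function(sd) {
    da <- ca$relative_distance_mm[usable & ca$side == sd]
    db <- cb$relative_distance_mm[usable & cb$side == sd]
    keep <- is.finite(da) & is.finite(db)
    if (sum(keep) < 2L) return(NULL)
    ht <- stats::t.test(db[keep], da[keep], paired = TRUE)
    list(n = sum(keep), mean_a = mean(da[keep]), sd_a = stats::sd(da[keep]),
         mean_b = mean(db[keep]), sd_b = stats::sd(db[keep]),
         p_value = ht$p.value)
  })

  dv <- distance_validation(cohort$distances)

  subregions <- vapply(seq_len(nrow(cohort$optimal)), function(i) {
    sd <- cohort$optimal$side[i]
    contact_subregion(cohort$anatomy[[sd]]$stn, cohort$anatomy[[sd]]$dorsolateral,
                      c(cohort$optimal$x[i], cohort$optimal$y[i],
                        cohort$optimal$z[i]))
  }, character(1))
  subregion <- subregion_rate(subregions)

  stage_log("report", "writing %s", paths$report)
  writeLines(report_markdown(comparison, consistency, n_above, reldist, dv,
                             subregion, config, seed),
             paths$report, sep = "\n")
  manifest <- list(tool = "dbsreco",
                   version = as.character(utils::packageVersion("dbsreco")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = seed,
                   config = unclass(config),
                   outputs = lapply(paths, normalizePath, mustWork = FALSE))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(comparison = comparison, relpos = relpos,
                 consistency = consistency, n_above_level = n_above,
                 relative_distance = reldist, distance_validation = dv,
                 subregion = subregion, subregion_labels = subregions,
                 paths = paths))
}

fmt_p <- function(p) {
  if (!is.finite(p)) return("NA")
  if (p < 1e-4) "<0.0001" else sprintf("%.4f", p)
}

report_markdown <- function(comparison, consistency, n_above, reldist, dv,
                            subregion, config, seed) {
  lines <- c(
    "# DBS electrode reconstruction method comparison",
    "",
    sprintf("Synthetic cohort: %d patients (%d electrodes), seed %d.",
            config$n_patients, 2L * config$n_patients, seed),
    "",
    "## Contact coordinates (mm, AC-PC, display convention)",
    "",
    "| Axis | Scope | Method A (mean +/- SD) | Method B (mean +/- SD) | Mean discrepancy | p value |",
    "| --- | --- | --- | --- | --- | --- |")
  for (i in seq_len(nrow(comparison))) {
    r <- comparison[i, ]
    lines <- c(lines, sprintf(
      "| %s | %s | %.2f +/- %.2f | %.2f +/- %.2f | %.2f | %s |",
      r$axis, r$scope, r$mean_a, r$sd_a, r$mean_b, r$sd_b,
      r$mean_discrepancy, fmt_p(r$p_value)))
  }
  lines <- c(lines, "",
    "## Relative position at the maximum RN level", "",
    sprintf("- consistent categorizations: %d/%d (%.1f%%)",
            consistency$matches, consistency$n, consistency$percent),
    sprintf("- electrodes above the maximum RN level (excluded): %d", n_above))
  for (sd in names(reldist)) {
    rl <- reldist[[sd]]
    if (is.null(rl)) next
    lines <- c(lines, sprintf(
      "- %s hemisphere relative distance: %.2f +/- %.2f vs %.2f +/- %.2f mm, paired t p = %s",
      sd, rl$mean_a, rl$sd_a, rl$mean_b, rl$sd_b, fmt_p(rl$p_value)))
  }
  lines <- c(lines, "",
    "## Tip-to-target distance vs MER depth", "",
    sprintf("- route: %s, overall p = %s", dv$route, fmt_p(dv$overall$p_value)))
  for (pr in dv$pairs) {
    lines <- c(lines, sprintf("- %s vs %s: p = %s", pr$a, pr$b, fmt_p(pr$p_value)))
  }
  c(lines, "",
    "## Optimal contacts", "",
    sprintf("- in the dorsolateral STN: %d/%d (%.1f%%)",
            subregion$count, subregion$n, subregion$percent))
}
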