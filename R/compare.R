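# Paired statistical ladder for comparing electrode localization methods:
# Lilliefors-gated paired t / Wilcoxon signed rank on per-axis pooled
# magnitudes, repeated-measures Tukey or Friedman + Dunn for three paired
# conditions, and the printed-count summary rates.

#' Normality check (Lilliefors-corrected Kolmogorov-Smirnov)
#'
#' One-sample KS against a normal with mean and SD estimated from the sample,
#' using the Lilliefors correction (plain KS with estimated parameters is
#' anti-conservative). A sample is called normal when p >= `alpha`.
#'
#' @param x numeric sample, n >= 5, non-constant.
#' @param alpha decision level (default 0.05).
#' @return list with `normal` (logical), `p_value`, `statistic`.
#' @export
ks_normality <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) < 5L)
    stop("insufficient sample: normality assessment needs n >= 5", call. = FALSE)
  if (stats::sd(x) < 1e-12)
    stop("constant sample (zero SD): normality is undefined", call. = FALSE)
  kt <- nortest::lillie.test(x)
  list(normal = kt$p.value >= alpha,
       p_value = unname(kt$p.value),
       statistic = unname(kt$statistic))
}

#' Paired coordinate table
#'
#' Long-format table of per-electrode averaged contact coordinates under two
#' or more localization methods: columns `patient_id`, `side`, `method`,
#' `x`, `y`, `z` (stored physical AC-PC mm). Validates that every
#' (patient, side) electrode carries exactly one row per method.
#'
#' @param df data.frame with the columns above.
#' @return the validated data.frame with class `paired_coordinate_table`.
#' @export
paired_coordinate_table <- function(df) {
  need <- c("patient_id", "side", "method", "x", "y", "z")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("paired coordinate table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  vapply(unique(df$side), check_side, character(1))
  if (!all(is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("non-finite coordinates in paired table", call. = FALSE)
  key <- interaction(df$patient_id, df$side, df$method, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (patient, side, method) rows in paired table", call. = FALSE)
  class(df) <- c("paired_coordinate_table", "data.frame")
  df
}

# matched per-electrode magnitude vectors for a set of methods
pooled_matrix <- function(table, axis, scope, methods) {
  axis <- match.arg(tolower(axis), c("x", "y", "z"))
  scope <- match.arg(scope, c("all", "right", "left"))
  df <- as.data.frame(table)
  if (scope != "all") df <- df[df$side == scope, , drop = FALSE]
  df <- df[df$method %in% methods, , drop = FALSE]
  if (nrow(df) == 0L) stop("no rows for requested scope/methods", call. = FALSE)
  eid <- paste(df$patient_id, df$side, sep = "/")
  wide_mag <- tapply(abs(df[[axis]]), list(eid, df$method), identity)
  wide_sgn <- tapply(display_coords(as.matrix(df[, c("x", "y", "z")]),
                                    df$side)[, match(axis, c("x", "y", "z"))],
                     list(eid, df$method), identity)
  complete <- stats::complete.cases(wide_mag[, methods, drop = FALSE])
  dropped <- sum(!complete)
  if (dropped > 0L)
    stage_log("compare", "dropped %d electrode(s) with incomplete method data", dropped)
  list(mag = wide_mag[complete, methods, drop = FALSE],
       disp = wide_sgn[complete, methods, drop = FALSE],
       n_dropped = dropped)
}

#' Mean discrepancy from printed method means
#'
#' The per-axis mean discrepancy of published coordinate tables is the
#' difference of the methods' pooled-magnitude means (method B minus method
#' A), rounded to 2 decimals. Accepts signed display-convention means (left
#' rows print negative): magnitudes are taken first.
#'
#' @param mean_a,mean_b printed per-axis means of methods A and B.
#' @param digits rounding for the reported value (default 2).
#' @return the rounded discrepancy (mm).
#' @examples
#' discrepancy_from_means(12.36, 12.23)    # -0.13
#' discrepancy_from_means(-12.11, -11.82)  # -0.29 (left rows, magnitudes)
#' @export
discrepancy_from_means <- function(mean_a, mean_b, digits = 2L) {
  round(abs(mean_b) - abs(mean_a), digits)
}

#' Paired per-axis comparison of two localization methods
#'
#' Pools per-electrode magnitudes on one axis (per [pool_magnitude()]'s
#' convention) for the requested scope, then compares the two methods with a
#' paired t-test when the paired differences pass [ks_normality()], and a
#' Wilcoxon signed-rank test otherwise. The mean discrepancy is
#' `mean(B) - mean(A)` on the pooled magnitudes. Degenerate all-equal
#' differences report p = 1 (zero shift) or p = 0 (constant non-zero shift).
#'
#' @param table a [paired_coordinate_table()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param scope `"all"` (both hemispheres, magnitude-pooled), `"right"` or
#'   `"left"`.
#' @param method_a,method_b method labels in the table.
#' @param test `"auto"` (normality-gated), `"t"` or `"wilcoxon"`.
#' @param alpha level for the normality gate.
#' @return a `dbs_comparison` list: axis, scope, n, means/SDs of the pooled
#'   magnitudes, signed display means, `mean_discrepancy`, `test_name`,
#'   `statistic`, `p_value`, `normality_p`.
#' @export
paired_axis_test <- function(table, axis, scope = "all",
                             method_a = "leaddbs", method_b = "surgiplan",
                             test = c("auto", "t", "wilcoxon"), alpha = 0.05) {
  test <- match.arg(test)
  pm <- pooled_matrix(table, axis, scope, c(method_a, method_b))
  a <- pm$mag[, method_a]; b <- pm$mag[, method_b]
  if (length(a) < 2L) stop("need at least 2 matched pairs", call. = FALSE)
  d <- b - a
  norm_p <- NA_real_
  if (test == "auto") {
    if (stats::sd(d) < 1e-12) {
      test <- "degenerate"
    } else {
      nr <- tryCatch(ks_normality(d, alpha), error = function(e) NULL)
      if (is.null(nr)) {
        test <- "t"                      # tiny n: default to the parametric test
      } else {
        norm_p <- nr$p_value
        test <- if (nr$normal) "t" else "wilcoxon"
      }
    }
  } else if (stats::sd(d) < 1e-12) {
    test <- "degenerate"
  }
  res <- switch(test,
    t = {
      ht <- stats::t.test(d)
      list(name = "paired t", stat = unname(ht$statistic), p = ht$p.value)
    },
    wilcoxon = {
      ht <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)
      list(name = "wilcoxon signed rank", stat = unname(ht$statistic), p = ht$p.value)
    },
    degenerate = {
      if (abs(mean(d)) < 1e-12) list(name = "degenerate (identical)", stat = 0, p = 1)
      else list(name = "degenerate (constant shift)", stat = Inf, p = 0)
    })
  disp_a <- pm$disp[, method_a]; disp_b <- pm$disp[, method_b]
  structure(list(axis = tolower(axis), scope = scope,
                 method_a = method_a, method_b = method_b,
                 n = length(a),
                 mean_a = mean(a), sd_a = stats::sd(a),
                 mean_b = mean(b), sd_b = stats::sd(b),
                 display_mean_a = mean(disp_a), display_sd_a = stats::sd(disp_a),
                 display_mean_b = mean(disp_b), display_sd_b = stats::sd(disp_b),
                 mean_discrepancy = mean(d),
                 test_name = res$name, statistic = res$stat,
                 p_value = res$p, normality_p = norm_p,
                 n_dropped = pm$n_dropped),
            class = "dbs_comparison")
}

#' @export
print.dbs_comparison <- function(x, ...) {
  pooled <- x$scope == "all"   # "All" rows print the magnitude-pooled sample
  cat(sprintf("%s axis (%s, n = %d): %s %.2f +/- %.2f vs %s %.2f +/- %.2f\n",
              toupper(x$axis), x$scope, x$n,
              x$method_a,
              if (pooled) x$mean_a else x$display_mean_a,
              if (pooled) x$sd_a else x$display_sd_a,
              x$method_b,
              if (pooled) x$mean_b else x$display_mean_b,
              if (pooled) x$sd_b else x$display_sd_b))
  cat(sprintf("  mean discrepancy %.2f mm, %s, p = %.4g\n",
              round(x$mean_discrepancy, 2), x$test_name, x$p_value))
  invisible(x)
}

# Dunn's multiple comparison (1964) following a Friedman test: z on the
# within-block rank means, Bonferroni-adjusted over the pairs.
dunn_pairs <- function(M) {
  n <- nrow(M); k <- ncol(M)
  ranks <- t(apply(M, 1L, rank))
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2L)
  m <- ncol(pairs)
  out <- vector("list", m)
  for (j in seq_len(m)) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    z <- (rbar[i2] - rbar[i1]) / se
    out[[j]] <- list(a = colnames(M)[i1], b = colnames(M)[i2],
                     statistic = unname(z),
                     p_value = min(1, m * 2 * stats::pnorm(-abs(z))))
  }
  out
}

tukey_pairs <- function(M) {
  k <- ncol(M); n <- nrow(M)
  long <- data.frame(value = as.vector(M),
                     method = factor(rep(colnames(M), each = n)),
                     subject = factor(rep(seq_len(n), k)))
  fit <- stats::aov(value ~ method + subject, data = long)
  th <- stats::TukeyHSD(fit, which = "method")$method
  out <- vector("list", nrow(th))
  nm <- rownames(th)
  for (j in seq_len(nrow(th))) {
    ab <- strsplit(nm[j], "-", fixed = TRUE)[[1L]]
    out[[j]] <- list(a = ab[2L], b = ab[1L],
                     statistic = unname(th[j, "diff"]),
                     p_value = unname(th[j, "p adj"]))
  }
  out
}

#' Paired three-condition post hoc comparison
#'
#' For three paired conditions (e.g. two reconstruction methods and a third
#' modality, or two Euclidean distances and the MER-recorded distance):
#' when every pairwise difference set passes [ks_normality()], a
#' repeated-measures ANOVA with Tukey's HSD on the within-subject error term;
#' otherwise a Friedman test followed by Dunn's multiple comparison
#' (Bonferroni over the three pairs). Incomplete condition triplets are
#' dropped listwise with a logged count.
#'
#' @param M an n x 3 matrix (rows = subjects/electrodes, named columns =
#'   conditions), or a [paired_coordinate_table()] together with `axis`.
#' @param axis when `M` is a paired table: the axis to pool (magnitudes).
#' @param methods when `M` is a paired table: the three method labels
#'   (defaults to all methods present).
#' @param alpha level for the normality gate.
#' @param route `"auto"` (normality-gated), or force `"tukey"` / `"dunn"`.
#' @return a `dbs_posthoc` list: `route` (`"tukey"`, `"dunn"` or
#'   `"degenerate"`), `overall` (F or chi-square test summary), and `pairs`
#'   (list of pairwise results with `a`, `b`, `statistic`, `p_value`).
#' @export
three_method_posthoc <- function(M, axis = NULL, methods = NULL, alpha = 0.05,
                                 route = c("auto", "tukey", "dunn")) {
  route <- match.arg(route)
  if (inherits(M, "paired_coordinate_table") || (is.data.frame(M) && !is.null(axis))) {
    methods <- methods %||% unique(M$method)
    if (length(methods) != 3L) stop("exactly 3 methods are required", call. = FALSE)
    pm <- pooled_matrix(M, axis, "all", methods)
    M <- pm$mag
  }
  M <- as.matrix(M)
  if (ncol(M) != 3L) stop("exactly 3 paired conditions are required", call. = FALSE)
  if (is.null(colnames(M))) colnames(M) <- c("A", "B", "C")
  cc <- stats::complete.cases(M)
  if (any(!cc))
    stage_log("compare", "dropped %d incomplete condition triplet(s)", sum(!cc))
  M <- M[cc, , drop = FALSE]
  if (nrow(M) < 3L) stop("fewer than 3 complete subjects remain", call. = FALSE)

  pair_idx <- utils::combn(3L, 2L)
  dsets <- lapply(seq_len(3L), function(j)
    M[, pair_idx[2L, j]] - M[, pair_idx[1L, j]])
  sds <- vapply(dsets, stats::sd, numeric(1))
  if (all(sds < 1e-12) && all(abs(vapply(dsets, mean, numeric(1))) < 1e-12)) {
    pairs <- lapply(seq_len(3L), function(j)
      list(a = colnames(M)[pair_idx[1L, j]], b = colnames(M)[pair_idx[2L, j]],
           statistic = 0, p_value = 1))
    return(structure(list(route = "degenerate",
                          overall = list(statistic = 0, p_value = 1),
                          pairs = pairs, n = nrow(M)),
                     class = "dbs_posthoc"))
  }
  # the rank route also covers constant (zero-SD) difference sets, where the
  # KS gate is undefined and a parametric MSE could collapse to zero
  normal <- switch(route,
    tukey = TRUE,
    dunn = FALSE,
    auto = all(sds >= 1e-12) && all(vapply(dsets, function(d) {
      ok <- tryCatch(ks_normality(d, alpha)$normal, error = function(e) NA)
      isTRUE(ok)
    }, logical(1))))
  if (normal) {
    long <- data.frame(value = as.vector(M),
                       method = factor(rep(colnames(M), each = nrow(M))),
                       subject = factor(rep(seq_len(nrow(M)), ncol(M))))
    fit <- stats::aov(value ~ method + subject, data = long)
    sm <- summary(fit)[[1L]]
    overall <- list(statistic = sm["method", "F value"],
                    p_value = sm["method", "Pr(>F)"])
    pairs <- tukey_pairs(M)
    route <- "tukey"
  } else {
    fr <- stats::friedman.test(M)
    overall <- list(statistic = unname(fr$statistic), p_value = fr$p.value)
    pairs <- dunn_pairs(M)
    route <- "dunn"
  }
  structure(list(route = route, overall = overall, pairs = pairs, n = nrow(M)),
            class = "dbs_posthoc")
}

#' @export
print.dbs_posthoc <- function(x, ...) {
  cat(sprintf("paired 3-condition post hoc (%s route, n = %d), overall p = %.4g\n",
              x$route, x$n, x$overall$p_value))
  for (pr in x$pairs) {
    cat(sprintf("  %s vs %s: stat %.3f, p = %.4g\n", pr$a, pr$b,
                pr$statistic, pr$p_value))
  }
  invisible(x)
}

#' Tip-to-target distance validation against MER depth
#'
#' Treats the two methods' Euclidean tip-to-target distances and the
#' intraoperatively recorded MER distance as three paired conditions and
#' applies [three_method_posthoc()].
#'
#' @param records data.frame with columns `euclid_a_mm`, `euclid_b_mm`,
#'   `mer_mm` (one row per electrode; `patient_id`/`side` are carried along
#'   if present).
#' @inheritParams three_method_posthoc
#' @return a `dbs_posthoc`.
#' @export
distance_validation <- function(records, alpha = 0.05) {
  need <- c("euclid_a_mm", "euclid_b_mm", "mer_mm")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("distance records missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(stats::na.omit(unlist(records[need])) < 0))
    stop("distances must be non-negative", call. = FALSE)
  M <- as.matrix(records[, need])
  colnames(M) <- c("euclid_a", "euclid_b", "mer")
  three_method_posthoc(M, alpha = alpha)
}

#' Consistency rate between two category sequences
#'
#' Fraction of index-matched equal categorizations (e.g. relative-position
#' categories of the same electrodes under two methods).
#'
#' @param categories_a,categories_b equal-length character vectors.
#' @return list with `matches`, `n`, `fraction` and `percent` (1 decimal).
#' @export
consistency_rate <- function(categories_a, categories_b) {
  if (length(categories_a) != length(categories_b))
    stop("category sequences differ in length", call. = FALSE)
  if (length(categories_a) == 0L) stop("empty category sequences", call. = FALSE)
  m <- sum(categories_a == categories_b)
  n <- length(categories_a)
  list(matches = m, n = n, fraction = m / n, percent = round(100 * m / n, 1L))
}

#' Dorsolateral subregion rate of optimal contacts
#'
#' Percentage of optimal contacts falling in the dorsolateral (sensorimotor)
#' STN subregion.
#'
#' @param labels character vector of [contact_subregion()] labels.
#' @return list with `count`, `n`, `percent` (1 decimal).
#' @export
subregion_rate <- function(labels) {
  if (length(labels) == 0L) stop("empty label list", call. = FALSE)
  k <- sum(labels == "dorsolateral")
  list(count = k, n = length(labels), percent = round(100 * k / length(labels), 1L))
}
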