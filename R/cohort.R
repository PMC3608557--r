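#' Percent volume
#'
#' Foreground voxels as a percentage of all stack voxels.
#'
#' @param vol a [binary_volume].
#' @return Numeric in `[0, 100]`.
#' @export
percent_volume <- function(vol) {
  stopifnot(inherits(vol, "binary_volume"))
  100 * sum(vol$voxels) / length(vol$voxels)
}

#' Median and interquartile range
#'
#' Median with the 25th/75th percentiles, using the linear-interpolation
#' percentile convention (`stats::quantile` type 7). Medians and IQRs are
#' preferred over means/SDs because dispersion indices are typically
#' non-normal across samples.
#'
#' @param values numeric vector, length >= 1.
#' @return Named numeric vector `c(median, q25, q75)`.
#' @export
summarize_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stopf("no values to summarize")
  c(median = median(values),
    q25 = unname(quantile(values, 0.25, type = 7)),
    q75 = unname(quantile(values, 0.75, type = 7)))
}

#' Welch's unequal-variance t-test (two-tailed p)
#'
#' @param a,b numeric samples, each with at least 2 values and nonzero
#'   variance.
#' @return List with `statistic`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stopf("each sample needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stopf("degenerate variance: both samples are constant")
  ht <- t.test(a, b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Wilcoxon rank-sum test (two-sided p)
#'
#' Unpaired rank-sum test: exact distribution when the pooled sample size is
#' at most 20 and there are no ties, otherwise the normal approximation with
#' tie correction (and continuity correction). The method used is recorded
#' in the result.
#'
#' @param a,b numeric samples (unpaired).
#' @return List with `statistic` (rank-sum W of `a`), `p`, `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
wilcoxon_rank <- function(a, b) {
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) stopf("all pooled values identical")
  ties <- anyDuplicated(pooled) > 0
  exact <- (length(pooled) <= 20) && !ties
  ht <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p = ht$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Quadratic fit of dispersion on percent volume
#'
#' Least-squares fit of `nhv = a * v_pct^2 + b * v_pct + c` with the
#' coefficient of determination. Within one sample, the per-class (V%, nHv)
#' points of a vascular network typically organize on a smooth monotone arc;
#' the quadratic fit and its R^2 quantify that organization.
#'
#' @param v_pct,nhv numeric vectors (same length, >= 3 points with >= 3
#'   distinct abscissae).
#' @return List with `a`, `b`, `c`, `r_squared`, `n`.
#' @export
quadratic_fit <- function(v_pct, nhv) {
  keep <- !is.na(v_pct) & !is.na(nhv)
  v <- v_pct[keep]; y <- nhv[keep]
  if (length(v) < 3 || length(unique(v)) < 3)
    stopf("need >= 3 points with >= 3 distinct abscissae")
  fit <- lm(y ~ v + I(v^2))
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stopf("response is constant; R^2 undefined")
  cf <- coef(fit)
  list(a = unname(cf["I(v^2)"]), b = unname(cf["v"]),
       c = unname(cf["(Intercept)"]),
       r_squared = 1 - ss_res / ss_tot, n = length(v))
}

#' Significance stars
#'
#' Strict thresholds: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' otherwise `ns` (a p of exactly 0.05 is `ns`).
#'
#' @param p numeric p-value(s).
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*" else "ns"
  }, character(1))
}

#' Cohort significance table
#'
#' For every caliber class and every pair of treatments, tests the percent
#' volume with Welch's t-test and the dispersion (nHv) with the Wilcoxon
#' rank-sum test, with star coding. Also returns per-treatment medians and
#' interquartile ranges and the per-sample quadratic V%-nHv fits. Cells
#' whose data are missing or degenerate are flagged `NA`, never fabricated.
#'
#' @param metrics data frame of per-sample, per-class metrics with columns
#'   `sample`, `treatment`, `class`, `v_pct`, `nhv` (e.g. from
#'   [run_pipeline()]).
#' @param adjust p-adjustment method passed to [stats::p.adjust()]
#'   (`"none"` by default; raw per-cell significance).
#' @return List of class `cohort_summary`: `tests` (class x treatment-pair
#'   grid with p-values and stars), `summaries` (medians/IQRs), `fits`
#'   (per-sample quadratic coefficients and R^2).
#' @export
build_significance_table <- function(metrics, adjust = "none") {
  need <- c("sample", "treatment", "class", "v_pct", "nhv")
  if (!all(need %in% names(metrics)))
    stopf("metrics must have columns: %s", paste(need, collapse = ", "))
  treatments <- unique(as.character(metrics$treatment))
  if (length(treatments) < 2) stopf("need >= 2 treatments to compare")
  classes <- sort(unique(metrics$class))
  pairs <- utils::combn(treatments, 2, simplify = FALSE)

  get <- function(tr, cl, col) {
    metrics[metrics$treatment == tr & metrics$class == cl, col]
  }
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  tests <- do.call(rbind, lapply(classes, function(cl) {
    do.call(rbind, lapply(pairs, function(pr) {
      va <- get(pr[1], cl, "v_pct"); vb <- get(pr[2], cl, "v_pct")
      ha <- get(pr[1], cl, "nhv"); hb <- get(pr[2], cl, "nhv")
      data.frame(class = cl, treatment_a = pr[1], treatment_b = pr[2],
                 p_v_pct = safe(welch_t(va, vb)$p),
                 p_nhv = safe(wilcoxon_rank(ha[!is.na(ha)], hb[!is.na(hb)])$p))
    }))
  }))
  if (adjust != "none") {
    tests$p_v_pct <- stats::p.adjust(tests$p_v_pct, method = adjust)
    tests$p_nhv <- stats::p.adjust(tests$p_nhv, method = adjust)
  }
  tests$stars_v_pct <- significance_stars(tests$p_v_pct)
  tests$stars_nhv <- significance_stars(tests$p_nhv)

  summaries <- do.call(rbind, lapply(treatments, function(tr) {
    do.call(rbind, lapply(classes, function(cl) {
      v <- summarize_iqr(get(tr, cl, "v_pct"))
      h <- tryCatch(summarize_iqr(get(tr, cl, "nhv")),
                    error = function(e) c(median = NA_real_, q25 = NA_real_, q75 = NA_real_))
      data.frame(treatment = tr, class = cl,
                 v_pct_median = v["median"], v_pct_q25 = v["q25"], v_pct_q75 = v["q75"],
                 nhv_median = h["median"], nhv_q25 = h["q25"], nhv_q75 = h["q75"],
                 row.names = NULL)
    }))
  }))

  samples <- unique(metrics[, c("sample", "treatment")])
  fits <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    m <- metrics[metrics$sample == samples$sample[i], ]
    f <- tryCatch(quadratic_fit(m$v_pct, m$nhv), error = function(e) NULL)
    data.frame(sample = samples$sample[i], treatment = samples$treatment[i],
               a = if (is.null(f)) NA_real_ else f$a,
               b = if (is.null(f)) NA_real_ else f$b,
               c = if (is.null(f)) NA_real_ else f$c,
               r_squared = if (is.null(f)) NA_real_ else f$r_squared,
               n_points = if (is.null(f)) 0L else f$n)
  }))
  structure(list(tests = tests, summaries = summaries, fits = fits),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort_summary\n\nPairwise tests (Welch on V%, Wilcoxon on nHv):\n")
  print(x$tests)
  cat("\nPer-sample quadratic V%-nHv fits:\n")
  print(x$fits)
  invisible(x)
}

#' Read a per-sample metrics spreadsheet (CSV layout)
#'
#' Reads a long-format CSV of per-sample, per-class metrics (columns
#' `sample`, `treatment`, `class`, `v_pct`, `nhv`, further columns kept),
#' the layout written by [run_pipeline()], so published or externally
#' computed values can be re-analyzed with [build_significance_table()].
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_metrics_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "treatment", "class", "v_pct", "nhv")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("metrics file lacks columns: %s", paste(miss, collapse = ", "))
  df
}
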