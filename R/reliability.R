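#' Ratings matrix of ALPS indices
#'
#' Builds the n subjects x k measurements matrix the reliability statistics
#' operate on, either from a wide matrix/data frame or from a long table.
#' Subjects with any missing cell are removed (listwise deletion) with a
#' message; no imputation is performed.
#'
#' @param x numeric matrix / wide data frame (rows = subjects), or a long
#'   data frame with subject, measurement and value columns.
#' @param subject,measurement,value column names used when `x` is long.
#' @return numeric matrix with subject rownames and measurement colnames.
#' @export
ratings_matrix <- function(x, subject = "subject_id",
                           measurement = "measurement_id", value = "alps_mean") {
  if (is.data.frame(x) && all(c(subject, measurement, value) %in% names(x))) {
    ids <- unique(x[[subject]])
    cols <- unique(x[[measurement]])
    m <- matrix(NA_real_, length(ids), length(cols),
                dimnames = list(ids, cols))
    m[cbind(match(x[[subject]], ids), match(x[[measurement]], cols))] <- x[[value]]
  } else {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    if (is.null(rownames(m))) rownames(m) <- sprintf("S%03d", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- sprintf("M%d", seq_len(ncol(m)))
  }
  incomplete <- rowSums(is.na(m)) > 0L
  if (any(incomplete)) {
    message("listwise deletion removed ", sum(incomplete),
            " subject(s) with missing measurements")
    m <- m[!incomplete, , drop = FALSE]
  }
  if (nrow(m) < 2L || ncol(m) < 2L)
    abort_dtialps("reliability analysis needs >= 2 subjects and >= 2 measurements",
                  "dtialps_design_error")
  m
}

#' Two-way ANOVA decomposition for ICC
#'
#' Mean squares of the two-way random-effects layout with single measures:
#' MS_R = k sum_i (xbar_i - xbar)^2 / (n - 1) for rows (subjects),
#' MS_C = n sum_j (xbar_j - xbar)^2 / (k - 1) for columns (raters/scanners),
#' MS_E = sum_ij (x_ij - xbar_i - xbar_j + xbar)^2 / ((n - 1)(k - 1)).
#'
#' @param m ratings matrix (n x k, complete).
#' @return object of class `anova_decomp` with `ms_rows`, `ms_cols`,
#'   `ms_error`, sums of squares, degrees of freedom, `n`, `k`.
#' @export
anova_decompose <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L)
    abort_dtialps("two-way decomposition needs n >= 2 and k >= 2",
                  "dtialps_design_error")
  if (anyNA(m))
    abort_dtialps("ratings matrix must be complete; build it with ratings_matrix()",
                  "dtialps_design_error")
  grand <- mean(m)
  rmeans <- rowMeans(m)
  cmeans <- colMeans(m)
  ss_rows <- k * sum((rmeans - grand)^2)
  ss_cols <- n * sum((cmeans - grand)^2)
  resid <- m - outer(rmeans, rep(1, k)) - outer(rep(1, n), cmeans) + grand
  ss_error <- sum(resid^2)
  structure(list(ms_rows = ss_rows / (n - 1),
                 ms_cols = ss_cols / (k - 1),
                 ms_error = ss_error / ((n - 1) * (k - 1)),
                 ss_rows = ss_rows, ss_cols = ss_cols, ss_error = ss_error,
                 ss_total = sum((m - grand)^2),
                 df_rows = n - 1L, df_cols = k - 1L,
                 df_error = (n - 1L) * (k - 1L),
                 n = n, k = k),
            class = "anova_decomp")
}

icc_result <- function(estimate, form, ci, p, n, k, f_value, degenerate = FALSE) {
  structure(list(estimate = estimate, form = form,
                 ci_lower = ci[1L], ci_upper = ci[2L], p_value = p,
                 band = if (is.na(estimate)) NA_character_ else interpret_icc(estimate),
                 n = n, k = k, f_value = f_value, degenerate = degenerate),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<icc_result> degenerate (constant ratings), ICC undefined\n")
    return(invisible(x))
  }
  cat(sprintf("<icc_result> ICC(%s,1) = %.3f (95%% CI [%.3f; %.3f], P = %.2g) — %s\n",
              if (x$form == "consistency") "C" else "A",
              x$estimate, x$ci_lower, x$ci_upper, x$p_value, x$band))
  invisible(x)
}

# shared one-sided test of ICC > 0 via F = MS_R / MS_E
icc_pvalue <- function(d) {
  if (d$ms_error == 0) return(if (d$ms_rows > 0) 0 else NA_real_)
  pf(d$ms_rows / d$ms_error, d$df_rows, d$df_error, lower.tail = FALSE)
}

#' Consistency ICC — two-way random effects, single measures
#'
#' ICC(C,1) = (MS_R - MS_E) / (MS_R + (k - 1) MS_E). Systematic column
#' (scanner) offsets do not affect it. The 95% confidence interval follows
#' the exact F-based single-measure procedure (McGraw & Wong 1996):
#' with F_obs = MS_R / MS_E and F* the alpha/2 quantiles on
#' (n-1, (n-1)(k-1)) df, bounds are (F_obs/F* - 1) / (F_obs/F* + k - 1).
#' The p-value is the one-sided test of ICC > 0 from the same F statistic.
#'
#' @param decomp an [anova_decompose()] result.
#' @param conf confidence level (default 0.95).
#' @return an `icc_result`.
#' @export
icc_consistency <- function(decomp, conf = 0.95) {
  d <- decomp
  if (d$ms_rows == 0 && d$ms_error == 0)
    return(icc_result(NA_real_, "consistency", c(NA_real_, NA_real_), NA_real_,
                      d$n, d$k, NA_real_, degenerate = TRUE))
  est <- (d$ms_rows - d$ms_error) / (d$ms_rows + (d$k - 1) * d$ms_error)
  alpha <- 1 - conf
  if (d$ms_error == 0) {
    ci <- c(1, 1); fv <- Inf
  } else {
    fv <- d$ms_rows / d$ms_error
    fl <- fv / qf(1 - alpha / 2, d$df_rows, d$df_error)
    fu <- fv * qf(1 - alpha / 2, d$df_error, d$df_rows)
    ci <- c((fl - 1) / (fl + d$k - 1), (fu - 1) / (fu + d$k - 1))
  }
  icc_result(est, "consistency", ci, icc_pvalue(d), d$n, d$k, fv)
}

#' Absolute-agreement ICC — two-way random effects, single measures
#'
#' ICC(A,1) = (MS_R - MS_E) /
#' (MS_R + (k - 1) MS_E + (k / n)(MS_C - MS_E)); unlike the consistency
#' form it penalizes systematic column offsets. The 95% confidence interval
#' uses the McGraw & Wong (1996) single-measure procedure with
#' Satterthwaite-approximated denominator degrees of freedom
#' v = (a MS_C + b MS_E)^2 / ((a MS_C)^2/(k-1) + (b MS_E)^2/((n-1)(k-1))),
#' a = k rho / (n (1 - rho)), b = 1 + k rho (n - 1) / (n (1 - rho)).
#' The p-value is the one-sided test of ICC > 0 via F = MS_R / MS_E.
#'
#' @inheritParams icc_consistency
#' @return an `icc_result`.
#' @export
icc_agreement <- function(decomp, conf = 0.95) {
  d <- decomp
  if (d$ms_rows == 0 && d$ms_error == 0)
    return(icc_result(NA_real_, "agreement", c(NA_real_, NA_real_), NA_real_,
                      d$n, d$k, NA_real_, degenerate = TRUE))
  n <- d$n; k <- d$k
  denom <- d$ms_rows + (k - 1) * d$ms_error + (k / n) * (d$ms_cols - d$ms_error)
  est <- (d$ms_rows - d$ms_error) / denom
  alpha <- 1 - conf
  fv <- if (d$ms_error > 0) d$ms_rows / d$ms_error else Inf
  if (est >= 1 - 1e-15) {
    ci <- c(1, 1)
  } else {
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    num_v <- (a * d$ms_cols + b * d$ms_error)^2
    den_v <- (a * d$ms_cols)^2 / (k - 1) +
             (b * d$ms_error)^2 / ((n - 1) * (k - 1))
    v <- if (den_v > 0) num_v / den_v else 1
    f_star <- qf(1 - alpha / 2, n - 1, v)
    f_low <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (d$ms_rows - f_star * d$ms_error) /
      (f_star * (k * d$ms_cols + (k * n - k - n) * d$ms_error) + n * d$ms_rows)
    upper <- n * (f_low * d$ms_rows - d$ms_error) /
      (k * d$ms_cols + (k * n - k - n) * d$ms_error + n * f_low * d$ms_rows)
    ci <- c(lower, upper)
  }
  icc_result(est, "agreement", ci, icc_pvalue(d), n, k, fv)
}

#' Interpretation band of an ICC estimate
#'
#' Conventional qualitative bands: poor below 0.5, moderate in \[0.5, 0.75),
#' good in \[0.75, 0.9), excellent at or above 0.9 (the boundary wording in
#' the literature is ambiguous; this package uses half-open intervals with
#' 0.9 mapping to excellent).
#'
#' @param estimate ICC estimate(s), each <= 1.
#' @return character vector of band labels.
#' @export
interpret_icc <- function(estimate) {
  if (any(estimate > 1 + 1e-12, na.rm = TRUE))
    abort_dtialps("ICC estimates cannot exceed 1", "dtialps_design_error")
  out <- ifelse(estimate < 0.5, "poor",
         ifelse(estimate < 0.75, "moderate",
         ifelse(estimate < 0.9, "good", "excellent")))
  out[is.na(estimate)] <- NA_character_
  out
}

#' Pairwise ICCs between measurement columns
#'
#' Computes the requested ICC form on every unordered pair of columns of the
#' ratings matrix (each pair analyzed as its own 2-column design), e.g. the
#' six scanner pairs of a four-scanner study.
#'
#' @param m ratings matrix.
#' @param form `"consistency"` or `"agreement"`.
#' @param conf confidence level.
#' @return data frame with one row per pair: `pair`, `col_a`, `col_b`,
#'   `estimate`, `ci_lower`, `ci_upper`, `p_value`, `band`.
#' @export
pairwise_icc <- function(m, form = c("consistency", "agreement"), conf = 0.95) {
  form <- match.arg(form)
  m <- as.matrix(m)
  if (ncol(m) < 2L)
    abort_dtialps("pairwise ICC needs k >= 2", "dtialps_design_error")
  pairs <- utils::combn(ncol(m), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    d <- anova_decompose(m[, c(i, j), drop = FALSE])
    r <- if (form == "consistency") icc_consistency(d, conf) else icc_agreement(d, conf)
    data.frame(pair = paste(colnames(m)[i], colnames(m)[j], sep = "-"),
               col_a = colnames(m)[i], col_b = colnames(m)[j],
               estimate = r$estimate, ci_lower = r$ci_lower,
               ci_upper = r$ci_upper, p_value = r$p_value, band = r$band,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bland-Altman agreement analysis
#'
#' Differences are `a - b`; bias is their mean and the 95% limits of
#' agreement are bias +/- 1.96 times the sample (n-1) standard deviation of
#' the differences. Plotting coordinates pair each difference with the
#' two measurements' mean.
#'
#' @param a,b equal-length paired measurement vectors.
#' @return object of class `bland_altman`: `bias`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `n`, and `data` (data frame `mean`, `difference`).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b))
    abort_dtialps("paired measurements must have equal length", "dtialps_design_error")
  ok <- !(is.na(a) | is.na(b))
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L)
    abort_dtialps("Bland-Altman analysis needs n >= 2 pairs", "dtialps_design_error")
  diffs <- a - b
  bias <- mean(diffs)
  s <- sd(diffs)
  structure(list(bias = bias, sd_diff = s,
                 loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
                 n = length(a),
                 data = data.frame(mean = (a + b) / 2, difference = diffs)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d | bias %.4g | LoA [%.4g; %.4g]\n",
              x$n, x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param ba a [bland_altman()] result.
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(ba, title = NULL) {
  stopifnot(inherits(ba, "bland_altman"))
  ggplot2::ggplot(ba$data, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(title = title, x = "Mean of pair", y = "Difference") +
    ggplot2::theme_minimal()
}

#' Instrumental validation report
#'
#' Applies the design-appropriate ICC form — consistency for inter-scanner
#' reproducibility, absolute agreement for inter-rater reliability and
#' test-retest repeatability — to a long-format table of ALPS indices, and
#' assembles overall and pairwise ICCs with confidence intervals,
#' interpretation bands, and Bland-Altman statistics per measurement pair.
#'
#' @param alps_table long data frame (`subject_id`, `measurement_id`, value
#'   column) or a wide ratings matrix.
#' @param design `"inter_scanner"`, `"inter_rater"` or `"test_retest"`.
#' @param value name of the value column for long input.
#' @param conf confidence level.
#' @return object of class `alps_validation_report`: `design`, `form`,
#'   `overall` (`icc_result`), `pairwise` (data frame), `bland_altman`
#'   (named list per pair), `matrix`.
#' @export
validation_report <- function(alps_table,
                              design = c("inter_scanner", "inter_rater",
                                         "test_retest"),
                              value = "alps_mean", conf = 0.95) {
  design <- match.arg(design)
  m <- ratings_matrix(alps_table, value = value)
  form <- if (design == "inter_scanner") "consistency" else "agreement"
  d <- anova_decompose(m)
  overall <- if (form == "consistency") icc_consistency(d, conf)
             else icc_agreement(d, conf)
  pw <- pairwise_icc(m, form = form, conf = conf)
  pairs <- utils::combn(ncol(m), 2L)
  ba <- lapply(seq_len(ncol(pairs)), function(p)
    bland_altman(m[, pairs[1L, p]], m[, pairs[2L, p]]))
  names(ba) <- pw$pair
  structure(list(design = design, form = form, overall = overall,
                 pairwise = pw, bland_altman = ba, matrix = m),
            class = "alps_validation_report")
}

#' @export
print.alps_validation_report <- function(x, ...) {
  cat("<alps_validation_report> design ", x$design, " (", x$form, " ICC), n = ",
      nrow(x$matrix), ", k = ", ncol(x$matrix), "\n", sep = "")
  print(x$overall)
  cat("pairwise:\n")
  print(x$pairwise[, c("pair", "estimate", "ci_lower", "ci_upper", "p_value", "band")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Flatten a validation report to a table of rows
#'
#' One row per pairwise ICC plus one `overall` row, mirroring the tabular
#' layout reliability studies publish (design, pair, estimate, CI, p, band).
#'
#' @param x an `alps_validation_report`.
#' @param row.names,optional,... standard [as.data.frame()] arguments (unused).
#' @return data frame.
#' @export
as.data.frame.alps_validation_report <- function(x, row.names = NULL,
                                                 optional = FALSE, ...) {
  overall <- data.frame(design = x$design, pair = "overall",
                        estimate = x$overall$estimate,
                        ci_lower = x$overall$ci_lower,
                        ci_upper = x$overall$ci_upper,
                        p_value = x$overall$p_value,
                        band = x$overall$band %||% NA_character_,
                        stringsAsFactors = FALSE)
  pw <- cbind(design = x$design,
              x$pairwise[, c("pair", "estimate", "ci_lower", "ci_upper",
                             "p_value", "band")])
  rbind(overall, pw)
}

#' @importFrom ggplot2 .data
NULL
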