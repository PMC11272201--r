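worked_matrix <- matrix(c(1, 3, 5, 2, 4, 6), nrow = 3)   # 3 subjects x 2 raters

test_that("two-way decomposition reproduces the hand-computed example", {
  d <- anova_decompose(worked_matrix)
  expect_equal(d$ms_rows, 8)
  expect_equal(d$ms_cols, 1.5)
  expect_equal(d$ms_error, 0)
  expect_equal(c(d$df_rows, d$df_cols, d$df_error), c(2L, 1L, 2L))
  # constant matrix: all mean squares zero
  d0 <- anova_decompose(matrix(2.2, 4, 3))
  expect_equal(c(d0$ms_rows, d0$ms_cols, d0$ms_error), c(0, 0, 0))
})

test_that("sum-of-squares identity and brute-force mean squares hold on random matrices", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      m <- matrix(rnorm(30, 1.5, 0.3), 10, 3)
      d <- anova_decompose(m)
      expect_lt(abs(d$ss_total - (d$ss_rows + d$ss_cols + d$ss_error)), 1e-10)
      bf <- brute_force_ms(m)
      expect_equal(d$ms_rows, bf$ms_r, tolerance = 1e-12)
      expect_equal(d$ms_cols, bf$ms_c, tolerance = 1e-12)
      expect_equal(d$ms_error, bf$ms_e, tolerance = 1e-12)
    }
  })
})

test_that("mean squares agree with base R's aov decomposition", {
  withr::with_seed(4, m <- matrix(rnorm(28, 1.4, 0.2), 7, 4))
  d <- anova_decompose(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(7), 4)),
                   rater = factor(rep(seq_len(4), each = 7)))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  expect_equal(d$ms_rows, tab["subj", "Mean Sq"], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(d$ms_cols, tab["rater", "Mean Sq"], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(d$ms_error, tab["Residuals", "Mean Sq"], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("ICC formulas reproduce the worked example and its degenerate cases", {
  d <- anova_decompose(worked_matrix)
  cc <- icc_consistency(d)
  expect_equal(cc$estimate, 1.0)
  expect_equal(c(cc$ci_lower, cc$ci_upper), c(1, 1))
  aa <- icc_agreement(d)
  expect_equal(aa$estimate, 8 / 9)
  # identical columns: perfect agreement
  ident <- matrix(c(1, 3, 5, 1, 3, 5), 3)
  ai <- icc_agreement(anova_decompose(ident))
  expect_equal(ai$estimate, 1)
  expect_equal(c(ai$ci_lower, ai$ci_upper), c(1, 1))
  # constant data: degenerate, reported as such
  dg <- icc_consistency(anova_decompose(matrix(1, 3, 2)))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$estimate))
})

test_that("formula ICCs match brute-force sum-of-squares estimates on 100 matrices", {
  withr::with_seed(23, {
    for (rep in 1:100) {
      m <- matrix(rnorm(30, 1.5, 0.25), 10, 3) +
        matrix(rnorm(10, 0, 0.2), 10, 3)       # add subject effects
      d <- anova_decompose(m)
      bf <- brute_force_ms(m)
      icc_c_bf <- (bf$ms_r - bf$ms_e) / (bf$ms_r + 2 * bf$ms_e)
      icc_a_bf <- (bf$ms_r - bf$ms_e) /
        (bf$ms_r + 2 * bf$ms_e + (3 / 10) * (bf$ms_c - bf$ms_e))
      expect_lt(abs(icc_consistency(d)$estimate - icc_c_bf), 1e-10)
      expect_lt(abs(icc_agreement(d)$estimate - icc_a_bf), 1e-10)
    }
  })
})

test_that("column offsets leave ICCc unchanged but strictly lower ICC_AA", {
  withr::with_seed(6, m <- matrix(rnorm(20, 1.5, 0.2), 10, 2) +
                     matrix(rnorm(10, 0, 0.3), 10, 2))
  shifted <- m
  shifted[, 2] <- shifted[, 2] + 0.1
  cc0 <- icc_consistency(anova_decompose(m))$estimate
  cc1 <- icc_consistency(anova_decompose(shifted))$estimate
  expect_equal(cc0, cc1, tolerance = 1e-12)
  aa0 <- icc_agreement(anova_decompose(m))$estimate
  aa1 <- icc_agreement(anova_decompose(shifted))$estimate
  expect_lt(aa1, aa0)
  expect_lt(aa1, cc1)
  # ICC_AA <= ICCc whenever MS_C >= MS_E; equality when MS_C = MS_E
  d <- anova_decompose(shifted)
  expect_true(d$ms_cols >= d$ms_error)
  d_eq <- d
  d_eq$ms_cols <- d_eq$ms_error
  expect_equal(icc_agreement(d_eq)$estimate, icc_consistency(d_eq)$estimate,
               tolerance = 1e-12)
})

test_that("estimates, p-values and intervals match an independent reference implementation", {
  # frozen oracle: pingouin.intraclass_corr on this exact matrix
  withr::with_seed(7, {
    m <- matrix(rnorm(15 * 4, 1.5, 0.2), 15, 4)
    m[, 2] <- m[, 2] + 0.1
  })
  d <- anova_decompose(m)
  cc <- icc_consistency(d)
  aa <- icc_agreement(d)
  expect_equal(cc$estimate, -0.09968835043838084, tolerance = 1e-12)
  expect_equal(aa$estimate, -0.09146623344363705, tolerance = 1e-12)
  expect_equal(cc$p_value, 0.8182507997176971, tolerance = 1e-12)
  expect_equal(aa$p_value, 0.8182507997176971, tolerance = 1e-12)
  expect_equal(round(c(cc$ci_lower, cc$ci_upper), 2), c(-0.22, 0.15))
  expect_equal(round(c(aa$ci_lower, aa$ci_upper), 2), c(-0.20, 0.14))
})

test_that("pairwise ICCs enumerate column pairs and match full-procedure submatrices", {
  withr::with_seed(13, m <- matrix(rnorm(60, 1.5, 0.2), 15, 4) +
                     matrix(rnorm(15, 0, 0.25), 15, 4))
  colnames(m) <- paste0("scanner", 1:4)
  pw <- pairwise_icc(m, "consistency")
  expect_equal(nrow(pw), 6L)          # k(k-1)/2 for k = 4
  for (r in seq_len(nrow(pw))) {
    sub <- m[, c(pw$col_a[r], pw$col_b[r])]
    ref <- icc_consistency(anova_decompose(sub))
    expect_equal(pw$estimate[r], ref$estimate)
    expect_equal(pw$ci_lower[r], ref$ci_lower)
  }
  # duplicated column: perfect ICC
  dup <- cbind(a = m[, 1], b = m[, 1])
  expect_equal(pairwise_icc(dup, "agreement")$estimate, 1)
})

test_that("Bland-Altman limits follow the sample-SD definition", {
  a <- c(1.2, 1.4, 1.6, 1.5)
  expect_equal(bland_altman(a, a)$bias, 0)
  expect_equal(bland_altman(a, a)$loa_upper, 0)
  shifted <- bland_altman(a, a + 0.1)
  expect_equal(shifted$bias, -0.1)
  expect_equal(shifted$sd_diff, 0)
  withr::with_seed(3, { x <- rnorm(30, 1.5, 0.2); y <- x + rnorm(30, 0.05, 0.08) })
  ba <- bland_altman(x, y)
  diffs <- x - y
  expect_equal(ba$bias, mean(diffs))
  expect_equal(ba$loa_lower, mean(diffs) - 1.96 * sd(diffs))
  expect_equal(ba$loa_upper, mean(diffs) + 1.96 * sd(diffs))
  expect_equal(ba$loa_upper - ba$loa_lower, 2 * 1.96 * ba$sd_diff)
  expect_equal(ba$data$mean, (x + y) / 2)
  expect_error(bland_altman(1, numeric(0)), class = "dtialps_design_error")
})

test_that("interpretation bands follow the published thresholds", {
  expect_equal(interpret_icc(c(0.3, 0.49999, 0.5, 0.6, 0.75, 0.77, 0.89, 0.9, 0.95, 1)),
               c("poor", "poor", "moderate", "moderate", "good", "good",
                 "good", "excellent", "excellent", "excellent"))
  expect_error(interpret_icc(1.2), class = "dtialps_design_error")
})

test_that("validation reports pick the design-appropriate form and structure", {
  cs <- cohort_spec(15, 4, sigma_subject = 0.15, sigma_error = 0.05, seed = 42)
  co <- simulate_cohort(cs)
  tab <- co$truth
  names(tab)[names(tab) == "true_alps"] <- "alps_mean"

  rep_s <- validation_report(tab, "inter_scanner")
  expect_equal(rep_s$form, "consistency")
  expect_equal(nrow(rep_s$pairwise), 6L)
  expect_length(rep_s$bland_altman, 6L)
  flat <- as.data.frame(rep_s)
  expect_equal(nrow(flat), 7L)        # overall + 6 pairs
  expect_equal(flat$pair[1], "overall")
  expect_true(all(flat$band %in% c("poor", "moderate", "good", "excellent")))

  rep_r <- validation_report(tab, "inter_rater")
  expect_equal(rep_r$form, "agreement")
  rep_t <- validation_report(tab[tab$measurement_id %in% c("M1", "M2"), ],
                             "test_retest")
  expect_equal(rep_t$form, "agreement")
  expect_equal(nrow(rep_t$pairwise), 1L)

  # noiseless cohort: every ICC = 1, every band excellent
  cs0 <- cohort_spec(8, 3, sigma_subject = 0.2, sigma_error = 0, seed = 5)
  t0 <- simulate_cohort(cs0)$truth
  names(t0)[3] <- "alps_mean"
  rep0 <- validation_report(t0, "test_retest")
  expect_equal(rep0$overall$estimate, 1)
  expect_true(all(rep0$pairwise$estimate == 1))
  expect_true(all(as.data.frame(rep0)$band == "excellent"))
})

test_that("ratings matrices apply listwise deletion and enforce the design", {
  long <- data.frame(subject_id = rep(c("a", "b", "c"), each = 2),
                     measurement_id = rep(c("M1", "M2"), 3),
                     alps_mean = c(1.1, 1.2, 1.3, NA, 1.4, 1.5))
  expect_message(m <- ratings_matrix(long), "listwise")
  expect_equal(dim(m), c(2L, 2L))
  expect_false("b" %in% rownames(m))
  expect_error(ratings_matrix(long[long$subject_id == "a", ]),
               class = "dtialps_design_error")
})

test_that("Bland-Altman plot is a ggplot with the three reference lines", {
  withr::with_seed(1, ba <- bland_altman(rnorm(20, 1.5, 0.2), rnorm(20, 1.55, 0.2)))
  p <- plot_bland_altman(ba, "pair")
  expect_s3_class(p, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p))
})
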