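# Group-level operations: Tukey-fence exclusion, per-line summaries, the
# line contrast on log parameters and the between-parameter correlations.

fits_table <- function(K, C = rep(1, length(K)), measure = "m",
                       line = rep("A", length(K)),
                       replicate = rep("rep1", length(K))) {
  data.frame(individual_id = sprintf("i%02d", seq_along(K)),
             measure = measure, line = line, replicate = replicate,
             K = K, C = C, T = C / K, x_inf = 0.1 / K,
             stringsAsFactors = FALSE)
}

test_that("Tukey fences flag extreme parameters and nothing else", {
  f <- fits_table(K = c(1, 1, 1, 1, 1, 1, 1, 100))
  out <- exclude_outliers(f)
  expect_identical(out$excluded, c(rep(FALSE, 7), TRUE))
  expect_identical(out$exclude_reason[8], "K")
  # hand-computed fences (type-7 quartiles) agree
  q <- quantile(f$K, c(0.25, 0.75), type = 7)
  expect_true(f$K[8] > q[2] + 1.5 * (q[2] - q[1]))
  # identical values: IQR collapses, equality is inside the fences
  all_same <- exclude_outliers(fits_table(K = rep(2, 6)))
  expect_false(any(all_same$excluded))
  # too few rows: warning, nothing flagged
  expect_warning(out3 <- exclude_outliers(fits_table(K = c(1, 50, 1))),
                 "fewer than")
  expect_false(any(out3$excluded))
})

test_that("exclusion is idempotent and the refit mode converges", {
  set.seed(77)
  f <- fits_table(K = c(rexp(9) + 1, 400))
  once <- exclude_outliers(f)
  twice <- exclude_outliers(once)
  expect_identical(once$excluded, twice$excluded)
  refit <- exclude_outliers(f, refit_fences = TRUE)
  expect_true(refit$excluded[10])
})

test_that("outliers planted in a synthetic cohort are the ones flagged", {
  spec <- cohort_spec(measures = "cortisol_release",
                      line_medians = data.frame(
                        line = "A", measure = "cortisol_release",
                        K = 0.03, C = 0.4),
                      n_lines = 1, n_replicates = 2,
                      n_individuals_per_cell = 4, dispersion = 0.2)
  co <- plant_outliers(generate_cohort(spec, seed = 31), k_outliers = 1,
                       magnitude = 20)
  pp <- preprocess_cohort(co$data, reference_means = spec$baseline_scale)
  fits <- exclude_outliers(fit_cohort(pp))
  expect_identical(sort(fits$individual_id[fits$excluded]),
                   sort(co$outliers$individual_id))
})

test_that("line summaries average derived values per individual", {
  f <- fits_table(K = c(0.1, 0.3), C = c(2, 3), line = c("A", "A"))
  s <- summarize_by_line(f)
  expect_equal(s$T, 15)              # (20 + 10) / 2, not meanC/meanK = 12.5
  expect_equal(s$K, 0.2)
  expect_equal(s$n, 2L)
  # a single individual per cell is its own summary
  f1 <- fits_table(K = 0.25, C = 1, line = "R")
  s1 <- summarize_by_line(f1)
  expect_equal(s1$K, 0.25)
  # excluded rows do not contribute
  f$excluded <- c(FALSE, TRUE)
  expect_equal(summarize_by_line(f)$K, 0.1)
})

test_that("line contrast drops degenerate terms and finds a planted effect", {
  set.seed(101)
  K_A <- exp(rnorm(8, log(0.05), 0.3))
  K_R <- exp(rnorm(8, log(0.05) + 2 * 0.3 * 2, 0.3))  # 4 log-SD apart
  f <- fits_table(K = c(K_A, K_R), line = rep(c("A", "R"), each = 8),
                  replicate = rep(c("rep1", "rep2"), times = 8))
  res <- line_effect_test(f, "m", "K")
  expect_lt(res$p_value, 0.01)
  expect_gt(res$estimates[["R"]], res$estimates[["A"]])
  # single replicate level: replicate term dropped automatically
  f1 <- fits_table(K = c(K_A, K_R), line = rep(c("A", "R"), each = 8))
  res1 <- line_effect_test(f1, "m", "K")
  expect_false(grepl("replicate", res1$formula))
  expect_error(line_effect_test(fits_table(K = 1:4), "m", "K"),
               "two lines")
})

test_that("null and separated cohorts give calibrated line p-values", {
  set.seed(202)
  p_null <- replicate(60, {
    f <- fits_table(K = exp(rnorm(16, log(0.1), 0.3)),
                    line = rep(c("A", "R"), each = 8),
                    replicate = rep(c("rep1", "rep2"), times = 8))
    line_effect_test(f, "m", "K")$p_value
  })
  # uniform-ish under the null
  expect_gt(mean(p_null < 0.05), 0)
  expect_lt(mean(p_null < 0.05), 0.2)
  expect_gt(median(p_null), 0.2)
})

test_that("parameter correlation matrix is symmetric with unit diagonal", {
  spec <- cohort_spec(measures = c("cortisol_release", "oxygen_consumption"),
                      n_individuals_per_cell = 4, cross_measure_cor = 0.9)
  co <- generate_cohort(spec, seed = 51)
  pp <- preprocess_cohort(co$data, reference_means = spec$baseline_scale)
  fits <- fit_cohort(pp)
  ct <- parameter_correlations(fits)
  expect_identical(dim(ct$r), c(4L, 4L))
  expect_equal(diag(ct$r), setNames(rep(1, 4), colnames(ct$r)))
  expect_equal(ct$r, t(ct$r))
  expect_true(all(ct$r >= -1 & ct$r <= 1, na.rm = TRUE))
  # generated cross-measure correlation of K shows up in the fitted values
  r_KK <- ct$r["cortisol_release_K", "oxygen_consumption_K"]
  expect_gt(r_KK, 0.5)
  # too few complete pairs leave the entry absent
  small <- fits[fits$measure == "cortisol_release", ][1:2, ]
  small2 <- rbind(small,
                  transform(small, measure = "oxygen_consumption"))
  ct2 <- parameter_correlations(small2)
  expect_true(is.na(ct2$r["cortisol_release_K", "oxygen_consumption_K"]))
})

test_that("full pipeline orders the line stiffness as generated", {
  spec <- cohort_spec(measures = "cortisol_release",
                      n_individuals_per_cell = 4, noise_sigma = 0.05)
  co <- generate_cohort(spec, seed = 61)
  pp <- preprocess_cohort(co$data)
  fits <- exclude_outliers(fit_cohort(pp))
  s <- summarize_by_line(fits)
  # generated with line R twice as stiff in cortisol release
  expect_gt(s$K[s$line == "R"], s$K[s$line == "A"])
})
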