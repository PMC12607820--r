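# Independent oracle: exact two-sided Mann-Whitney p by full enumeration
# of all C(n1+n2, n1) rank assignments.
enumerate_mw_p <- function(u_obs, n1, n2) {
  ranks <- seq_len(n1 + n2)
  combos <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(ranks[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  # two-sided: double the smaller tail (as for the exact U distribution)
  if (u_obs > mu) {
    min(1, 2 * mean(u_all >= u_obs))
  } else {
    min(1, 2 * mean(u_all <= u_obs))
  }
}

test_that("normality screening reaches verdicts at the nominal level and power", {
  set.seed(101)
  verdicts_norm <- replicate(100, assess_normality(rnorm(50))$verdict)
  expect_gte(sum(verdicts_norm == "normal"), 90)
  verdicts_lnorm <- replicate(100, assess_normality(rlnorm(50, sdlog = 1))$verdict)
  expect_gte(sum(verdicts_lnorm == "non_normal"), 95)
  expect_error(assess_normality(c(1, 2)), "at least 3")
  expect_error(assess_normality(rep(5, 10)), "constant")
})

test_that("log transform fires only on non-normal verdicts and handles zeros", {
  set.seed(102)
  x <- rnorm(50)
  rep_n <- assess_normality(x)
  if (rep_n$verdict == "normal") {
    out <- log_transform_if_needed(x, rep_n)
    expect_identical(out$values, x)
    expect_false(out$transformed)
  }
  fake_nn <- structure(list(verdict = "non_normal"), class = "normality_report")
  vals <- c(1, exp(1), exp(2))
  out2 <- log_transform_if_needed(vals, fake_nn)
  expect_equal(out2$values, c(0, 1, 2))
  expect_true(out2$transformed)
  with_zero <- c(0, 0.5, 2, 8)
  out3 <- log_transform_if_needed(with_zero, fake_nn)
  expect_equal(out3$offset, 0.5)
  expect_equal(out3$values, log(with_zero + 0.5))
  expect_error(log_transform_if_needed(c(-1, 0, -3), fake_nn), "no positive")
})

test_that("Pearson correlation matches hand computation and labels strength", {
  x <- c(1, 2, 3, 4)
  r <- pearson_correlation(x, c(1, 3, 2, 4))
  expect_equal(r$r, 0.8)
  expect_equal(r$strength_label, "strong")   # 0.8 falls in the (0.6, 0.8] band
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearson_correlation(x, -x)$r, -1.0)
  expect_equal(pearson_correlation(x, -x)$strength_label, "very strong")
  expect_equal(correlation_strength(0.15), "very weak")
  expect_equal(correlation_strength(-0.45), "moderate")
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("Mann-Whitney U matches the enumeration oracle on small samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_value, 0.1)               # 2/20 arrangements as extreme
  expect_equal(r$method, "exact")
  # symmetric identical groups: midranks give U = n1*n2/2
  sym <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(sym$u_statistic, 8)
  # spot-check exact p against enumeration on random tie-free data
  set.seed(103)
  for (i in 1:10) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    v <- sample(seq_len(100), n1 + n2)
    r <- mann_whitney_u(v[1:n1], v[(n1 + 1):(n1 + n2)])
    expect_equal(r$p_value, enumerate_mw_p(r$u_statistic, n1, n2),
                 tolerance = 1e-12)
  }
})

test_that("exact and approximate Mann-Whitney p agree for moderate samples", {
  set.seed(104)
  for (i in 1:5) {
    a <- rnorm(20); b <- rnorm(20, 0.3)
    pe <- mann_whitney_u(a, b, method = "exact")$p_value
    pa <- mann_whitney_u(a, b, method = "approx")$p_value
    expect_lt(abs(pe - pa), 0.01)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
  expect_error(mann_whitney_u(c(1, 1, 2), c(1, 3, 4), method = "exact"), "ties")
})

test_that("predictor selection enforces the r, p and collinearity screens", {
  cand <- data.frame(parameter = c("A", "B", "C"),
                     r = c(0.30, 0.20, 0.40), p = c(0.01, 0.01, 0.20))
  ic <- diag(3); dimnames(ic) <- list(c("A", "B", "C"), c("A", "B", "C"))
  sel <- select_predictors(cand, ic)
  expect_identical(as.character(sel), "A")   # B fails |r|, C fails p

  cand2 <- data.frame(parameter = c("A", "B"),
                      r = c(0.6, 0.5), p = c(0.001, 0.001))
  ic2 <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  sel2 <- select_predictors(cand2, ic2)
  expect_identical(as.character(sel2), "A")  # B dropped: weaker outcome correlate
  expect_match(paste(attr(sel2, "log"), collapse = ";"), "dropped B")

  # tie in |r|: the later row is dropped
  cand3 <- data.frame(parameter = c("A", "B"),
                      r = c(0.5, -0.5), p = c(0.001, 0.001))
  sel3 <- select_predictors(cand3, ic2)
  expect_identical(as.character(sel3), "A")
})

test_that("Enter regression reports R2, effect sizes and exact fits", {
  set.seed(105)
  x <- rnorm(100)
  df <- data.frame(y = x, x = x)
  fit <- fit_linear_regression_enter(df, "y", "x")
  expect_equal(fit$r_squared, 1.0)
  expect_lt(max(abs(stats::residuals(fit$fit))), 1e-10)
  expect_equal(fit$effect_size_label, "large")

  expect_equal(cohen_r2_label(0.64), "large")
  expect_equal(cohen_r2_label(0.20), "medium")
  expect_equal(cohen_r2_label(0.05), "small")
  expect_equal(cohen_r2_label(0.01), "negligible")

  # collinear design is reported, not silently dropped
  df2 <- data.frame(y = rnorm(50), a = rnorm(50))
  df2$b <- 2 * df2$a
  expect_error(fit_linear_regression_enter(df2, "y", c("a", "b")),
               "rank-deficient")
})

test_that("simple-regression R2 equals the squared Pearson correlation", {
  set.seed(106)
  for (i in 1:10) {
    x <- rnorm(40); y <- 0.5 * x + rnorm(40)
    fit <- fit_linear_regression_enter(data.frame(y = y, x = x), "y", "x")
    r <- pearson_correlation(x, y)$r
    expect_equal(fit$r_squared, r^2, tolerance = 1e-12)
  }
})

test_that("validity workflow recovers near-perfect coupling and rejects shuffled pairings", {
  # noise-free coupling at the parameter level: COM parameters from the
  # ground-truth trajectory, COP parameters from the coupled recording
  base <- sway_model_params(amplitude_x = 3, amplitude_y = 4, bandwidth_hz = 2,
                            duration_s = 10, rate_hz = 30)
  spec <- cohort_spec(n_cp = 10, n_control = 10, coupling_noise_sd = 0,
                      tremor_amplitude = 0, seed = 42)
  co <- generate_cohort(spec, base)
  img <- list(); cp <- list()
  for (tr in co$trials) {
    keys <- list(subject_id = tr$subject_id, group = tr$group,
                 condition = tr$condition)
    img[[length(img) + 1L]] <-
      sway_parameters_row(compute_sway_parameters(tr$traj), "COM", keys)
    rec <- butterworth_lowpass(tr$cop)
    cp[[length(cp) + 1L]] <-
      sway_parameters_row(compute_sway_parameters(cop_to_trajectory(rec)),
                          "COP", keys)
  }
  img <- do.call(rbind, img); cp <- do.call(rbind, cp)
  report <- run_validation(img, cp)
  vr <- report$correlations
  vr <- vr[vr$scope == "pooled" &
           vr$image_parameter == "Vmean_COMr" &
           vr$cop_parameter == "Vmean_COPr", ]
  expect_equal(nrow(vr), 4)
  expect_true(all(vr$r >= 0.95))
  # models respect the selection rules
  expect_true(all(report$models$n_predictors >= 0))
  expect_true(all(report$models$r_squared[!is.na(report$models$r_squared)] <= 1))

  # shuffled pairing destroys the association
  set.seed(7)
  cp_shuffled <- cp
  for (cond in unique(cp$condition)) {
    i <- which(cp$condition == cond)
    cp_shuffled$subject_id[i] <- sample(cp$subject_id[i])
  }
  rep_null <- run_validation(img, cp_shuffled, transform = FALSE)
  vn <- rep_null$correlations
  vn <- vn[vn$scope == "pooled", ]
  expect_lt(mean(abs(vn$r)), 0.25)
})

test_that("mismatched tables produce a join error listing offending keys", {
  df <- data.frame(subject_id = c("S1", "S2"), group = "cp",
                   condition = "EO_apart")
  for (cc in paste0(rep(c("Vmean_", "Vstd_", "Ctotal_"), each = 3),
                    "COM", c("x", "y", "r"))) df[[cc]] <- rnorm(2)
  df2 <- data.frame(subject_id = c("S1", "S3"), group = "cp",
                    condition = "EO_apart")
  for (cc in paste0(rep(c("Vmean_", "Vstd_", "Ctotal_"), each = 3),
                    "COP", c("x", "y", "r"))) df2[[cc]] <- rnorm(2)
  expect_error(run_validation(df, df2), "S2")
})
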