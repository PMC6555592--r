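toy_panel <- function(mean_map, reps = 5, cv = 0, seed = 1,
                      analyte = "IL6", unit = "pg/mL") {
  set.seed(seed)
  rows <- lapply(names(mean_map), function(key) {
    parts <- strsplit(key, "@", fixed = TRUE)[[1]]
    mu <- mean_map[[key]]
    tibble::tibble(
      analyte = analyte, treatment = parts[1],
      time_h = as.numeric(parts[2]), replicate = seq_len(reps),
      concentration = mu * (1 + cv * rnorm(reps)), unit = unit
    )
  })
  dplyr::bind_rows(rows)
}

test_that("protein fold changes are ratios of group means", {
  panel <- toy_panel(c("LPS@4" = 100, "saline@4" = 20,
                       "LPS@8" = 50, "saline@8" = 50))
  fc <- protein_fold_change(panel)
  expect_equal(fc$fc[fc$time_h == 4], 5)
  expect_equal(fc$fc[fc$time_h == 8], 1)
  expect_equal(fc$log2fc[fc$time_h == 4], log2(5))
  # scale equivariance: multiplying all concentrations leaves FC unchanged
  panel2 <- dplyr::mutate(panel, concentration = concentration * 37)
  expect_equal(protein_fold_change(panel2)$fc, fc$fc)
  # missing saline is an error
  expect_error(protein_fold_change(dplyr::filter(panel,
                                                 treatment != "saline")),
               "saline")
})

test_that("a zero saline mean falls back to the detection floor", {
  panel <- toy_panel(c("LPS@4" = 10, "saline@4" = 0))
  fc <- protein_fold_change(panel)
  # floor is half the smallest non-zero concentration (10) -> FC = 2
  expect_equal(fc$fc, 2)
  expect_identical(attr(fc, "n_floored"), 1L)
})

test_that("Dunnett with one comparison reduces to the two-sample t-test", {
  panel <- toy_panel(c("LPS@4" = 100, "saline@4" = 60,
                       "LPS@8" = 80, "saline@8" = 60), cv = 0.3, seed = 2)
  res <- anova_dunnett(panel, "IL6", scale = "raw")
  expect_identical(nrow(res$comparisons), 2L)
  # oracle: pooled two-sample t with the model's residual error
  d <- panel
  fit <- lm(concentration ~ factor(treatment) * factor(time_h), data = d)
  mse <- sum(fit$residuals^2) / fit$df.residual
  for (t_h in c(4, 8)) {
    y1 <- d$concentration[d$treatment == "LPS" & d$time_h == t_h]
    y0 <- d$concentration[d$treatment == "saline" & d$time_h == t_h]
    tstat <- (mean(y1) - mean(y0)) / sqrt(mse * (2 / 5))
    p_ref <- 2 * pt(-abs(tstat), fit$df.residual)
    row <- res$comparisons[res$comparisons$time_h == t_h, ]
    expect_equal(row$statistic, tstat, tolerance = 1e-10)
    expect_equal(row$p.adj, p_ref, tolerance = 1e-10)
  }
})

test_that("Dunnett critical value matches the Monte-Carlo max-|t| oracle", {
  # balanced k = 3 comparisons, n = 6 per group -> residual df = 20
  crit_mc <- dunnett_crit_mc(k = 3, n = 6, alpha = 0.05)
  # invert the package's adjusted p to its implied critical value
  crit_pkg <- uniroot(function(t) {
    vaxsig:::dunnett_p(rep(t, 3), n_trt = rep(6, 3), n0 = 6,
                       df = 20)[1] - 0.05
  }, c(1.5, 4))$root
  expect_lt(abs(crit_pkg - crit_mc), 0.02)
})

test_that("Dunnett adjustment grows with the number of comparisons", {
  p1 <- vaxsig:::dunnett_p(2.2, n_trt = 5, n0 = 5, df = 40)
  p3 <- vaxsig:::dunnett_p(c(2.2, 1, 1), n_trt = rep(5, 3), n0 = 5,
                           df = 40)[1]
  p6 <- vaxsig:::dunnett_p(c(2.2, rep(1, 5)), n_trt = rep(5, 6), n0 = 5,
                           df = 40)[1]
  expect_gt(p3, p1)
  expect_gt(p6, p3)
  expect_gte(p3, p1)  # adjusted p never below unadjusted
})

test_that("ANOVA validates its design requirements", {
  lonely <- toy_panel(c("LPS@4" = 1, "saline@4" = 1,
                        "LPS@8" = 1, "saline@8" = 1), reps = 1)
  expect_error(anova_dunnett(lonely, "IL6"), "< 2 replicates")
  one_time <- toy_panel(c("LPS@4" = 1, "saline@4" = 1))
  expect_error(anova_dunnett(one_time, "IL6"), ">= 2 time points")
  expect_error(anova_dunnett(toy_panel(c("LPS@4" = 1, "LPS@8" = 1)),
                             "IL6"), "saline")
  expect_error(anova_dunnett(toy_panel(c("LPS@4" = 1)), "TNF"),
               "not in panel")
})

test_that("trapezoidal AUC is exact and additive", {
  expect_equal(auc_trapezoid(c(0, 4, 8), c(0, 10, 10)), 60)
  expect_equal(auc_trapezoid(c(0, 24), c(7, 7)), 7 * 24)  # constant c*T
  # piecewise-linear series sampled at its knots: equals the true integral
  knots_t <- c(0, 4, 8, 24, 48)
  knots_c <- c(0, 8, 2, 6, 0)
  exact <- sum(diff(knots_t) * (head(knots_c, -1) + tail(knots_c, -1)) / 2)
  expect_equal(auc_trapezoid(knots_t, knots_c), exact)
  # additivity over adjacent intervals
  expect_equal(auc_trapezoid(knots_t[1:3], knots_c[1:3]) +
                 auc_trapezoid(knots_t[3:5], knots_c[3:5]),
               auc_trapezoid(knots_t, knots_c))
  expect_error(auc_trapezoid(c(4, 4, 8), c(1, 2, 3)), "increasing")
  expect_error(auc_trapezoid(4, 1), ">= 2 points")
})

test_that("panel AUC integrates mean concentration profiles", {
  panel <- toy_panel(c("LPS@0" = 0, "LPS@4" = 10, "LPS@8" = 10,
                       "saline@0" = 1, "saline@4" = 1, "saline@8" = 1))
  auc <- protein_auc(panel)
  expect_equal(auc$auc[auc$treatment == "LPS"], 60)
  expect_equal(auc$auc[auc$treatment == "saline"], 8)
  expect_identical(unique(auc$unit), "pg/mL.hr")
})

test_that("the volcano table labels strictly below adjusted p 0.01", {
  fc <- tibble::tibble(analyte = "IL6", treatment = "LPS",
                       time_h = c(4, 8, 24), log2fc = c(3, 1, 0))
  stats <- structure(list(
    analyte = "IL6", scale = "log2",
    comparisons = tibble::tibble(treatment = "LPS", time_h = c(4, 8, 24),
                                 p.adj = c(0.005, 0.01, 0.5))
  ), class = "anova_dunnett")
  v <- volcano_table(fc, stats)
  expect_identical(v$labelled, c(TRUE, FALSE, FALSE))
  expect_true(0 %in% v$log2fc)  # FC = 1 rows are retained
})

test_that("family-wise error is controlled under the null", {
  # quick sanity at 400 reps; the 2,000-rep calibration at the tight
  # tolerance lives in the acceptance suite
  set.seed(9)
  reps <- 400
  fwe <- mean(replicate(reps, {
    panel <- tibble::tibble(
      analyte = "A",
      treatment = rep(rep(c("saline", "t1", "t2"), each = 3), 2),
      time_h = rep(c(4, 8), each = 9),
      replicate = rep(1:3, 6),
      concentration = rnorm(18, 100, 10), unit = "pg/mL"
    )
    res <- anova_dunnett(panel, "A", scale = "raw")
    any(res$comparisons$p.adj[res$comparisons$time_h == 4] < 0.05)
  }))
  expect_lt(abs(fwe - 0.05), 0.035)
})

test_that("transcript-protein correlation recovers coupling", {
  # proportional series gives r = 1 with three-star significance
  times <- c(4, 8, 24, 48, 72, 168)
  prot_fc <- tibble::tibble(analyte = "IL6", treatment = "LPS",
                            time_h = times,
                            log2fc = c(2, 1.6, 0.7, 0.2, 0.05, 0))
  de <- tibble::tibble(gene = "g1", tissue = "muscle", treatment = "LPS",
                       time_h = times,
                       log2fc = 2 * c(2, 1.6, 0.7, 0.2, 0.05, 0))
  tp <- transcript_protein_correlation(
    prot_fc, de, tibble::tibble(analyte = "IL6", gene = "g1"))
  expect_equal(tp$r, 1, tolerance = 1e-10)
  expect_identical(tp$stars, "***")
  expect_identical(tp$n_times, 6L)
  # constant transcript profile is skipped as NA
  de2 <- dplyr::mutate(de, log2fc = 1)
  tp2 <- transcript_protein_correlation(
    prot_fc, de2, tibble::tibble(analyte = "IL6", gene = "g1"))
  expect_true(is.na(tp2$r))
})

test_that("coupled analytes correlate with transcripts in a full study", {
  st <- generate_study(small_config(seed = 61))
  norm <- lapply(st$expression, quantile_normalize)
  de <- run_de(norm, st$samples)
  fc <- protein_fold_change(st$proteins)
  coupling <- attr(st$proteins, "coupling")
  tp <- transcript_protein_correlation(
    fc, de, dplyr::select(coupling, analyte, gene))
  # zero-lag cytokines under the biomarker treatments: strong positive r
  lag0 <- coupling$analyte[coupling$lag_h == 0]
  hit <- dplyr::filter(tp, analyte %in% lag0, tissue == "muscle",
                       treatment %in% st$config$biomarker_treatments)
  expect_gt(median(hit$r, na.rm = TRUE), 0.6)
  expect_true(any(hit$p < 0.05))
})
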