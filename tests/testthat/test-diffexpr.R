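# metadata for a minimal two-group, two-time design (+ unvaccinated cells)
toy_meta <- function(treatments = c("LPS", "saline"), times = c(0, 24),
                     reps = 2, tissue = "muscle") {
  g <- expand.grid(treatment = treatments, time_h = times,
                   replicate = seq_len(reps), stringsAsFactors = FALSE)
  g$tissue <- tissue
  g$sample_id <- sprintf("%s_%s_%d_%d", tissue, g$treatment, g$time_h,
                         g$replicate)
  tibble::as_tibble(g)
}

toy_expr <- function(meta, cell_means, noise_sd = 0, n_genes = 1,
                     seed = 1) {
  set.seed(seed)
  key <- paste(meta$treatment, meta$time_h)
  mu <- cell_means[key]
  m <- matrix(rep(mu, each = n_genes), n_genes, nrow(meta)) +
    rnorm(n_genes * nrow(meta), 0, noise_sd)
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)), meta$sample_id)
  m
}

test_that("design construction counts cells and validates input", {
  meta <- toy_meta(times = c(4, 24))
  X <- build_design(meta)
  expect_identical(dim(X), c(8L, 4L))
  expect_identical(qr(X)$rank, 4L)
  expect_true(all(rowSums(X) == 1))

  dup <- meta; dup$sample_id[2] <- dup$sample_id[1]
  expect_error(build_design(dup), "duplicated sample ID")
  two_tissue <- meta; two_tissue$tissue[1] <- "blood"
  expect_error(build_design(two_tissue), "more than one tissue")
})

test_that("interaction contrast reproduces hand arithmetic on cell means", {
  meta <- toy_meta()
  cm <- c("LPS 24" = 8, "LPS 0" = 5, "saline 24" = 4, "saline 0" = 4)
  expr <- toy_expr(meta, cm)
  X <- build_design(meta)
  fit <- fit_genewise(expr, X)
  w <- interaction_contrast(X, "LPS", 24)
  expect_equal(sum(w), 0)
  expect_equal(drop(fit$coefficients %*% w), c(g001 = (8 - 5) - (4 - 4)))

  # all cells equal and parallel saline response both give zero
  cm0 <- c("LPS 24" = 5, "LPS 0" = 5, "saline 24" = 5, "saline 0" = 5)
  fit0 <- fit_genewise(toy_expr(meta, cm0), X)
  expect_equal(drop(fit0$coefficients %*% w), c(g001 = 0))
  cmp <- c("LPS 24" = 9, "LPS 0" = 5, "saline 24" = 8, "saline 0" = 4)
  fitp <- fit_genewise(toy_expr(meta, cmp), X)
  expect_equal(drop(fitp$coefficients %*% w), c(g001 = 0))

  expect_error(interaction_contrast(X, "saline", 24), "degenerates")
  expect_error(interaction_contrast(X, "LPS", 999), "lacks cell")
})

test_that("genewise OLS equals the cell means and the normal equations", {
  meta <- toy_meta()
  cm <- c("LPS 24" = 8, "LPS 0" = 5, "saline 24" = 4, "saline 0" = 4)
  X <- build_design(meta)
  fit <- fit_genewise(toy_expr(meta, cm), X)
  expect_equal(sort(unname(drop(fit$coefficients))), sort(unname(cm)))
  expect_equal(fit$sigma2, 0)

  set.seed(20)
  noisy <- toy_expr(meta, cm, noise_sd = 1, n_genes = 10)
  fit2 <- fit_genewise(noisy, X)
  # brute-force normal-equation oracle
  bhat <- t(solve(t(X) %*% X) %*% t(X) %*% t(noisy))
  expect_equal(unname(fit2$coefficients), unname(bhat), tolerance = 1e-10)
  res <- t(noisy) - X %*% t(bhat)
  expect_equal(fit2$sigma2, unname(colSums(res^2) / (8 - 4)),
               tolerance = 1e-10)
})

test_that("moderation hyperparameters are recovered from simulated variances", {
  set.seed(30)
  d0 <- 4; s02 <- 0.05; d <- 8; n <- 20000
  sigma2_true <- s02 * d0 / rchisq(n, d0)
  s2 <- sigma2_true * rchisq(n, d) / d
  fit <- structure(list(sigma2 = s2, df_residual = d,
                        genes = sprintf("g%05d", 1:n)),
                   class = "gene_fit")
  mp <- estimate_moderation(fit)
  expect_lt(abs(mp$df_prior - d0) / d0, 0.25)
  expect_lt(abs(mp$var_prior - s02) / s02, 0.10)
})

test_that("moderation agrees with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(31)
  s2 <- 0.04 * 6 / rchisq(5000, 6) * rchisq(5000, 10) / 10
  fit <- structure(list(sigma2 = s2, df_residual = 10,
                        genes = sprintf("g%04d", 1:5000)),
                   class = "gene_fit")
  mp <- estimate_moderation(fit)
  ref <- limma::squeezeVar(s2, df = 10)
  expect_equal(mp$df_prior, ref$df.prior, tolerance = 0.02 * ref$df.prior)
  expect_equal(mp$var_prior, ref$var.prior,
               tolerance = 0.02 * ref$var.prior)
})

test_that("zero-dispersion variances take the infinite-prior branch", {
  fit <- structure(list(sigma2 = rep(0.25, 100), df_residual = 5,
                        genes = sprintf("g%03d", 1:100)),
                   class = "gene_fit")
  mp <- estimate_moderation(fit)
  expect_identical(mp$df_prior, Inf)
  # moment matching on the log scale: s0^2 = s^2 * exp(log(d/2) - psi(d/2))
  expect_equal(mp$var_prior, 0.25 * exp(log(2.5) - digamma(2.5)),
               tolerance = 1e-8)
  tiny <- structure(list(sigma2 = c(0.1, 0.2), df_residual = 5,
                         genes = c("a", "b")), class = "gene_fit")
  expect_error(estimate_moderation(tiny), ">= 50 genes")
  zero <- structure(list(sigma2 = rep(0, 60), df_residual = 5,
                         genes = sprintf("g%02d", 1:60)),
                    class = "gene_fit")
  expect_error(estimate_moderation(zero), "zero")
})

test_that("moderated t has the right shrinkage limits", {
  meta <- toy_meta(reps = 3)
  set.seed(40)
  cm <- c("LPS 24" = 8, "LPS 0" = 5, "saline 24" = 4, "saline 0" = 4)
  expr <- toy_expr(meta, cm, noise_sd = 0.5, n_genes = 100)
  X <- build_design(meta)
  fit <- fit_genewise(expr, X)
  w <- interaction_contrast(X, "LPS", 24)

  # d0 -> 0: ordinary t with d_g degrees of freedom
  none <- structure(list(df_prior = 0, var_prior = 1),
                    class = "moderation_params")
  res0 <- moderated_t(fit, none, w)
  u <- sqrt(drop(t(replace(setNames(numeric(4), colnames(X)),
                           names(w), w)) %*% fit$cov_unscaled %*%
                   replace(setNames(numeric(4), colnames(X)),
                           names(w), w)))
  t_ord <- drop(fit$coefficients %*% w) / (sqrt(fit$sigma2) * u)
  expect_equal(res0$t, unname(t_ord), tolerance = 1e-10)
  expect_equal(res0$p, unname(2 * pt(-abs(t_ord), fit$df_residual)),
               tolerance = 1e-10)

  # d0 = Inf: posterior variance pinned at the prior
  full <- structure(list(df_prior = Inf, var_prior = 0.3),
                    class = "moderation_params")
  resI <- moderated_t(fit, full, w)
  expect_equal(resI$t, res0$t * sqrt(fit$sigma2) / sqrt(0.3),
               tolerance = 1e-10)
})

test_that("p-values are uniform under the null", {
  meta <- toy_meta(reps = 5)
  set.seed(50)
  cm <- c("LPS 24" = 5, "LPS 0" = 5, "saline 24" = 5, "saline 0" = 5)
  expr <- toy_expr(meta, cm, noise_sd = 0.5, n_genes = 5000)
  de <- moderated_de(expr, meta)
  ks <- stats::ks.test(de$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(60)
  for (i in 1:200) {
    m <- sample(1:12, 1)
    p <- runif(m)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.1, NaN)), "NA/NaN")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("interaction contrasts are invariant to a constant shift", {
  meta <- toy_meta(reps = 3)
  set.seed(70)
  cm <- c("LPS 24" = 8, "LPS 0" = 5, "saline 24" = 4, "saline 0" = 4)
  expr <- toy_expr(meta, cm, noise_sd = 0.4, n_genes = 50)
  a <- moderated_de(expr, meta)
  b <- moderated_de(expr + 7, meta)
  expect_equal(a$log2fc, b$log2fc, tolerance = 1e-10)
  expect_equal(a$t, b$t, tolerance = 1e-8)
})

test_that("DE counting recovers planted direction and validates thresholds", {
  cfg <- sim_config(n_genes = 500, treatments = c("LPS", "saline"),
                    de_fraction = 0.2, de_direction_prob_up = 1,
                    shared_de_fraction = 1, n_modules = 0,
                    n_biomarkers = 0, seed = 80)
  st <- generate_study(cfg)
  de <- moderated_de(st$expression$muscle,
                     st$samples[st$samples$tissue == "muscle", ])
  counts <- count_de(de, 0.01)
  peak <- counts[counts$time_h == 4, ]  # early-transient kinetics peak
  expect_gte(peak$n_up, 90)
  expect_lte(peak$n_down, 2)
  expect_error(count_de(de, 1), class = "vaxsig_config_error")
  expect_error(count_de(de, 0), class = "vaxsig_config_error")
  # stricter both-controls mode only removes hits
  de2 <- moderated_de(st$expression$muscle,
                      st$samples[st$samples$tissue == "muscle", ],
                      dual_control = TRUE)
  c_int <- count_de(de2, 0.01)
  c_both <- count_de(de2, 0.01, mode = "both")
  expect_true(all(c_both$n_up <= c_int$n_up))
})
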