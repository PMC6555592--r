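# expression with two perfectly correlated blocks plus independent genes
block_expr <- function(n_block = 40, n_noise = 20, n_samples = 30,
                       noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
  m <- rbind(
    matrix(rep(f1, each = n_block), n_block) +
      rnorm(n_block * n_samples, 0, noise_sd),
    matrix(rep(f2, each = n_block), n_block) +
      rnorm(n_block * n_samples, 0, noise_sd),
    if (n_noise > 0) matrix(rnorm(n_noise * n_samples), n_noise)
  )
  dimnames(m) <- list(sprintf("g%03d", seq_len(nrow(m))),
                      sprintf("s%03d", seq_len(n_samples)))
  m
}

test_that("signed adjacency matches hand values and its invariants", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1),
             d = c(1, 3, 2, 4))
  colnames(x) <- paste0("s", 1:4)
  adj <- build_signed_adjacency(x, beta = 12)
  a <- adj$adjacency
  expect_equal(a["a", "b"], 1)              # cor = +1
  expect_equal(a["a", "c"], 0)              # cor = -1 suppressed
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(a, t(a))
  expect_equal(unname(diag(a)), rep(1, 4))
  # cor = 0 at beta = 12 gives 0.5^12
  y <- rbind(u = c(1, -1, 1, -1, 1, -1, 1, -1),
             v = c(1, 1, -1, -1, 1, 1, -1, -1))
  colnames(y) <- paste0("s", 1:8)
  expect_equal(build_signed_adjacency(y, 12)$adjacency["u", "v"],
               0.5^12, tolerance = 1e-12)
  expect_error(build_signed_adjacency(x, beta = 0),
               class = "vaxsig_config_error")
  expect_error(build_signed_adjacency(x[, 1:2]), ">= 3 samples")
})

test_that("constant genes are removed before network construction", {
  x <- block_expr(10, 5, 20)
  x[3, ] <- 7
  adj <- build_signed_adjacency(x)
  expect_false("g003" %in% adj$genes)
  expect_identical(adj$n_constant, 1L)
})

test_that("block-structured data yields exactly the planted modules", {
  m <- block_expr(40, 20, 30, seed = 2)
  adj <- build_signed_adjacency(m)
  assign <- detect_modules(adj, min_size = 20, expr = m)
  blocks <- assign$module[match(sprintf("g%03d", 1:80), assign$gene)]
  noise <- assign$module[match(sprintf("g%03d", 81:100), assign$gene)]
  expect_identical(length(unique(blocks[1:40])), 1L)
  expect_identical(length(unique(blocks[41:80])), 1L)
  expect_false(blocks[1] == blocks[41])
  expect_true(all(noise == "M0"))
})

test_that("module detection is equivariant to gene relabeling", {
  m <- block_expr(25, 10, 25, seed = 3)
  adj <- build_signed_adjacency(m)
  a1 <- detect_modules(adj, min_size = 20, expr = m)
  set.seed(4)
  perm <- sample(nrow(m))
  mp <- m[perm, ]
  a2 <- detect_modules(build_signed_adjacency(mp), min_size = 20, expr = mp)
  j <- dplyr::inner_join(a1, a2, by = "gene")
  # identical partition up to label names
  expect_identical(length(unique(paste(j$module.x, j$module.y))),
                   length(unique(j$module.x)))
})

test_that("min_size larger than any block leaves everything unassigned", {
  m <- block_expr(15, 10, 20, seed = 5)
  adj <- build_signed_adjacency(m)
  expect_warning(
    assign <- detect_modules(adj, min_size = 50, expr = m),
    "unassigned"
  )
  expect_true(all(assign$module == "M0"))
})

test_that("eigengenes are optimal, unit norm and sign-aligned", {
  m <- block_expr(30, 0, 25, noise_sd = 0.2, seed = 6)
  assign <- tibble::tibble(gene = rownames(m),
                           module = rep(c("M1", "M2"), each = 30))
  eig <- compute_eigengenes(m, assign)
  expect_equal(unname(rowSums(eig^2)), c(1, 1), tolerance = 1e-10)
  # Rayleigh-quotient optimality against a dense eigendecomposition oracle
  for (mod in c("M1", "M2")) {
    sub <- t(scale(t(m[assign$gene[assign$module == mod], ])))
    ev <- eigen(crossprod(sub), symmetric = TRUE)
    v1 <- ev$vectors[, 1]
    expect_equal(abs(sum(eig[mod, ] * v1)), 1, tolerance = 1e-8)
    q_eig <- drop(eig[mod, ] %*% crossprod(sub) %*% eig[mod, ])
    set.seed(7)
    for (i in 1:20) {
      u <- rnorm(ncol(sub)); u <- u / sqrt(sum(u^2))
      expect_gte(q_eig + 1e-8, drop(u %*% crossprod(sub) %*% u))
    }
    # sign convention: non-negative correlation with the average profile
    expect_gte(cor(eig[mod, ], colMeans(m[assign$module == mod, ])), 0)
  }
  # identical gene profiles: eigengene proportional to the shared profile
  flat <- matrix(rep(rnorm(10), each = 5), 5, 10,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  e1 <- compute_eigengenes(flat, tibble::tibble(gene = paste0("g", 1:5),
                                                module = "M1"))
  expect_equal(abs(cor(e1["M1", ], flat[1, ])), 1, tolerance = 1e-10)
  # flipping all profiles flips then re-aligns the sign
  e2 <- compute_eigengenes(-flat, tibble::tibble(gene = paste0("g", 1:5),
                                                 module = "M1"))
  expect_gte(cor(e2["M1", ], colMeans(-flat)), 0)
})

test_that("module-trait correlation behaves at its extremes", {
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:20),
    treatment = rep(c("LPS", "saline"), each = 10),
    time_h = rep(c(0, 4, 8, 24, 48), 4),
    tissue = "muscle"
  )
  ind <- as.numeric(meta$treatment == "LPS" & meta$time_h > 0)
  eig <- rbind(M1 = ind, M2 = rep(c(1, -1), 10))
  colnames(eig) <- meta$sample_id
  eig <- eig / sqrt(rowSums(eig^2))
  mtc <- module_trait_correlation(eig, meta)
  expect_equal(mtc$r[mtc$module == "M1" & mtc$treatment == "LPS"], 1,
               tolerance = 1e-10)
  expect_lt(abs(mtc$r[mtc$module == "M2" & mtc$treatment == "LPS"]), 0.35)
  expect_true(all(mtc$r >= -1 & mtc$r <= 1))
})

test_that("hypergeometric overlap equals exhaustive enumeration", {
  # worked example: N=20, K=5, n=6, k>=4 has p = 540/38760
  universe <- paste0("g", 1:20)
  assign <- tibble::tibble(gene = paste0("g", c(1:4, 19, 20)),
                           module = "M1")
  ref <- gene_set_collection(list(rs = paste0("g", 1:5)))
  res <- module_overlap_hypergeometric(assign, ref, universe)
  expect_equal(res$p, 540 / 38760, tolerance = 1e-12)
  expect_equal(res$p, hyper_oracle(20, 5, 6, 4), tolerance = 1e-12)
  # randomized configurations, N <= 12, against the enumeration oracle
  set.seed(8)
  for (i in 1:25) {
    N <- sample(5:12, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    uni <- paste0("u", 1:N)
    mod <- tibble::tibble(gene = sample(uni, n), module = "M1")
    rf <- gene_set_collection(list(rs = uni[1:K]))
    k_obs <- length(intersect(mod$gene, uni[1:K]))
    got <- module_overlap_hypergeometric(mod, rf, uni)$p
    expect_equal(got, hyper_oracle(N, K, n, k_obs), tolerance = 1e-10)
  }
  # module fully inside the reference set: minimal possible p
  sub <- tibble::tibble(gene = paste0("g", 1:5), module = "M1")
  res2 <- module_overlap_hypergeometric(sub, ref, universe)
  expect_equal(res2$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_error(module_overlap_hypergeometric(sub, ref, character(0)),
               "empty")
})

test_that("consensus graph connects shared modules across tissues", {
  a <- tibble::tibble(gene = sprintf("g%03d", 1:60),
                      module = rep(c("M1", "M2"), each = 30))
  graph <- consensus_graph(list(muscle = a, mln = a), min_shared = 10)
  expect_identical(nrow(graph$edges), 2L)
  expect_true(all(graph$edges$shared == 30))
  expect_identical(max(graph$components$component), 2)
  # disjoint modules: no edges, all singleton components
  b <- dplyr::mutate(a, gene = sprintf("h%03d", 1:60))
  g2 <- consensus_graph(list(muscle = a, mln = b), min_shared = 5)
  expect_identical(nrow(g2$edges), 0L)
  expect_identical(max(g2$components$component), 4)
  expect_error(consensus_graph(list(muscle = a)), ">= 2 tissues")
})

test_that("planted modules drive trait correlations in a full study", {
  st <- generate_study(small_config(seed = 41, n_modules = 3,
                                    module_size_range = c(30, 30)))
  m <- quantile_normalize(st$expression$muscle)
  adj <- build_signed_adjacency(m)
  assign <- detect_modules(adj, min_size = 20, expr = m)
  eig <- compute_eigengenes(m, assign)
  meta <- st$samples[st$samples$tissue == "muscle", ]
  mm <- st$truth$module_membership
  drivers <- st$truth$module_drivers
  # each planted module is substantially recovered by detection
  for (sim_mod in unique(mm$module)) {
    det <- assign$module[assign$gene %in% mm$gene[mm$module == sim_mod]]
    expect_gt(mean(det != "M0"), 0.8)
  }
  # eigengenes over the true membership correlate with the driving
  # treatment's immunisation indicator past the reporting threshold
  eig_true <- compute_eigengenes(
    m, dplyr::rename(mm, module_lbl = module) |>
      dplyr::transmute(gene, module = module_lbl))
  mtc <- module_trait_correlation(eig_true, meta)
  for (sim_mod in unique(mm$module)) {
    r <- mtc$r[mtc$module == sim_mod & mtc$treatment == drivers[[sim_mod]]]
    expect_gt(abs(r), 0.3)
  }
})
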