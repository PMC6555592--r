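#' Build a cell-means design matrix for one tissue
#'
#' One coefficient per (treatment, time) cell, including the unvaccinated
#' cells (encoded as time 0).  All treatments and time points are part of a
#' single model; separate models are fitted per tissue.
#'
#' @param meta sample metadata tibble with columns `sample_id`, `treatment`,
#'   `time_h` (0 = unvaccinated) and optionally `tissue` (must be a single
#'   tissue).
#' @return samples x coefficients indicator matrix with row names
#'   `sample_id` and coefficient names `<treatment>.t<time>` /
#'   `<treatment>.unvacc`; the metadata is attached as attribute `"meta"`.
#' @export
build_design <- function(meta) {
  need <- c("sample_id", "treatment", "time_h")
  if (!all(need %in% names(meta))) {
    stop_input(paste("metadata must have columns:",
                     paste(need, collapse = ", ")))
  }
  if ("tissue" %in% names(meta) && length(unique(meta$tissue)) > 1L) {
    stop_input("metadata covers more than one tissue; fit per tissue")
  }
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup)) {
    stop_input(paste("duplicated sample ID(s):",
                     paste(unique(dup), collapse = ", ")))
  }
  cell <- cell_label(meta$treatment, meta$time_h)
  X <- model.matrix(~ 0 + factor(cell, levels = unique(cell)))
  colnames(X) <- unique(cell)
  rownames(X) <- meta$sample_id
  zero <- colnames(X)[colSums(X) == 0]
  if (length(zero)) {
    stop_input(paste("empty design column(s):", paste(zero, collapse = ", ")))
  }
  if (qr(X)$rank < ncol(X)) stop_input("design matrix is rank deficient")
  attr(X, "meta") <- meta
  X
}

cell_label <- function(treatment, time_h) {
  paste0(gsub("[^A-Za-z0-9]", "", treatment),
         ifelse(time_h == 0, ".unvacc", paste0(".t", time_h)))
}

#' Dual-control interaction contrast
#'
#' The study's differential-expression contrast
#' `(treatment at t - treatment unvaccinated) - (saline at t - saline
#' unvaccinated)`: weights `+1, -1, -1, +1` on the four named cells.  With a
#' shared unvaccinated group the two unvaccinated terms cancel and the
#' contrast reduces to `treatment at t - saline at t`.
#'
#' @param design matrix from [build_design()].
#' @param treatment active treatment label (not the saline control).
#' @param time_h post-injection time of the tested cell.
#' @param saline label of the saline control group.
#' @return named numeric weight vector over the design's coefficients
#'   (weights sum to zero).
#' @export
interaction_contrast <- function(design, treatment, time_h,
                                 saline = "saline") {
  if (treatment == saline) {
    stop_input("contrast degenerates when treatment == saline")
  }
  cn <- colnames(design)
  unvacc_cell <- function(trt) {
    own <- cell_label(trt, 0)
    if (own %in% cn) own else cell_label("unvaccinated", 0)
  }
  cells <- c(cell_label(treatment, time_h), unvacc_cell(treatment),
             cell_label(saline, time_h), unvacc_cell(saline))
  w_raw <- c(1, -1, -1, 1)
  missing <- setdiff(unique(cells), cn)
  if (length(missing)) {
    stop_input(paste("design lacks cell(s):", paste(missing, collapse = ", ")))
  }
  w <- setNames(numeric(length(cn)), cn)
  for (i in seq_along(cells)) w[cells[i]] <- w[cells[i]] + w_raw[i]
  w
}

#' Ordinary least squares fit per gene
#'
#' Fits the cell-means model to every gene by OLS, retaining the residual
#' standard deviation `s_g`, the residual degrees of freedom and the
#' unscaled covariance of the coefficients for downstream contrast tests.
#'
#' @param expr genes x samples log2 expression matrix; column names must
#'   match the design's row names.
#' @param design matrix from [build_design()].
#' @return object of class `gene_fit`: list with `coefficients`
#'   (genes x p), `sigma2` (residual variances), `df_residual`,
#'   `cov_unscaled`, `design`, `genes`.
#' @export
fit_genewise <- function(expr, design) {
  check_matrix(unclass(expr), "expr")
  if (is.null(colnames(expr)) || is.null(rownames(design)) ||
      !identical(colnames(expr), rownames(design))) {
    stop_input("expression columns must match design rows (same order)")
  }
  n <- nrow(design); p <- ncol(design)
  df <- n - p
  if (df < 1L) stop_input("saturated design: no residual degrees of freedom")
  fit <- lm.fit(design, t(expr))
  coefs <- matrix(t(fit$coefficients), nrow(expr), p,
                  dimnames = list(rownames(expr), colnames(design)))
  res <- matrix(fit$residuals, n, nrow(expr))  # samples x genes
  sigma2 <- colSums(res^2) / df
  structure(
    list(coefficients = coefs, sigma2 = unname(sigma2),
         df_residual = df, cov_unscaled = chol2inv(chol(crossprod(design))),
         design = design, genes = rownames(expr)),
    class = "gene_fit"
  )
}

#' @export
print.gene_fit <- function(x, ...) {
  cat("<gene_fit> ", length(x$genes), " genes, ",
      ncol(x$coefficients), " coefficients, residual df ",
      x$df_residual, "\n", sep = "")
  invisible(x)
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the hierarchical variance model `s_g^2 ~ s0^2 * F(d_g, d0)` by
#' matching the first two moments of `log s_g^2` through the
#' digamma/trigamma relations.  `d0 = Inf` is returned when the observed
#' dispersion of `log s_g^2` is at or below the value implied by the
#' residual degrees of freedom alone.  Genes with `s_g = 0` are excluded
#' from estimation (count attached as attribute `"n_zero"`).
#'
#' @param fit a [fit_genewise()] object with at least 50 genes.
#' @return object of class `moderation_params`: list with `df_prior` (d0,
#'   possibly `Inf`) and `var_prior` (s0^2).
#' @export
estimate_moderation <- function(fit) {
  s2 <- fit$sigma2
  d <- fit$df_residual
  keep <- s2 > 0
  if (!any(keep)) stop_input("all residual variances are zero")
  if (sum(keep) < 50L) {
    stop_input("need >= 50 genes with positive residual variance")
  }
  z <- log(s2[keep])
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
  }
  structure(list(df_prior = d0, var_prior = s02, n_zero = sum(!keep)),
            class = "moderation_params")
}

# solve trigamma(x) = y by Newton iteration (monotone decreasing, convex)
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-10) break
  }
  x
}

#' @export
print.moderation_params <- function(x, ...) {
  cat("<moderation_params> d0 = ", format(x$df_prior),
      ", s0^2 = ", format(x$var_prior), "\n", sep = "")
  invisible(x)
}

#' Moderated t-test for one contrast
#'
#' Shrinks each gene's residual variance toward the prior,
#' `s_post^2 = (d0 s0^2 + d s_g^2) / (d0 + d)`, and refers
#' `t = estimate / (s_post * u)` to a t distribution with `d0 + d` degrees
#' of freedom (normal in the full-shrinkage limit `d0 = Inf`).  `u` is the
#' unscaled standard deviation of the contrast from the design geometry.
#'
#' @param fit a [fit_genewise()] object.
#' @param params a [estimate_moderation()] object (use
#'   `moderation_params(0)`-like prior df 0 for ordinary t-tests).
#' @param contrast named weight vector from [interaction_contrast()].
#' @return tibble: gene, log2fc, t, p, df_total, plus BH `q` and
#'   `direction` (`"up"`/`"down"`).
#' @export
moderated_t <- function(fit, params, contrast) {
  w <- setNames(numeric(ncol(fit$coefficients)), colnames(fit$coefficients))
  if (!all(names(contrast) %in% names(w))) {
    stop_input("contrast names do not match fitted coefficients")
  }
  w[names(contrast)] <- contrast
  beta <- drop(fit$coefficients %*% w)
  u2 <- drop(t(w) %*% fit$cov_unscaled %*% w)
  if (u2 <= 0) stop_input("contrast is untestable under this design (u = 0)")
  u <- sqrt(u2)
  d0 <- params$df_prior
  d <- fit$df_residual
  s2_post <- if (is.infinite(d0)) {
    rep(params$var_prior, length(beta))
  } else if (d0 == 0) {
    fit$sigma2
  } else {
    (d0 * params$var_prior + d * fit$sigma2) / (d0 + d)
  }
  tstat <- beta / (sqrt(s2_post) * u)
  df_total <- d0 + d
  p <- 2 * pt(-abs(tstat), df = df_total)
  tibble(
    gene = fit$genes, log2fc = unname(beta), t = unname(tstat),
    p = unname(p), df_total = df_total, q = bh_adjust(unname(p)),
    direction = ifelse(beta >= 0, "up", "down")
  )
}

#' Moderated differential expression over all treatment-time cells
#'
#' For one tissue: fits the single cell-means model, estimates the variance
#' prior once, then evaluates the dual-control interaction contrast for
#' every (active treatment, post-injection time) cell.  BH adjustment is
#' applied within each contrast.
#'
#' @param expr genes x samples log2 matrix for one tissue.
#' @param meta matching sample metadata (see [build_design()]).
#' @param saline saline control label.
#' @param dual_control additionally compute the direct
#'   treatment-vs-unvaccinated contrast and report its `p_direct` /
#'   `q_direct` columns (the stricter both-controls DE mode).
#' @return tibble: gene, treatment, time_h, log2fc, t, p, q, direction
#'   (plus `p_direct`, `q_direct` if requested).
#' @export
moderated_de <- function(expr, meta, saline = "saline",
                         dual_control = FALSE) {
  meta <- meta[match(colnames(expr), meta$sample_id), ]
  if (anyNA(meta$sample_id)) {
    stop_input("metadata is missing samples present in the matrix")
  }
  design <- build_design(meta)
  fit <- fit_genewise(expr, design)
  params <- estimate_moderation(fit)
  active <- setdiff(unique(meta$treatment), c(saline, "unvaccinated"))
  times <- sort(unique(meta$time_h[meta$time_h > 0]))
  out <- list()
  for (trt in active) {
    for (t_h in times) {
      ct <- interaction_contrast(design, trt, t_h, saline = saline)
      res <- moderated_t(fit, params, ct)
      res$treatment <- trt
      res$time_h <- t_h
      if (dual_control) {
        cells <- c(cell_label(trt, t_h),
                   if (cell_label(trt, 0) %in% colnames(design)) {
                     cell_label(trt, 0)
                   } else cell_label("unvaccinated", 0))
        cd <- setNames(c(1, -1), cells)
        rd <- moderated_t(fit, params, cd)
        res$p_direct <- rd$p
        res$q_direct <- rd$q
      }
      out[[length(out) + 1L]] <- res
    }
  }
  res <- list_rbind(out)
  attr(res, "moderation") <- params
  select(res, "gene", "treatment", "time_h", dplyr::everything(),
         -"df_total")
}

#' Run differential expression for every tissue of a study
#'
#' @param expression named list of genes x samples matrices (one per tissue).
#' @param samples sample metadata covering all tissues.
#' @param ... passed to [moderated_de()].
#' @return tibble with a `tissue` column prepended.
#' @export
run_de <- function(expression, samples, ...) {
  out <- imap(expression, function(mat, tis) {
    res <- moderated_de(mat, samples[samples$tissue == tis, ], ...)
    mutate(res, tissue = tis)
  })
  select(list_rbind(out), "tissue", dplyr::everything())
}

#' Count differentially expressed genes per condition
#'
#' A gene counts as DE for a (tissue, treatment, time) cell iff its
#' BH-adjusted q-value from the dual-control interaction contrast is below
#' the threshold (and, in `mode = "both"`, also below it in the direct
#' vs-unvaccinated contrast); direction follows the sign of the log2 fold
#' change.
#'
#' @param results tibble from [run_de()] / [moderated_de()].
#' @param q_threshold BH q cutoff, strictly inside (0, 1); default 0.01.
#' @param mode `"interaction"` (default) or `"both"` (requires the
#'   `q_direct` column from `dual_control = TRUE`).
#' @return tibble: (tissue,) treatment, time_h, n_up, n_down.
#' @export
count_de <- function(results, q_threshold = 0.01,
                     mode = c("interaction", "both")) {
  mode <- match.arg(mode)
  check_number(q_threshold, "q_threshold", 0, 1, strict_lower = TRUE,
               strict_upper = TRUE)
  hit <- results$q < q_threshold
  if (mode == "both") {
    if (!"q_direct" %in% names(results)) {
      stop_input("mode = \"both\" needs `q_direct` (run with dual_control)")
    }
    hit <- hit & results$q_direct < q_threshold
  }
  keys <- intersect(c("tissue", "treatment", "time_h"), names(results))
  results |>
    mutate(.hit = hit) |>
    group_by(dplyr::across(dplyr::all_of(keys))) |>
    summarise(
      n_up = sum(.data$.hit & .data$direction == "up"),
      n_down = sum(.data$.hit & .data$direction == "down"),
      .groups = "drop"
    )
}
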