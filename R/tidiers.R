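#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a genewise OLS fit
#'
#' @param x a [fit_genewise()] object.
#' @param ... unused.
#' @return long tibble: gene, term (cell coefficient), estimate, plus the
#'   gene's residual sd and df.
#' @export
tidy.gene_fit <- function(x, ...) {
  co <- x$coefficients
  tibble(
    gene = rep(rownames(co), ncol(co)),
    term = rep(colnames(co), each = nrow(co)),
    estimate = as.vector(co)
  ) |>
    left_join(tibble(gene = x$genes, sigma = sqrt(x$sigma2),
                     df_residual = x$df_residual), by = "gene")
}

#' @rdname tidy.gene_fit
#' @export
glance.gene_fit <- function(x, ...) {
  tibble(n_genes = length(x$genes), n_coefficients = ncol(x$coefficients),
         df_residual = x$df_residual, median_sigma = median(sqrt(x$sigma2)))
}

#' One-row summary of the empirical-Bayes variance prior
#'
#' @param x a [estimate_moderation()] object.
#' @param ... unused.
#' @export
glance.moderation_params <- function(x, ...) {
  tibble(df_prior = x$df_prior, var_prior = x$var_prior,
         n_zero_variance = x$n_zero %||% 0L)
}

#' Tidy Dunnett comparisons of a protein ANOVA
#'
#' @param x an [anova_dunnett()] object.
#' @param ... unused.
#' @export
tidy.anova_dunnett <- function(x, ...) {
  mutate(x$comparisons, analyte = x$analyte)
}

#' @rdname tidy.anova_dunnett
#' @export
glance.anova_dunnett <- function(x, ...) {
  a <- x$anova
  tibble(
    analyte = x$analyte, scale = x$scale,
    p_treatment = a$p.value[a$term == "treatment"],
    p_time = a$p.value[a$term == "time"],
    p_interaction = a$p.value[a$term == "treatment:time"],
    df_residual = a$df[a$term == "residual"]
  )
}
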