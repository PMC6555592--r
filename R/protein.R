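#' Serum-analyte fold changes versus the saline control
#'
#' Per (analyte, treatment, time): ratio of the treatment-group mean
#' concentration to the saline-group mean at the same time.  A saline mean
#' of zero is replaced by a detection floor (half the smallest non-zero
#' concentration of that analyte); the number of floored cells is attached
#' as attribute `"n_floored"`.
#'
#' @param panel long tibble: analyte, treatment, time_h, replicate,
#'   concentration, unit.
#' @param saline saline control label; must be present at each requested
#'   time.
#' @return tibble: analyte, treatment, time_h, fc, log2fc, unit.
#' @export
protein_fold_change <- function(panel, saline = "saline") {
  check_panel(panel)
  if (!saline %in% panel$treatment) {
    stop_input("saline control group missing from the panel")
  }
  means <- panel |>
    group_by(.data$analyte, .data$treatment, .data$time_h, .data$unit) |>
    summarise(mean_conc = mean(.data$concentration), .groups = "drop")
  sal <- means |>
    filter(.data$treatment == saline) |>
    select("analyte", "time_h", saline_mean = "mean_conc")
  floors <- panel |>
    group_by(.data$analyte) |>
    summarise(floor = {
      nz <- .data$concentration[.data$concentration > 0]
      if (length(nz)) min(nz) / 2 else NA_real_
    }, .groups = "drop")
  out <- means |>
    filter(.data$treatment != saline) |>
    left_join(sal, by = c("analyte", "time_h")) |>
    left_join(floors, by = "analyte")
  if (anyNA(out$saline_mean)) {
    miss <- unique(out$time_h[is.na(out$saline_mean)])
    stop_input(paste("no saline measurements at time(s):",
                     paste(miss, collapse = ", ")))
  }
  n_floored <- sum(out$saline_mean == 0)
  out <- out |>
    mutate(denom = ifelse(.data$saline_mean > 0, .data$saline_mean,
                          .data$floor),
           fc = .data$mean_conc / .data$denom,
           log2fc = log2(.data$fc)) |>
    select("analyte", "treatment", "time_h", "fc", "log2fc", "unit")
  attr(out, "n_floored") <- n_floored
  out
}

check_panel <- function(panel) {
  need <- c("analyte", "treatment", "time_h", "replicate", "concentration")
  if (!all(need %in% names(panel))) {
    stop_input(paste("protein panel needs columns:",
                     paste(need, collapse = ", ")))
  }
  if (any(panel$concentration < 0)) stop_input("negative concentrations")
  if (!"unit" %in% names(panel)) panel$unit <- ""
  invisible(panel)
}

#' Two-way ANOVA with Dunnett many-to-one comparisons for one analyte
#'
#' Fits a fixed-effects two-way ANOVA (treatment, time, interaction) to one
#' analyte's concentrations on the configured scale, then compares every
#' active treatment to saline within each time point using the model's
#' residual error term.  Adjusted p-values come from the multivariate-t
#' distribution of the maximum absolute statistic over the comparisons of
#' each time point (the Dunnett test); with a single comparison this reduces
#' exactly to the two-sample t-test on the pooled error.
#'
#' @param panel long protein tibble (see [protein_fold_change()]).
#' @param analyte analyte to analyse.
#' @param scale `"log2"` (default; concentrations analysed as
#'   `log2(concentration + floor)` with floor = half the smallest non-zero
#'   value, a multiplicative-noise model) or `"raw"`.
#' @param saline control label.
#' @return object of class `anova_dunnett`: list with `anova` (tibble:
#'   term, df, sumsq, meansq, statistic, p.value), `comparisons` (tibble:
#'   treatment, time_h, estimate, se, statistic, df, p.adj, tier with tiers
#'   ns / ** / *** / ****), `analyte`, `scale`.
#' @export
anova_dunnett <- function(panel, analyte, scale = c("log2", "raw"),
                          saline = "saline") {
  scale <- match.arg(scale)
  check_panel(panel)
  d <- panel[panel$analyte == analyte, ]
  if (nrow(d) == 0L) stop_input(paste("analyte not in panel:", analyte))
  if (length(unique(d$treatment)) < 2L || !saline %in% d$treatment) {
    stop_input("need >= 2 treatments including the saline control")
  }
  if (length(unique(d$time_h)) < 2L) stop_input("need >= 2 time points")
  cells <- d |>
    count(.data$treatment, .data$time_h) |>
    filter(.data$n < 2L)
  if (nrow(cells)) {
    stop_input(paste0("cells with < 2 replicates: ",
                      paste(cell_label(cells$treatment, cells$time_h),
                            collapse = ", ")))
  }
  y <- if (scale == "log2") {
    nz <- d$concentration[d$concentration > 0]
    fl <- if (length(nz)) min(nz) / 2 else 1
    log2(d$concentration + fl)
  } else {
    d$concentration
  }
  dat <- data.frame(y = y, treatment = factor(d$treatment),
                    time = factor(d$time_h))
  fit <- lm(y ~ treatment * time, data = dat)
  an <- anova(fit)
  anova_tbl <- tibble(
    term = c("treatment", "time", "treatment:time", "residual"),
    df = an$Df, sumsq = an$`Sum Sq`, meansq = an$`Mean Sq`,
    statistic = an$`F value`, p.value = an$`Pr(>F)`
  )
  mse <- an$`Mean Sq`[4]
  df_err <- an$Df[4]

  comps <- list()
  for (t_h in sort(unique(d$time_h))) {
    sub <- dat[dat$time == as.character(t_h), ]
    trts <- setdiff(unique(as.character(sub$treatment)), saline)
    n0 <- sum(sub$treatment == saline)
    m0 <- mean(sub$y[sub$treatment == saline])
    est <- se <- tt <- numeric(length(trts))
    nn <- integer(length(trts))
    for (i in seq_along(trts)) {
      yi <- sub$y[sub$treatment == trts[i]]
      nn[i] <- length(yi)
      est[i] <- mean(yi) - m0
      se[i] <- sqrt(mse * (1 / nn[i] + 1 / n0))
      tt[i] <- est[i] / se[i]
    }
    p_adj <- dunnett_p(tt, nn, n0, df_err)
    comps[[length(comps) + 1L]] <- tibble(
      treatment = trts, time_h = t_h, estimate = est, se = se,
      statistic = tt, df = df_err, p.adj = p_adj,
      tier = significance_tier(p_adj)
    )
  }
  structure(
    list(anova = anova_tbl, comparisons = list_rbind(comps),
         analyte = analyte, scale = scale),
    class = "anova_dunnett"
  )
}

# Dunnett adjusted p-values: P(max_j |T_j| >= |t_i|) under the joint
# multivariate-t of the k many-to-one comparisons (correlation
# lambda_i lambda_j with lambda_i = sqrt(n_i / (n_i + n0)))
dunnett_p <- function(tstat, n_trt, n0, df) {
  k <- length(tstat)
  if (k == 1L) return(2 * pt(-abs(tstat), df))
  lam <- sqrt(n_trt / (n_trt + n0))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  vapply(abs(tstat), function(tc) {
    pr <- with_local_seed(1L, mvtnorm::pmvt(
      lower = rep(-tc, k), upper = rep(tc, k), df = df, corr = corr,
      algorithm = mvtnorm::GenzBretz(abseps = 1e-5, maxpts = 100000)
    ))
    min(max(1 - as.numeric(pr), 0), 1)
  }, 0)
}

significance_tier <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**", "ns")))
}

#' @export
print.anova_dunnett <- function(x, ...) {
  cat("<anova_dunnett> analyte ", x$analyte, " (", x$scale, " scale), ",
      nrow(x$comparisons), " comparisons\n", sep = "")
  invisible(x)
}

#' Trapezoidal area under a time-concentration curve
#'
#' `sum(0.5 * (c_i + c_{i+1}) * (t_{i+1} - t_i))` over adjacent pairs;
#' exact for piecewise-linear series sampled at their knots, and additive
#' over adjacent time intervals.
#'
#' @param time_h strictly increasing times (hours).
#' @param concentration matching concentrations.
#' @return the AUC in concentration x hours.
#' @examples
#' auc_trapezoid(c(0, 4, 8), c(0, 10, 10))  # 60
#' @export
auc_trapezoid <- function(time_h, concentration) {
  if (length(time_h) < 2L) stop_input("need >= 2 points")
  if (length(time_h) != length(concentration)) {
    stop_input("time and concentration lengths differ")
  }
  if (any(diff(time_h) <= 0)) stop_input("times must be strictly increasing")
  sum(0.5 * (head(concentration, -1) + tail(concentration, -1)) *
        diff(time_h))
}

#' Per-treatment time-course AUC of each analyte
#'
#' Trapezoidal AUC of the mean concentration profile over the panel's time
#' grid.
#'
#' @param panel long protein tibble.
#' @return tibble: analyte, treatment, auc, unit (concentration x hr).
#' @export
protein_auc <- function(panel) {
  check_panel(panel)
  panel |>
    group_by(.data$analyte, .data$treatment, .data$time_h, .data$unit) |>
    summarise(mean_conc = mean(.data$concentration), .groups = "drop") |>
    arrange(.data$time_h) |>
    group_by(.data$analyte, .data$treatment, .data$unit) |>
    summarise(auc = auc_trapezoid(.data$time_h, .data$mean_conc),
              .groups = "drop") |>
    mutate(unit = paste0(.data$unit, ".hr")) |>
    select("analyte", "treatment", "auc", "unit")
}

#' Volcano table of protein responses
#'
#' Joins fold changes with Dunnett-adjusted p-values; rows with adjusted
#' p < 0.01 get the label flag (strict inequality).
#'
#' @param fc tibble from [protein_fold_change()].
#' @param stats a single [anova_dunnett()] result or a list of them.
#' @param label_p label threshold (default 0.01).
#' @return tibble: analyte, treatment, time_h, log2fc, p.adj, labelled.
#' @export
volcano_table <- function(fc, stats, label_p = 0.01) {
  if (inherits(stats, "anova_dunnett")) stats <- list(stats)
  comp <- list_rbind(map(stats, function(s) {
    mutate(s$comparisons, analyte = s$analyte)
  }))
  j <- dplyr::inner_join(
    select(fc, "analyte", "treatment", "time_h", "log2fc"),
    select(comp, "analyte", "treatment", "time_h", "p.adj"),
    by = c("analyte", "treatment", "time_h")
  )
  if (nrow(j) == 0L) stop_input("fold changes and statistics do not join")
  mutate(j, labelled = .data$p.adj < label_p)
}

#' Transcript-protein fold-change correlations
#'
#' Pearson correlation, per (analyte, tissue, treatment), between the serum
#' log2 fold-change profile and the coupled transcript's log2 fold-change
#' profile over the shared post-injection time grid, with significance
#' stars (* p<0.05, ** p<0.01, *** p<0.001).  Correlations are computed on
#' log2 fold changes so up- and down-regulation are treated symmetrically.
#'
#' @param protein_fc tibble from [protein_fold_change()].
#' @param de_results multi-tissue DE tibble from [run_de()].
#' @param analyte_genes tibble mapping `analyte` to its transcript `gene`.
#' @param min_points minimum shared time points (default 3; pairs with
#'   fewer are skipped with a reason).
#' @return tibble: analyte, gene, tissue, treatment, n_times, r, p, stars.
#' @export
transcript_protein_correlation <- function(protein_fc, de_results,
                                           analyte_genes, min_points = 3L) {
  if (!all(c("analyte", "gene") %in% names(analyte_genes))) {
    stop_input("`analyte_genes` needs columns `analyte`, `gene`")
  }
  pf <- protein_fc |>
    filter(.data$time_h > 0) |>
    dplyr::inner_join(analyte_genes, by = "analyte")
  j <- dplyr::inner_join(
    select(pf, "analyte", "gene", "treatment", "time_h",
           protein_lfc = "log2fc"),
    select(de_results, "gene", "tissue", "treatment", "time_h",
           transcript_lfc = "log2fc"),
    by = c("gene", "treatment", "time_h")
  )
  j |>
    group_by(.data$analyte, .data$gene, .data$tissue, .data$treatment) |>
    summarise(
      n_times = dplyr::n(),
      r = if (dplyr::n() >= min_points && sd(.data$protein_lfc) > 0 &&
              sd(.data$transcript_lfc) > 0)
        cor(.data$protein_lfc, .data$transcript_lfc) else NA_real_,
      p = if (dplyr::n() >= min_points && sd(.data$protein_lfc) > 0 &&
              sd(.data$transcript_lfc) > 0)
        cor.test(.data$protein_lfc, .data$transcript_lfc)$p.value
      else NA_real_,
      .groups = "drop"
    ) |>
    mutate(stars = ifelse(is.na(.data$p), "",
                   ifelse(.data$p < 0.001, "***",
                   ifelse(.data$p < 0.01, "**",
                   ifelse(.data$p < 0.05, "*", "")))))
}
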