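#' Concordance/discordance (disco) score between two tissues
#'
#' For each gene and condition shared by two tissues' differential-expression
#' slices, `score = log2fc_A * log2fc_B * w(q_A) * w(q_B)` with significance
#' weight `w(q) = min(-log10(q), w_max)` floored at 0.  Positive scores mean
#' concordant regulation, negative discordant; either q-value at 1 zeroes
#' the score.
#'
#' @param de_a,de_b DE tibbles for the two tissues (columns `gene`,
#'   `treatment`, `time_h`, `log2fc`, `q`).
#' @param w_max cap on the significance weight (applied when q underflows
#'   to 0); default 12.
#' @return tibble: gene, treatment, time_h, log2fc_a, log2fc_b, q_a, q_b,
#'   disco.
#' @export
disco_score <- function(de_a, de_b, w_max = 12) {
  check_number(w_max, "w_max", 0, strict_lower = TRUE)
  j <- dplyr::inner_join(
    select(de_a, "gene", "treatment", "time_h",
           log2fc_a = "log2fc", q_a = "q"),
    select(de_b, "gene", "treatment", "time_h",
           log2fc_b = "log2fc", q_b = "q"),
    by = c("gene", "treatment", "time_h")
  )
  w <- function(q) pmin(pmax(-log10(pmax(q, 10^(-w_max))), 0), w_max)
  mutate(j, disco = .data$log2fc_a * .data$log2fc_b *
           w(.data$q_a) * w(.data$q_b))
}

#' Select the top genes differentially regulated in two tissues
#'
#' Genes DE (q below threshold at any time point, any treatment) in both
#' tissues, ranked by the sum over the two tissues of each gene's minimum
#' q-value (ascending), ties broken by descending maximum absolute log2 fold
#' change then gene ID, truncated to `k`.  Deterministic and invariant to
#' input row order.
#'
#' @param de_muscle,de_mln DE tibbles for the two tissues.
#' @param k number of genes to keep (default 100).
#' @param q_threshold DE definition threshold (default 0.01).
#' @return tibble: gene, min_q_a, min_q_b, max_abs_lfc, rank.  Fewer than
#'   `k` qualifying genes returns them all.
#' @export
select_common_top <- function(de_muscle, de_mln, k = 100,
                              q_threshold = 0.01) {
  check_count(k, "k", min = 1L)
  summarise_de <- function(de, suffix) {
    de |>
      group_by(.data$gene) |>
      summarise(min_q = min(.data$q),
                max_abs_lfc = max(abs(.data$log2fc)), .groups = "drop") |>
      filter(.data$min_q < q_threshold) |>
      rename_with(function(x) paste0(x, suffix), -"gene")
  }
  j <- dplyr::inner_join(summarise_de(de_muscle, "_a"),
                         summarise_de(de_mln, "_b"), by = "gene")
  if (nrow(j) == 0L) {
    return(tibble(gene = character(), min_q_a = numeric(),
                  min_q_b = numeric(), max_abs_lfc = numeric(),
                  rank = integer()))
  }
  j <- j |>
    mutate(key_q = .data$min_q_a + .data$min_q_b,
           max_abs_lfc = pmax(.data$max_abs_lfc_a, .data$max_abs_lfc_b)) |>
    arrange(.data$key_q, desc(.data$max_abs_lfc), .data$gene) |>
    mutate(rank = row_number()) |>
    select("gene", "min_q_a", "min_q_b", "max_abs_lfc", "rank")
  slice_head(j, n = min(k, nrow(j)))
}

#' @importFrom dplyr rename_with
NULL

#' Flag which candidate genes are also DE in blood
#'
#' @param genes character vector (or tibble with a `gene` column).
#' @param de_blood blood DE tibble.
#' @param q_threshold DE definition threshold.
#' @return tibble: gene, blood_de.
#' @export
check_blood <- function(genes, de_blood, q_threshold = 0.01) {
  if (is.data.frame(genes)) genes <- genes$gene
  hits <- unique(de_blood$gene[de_blood$q < q_threshold])
  tibble(gene = genes, blood_de = genes %in% hits)
}

#' Per-gene cross-tissue fold-change correlations
#'
#' Pearson correlation between two tissues' log2 fold-change time profiles
#' for each gene-treatment combination, over the shared time grid (>= 3
#' points required).  Constant profiles yield a missing correlation with a
#' reason.
#'
#' @param de_results multi-tissue DE tibble from [run_de()].
#' @param genes optional gene subset.
#' @return tibble: gene, treatment, tissue_a, tissue_b, n_times, r, sign,
#'   reason.
#' @export
cross_tissue_correlation <- function(de_results, genes = NULL) {
  if (!is.null(genes)) {
    de_results <- filter(de_results, .data$gene %in% genes)
  }
  tissues <- sort(unique(de_results$tissue))
  if (length(tissues) < 2L) stop_input("need >= 2 tissues")
  prof <- de_results |>
    select("tissue", "gene", "treatment", "time_h", "log2fc")
  out <- list()
  for (i in seq_len(length(tissues) - 1L)) {
    for (j in seq(i + 1L, length(tissues))) {
      a <- filter(prof, .data$tissue == tissues[i])
      b <- filter(prof, .data$tissue == tissues[j])
      jj <- dplyr::inner_join(
        select(a, -"tissue"), select(b, -"tissue"),
        by = c("gene", "treatment", "time_h"), suffix = c("_a", "_b")
      )
      rows <- jj |>
        group_by(.data$gene, .data$treatment) |>
        summarise(
          n_times = dplyr::n(),
          r = if (dplyr::n() < 3 || sd(.data$log2fc_a) == 0 ||
                  sd(.data$log2fc_b) == 0) NA_real_ else
            cor(.data$log2fc_a, .data$log2fc_b),
          reason = if (dplyr::n() < 3) "fewer than 3 shared time points"
                   else if (sd(.data$log2fc_a) == 0 ||
                            sd(.data$log2fc_b) == 0) "constant profile"
                   else NA_character_,
          .groups = "drop"
        ) |>
        mutate(tissue_a = tissues[i], tissue_b = tissues[j],
               sign = ifelse(is.na(.data$r), NA_character_,
                             ifelse(.data$r >= 0, "positive", "negative")))
      out[[length(out) + 1L]] <- rows
    }
  }
  select(list_rbind(out), "gene", "treatment", "tissue_a", "tissue_b",
         "n_times", "r", "sign", "reason")
}

#' Assemble the soluble biomarker panel
#'
#' Filters candidate genes to those annotated soluble (genes missing from
#' the annotation count as not soluble; count attached as attribute
#' `"n_unannotated"`), carrying forward the selection provenance.
#'
#' @param candidates tibble from [select_common_top()], optionally joined
#'   with [check_blood()] output.
#' @param soluble_annotation tibble with columns `gene` and `soluble`
#'   (logical).
#' @return the filtered, ranked candidate tibble with a `soluble` column.
#' @export
assemble_panel <- function(candidates, soluble_annotation) {
  if (!all(c("gene", "soluble") %in% names(soluble_annotation))) {
    stop_input("annotation needs columns `gene` and `soluble`")
  }
  j <- left_join(candidates, distinct(soluble_annotation, .data$gene,
                                      .keep_all = TRUE), by = "gene")
  n_unann <- sum(is.na(j$soluble))
  j$soluble[is.na(j$soluble)] <- FALSE
  out <- filter(j, .data$soluble)
  if (nrow(out) == 0L) warn("no soluble candidates: empty panel")
  attr(out, "n_unannotated") <- n_unann
  out
}

#' End-to-end biomarker selection
#'
#' The study's selection rule: take the top `k` genes differentially
#' regulated in both muscle and the draining lymph node, flag which are also
#' DE in blood, attach per-gene cross-tissue fold-change correlations and
#' disco summaries, and keep the soluble ones.
#'
#' @param de_results multi-tissue DE tibble from [run_de()] (tissues
#'   `muscle`, `mln`, `blood`).
#' @param soluble_annotation tibble with `gene`, `soluble`.
#' @param k top-gene count (default 100).
#' @param q_threshold DE definition threshold (default 0.01).
#' @return tibble: one row per panel gene with provenance columns.
#' @export
biomarker_panel <- function(de_results, soluble_annotation, k = 100,
                            q_threshold = 0.01) {
  de_by <- split(de_results, de_results$tissue)
  need <- c("muscle", "mln", "blood")
  if (!all(need %in% names(de_by))) {
    stop_input(paste("DE results must cover tissues:",
                     paste(need, collapse = ", ")))
  }
  top <- select_common_top(de_by$muscle, de_by$mln, k = k,
                           q_threshold = q_threshold)
  top <- left_join(top, check_blood(top$gene, de_by$blood, q_threshold),
                   by = "gene")
  if (nrow(top)) {
    disco <- disco_score(de_by$muscle, de_by$mln) |>
      filter(.data$gene %in% top$gene) |>
      group_by(.data$gene) |>
      summarise(disco_max = max(.data$disco),
                disco_min = min(.data$disco), .groups = "drop")
    top <- left_join(top, disco, by = "gene")
    xc <- cross_tissue_correlation(de_results, genes = top$gene) |>
      group_by(.data$gene) |>
      summarise(mean_cross_r = mean(.data$r, na.rm = TRUE),
                .groups = "drop")
    top <- left_join(top, xc, by = "gene")
  }
  assemble_panel(top, soluble_annotation)
}
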