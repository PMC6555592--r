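#' Gene-set collection (BTM-style)
#'
#' Named gene sets with an optional high-level annotation group per set
#' (carried in the GMT description field).
#'
#' @param sets named list of character vectors (no duplicate genes within a
#'   set; sizes >= 1).
#' @param annotation named character vector of high-level group labels;
#'   missing names default to `""`.
#' @return object of class `gene_set_collection`.
#' @seealso [read_gmt()], [write_gmt()]
#' @export
gene_set_collection <- function(sets, annotation = NULL) {
  if (is.null(names(sets)) && length(sets)) {
    stop_input("gene sets must be named")
  }
  sets <- lapply(sets, function(g) {
    g <- as.character(g)
    if (length(g) < 1L) stop_input("gene sets must have size >= 1")
    if (anyDuplicated(g)) stop_input("duplicate genes within a set")
    g
  })
  ann <- setNames(rep("", length(sets)), names(sets))
  if (!is.null(annotation)) {
    ann[names(annotation)[names(annotation) %in% names(ann)]] <-
      annotation[names(annotation) %in% names(ann)]
  }
  structure(list(sets = sets, annotation = ann),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", length(x$sets), " set(s)", sep = "")
  if (length(x$sets)) {
    cat("; sizes ", min(lengths(x$sets)), "-", max(lengths(x$sets)), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Rank genes for enrichment testing
#'
#' Orders one differential-expression slice by ascending raw p-value, ties
#' broken by descending absolute log2 fold change, then lexicographic gene
#' ID, so the ranking is a deterministic permutation of the universe.
#'
#' @param de_slice tibble with columns `gene`, `p`, `log2fc` for a single
#'   (tissue, treatment, time) condition.
#' @return character vector of gene IDs, most significant first.
#' @export
rank_genes <- function(de_slice) {
  if (nrow(de_slice) == 0L) stop_input("empty differential-expression slice")
  o <- order(de_slice$p, -abs(de_slice$log2fc), de_slice$gene)
  de_slice$gene[o]
}

#' CERNO rank-based gene-set test
#'
#' Combines the ranks of a set's genes in an ordered list via
#' `f = -2 * sum(log(r_i / N))`, referred to a chi-squared distribution with
#' `2k` degrees of freedom, together with the rank-sum (Mann-Whitney) AUC
#' effect size of set genes versus non-set genes.
#'
#' @param ranked character vector from [rank_genes()] (the universe, most
#'   significant first).
#' @param set character vector of gene IDs.
#' @return one-row tibble: k (set size in universe), f, df, p, auc.  When
#'   the set is disjoint from the universe the row is flagged untestable
#'   (`k = 0`, statistics `NA`).  `auc` is `NA` when the set covers the
#'   whole universe.
#' @examples
#' ranked <- paste0("g", 1:100)
#' cerno_test(ranked, c("g1", "g2"))
#' @export
cerno_test <- function(ranked, set) {
  N <- length(ranked)
  r <- which(ranked %in% set)
  k <- length(r)
  if (k == 0L) {
    return(tibble(k = 0L, f = NA_real_, df = NA_real_, p = NA_real_,
                  auc = NA_real_))
  }
  f <- -2 * sum(log(r / N))
  p <- pchisq(f, df = 2 * k, lower.tail = FALSE)
  tibble(k = k, f = f, df = 2 * k, p = p, auc = auc_effect_ranks(r, N))
}

#' Rank-sum AUC effect size of a gene set
#'
#' The probability that a random set gene outranks a random non-set gene in
#' the ordered list: `AUC = 1 - (sum(r_i) - k(k+1)/2) / (k(N-k))`.
#'
#' @inheritParams cerno_test
#' @return a number in `[0, 1]`; `NA` when the set covers the universe
#'   (`k = N`, undefined).
#' @export
auc_effect <- function(ranked, set) {
  r <- which(ranked %in% set)
  if (length(r) == 0L) stop_input("set is disjoint from the universe")
  auc_effect_ranks(r, length(ranked))
}

auc_effect_ranks <- function(r, N) {
  k <- length(r)
  if (k == N) return(NA_real_)
  1 - (sum(r) - k * (k + 1) / 2) / (k * (N - k))
}

#' Run CERNO enrichment over a collection for every DE condition
#'
#' Ranks each (tissue, treatment, time) slice of the differential-expression
#' results and tests every set of the collection; BH adjustment is applied
#' across sets within each slice.
#'
#' @param de_results tibble from [run_de()].
#' @param collection a [gene_set_collection()].
#' @param ortholog_map optional two-column mapping applied to the
#'   collection's genes first (see [map_orthologs()]).
#' @return tibble: tissue, treatment, time_h, set, annotation, k, f, df, p,
#'   q, auc.
#' @export
run_enrichment <- function(de_results, collection, ortholog_map = NULL) {
  sets <- collection$sets
  if (!is.null(ortholog_map)) {
    sets <- lapply(sets, map_orthologs, map_table = ortholog_map)
    sets <- sets[lengths(sets) > 0]
  }
  keys <- intersect(c("tissue", "treatment", "time_h"), names(de_results))
  slices <- split(de_results,
                  lapply(keys, function(k) de_results[[k]]), drop = TRUE)
  out <- map(slices, function(sl) {
    ranked <- rank_genes(sl)
    rows <- map(sets, cerno_test, ranked = ranked) |> list_rbind()
    rows$set <- names(sets)
    rows$annotation <- unname(collection$annotation[names(sets)])
    for (k in keys) rows[[k]] <- sl[[k]][1]
    ok <- !is.na(rows$p)
    rows$q <- NA_real_
    rows$q[ok] <- bh_adjust(rows$p[ok])
    rows
  })
  select(list_rbind(out), dplyr::all_of(keys), "set", "annotation",
         "k", "f", "df", "p", "q", "auc")
}

#' Filter enrichment results at the reporting thresholds
#'
#' Retains rows with `p < p_max` and `auc > auc_min` (strict inequalities);
#' defaults are the reporting thresholds used throughout the package,
#' p < 1e-6 and AUC > 0.8.
#'
#' @param results tibble from [run_enrichment()].
#' @param p_max,auc_min thresholds.
#' @export
filter_enriched <- function(results, p_max = 1e-6, auc_min = 0.8) {
  filter(results, !is.na(.data$p), !is.na(.data$auc),
         .data$p < p_max, .data$auc > auc_min)
}

#' Apply a one-to-one ortholog map to a gene list
#'
#' Only unambiguous (one-to-one) rows of the mapping are applied; source
#' genes with one-to-many fan-out, targets with many-to-one fan-in, and
#' unmapped genes are dropped.  Drop counts are attached as attribute
#' `"dropped"`.
#'
#' @param genes character vector of source-namespace gene IDs.
#' @param map_table data frame whose first two columns are source and
#'   target IDs.
#' @return character vector of mapped target IDs.
#' @export
map_orthologs <- function(genes, map_table) {
  if (!is.data.frame(map_table) || ncol(map_table) < 2L) {
    stop_input("ortholog map must be a data frame with >= 2 columns")
  }
  src <- as.character(map_table[[1]])
  tgt <- as.character(map_table[[2]])
  bad <- which(is.na(src) | is.na(tgt) | src == "" | tgt == "")
  if (length(bad)) {
    stop_input(sprintf("malformed ortholog map at line %d", bad[1]))
  }
  one_to_many <- unique(src[duplicated(src)])
  many_to_one <- unique(tgt[duplicated(tgt)])
  keep <- !(src %in% one_to_many) & !(tgt %in% many_to_one)
  lut <- setNames(tgt[keep], src[keep])
  mapped <- lut[genes]
  out <- unname(mapped[!is.na(mapped)])
  attr(out, "dropped") <- c(
    unmapped = sum(is.na(mapped)) -
      sum(genes %in% one_to_many),
    ambiguous = sum(genes %in% one_to_many)
  )
  out
}
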