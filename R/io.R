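#' Read and write the pipeline's interchange formats
#'
#' Plain-text formats throughout: expression matrices as TSV (first column
#' `gene`, remaining columns sample IDs), sample metadata as TSV, gene sets
#' as GMT (name, annotation group in the description field, tab-separated
#' gene IDs), protein panels as CSV.  All readers validate the schema and
#' report the offending file/line/column; write-then-read round-trips are
#' lossless.
#'
#' @name vaxsig-io
NULL

#' @rdname vaxsig-io
#' @param mat genes x samples matrix.
#' @param path file path.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- tibble::rownames_to_column(as.data.frame(mat), "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname vaxsig-io
#' @export
read_expression_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "gene") {
    stop_input(sprintf("%s: first column must be 'gene'", path))
  }
  if (anyDuplicated(df$gene)) {
    stop_input(sprintf("%s: duplicated gene IDs", path))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  if (!is.numeric(m)) stop_input(sprintf("%s: non-numeric values", path))
  m
}

#' @rdname vaxsig-io
#' @param meta sample metadata tibble.
#' @export
write_metadata <- function(meta, path) {
  readr::write_tsv(meta, path)
  invisible(path)
}

#' @rdname vaxsig-io
#' @param expression optional named list of matrices to validate sample IDs
#'   against.
#' @export
read_metadata <- function(path, expression = NULL) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "tissue", "treatment", "time_h", "replicate")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    stop_input(sprintf("%s: missing column(s) %s", path,
                       paste(missing_cols, collapse = ", ")))
  }
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup)) {
    stop_input(sprintf("%s: duplicated sample_id '%s' (line %d)", path,
                       dup[1], which(meta$sample_id == dup[1])[2] + 1L))
  }
  if (!is.null(expression)) {
    for (tis in names(expression)) {
      ids <- meta$sample_id[meta$tissue == tis]
      absent <- setdiff(ids, colnames(expression[[tis]]))
      if (length(absent)) {
        stop_input(sprintf("%s: sample '%s' absent from the %s matrix",
                           path, absent[1], tis))
      }
    }
  }
  meta
}

#' @rdname vaxsig-io
#' @param collection a [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$annotation[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname vaxsig-io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); ann <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop_input(sprintf("%s: line %d has fewer than 3 fields", path, i))
    }
    sets[[parts[1]]] <- parts[-(1:2)]
    ann[parts[1]] <- parts[2]
  }
  gene_set_collection(sets, ann)
}

#' @rdname vaxsig-io
#' @param panel long protein tibble.
#' @export
write_protein_csv <- function(panel, path) {
  readr::write_csv(panel, path)
  invisible(path)
}

#' @rdname vaxsig-io
#' @export
read_protein_csv <- function(path) {
  panel <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("analyte", "treatment", "time_h", "replicate", "concentration",
            "unit")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    stop_input(sprintf("%s: missing column(s) %s", path,
                       paste(missing_cols, collapse = ", ")))
  }
  bad <- which(panel$concentration < 0)
  if (length(bad)) {
    stop_input(sprintf("%s: negative concentration at line %d", path,
                       bad[1] + 1L))
  }
  units_per_analyte <- panel |>
    distinct(.data$analyte, .data$unit) |>
    count(.data$analyte) |>
    filter(.data$n > 1L)
  if (nrow(units_per_analyte)) {
    stop_input(sprintf("%s: analyte '%s' has inconsistent units", path,
                       units_per_analyte$analyte[1]))
  }
  panel
}

#' Serialize a synthetic study to a directory of plain-text files
#'
#' Writes one expression TSV per tissue, the metadata TSV, the gene sets as
#' GMT, the protein panel as CSV, and the ground truth as a set of TSV/text
#' files under `truth/`.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tis in names(study$expression)) {
    write_expression_matrix(study$expression[[tis]],
                            file.path(dir, paste0("expression_", tis, ".tsv")))
  }
  write_metadata(study$samples, file.path(dir, "metadata.tsv"))
  write_gmt(study$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_protein_csv(study$proteins, file.path(dir, "proteins.csv"))
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  readr::write_tsv(study$truth$de_genes, file.path(tdir, "de_genes.tsv"))
  readr::write_tsv(study$truth$module_membership,
                   file.path(tdir, "module_membership.tsv"))
  writeLines(study$truth$biomarker_genes, file.path(tdir, "biomarkers.txt"))
  writeLines(study$truth$soluble_genes, file.path(tdir, "soluble.txt"))
  invisible(dir)
}

#' Read back a serialized study directory
#'
#' @param dir directory written by [write_study()].
#' @return list with `expression`, `samples`, `gene_sets`, `proteins` and
#'   (if present) `truth` (the serialized subset: DE genes, module
#'   membership, biomarker and soluble gene lists).
#' @export
read_study <- function(dir) {
  mats <- list.files(dir, pattern = "^expression_.*\\.tsv$")
  expression <- list()
  for (f in mats) {
    tis <- sub("^expression_(.*)\\.tsv$", "\\1", f)
    expression[[tis]] <- read_expression_matrix(file.path(dir, f))
  }
  out <- list(
    expression = expression,
    samples = read_metadata(file.path(dir, "metadata.tsv"), expression),
    gene_sets = read_gmt(file.path(dir, "gene_sets.gmt")),
    proteins = read_protein_csv(file.path(dir, "proteins.csv"))
  )
  tdir <- file.path(dir, "truth")
  if (dir.exists(tdir)) {
    out$truth <- list(
      de_genes = readr::read_tsv(file.path(tdir, "de_genes.tsv"),
                                 show_col_types = FALSE, progress = FALSE),
      module_membership = readr::read_tsv(
        file.path(tdir, "module_membership.tsv"),
        show_col_types = FALSE, progress = FALSE),
      biomarker_genes = readLines(file.path(tdir, "biomarkers.txt")),
      soluble_genes = readLines(file.path(tdir, "soluble.txt"))
    )
  }
  out
}
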