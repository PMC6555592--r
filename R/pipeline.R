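#' Pipeline run configuration
#'
#' Collects every stage parameter with defaults that reproduce the study's
#' reporting thresholds: DE at BH q < 0.01 (vs both controls through the
#' interaction contrast), enrichment reported at p < 1e-6 and AUC > 0.8,
#' module overlap at adjusted p < 0.05, module-trait reporting at |r| > 0.3,
#' minimum module size 20, soft power 12, top-100 cross-tissue gene
#' selection, protein volcano labels at adjusted p < 0.01.
#'
#' @param sim a [sim_config()] for the synthetic study (or `NULL` when
#'   `study` is given to [run_pipeline()] directly).
#' @param out_dir output directory for the stage tables and manifest.
#' @param seed integer seed propagated to the simulation.
#' @param q_threshold DE q cutoff.
#' @param enrich_p_max,enrich_auc_min enrichment reporting filter.
#' @param overlap_q module-overlap significance threshold.
#' @param trait_r module-trait reporting threshold.
#' @param beta soft-thresholding power for the signed network.
#' @param min_module_size minimum detected module size.
#' @param top_k cross-tissue top-gene count.
#' @param min_shared consensus-graph minimum shared-gene count.
#' @param volcano_label_p protein volcano label threshold.
#' @param skip character vector of stages to skip (subset of
#'   `c("enrich", "coexpr", "crosstissue", "protein")`).
#' @return a named list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), out_dir = tempfile("vaxsig_run_"),
                       seed = NULL, q_threshold = 0.01,
                       enrich_p_max = 1e-6, enrich_auc_min = 0.8,
                       overlap_q = 0.05, trait_r = 0.3, beta = 12,
                       min_module_size = 20, top_k = 100, min_shared = 10,
                       volcano_label_p = 0.01, skip = character(0)) {
  if (!is.null(seed) && !is.null(sim)) sim$seed <- check_count(seed, "seed")
  structure(list(
    sim = sim, out_dir = out_dir,
    q_threshold = check_number(q_threshold, "q_threshold", 0, 1,
                               strict_lower = TRUE, strict_upper = TRUE),
    enrich_p_max = enrich_p_max, enrich_auc_min = enrich_auc_min,
    overlap_q = overlap_q, trait_r = trait_r,
    beta = beta, min_module_size = min_module_size, top_k = top_k,
    min_shared = min_shared, volcano_label_p = volcano_label_p,
    skip = skip
  ), class = "run_config")
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes simulate (unless a study is supplied) -> normalize (quantile,
#' between arrays) -> differential expression -> gene-set enrichment ->
#' co-expression modules -> cross-tissue biomarker selection -> serum
#' protein statistics, writing every stage's tables as TSV under
#' `config$out_dir` together with a YAML run manifest (config echo, file
#' hashes, stage timings, warning count).  The manifest is written on both
#' success and failure; the run is deterministic given the simulation seed.
#'
#' @param config a [run_config()].
#' @param study optionally, a pre-built [generate_study()] result (the
#'   simulate stage is then skipped).
#' @return the manifest list, invisibly; the `results` attribute carries
#'   the in-memory stage outputs.
#' @export
run_pipeline <- function(config = run_config(), study = NULL) {
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = manifest_config(config), stages = list(),
                   files = list(), n_warnings = 0L, status = "running")
  results <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- withCallingHandlers(expr, warning = function(w) {
      manifest$n_warnings <<- manifest$n_warnings + 1L
      invokeRestart("muffleWarning")
    })
    manifest$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    val
  }
  emit <- function(tbl, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(tbl, path)
    manifest$files[[paste0(name, ".tsv")]] <<-
      unname(tools::md5sum(path))
    invisible(path)
  }

  finish <- function(status) {
    manifest$status <<- status
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }

  tryCatch({
    study <- t_stage("simulate", study %||% generate_study(config$sim))
    results$study <- study

    norm <- t_stage("normalize", lapply(study$expression, function(m) {
      quantile_normalize(m)
    }))

    de <- t_stage("de", run_de(norm, study$samples))
    results$de <- de
    emit(de, "de_results")
    results$de_counts <- count_de(de, config$q_threshold)
    emit(results$de_counts, "de_counts")

    if (!"enrich" %in% config$skip) {
      enr <- t_stage("enrich", run_enrichment(de, study$gene_sets))
      results$enrichment <- enr
      emit(enr, "enrichment")
      emit(filter_enriched(enr, config$enrich_p_max, config$enrich_auc_min),
           "enrichment_filtered")
    }

    if (!"coexpr" %in% config$skip) {
      cx <- t_stage("coexpr", {
        per_tissue <- imap(norm, function(m, tis) {
          adj <- build_signed_adjacency(m, beta = config$beta)
          assign <- detect_modules(adj, min_size = config$min_module_size,
                                   expr = m)
          eig <- if (any(assign$module != "M0")) {
            compute_eigengenes(m, assign)
          } else NULL
          mtc <- if (!is.null(eig)) {
            module_trait_correlation(
              eig, study$samples[study$samples$tissue == tis, ],
              r_threshold = config$trait_r)
          } else NULL
          ovl <- if (any(assign$module != "M0")) {
            module_overlap_hypergeometric(assign, study$gene_sets,
                                          q_threshold = config$overlap_q)
          } else NULL
          list(assignment = assign, eigengenes = eig, trait = mtc,
               overlap = ovl)
        })
        cons <- consensus_graph(lapply(per_tissue, `[[`, "assignment"),
                                min_shared = config$min_shared)
        list(per_tissue = per_tissue, consensus = cons)
      })
      results$coexpr <- cx
      assign_tbl <- imap(cx$per_tissue, function(x, tis) {
        mutate(x$assignment, tissue = tis)
      }) |> list_rbind()
      emit(assign_tbl, "module_assignment")
      trait_tbl <- imap(cx$per_tissue, function(x, tis) {
        if (is.null(x$trait)) NULL else mutate(x$trait, tissue = tis)
      }) |> list_rbind()
      if (nrow(trait_tbl)) emit(trait_tbl, "module_trait")
      ovl_tbl <- imap(cx$per_tissue, function(x, tis) {
        if (is.null(x$overlap)) NULL else mutate(x$overlap, tissue = tis)
      }) |> list_rbind()
      if (nrow(ovl_tbl)) emit(ovl_tbl, "module_overlap")
      emit(cx$consensus$edges, "consensus_edges")
    }

    if (!"crosstissue" %in% config$skip) {
      soluble <- tibble(
        gene = rownames(study$expression[[1]]),
        soluble = rownames(study$expression[[1]]) %in%
          study$truth$soluble_genes
      )
      panel <- t_stage("crosstissue",
                       biomarker_panel(de, soluble, k = config$top_k,
                                       q_threshold = config$q_threshold))
      results$panel <- panel
      emit(panel, "biomarker_panel")
      de_by <- split(de, de$tissue)
      if (all(c("muscle", "mln") %in% names(de_by))) {
        emit(disco_score(de_by$muscle, de_by$mln), "disco_muscle_mln")
      }
    }

    if (!"protein" %in% config$skip && nrow(study$proteins)) {
      prot <- t_stage("protein", {
        fc <- protein_fold_change(study$proteins)
        stats <- lapply(unique(study$proteins$analyte), function(a) {
          anova_dunnett(study$proteins, a)
        })
        coupling <- attr(study$proteins, "coupling")
        tp <- if (!is.null(coupling)) {
          transcript_protein_correlation(
            fc, de, select(coupling, "analyte", "gene"))
        } else NULL
        list(fc = fc, stats = stats, auc = protein_auc(study$proteins),
             volcano = volcano_table(fc, stats, config$volcano_label_p),
             transcript_protein = tp)
      })
      results$protein <- prot
      emit(prot$fc, "protein_fold_change")
      emit(prot$auc, "protein_auc")
      emit(prot$volcano, "protein_volcano")
      emit(list_rbind(map(prot$stats, function(s) {
        mutate(s$comparisons, analyte = s$analyte)
      })), "protein_dunnett")
      if (!is.null(prot$transcript_protein)) {
        emit(prot$transcript_protein, "transcript_protein_correlation")
      }
    }

    finish("complete")
    attr(manifest, "results") <- results
    invisible(manifest)
  }, error = function(e) {
    finish(paste("failed:", conditionMessage(e)))
    stop(e)
  })
}

# config echo with the nested sim_config flattened to plain lists for YAML
manifest_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$sim)) {
    sim <- unclass(cfg$sim)
    sim$protein_coupling <- NULL
    cfg$sim <- lapply(sim, function(x) {
      if (is.numeric(x) || is.character(x) || is.logical(x)) x else
        as.character(x)
    })
  }
  cfg
}
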