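#' Configure a synthetic immunisation study
#'
#' Builds the configuration object consumed by [generate_study()].  The
#' defaults emulate the design of the mouse reactogenicity study the package
#' models: three tissues (injected muscle, draining lymph node, blood), seven
#' active treatments plus a saline control, sampling at 4, 8, 24, 48, 72 and
#' 168 h post-injection with five replicates per group and time, and an
#' unvaccinated control group per treatment.
#'
#' @param n_genes number of genes on the synthetic array.
#' @param tissues character vector of tissue labels.
#' @param treatments character vector of treatment labels; must contain
#'   `"saline"`.  All other labels are active immunisations.
#' @param time_points_h strictly increasing post-injection sampling times in
#'   hours.
#' @param n_replicates animals per (treatment, time) cell; >= 2.
#' @param de_fraction fraction of eligible genes planted differentially
#'   expressed per active treatment, in `[0, 1)`.
#' @param effect_size_sd_units planted peak effect magnitude, in units of the
#'   gene's own residual SD (log2 scale).
#' @param de_direction_prob_up probability a planted effect is upregulation.
#' @param shared_de_fraction fraction of each treatment's planted genes that
#'   are shared across all tissues (the rest are tissue-private).
#' @param kinetic_profiles named character vector mapping each active
#'   treatment to `"early_transient"`, `"late_sustained"` or `"mixed"`.
#'   `NULL` chooses a default map (LPS/PolyIC early, Pentavac and
#'   MF59-adjuvanted flu mixed, others late).
#' @param n_biomarkers number of genes planted DE in every tissue, coupled to
#'   serum analytes and annotated soluble.
#' @param biomarker_boost multiplier on `effect_size_sd_units` for biomarker
#'   genes.
#' @param biomarker_treatments treatments under which biomarker genes are
#'   planted; `NULL` picks the inflammatory defaults present in `treatments`.
#' @param n_modules number of planted co-expression modules.
#' @param module_size_range integer `(min, max)` module sizes; min >= 20 so
#'   modules are detectable at the pipeline's minimum module size.
#' @param module_amplitude peak amplitude (log2 units) of each module's
#'   treatment-driven latent factor.
#' @param module_latent_sd SD of the per-sample latent jitter shared by a
#'   module's genes.
#' @param noise_sd typical per-gene residual SD on the log2 scale; per-gene
#'   SDs are drawn from a scaled inverse-chi-squared prior around it.
#' @param var_prior_df degrees of freedom of the per-gene variance prior.
#' @param baseline_mean,baseline_sd normal distribution of per-gene baseline
#'   log2 expression.
#' @param unvaccinated `"per_treatment"` (one unvaccinated group per
#'   treatment, as in the study) or `"shared"` (a single unvaccinated group).
#' @param protein_treatments treatments measured on the serum panel
#'   (intersected with `treatments`); must retain `"saline"`.
#' @param protein_coupling optional tibble with columns `analyte`, `gene`,
#'   `coupling`, `lag_h`, `baseline`, `noise_cv`, `unit`; `NULL` auto-maps a
#'   9-plex cytokine panel plus an SAA3-like acute-phase analyte (baseline
#'   in ug/mL, roughly a thousand-fold above the cytokines) onto the
#'   biomarker genes.
#' @param n_decoy_sets number of random decoy gene sets emitted by
#'   [generate_gene_sets()].
#' @param n_soluble_decoys number of non-DE genes additionally flagged
#'   soluble in the synthetic annotation table.
#' @param seed integer RNG seed; the whole study is a pure function of the
#'   configuration including this seed.
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [generate_study()]
#' @export
sim_config <- function(n_genes = 2000,
                       tissues = c("muscle", "mln", "blood"),
                       treatments = c("Pentavac", "Tri-Flu", "Tri-Flu+MF59",
                                      "EngerixB", "IFA", "LPS", "PolyIC",
                                      "saline"),
                       time_points_h = c(4, 8, 24, 48, 72, 168),
                       n_replicates = 5,
                       de_fraction = 0.1,
                       effect_size_sd_units = 4,
                       de_direction_prob_up = 0.5,
                       shared_de_fraction = 1 / 3,
                       kinetic_profiles = NULL,
                       n_biomarkers = 10,
                       biomarker_boost = 2,
                       biomarker_treatments = NULL,
                       n_modules = 5,
                       module_size_range = c(30, 50),
                       module_amplitude = 2.5,
                       module_latent_sd = 0.5,
                       noise_sd = 0.25,
                       var_prior_df = 20,
                       baseline_mean = 8,
                       baseline_sd = 1.5,
                       unvaccinated = c("per_treatment", "shared"),
                       protein_treatments = c("Pentavac", "Tri-Flu+MF59",
                                              "LPS", "PolyIC", "saline"),
                       protein_coupling = NULL,
                       n_decoy_sets = 20,
                       n_soluble_decoys = 50,
                       seed = 1L) {
  unvaccinated <- match.arg(unvaccinated)
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes", min = 10L),
    tissues = as.character(tissues),
    treatments = as.character(treatments),
    time_points_h = as.numeric(time_points_h),
    n_replicates = check_count(n_replicates, "n_replicates", min = 2L),
    de_fraction = check_number(de_fraction, "de_fraction", 0, 1,
                               strict_upper = TRUE),
    effect_size_sd_units = check_number(effect_size_sd_units,
                                        "effect_size_sd_units", 0,
                                        strict_lower = TRUE),
    de_direction_prob_up = check_number(de_direction_prob_up,
                                        "de_direction_prob_up", 0, 1),
    shared_de_fraction = check_number(shared_de_fraction,
                                      "shared_de_fraction", 0, 1),
    kinetic_profiles = kinetic_profiles,
    n_biomarkers = check_count(n_biomarkers, "n_biomarkers"),
    biomarker_boost = check_number(biomarker_boost, "biomarker_boost", 1),
    biomarker_treatments = biomarker_treatments,
    n_modules = check_count(n_modules, "n_modules"),
    module_size_range = as.integer(module_size_range),
    module_amplitude = check_number(module_amplitude, "module_amplitude", 0),
    module_latent_sd = check_number(module_latent_sd, "module_latent_sd", 0),
    noise_sd = check_number(noise_sd, "noise_sd", 0, strict_lower = TRUE),
    var_prior_df = check_number(var_prior_df, "var_prior_df", 1),
    baseline_mean = check_number(baseline_mean, "baseline_mean"),
    baseline_sd = check_number(baseline_sd, "baseline_sd", 0),
    unvaccinated = unvaccinated,
    protein_treatments = as.character(protein_treatments),
    protein_coupling = protein_coupling,
    n_decoy_sets = check_count(n_decoy_sets, "n_decoy_sets"),
    n_soluble_decoys = check_count(n_soluble_decoys, "n_soluble_decoys"),
    seed = check_count(seed, "seed")
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (length(cfg$tissues) < 1L) stop_config("at least one tissue required",
                                            "tissues")
  if (!"saline" %in% cfg$treatments) {
    stop_config("`treatments` must include \"saline\"", "treatments")
  }
  if (anyDuplicated(cfg$treatments)) {
    stop_config("duplicated treatment labels", "treatments")
  }
  if (length(cfg$time_points_h) < 2L ||
      any(diff(cfg$time_points_h) <= 0) || any(cfg$time_points_h <= 0)) {
    stop_config("`time_points_h` must be positive and strictly increasing",
                "time_points_h")
  }
  if (cfg$n_modules > 0L) {
    if (length(cfg$module_size_range) != 2L ||
        cfg$module_size_range[1] < 20L ||
        cfg$module_size_range[2] < cfg$module_size_range[1]) {
      stop_config("`module_size_range` must be (min, max) with min >= 20",
                  "module_size_range")
    }
    if (cfg$n_modules * cfg$module_size_range[2] > cfg$n_genes / 2) {
      stop_config("planted modules would occupy more than half the genes",
                  "n_modules")
    }
  }
  active <- setdiff(cfg$treatments, "saline")
  if (is.null(cfg$kinetic_profiles)) {
    cfg$kinetic_profiles <- default_kinetics(active)
  }
  bad <- setdiff(cfg$kinetic_profiles,
                 c("early_transient", "late_sustained", "mixed"))
  if (length(bad)) {
    stop_config(paste0("unknown kinetic profile(s): ",
                       paste(bad, collapse = ", ")), "kinetic_profiles")
  }
  if (!all(active %in% names(cfg$kinetic_profiles))) {
    stop_config("`kinetic_profiles` must cover every active treatment",
                "kinetic_profiles")
  }
  if (is.null(cfg$biomarker_treatments)) {
    pref <- intersect(c("LPS", "Pentavac", "PolyIC"), active)
    cfg$biomarker_treatments <- if (length(pref)) pref else head(active, 1L)
  }
  if (!all(cfg$biomarker_treatments %in% active)) {
    stop_config("`biomarker_treatments` must be active treatments",
                "biomarker_treatments")
  }
  cfg$protein_treatments <- intersect(cfg$protein_treatments, cfg$treatments)
  if (length(cfg$protein_treatments) &&
      !"saline" %in% cfg$protein_treatments) {
    stop_config("`protein_treatments` must retain \"saline\"",
                "protein_treatments")
  }
  if (!is.null(cfg$protein_coupling)) {
    pc <- cfg$protein_coupling
    need <- c("analyte", "gene", "coupling", "lag_h", "baseline",
              "noise_cv", "unit")
    if (!all(need %in% names(pc))) {
      stop_config(paste("`protein_coupling` must have columns:",
                        paste(need, collapse = ", ")), "protein_coupling")
    }
    if (any(pc$baseline < 0)) stop_config("negative baseline", "protein_coupling")
    if (any(pc$noise_cv < 0)) stop_config("negative noise_cv", "protein_coupling")
  }
  structure(cfg, class = "sim_config")
}

default_kinetics <- function(active) {
  map <- setNames(rep("late_sustained", length(active)), active)
  map[names(map) %in% c("LPS", "PolyIC")] <- "early_transient"
  map[names(map) %in% c("Pentavac", "Tri-Flu+MF59")] <- "mixed"
  map
}

# kinetic archetypes evaluated on an arbitrary hour grid, peak scaled to 1:
# early_transient decays exponentially from the first sampling time;
# late_sustained rises logistically from about 48 h and stays up through
# the end of the time course (anchored to zero at injection time)
kinetic_profile <- function(archetype, time_h) {
  t0 <- min(time_h)
  p <- switch(archetype,
    early_transient = exp(-(time_h - t0) / 20),
    late_sustained  = stats::plogis((time_h - 60) / 25) -
      stats::plogis(-60 / 25),
    stop_input(paste("unknown archetype:", archetype))
  )
  p / max(p)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_genes, " genes, ",
      length(x$tissues), " tissues, ",
      length(x$treatments), " treatments x ",
      length(x$time_points_h), " times x ", x$n_replicates, " reps, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a complete synthetic study with known ground truth
#'
#' Simulates per-tissue log2 expression matrices, sample metadata, BTM-style
#' gene-set collections, a serum-protein panel and the full ground truth
#' (planted DE genes with their true log2 fold changes, module membership and
#' latent factors, biomarker genes, soluble annotation).  Deterministic given
#' the configuration's seed.
#'
#' The expression model is additive Gaussian on the log2 scale: baseline +
#' planted treatment effect (the treatment's kinetic profile scaled by a
#' per-gene effect size in units of that gene's residual SD) + module latent
#' factor loading + independent noise.  Saline and unvaccinated samples carry
#' no planted treatment effect.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `synthetic_study`: a list with elements
#'   `expression` (named list of genes x samples matrices, one per tissue),
#'   `samples` (tibble: sample_id, tissue, treatment, time_h, replicate),
#'   `gene_sets` (a `gene_set_collection`), `proteins` (long tibble),
#'   `truth` (list: `de_genes`, `module_membership`, `latent_factors`,
#'   `module_loadings`, `biomarker_genes`, `soluble_genes`, `effects`) and
#'   `config`.
#' @examples
#' study <- generate_study(sim_config(n_genes = 200, n_modules = 0,
#'                                    treatments = c("LPS", "saline"),
#'                                    n_biomarkers = 2, seed = 7))
#' dim(study$expression$muscle)
#' @export
generate_study <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  set.seed(cfg$seed)

  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  active <- setdiff(cfg$treatments, "saline")
  times <- cfg$time_points_h

  ## ---- gene architecture -------------------------------------------------
  sigma_g <- cfg$noise_sd *
    sqrt(cfg$var_prior_df / rchisq(cfg$n_genes, cfg$var_prior_df))
  mu_g <- rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  names(sigma_g) <- names(mu_g) <- genes

  # planted modules occupy a dedicated block, disjoint from DE-eligible genes
  module_membership <- tibble(gene = character(), module = character())
  module_sizes <- integer(0)
  if (cfg$n_modules > 0L) {
    size_pool <- seq(cfg$module_size_range[1], cfg$module_size_range[2])
    module_sizes <- size_pool[sample.int(length(size_pool), cfg$n_modules,
                                         replace = TRUE)]
    mod_genes <- sample(genes, sum(module_sizes))
    module_membership <- tibble(
      gene = mod_genes,
      module = rep(sprintf("sim%02d", seq_len(cfg$n_modules)), module_sizes)
    )
  }
  eligible <- setdiff(genes, module_membership$gene)

  ## ---- planted DE design -------------------------------------------------
  n_bm <- min(cfg$n_biomarkers, length(eligible))
  biomarkers <- sort(sample(eligible, n_bm))
  n_de <- round(cfg$de_fraction * cfg$n_genes)
  n_shared <- round(cfg$shared_de_fraction * n_de)

  # effects[[trt]]: tibble(gene, tissue ("*" = all), beta, archetype)
  effects <- list()
  for (trt in active) {
    if (n_de == 0L && !(trt %in% cfg$biomarker_treatments && n_bm > 0)) next
    arch_trt <- cfg$kinetic_profiles[[trt]] %||%
      default_kinetics(active)[[trt]]
    shared <- character(0)
    rows <- NULL
    if (n_de > 0L) {
      shared <- sample(eligible, min(n_shared, length(eligible)))
      if (trt %in% cfg$biomarker_treatments) {
        shared <- union(biomarkers, shared)[seq_len(max(n_shared, n_bm))]
        shared <- union(biomarkers, shared)
      }
      rows <- tibble(gene = shared, tissue = "*")
      n_priv <- max(n_de - length(shared), 0L)
      for (tis in cfg$tissues) {
        pool <- setdiff(eligible, shared)
        priv <- sample(pool, min(n_priv, length(pool)))
        rows <- bind_rows(rows, tibble(gene = priv, tissue = tis))
      }
    } else if (trt %in% cfg$biomarker_treatments && n_bm > 0) {
      rows <- tibble(gene = biomarkers, tissue = "*")
    }
    if (is.null(rows) || nrow(rows) == 0L) next
    boost <- ifelse(rows$gene %in% biomarkers, cfg$biomarker_boost, 1)
    mag <- cfg$effect_size_sd_units * sigma_g[rows$gene] *
      runif(nrow(rows), 1, 1.5) * boost
    sign <- ifelse(rows$gene %in% biomarkers, 1,
                   ifelse(runif(nrow(rows)) < cfg$de_direction_prob_up, 1, -1))
    arch <- if (arch_trt == "mixed") {
      sample(c("early_transient", "late_sustained"), nrow(rows),
             replace = TRUE)
    } else rep(arch_trt, nrow(rows))
    effects[[trt]] <- mutate(rows, beta = mag * sign, archetype = arch)
  }

  ## ---- samples -----------------------------------------------------------
  samples <- make_sample_sheet(cfg)

  ## ---- expression per tissue --------------------------------------------
  profiles <- list(
    early_transient = kinetic_profile("early_transient", times),
    late_sustained  = kinetic_profile("late_sustained", times)
  )
  expression <- list()
  latent_factors <- list()
  loadings <- runif(nrow(module_membership), 0.8, 1.2)
  names(loadings) <- module_membership$gene
  module_drivers <- character(0)
  if (cfg$n_modules > 0L && length(active)) {
    module_drivers <- setNames(
      rep(active, length.out = cfg$n_modules),
      sprintf("sim%02d", seq_len(cfg$n_modules))
    )
  }
  module_arch <- setNames(
    rep(c("early_transient", "late_sustained"),
        length.out = max(cfg$n_modules, 1L)),
    names(module_drivers)[seq_len(cfg$n_modules)]
  )

  truth_de <- list()
  for (tis in cfg$tissues) {
    meta <- samples[samples$tissue == tis, ]
    n_s <- nrow(meta)
    mat <- matrix(rnorm(cfg$n_genes * n_s, 0, sigma_g), cfg$n_genes, n_s) +
      mu_g
    dimnames(mat) <- list(genes, meta$sample_id)

    # planted treatment effects
    for (trt in names(effects)) {
      eff <- effects[[trt]]
      eff <- eff[eff$tissue %in% c("*", tis), ]
      if (nrow(eff) == 0L) next
      for (ti in seq_along(times)) {
        cols <- which(meta$treatment == trt & meta$time_h == times[ti])
        if (!length(cols)) next
        shift <- eff$beta *
          vapply(eff$archetype, function(a) profiles[[a]][ti], 0)
        mat[eff$gene, cols] <- mat[eff$gene, cols] + shift
        truth_de[[length(truth_de) + 1L]] <- tibble(
          tissue = tis, treatment = trt, time_h = times[ti],
          gene = eff$gene, true_log2fc = unname(shift)
        )
      }
    }

    # planted co-expression modules: latent factor + loadings
    if (cfg$n_modules > 0L) {
      fac <- matrix(rnorm(cfg$n_modules * n_s, 0, cfg$module_latent_sd),
                    cfg$n_modules, n_s,
                    dimnames = list(names(module_drivers), meta$sample_id))
      for (m in names(module_drivers)) {
        drv <- module_drivers[[m]]
        prof <- profiles[[module_arch[[m]]]]
        idx <- meta$treatment == drv & meta$time_h > 0
        fac[m, idx] <- fac[m, idx] + cfg$module_amplitude *
          prof[match(meta$time_h[idx], times)]
      }
      mm <- module_membership
      mat[mm$gene, ] <- mat[mm$gene, ] +
        loadings[mm$gene] * fac[mm$module, , drop = FALSE]
      latent_factors[[tis]] <- fac
    }
    expression[[tis]] <- mat
  }

  truth <- list(
    de_genes = if (length(truth_de)) {
      filter(list_rbind(truth_de), abs(.data$true_log2fc) > 1e-12)
    } else {
      tibble(tissue = character(), treatment = character(),
             time_h = numeric(), gene = character(),
             true_log2fc = numeric())
    },
    module_membership = module_membership,
    module_drivers = module_drivers,
    latent_factors = latent_factors,
    module_loadings = loadings,
    biomarker_genes = biomarkers,
    soluble_genes = character(0),
    effects = effects
  )

  # synthetic soluble annotation: biomarkers plus non-DE decoy genes
  de_union <- unique(unlist(lapply(effects, function(e) e$gene)))
  non_de <- setdiff(eligible, de_union)
  truth$soluble_genes <- sort(c(
    biomarkers,
    sample(non_de, min(cfg$n_soluble_decoys, length(non_de)))
  ))

  gene_sets <- generate_gene_sets(cfg, truth)
  proteins <- generate_protein_panel(truth, cfg)

  structure(
    list(expression = expression, samples = samples, gene_sets = gene_sets,
         proteins = proteins, truth = truth, config = cfg),
    class = "synthetic_study"
  )
}

make_sample_sheet <- function(cfg) {
  times_all <- c(0, cfg$time_points_h)  # 0 encodes the unvaccinated group
  rows <- list()
  for (tis in cfg$tissues) {
    if (cfg$unvaccinated == "per_treatment") {
      grid <- expand.grid(treatment = cfg$treatments, time_h = times_all,
                          replicate = seq_len(cfg$n_replicates),
                          stringsAsFactors = FALSE)
    } else {
      grid <- rbind(
        expand.grid(treatment = cfg$treatments, time_h = cfg$time_points_h,
                    replicate = seq_len(cfg$n_replicates),
                    stringsAsFactors = FALSE),
        expand.grid(treatment = "unvaccinated", time_h = 0,
                    replicate = seq_len(cfg$n_replicates),
                    stringsAsFactors = FALSE)
      )
    }
    grid$tissue <- tis
    rows[[tis]] <- grid
  }
  out <- as_tibble(bind_rows(rows))
  attr(out, "out.attrs") <- NULL
  out <- out[order(out$tissue, out$treatment, out$time_h, out$replicate), ]
  out$sample_id <- sprintf(
    "%s_%s_t%03d_r%d", out$tissue,
    gsub("[^A-Za-z0-9]", "", out$treatment), out$time_h, out$replicate
  )
  select(out, "sample_id", "tissue", "treatment", "time_h", "replicate")
}

#' Generate BTM-style gene-set collections matched to a study's ground truth
#'
#' Emits three kinds of sets: response sets matching each treatment's planted
#' DE genes (enrichment-positive), module sets matching each planted
#' co-expression module (overlap-positive), and random decoy sets.  Each set
#' carries a high-level annotation group in the GMT description field.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element of a [generate_study()] result.
#' @param max_set_size cap on emitted response-set sizes.
#' @return a [gene_set_collection()].
#' @export
generate_gene_sets <- function(config, truth, max_set_size = 50L) {
  cfg <- if (inherits(config, "sim_config")) config else
    do.call(sim_config, config)
  if (max_set_size > cfg$n_genes) {
    stop_input("requested set size exceeds the gene universe")
  }
  set.seed(derive_seed(cfg$seed, 1L))
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  sets <- list(); ann <- character(0)

  for (trt in names(truth$effects)) {
    g <- truth$effects[[trt]]
    g <- unique(g$gene[g$tissue == "*"])
    if (!length(g)) next
    if (length(g) > max_set_size) g <- sample(g, max_set_size)
    nm <- paste0("resp_", gsub("[^A-Za-z0-9]", "", trt))
    sets[[nm]] <- sort(g)
    ann[nm] <- "planted_response"
  }
  mm <- truth$module_membership
  for (m in unique(mm$module)) {
    nm <- paste0("set_", m)
    sets[[nm]] <- sort(mm$gene[mm$module == m])
    ann[nm] <- "planted_module"
  }
  if (cfg$n_decoy_sets > 0L) {
    for (i in seq_len(cfg$n_decoy_sets)) {
      k <- sample(20:min(max_set_size, cfg$n_genes), 1L)
      nm <- sprintf("decoy_%02d", i)
      sets[[nm]] <- sort(sample(genes, k))
      ann[nm] <- "decoy"
    }
  }
  gene_set_collection(sets, ann)
}

#' Generate a synthetic serum-protein panel coupled to transcript truth
#'
#' Concentrations follow
#' `baseline * 2^(coupling * true_log2fc(source gene, t - lag)) * noise`,
#' with multiplicative lognormal noise of the configured coefficient of
#' variation (mean 1).  Saline (and any treatment the source gene is not
#' planted under) stays at `baseline * noise`.  One analyte is configured
#' acute-phase-like: microgram-scale baseline (the cytokines are at picogram
#' scale) with lagged, long-duration kinetics.
#'
#' @param truth,config as in [generate_gene_sets()].
#' @return long tibble: analyte, treatment, time_h, replicate,
#'   concentration, unit; the coupling table is attached as attribute
#'   `"coupling"`.
#' @export
generate_protein_panel <- function(truth, config) {
  cfg <- if (inherits(config, "sim_config")) config else
    do.call(sim_config, config)
  set.seed(derive_seed(cfg$seed, 2L))
  coupling <- cfg$protein_coupling %||% default_coupling(truth$biomarker_genes)
  if (any(coupling$baseline < 0)) stop_input("negative baseline")
  if (any(coupling$noise_cv < 0)) stop_input("negative noise_cv")
  missing_src <- setdiff(coupling$gene,
                         sprintf("g%05d", seq_len(cfg$n_genes)))
  if (length(missing_src)) {
    stop_input(paste("coupled source gene(s) not in study:",
                     paste(missing_src, collapse = ", ")))
  }
  trts <- cfg$protein_treatments
  if (!length(trts)) {
    return(tibble(analyte = character(), treatment = character(),
                  time_h = numeric(), replicate = integer(),
                  concentration = numeric(), unit = character()))
  }
  times <- c(0, cfg$time_points_h)

  # per (gene, treatment) true log2FC profile on the transcript grid
  lfc_at <- function(gene, trt, t_eval) {
    eff <- truth$effects[[trt]]
    if (is.null(eff)) return(rep(0, length(t_eval)))
    eff <- eff[eff$gene == gene & eff$tissue == "*", ]
    if (nrow(eff) == 0L) return(rep(0, length(t_eval)))
    prof <- kinetic_profile(eff$archetype[1], cfg$time_points_h) *
      eff$beta[1]
    approx(x = c(0, cfg$time_points_h), y = c(0, prof),
           xout = pmax(t_eval, 0), rule = 2)$y
  }

  rows <- list()
  for (i in seq_len(nrow(coupling))) {
    cp <- coupling[i, ]
    sdlog <- sqrt(log(1 + cp$noise_cv^2))
    for (trt in trts) {
      lfc <- if (trt == "saline") rep(0, length(times)) else
        lfc_at(cp$gene, trt, times - cp$lag_h)
      mean_conc <- cp$baseline * 2^(cp$coupling * lfc)
      n_obs <- length(times) * cfg$n_replicates
      noise <- if (sdlog > 0) {
        rlnorm(n_obs, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else rep(1, n_obs)
      rows[[length(rows) + 1L]] <- tibble(
        analyte = cp$analyte, treatment = trt,
        time_h = rep(times, each = cfg$n_replicates),
        replicate = rep(seq_len(cfg$n_replicates), length(times)),
        concentration = rep(mean_conc, each = cfg$n_replicates) * noise,
        unit = cp$unit
      )
    }
  }
  out <- list_rbind(rows)
  attr(out, "coupling") <- coupling
  out
}

default_coupling <- function(biomarkers) {
  cyto <- c("CCL2", "CCL3", "CCL4", "CCL5", "CXCL1", "CXCL2", "CXCL10",
            "IL6", "TNFa")
  n_cyto <- min(length(cyto), max(length(biomarkers) - 1L, 0L))
  base <- c(120, 40, 60, 150, 100, 50, 200, 90, 70)
  out <- tibble(
    analyte = cyto[seq_len(n_cyto)],
    gene = biomarkers[seq_len(n_cyto)],
    coupling = 1, lag_h = 0,
    baseline = base[seq_len(n_cyto)],
    noise_cv = 0.2, unit = "pg/mL"
  )
  if (length(biomarkers) > n_cyto) {
    out <- bind_rows(out, tibble(
      analyte = "SAA3", gene = biomarkers[n_cyto + 1L],
      coupling = 1.5, lag_h = 12, baseline = 3,
      noise_cv = 0.25, unit = "ug/mL"
    ))
  }
  out
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> ", length(x$expression), " tissue(s), ",
      nrow(x$expression[[1]]), " genes x ", ncol(x$expression[[1]]),
      " samples each; ", length(x$gene_sets$sets), " gene sets; ",
      length(unique(x$proteins$analyte)), " serum analytes\n", sep = "")
  invisible(x)
}
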