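#' Signed weighted co-expression adjacency
#'
#' Pearson correlation across samples mapped to `[0, 1]` and raised to a
#' soft-thresholding power: `a_ij = ((1 + cor(x_i, x_j)) / 2)^beta`.
#' Anticorrelated genes are thereby suppressed (signed network).
#' Constant-expression genes are removed first (count attached as attribute
#' `"n_constant"`).
#'
#' @param expr genes x samples log2 matrix with >= 3 samples.
#' @param beta positive soft power (default 12, the usual signed-network
#'   convention).
#' @return object of class `signed_adjacency`: list with `adjacency`
#'   (symmetric, unit diagonal, entries in `[0, 1]`), `beta`, `genes`.
#' @export
build_signed_adjacency <- function(expr, beta = 12) {
  check_number(beta, "beta", 0, strict_lower = TRUE)
  check_matrix(expr, "expr")
  if (ncol(expr) < 3L) stop_input("need >= 3 samples")
  v <- apply(expr, 1, var)
  n_const <- sum(v == 0)
  expr <- expr[v > 0, , drop = FALSE]
  a <- ((1 + cor(t(expr))) / 2)^beta
  diag(a) <- 1
  structure(list(adjacency = a, beta = beta, genes = rownames(expr),
                 n_constant = n_const),
            class = "signed_adjacency")
}

# topological overlap similarity of a signed adjacency matrix;
# (A %*% A)_ij includes the u = i and u = j terms (diag(A) = 1), each a_ij,
# so the shared-neighbour sum over u != i, j is (A %*% A)_ij - 2 a_ij
tom_similarity <- function(a) {
  k <- colSums(a) - 1
  l <- a %*% a - 2 * a
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules
#'
#' Clusters genes by average-linkage hierarchical clustering of the
#' topological-overlap dissimilarity (or `1 - adjacency` when `use_tom =
#' FALSE`), cuts the tree at a fixed dissimilarity height, then (when the
#' expression matrix is supplied) merges sub-minimum clusters into the
#' best-correlated module by eigengene correlation and fuses near-identical
#' modules at eigengene correlation > `merge_cor`.  Deterministic: no RNG.
#' Modules are labelled `M1, M2, ...` in decreasing size order; unassigned
#' genes get the reserved label `M0`.
#'
#' @param adj a [build_signed_adjacency()] object.
#' @param min_size minimum module size (default 20).
#' @param cut_height tree cut height on the dissimilarity scale.
#' @param use_tom cluster on topological-overlap dissimilarity (default)
#'   rather than `1 - adjacency`.
#' @param expr optional genes x samples matrix enabling the eigengene-based
#'   rescue/merge steps.
#' @param merge_cor eigengene correlation above which two modules are fused.
#' @param rescue_cor minimum eigengene correlation for absorbing a
#'   sub-minimum cluster into a module.
#' @param kme_min minimum module membership (correlation of a gene's
#'   profile with its module eigengene); weaker genes are unassigned.
#' @return tibble: gene, module.
#' @export
detect_modules <- function(adj, min_size = 20, cut_height = 0.995,
                           use_tom = TRUE, expr = NULL, merge_cor = 0.85,
                           rescue_cor = 0.5, kme_min = 0.5) {
  check_count(min_size, "min_size", min = 2L)
  a <- adj$adjacency
  genes <- adj$genes
  if (length(genes) < min_size) {
    warn("fewer genes than min_size: everything unassigned")
    return(tibble(gene = genes, module = "M0"))
  }
  diss <- if (use_tom) 1 - tom_similarity(a) else 1 - a
  tree <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(tree, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_size]
  label <- ifelse(cl %in% as.integer(big), as.character(cl), "small")
  names(label) <- genes

  if (!is.null(expr) && length(big)) {
    expr <- expr[genes, , drop = FALSE]
    eig_of <- function(members) {
      module_eigengene(expr[members, , drop = FALSE])
    }
    eigs <- lapply(big, function(b) eig_of(genes[label == b]))
    names(eigs) <- big
    # fuse near-identical modules
    repeat {
      if (length(eigs) < 2L) break
      em <- do.call(cbind, eigs)
      cc <- cor(em); diag(cc) <- 0
      top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      if (max(cc) <= merge_cor) break
      keep <- colnames(em)[top[1]]; drop_m <- colnames(em)[top[2]]
      label[label == drop_m] <- keep
      eigs[[drop_m]] <- NULL
      eigs[[keep]] <- eig_of(genes[label == keep])
    }
    # absorb sub-minimum clusters into the best-correlated module
    small_cl <- setdiff(unique(cl), as.integer(names(eigs)))
    for (sc in small_cl) {
      members <- genes[cl == sc]
      if (!length(members) || !length(eigs)) next
      prof <- colMeans(expr[members, , drop = FALSE])
      rr <- vapply(eigs, function(e) cor(prof, e), 0)
      if (max(rr) > rescue_cor) {
        label[members] <- names(eigs)[which.max(rr)]
      } else {
        label[members] <- "M0"
      }
    }
    label[label == "small"] <- "M0"
    # module-membership filter: genes weakly correlated with their own
    # module's eigengene are unassigned; modules shrinking below the
    # minimum size dissolve
    for (mod in setdiff(unique(label), "M0")) {
      members <- genes[label == mod]
      e <- eig_of(members)
      kme <- suppressWarnings(
        vapply(members, function(g) cor(expr[g, ], e), 0)
      )
      kme[is.na(kme)] <- 0
      label[members[kme < kme_min]] <- "M0"
      if (sum(label == mod) < min_size) label[label == mod] <- "M0"
    }
  } else {
    label[label == "small"] <- "M0"
  }

  # size-ranked final labels
  tab <- sort(table(label[label != "M0"]), decreasing = TRUE)
  relab <- setNames(paste0("M", seq_along(tab)), names(tab))
  relab["M0"] <- "M0"
  tibble(gene = genes, module = unname(relab[label]))
}

# first right singular vector of the row-standardised submatrix,
# unit norm over samples, sign-aligned with the average expression profile
module_eigengene <- function(submat) {
  v <- apply(submat, 1, var)
  if (all(v == 0)) {
    stop_input("module contains only zero-variance genes")
  }
  sm <- submat[v > 0, , drop = FALSE]
  sm <- t(scale(t(sm)))
  e <- svd(sm, nu = 0, nv = 1)$v[, 1]
  if (cor(e, colMeans(submat)) < 0) e <- -e
  e / sqrt(sum(e^2))
}

#' Module eigengenes
#'
#' First principal component of each module's expression submatrix over
#' samples: rows are standardised, the leading right singular vector is
#' taken, normalised to unit length and sign-fixed to correlate
#' non-negatively with the module's average expression profile.
#'
#' @param expr genes x samples matrix.
#' @param assignment tibble from [detect_modules()] (label `M0` is skipped).
#' @return modules x samples matrix.
#' @export
compute_eigengenes <- function(expr, assignment) {
  mods <- setdiff(unique(assignment$module), "M0")
  if (!length(mods)) stop_input("no assigned modules")
  out <- matrix(NA_real_, length(mods), ncol(expr),
                dimnames = list(mods, colnames(expr)))
  for (m in mods) {
    members <- assignment$gene[assignment$module == m]
    if (length(members) < 2L) stop_input(sprintf("module %s has < 2 genes", m))
    sub <- expr[members, , drop = FALSE]
    if (all(apply(sub, 1, var) == 0)) {
      stop_input(sprintf("module %s contains only zero-variance genes", m))
    }
    out[m, ] <- module_eigengene(sub)
  }
  out
}

#' Module-trait correlations
#'
#' Pearson correlation of each module eigengene with the binary immunisation
#' indicator of each treatment (1 = sample received that treatment at a
#' post-injection time, 0 otherwise), with two-sided p-values.  Treatments
#' whose indicator is constant over the samples are skipped.
#'
#' @param eigengenes modules x samples matrix from [compute_eigengenes()].
#' @param meta sample metadata matching the eigengene columns.
#' @param r_threshold reporting convention attached to the result
#'   (`reported = |r| > r_threshold`); default 0.3.
#' @return tibble: module, treatment, r, p, reported.
#' @export
module_trait_correlation <- function(eigengenes, meta, r_threshold = 0.3) {
  meta <- meta[match(colnames(eigengenes), meta$sample_id), ]
  if (anyNA(meta$sample_id)) stop_input("metadata missing eigengene samples")
  trts <- setdiff(unique(meta$treatment), "unvaccinated")
  out <- list()
  for (trt in trts) {
    ind <- as.numeric(meta$treatment == trt & meta$time_h > 0)
    if (var(ind) == 0) next
    for (m in rownames(eigengenes)) {
      ct <- cor.test(eigengenes[m, ], ind)
      out[[length(out) + 1L]] <- tibble(
        module = m, treatment = trt,
        r = unname(ct$estimate), p = ct$p.value
      )
    }
  }
  res <- list_rbind(out)
  mutate(res, reported = abs(.data$r) > r_threshold)
}

#' Hypergeometric overlap of detected modules with reference sets
#'
#' Upper-tail hypergeometric test `P(X >= k)` of each (module, reference
#' set) overlap within a shared gene universe, BH-adjusted across all pairs.
#'
#' @param assignment tibble from [detect_modules()].
#' @param reference a [gene_set_collection()].
#' @param universe character vector of genes present in both analyses;
#'   defaults to the assignment's genes.
#' @param q_threshold significance convention attached to the result
#'   (`significant = q < q_threshold`); default 0.05.
#' @return tibble: module, set, k, module_size, set_size, p, q, significant.
#' @export
module_overlap_hypergeometric <- function(assignment, reference,
                                          universe = NULL,
                                          q_threshold = 0.05) {
  universe <- universe %||% unique(assignment$gene)
  if (!length(universe)) stop_input("empty gene universe")
  N <- length(universe)
  mods <- setdiff(unique(assignment$module), "M0")
  out <- list()
  for (m in mods) {
    members <- intersect(assignment$gene[assignment$module == m], universe)
    n_draw <- length(members)
    for (s in names(reference$sets)) {
      K <- length(intersect(reference$sets[[s]], universe))
      k <- length(intersect(members, reference$sets[[s]]))
      p <- if (K == 0L || n_draw == 0L) 1 else
        phyper(k - 1, K, N - K, n_draw, lower.tail = FALSE)
      out[[length(out) + 1L]] <- tibble(
        module = m, set = s, k = k, module_size = n_draw, set_size = K,
        p = min(p, 1)
      )
    }
  }
  res <- list_rbind(out)
  res$q <- bh_adjust(res$p)
  mutate(res, significant = .data$q < q_threshold)
}

#' Cross-tissue consensus module graph
#'
#' Connects (tissue, module) nodes whose gene memberships share at least
#' `min_shared` genes; edge weight is the shared-gene count.  Connected
#' components are reported as consensus clusters.
#'
#' @param assignments named list (by tissue) of [detect_modules()] tibbles;
#'   needs >= 2 tissues.
#' @param min_shared minimum shared-gene count for an edge.
#' @return list with `edges` (tibble: tissue_a, module_a, tissue_b,
#'   module_b, shared) and `components` (tibble: tissue, module, component).
#' @export
consensus_graph <- function(assignments, min_shared = 10) {
  if (length(assignments) < 2L) stop_input("need >= 2 tissues")
  if (is.null(names(assignments))) stop_input("assignments must be named by tissue")
  nodes <- list(); members <- list()
  for (tis in names(assignments)) {
    a <- assignments[[tis]]
    for (m in setdiff(unique(a$module), "M0")) {
      id <- paste(tis, m, sep = ":")
      nodes[[id]] <- c(tissue = tis, module = m)
      members[[id]] <- a$gene[a$module == m]
    }
  }
  ids <- names(nodes)
  edges <- list()
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq(i + 1L, length(ids))) {
        ta <- nodes[[ids[i]]][["tissue"]]; tb <- nodes[[ids[j]]][["tissue"]]
        if (ta == tb) next
        sh <- length(intersect(members[[ids[i]]], members[[ids[j]]]))
        if (sh >= min_shared) {
          edges[[length(edges) + 1L]] <- tibble(
            tissue_a = ta, module_a = nodes[[ids[i]]][["module"]],
            tissue_b = tb, module_b = nodes[[ids[j]]][["module"]],
            shared = sh
          )
        }
      }
    }
  }
  edges <- if (length(edges)) list_rbind(edges) else
    tibble(tissue_a = character(), module_a = character(),
           tissue_b = character(), module_b = character(),
           shared = integer())
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(
      paste(edges$tissue_a, edges$module_a, sep = ":"),
      paste(edges$tissue_b, edges$module_b, sep = ":")
    ))
  }
  comp <- igraph::components(g)$membership
  components <- tibble(
    tissue = vapply(nodes, `[[`, "", "tissue"),
    module = vapply(nodes, `[[`, "", "module"),
    component = unname(comp[ids])
  )
  list(edges = edges, components = components)
}
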