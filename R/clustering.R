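# Two-modality donor clustering: lifetime attribute counts plus an
# age-resolved temporal matrix, each normalized and reduced by PCA, combined
# with per-donor weighted-nearest-neighbor modality weights, clustered with
# Leiden community detection, and profiled with overrepresentation and
# marker-attribute tests.

#' Build the two clustering modalities
#'
#' The flattened modality counts, per donor, the distinct observation years
#' of each attribute over the whole lifetime. The temporal modality counts
#' observations inside overlapping age bins (default width 30 years stepping
#' by 5; a bin covers the half-open interval `[start, start + width)`), one
#' column per attribute x bin.
#'
#' @param trajectory long observation data.frame (needs `age`).
#' @param donor_ids donors (row order of the result).
#' @param attributes attribute universe (default: those observed).
#' @param bin_width,bin_step temporal bin geometry.
#' @param age_range numeric length 2; default spans the observed ages rounded
#'   to multiples of `bin_step`.
#' @return list with `flattened` and `temporal` count matrices and `bins`.
#' @export
build_matrices <- function(trajectory, donor_ids, attributes = NULL,
                           bin_width = 30, bin_step = 5, age_range = NULL) {
  obs <- trajectory[trajectory$present == 1, , drop = FALSE]
  obs <- obs[obs$donor_id %in% donor_ids, , drop = FALSE]
  attributes <- attributes %||% sort(unique(obs$attribute_id))
  flattened <- count_matrix(trajectory, donor_ids, attributes)
  aged <- obs[!is.na(obs$age), , drop = FALSE]
  if (is.null(age_range)) {
    if (!nrow(aged)) nt_stop("no aged observations to bin",
                             "neurotraj_validation_error")
    age_range <- c(bin_step * floor(min(aged$age) / bin_step),
                   bin_step * ceiling(max(aged$age) / bin_step))
  }
  starts <- seq(age_range[1], max(age_range[1], age_range[2] - bin_width),
                by = bin_step)
  bins <- data.frame(start = starts, end = starts + bin_width)
  temporal <- matrix(
    0L, length(donor_ids), length(attributes) * nrow(bins),
    dimnames = list(donor_ids, as.vector(outer(
      attributes, sprintf("%d_%d", bins$start, bins$end), paste, sep = "@"))))
  di <- match(aged$donor_id, donor_ids)
  ai <- match(aged$attribute_id, attributes)
  for (b in seq_len(nrow(bins))) {
    inbin <- aged$age >= bins$start[b] & aged$age < bins$end[b]
    if (!any(inbin)) next
    tab <- table(di[inbin], ai[inbin])
    # column layout from outer(): attribute varies fastest within each bin
    cols <- (b - 1L) * length(attributes) + as.integer(colnames(tab))
    rows <- as.integer(rownames(tab))
    for (jj in seq_along(cols)) {
      temporal[rows, cols[jj]] <- temporal[rows, cols[jj]] +
        as.integer(tab[, jj])
    }
  }
  list(flattened = flattened, temporal = temporal, bins = bins)
}

#' Normalize, scale and reduce a count matrix
#'
#' Counts are depth-normalized per donor (`x / total * 1e4`), log1p
#' transformed, z-scaled per feature (zero-variance features dropped) and
#' reduced by PCA. Principal-component signs are fixed so the largest-magnitude
#' loading of each component is positive, making the embedding deterministic.
#'
#' @param counts donors x features count matrix.
#' @param n_pcs number of components (capped at the available rank).
#' @return list with `embedding` (donors x PCs), `sdev`, `kept` feature names.
#' @export
normalize_scale_pca <- function(counts, n_pcs = 30) {
  totals <- pmax(rowSums(counts), 1)
  x <- log1p(counts / totals * 1e4)
  v <- apply(x, 2, stats::var)
  keep <- which(v > 0)
  if (!length(keep)) nt_stop("all features have zero variance",
                             "neurotraj_validation_error")
  x <- scale(x[, keep, drop = FALSE])
  n_pcs <- min(n_pcs, ncol(x), nrow(x) - 1)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = n_pcs)
  flip <- apply(pc$rotation, 2, function(w) sign(w[which.max(abs(w))]))
  emb <- sweep(pc$x, 2, flip, "*")
  rownames(emb) <- rownames(counts)
  list(embedding = emb, sdev = pc$sdev[seq_len(n_pcs)],
       kept = colnames(counts)[keep])
}

knn_index <- function(emb, k) {
  d <- as.matrix(stats::dist(emb))
  diag(d) <- Inf
  idx <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  dist <- t(vapply(seq_len(nrow(d)), function(i) d[i, idx[i, ]],
                   numeric(k)))
  list(idx = idx, dist = dist, d = d)
}

#' Weighted-nearest-neighbor graph over two or more modalities
#'
#' Per-donor modality weights compare how well a donor's embedding in each
#' modality is predicted by its within-modality neighbors versus its
#' neighbors from the other modalities: affinities use an exponential kernel
#' `exp(-max(d - d_nearest, 0) / sigma)` with per-donor bandwidth
#' `sigma = max(d_k - d_nearest, eps)`, the within/cross affinity ratio is
#' passed through a softmax across modalities, and the joint neighbor graph
#' sums the weight-scaled kernels over the union of modality neighbor sets
#' (keeping the top `k` edges per donor).
#'
#' @param embeddings named list of donors x PCs matrices (same row order).
#' @param k neighbors per modality (default 20, capped at n - 1).
#' @param equal_weights bypass the weighting and use 1/M per modality.
#' @return list with `graph` (igraph, weighted), `weights` (donors x
#'   modalities), `neighbors`.
#' @export
wnn_graph <- function(embeddings, k = 20, equal_weights = FALSE) {
  M <- length(embeddings)
  stopifnot(M >= 1)
  n <- nrow(embeddings[[1]])
  k <- min(k, n - 1)
  eps <- 1e-12
  kn <- lapply(embeddings, knn_index, k = k)
  sigma <- lapply(kn, function(x)
    pmax(x$dist[, k] - x$dist[, 1], eps))
  affin <- function(m, dists) {
    exp(-pmax(dists - kn[[m]]$dist[, 1], 0) / sigma[[m]])
  }
  if (equal_weights || M == 1) {
    weights <- matrix(1 / M, n, M)
  } else {
    ratio <- sapply(seq_len(M), function(m) {
      emb <- embeddings[[m]]
      pred_d <- function(idx) {
        vapply(seq_len(n), function(i)
          sqrt(sum((emb[i, ] - colMeans(emb[idx[i, , drop = FALSE], ,
                                            drop = FALSE]))^2)),
          numeric(1))
      }
      within <- affin(m, pred_d(kn[[m]]$idx))
      cross <- rowMeans(sapply(setdiff(seq_len(M), m), function(m2)
        affin(m, pred_d(kn[[m2]]$idx))))
      within / (cross + 1e-4)
    })
    weights <- exp(ratio - apply(ratio, 1, max))
    weights <- weights / rowSums(weights)
  }
  colnames(weights) <- names(embeddings)
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    nbr <- sort(unique(as.vector(vapply(kn, function(x) x$idx[i, ],
                                        integer(k)))))
    theta <- numeric(length(nbr))
    for (m in seq_len(M)) {
      dij <- kn[[m]]$d[i, nbr]
      theta <- theta + weights[i, m] *
        exp(-pmax(dij - kn[[m]]$dist[i, 1], 0) / sigma[[m]][i])
    }
    ord <- order(theta, decreasing = TRUE)[seq_len(min(k, length(nbr)))]
    edges[[i]] <- data.frame(from = i, to = nbr[ord], w = theta[ord])
  }
  ed <- do.call(rbind, edges)
  key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  ed <- ed[!duplicated(key), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  igraph::E(g)$weight <- ed$w
  list(graph = g, weights = weights, neighbors = kn)
}

#' Leiden clustering of a weighted neighbor graph
#'
#' @param graph igraph object with edge weights.
#' @param resolution modularity resolution (default 0.8).
#' @param seed integer seed.
#' @return integer cluster memberships (1-based, ordered by size).
#' @export
cluster_graph <- function(graph, resolution = 0.8, seed = 1) {
  cl <- with_seed(seed, igraph::cluster_leiden(
    graph, objective_function = "modularity",
    resolution = resolution, n_iterations = 10))
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  as.integer(factor(memb, levels = names(sizes)))
}

#' Two-dimensional embedding for display
#'
#' @param embedding donors x PCs matrix (typically the weighted-neighbor PCA
#'   concatenation, or a single modality embedding).
#' @param seed integer seed.
#' @param ... passed to [uwot::umap()].
#' @return donors x 2 matrix.
#' @export
embed_2d <- function(embedding, seed = 1, ...) {
  with_seed(seed, uwot::umap(embedding, n_threads = 1, ...))
}

#' Fisher overrepresentation of donor labels per cluster
#'
#' One-sided (greater) by default, as for diagnosis enrichment per cluster;
#' use `alternative = "two.sided"` for e.g. genotype comparisons.
#'
#' @param clusters integer memberships.
#' @param labels character labels per donor (e.g. diagnosis, APOE genotype).
#' @param alternative passed to [stats::fisher.test()].
#' @return data.frame cluster, label, in_cluster, out_cluster, p, q (BH).
#' @export
fisher_overrepresentation <- function(clusters, labels,
                                      alternative = "greater") {
  stopifnot(length(clusters) == length(labels))
  rows <- list()
  for (cl in sort(unique(clusters))) {
    for (lb in sort(unique(labels))) {
      a <- sum(clusters == cl & labels == lb)
      b <- sum(clusters == cl & labels != lb)
      c_ <- sum(clusters != cl & labels == lb)
      d <- sum(clusters != cl & labels != lb)
      p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                              alternative = alternative)$p.value
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, label = lb, in_cluster = a, in_rest = c_, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Marker attributes per cluster
#'
#' Rank-sum (Mann-Whitney) test of each feature, cluster versus all other
#' donors, run on both modality matrices; BH-corrected with effect direction.
#' Singleton clusters are skipped with a warning.
#'
#' @param clusters integer memberships.
#' @param matrices named list of donors x features matrices.
#' @param max_features cap per matrix (highest-variance features; default all).
#' @return data.frame cluster, modality, feature, statistic, direction
#'   (`up`/`down` by mean difference), p, q.
#' @export
find_markers <- function(clusters, matrices, max_features = NULL) {
  rows <- list()
  for (cl in sort(unique(clusters))) {
    inc <- clusters == cl
    if (sum(inc) < 2) {
      warning(sprintf("cluster %d is a singleton; markers skipped", cl),
              call. = FALSE)
      next
    }
    for (mod in names(matrices)) {
      mat <- matrices[[mod]]
      feats <- colnames(mat)
      if (!is.null(max_features) && length(feats) > max_features) {
        v <- apply(mat, 2, stats::var)
        feats <- feats[order(v, decreasing = TRUE)[seq_len(max_features)]]
      }
      for (f in feats) {
        x <- mat[inc, f]; y <- mat[!inc, f]
        if (stats::var(c(x, y)) == 0) next
        tst <- mwu_test(x, y)
        rows[[length(rows) + 1]] <- data.frame(
          cluster = cl, modality = mod, feature = f, statistic = tst$U,
          direction = if (mean(x) >= mean(y)) "up" else "down",
          p = tst$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$q <- bh_fdr(out$p)
  out[order(out$cluster, out$q), ]
}

#' Cluster a donor cohort from trajectories
#'
#' Full pipeline: build the flattened and temporal matrices, normalize and
#' reduce each, compute per-donor modality weights, cluster the joint
#' neighbor graph with Leiden, and embed in two dimensions for display.
#'
#' @param trajectory long observation data.frame (with ages).
#' @param donor_ids donors to cluster.
#' @param modalities subset of `c("flattened", "temporal")`.
#' @param n_pcs PCs per modality.
#' @param k neighbors.
#' @param resolution Leiden modularity resolution (default 0.8).
#' @param seed integer seed.
#' @param equal_weights see [wnn_graph()].
#' @param compute_embedding set `FALSE` to skip the 2-D display embedding.
#' @param ... passed to [build_matrices()].
#' @return a `subtype_result`: clusters, weights, matrices, embeddings,
#'   layout, parameters.
#' @export
cluster_cohort <- function(trajectory, donor_ids,
                           modalities = c("flattened", "temporal"),
                           n_pcs = 30, k = 20, resolution = 0.8, seed = 1,
                           equal_weights = FALSE, compute_embedding = TRUE,
                           ...) {
  modalities <- match.arg(modalities, several.ok = TRUE)
  mats <- build_matrices(trajectory, donor_ids, ...)
  mats_used <- mats[modalities]
  red <- lapply(mats_used, normalize_scale_pca, n_pcs = n_pcs)
  embeddings <- lapply(red, `[[`, "embedding")
  wnn <- wnn_graph(embeddings, k = k, equal_weights = equal_weights)
  clusters <- cluster_graph(wnn$graph, resolution = resolution, seed = seed)
  layout <- NULL
  if (compute_embedding) {
    joint <- do.call(cbind, embeddings)
    layout <- embed_2d(joint, seed = seed)
    rownames(layout) <- donor_ids
  }
  structure(list(donor_ids = donor_ids, clusters = clusters,
                 weights = wnn$weights, matrices = mats,
                 embeddings = embeddings, layout = layout,
                 parameters = list(modalities = modalities, n_pcs = n_pcs,
                                   k = k, resolution = resolution,
                                   seed = seed,
                                   equal_weights = equal_weights)),
            class = "subtype_result")
}

#' @export
print.subtype_result <- function(x, ...) {
  tab <- table(x$clusters)
  cat(sprintf("Subtype clustering: %d donors in %d clusters (sizes %s); modalities: %s\n",
              length(x$donor_ids), length(tab),
              paste(as.integer(tab), collapse = ", "),
              paste(x$parameters$modalities, collapse = " + ")))
  invisible(x)
}

#' Subcluster one cluster of a subtype result
#'
#' Re-runs the full pipeline on the donors of one cluster. When the requested
#' neighbor count is too large for the subset it is shrunk with a warning.
#'
#' @param result a `subtype_result`.
#' @param cluster cluster id to refine.
#' @param trajectory the trajectory the result was built from.
#' @param ... overrides passed to [cluster_cohort()].
#' @return a `subtype_result` over the subset.
#' @export
subcluster <- function(result, cluster, trajectory, ...) {
  ids <- result$donor_ids[result$clusters == cluster]
  if (length(ids) < 3) {
    nt_stop("cluster too small to subcluster", "neurotraj_validation_error")
  }
  args <- utils::modifyList(result$parameters, list(...))
  k <- args$k %||% 20
  if (k >= length(ids)) {
    k <- max(2, length(ids) - 1)
    warning(sprintf("neighbor count shrunk to %d for a %d-donor subset",
                    k, length(ids)), call. = FALSE)
  }
  cluster_cohort(trajectory, ids, modalities = args$modalities,
                 n_pcs = args$n_pcs, k = k, resolution = args$resolution,
                 seed = args$seed, equal_weights = args$equal_weights)
}
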