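test_that("modality matrices count lifetime and binned observations", {
  traj <- data.frame(
    donor_id = c("d1", "d1", "d1", "d2"),
    year = c(2000L, 2001L, 2010L, 2005L),
    age = c(60L, 61L, 70L, 44L),
    attribute_id = c("tremor", "tremor", "falls", "tremor"),
    present = 1L, imputed = FALSE, stringsAsFactors = FALSE)
  mats <- build_matrices(traj, c("d1", "d2"), bin_width = 30, bin_step = 5,
                         age_range = c(40, 75))
  expect_equal(mats$flattened["d1", "tremor"], 2)
  expect_equal(mats$flattened["d1", "falls"], 1)
  expect_equal(mats$flattened["d2", "tremor"], 1)
  # bins are half-open [start, start + width): age 70 is NOT in 40-70
  expect_equal(unname(mats$temporal["d1", "falls@40_70"]), 0)
  expect_equal(unname(mats$temporal["d1", "falls@45_75"]), 1)
  expect_equal(unname(mats$temporal["d2", "tremor@40_70"]), 1)
  # age 44 misses the [45, 75) bin
  expect_equal(unname(mats$temporal["d2", "tremor@45_75"]), 0)
  expect_equal(nrow(mats$bins), 2)
})

test_that("normalization drops zero-variance features and fixes PC signs", {
  set.seed(3)
  counts <- cbind(matrix(rpois(60, 3), 20), constant = 0)
  rownames(counts) <- sprintf("d%02d", 1:20)
  colnames(counts)[1:3] <- c("a", "b", "c")
  red <- normalize_scale_pca(counts, n_pcs = 3)
  expect_false("constant" %in% red$kept)
  expect_equal(ncol(red$embedding), 3)
  red2 <- normalize_scale_pca(counts, n_pcs = 3)
  expect_identical(red$embedding, red2$embedding)
  expect_error(normalize_scale_pca(matrix(1, 4, 2)),
               class = "neurotraj_validation_error")
})

test_that("weighted-nearest-neighbor weights are a per-donor softmax", {
  set.seed(6)
  e1 <- matrix(rnorm(40 * 3), 40)
  e2 <- matrix(rnorm(40 * 3), 40)
  rownames(e1) <- rownames(e2) <- sprintf("d%02d", 1:40)
  wnn <- wnn_graph(list(flattened = e1, temporal = e2), k = 10)
  expect_equal(rowSums(wnn$weights), rep(1, 40))
  expect_true(all(wnn$weights > 0))
  expect_s3_class(wnn$graph, "igraph")
  eq <- wnn_graph(list(flattened = e1, temporal = e2), k = 10,
                  equal_weights = TRUE)
  expect_equal(unname(eq$weights), matrix(0.5, 40, 2))
})

test_that("Fisher overrepresentation matches the hand oracle", {
  clusters <- rep(c(1L, 2L), each = 5)
  labels <- rep(c("X", "Y"), each = 5)
  out <- fisher_overrepresentation(clusters, labels)
  # 5-of-5 X donors inside cluster 1 out of 5-of-10 overall: p = 1/252
  row <- out[out$cluster == 1 & out$label == "X", ]
  expect_equal(row$p, 1 / 252)
  expect_true(all(out$q >= out$p - 1e-12))
  two <- fisher_overrepresentation(clusters, labels,
                                   alternative = "two.sided")
  expect_equal(two$p[two$cluster == 1 & two$label == "X"], 2 / 252)
})

test_that("marker detection skips singletons and reports directions", {
  set.seed(9)
  m <- matrix(rpois(30 * 4, 2), 30,
              dimnames = list(NULL, c("up_attr", "b", "c", "d")))
  clusters <- c(rep(1L, 15), rep(2L, 14), 3L)
  m[clusters == 1, "up_attr"] <- m[clusters == 1, "up_attr"] + 6
  expect_warning(mk <- find_markers(clusters, list(flattened = m)),
                 "singleton")
  top <- mk[mk$cluster == 1 & mk$feature == "up_attr", ]
  expect_equal(top$direction, "up")
  expect_lt(top$q, 0.01)
  expect_false(3L %in% mk$cluster)
})

test_that("the clustering pipeline separates planted diagnosis groups", {
  fl <- filter_cohort(nt_cohort$donors, nt_trajectory, "clustering")
  dm <- nt_cohort$donors[nt_cohort$donors$donor_id %in% fl$selected, ]
  trf <- nt_trajectory[nt_trajectory$donor_id %in% dm$donor_id, ]
  res <- cluster_cohort(trf, dm$donor_id, seed = 2,
                        compute_embedding = FALSE)
  expect_equal(length(res$clusters), nrow(dm))
  expect_gt(length(unique(res$clusters)), 2)
  # deterministic under the seed
  res2 <- cluster_cohort(trf, dm$donor_id, seed = 2,
                         compute_embedding = FALSE)
  expect_identical(res$clusters, res2$clusters)
  # clusters reflect diagnoses far better than chance
  expect_gt(nt_ari(res$clusters, dm$nd_codes), 0.3)
  # the 2-D embedding has one row per donor
  lay <- embed_2d(res$embeddings$flattened, seed = 1)
  expect_equal(dim(lay), c(nrow(dm), 2))
})

test_that("subclustering re-runs on the subset and shrinks k if needed", {
  fl <- filter_cohort(nt_cohort$donors, nt_trajectory, "clustering")
  dm <- nt_cohort$donors[nt_cohort$donors$donor_id %in% fl$selected, ]
  trf <- nt_trajectory[nt_trajectory$donor_id %in% dm$donor_id, ]
  res <- cluster_cohort(trf, dm$donor_id, seed = 2,
                        compute_embedding = FALSE)
  small <- as.integer(names(sort(table(res$clusters)))[1])
  if (sum(res$clusters == small) < 3) small <- res$clusters[1]
  sub <- suppressWarnings(subcluster(res, small, trf,
                                     compute_embedding = FALSE))
  expect_s3_class(sub, "subtype_result")
  expect_setequal(sub$donor_ids, res$donor_ids[res$clusters == small])
})
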