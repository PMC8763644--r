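two_batch_blobs <- function(sep = 6, n_per = 60, sd = 0.3, seed = 31) {
  # two cell types; batches perfectly mixed inside each type
  centers <- rbind(c(0, 0), c(sep, 0))
  emb <- make_blobs(centers, n_per = n_per, sd = sd, seed = seed,
                    batch = c("b1", "b2"))
  emb
}

test_that("entropy of batch mixing hits its analytic anchors", {
  # pure regions: batches fully separated -> 0
  sep <- make_blobs(rbind(c(0, 0), c(50, 0)), n_per = 40, sd = 0.2, seed = 1)
  sep$cell_meta$study <- rep(c("b1", "b2"), each = 40)
  expect_equal(as.numeric(entropy_batch_mixing(sep, k = 15, seed = 3)), 0)
  # alternating batches along a line: every 15-neighbourhood is a near-even
  # two-batch mix (7/8 at worst), so the base-2 entropy is close to 1
  line <- latent_embedding(cbind(seq_len(200), 0),
                           data.frame(cell_id = paste0("c", 1:200),
                                      study = rep(c("b1", "b2"), 100)))
  expect_gte(as.numeric(entropy_batch_mixing(line, k = 15, seed = 3)), 0.98)
  expect_error(entropy_batch_mixing(sep, batch_labels = rep("b1", 80)),
               "two batches")
})

test_that("entropy of batch mixing equals a brute-force oracle", {
  set.seed(37)
  coords <- matrix(rnorm(120 * 3), 120)
  batch <- sample(c("b1", "b2", "b3"), 120, replace = TRUE)
  ours <- entropy_batch_mixing(coords, batch, k = 15, n_draws = 50, seed = 7)
  expect_equal(as.numeric(ours), oracle_ebm(coords, batch, k = 15,
                                            n_draws = 50, seed = 7),
               tolerance = 1e-12)
  expect_true(is.numeric(attr(ours, "mc_se")))
})

test_that("silhouette scores match the oracle and their affine transforms", {
  set.seed(41)
  coords <- rbind(matrix(rnorm(60, 0, 1), 30, 2),
                  matrix(rnorm(60, 4, 1), 30, 2))
  types <- rep(c("A", "B"), each = 30)
  raw <- oracle_silhouette_mean(coords, types)
  expect_equal(asw_celltype(coords, types), (raw + 1) / 2, tolerance = 1e-12)
  # well separated tight clusters approach 1; labels interleaved across both
  # clusters make the grouping uninformative (raw silhouette near 0 -> 0.5)
  tight <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
                 matrix(rnorm(40, 10, 0.1), 20, 2))
  expect_gt(asw_celltype(tight, rep(c("A", "B"), each = 20)), 0.95)
  expect_equal(asw_celltype(tight, rep(c("A", "B"), 20)), 0.5,
               tolerance = 0.05)
})

test_that("batch silhouette rewards mixing and punishes separation", {
  mixed <- two_batch_blobs()
  expect_gt(asw_batch(mixed), 0.9)
  # batches separated inside each type: raw |ASW| near 1 -> score near 0
  bad <- mixed
  ord <- order(bad$cell_meta$cell_type, bad$coords[, 2])
  # move batch b2 cells of each type far away
  shift <- bad$cell_meta$study == "b2"
  bad$coords[shift, 2] <- bad$coords[shift, 2] + 50
  expect_lt(asw_batch(bad), 0.1)
  # oracle agreement on one type's cells
  ct <- mixed$cell_meta$cell_type
  i <- ct == "t1"
  raw <- oracle_silhouette_mean(mixed$coords[i, ], mixed$cell_meta$study[i])
  only1 <- latent_embedding(mixed$coords[i, ], mixed$cell_meta[i, ])
  expect_equal(asw_batch(only1), 1 - abs(raw), tolerance = 1e-12)
})

test_that("NMI matches the entropy oracle and its degenerate conventions", {
  a <- rep(c("x", "y", "z"), times = c(10, 15, 5))
  expect_equal(nmi_score(a, a), 1)
  expect_equal(nmi_score(a, rep("k", 30)), 0)
  set.seed(43)
  b <- sample(1:4, 30, replace = TRUE)
  expect_equal(nmi_score(a, b), oracle_nmi(a, b), tolerance = 1e-12)
  # independent labelings at large n drift to zero
  set.seed(44)
  big_a <- sample(1:4, 2000, replace = TRUE)
  big_b <- sample(1:4, 2000, replace = TRUE)
  expect_lt(nmi_score(big_a, big_b), 0.05)
})

test_that("ARI matches pair-counting oracles", {
  a <- c(1, 1, 1, 2, 2, 3)
  b <- c(1, 1, 2, 2, 3, 3)
  expect_equal(as.numeric(ari_score(a, a)), 1)
  expect_equal(attr(ari_score(a, b), "raw"), oracle_ari(a, b),
               tolerance = 1e-12)
  skip_if_not_installed("mclust")
  expect_equal(attr(ari_score(a, b), "raw"),
               mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  set.seed(47)
  x <- sample(1:3, 40, replace = TRUE)
  y <- sample(1:3, 40, replace = TRUE)
  expect_equal(attr(ari_score(x, y), "raw"), mclust::adjustedRandIndex(x, y),
               tolerance = 1e-12)
  expect_gte(as.numeric(ari_score(x, y)), 0)
})

test_that("PC regression isolates batch variance", {
  set.seed(53)
  n <- 200
  batch <- rep(c("b1", "b2"), each = n / 2)
  # batch-independent data: score near 1
  x0 <- matrix(rnorm(n * 10), n)
  expect_gt(as.numeric(pc_regression(x0, batch, n_pcs = 10)), 0.95)
  # first PC exactly the batch indicator: score = 1 - Var(PC1)/sum(Var)
  ind <- ifelse(batch == "b1", 10, -10)
  x1 <- cbind(ind, matrix(rnorm(n * 5, 0, 1), n))
  res <- pc_regression(x1, batch, n_pcs = 6)
  vars <- prcomp(x1)$sdev[1:6]^2
  expect_equal(as.numeric(res), 1 - vars[1] / sum(vars), tolerance = 0.02)
  # shuffling batch labels cannot increase explained variance
  set.seed(54)
  shuf <- sample(batch)
  expect_gte(as.numeric(pc_regression(x1, shuf, n_pcs = 6)),
             as.numeric(res))
})

test_that("graph connectivity scores split and intact labels", {
  # one tight blob per label -> 1
  good <- make_blobs(rbind(c(0, 0), c(8, 0)), n_per = 30, sd = 0.3, seed = 57)
  expect_equal(graph_connectivity(good, k_graph = 5), 1)
  # one label split into two far halves disconnects its kNN subgraph
  split_coords <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
                        matrix(rnorm(40, 100, 0.2), 20, 2))
  lab <- rep("t1", 40)
  expect_equal(graph_connectivity(split_coords, lab, k_graph = 5), 0.5)
  expect_equal(oracle_lcc_fraction(split_coords, k = 5), 0.5)
  # arithmetic mean across labels: contributions 1 and 0.5 give 0.75
  coords <- rbind(split_coords, matrix(rnorm(40, 50, 0.2), 20, 2))
  labs <- c(lab, rep("t2", 20))
  expect_equal(graph_connectivity(coords, labs, k_graph = 5), 0.75)
})

test_that("isolated label F1 follows direct precision/recall arithmetic", {
  # 60 cells, label L only in batch b1 (others span both batches)
  ct <- c(rep("L", 20), rep("M", 40))
  batch <- c(rep("b1", 20), rep(c("b1", "b2"), 20))
  coords <- matrix(rnorm(120), 60)
  # cluster equals the label exactly -> 1
  cl_exact <- c(rep(1, 20), rep(2, 40))
  expect_equal(isolated_label_f1(coords, ct, batch, cl_exact), 1)
  # cluster captures half the label, nothing else: precision 1, recall 0.5
  cl_half <- c(rep(1, 10), rep(2, 10), rep(2, 40))
  expect_equal(isolated_label_f1(coords, ct, batch, cl_half), 2 / 3)
  # best cluster dominated by other labels: low F1
  cl_mix <- c(rep(1, 20), rep(1, 40))
  expect_equal(isolated_label_f1(coords, ct, batch, cl_mix),
               2 * (20 / 60) * 1 / (20 / 60 + 1))
})

test_that("isolated label silhouette mirrors the cell-type transform", {
  ct <- c(rep("L", 25), rep("M", 25))
  batch <- c(rep("b1", 25), rep(c("b1", "b2"), length.out = 25))
  coords <- rbind(matrix(rnorm(50, 0, 0.5), 25, 2),
                  matrix(rnorm(50, 6, 0.5), 25, 2))
  raw <- oracle_silhouette_mean(coords, ct, subset = ct == "L")
  expect_equal(isolated_label_silhouette(coords, ct, batch), (raw + 1) / 2,
               tolerance = 1e-12)
  expect_gt(isolated_label_silhouette(coords, ct, batch), 0.9)
})

test_that("kNN accuracy macro-averages per-cell purity", {
  pure <- make_blobs(rbind(c(0, 0), c(9, 0)), n_per = 25, sd = 0.3, seed = 61)
  expect_equal(knn_accuracy(pure, k = 10), 1)
  # fully interleaved equal types hover near one half
  set.seed(62)
  coords <- matrix(rnorm(400), 200)
  labs <- rep(c("A", "B"), 100)
  expect_equal(knn_accuracy(coords, labs, k = 15), 0.5, tolerance = 0.06)
  # 30-cell fixture vs the loop oracle (includes a rare type)
  set.seed(63)
  c30 <- matrix(rnorm(60), 30)
  l30 <- c(rep("A", 20), rep("B", 7), rep("C", 3))
  expect_equal(knn_accuracy(c30, l30, k = 5),
               oracle_knn_accuracy(c30, l30, k = 5), tolerance = 1e-12)
})

test_that("report aggregation uses the 40:60 weighting and min-max scaling", {
  batch_half <- setNames(rep(0.5, 4),
                         c("EBM", "ASW_batch", "PCR", "graph_connectivity"))
  bio_one <- setNames(rep(1, 6),
                      c("NMI", "ARI", "ASW_celltype", "kNN_accuracy",
                        "isolated_F1", "isolated_silhouette"))
  rep1 <- scgraft:::make_metric_report(c(batch_half, bio_one))
  expect_equal(rep1$overall, 0.4 * 0.5 + 0.6 * 1)
  # single model: identity scaling
  agg1 <- aggregate_report(list(m1 = rep1))
  expect_equal(agg1$overall, 0.8)
  expect_equal(unlist(agg1[1, names(batch_half)]), batch_half)
  # two models: each varying metric min-max scaled to {0, 1}
  rep2 <- scgraft:::make_metric_report(c(batch_half + 0.2, bio_one - 0.5))
  agg2 <- aggregate_report(list(worse = rep1, better = rep2))
  expect_equal(agg2["worse", "EBM"], 0)
  expect_equal(agg2["better", "EBM"], 1)
  expect_equal(agg2["worse", "NMI"], 1)
  expect_equal(agg2["better", "overall"], 0.4 * 1 + 0.6 * 0)
})

test_that("metrics are invariant under rotation and label renaming", {
  emb <- two_batch_blobs(seed = 67)
  R <- random_rotation(2, seed = 3)
  rot <- rotate_embedding(emb, R)
  expect_equal(as.numeric(entropy_batch_mixing(emb, seed = 5)),
               as.numeric(entropy_batch_mixing(rot, seed = 5)),
               tolerance = 1e-9)
  expect_equal(asw_celltype(emb$coords, emb$cell_meta$cell_type),
               asw_celltype(rot$coords, rot$cell_meta$cell_type),
               tolerance = 1e-9)
  expect_equal(graph_connectivity(emb), graph_connectivity(rot))
  expect_equal(knn_accuracy(emb), knn_accuracy(rot))
  # category renaming leaves partition metrics unchanged
  a <- rep(c("x", "y", "z"), 10)
  b <- rep(c(1, 1, 2), 10)
  ren <- c(x = "beta", y = "alpha", z = "delta")[a]
  expect_equal(nmi_score(a, b), nmi_score(ren, b))
  expect_equal(as.numeric(ari_score(a, b)), as.numeric(ari_score(ren, b)))
})

test_that("the full report runs on a small integrated embedding", {
  emb <- two_batch_blobs(n_per = 80, seed = 71)
  rep <- evaluate_integration(emb, seed = 9)
  expect_length(rep$scores, 10)
  expect_true(all(rep$scores >= 0 & rep$scores <= 1))
  expect_equal(rep$overall, 0.4 * rep$batch_score + 0.6 * rep$bio_score)
  # well-separated types, mixed batches: high marks across the board
  expect_gt(rep$scores["ASW_celltype"], 0.9)
  expect_gt(rep$scores["EBM"], 0.9)
  expect_equal(as.numeric(rep$scores["graph_connectivity"]), 1)
})
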