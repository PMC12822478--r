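two_block_matrix <- function(n_per = 20, n_feat = 60, shift = 4, sd = 0.5, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n_feat * 2 * n_per, sd = sd), n_feat)
  v[seq_len(n_feat / 2), seq_len(n_per)] <- v[seq_len(n_feat / 2), seq_len(n_per)] + shift
  toy_matrix(v, samples = sprintf("S%02d", seq_len(2 * n_per)))
}

test_that("well-separated blocks give a clean consensus and perfect recovery", {
  m <- two_block_matrix()
  res <- consensus_cluster(m, feature_ids(m), k_range = 2:3, n_iter = 40,
                           seed = 5, store_assignments = TRUE)
  truth <- rep(c(1, 2), each = 20)
  names(truth) <- sample_ids(m)
  expect_equal(adjusted_rand(res$labels[["2"]], truth), 1)
  cm <- res$consensus[["2"]]
  expect_true(all(abs(cm - t(cm)) < 1e-12, na.rm = TRUE))
  expect_equal(unname(diag(cm)), rep(1, 40))
  expect_gt(within_cluster_consensus(res, 2), 0.99)
})

test_that("consensus entries equal brute-force co-cluster / co-sample tallies", {
  m <- two_block_matrix(n_per = 10, seed = 2)
  res <- consensus_cluster(m, feature_ids(m), k_range = 2:2, n_iter = 25,
                           seed = 8, store_assignments = TRUE)
  n <- 20
  co_cl <- matrix(0, n, n); co_sa <- matrix(0, n, n)
  for (a in res$assignments) {
    co_sa[a$idx, a$idx] <- co_sa[a$idx, a$idx] + 1
    cl <- a$clusters[["2"]]
    co_cl[a$idx, a$idx] <- co_cl[a$idx, a$idx] + outer(cl, cl, "==")
  }
  expected <- co_cl / pmax(co_sa, 1)
  expected[co_sa == 0] <- NA
  diag(expected) <- 1
  observed <- res$consensus[["2"]]
  dimnames(expected) <- dimnames(observed)
  expect_equal(observed, expected, tolerance = 1e-12)
})

test_that("a single Gaussian blob is flagged as unstable at k = 2", {
  set.seed(13)
  m <- toy_matrix(matrix(rnorm(60 * 40), 60, 40))
  res <- consensus_cluster(m, feature_ids(m), k_range = 2:2, n_iter = 80, seed = 14)
  expect_lt(within_cluster_consensus(res, 2), 0.8)
})

test_that("k selection recovers planted 2- and 3-block structure", {
  m2 <- two_block_matrix(n_per = 15, seed = 21)
  res2 <- consensus_cluster(m2, feature_ids(m2), k_range = 2:4, n_iter = 40, seed = 22)
  expect_equal(select_k(res2)$k, 2)
  set.seed(23)
  v <- matrix(rnorm(60 * 30, sd = 0.5), 60, 30)
  v[1:20, 1:10] <- v[1:20, 1:10] + 4
  v[21:40, 11:20] <- v[21:40, 11:20] + 4
  m3 <- toy_matrix(v)
  res3 <- consensus_cluster(m3, feature_ids(m3), k_range = 2:4, n_iter = 40, seed = 24)
  expect_equal(select_k(res3)$k, 3)
  # override contract
  forced <- select_k(res3, override_k = 2)
  expect_equal(forced$k, 2)
  expect_equal(length(unique(forced$labels)), 2)
})

test_that("consensus labels are invariant to sample input order", {
  m <- two_block_matrix(n_per = 12, seed = 31)
  res_a <- consensus_cluster(m, feature_ids(m), k_range = 2:2, n_iter = 30, seed = 32)
  perm <- sample(sample_ids(m))
  m_perm <- subset_omics(m, samples = perm)
  res_b <- consensus_cluster(m_perm, feature_ids(m), k_range = 2:2, n_iter = 30, seed = 33)
  expect_equal(adjusted_rand(res_a$labels[["2"]],
                             res_b$labels[["2"]][names(res_a$labels[["2"]])]), 1)
})

test_that("canonical labels follow the metabolism-score convention", {
  m <- two_block_matrix(n_per = 10, seed = 41)
  # give the second feature block its own shift in the second sample group
  m$values[31:60, 11:20] <- m$values[31:60, 11:20] + 4
  labels <- stats::setNames(rep(c(1, 2), each = 10), sample_ids(m))
  # features F01..F30 are high in samples S01..S10 (cluster 1)
  lab <- canonical_subtype_labels(labels, m, metabolism_set = feature_ids(m)[1:30])
  expect_equal(unname(lab[1]), "C1")
  expect_equal(unname(lab[20]), "C2")
  # a metabolism set matching the other block flips the naming
  lab2 <- canonical_subtype_labels(labels, m, metabolism_set = feature_ids(m)[31:60])
  expect_equal(unname(lab2[1]), "C2")
  # without a set, the larger cluster is C1
  labels_uneven <- stats::setNames(rep(c(1, 2), c(5, 15)), sample_ids(m))
  expect_equal(unname(canonical_subtype_labels(labels_uneven)[20]), "C1")
})

test_that("subtypes are recovered on a synthetic LM cohort", {
  b <- generate_cohort(small_cohort_config(801, n_patients = 40))
  prot <- normalized_layers(b)$protein
  lm <- tissue_samples(b$clinical, "LM")
  feats <- suppressWarnings(mad_select(prot, 1, samples = lm))
  expect_gt(length(feats), 20)
  res <- consensus_cluster(prot, feats, samples = lm, k_range = 2:2,
                           n_iter = 100, seed = 802)
  truth <- b$truth$subtype[sub("_LM$", "", lm)]
  names(truth) <- lm
  expect_gte(adjusted_rand(res$labels[["2"]], truth), 0.9)
})
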