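make_two_group_sim <- function(seed = 21, fold = 6, n_genes = 200,
                               cells = 150) {
  cfg <- sc_sim_config(n_clusters = 1, cells_per_cluster = cells,
                       n_genes = n_genes, base_mean = 2, dispersion = 2,
                       circadian_genes = lapply(1:30, function(i)
                         list(gene = i, fold = fold)),
                       condition_fractions = c(CT7.5 = 0.5, CT15.5 = 0.5),
                       seed = seed)
  simulate_sc_counts(cfg)
}

test_that("well-separated synthetic conditions are recovered exactly (ARI 1)", {
  skip_if_not_installed("mclust")
  sim <- make_two_group_sim(fold = 8)
  norm <- normalize_counts(sim$matrix)
  a <- cluster_cells(norm, k = 2, method = "kmeans", seed = 4)
  expect_equal(ari(a$labels, sim$truth$condition), 1.0)
  # determinism under a fixed seed
  a2 <- cluster_cells(norm, k = 2, method = "kmeans", seed = 4)
  expect_identical(a$labels, a2$labels)
  # labels contiguous starting at 1
  expect_setequal(unique(a$labels), 1:2)
})

test_that("k = 1 yields a single label and k > n cells errors", {
  sim <- make_two_group_sim(cells = 20, n_genes = 50)
  norm <- normalize_counts(sim$matrix)
  a <- cluster_cells(norm, k = 1, method = "graph", seed = 1)
  expect_true(all(a$labels == 1L))
  expect_error(cluster_cells(norm, k = 1000, seed = 1), "exceeds")
})

test_that("condition coverage reproduces the purity arithmetic", {
  labels <- rep(c(1, 2), each = 500)
  conds <- c(rep("CT15.5", 494), rep("CT7.5", 6), rep("CT7.5", 500))
  cov <- condition_coverage(mk_assign(labels), conds)
  expect_equal(cov$purity_pct[cov$cluster == 1], 98.8)
  expect_equal(cov$majority_condition, c("CT15.5", "CT7.5"))
  expect_equal(cov$purity_pct[cov$cluster == 2], 100)

  # uniform mixing approaches 50%
  set.seed(6)
  conds2 <- sample(c("A", "B"), 4000, replace = TRUE)
  cov2 <- condition_coverage(mk_assign(rep(1, 4000)), conds2)
  expect_lt(cov2$purity_pct, 53)
})

test_that("exact test matches a brute-force enumeration oracle on tiny data", {
  # equal library sizes so size factors are 1 and normalized counts are raw
  counts <- rbind(c(3L, 5L, 1L, 0L),
                  c(7L, 5L, 9L, 10L))
  m <- mk_counts(counts)
  phi <- 0.5
  de <- nb_exact_test(m, 1:2, 3:4, dispersion = phi)

  # oracle: condition on the gene total, enumerate all splits of it between
  # the group sums, accumulate the probabilities of splits no more likely
  # than the observed one
  oracle <- function(ya, yb, na, nb, phi) {
    tot <- ya + yb
    mu <- tot / (na + nb)
    pr <- sapply(0:tot, function(s)
      dnbinom(s, mu = na * mu, size = na / phi) *
        dnbinom(tot - s, mu = nb * mu, size = nb / phi))
    sum(pr[pr <= pr[ya + 1] * (1 + 1e-8)]) / sum(pr)
  }
  expect_equal(de$p_value[1], oracle(8, 1, 2, 2, phi), tolerance = 1e-12)
  expect_equal(de$p_value[2], oracle(12, 19, 2, 2, phi), tolerance = 1e-12)
})

test_that("group swap negates log2fc and preserves p-values", {
  sim <- make_two_group_sim(seed = 30, fold = 3, n_genes = 80, cells = 60)
  ca <- which(sim$truth$condition == "CT7.5")
  cb <- which(sim$truth$condition == "CT15.5")
  d1 <- nb_exact_test(sim$matrix, ca, cb)
  d2 <- nb_exact_test(sim$matrix, cb, ca)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-12)
  expect_equal(d1$log2fc, -d2$log2fc, tolerance = 1e-12)
})

test_that("all-zero genes get p = 1 and log2fc = 0, not an error", {
  counts <- rbind(c(0L, 0L, 0L, 0L), c(4L, 6L, 5L, 5L))
  de <- nb_exact_test(mk_counts(counts), 1:2, 3:4, dispersion = 0.5)
  expect_equal(de$p_value[1], 1)
  expect_equal(de$log2fc[1], 0)
})

test_that("p-values are invariant to rescaling the size factors", {
  sim <- make_two_group_sim(seed = 31, fold = 1, n_genes = 60, cells = 40)
  ca <- which(sim$truth$condition == "CT7.5")
  cb <- which(sim$truth$condition == "CT15.5")
  sf <- Matrix::colSums(sim$matrix$counts[, c(ca, cb)])
  d1 <- nb_exact_test(sim$matrix, ca, cb, size_factors = sf)
  d2 <- nb_exact_test(sim$matrix, ca, cb, size_factors = sf * 7)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-12)
})

test_that("adjusted p-values equal the textbook BH step-up", {
  sim <- make_two_group_sim(seed = 32, fold = 2, n_genes = 50, cells = 40)
  ca <- which(sim$truth$condition == "CT7.5")
  cb <- which(sim$truth$condition == "CT15.5")
  de <- nb_exact_test(sim$matrix, ca, cb)
  expect_equal(de$p_adj, bh_stepup(de$p_value), tolerance = 1e-12)
  expect_true(all(de$p_adj >= de$p_value))
})

test_that("planted markers top the one-vs-rest ranking", {
  cfg <- sc_sim_config(
    n_clusters = 2, cells_per_cluster = 150, n_genes = 100, base_mean = 2,
    axis_programs = list(list(ligand = 7, receptor = 8, source_clusters = 1,
                              target_clusters = 2, fold_up = 10)),
    condition_fractions = c(CT7.5 = 1), seed = 33)
  sim <- simulate_sc_counts(cfg)
  mk <- top_markers(sim$matrix, mk_assign(sim$truth$cluster), n_top = 5)
  expect_equal(mk[["1"]]$gene[1], "g0007")
  expect_equal(mk[["2"]]$gene[1], "g0008")
  expect_lte(nrow(mk[["1"]]), 5)
})

test_that("identical clusters yield empty marker lists", {
  cfg <- sc_sim_config(n_clusters = 1, cells_per_cluster = 120, n_genes = 60,
                       base_mean = 3, condition_fractions = c(A = 1),
                       seed = 34)
  sim <- simulate_sc_counts(cfg)
  labels <- rep(1:2, each = 60)
  mk <- top_markers(sim$matrix, mk_assign(labels), n_top = 5)
  expect_true(all(vapply(mk, nrow, integer(1)) <= 2))  # chance hits only
  # n_top larger than passing genes returns what passes
  mk2 <- top_markers(sim$matrix, mk_assign(labels), n_top = 1000)
  expect_true(all(vapply(mk2, nrow, integer(1)) < 1000))
})
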