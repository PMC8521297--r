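test_that("positivity rules behave as specified", {
  mat <- matrix(0L, 2, 4)
  mat[1, ] <- c(0L, 1L, 5L, 10L)
  m <- mk_counts(mat, genes = c("Prok2", "Grp"))

  expect_identical(positive_cells(m, "Prok2", "nonzero"),
                   c("cell02", "cell03", "cell04"))
  # range rule: threshold = 0 + 0.9 * 10 = 9, only the 10-count cell passes
  expect_identical(positive_cells(m, "Prok2", "range_fraction", q = 0.9),
                   "cell04")
  # monotone: the q = 0.9 set is contained in the q = 0.5 set
  p9 <- positive_cells(m, "Prok2", "range_fraction", q = 0.9)
  p5 <- positive_cells(m, "Prok2", "range_fraction", q = 0.5)
  expect_true(all(p9 %in% p5))
  # absent everywhere: empty under both rules
  expect_length(positive_cells(m, "Grp", "nonzero"), 0)
  expect_length(positive_cells(m, "Grp", "range_fraction"), 0)
  expect_error(positive_cells(m, "Vip"), "not present")
})

test_that("overlap summary matches an exhaustive set oracle", {
  set.seed(8)
  for (i in 1:20) {
    a <- sample(letters, sample(0:15, 1))
    b <- sample(letters, sample(1:15, 1))
    s <- suppressWarnings(overlap_summary(list(A = a, B = b)))
    ni <- sum(a %in% b)
    expect_equal(s$pairs$n_intersect, ni)
    expect_equal(s$pairs$pct_a_in_b,
                 if (length(a)) 100 * ni / length(a) else 0)
    expect_equal(s$pairs$pct_b_in_a, 100 * ni / length(b))
    expect_lte(s$pairs$n_intersect, min(s$pairs$n_a, s$pairs$n_b))
  }
  # A subset of B: 100% of A in B; disjoint: all zero
  s2 <- overlap_summary(list(A = c("x", "y"), B = c("x", "y", "z")))
  expect_equal(s2$pairs$pct_a_in_b, 100)
  s3 <- overlap_summary(list(A = c("x"), B = c("y")))
  expect_equal(s3$pairs$pct_a_in_b, 0)
  expect_equal(s3$pairs$pct_b_in_a, 0)
})

test_that("ligand share reproduces the printed day-time proportion", {
  expect_equal(round(union_share_pct(683, 886)), 77)
  # same computation from explicit sets
  a <- paste0("c", 1:683)
  b <- paste0("c", 481:886)   # union size 886
  expect_equal(round(union_share_pct(a, b)), 77)
})

test_that("cluster means are the arithmetic mean of raw counts", {
  mat <- matrix(0L, 1, 5)
  mat[1, ] <- c(0L, 0L, 4L, 2L, 2L)
  m <- mk_counts(mat, genes = "Vip")
  a <- mk_assign(c(1, 1, 1, 2, 2))
  expect_equal(unname(cluster_mean_expression(m, a, "Vip")), c(4 / 3, 2))
})

test_that("edge weights are the outer product, rank 1 and bilinear", {
  mL <- c(2, 0, 1); mR <- c(0.5, 1, 0)
  W <- edge_weights(mL, mR)
  expect_equal(W, outer(mL, mR))
  expect_equal(W[1, 2], 2)
  expect_equal(W[1, 1], 1)          # autocrine diagonal retained
  expect_true(all(W[2, ] == 0))
  expect_equal(sum(W), 4.5)
  expect_equal(qr(W)$rank, 1)
  expect_equal(edge_weights(2 * mL, mR), 2 * W)
  expect_error(edge_weights(c(-1, 0), c(1, 1)), "non-negative")
})

test_that("min-max scaling modes behave and joint scaling is comparable", {
  W <- matrix(c(0, 2, 4.5, 1), 2, 2)
  Ws <- scale_weights(W, mode = "per_matrix_minmax")
  expect_equal(Ws[2, 1], 2 / 4.5)
  expect_equal(range(Ws), c(0, 1))

  expect_warning(scale_weights(matrix(3, 2, 2)), "constant")
  expect_equal(suppressWarnings(scale_weights(matrix(3, 2, 2))),
               matrix(0, 2, 2))

  # joint min-max: multiplying both conditions' raw counts by 3 scales W by 9
  # but leaves jointly scaled weights unchanged
  Wd <- matrix(c(0, 1, 3, 2), 2, 2); Wn <- matrix(c(0, 0.5, 1, 0.2), 2, 2)
  s1 <- scale_weights(Wd, Wn)
  s2 <- scale_weights(9 * Wd, 9 * Wn)
  expect_equal(s1, s2)
  # sigma additive over disjoint edge subsets
  expect_equal(network_sigma(Wd), sum(Wd[1, ]) + sum(Wd[2, ]))
})

test_that("source clusters are flagged by enrichment and marker support", {
  expect_equal(unname(identify_source_clusters(c(10, 1, 1, 1))),
               c(TRUE, FALSE, FALSE, FALSE))
  expect_false(any(identify_source_clusters(c(2, 2, 2))))
  # monotone in the enrichment factor
  means <- c(8, 3, 1, 1)
  f3 <- identify_source_clusters(means, factor = 3)
  f2 <- identify_source_clusters(means, factor = 2)
  expect_true(all(which(f3) %in% which(f2)))
})

test_that("day/night comparison detects a dismantled night network", {
  ax <- list(list(ligand = "g0010", receptor = "g0011", source_clusters = 1,
                  target_clusters = 3, fold_up = 10, conditions = "day"))
  cfg <- sc_sim_config(n_clusters = 4, cells_per_cluster = 120, n_genes = 80,
                       base_mean = 1, axis_programs = ax,
                       condition_fractions = c(day = 0.5, night = 0.5),
                       seed = 44)
  sim <- simulate_sc_counts(cfg)
  m <- sim$matrix
  spec <- axis_spec("test", "g0010", "g0011")
  day_sel <- m$cell_meta$condition == "day"
  nd <- axis_network(m[, day_sel], mk_assign(sim$truth$cluster[day_sel]),
                     spec, "day")
  nn <- axis_network(m[, !day_sel], mk_assign(sim$truth$cluster[!day_sel]),
                     spec, "night")
  cmp <- compare_networks(nd, nn)
  expect_gt(cmp$sigma_day, cmp$sigma_night)
  expect_true(cmp$disassembled_at_night)
  W <- cmp$day$W_raw
  expect_equal(unname(which(W == max(W), arr.ind = TRUE)[1, ]), c(1, 3))
  expect_true(nd$source_flags[1])
  expect_false(any(nd$source_flags[-1]))

  # identical networks: delta 0, ratio 1
  cmp0 <- compare_networks(nd, nd)
  expect_equal(cmp0$delta, cmp0$delta * 0)
  expect_equal(cmp0$sigma_ratio, 1)

  # a receptor with zero detected counts yields a zero network, not an error
  zero_net <- nd
  zero_net$W_raw <- nd$W_raw * 0
  cmpz <- compare_networks(nd, zero_net)
  expect_equal(cmpz$sigma_night, 0)
  expect_equal(cmpz$sigma_ratio, 0)
})

test_that("networks export as GraphML and JSON edge lists", {
  mL <- c(2, 1); mR <- c(1, 3)
  net <- structure(list(axis = "toy", condition = "day",
                        clusters = c("A", "B"), means_ligand = mL,
                        means_receptor = mR, W_raw = edge_weights(mL, mR),
                        W_scaled = NULL, sigma = NULL,
                        source_flags = c(A = TRUE, B = FALSE)),
                   class = "axis_network")
  d <- withr::local_tempdir()
  edges <- export_network(net, graphml = file.path(d, "n.graphml"),
                          json = file.path(d, "n.json"))
  expect_equal(nrow(edges), 4)
  g <- igraph::read_graph(file.path(d, "n.graphml"), format = "graphml")
  expect_equal(igraph::gsize(g), 4)
  j <- jsonlite::read_json(file.path(d, "n.json"), simplifyVector = TRUE)
  expect_equal(sort(j$weight_raw), sort(as.numeric(net$W_raw)))
})
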