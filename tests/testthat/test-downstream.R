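cluster_purity <- function(clusters, truth) {
  tab <- table(clusters, truth)
  sum(apply(tab, 1, max)) / sum(tab)
}

test_that("novel-cell clustering separates two planted types", {
  d <- cached("downstream_data", generate_scenario(downstream_scenario(),
                                                   seed = 0))
  idx <- which(d$query_novel)
  novel_m <- cellnovelty:::subset_matrix(d$query, idx)
  cl <- cluster_novel(novel_m, k = 15, resolution = 0.3, n_pcs = 10,
                      seed = 0)
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_identical(sort(unique(cl$cluster)), c(0L, 1L))
  expect_gte(cluster_purity(cl$cluster, d$query_labels[idx]), 0.95)

  # cell order must not change the partition (up to label names)
  set.seed(1)
  perm <- sample(seq_along(idx))
  cl_perm <- cluster_novel(cellnovelty:::subset_matrix(novel_m, perm),
                           k = 15, resolution = 0.3, n_pcs = 10, seed = 0)
  joined <- merge(as.data.frame(cl), as.data.frame(cl_perm),
                  by = "cell_id")
  cross <- table(joined$cluster.x, joined$cluster.y)
  expect_true(all(rowSums(cross > 0) == 1))
})

test_that("degenerate clustering inputs are handled", {
  flat <- expression_matrix(matrix(5, 40, 10))
  cl <- cluster_novel(flat, k = 5, seed = 0)
  expect_identical(unique(cl$cluster), 0L)
  expect_error(cluster_novel(flat, k = 50), "lower `k`")
})

test_that("a planted 8x marker ranks first for its type", {
  sc <- downstream_scenario(n_markers_novel = 1L)
  d <- generate_scenario(sc, seed = 0)
  idx <- which(d$query_novel)
  novel_m <- cellnovelty:::subset_matrix(d$query, idx)
  truth_cluster <- as.integer(d$query_labels[idx] == "n2")
  mk <- rank_marker_genes(novel_m, truth_cluster, top_n = 3)
  sets <- scenario_marker_sets(sc)
  gene_ids <- d$query$gene_ids
  expect_identical(mk$gene_id[mk$cluster == 0 & mk$rank == 1],
                   gene_ids[sets[["n1"]]])
  expect_identical(mk$gene_id[mk$cluster == 1 & mk$rank == 1],
                   gene_ids[sets[["n2"]]])
  expect_true(all(mk$p_adj >= mk$p_value - 1e-15))

  # top_n beyond the gene count returns every gene without error
  mk_all <- rank_marker_genes(novel_m, truth_cluster, top_n = 10000)
  expect_equal(nrow(mk_all), 2L * ncol(novel_m$values))
  expect_error(rank_marker_genes(novel_m, rep(0L, nrow(novel_m$values))),
               "2 clusters")
})

test_that("marker ranking is calibrated under the null", {
  # under the global null a replicate yields a spurious BH discovery
  # with probability ~0.05 (Simes equality), so the number of dirty
  # replicates out of 20 is Binomial(20, 0.05): 3 is the ~2% upper bound
  dirty <- vapply(1:20, function(s) {
    set.seed(s)
    m <- expression_matrix(matrix(rpois(30 * 50, 4), 30, 50))
    fake <- rep(0:1, each = 15)
    mk <- rank_marker_genes(m, fake, top_n = 50)
    any(mk$p_adj < 0.05)
  }, TRUE)
  expect_lte(sum(dirty), 3)
})

test_that("two-group differential expression recovers a planted gene", {
  set.seed(0)
  n_genes <- 200
  mu <- exp(rnorm(n_genes, 1, 0.5))
  draw <- function(n, mu) {
    matrix(rnbinom(n * length(mu), size = 1 / 0.3,
                   mu = rep(mu, each = n)), n, length(mu))
  }
  mu_dis <- mu
  mu_dis[1] <- mu_dis[1] * 4
  m <- expression_matrix(rbind(draw(100, mu_dis), draw(100, mu)))
  groups <- rep(c("disease", "healthy"), each = 100)
  de <- group_de(m, groups)
  expect_lt(de$p_adj[1], 0.01)
  expect_gt(de$log2fc[1], 1.5)
  expect_lt(de$log2fc[1], 2.5)
  expect_true(de$significant[1])

  # flipping the comparison negates fold-changes and keeps p-values
  de_swap <- group_de(m, factor(groups, levels = c("healthy", "disease")))
  expect_equal(de_swap$log2fc, -de$log2fc)
  expect_equal(de_swap$p_value, de$p_value)
})

test_that("identical groups give zero fold-change everywhere", {
  vals <- matrix(rpois(40 * 20, 5), 40, 20)
  m <- expression_matrix(rbind(vals, vals))
  de <- group_de(m, rep(c("g1", "g2"), each = 40))
  expect_true(all(de$log2fc == 0))
  expect_error(group_de(m, rep("g1", 80)), "2 levels")
})

test_that("small-sample rank-sum p-values match exact permutation enumeration", {
  set.seed(13)
  x <- rnorm(6)
  y <- rnorm(6) + 0.8
  m <- expression_matrix(matrix(c(x, y), ncol = 1),
                         gene_ids = "g1", layer = "normalized")
  de <- group_de(m, rep(c("a", "b"), each = 6))

  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[1:6]) - 6 * 7 / 2
  combos <- utils::combn(12, 6)
  w_all <- apply(combos, 2, function(ix) sum(r[ix]) - 6 * 7 / 2)
  p_exact <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
  expect_equal(de$p_value[1], p_exact, tolerance = 1e-12)
})
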