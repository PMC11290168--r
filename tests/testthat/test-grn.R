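fixture_result <- function(pips1, pips2) {
  selection_result(score_table(names(pips1), pips1, 1, "pip"),
                   score_table(names(pips2), pips2, 2, "pip"),
                   backend = "fixture")
}

test_that("build_grn wires significant nodes, mask edges, and modes", {
  # 3 significant SNPs -> 2 significant genes, mask nnz = 3
  snps <- c(s1 = 0.9, s2 = 0.8, s3 = 0.7, s4 = 0.1)
  genes <- c(gA = 0.95, gB = 0.6, gC = 0.2)
  m <- mask_from_list(names(snps),
                      list(gA = c("s1", "s2"), gB = "s3", gC = "s4"))
  g <- build_grn(fixture_result(snps, genes), m,
                 l1_mode = "none", l2_mode = "complete")
  expect_equal(nrow(g$nodes), 5L)
  expect_equal(sum(g$edges$kind == "cross_level"), 3L)
  cross <- g$edges[g$edges$kind == "cross_level", ]
  expect_true(all(cross$directed))
  within <- g$edges[g$edges$kind == "within_level", ]
  expect_equal(nrow(within), 1L)  # gA -- gB only; no SNP-SNP edges
  expect_setequal(c(within$source, within$target), c("gA", "gB"))
  expect_false(any(g$nodes$orphan))
  expect_equal(g$metadata$l2_connectivity, "complete")
  expect_equal(g$memberships$s1, "gA")

  # nothing passes -> empty GRN
  g0 <- build_grn(fixture_result(snps * 0, genes * 0), m,
                  l1_cutoff = 0.5, l2_cutoff = 0.5)
  expect_equal(nrow(g0$nodes), 0L)
  expect_equal(nrow(g0$edges), 0L)

  # complete mode edge count k(k-1)/2
  genes5 <- setNames(rep(0.9, 5), paste0("g", 1:5))
  m5 <- mask_from_list("s1", as.list(setNames(rep("s1", 5), paste0("g", 1:5))))
  g5 <- build_grn(fixture_result(c(s1 = 0), genes5), m5,
                  l2_mode = "complete")
  expect_equal(sum(g5$edges$kind == "within_level"), 10L)
})

test_that("orphan SNPs are kept and flagged; cutoffs validate against kind", {
  snps <- c(s1 = 0.9)
  genes <- c(gA = 0.1)
  m <- mask_from_list("s1", list(gA = "s1"))
  g <- build_grn(fixture_result(snps, genes), m)
  expect_equal(g$nodes$id, "s1")
  expect_true(g$nodes$orphan)
  expect_equal(nrow(g$edges), 0L)

  expect_error(build_grn(fixture_result(snps, genes), m, l1_cutoff = 1.5),
               class = "grn_usage_error")
  expect_error(build_grn(fixture_result(snps, genes), m,
                         l1_mode = "sparse"),
               class = "grn_usage_error")  # tau missing
  expect_error(build_grn(fixture_result(snps, genes), m,
                         l1_mode = connectivity_mode("sparse", 0.3)),
               class = "grn_usage_error")  # level_data missing
})

test_that("sparse within-level edges recover a planted correlation block", {
  set.seed(55)
  n <- 2000
  base <- rnorm(n)
  # columns 1-3 share a factor (pairwise r ~= 0.6); column 4 independent
  D <- cbind(a = sqrt(0.6) * base + sqrt(0.4) * rnorm(n),
             b = sqrt(0.6) * base + sqrt(0.4) * rnorm(n),
             c = sqrt(0.6) * base + sqrt(0.4) * rnorm(n),
             d = rnorm(n))
  e <- sparse_within_edges(D, colnames(D), tau = 0.3)
  got <- paste(e$source, e$target)
  expect_setequal(got, c("a b", "a c", "b c"))
  # brute-force oracle on the same fixture
  for (i in seq_len(nrow(e)))
    expect_equal(e$weight[i], abs(cor(D[, e$source[i]], D[, e$target[i]])))

  # duplicate column pair -> |r| = 1 edge at any tau
  D2 <- cbind(x = base, y = base)
  e2 <- sparse_within_edges(D2, colnames(D2), tau = 1)
  expect_equal(nrow(e2), 1L)
  expect_equal(e2$weight, 1)

  # tau = 1 on continuous noise: no edges
  set.seed(56)
  D3 <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("p", "q", "r")))
  expect_equal(nrow(sparse_within_edges(D3, colnames(D3), tau = 1)), 0L)

  # constant column: no edges, flagged
  D4 <- cbind(u = rep(1, 50), v = rnorm(50), w = rnorm(50))
  e4 <- sparse_within_edges(D4, colnames(D4), tau = 0)
  expect_false("u" %in% c(e4$source, e4$target))
  expect_equal(attr(e4, "constant"), "u")
})

test_that("sparse mode integrates into build_grn with weights = |r|", {
  set.seed(57)
  sim <- simulate_dataset(n = 150, J = 30, G = 10, causal_k = 2, h2 = 0.7,
                          intergenic_fraction = 0, seed = 57)
  res <- fit_two_level(sim$data, sim$mask, backend_config(seed = 57))
  H <- build_group_features(sim$data, sim$mask)
  g <- build_grn(res, sim$mask,
                 l1_mode = connectivity_mode("sparse", 0.1),
                 l2_mode = connectivity_mode("sparse", 0.1),
                 level_data = list(l1 = standardize_columns(sim$data$X),
                                   l2 = H))
  within <- g$edges[g$edges$kind == "within_level", ]
  if (nrow(within)) {
    expect_true(all(within$weight >= 0.1))
    expect_true(all(!within$directed))
  }
  expect_equal(g$metadata$l1_edge_threshold, 0.1)
})

test_that("cross-level edges always respect the mask and thresholds are monotone", {
  for (seed in 1:30) {
    set.seed(seed)
    J <- 8; G <- 4
    ids <- paste0("s", 1:J)
    vals <- matrix(rbinom(J * G, 1, 0.3), J, G,
                   dimnames = list(ids, paste0("g", 1:G)))
    if (any(rowSums(vals) == 0)) vals[rowSums(vals) == 0, 1] <- 1L
    m <- annotation_mask(vals)
    res <- fixture_result(setNames(runif(J), ids),
                          setNames(runif(G), colnames(vals)))
    g_lo <- build_grn(res, m, l1_cutoff = 0.3, l2_cutoff = 0.3)
    cross <- g_lo$edges[g_lo$edges$kind == "cross_level", ]
    for (i in seq_len(nrow(cross)))
      expect_equal(unclass(m)[cross$source[i], cross$target[i]], 1L)
    # raising a cutoff never adds nodes or edges
    g_hi <- build_grn(res, m, l1_cutoff = 0.6, l2_cutoff = 0.3)
    expect_true(all(g_hi$nodes$id %in% g_lo$nodes$id))
    expect_true(all(edge_keys_test(g_hi$edges) %in%
                      edge_keys_test(g_lo$edges)))
    # purity: identical inputs give identical networks
    expect_identical(build_grn(res, m, l1_cutoff = 0.3, l2_cutoff = 0.3),
                     g_lo)
  }
})

test_that("diff_grn performs canonical set algebra with score deltas", {
  g <- random_grn(12)
  d0 <- diff_grn(g, g)
  expect_length(d0$nodes_added, 0)
  expect_length(d0$nodes_removed, 0)
  expect_equal(d0$nodes_persisting$delta, rep(0, nrow(g$nodes)))
  expect_equal(nrow(d0$edges_added), 0L)

  a <- grn(nodes = data.frame(id = "A", level = 1L, score = 0.9,
                              score_kind = "pip", significant = TRUE,
                              orphan = TRUE))
  b <- grn(nodes = data.frame(id = "B", level = 1L, score = 0.8,
                              score_kind = "pip", significant = TRUE,
                              orphan = TRUE))
  d <- diff_grn(a, b)
  expect_equal(d$nodes_removed, "A")
  expect_equal(d$nodes_added, "B")

  # antisymmetry on random pairs; undirected edges canonicalized
  for (s in 1:10) {
    x <- random_grn(100 + s); y <- random_grn(200 + s)
    expect_setequal(diff_grn(x, y)$nodes_added,
                    diff_grn(y, x)$nodes_removed)
    expect_setequal(diff_grn(x, y)$nodes_removed,
                    diff_grn(y, x)$nodes_added)
  }
  # swapping undirected endpoint order is not a change
  g1 <- grn(nodes = data.frame(id = c("x", "y"), level = 2L,
                               score = c(0.6, 0.7), score_kind = "pip",
                               significant = TRUE, orphan = FALSE),
            edges = data.frame(source = "x", target = "y",
                               directed = FALSE, kind = "within_level",
                               weight = NA_real_))
  g2 <- grn(nodes = g1$nodes,
            edges = data.frame(source = "y", target = "x",
                               directed = FALSE, kind = "within_level",
                               weight = NA_real_))
  dd <- diff_grn(g1, g2)
  expect_equal(nrow(dd$edges_added), 0L)
  expect_equal(nrow(dd$edges_removed), 0L)
})

test_that("layout hints validate, persist, and overwrite", {
  g <- random_grn(5)
  g <- layout_hint(g, "layout_with_kk")
  p <- withr::local_tempfile(fileext = ".json")
  write_grn(g, p)
  expect_equal(read_grn(p)$metadata$layout, "layout_with_kk")
  g <- layout_hint(g, "layout_circle")
  expect_equal(g$metadata$layout, "layout_circle")
  expect_error(layout_hint(g, "layout_foo"), "layout_foo",
               class = "grn_usage_error")
})
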