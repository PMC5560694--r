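random_weight_matrix <- function(seed, n) {
  set.seed(seed)
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- runif(n * (n - 1) / 2)
  W + t(W)
}

test_that("the maximum spanning tree attains the brute-force maximum", {
  # 5-node graphs: 125 spanning trees enumerated via Prufer sequences
  for (seed in 1:25) {
    W <- random_weight_matrix(seed, 5)
    mst <- build_mst(W)
    expect_equal(nrow(mst$edges), 4)
    expect_equal(sum(mst$weights), oracle_max_tree_weight(W), tolerance = 1e-12)
  }
})

test_that("MST handles degenerate sizes and equal-weight ties deterministically", {
  expect_equal(nrow(build_mst(matrix(0, 1, 1))$edges), 0)
  m2 <- build_mst(matrix(c(0, 0.3, 0.3, 0), 2, 2))
  expect_equal(m2$edges, matrix(c(1, 2), 1))

  Wt <- matrix(1, 4, 4); diag(Wt) <- 0
  t1 <- build_mst(Wt)
  t2 <- build_mst(Wt)
  expect_identical(t1$edges, t2$edges)
  # documented tie-break: Prim from node 1 picks lexicographically smallest
  expect_equal(t1$edges, matrix(c(1, 1, 1, 2, 3, 4), 3, 2))
})

test_that("MST agrees with an independent graph-library implementation", {
  for (seed in 1:10) {
    W <- random_weight_matrix(seed + 100, 6)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    # igraph minimizes, so negate to get a maximum spanning tree
    ref <- igraph::mst(g, weights = -igraph::E(g)$weight)
    expect_equal(sum(build_mst(W)$weights),
                 sum(igraph::E(ref)$weight), tolerance = 1e-12)
  }
})

test_that("directing a tree orients all arcs away from the root", {
  # path 1-2-3 rooted at the middle
  tree <- structure(list(n = 3L, edges = rbind(c(1L, 2L), c(2L, 3L)),
                         weights = c(1, 1)), class = "mst_tree")
  dt <- direct_tree(tree, 2)
  expect_equal(dt$parent, c(2L, NA, 2L))
  expect_equal(dt$depth, c(1L, 0L, 1L))
  expect_error(direct_tree(tree, 9), "not a tree node")

  # all n rootings share the same skeleton but differ as parent maps
  W <- random_weight_matrix(3, 5)
  mst <- build_mst(W)
  maps <- lapply(1:5, function(r) direct_tree(mst, r)$parent)
  expect_equal(length(unique(maps)), 5)
  skel <- lapply(1:5, function(r) {
    pm <- maps[[r]]
    sort(apply(cbind(seq_len(5), pm)[!is.na(pm), , drop = FALSE], 1,
               function(e) paste(sort(e), collapse = "-")))
  })
  expect_equal(length(unique(skel)), 1)
})

test_that("k-dependence extension keeps the tree parent and adds top-CMI ancestors", {
  # chain r -> a -> b, k = 2: b's only candidate extra ancestor is the root
  tree <- structure(list(n = 3L, edges = rbind(c(1L, 2L), c(2L, 3L)),
                         weights = c(1, 1)), class = "mst_tree")
  W <- matrix(0.1, 3, 3); diag(W) <- NA
  dt <- direct_tree(tree, 1)
  st <- extend_to_k_dependence(dt, W, k = 2)
  expect_equal(st$parents[[1]], integer(0))
  expect_equal(st$parents[[2]], 1L)
  expect_equal(sort(st$parents[[3]]), c(1L, 2L))

  # k = 1 returns the directed tree unchanged
  st1 <- extend_to_k_dependence(dt, W, k = 1)
  expect_equal(st1$parents[[3]], 2L)
  expect_error(extend_to_k_dependence(dt, W, k = 0), ">= 1")
})

test_that("extra parents equal an exhaustive ancestor scan on a deep chain", {
  # chain 1 -> 2 -> 3 -> 4 -> 5 with engineered CMI weights
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 5L))
  tree <- structure(list(n = 5L, edges = edges, weights = rep(1, 4)),
                    class = "mst_tree")
  dt <- direct_tree(tree, 1)
  set.seed(8)
  W <- random_weight_matrix(8, 5)
  st <- extend_to_k_dependence(dt, W, k = 2)
  for (j in 2:5) {
    anc <- rev(seq_len(j - 1))      # ancestors nearest first
    expect_equal(st$parents[[j]][1], j - 1L)  # tree parent retained
    if (length(anc) > 1) {
      pool <- anc[-1]
      best <- pool[which.max(W[pool, j])]
      expect_equal(st$parents[[j]][2], best)
      expect_equal(length(st$parents[[j]]), 2L)
    }
  }
})

test_that("every KCF submodel has min(depth, k) parents and is acyclic", {
  ds <- rand_ds(21, n = 80, attrs = 6, card = 3, t = 2)
  cache <- count_cache(ds)
  W <- cmi_matrix(cache)
  mst <- build_mst(W)
  for (r in 1:6) {
    dt <- direct_tree(mst, r)
    for (k in 1:3) {
      st <- extend_to_k_dependence(dt, W, k)
      expect_equal(lengths(st$parents), pmin(dt$depth, k))
      # acyclicity: parents are strict root-path ancestors
      for (j in seq_len(6)) {
        if (j == r) next
        anc <- local({
          a <- integer(0); p <- dt$parent[j]
          while (!is.na(p)) { a <- c(a, p); p <- dt$parent[p] }
          a
        })
        expect_true(all(st$parents[[j]] %in% anc))
      }
    }
  }
})

test_that("KDB parent selection follows the MI order and per-attribute top-k CMI", {
  ds <- rand_ds(31, n = 120, attrs = 6, card = 2, t = 2)
  cache <- count_cache(ds)
  for (k in 0:2) {
    st <- learn_kdb_structure(cache, k)
    ord <- rank_attributes_by_mi(cache)
    for (pos in seq_along(ord)) {
      a <- ord[pos]
      expect_equal(length(st$parents[[a]]), min(pos - 1, k))
      if (pos > 1 && k > 0) {
        cand <- ord[seq_len(pos - 1)]
        cmi <- vapply(cand, function(b)
          conditional_mutual_information(cache, a, b), numeric(1))
        top <- cand[order(-cmi, seq_along(cand))][seq_len(min(pos - 1, k))]
        expect_setequal(st$parents[[a]], top)
      }
    }
  }
  # k = 0 is the naive Bayes structure
  st0 <- learn_kdb_structure(cache, 0)
  expect_true(all(lengths(st0$parents) == 0))
})

test_that("structures are deterministic and exportable", {
  ds <- rand_ds(77, n = 50, attrs = 5, card = 2, t = 2)
  cache <- count_cache(ds)
  W <- cmi_matrix(cache)
  s1 <- extend_to_k_dependence(direct_tree(build_mst(W), 2), W, 2)
  s2 <- extend_to_k_dependence(direct_tree(build_mst(W), 2), W, 2)
  expect_identical(s1$parents, s2$parents)

  csv <- withr::local_tempfile(fileext = ".csv")
  dot <- withr::local_tempfile(fileext = ".dot")
  write_structures(list(a = s1), csv)
  write_structures(list(a = s1), dot)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), sum(lengths(s1$parents)))
  expect_true(any(grepl("digraph", readLines(dot))))
})
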