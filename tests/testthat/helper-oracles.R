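# Independent oracles used to freeze expected values. These deliberately use
# naive enumeration / hand formulas, not the package's code paths.

# plug-in mutual information from a (values x classes) count matrix, bits
oracle_mi <- function(counts) {
  N <- sum(counts)
  total <- 0
  for (a in seq_len(nrow(counts))) {
    for (c in seq_len(ncol(counts))) {
      nac <- counts[a, c]
      if (nac == 0) next
      total <- total +
        (nac / N) * log2((nac / N) / ((sum(counts[a, ]) / N) * (sum(counts[, c]) / N)))
    }
  }
  total
}

# plug-in conditional mutual information from a (d_i x d_j x t) count array
oracle_cmi <- function(arr) {
  N <- sum(arr)
  total <- 0
  for (a in seq_len(dim(arr)[1])) {
    for (b in seq_len(dim(arr)[2])) {
      for (c in seq_len(dim(arr)[3])) {
        nabc <- arr[a, b, c]
        if (nabc == 0) next
        nc <- sum(arr[, , c])
        na_c <- sum(arr[a, , c])
        nb_c <- sum(arr[, b, c])
        total <- total + (nabc / N) * log2((nabc * nc) / (na_c * nb_c))
      }
    }
  }
  total
}

oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# conditional entropy H(X|C) from a (values x classes) count matrix
oracle_cond_entropy <- function(counts) {
  N <- sum(counts)
  total <- 0
  for (c in seq_len(ncol(counts))) {
    nc <- sum(counts[, c])
    if (nc == 0) next
    total <- total + (nc / N) * oracle_entropy(counts[, c])
  }
  total
}

# hand type-7 quantile (sorted interpolation), independent of stats::quantile
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
}

# enumerate all labeled spanning trees on n nodes via Prufer sequences
# (own decode, written index-forward rather than degree-based)
oracle_all_trees <- function(n) {
  if (n == 1L) return(list(matrix(integer(0), ncol = 2)))
  if (n == 2L) return(list(matrix(c(1L, 2L), ncol = 2)))
  seqs <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), n - 2L)))
  lapply(seq_len(nrow(seqs)), function(r) {
    prufer <- as.integer(seqs[r, ])
    nodes <- seq_len(n)
    deg <- rep(1L, n)
    for (v in prufer) deg[v] <- deg[v] + 1L
    edges <- matrix(0L, n - 1L, 2L)
    avail <- rep(TRUE, n)
    for (i in seq_along(prufer)) {
      leaf <- min(nodes[avail & deg == 1L])
      edges[i, ] <- sort(c(leaf, prufer[i]))
      avail[leaf] <- FALSE
      deg[leaf] <- 0L
      deg[prufer[i]] <- deg[prufer[i]] - 1L
    }
    edges[n - 1L, ] <- sort(nodes[avail & deg == 1L])
    edges
  })
}

oracle_max_tree_weight <- function(W) {
  trees <- oracle_all_trees(nrow(W))
  max(vapply(trees, function(ed) {
    sum(W[cbind(ed[, 1], ed[, 2])])
  }, numeric(1)))
}

# exact posterior by full-joint enumeration over all attribute values
# prior: length-t; tables: list of prob arrays dim (d_j, t, parents...);
# parents: list of parent index vectors; x: observed value indices
oracle_joint_posterior <- function(prior, tables, parents, card, x) {
  t <- length(prior)
  post <- numeric(t)
  for (c in seq_len(t)) {
    p <- prior[c]
    for (j in seq_along(tables)) {
      idx <- c(x[j], c, x[parents[[j]]])
      p <- p * tables[[j]][matrix(idx, 1)]
    }
    post[c] <- p
  }
  post / sum(post)
}

# small deterministic dataset builders -------------------------------------

toy_ds <- function(df, class_col = "class") {
  kcforest::discrete_dataset(df, class_col)
}

# random fully-observed categorical dataset
rand_ds <- function(seed, n = 40, attrs = 3, card = 2, t = 2) {
  set.seed(seed)
  cols <- lapply(seq_len(attrs), function(j) {
    factor(sample(letters[seq_len(card)], n, replace = TRUE),
           levels = letters[seq_len(card)])
  })
  names(cols) <- paste0("x", seq_len(attrs))
  cols$class <- factor(sample(LETTERS[seq_len(t)], n, replace = TRUE),
                       levels = LETTERS[seq_len(t)])
  toy_ds(as.data.frame(cols))
}

# dataset from explicit per-row strings, e.g. rows = c("aaA","abB")
ds_from_rows <- function(rows, attrs, class_levels = NULL) {
  mat <- do.call(rbind, strsplit(rows, ""))
  df <- as.data.frame(mat[, seq_len(attrs), drop = FALSE])
  names(df) <- paste0("x", seq_len(attrs))
  df$class <- mat[, attrs + 1L]
  df[] <- lapply(df, factor)
  if (!is.null(class_levels)) df$class <- factor(df$class, levels = class_levels)
  toy_ds(df)
}
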