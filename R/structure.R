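#' Maximum spanning tree over attributes
#'
#' Prim's algorithm on the complete graph whose edge weights are conditional
#' mutual informations, started from the first attribute. Ties between
#' equal-weight candidate edges are broken by preferring the lexicographically
#' smaller `(min index, max index)` pair, so the tree is deterministic and
#' bit-identical across runs.
#'
#' @param weights Symmetric numeric matrix of edge weights (diagonal
#'   ignored), e.g. from [cmi_matrix()].
#' @return Object of class `mst_tree`: list with `n`, `edges` (an
#'   `(n-1) x 2` matrix of node pairs, smaller index first) and `weights`
#'   (edge weights in the same order). `n = 1` yields an empty edge set.
#' @export
build_mst <- function(weights) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  n <- nrow(weights)
  edges <- matrix(integer(0), ncol = 2)
  w <- numeric(0)
  if (n >= 2L) {
    in_tree <- c(TRUE, rep(FALSE, n - 1L))
    for (step in seq_len(n - 1L)) {
      best <- NULL
      for (u in which(in_tree)) {
        for (v in which(!in_tree)) {
          cand <- c(weights[u, v], min(u, v), max(u, v))
          if (is.null(best) ||
              cand[1] > best[1] + 1e-15 ||
              (abs(cand[1] - best[1]) <= 1e-15 &&
               (cand[2] < best[2] || (cand[2] == best[2] && cand[3] < best[3])))) {
            best <- cand
          }
        }
      }
      edges <- rbind(edges, c(best[2], best[3]))
      w <- c(w, best[1])
      in_tree[best[2]] <- in_tree[best[3]] <- TRUE
    }
  }
  structure(list(n = n, edges = edges, weights = w), class = "mst_tree")
}

#' @export
print.mst_tree <- function(x, ...) {
  cat("<mst_tree> ", x$n, " nodes, total weight ",
      format(sum(x$weights)), " bits\n", sep = "")
  invisible(x)
}

#' Tidy edge list of a spanning tree
#'
#' @param x An `mst_tree`.
#' @param ... Unused.
#' @return Tibble with columns `from`, `to`, `weight_bits`.
#' @export
tidy.mst_tree <- function(x, ...) {
  tibble::tibble(from = as.integer(x$edges[, 1]),
                 to = as.integer(x$edges[, 2]),
                 weight_bits = x$weights)
}

#' Direct a spanning tree away from a chosen root
#'
#' Breadth-first orientation: every arc points away from the root, so each
#' non-root node has exactly one tree parent. One undirected tree yields `n`
#' distinct directed trees, one per root choice, all sharing the same
#' skeleton.
#'
#' @param tree An `mst_tree` from [build_mst()].
#' @param root Attribute index to root at.
#' @return Object of class `directed_tree`: list with `root`, `parent`
#'   (integer vector, `NA` at the root) and `depth` (number of ancestors on
#'   the root path; 0 at the root).
#' @export
direct_tree <- function(tree, root) {
  stopifnot(inherits(tree, "mst_tree"))
  n <- tree$n
  if (root < 1L || root > n) stop("root ", root, " is not a tree node", call. = FALSE)
  adj <- vector("list", n)
  if (nrow(tree$edges)) {
    for (e in seq_len(nrow(tree$edges))) {
      a <- tree$edges[e, 1]; b <- tree$edges[e, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  parent <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  depth[root] <- 0L
  queue <- root
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) {
      if (is.na(depth[v])) {
        parent[v] <- u
        depth[v] <- depth[u] + 1L
        queue <- c(queue, v)
      }
    }
  }
  if (anyNA(depth)) stop("tree is not connected", call. = FALSE)
  structure(list(root = as.integer(root), parent = parent, depth = depth),
            class = "directed_tree")
}

root_path_ancestors <- function(tree, j) {
  anc <- integer(0)
  p <- tree$parent[j]
  while (!is.na(p)) {
    anc <- c(anc, p)
    p <- tree$parent[p]
  }
  anc  # ordered nearest first, root last
}

#' Bayesian-network structure over attributes
#'
#' @param parents List (one element per attribute) of ordered integer
#'   attribute-parent vectors. The class node is implicitly a parent of every
#'   attribute and is not listed.
#' @param k Dependence bound (max attribute parents per node).
#' @param root Optional generating root (for tree-derived structures).
#' @param names Optional attribute names.
#' @return Object of class `bn_structure`.
#' @export
bn_structure <- function(parents, k, root = NA_integer_, names = NULL) {
  stopifnot(is.list(parents))
  if (any(vapply(parents, length, integer(1)) > k)) {
    stop("a node exceeds the dependence bound k = ", k, call. = FALSE)
  }
  structure(list(parents = lapply(parents, as.integer), k = as.integer(k),
                 root = as.integer(root), names = names,
                 n = length(parents)),
            class = "bn_structure")
}

#' @export
print.bn_structure <- function(x, ...) {
  cat("<bn_structure> ", x$n, " attributes, k = ", x$k,
      if (!is.na(x$root)) paste0(", root = ", x$root), "\n", sep = "")
  invisible(x)
}

#' Tidy arc list of a network structure
#'
#' @param x A `bn_structure`.
#' @param ... Unused.
#' @return Tibble with columns `child`, `parent` (attribute indices) and, if
#'   names are attached, `child_name` / `parent_name`. Class arcs are not
#'   listed (the class parents every attribute by construction).
#' @export
tidy.bn_structure <- function(x, ...) {
  rows <- purrr::imap(x$parents, function(pa, ch) {
    if (length(pa)) tibble::tibble(child = as.integer(ch), parent = pa) else NULL
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) out <- tibble::tibble(child = integer(0), parent = integer(0))
  if (!is.null(x$names)) {
    out$child_name <- x$names[out$child]
    out$parent_name <- x$names[out$parent]
  }
  out
}

#' Extend a directed tree to a k-dependence structure
#'
#' Each non-root node `X_j` keeps its tree parent and additionally adopts the
#' `m - 1` root-path ancestors with the highest conditional mutual
#' information `I(X_P; X_j | C)`, where `m = min(d, k)` and `d` is the number
#' of ancestors of `X_j` on its root path. The tree parent always counts
#' toward `m`, so a direct child of the root gains nothing and `k = 1`
#' returns the tree unchanged. Ties between candidate ancestors are broken by
#' preferring the ancestor nearer `X_j` on the path, then the smaller index.
#'
#' @param tree A [direct_tree()] result.
#' @param weights Symmetric CMI matrix (same indexing as the tree).
#' @param k Dependence bound, `k >= 1`.
#' @return A [bn_structure()] whose parent sets are subsets of each node's
#'   root-path ancestors; the root has only the class parent.
#' @export
extend_to_k_dependence <- function(tree, weights, k) {
  stopifnot(inherits(tree, "directed_tree"))
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  n <- length(tree$parent)
  parents <- vector("list", n)
  for (j in seq_len(n)) {
    if (j == tree$root) {
      parents[[j]] <- integer(0)
      next
    }
    anc <- root_path_ancestors(tree, j)
    d <- length(anc)
    m <- min(d, k)
    extra <- integer(0)
    if (m > 1L) {
      cand <- anc[-1]                      # beyond the tree parent
      dist <- seq_along(anc)[-1]           # path distance to j
      ord <- order(-weights[cand, j], dist, cand)
      extra <- cand[ord][seq_len(m - 1L)]
    }
    parents[[j]] <- c(tree$parent[j], extra)
  }
  bn_structure(parents, k = k, root = tree$root,
               names = colnames(weights))
}

#' Learn the KDB structure
#'
#' The classical k-dependence Bayesian classifier structure: attributes are
#' processed in descending order of mutual information with the class; the
#' attribute at position `j` takes `min(j - 1, k)` parents, chosen as the
#' highest-CMI attributes among those earlier in the order (ties broken by
#' earlier order position, then smaller index). `k = 0` gives the naive
#' Bayes structure.
#'
#' @param cache A [count_cache()].
#' @param k Dependence bound, `k >= 0`.
#' @return A [bn_structure()].
#' @export
learn_kdb_structure <- function(cache, k) {
  stopifnot(inherits(cache, "count_cache"))
  if (k < 0L) stop("k must be >= 0", call. = FALSE)
  ord <- rank_attributes_by_mi(cache)
  n <- cache$n
  parents <- vector("list", n)
  for (pos in seq_len(n)) {
    a <- ord[pos]
    p <- min(pos - 1L, k)
    if (p == 0L) {
      parents[[a]] <- integer(0)
    } else {
      cand <- ord[seq_len(pos - 1L)]
      cmi <- vapply(cand, function(b) conditional_mutual_information(cache, a, b),
                    numeric(1))
      sel <- order(-cmi, seq_along(cand), cand)[seq_len(p)]
      parents[[a]] <- cand[sel]
    }
  }
  st <- bn_structure(parents, k = k, names = colnames(cache$x))
  st$order <- ord
  st
}

#' Export structures as DOT or edge-list CSV
#'
#' @param structures A `bn_structure` or a (possibly named) list of them.
#' @param path Output file; `.dot` gives one `digraph` per structure,
#'   anything else a `child,parent,submodel` CSV of attribute arcs.
#' @return `path`, invisibly.
#' @export
write_structures <- function(structures, path) {
  if (inherits(structures, "bn_structure")) structures <- list(structures)
  nm <- names(structures)
  if (is.null(nm)) nm <- paste0("structure_", seq_along(structures))
  if (grepl("\\.dot$", path, ignore.case = TRUE)) {
    lines <- unlist(purrr::imap(structures, function(st, i) {
      label <- if (is.character(i)) i else nm[[i]]
      node_name <- function(v) {
        if (!is.null(st$names)) st$names[v] else paste0("X", v)
      }
      arcs <- tidy.bn_structure(st)
      c(paste0("digraph \"", label, "\" {"),
        paste0("  C -> \"", vapply(seq_len(st$n), node_name, character(1)), "\";"),
        if (nrow(arcs)) paste0("  \"", vapply(arcs$parent, node_name, character(1)),
                               "\" -> \"", vapply(arcs$child, node_name, character(1)),
                               "\";"),
        "}")
    }))
    writeLines(lines, path)
  } else {
    tbl <- dplyr::bind_rows(purrr::imap(structures, function(st, i) {
      label <- if (is.character(i)) i else nm[[i]]
      arcs <- tidy.bn_structure(st)
      if (nrow(arcs)) arcs$submodel <- label
      arcs
    }))
    utils::write.csv(tbl, path, row.names = FALSE)
  }
  invisible(path)
}
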