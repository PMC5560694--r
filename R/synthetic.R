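rdirichlet1 <- function(d, conc) {
  g <- stats::rgamma(d, shape = conc)
  if (sum(g) <= 0) return(rep(1 / d, d))
  g / sum(g)
}

decode_prufer <- function(seq, n) {
  # standard Prufer decode; returns (n-1) x 2 edge matrix, smaller index first
  if (n == 1L) return(matrix(integer(0), ncol = 2))
  if (n == 2L) return(matrix(c(1L, 2L), ncol = 2))
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(integer(0), ncol = 2)
  for (s in seq) {
    leaf <- which(degree == 1L)[1]
    edges <- rbind(edges, c(min(leaf, s), max(leaf, s)))
    degree[leaf] <- degree[leaf] - 1L
    degree[s] <- degree[s] - 1L
  }
  last <- which(degree == 1L)
  edges <- rbind(edges, c(min(last), max(last)))
  edges
}

random_tree <- function(n) {
  if (n <= 2L) return(decode_prufer(integer(0), n))
  decode_prufer(sample.int(n, n - 2L, replace = TRUE), n)
}

tree_as_mst <- function(edges, n) {
  structure(list(n = n, edges = edges, weights = rep(NA_real_, nrow(edges))),
            class = "mst_tree")
}

#' Random ground-truth model for a k-dependence causal-forest submodel
#'
#' Draws a uniformly random labeled tree over the attributes, roots it at a
#' random attribute, extends each node with up to `k - 1` additional
#' root-path-ancestor parents, and fills the class prior and all conditional
#' tables from a symmetric Dirichlet. The resulting model is exactly
#' representable by one KCF submodel, so sampled data have a known
#' recoverable structure and known CPTs.
#'
#' Two independent guarantees are available, both enforced by exact
#' enumeration of the model's joint distribution with rejection sampling:
#'
#' * `ensure_recoverable = TRUE` guarantees that the generating tree is the
#'   unique conditional-mutual-information maximum spanning tree with a
#'   margin of at least `cmi_gap` bits over every non-tree edge, and that
#'   each node's extra parents are the exact-CMI argmax among its root-path
#'   ancestors with the same margin. In this mode the conditionals are
#'   sharpened: each child's table is mixed with a deterministic channel
#'   from its tree parent (per-edge copy weight drawn in `[0.5, 0.75]`) and,
#'   when present, its extra parent (weight 0.15), and all sampled
#'   distributions are floored by a uniform component, which makes
#'   well-separated CMI values typical rather than rare.
#' * `ensure_config_prob = TRUE` guarantees that every
#'   (class, parent-configuration) cell has probability at least
#'   `min_config_prob`, so finite samples estimate every conditional table
#'   entry well; useful for parameter-recovery studies (pair it with a
#'   smoother `concentration`, e.g. 2 or 3).
#'
#' @param n_attributes Number of attributes (`>= 1`).
#' @param k Dependence bound (`>= 1`, default 2).
#' @param domain_size Attribute domain sizes: scalar or length-`n` vector
#'   (default 3).
#' @param n_classes Number of class labels (default 2).
#' @param seed Integer seed (mandatory; the spec is fully reproducible).
#' @param concentration Symmetric Dirichlet concentration for all sampled
#'   distributions (default 1: uniform over the simplex).
#' @param ensure_recoverable Enforce the exact-CMI margin conditions above.
#' @param ensure_config_prob Enforce the parent-configuration floor above.
#' @param cmi_gap Margin in bits (default 0.02).
#' @param min_config_prob Minimum parent-configuration probability
#'   (default 0.02).
#' @param max_tries Rejection-sampling budget (default 500).
#' @param sample_size Default number of rows for [sample_dataset()]
#'   (default 1000).
#' @param attr_names,domains,class_domain Optional custom labels.
#' @return Object of class `bn_generator` with the true `structure`
#'   ([bn_structure()]), `tree` ([direct_tree()] result), `prior`, `cpts`,
#'   domains and the seed.
#' @export
random_kcf_model <- function(n_attributes, k = 2L, domain_size = 3L,
                             n_classes = 2L, seed,
                             concentration = 1,
                             ensure_recoverable = FALSE,
                             ensure_config_prob = FALSE,
                             cmi_gap = 0.02, min_config_prob = 0.02,
                             max_tries = 500L, sample_size = 1000L,
                             attr_names = NULL, domains = NULL,
                             class_domain = NULL) {
  if (n_attributes < 1L) stop("need at least one attribute", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (n_classes < 2L) stop("need at least two classes", call. = FALSE)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  n <- as.integer(n_attributes)
  card <- rep_len(as.integer(domain_size), n)
  if (any(card < 2L)) stop("attribute domains need at least 2 values", call. = FALSE)
  t <- as.integer(n_classes)
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    spec <- draw_generator(n, k, card, t, concentration, ensure_recoverable)
    ok <- (!ensure_recoverable || check_recoverable(spec, cmi_gap)) &&
      (!ensure_config_prob || check_config_prob(spec, min_config_prob))
    if (ok) {
      spec$seed <- as.integer(seed)
      spec$sample_size <- as.integer(sample_size)
      spec$attr_names <- attr_names %||% paste0("X", seq_len(n))
      spec$domains <- domains %||% lapply(card, function(d) paste0("v", seq_len(d)))
      spec$class_domain <- class_domain %||% paste0("c", seq_len(t))
      spec$structure$names <- spec$attr_names
      return(spec)
    }
  }
  stop("could not draw a recoverable model within max_tries; ",
       "relax cmi_gap/min_config_prob or sharpen concentration",
       call. = FALSE)
}

draw_generator <- function(n, k, card, t, concentration, sharpen) {
  edges <- random_tree(n)
  root <- sample.int(n, 1L)
  tree <- direct_tree(tree_as_mst(edges, n), root)
  parents <- vector("list", n)
  for (j in seq_len(n)) {
    if (j == root) { parents[[j]] <- integer(0); next }
    anc <- root_path_ancestors(tree, j)
    m <- min(length(anc), k)
    extra <- if (m > 1L) {
      pool <- anc[-1]
      pool[sample.int(length(pool), m - 1L)]
    } else integer(0)
    parents[[j]] <- c(tree$parent[j], extra)
  }
  st <- bn_structure(parents, k = k, root = root)
  prior <- rdirichlet1(t, concentration)
  if (sharpen) prior <- 0.7 * prior + 0.3 / t
  cpts <- vector("list", n)
  for (j in seq_len(n)) {
    pa <- parents[[j]]
    dims <- c(card[j], t, card[pa])
    ncfg <- prod(dims[-1])
    M <- matrix(0, card[j], ncfg)
    for (cfg in seq_len(ncfg)) M[, cfg] <- rdirichlet1(card[j], concentration)
    if (sharpen) M <- 0.75 * M + 0.25 / card[j]
    if (sharpen && length(pa)) {
      # deterministic channels: copy (a permuted image of) the tree parent,
      # and more weakly the extra parent, on top of the Dirichlet draw
      w_p <- stats::runif(1, 0.5, 0.75)
      w_e <- if (length(pa) >= 2L) 0.15 else 0
      sigma <- sample.int(card[j])
      tau <- if (w_e > 0) sample.int(card[j]) else NULL
      cfg_idx <- arrayInd(seq_len(ncfg), .dim = dims[-1])
      for (cfg in seq_len(ncfg)) {
        p_val <- cfg_idx[cfg, 2]
        targ_p <- sigma[(p_val - 1L) %% card[j] + 1L]
        base <- (1 - w_p - w_e) * M[, cfg]
        base[targ_p] <- base[targ_p] + w_p
        if (w_e > 0) {
          e_val <- cfg_idx[cfg, 3]
          targ_e <- tau[(e_val - 1L) %% card[j] + 1L]
          base[targ_e] <- base[targ_e] + w_e
        }
        M[, cfg] <- base
      }
    }
    cpts[[j]] <- array(M, dim = dims)
  }
  structure(list(n = n, k = as.integer(k), card = card, t = t,
                 tree = tree, structure = st, prior = prior, cpts = cpts,
                 concentration = concentration),
            class = "bn_generator")
}

#' @export
print.bn_generator <- function(x, ...) {
  cat("<bn_generator> ", x$n, " attributes (root ", x$tree$root,
      "), k = ", x$k, ", ", x$t, " classes, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

topo_order <- function(tree) order(tree$depth, seq_along(tree$depth))

#' Exact joint distribution of a generator model
#'
#' Enumerates `P(c, x_1, ..., x_n)` over the full grid (guarded to at most
#' 200,000 cells), for oracle checks and for the recoverability conditions.
#'
#' @param spec A [random_kcf_model()] spec.
#' @return List with `grid` (integer matrix, first column the class) and
#'   `p` (probabilities summing to 1).
#' @export
exact_joint <- function(spec) {
  cells <- spec$t * prod(spec$card)
  if (cells > 2e5) stop("joint too large to enumerate", call. = FALSE)
  grid <- as.matrix(expand.grid(c(list(seq_len(spec$t)),
                                  lapply(spec$card, seq_len))))
  colnames(grid) <- NULL
  p <- spec$prior[grid[, 1]]
  for (j in topo_order(spec$tree)) {
    arr <- spec$cpts[[j]]
    pa <- spec$structure$parents[[j]]
    lin <- grid[, j + 1] + spec$card[j] * (grid[, 1] - 1L)
    mult <- spec$card[j] * spec$t
    for (q in pa) {
      lin <- lin + mult * (grid[, q + 1] - 1L)
      mult <- mult * spec$card[q]
    }
    p <- p * arr[lin]
  }
  list(grid = grid, p = p)
}

#' Exact conditional-mutual-information matrix of a generator model
#'
#' `I(X_i; X_j | C)` in bits computed from the enumerated joint (no
#' sampling), the population counterpart of [cmi_matrix()].
#'
#' @param spec A [random_kcf_model()] spec.
#' @return Symmetric `n x n` matrix, `NA` diagonal.
#' @export
exact_cmi_matrix <- function(spec) {
  jt <- exact_joint(spec)
  n <- spec$n
  W <- matrix(NA_real_, n, n)
  if (n < 2L) return(W)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      key <- paste(jt$grid[, 1], jt$grid[, i + 1], jt$grid[, j + 1])
      p3 <- rowsum(jt$p, key)
      lab <- matrix(as.integer(unlist(strsplit(rownames(p3), " "))),
                    ncol = 3, byrow = TRUE)
      val <- 0
      for (c in seq_len(spec$t)) {
        sel <- lab[, 1] == c & p3[, 1] > 0
        if (!any(sel)) next
        pc <- sum(p3[lab[, 1] == c, 1])
        pi_ <- rowsum(p3[lab[, 1] == c, 1], lab[lab[, 1] == c, 2])
        pj_ <- rowsum(p3[lab[, 1] == c, 1], lab[lab[, 1] == c, 3])
        pij <- p3[sel, 1]
        li <- pi_[as.character(lab[sel, 2]), 1]
        lj <- pj_[as.character(lab[sel, 3]), 1]
        val <- val + sum(pij * log2(pij * pc / (li * lj)))
      }
      W[i, j] <- W[j, i] <- val
    }
  }
  W
}

tree_path_min_weight <- function(tree, W, u, v) {
  # min edge weight on the unique tree path between u and v
  anc_u <- c(u, root_path_ancestors(tree, u))
  anc_v <- c(v, root_path_ancestors(tree, v))
  meet <- intersect(anc_u, anc_v)[1]
  path_w <- numeric(0)
  for (node in anc_u[seq_len(match(meet, anc_u) - 1L)]) {
    path_w <- c(path_w, W[node, tree$parent[node]])
  }
  for (node in anc_v[seq_len(match(meet, anc_v) - 1L)]) {
    path_w <- c(path_w, W[node, tree$parent[node]])
  }
  min(path_w)
}

check_recoverable <- function(spec, cmi_gap) {
  W <- exact_cmi_matrix(spec)
  n <- spec$n
  tree <- spec$tree
  if (n >= 2L) {
    tree_pairs <- matrix(FALSE, n, n)
    for (j in seq_len(n)) {
      if (!is.na(tree$parent[j])) {
        tree_pairs[j, tree$parent[j]] <- tree_pairs[tree$parent[j], j] <- TRUE
      }
    }
    for (u in seq_len(n - 1L)) {
      for (v in seq.int(u + 1L, n)) {
        if (tree_pairs[u, v]) next
        if (W[u, v] + cmi_gap > tree_path_min_weight(tree, W, u, v)) {
          return(FALSE)
        }
      }
    }
  }
  # extra parents must be the exact-CMI argmax among remaining ancestors
  for (j in seq_len(n)) {
    pa <- spec$structure$parents[[j]]
    if (length(pa) < 2L) next
    extra <- pa[-1]
    anc <- root_path_ancestors(tree, j)
    others <- setdiff(anc[-1], extra)
    if (length(others) &&
        min(W[extra, j]) < max(W[others, j]) + cmi_gap) {
      return(FALSE)
    }
  }
  TRUE
}

check_config_prob <- function(spec, min_config_prob) {
  jt <- exact_joint(spec)
  for (j in seq_len(spec$n)) {
    pa <- spec$structure$parents[[j]]
    key <- do.call(paste, c(list(jt$grid[, 1]),
                            lapply(pa, function(q) jt$grid[, q + 1])))
    if (min(rowsum(jt$p, key)) < min_config_prob) return(FALSE)
  }
  TRUE
}

#' Ancestral sampling from a generator model
#'
#' Samples the class from the prior, then each attribute in topological
#' order from its conditional table. Fully vectorized and reproducible
#' bit-for-bit under a fixed seed.
#'
#' @param spec A [random_kcf_model()] spec.
#' @param n Number of rows (defaults to the spec's `sample_size`).
#' @param seed Integer seed (defaults to `spec$seed + 1` so that model
#'   drawing and data sampling are decoupled).
#' @return A [discrete_dataset()] with the spec's domains.
#' @export
sample_dataset <- function(spec, n = spec$sample_size, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "bn_generator"))
  set.seed(seed)
  y <- sample.int(spec$t, n, replace = TRUE, prob = spec$prior)
  x <- matrix(NA_integer_, n, spec$n)
  for (j in topo_order(spec$tree)) {
    pa <- spec$structure$parents[[j]]
    dj <- spec$card[j]
    M <- matrix(spec$cpts[[j]], nrow = dj)
    col <- y
    mult <- spec$t
    for (q in pa) {
      col <- col + mult * (x[, q] - 1L)
      mult <- mult * spec$card[q]
    }
    for (cfg in unique(col)) {
      idx <- which(col == cfg)
      x[idx, j] <- sample.int(dj, length(idx), replace = TRUE, prob = M[, cfg])
    }
  }
  colnames(x) <- spec$attr_names
  new_discrete_dataset(
    x = x, y = y,
    attributes = tibble::tibble(
      name = spec$attr_names,
      kind = ifelse(spec$card == 2L, "binary", "categorical"),
      domain = spec$domains),
    class_domain = spec$class_domain)
}

#' Thyroid-like synthetic schema
#'
#' A generator whose *shape* mirrors a thyroid-disease screening table:
#' 29 attributes -- 21 binary indicator flags, 7 ten-bin numeric assays
#' (age, TSH, T3, TT4, T4U, FTI, TBG) and one 6-level referral-source
#' category -- with a 7-group diagnostic class and randomized dependencies
#' (random tree, k = 2 ancestor extension, Dirichlet tables). It makes no
#' attempt to emulate the real data's empirical distributions.
#'
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration (default 1).
#' @return A [random_kcf_model()] spec with named attributes.
#' @export
thyroid_like_schema <- function(seed, concentration = 1) {
  nms <- thyroid_columns()[1:29]
  numeric_attrs <- c("age", "TSH", "T3", "TT4", "T4U", "FTI", "TBG")
  card <- ifelse(nms %in% numeric_attrs, 10L,
                 ifelse(nms == "referral_source", 6L, 2L))
  domains <- lapply(seq_along(nms), function(i) {
    if (card[i] == 10L) paste0("bin", 1:10)
    else if (card[i] == 6L) c("WEST", "STMW", "SVHC", "SVI", "SVHD", "other")
    else c("f", "t")
  })
  groups <- c("hyperthyroid", "hypothyroid", "binding_protein",
              "general_health", "replacement_therapy",
              "antithyroid_treatment", "miscellaneous")
  spec <- random_kcf_model(
    n_attributes = 29L, k = 2L, domain_size = card, n_classes = 7L,
    seed = seed, concentration = concentration,
    attr_names = nms, domains = domains, class_domain = groups)
  spec
}

#' Write a sampled fixture with its ground truth
#'
#' Writes the sampled dataset as CSV and a JSON sidecar holding the true
#' structure, prior, CPTs and seed, so downstream runs can score recovery.
#'
#' @param spec A [random_kcf_model()] spec.
#' @param n Rows to sample.
#' @param data_path,truth_path Output files.
#' @param seed Sampling seed (see [sample_dataset()]).
#' @return `data_path`, invisibly.
#' @export
write_simulation <- function(spec, n, data_path, truth_path,
                             seed = spec$seed + 1L) {
  ds <- sample_dataset(spec, n, seed)
  utils::write.csv(as.data.frame(as_tibble.discrete_dataset(ds)),
                   data_path, row.names = FALSE)
  truth <- list(
    version = 1L,
    n_attributes = spec$n, k = spec$k, seed = spec$seed,
    sampling_seed = seed,
    root = spec$tree$root,
    tree_parent = as.list(spec$tree$parent),
    parents = spec$structure$parents,
    prior = spec$prior,
    cpts = purrr::map(spec$cpts, function(a) {
      list(dim = dim(a), values = as.vector(a))
    }),
    attr_names = spec$attr_names,
    class_domain = spec$class_domain)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(data_path)
}
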