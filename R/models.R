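#' Estimate conditional probability tables for a structure
#'
#' For every attribute `X_j` with parent set `Pa_j` (plus the class), the
#' conditional table is the Laplace-smoothed count ratio
#' `P(x_j | c, pa) = (n(x_j, c, pa) + alpha) / (n(c, pa) + alpha * |dom(X_j)|)`,
#' and the class prior is smoothed the same way. With `alpha = 0` the tables
#' are raw maximum-likelihood ratios (unobserved parent configurations fall
#' back to a uniform conditional so that every stored distribution is
#' proper). Rows with a missing cell among `{X_j, Pa_j, C}` are excluded from
#' that table only.
#'
#' @param ds Training [discrete_dataset()].
#' @param structure A [bn_structure()] over the same attributes.
#' @param alpha Non-negative smoothing pseudo-count (default 1, Laplace).
#' @return Object of class `cpt_set`: list with `prior` (class
#'   probabilities), `tables` (per attribute, a probability array with dims
#'   `(|dom_j|, t, |dom_p1|, ...)`), `parents`, and `alpha`.
#' @export
fit_cpts <- function(ds, structure, alpha = 1) {
  stopifnot(inherits(ds, "discrete_dataset"), inherits(structure, "bn_structure"))
  if (alpha < 0) stop("alpha must be non-negative", call. = FALSE)
  if (structure$n != ncol(ds$x)) {
    stop("structure and dataset disagree on the number of attributes",
         call. = FALSE)
  }
  card <- domain_sizes(ds)
  t <- n_classes(ds)
  cls <- tabulate(ds$y[!is.na(ds$y)], nbins = t)
  prior <- (cls + alpha) / (sum(cls) + alpha * t)
  if (alpha == 0 && sum(cls) == 0) prior <- rep(1 / t, t)
  tables <- vector("list", structure$n)
  for (j in seq_len(structure$n)) {
    pa <- structure$parents[[j]]
    dims <- c(card[j], t, card[pa])
    ok <- !is.na(ds$x[, j]) & !is.na(ds$y)
    for (p in pa) ok <- ok & !is.na(ds$x[, p])
    idx <- ds$x[ok, j] + card[j] * (ds$y[ok] - 1L)
    mult <- card[j] * t
    for (p in pa) {
      idx <- idx + mult * (ds$x[ok, p] - 1L)
      mult <- mult * card[p]
    }
    cnt <- tabulate(idx, nbins = prod(dims))
    denom <- colSums(matrix(cnt, nrow = card[j]))  # per (class, parent config)
    prob <- array((cnt + alpha) / rep(denom + alpha * card[j], each = card[j]),
                  dim = dims)
    if (alpha == 0) {
      # unobserved parent configurations: uniform fallback
      bad <- !is.finite(prob)
      if (any(bad)) prob[bad] <- 1 / card[j]
    }
    tables[[j]] <- prob
  }
  structure(list(prior = prior, tables = tables,
                 parents = structure$parents, alpha = alpha,
                 card = card, t = t),
            class = "cpt_set")
}

#' @export
print.cpt_set <- function(x, ...) {
  cat("<cpt_set> ", length(x$tables), " attribute tables, ",
      x$t, " classes, alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Class posteriors under a fitted structure
#'
#' Computes `P(c | x)` proportional to `P(c) * prod_j P(x_j | c, pa_j(x))`
#' for every instance, in log space with max-shift normalization. This one
#' routine serves naive Bayes (empty parent sets), TAN (single parents), and
#' KDB / KCF submodels (up to `k` parents). A factor whose child or parent
#' value is missing/unseen (`NA` index) is skipped as uninformative, so
#' unseen test values never zero the posterior and never error.
#'
#' @param cpts A [fit_cpts()] result.
#' @param ds A [discrete_dataset()] with the same schema (class column may be
#'   all-`NA` for unlabeled data).
#' @return Numeric matrix, instances by classes; rows sum to 1.
#' @export
posterior <- function(cpts, ds) {
  stopifnot(inherits(cpts, "cpt_set"), inherits(ds, "discrete_dataset"))
  if (length(cpts$tables) != ncol(ds$x) ||
      !identical(cpts$card, domain_sizes(ds)) || cpts$t != n_classes(ds)) {
    stop("instance schema does not match the fitted tables", call. = FALSE)
  }
  n <- nrow(ds$x)
  t <- cpts$t
  lp <- matrix(rep(log(cpts$prior), each = n), nrow = n)
  for (j in seq_along(cpts$tables)) {
    pa <- cpts$parents[[j]]
    arr <- cpts$tables[[j]]
    dj <- cpts$card[j]
    ok <- !is.na(ds$x[, j])
    for (p in pa) ok <- ok & !is.na(ds$x[, p])
    if (!any(ok)) next
    base <- ds$x[ok, j]
    mult0 <- dj * t
    off <- 0
    mult <- mult0
    for (p in pa) {
      off <- off + mult * (ds$x[ok, p] - 1L)
      mult <- mult * cpts$card[p]
    }
    for (c in seq_len(t)) {
      lin <- base + dj * (c - 1L) + off
      lp[ok, c] <- lp[ok, c] + log(arr[lin])
    }
  }
  shift <- apply(lp, 1, max)
  post <- exp(lp - shift)
  post / rowSums(post)
}

# ---- user-facing fitted models --------------------------------------------

#' Fit a Bayesian network classifier
#'
#' Single tidy entry point for the five classifiers. Numeric attribute
#' columns are binned by equal-frequency discretization fitted on `data`
#' itself (see [fit_discretization()]); the map is stored in the model and
#' re-applied to prediction data.
#'
#' * `"nb"` -- naive Bayes: every attribute's only parent is the class.
#' * `"tan"` -- tree-augmented naive Bayes: Chow-Liu maximum spanning tree on
#'   conditional mutual information, rooted at the attribute with the highest
#'   mutual information with the class; one attribute parent each.
#' * `"kdb"` -- k-dependence Bayesian classifier ([learn_kdb_structure()]).
#' * `"kcf"` -- k-dependence causal forest: one submodel per root attribute
#'   of the shared maximum spanning tree, each extended to `k` dependence
#'   ([extend_to_k_dependence()]); prediction averages the submodel
#'   posteriors with equal weight.
#' * `"aode"` -- averaged one-dependence estimators: one superparent model
#'   per attribute; prediction averages the `n` SPODE posteriors.
#'
#' @param data Data frame (raw; numeric columns allowed) or a
#'   [discrete_dataset()].
#' @param class_col Class column name (data-frame input only).
#' @param model One of `"nb"`, `"tan"`, `"kdb"`, `"kcf"`, `"aode"`.
#' @param k Dependence bound for `"kdb"` / `"kcf"` (default 2).
#' @param alpha Smoothing pseudo-count (default 1).
#' @param bins Equal-frequency bins for numeric attributes (default 10).
#' @param missing_policy Passed to [fit_discretization()].
#' @return Object of classes `c("bnc_<model>", "bnc")` with elements
#'   `model`, `k`, `alpha`, `structures` (list of [bn_structure()]),
#'   `cpts` (list of [fit_cpts()] results, parallel to `structures`),
#'   `mst` (for tree-based models), `map` (discretization map or `NULL`),
#'   `attributes`, and `class_domain`.
#' @examples
#' d <- data.frame(a = rep(c("y", "n"), 10), b = rep(c("l", "h"), each = 10),
#'                 class = rep(c("p", "n"), 10))
#' fit <- fit_bnc(d, model = "nb")
#' predict(fit, d)
#' @export
fit_bnc <- function(data, class_col = "class",
                    model = c("kcf", "nb", "tan", "kdb", "aode"),
                    k = 2L, alpha = 1, bins = 10L,
                    missing_policy = "category") {
  model <- match.arg(model)
  if (inherits(data, "discrete_dataset")) {
    ds <- data
    map <- NULL
  } else {
    map <- fit_discretization(data, class_col, bins, missing_policy)
    ds <- apply_discretization(data, map)
  }
  fit <- switch(model,
    nb = fit_nb(ds, alpha),
    tan = fit_tan(ds, alpha),
    kdb = fit_kdb(ds, k, alpha),
    kcf = fit_kcf(ds, k, alpha),
    aode = fit_aode(ds, alpha))
  fit$map <- map
  fit$attributes <- ds$attributes
  fit$class_domain <- ds$class_domain
  fit$n_train <- nrow(ds$x)
  class(fit) <- c(paste0("bnc_", model), "bnc")
  fit
}

nb_structure_for <- function(n, names = NULL) {
  bn_structure(rep(list(integer(0)), n), k = 0L, names = names)
}

fit_nb <- function(ds, alpha) {
  st <- nb_structure_for(ncol(ds$x), ds$attributes$name)
  list(model = "nb", k = 0L, alpha = alpha,
       structures = list(st), cpts = list(fit_cpts(ds, st, alpha)))
}

fit_tan <- function(ds, alpha) {
  cache <- count_cache(ds)
  W <- cmi_matrix(cache)
  mst <- build_mst(W)
  root <- rank_attributes_by_mi(cache)[1]
  st <- extend_to_k_dependence(direct_tree(mst, root), W, k = 1L)
  list(model = "tan", k = 1L, alpha = alpha, mst = mst, root = root,
       structures = list(st), cpts = list(fit_cpts(ds, st, alpha)))
}

fit_kdb <- function(ds, k, alpha) {
  cache <- count_cache(ds)
  st <- learn_kdb_structure(cache, k)
  list(model = "kdb", k = as.integer(k), alpha = alpha,
       structures = list(st), cpts = list(fit_cpts(ds, st, alpha)))
}

fit_kcf <- function(ds, k, alpha) {
  if (k < 1L) stop("KCF requires k >= 1", call. = FALSE)
  cache <- count_cache(ds)
  W <- cmi_matrix(cache)
  mst <- build_mst(W)
  n <- ncol(ds$x)
  structures <- lapply(seq_len(n), function(r) {
    extend_to_k_dependence(direct_tree(mst, r), W, k)
  })
  cpts <- lapply(structures, function(st) fit_cpts(ds, st, alpha))
  list(model = "kcf", k = as.integer(k), alpha = alpha, mst = mst,
       structures = structures, cpts = cpts)
}

fit_aode <- function(ds, alpha) {
  n <- ncol(ds$x)
  structures <- lapply(seq_len(n), function(sp) {
    parents <- rep(list(as.integer(sp)), n)
    parents[[sp]] <- integer(0)
    st <- bn_structure(parents, k = 1L, names = ds$attributes$name)
    st$root <- as.integer(sp)
    st
  })
  cpts <- lapply(structures, function(st) fit_cpts(ds, st, alpha))
  list(model = "aode", k = 1L, alpha = alpha,
       structures = structures, cpts = cpts)
}

#' Train a KCF ensemble on a discrete dataset
#'
#' Lower-level constructor mirroring the training algorithm directly:
#' CMI matrix, shared maximum spanning tree, then for every attribute root a
#' directed tree extended to `k` dependence with class arcs and smoothed
#' CPTs. Equivalent to `fit_bnc(ds, model = "kcf", ...)`.
#'
#' @param ds A [discrete_dataset()].
#' @param k Dependence bound (default 2).
#' @param alpha Smoothing pseudo-count (default 1).
#' @return A fitted `bnc_kcf` object with `n` submodels.
#' @export
train_kcf <- function(ds, k = 2L, alpha = 1) {
  fit_bnc(ds, model = "kcf", k = k, alpha = alpha)
}

prepare_newdata <- function(object, new_data) {
  if (inherits(new_data, "discrete_dataset")) {
    check_same_schema(new_data, object$attributes, object$class_domain)
    return(new_data)
  }
  if (!is.null(object$map)) {
    df <- new_data
    if (!object$map$class_col %in% names(df)) {
      df[[object$map$class_col]] <- NA_character_
    }
    return(apply_discretization(df, object$map))
  }
  # model fitted on an already-discrete dataset: rebuild indices from domains
  x <- matrix(NA_integer_, nrow(new_data), nrow(object$attributes))
  for (j in seq_len(nrow(object$attributes))) {
    nm <- object$attributes$name[j]
    if (!nm %in% names(new_data)) stop("column '", nm, "' absent", call. = FALSE)
    x[, j] <- match(as.character(new_data[[nm]]), object$attributes$domain[[j]])
  }
  y <- rep(NA_integer_, nrow(new_data))
  if ("class" %in% names(new_data)) {
    y <- match(as.character(new_data$class), object$class_domain)
  }
  new_discrete_dataset(x, y, object$attributes, object$class_domain)
}

#' Posterior matrix of a fitted classifier
#'
#' Ensemble models (`kcf`, `aode`) return the equal-weight average of their
#' submodel posteriors; single-structure models return that structure's
#' posterior. Averaging normalized distributions keeps rows summing to 1.
#'
#' @param object A fitted `bnc` model.
#' @param ds A [discrete_dataset()] matching the model schema.
#' @return Instances-by-classes probability matrix.
#' @export
posterior_matrix <- function(object, ds) {
  mats <- purrr::map(object$cpts, posterior, ds = ds)
  Reduce(`+`, mats) / length(mats)
}

#' Predict with a Bayesian network classifier
#'
#' @param object A [fit_bnc()] model.
#' @param new_data Data frame (raw; the stored discretization map is applied)
#'   or [discrete_dataset()].
#' @param type `"prob"` (default) returns one `.pred_<label>` column per
#'   class plus `.pred_class`; `"class"` returns `.pred_class` only. The
#'   predicted label is the posterior argmax, ties broken by the smallest
#'   class index.
#' @param ... Unused.
#' @return A tibble with one row per instance.
#' @export
predict.bnc <- function(object, new_data, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  ds <- prepare_newdata(object, new_data)
  post <- posterior_matrix(object, ds)
  pred_idx <- apply(post, 1, which.max)  # which.max: smallest index on ties
  pred <- factor(object$class_domain[pred_idx], levels = object$class_domain)
  if (type == "class") return(tibble::tibble(.pred_class = pred))
  out <- tibble::as_tibble(as.data.frame(post))
  names(out) <- paste0(".pred_", object$class_domain)
  out$.pred_class <- pred
  out
}

#' @export
print.bnc <- function(x, ...) {
  cat("<bnc:", x$model, "> ", length(x$structures), " structure(s), k = ",
      x$k, ", alpha = ", x$alpha, ", ", nrow(x$attributes),
      " attributes, classes: ", paste(x$class_domain, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Tidy arc list of a fitted classifier
#'
#' One row per attribute arc across all submodels.
#'
#' @param x A fitted `bnc` model.
#' @param ... Unused.
#' @return Tibble with `submodel_root`, `child`, `parent` (+ name columns).
#' @export
tidy.bnc <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$structures, function(st) {
    arcs <- tidy.bn_structure(st)
    arcs$submodel_root <- if (!is.null(st$root) && !is.na(st$root))
      as.integer(st$root) else NA_integer_
    arcs
  })) |>
    dplyr::relocate("submodel_root")
}

#' One-row model summary
#'
#' @param x A fitted `bnc` model.
#' @param ... Unused.
#' @return Tibble with `model`, `k`, `alpha`, `n_attributes`, `n_classes`,
#'   `n_submodels`, `n_arcs`, `n_train`.
#' @export
glance.bnc <- function(x, ...) {
  tibble::tibble(
    model = x$model, k = x$k, alpha = x$alpha,
    n_attributes = nrow(x$attributes),
    n_classes = length(x$class_domain),
    n_submodels = length(x$structures),
    n_arcs = sum(vapply(x$structures,
                        function(st) sum(lengths(st$parents)), numeric(1))),
    n_train = x$n_train %||% NA_integer_)
}
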