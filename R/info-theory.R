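#' Joint count tables for a discrete dataset
#'
#' Builds the frequency tables every structure decision is driven by: class
#' counts, per-attribute (value, class) counts, and -- materialized lazily on
#' first use and then cached -- per-attribute-pair (value, value, class)
#' counts. Rows with a missing cell are excluded from the tables that
#' reference that cell only, so marginal consistency holds on fully observed
#' data.
#'
#' @param ds A [discrete_dataset()].
#' @return Object of class `count_cache` (an environment).
#' @export
count_cache <- function(ds) {
  stopifnot(inherits(ds, "discrete_dataset"))
  if (nrow(ds$x) == 0L) stop("empty dataset: no counts available", call. = FALSE)
  e <- new.env(parent = emptyenv())
  e$x <- ds$x
  e$y <- ds$y
  e$card <- domain_sizes(ds)
  e$t <- n_classes(ds)
  e$n <- ncol(ds$x)
  e$N <- nrow(ds$x)
  e$class_counts <- tabulate(ds$y, nbins = e$t)
  e$xy <- vector("list", e$n)
  e$pair <- new.env(parent = emptyenv())
  class(e) <- "count_cache"
  e
}

#' @export
print.count_cache <- function(x, ...) {
  cat("<count_cache> N =", x$N, "instances,", x$n, "attributes,",
      x$t, "classes\n")
  invisible(x)
}

xy_counts <- function(cache, i) {
  if (is.null(cache$xy[[i]])) {
    ok <- !is.na(cache$x[, i]) & !is.na(cache$y)
    cnt <- matrix(0, cache$card[i], cache$t)
    tab <- tabulate(cache$x[ok, i] + cache$card[i] * (cache$y[ok] - 1L),
                    nbins = cache$card[i] * cache$t)
    cnt[] <- tab
    cache$xy[[i]] <- cnt
  }
  cache$xy[[i]]
}

pair_counts <- function(cache, i, j) {
  key <- paste0(min(i, j), ":", max(i, j))
  if (is.null(cache$pair[[key]])) {
    a <- min(i, j); b <- max(i, j)
    da <- cache$card[a]; db <- cache$card[b]
    ok <- !is.na(cache$x[, a]) & !is.na(cache$x[, b]) & !is.na(cache$y)
    idx <- cache$x[ok, a] + da * (cache$x[ok, b] - 1L) +
      da * db * (cache$y[ok] - 1L)
    arr <- array(tabulate(idx, nbins = da * db * cache$t), dim = c(da, db, cache$t))
    cache$pair[[key]] <- arr
  }
  arr <- cache$pair[[key]]
  if (i <= j) arr else aperm(arr, c(2, 1, 3))
}

#' Mutual information between an attribute and the class
#'
#' Empirical (maximum-likelihood plug-in) mutual information
#' `I(X_i; C) = sum p(x,c) log2( p(x,c) / (p(x) p(c)) )` in bits, with the
#' `0 log 0 = 0` convention. No smoothing is applied: plug-in estimates are
#' the conventional structure score.
#'
#' @param cache A [count_cache()].
#' @param i Attribute index (1-based).
#' @return Mutual information in bits (non-negative).
#' @export
mutual_information <- function(cache, i) {
  stopifnot(inherits(cache, "count_cache"))
  cnt <- xy_counts(cache, i)
  N <- sum(cnt)
  if (N == 0) stop("no complete observations for attribute ", i, call. = FALSE)
  p <- cnt / N
  px <- rowSums(p)
  pc <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, pc)[nz]))
}

#' Conditional mutual information between two attributes given the class
#'
#' Empirical `I(X_i; X_j | C) = sum p(x_i, x_j, c)
#' log2( p(x_i, x_j | c) / (p(x_i | c) p(x_j | c)) )` in bits, plug-in
#' probabilities, `0 log 0 = 0`. Symmetric in `(i, j)`: both orders share one
#' cached pair table, so the value is bit-identical.
#'
#' @inheritParams mutual_information
#' @param j Second attribute index; must differ from `i`.
#' @return Conditional mutual information in bits (non-negative).
#' @export
conditional_mutual_information <- function(cache, i, j) {
  stopifnot(inherits(cache, "count_cache"))
  if (i == j) {
    stop("i and j must differ: self-information is not a valid edge weight",
         call. = FALSE)
  }
  arr <- pair_counts(cache, i, j)
  N <- sum(arr)
  if (N == 0) return(0)
  total <- 0
  for (c in seq_len(dim(arr)[3])) {
    s <- arr[, , c, drop = TRUE]
    if (!is.matrix(s)) s <- matrix(s, dim(arr)[1], dim(arr)[2])
    nc <- sum(s)
    if (nc == 0) next
    ri <- rowSums(s)
    rj <- colSums(s)
    nz <- s > 0
    total <- total + sum((s[nz] / N) * log2(s[nz] * nc / outer(ri, rj)[nz]))
  }
  total
}

#' Rank attributes by mutual information with the class
#'
#' Attributes sorted by descending `I(X_i; C)`; ties broken by ascending
#' attribute index, so the order is deterministic.
#'
#' @inheritParams mutual_information
#' @return Integer vector of attribute indices, best first.
#' @export
rank_attributes_by_mi <- function(cache) {
  mi <- vapply(seq_len(cache$n), function(i) mutual_information(cache, i),
               numeric(1))
  order(-mi, seq_along(mi))
}

#' Per-attribute mutual information as a tibble
#'
#' Tidy wrapper around [mutual_information()] /
#' [rank_attributes_by_mi()] for data-frame input.
#'
#' @param data A data frame of categorical columns (or a
#'   [discrete_dataset()]).
#' @param class_col Class column name (ignored for `discrete_dataset` input).
#' @return Tibble with columns `attribute`, `index`, `mi_bits`, sorted
#'   descending by `mi_bits` (ties by index).
#' @export
attribute_mi <- function(data, class_col = "class") {
  ds <- if (inherits(data, "discrete_dataset")) data else
    discrete_dataset(data, class_col)
  cache <- count_cache(ds)
  mi <- vapply(seq_len(cache$n), function(i) mutual_information(cache, i),
               numeric(1))
  tibble::tibble(attribute = ds$attributes$name,
                 index = seq_along(mi), mi_bits = mi) |>
    dplyr::arrange(dplyr::desc(.data$mi_bits), .data$index)
}

#' Conditional-mutual-information matrix
#'
#' Symmetric matrix of `I(X_i; X_j | C)` over all attribute pairs, the edge
#' weights of the maximum spanning tree. The diagonal is `NA`.
#'
#' @inheritParams mutual_information
#' @return Numeric `n x n` matrix with attribute names as dimnames.
#' @export
cmi_matrix <- function(cache) {
  stopifnot(inherits(cache, "count_cache"))
  n <- cache$n
  W <- matrix(NA_real_, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        W[i, j] <- W[j, i] <- conditional_mutual_information(cache, i, j)
      }
    }
  }
  nm <- colnames(cache$x)
  dimnames(W) <- list(nm, nm)
  W
}

#' Write a CMI matrix as CSV
#'
#' Symmetric layout with a blank diagonal, one row/column per attribute.
#'
#' @param W Matrix from [cmi_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cmi_matrix <- function(W, path) {
  out <- as.data.frame(W)
  out <- cbind(attribute = rownames(W), out)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
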