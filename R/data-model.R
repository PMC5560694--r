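#' Discrete classification dataset
#'
#' Bundles a table of categorical attributes with a single class column into
#' the indexed form used by every classifier in the package: an integer matrix
#' of attribute value indices, an integer class vector, and the attribute /
#' class domains. All columns of `data` must already be categorical (factor or
#' character); numeric columns must be binned first, see
#' [fit_discretization()].
#'
#' Cells that are `NA` are kept as `NA` indices. At prediction time an `NA`
#' index means "value unseen or unavailable" and the corresponding
#' probability factor is skipped; at fitting time rows contribute to every
#' count table for which all referenced cells are observed.
#'
#' @param data A data frame; all columns categorical.
#' @param class_col Name of the class column. Default `"class"`.
#' @param kinds Optional character vector (one per attribute, in column
#'   order) of attribute kinds: `"categorical"`, `"binary"` or `"numeric"`
#'   (the latter meaning a binned numeric attribute). Inferred when `NULL`.
#' @return An object of class `discrete_dataset`: a list with elements
#'   `x` (instances-by-attributes integer matrix), `y` (integer class vector),
#'   `attributes` (tibble with columns `name`, `kind`, `domain` list-column),
#'   and `class_domain` (character vector of class labels).
#' @examples
#' d <- discrete_dataset(
#'   data.frame(a = c("y", "n", "y"), b = c("l", "l", "h"),
#'              class = c("p", "n", "p")))
#' d$attributes
#' @export
discrete_dataset <- function(data, class_col = "class", kinds = NULL) {
  stopifnot(is.data.frame(data))
  if (!class_col %in% names(data)) {
    stop("class column '", class_col, "' not found in data", call. = FALSE)
  }
  attr_names <- setdiff(names(data), class_col)
  if (length(attr_names) < 1L) {
    stop("dataset needs at least one predictive attribute", call. = FALSE)
  }
  num_cols <- attr_names[vapply(data[attr_names], is.numeric, logical(1))]
  if (length(num_cols)) {
    stop("numeric attribute(s) ", paste(num_cols, collapse = ", "),
         " must be discretized first (see fit_discretization)", call. = FALSE)
  }
  fac <- lapply(data[attr_names], function(col) {
    if (is.factor(col)) col else factor(as.character(col))
  })
  bad <- attr_names[vapply(fac, function(f) length(levels(f)) == 0L, logical(1))]
  if (length(bad)) {
    stop("attribute(s) with empty domain: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ycol <- data[[class_col]]
  yfac <- if (is.factor(ycol)) ycol else factor(as.character(ycol))
  if (length(levels(yfac)) < 2L) {
    stop("class domain must contain at least two labels", call. = FALSE)
  }
  x <- matrix(NA_integer_, nrow = nrow(data), ncol = length(attr_names),
              dimnames = list(NULL, attr_names))
  for (j in seq_along(fac)) x[, j] <- as.integer(fac[[j]])
  if (is.null(kinds)) {
    kinds <- vapply(fac, function(f) {
      if (length(levels(f)) == 2L) "binary" else "categorical"
    }, character(1))
  }
  new_discrete_dataset(
    x = x, y = as.integer(yfac),
    attributes = tibble::tibble(
      name = attr_names, kind = unname(kinds),
      domain = lapply(fac, levels)),
    class_domain = levels(yfac))
}

new_discrete_dataset <- function(x, y, attributes, class_domain) {
  structure(
    list(x = x, y = y, attributes = attributes, class_domain = class_domain),
    class = "discrete_dataset")
}

#' @export
print.discrete_dataset <- function(x, ...) {
  cat("<discrete_dataset> ", nrow(x$x), " instances, ",
      ncol(x$x), " attributes, ", length(x$class_domain), " classes\n",
      sep = "")
  invisible(x)
}

#' @export
dim.discrete_dataset <- function(x) dim(x$x)

#' Convert a discrete dataset back to a tibble of factors
#'
#' @param x A [discrete_dataset()].
#' @param ... Unused.
#' @return A tibble with one factor column per attribute plus a `class`
#'   factor column. `NA` indices become `NA` cells.
#' @export
as_tibble.discrete_dataset <- function(x, ...) {
  cols <- purrr::map2(
    seq_len(ncol(x$x)), x$attributes$domain,
    function(j, dom) factor(dom[x$x[, j]], levels = dom))
  names(cols) <- x$attributes$name
  cols$class <- factor(x$class_domain[x$y], levels = x$class_domain)
  tibble::as_tibble(cols)
}

domain_sizes <- function(ds) {
  unname(vapply(ds$attributes$domain, length, integer(1)))
}

n_classes <- function(ds) length(ds$class_domain)

check_same_schema <- function(ds, model_attributes, model_classes) {
  if (!identical(ds$attributes$name, model_attributes$name) ||
      !identical(lapply(ds$attributes$domain, as.character),
                 lapply(model_attributes$domain, as.character)) ||
      !identical(as.character(ds$class_domain), as.character(model_classes))) {
    stop("instance schema does not match the model schema", call. = FALSE)
  }
  invisible(TRUE)
}

#' Equal-frequency bin boundaries for a numeric attribute
#'
#' Computes cut points at the empirical quantiles `i/bins` (inclusive
#' linear-interpolation definition, `stats::quantile` type 7) of the
#' non-missing values, then merges duplicates and drops cut points that
#' coincide with the data minimum or maximum, so that every resulting bin is
#' occupied on the fitting data. A constant vector therefore yields a single
#' bin; the number of bins never exceeds `bins`.
#'
#' @param values Numeric vector (may contain `NA`).
#' @param bins Target number of bins, default 10.
#' @return Object of class `eq_freq_map`: list with `cuts` (strictly
#'   increasing internal cut points, possibly empty) and `bins`
#'   (number of bins = `length(cuts) + 1`).
#' @examples
#' discretize_equal_frequency(1:20, bins = 10)$bins  # 10 bins of 2
#' @export
discretize_equal_frequency <- function(values, bins = 10L) {
  stopifnot(bins >= 1L)
  v <- values[!is.na(values)]
  if (length(v) == 0L) {
    stop("cannot discretize an all-missing attribute", call. = FALSE)
  }
  cuts <- if (bins > 1L) {
    unname(stats::quantile(v, probs = seq_len(bins - 1L) / bins, type = 7))
  } else numeric(0)
  cuts <- unique(cuts)
  cuts <- cuts[cuts > min(v) & cuts <= max(v)]
  structure(list(cuts = cuts, bins = length(cuts) + 1L),
            class = "eq_freq_map")
}

#' Assign values to equal-frequency bins
#'
#' Values in `[cut_i, cut_{i+1})` get bin `i + 1`; values below the first cut
#' get bin 1 and values at or above the last cut get the last bin, so unseen
#' out-of-range values are always mapped, never rejected. Monotone:
#' `u <= v` implies `bin(u) <= bin(v)`.
#'
#' @param values Numeric vector.
#' @param map An `eq_freq_map` from [discretize_equal_frequency()].
#' @return Integer bin indices in `1:map$bins` (`NA` stays `NA`).
#' @export
assign_bins <- function(values, map) {
  stopifnot(inherits(map, "eq_freq_map"))
  findInterval(values, map$cuts) + 1L
}

bin_labels <- function(map) paste0("bin", seq_len(map$bins))

#' Fit a discretization map on a training table
#'
#' Learns, from the training split only, everything needed to turn a raw
#' table into a [discrete_dataset()]: equal-frequency bin boundaries for each
#' numeric column, the category domain of each categorical column, and the
#' class domain. Missing values (`NA`) are handled by `missing_policy`:
#' `"category"` adds an explicit `"?"` level to each attribute that has
#' missing training cells (all instances are kept and count tables stay
#' well-defined); `"drop-row"` removes incomplete rows before fitting and at
#' apply time.
#'
#' @param data Training data frame (numeric and/or categorical columns plus
#'   the class column).
#' @param class_col Name of the class column.
#' @param bins Target bins per numeric attribute (default 10).
#' @param missing_policy `"category"` (default) or `"drop-row"`.
#' @return Object of class `discretization_map`.
#' @seealso [apply_discretization()]
#' @export
fit_discretization <- function(data, class_col = "class", bins = 10L,
                               missing_policy = c("category", "drop-row")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(is.data.frame(data))
  if (!class_col %in% names(data)) {
    stop("class column '", class_col, "' not found in data", call. = FALSE)
  }
  if (missing_policy == "drop-row") {
    data <- data[stats::complete.cases(data), , drop = FALSE]
  }
  attr_names <- setdiff(names(data), class_col)
  specs <- lapply(attr_names, function(nm) {
    col <- data[[nm]]
    if (is.numeric(col)) {
      map <- discretize_equal_frequency(col, bins)
      dom <- bin_labels(map)
      if (missing_policy == "category" && anyNA(col)) dom <- c(dom, "?")
      list(name = nm, kind = "numeric", map = map, domain = dom)
    } else {
      lev <- if (is.factor(col)) levels(col) else sort(unique(as.character(col[!is.na(col)])))
      if (missing_policy == "category" && anyNA(col)) lev <- c(lev, "?")
      kind <- if (length(lev) == 2L) "binary" else "categorical"
      list(name = nm, kind = kind, map = NULL, domain = lev)
    }
  })
  names(specs) <- attr_names
  ycol <- data[[class_col]]
  class_domain <- if (is.factor(ycol)) levels(ycol) else
    sort(unique(as.character(ycol[!is.na(ycol)])))
  structure(
    list(specs = specs, class_col = class_col, class_domain = class_domain,
         bins = bins, missing_policy = missing_policy),
    class = "discretization_map")
}

#' @export
print.discretization_map <- function(x, ...) {
  n_num <- sum(vapply(x$specs, function(s) s$kind == "numeric", logical(1)))
  cat("<discretization_map> ", length(x$specs), " attributes (",
      n_num, " binned numeric), class '", x$class_col, "' with ",
      length(x$class_domain), " labels\n", sep = "")
  invisible(x)
}

#' Apply a fitted discretization map to a raw table
#'
#' Numeric cells are replaced by their bin label, categorical cells are
#' passed through, and missing cells follow the map's missing-value policy.
#' Categorical levels (or class labels in prediction data) never seen during
#' fitting are mapped to the dedicated unseen code (`NA` index, skipped as a
#' probability factor at prediction time) -- never an error, so a map fitted
#' on a training fold can always be applied to a held-out fold.
#'
#' @param data Data frame with the same columns the map was fitted on
#'   (the class column may be absent; then a placeholder class is attached
#'   internally and callers should ignore `y`).
#' @param map A [fit_discretization()] result.
#' @return A [discrete_dataset()].
#' @export
apply_discretization <- function(data, map) {
  stopifnot(inherits(map, "discretization_map"))
  if (map$missing_policy == "drop-row") {
    keep_cols <- intersect(names(data), c(names(map$specs), map$class_col))
    data <- data[stats::complete.cases(data[keep_cols]), , drop = FALSE]
  }
  n <- nrow(data)
  x <- matrix(NA_integer_, nrow = n, ncol = length(map$specs),
              dimnames = list(NULL, names(map$specs)))
  for (j in seq_along(map$specs)) {
    sp <- map$specs[[j]]
    if (!sp$name %in% names(data)) {
      stop("column '", sp$name, "' absent from data", call. = FALSE)
    }
    col <- data[[sp$name]]
    if (sp$kind == "numeric") {
      if (!is.numeric(col)) {
        stop("column '", sp$name, "' was numeric at fit time", call. = FALSE)
      }
      idx <- assign_bins(col, sp$map)
      if ("?" %in% sp$domain) idx[is.na(col)] <- match("?", sp$domain)
      x[, j] <- idx
    } else {
      chr <- as.character(col)
      if ("?" %in% sp$domain) chr[is.na(chr)] <- "?"
      x[, j] <- match(chr, sp$domain)  # unknown level -> NA (unseen code)
    }
  }
  if (map$class_col %in% names(data)) {
    y <- match(as.character(data[[map$class_col]]), map$class_domain)
  } else {
    y <- rep(NA_integer_, n)
  }
  new_discrete_dataset(
    x = x, y = y,
    attributes = tibble::tibble(
      name = names(map$specs),
      kind = vapply(map$specs, `[[`, character(1), "kind"),
      domain = lapply(map$specs, `[[`, "domain")),
    class_domain = map$class_domain)
}

#' Fit and apply equal-frequency discretization in one step
#'
#' Convenience wrapper: fits [fit_discretization()] on `data` and returns the
#' discretized table as a tibble of factors (via [apply_discretization()] and
#' [as_tibble.discrete_dataset()]).
#'
#' @inheritParams fit_discretization
#' @return A tibble of factor columns (class column named `class`).
#' @export
discretize_table <- function(data, class_col = "class", bins = 10L,
                             missing_policy = c("category", "drop-row")) {
  map <- fit_discretization(data, class_col, bins, missing_policy)
  as_tibble.discrete_dataset(apply_discretization(data, map))
}
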