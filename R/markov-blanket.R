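#' Markov blanket of an attribute
#'
#' Parents, children, and parents-of-children of the target in the
#' attribute-only graph of a structure (class arcs are excluded throughout:
#' the class node parents every attribute by construction and is never a
#' blanket member). The co-parent set excludes the target itself.
#'
#' @param structure A [bn_structure()].
#' @param target Attribute index.
#' @return Object of class `markov_blanket`: list with `target`, `parents`,
#'   `children`, `coparents` and `members` (sorted union of the three sets).
#' @export
markov_blanket <- function(structure, target) {
  stopifnot(inherits(structure, "bn_structure"))
  if (target < 1L || target > structure$n) {
    stop("unknown target attribute ", target, call. = FALSE)
  }
  parents <- structure$parents[[target]]
  children <- which(vapply(structure$parents, function(pa) target %in% pa,
                           logical(1)))
  coparents <- setdiff(sort(unique(unlist(structure$parents[children]))), target)
  structure(list(target = as.integer(target),
                 parents = as.integer(parents),
                 children = as.integer(children),
                 coparents = as.integer(coparents),
                 members = sort(unique(c(parents, children, coparents)))),
            class = "markov_blanket")
}

#' @export
print.markov_blanket <- function(x, ...) {
  cat("<markov_blanket> target ", x$target, ": ", length(x$members),
      " member(s) {", paste(x$members, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Dependency mass captured by a Markov blanket
#'
#' Sums the conditional mutual information over all blanket relations of the
#' target `X_k`: `I(X_i; X_k | C)` over parents `X_i`, `I(X_j; X_k | C)` over
#' children `X_j`, and `I(X_i'; X_j' | C)` over all (co-parent, child) pairs.
#' The three sums are taken literally over their index sets, with no
#' deduplication when a node occurs in more than one set; a (co-parent,
#' child) pair with identical indices (a child that co-parents another
#' child, paired with itself) is skipped, since self-information is not a
#' pairwise dependence. Units: bits.
#'
#' @param cache A [count_cache()] from the same data.
#' @param structure A [bn_structure()].
#' @param target Attribute index.
#' @return Total blanket dependency mass in bits (0 for an empty blanket).
#' @export
mb_info <- function(cache, structure, target) {
  mb <- markov_blanket(structure, target)
  total <- 0
  for (i in mb$parents) {
    total <- total + conditional_mutual_information(cache, i, target)
  }
  for (j in mb$children) {
    total <- total + conditional_mutual_information(cache, j, target)
  }
  for (i in mb$coparents) {
    for (j in mb$children) {
      if (i == j) next
      total <- total + conditional_mutual_information(cache, i, j)
    }
  }
  total
}

#' Average dependency weight per Markov-blanket member
#'
#' [mb_info()] divided by the blanket size; defined as 0 for an empty
#' blanket (rather than undefined), so attributes that depend only on the
#' class report zero dependency mass.
#'
#' @inheritParams mb_info
#' @return Average blanket dependency in bits.
#' @export
avg_mb_info <- function(cache, structure, target) {
  mb <- markov_blanket(structure, target)
  if (length(mb$members) == 0L) return(0)
  mb_info(cache, structure, target) / length(mb$members)
}

#' Markov-blanket summary table for one or more structures
#'
#' Per structure (e.g. a KDB model vs a designated KCF submodel) and per
#' attribute: the blanket member list, its size, [mb_info()] and
#' [avg_mb_info()]. Column sums and means over attributes are attached as
#' the `"totals"` attribute and shown by `summary()`-style printing.
#'
#' @param cache A [count_cache()].
#' @param structures A named list of [bn_structure()] objects (a single
#'   structure is accepted and wrapped).
#' @return Tibble with columns `model`, `attribute`, `submodel_root`,
#'   `mb_members`, `mb_size`, `mb_info_bits`, `avg_mb_info_bits`; attribute
#'   `"totals"` holds per-model sums and means.
#' @export
mb_summary <- function(cache, structures) {
  if (inherits(structures, "bn_structure")) {
    structures <- list(model = structures)
  }
  if (is.null(names(structures))) {
    names(structures) <- paste0("model_", seq_along(structures))
  }
  rows <- purrr::imap(structures, function(st, label) {
    nms <- st$names %||% paste0("X", seq_len(st$n))
    purrr::map(seq_len(st$n), function(a) {
      mb <- markov_blanket(st, a)
      tibble::tibble(
        model = label,
        attribute = nms[a],
        submodel_root = if (!is.null(st$root) && !is.na(st$root))
          nms[st$root] else NA_character_,
        mb_members = paste(nms[mb$members], collapse = ";"),
        mb_size = length(mb$members),
        mb_info_bits = mb_info(cache, st, a),
        avg_mb_info_bits = avg_mb_info(cache, st, a))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  totals <- rows |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      mean_mb_size = mean(.data$mb_size),
      sum_mb_info_bits = sum(.data$mb_info_bits),
      sum_avg_mb_info_bits = sum(.data$avg_mb_info_bits),
      .groups = "drop")
  attr(rows, "totals") <- totals
  class(rows) <- c("mb_summary", class(rows))
  rows
}

#' @export
print.mb_summary <- function(x, ...) {
  NextMethod()
  tot <- attr(x, "totals")
  if (!is.null(tot)) {
    cat("\nPer-model totals:\n")
    print(tot)
  }
  invisible(x)
}

#' Write a Markov-blanket summary as CSV
#'
#' @param x A [mb_summary()] tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mb_summary <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
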