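#' Serialize a fitted classifier to versioned JSON
#'
#' Writes the schema (attribute names, kinds, domains, class domain), every
#' structure and CPT, the smoothing constant and `k`, and the discretization
#' map if one was fitted. The output is deterministic: retraining on the
#' same data and rewriting gives a byte-identical file.
#'
#' @param model A [fit_bnc()] model.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bnc <- function(model, path) {
  stopifnot(inherits(model, "bnc"))
  ser_struct <- function(st) {
    list(parents = st$parents, k = st$k,
         root = if (is.null(st$root) || is.na(st$root)) NULL else st$root)
  }
  ser_cpts <- function(cp) {
    list(prior = cp$prior, alpha = cp$alpha,
         tables = purrr::map(cp$tables, function(a) {
           list(dim = dim(a), values = as.vector(a))
         }))
  }
  ser_map <- if (is.null(model$map)) NULL else {
    list(class_col = model$map$class_col,
         class_domain = model$map$class_domain,
         bins = model$map$bins,
         missing_policy = model$map$missing_policy,
         specs = purrr::map(model$map$specs, function(sp) {
           list(name = sp$name, kind = sp$kind, domain = sp$domain,
                cuts = if (is.null(sp$map)) NULL else sp$map$cuts)
         }))
  }
  doc <- list(
    format = "kcforest-model", version = 1L,
    model = model$model, k = model$k, alpha = model$alpha,
    attributes = list(name = model$attributes$name,
                      kind = model$attributes$kind,
                      domain = model$attributes$domain),
    class_domain = model$class_domain,
    n_train = model$n_train,
    structures = purrr::map(model$structures, ser_struct),
    cpts = purrr::map(model$cpts, ser_cpts),
    map = ser_map)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a serialized classifier
#'
#' @param path A file written by [write_bnc()].
#' @return The fitted `bnc` model.
#' @export
read_bnc <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(doc$format, "kcforest-model")) {
    stop("not a kcforest model file: ", path, call. = FALSE)
  }
  attributes <- tibble::tibble(
    name = unlist(doc$attributes$name),
    kind = unlist(doc$attributes$kind),
    domain = lapply(doc$attributes$domain, unlist))
  card <- unname(vapply(attributes$domain, length, integer(1)))
  t <- length(doc$class_domain)
  structures <- purrr::map(doc$structures, function(s) {
    st <- bn_structure(purrr::map(s$parents, function(p) unlist(p) %||% integer(0)),
                       k = s$k,
                       root = if (is.null(s$root)) NA_integer_ else s$root,
                       names = attributes$name)
    st
  })
  cpts <- purrr::map2(doc$cpts, structures, function(cp, st) {
    tables <- purrr::map(cp$tables, function(tb) {
      array(unlist(tb$values), dim = unlist(tb$dim))
    })
    structure(list(prior = unlist(cp$prior), tables = tables,
                   parents = st$parents, alpha = cp$alpha,
                   card = card, t = t),
              class = "cpt_set")
  })
  map <- NULL
  if (!is.null(doc$map)) {
    specs <- purrr::map(doc$map$specs, function(sp) {
      m <- NULL
      if (!is.null(sp$cuts)) {
        cuts <- unlist(sp$cuts) %||% numeric(0)
        m <- structure(list(cuts = cuts, bins = length(cuts) + 1L),
                       class = "eq_freq_map")
        # a "?" level does not count as a bin
      }
      list(name = sp$name, kind = sp$kind, domain = unlist(sp$domain), map = m)
    })
    names(specs) <- vapply(specs, `[[`, character(1), "name")
    map <- structure(
      list(specs = specs, class_col = doc$map$class_col,
           class_domain = unlist(doc$map$class_domain),
           bins = doc$map$bins, missing_policy = doc$map$missing_policy),
      class = "discretization_map")
  }
  fit <- list(model = doc$model, k = doc$k, alpha = doc$alpha,
              structures = structures, cpts = cpts, map = map,
              attributes = attributes,
              class_domain = unlist(doc$class_domain),
              n_train = doc$n_train)
  class(fit) <- c(paste0("bnc_", doc$model), "bnc")
  fit
}
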