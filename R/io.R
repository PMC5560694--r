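#' Read a classification table from CSV or ARFF
#'
#' CSV files (RFC 4180, header row required) are read with `readr`; ARFF
#' files with `foreign::read.arff`. In both dialects `"?"` and empty cells
#' are flagged missing (`NA`), the ARFF convention. The class column must be
#' present; numeric columns are kept numeric so they can be binned with
#' [fit_discretization()].
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"arff"`.
#' @param class_col Name of the class column (checked to exist).
#' @return A tibble of raw attribute columns plus the class column.
#' @export
read_classification_table <- function(path, format = c("auto", "csv", "arff"),
                                      class_col = "class") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  tbl <- if (format == "arff") {
    tibble::as_tibble(foreign::read.arff(path))
  } else {
    readr::read_csv(path, na = c("", "NA", "?"), show_col_types = FALSE,
                    progress = FALSE)
  }
  if (!class_col %in% names(tbl)) {
    stop("class column '", class_col, "' not found in ", path, call. = FALSE)
  }
  tbl
}

#' Column layout of the UCI thyroid-disease table
#'
#' 29 predictive attributes (age; sex; 19 further binary history/measurement
#' indicator flags; the numeric hormone assays TSH, T3, TT4, T4U, FTI, TBG;
#' and the referral source) followed by the diagnosis class.
#'
#' @return Character vector of the 30 column names.
#' @export
thyroid_columns <- function() {
  c("age", "sex", "on_thyroxine", "query_on_thyroxine",
    "on_antithyroid_medication", "sick", "pregnant", "thyroid_surgery",
    "I131_treatment", "query_hypothyroid", "query_hyperthyroid", "lithium",
    "goitre", "tumor", "hypopituitary", "psych", "TSH_measured", "TSH",
    "T3_measured", "T3", "TT4_measured", "TT4", "T4U_measured", "T4U",
    "FTI_measured", "FTI", "TBG_measured", "TBG", "referral_source", "class")
}

#' Read a file in the UCI thyroid-disease layout
#'
#' Expects the raw headerless comma-separated layout: 29 attribute columns
#' followed by a diagnosis field of the form `label.|record_id` (the trailing
#' `.|record_id` part is stripped when present). `"?"` cells become missing.
#' The numeric assay columns (age, TSH, T3, TT4, T4U, FTI, TBG) are parsed as
#' numeric; everything else is categorical. The raw diagnosis labels are kept
#' as the class; pass `grouping` (a two-column data frame or CSV path,
#' `label,group`) to collapse them into coarser diagnostic groups.
#'
#' @param path File path.
#' @param grouping Optional label-to-group mapping: data frame with columns
#'   `label` and `group`, or path to such a CSV.
#' @return A tibble with the 29 attributes plus `class`.
#' @export
read_thyroid <- function(path, grouping = NULL) {
  cols <- thyroid_columns()
  tbl <- utils::read.csv(path, header = FALSE, col.names = cols,
                         na.strings = "?", colClasses = "character",
                         strip.white = TRUE)
  tbl <- tibble::as_tibble(tbl)
  tbl$class <- sub("[.|].*$", "", tbl$class)
  num <- c("age", "TSH", "T3", "TT4", "T4U", "FTI", "TBG")
  for (nm in num) tbl[[nm]] <- suppressWarnings(as.numeric(tbl[[nm]]))
  if (!is.null(grouping)) {
    if (is.character(grouping)) {
      grouping <- utils::read.csv(grouping, colClasses = "character")
    }
    stopifnot(all(c("label", "group") %in% names(grouping)))
    idx <- match(tbl$class, grouping$label)
    if (anyNA(idx)) {
      stop("class label(s) without a group: ",
           paste(unique(tbl$class[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    tbl$class <- grouping$group[idx]
  }
  tbl
}
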