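#' Bundled benchmark metric tables
#'
#' Two small reference tables of reported results for five Bayesian network
#' classifiers (NB, TAN, AODE, KDB, KCF) on UCI binary-class datasets,
#' shipped as worked-example inputs for the comparison machinery:
#'
#' * `"accuracy"` -- 10-fold cross-validation accuracy (percent) on 12
#'   datasets; feed it to [friedman_rank_test()].
#' * `"sens_spec"` -- sensitivity, specificity and balanced accuracy on the
#'   4 medical datasets, in long form with a `metric` column; the `bac` rows
#'   can be recomputed from the other two with [balanced_accuracy()] (note
#'   that two of the reported NB/KDB `bac` cells are not the mean of their
#'   own sensitivity/specificity rows -- the recomputed value is the
#'   consistent one).
#'
#' @param which `"accuracy"` or `"sens_spec"`.
#' @return A tibble.
#' @examples
#' friedman_rank_test(bnc_benchmark("accuracy"), alpha = 0.02)
#' @export
bnc_benchmark <- function(which = c("accuracy", "sens_spec")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("bnc_benchmark_", which, ".csv"),
                      package = "kcforest", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
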