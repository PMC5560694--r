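#' Fold assignment for cross-validation
#'
#' Uniform unstratified shuffling under an explicit seed (stratified
#' optionally): instances are randomly permuted and dealt into `folds`
#' mutually exclusive subsets whose sizes differ by at most one.
#'
#' @param n Number of instances.
#' @param folds Number of folds.
#' @param seed Integer seed (required: every stochastic step in the package
#'   takes one).
#' @param strata Optional vector of length `n`; when given, the deal is done
#'   within each stratum (e.g. class labels).
#' @return Integer vector of fold ids in `1:folds`.
#' @export
make_folds <- function(n, folds, seed, strata = NULL) {
  if (folds > n) stop("more folds than instances", call. = FALSE)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  set.seed(seed)
  fold_id <- integer(n)
  if (is.null(strata)) {
    fold_id[sample.int(n)] <- rep(seq_len(folds), length.out = n)
  } else {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      fold_id[idx[sample.int(length(idx))]] <-
        rep(seq_len(folds), length.out = length(idx))
    }
  }
  fold_id
}

#' k-fold cross-validation of a Bayesian network classifier
#'
#' For each fold the model is trained on the remaining folds -- including a
#' refit of the equal-frequency discretization on the training split only,
#' so no information leaks from held-out values -- and evaluated on the held
#' out fold. Accuracy is the complement of zero-one loss; the reported mean
#' is the mean of the fold accuracies. Every instance is predicted exactly
#' once.
#'
#' @param data Raw data frame (numeric columns allowed).
#' @param class_col Class column name.
#' @param model Classifier name, as in [fit_bnc()].
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment (required).
#' @param k,alpha,bins,missing_policy Passed to [fit_bnc()].
#' @param stratified Stratify folds by class (default `FALSE`).
#' @return Object of class `bnc_cv`: list with `folds` (tibble: `fold`,
#'   `n_test`, `accuracy`), `predictions` (tibble: `row`, `fold`, `truth`,
#'   `estimate`), `mean_accuracy`, and the call parameters.
#' @export
cross_validate <- function(data, class_col = "class",
                           model = c("kcf", "nb", "tan", "kdb", "aode"),
                           folds = 10L, seed, k = 2L, alpha = 1, bins = 10L,
                           missing_policy = "category", stratified = FALSE) {
  model <- match.arg(model)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  n <- nrow(data)
  strata <- if (stratified) as.character(data[[class_col]]) else NULL
  fold_id <- make_folds(n, folds, seed, strata)
  truth <- as.character(data[[class_col]])
  preds <- character(n)
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    fit <- fit_bnc(data[!test, , drop = FALSE], class_col, model,
                   k = k, alpha = alpha, bins = bins,
                   missing_policy = missing_policy)
    p <- predict(fit, data[test, , drop = FALSE], type = "class")
    preds[test] <- as.character(p$.pred_class)
    acc[f] <- mean(preds[test] == truth[test])
  }
  structure(list(
    folds = tibble::tibble(fold = seq_len(folds),
                           n_test = as.integer(table(factor(fold_id, seq_len(folds)))),
                           accuracy = acc),
    predictions = tibble::tibble(row = seq_len(n), fold = fold_id,
                                 truth = truth, estimate = preds),
    mean_accuracy = mean(acc),
    model = model, k = k, alpha = alpha, bins = bins,
    n_folds = folds, seed = seed, stratified = stratified),
    class = "bnc_cv")
}

#' @export
print.bnc_cv <- function(x, ...) {
  cat("<bnc_cv> ", x$model, ", ", x$n_folds, "-fold (seed ", x$seed,
      "): mean accuracy ", sprintf("%.4f", x$mean_accuracy), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.bnc_cv <- function(x, ...) x$folds

#' @export
glance.bnc_cv <- function(x, ...) {
  tibble::tibble(model = x$model, folds = x$n_folds, seed = x$seed,
                 mean_accuracy = x$mean_accuracy,
                 sd_accuracy = stats::sd(x$folds$accuracy))
}

#' Confusion counts for a designated positive class
#'
#' @param truth,estimate Vectors of observed and predicted labels.
#' @param positive The positive class label.
#' @return List with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, estimate, positive) {
  truth <- as.character(truth); estimate <- as.character(estimate)
  stopifnot(length(truth) == length(estimate))
  list(TP = sum(truth == positive & estimate == positive),
       FP = sum(truth != positive & estimate == positive),
       TN = sum(truth != positive & estimate != positive),
       FN = sum(truth == positive & estimate != positive))
}

#' Sensitivity and specificity from confusion counts
#'
#' Sensitivity `TP / (TP + FN)` (true positives not missed) and specificity
#' `TN / (TN + FP)` (predicted positives really positive-class driven).
#'
#' @param conf A [confusion_counts()] list.
#' @return Named numeric vector `c(sensitivity = , specificity = )`.
#' @export
sensitivity_specificity <- function(conf) {
  if (conf$TP + conf$FN == 0) {
    stop("sensitivity undefined: no positive instances", call. = FALSE)
  }
  if (conf$TN + conf$FP == 0) {
    stop("specificity undefined: no negative instances", call. = FALSE)
  }
  c(sensitivity = conf$TP / (conf$TP + conf$FN),
    specificity = conf$TN / (conf$TN + conf$FP))
}

#' Balanced accuracy
#'
#' The arithmetic mean of sensitivity and specificity; robust to class
#' imbalance where plain accuracy is inflated by the majority class.
#'
#' @param sensitivity,specificity Values in `[0, 1]`.
#' @return `(sensitivity + specificity) / 2`.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  (sensitivity + specificity) / 2
}

#' Friedman rank test over an algorithms-by-datasets metric table
#'
#' Ranks the `t` algorithms within each of the `N` datasets (higher metric
#' value gets the higher rank; average ranks on ties), sums the ranks per
#' algorithm into `R_j`, and computes the Friedman statistic
#' `F_r = 12 / (N t (t + 1)) * sum R_j^2 - 3 N (t + 1)`, compared to the
#' upper-tail chi-square critical value with `t - 1` degrees of freedom from
#' the chi-square quantile function.
#'
#' @param table Data frame or matrix, rows = datasets, columns = algorithms.
#'   Non-numeric columns (e.g. a dataset id) are dropped with a message-free
#'   pass; missing cells are an error.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `friedman_rank_test`: list with `avg_ranks`
#'   (tibble: `algorithm`, `rank_sum`, `avg_rank`), `statistic`, `df`,
#'   `critical`, `p_value`, `alpha`, `reject`, `n_datasets`,
#'   `n_algorithms`.
#' @export
friedman_rank_test <- function(table, alpha = 0.05) {
  tbl <- as.data.frame(table)
  tbl <- tbl[vapply(tbl, is.numeric, logical(1))]
  if (ncol(tbl) < 2L || nrow(tbl) < 2L) {
    stop("need at least 2 algorithms and 2 datasets", call. = FALSE)
  }
  m <- as.matrix(tbl)
  if (anyNA(m)) stop("metric table has missing cells", call. = FALSE)
  ranks <- t(apply(m, 1, rank))
  N <- nrow(m); t_ <- ncol(m)
  Rj <- unname(colSums(ranks))
  Fr <- 12 / (N * t_ * (t_ + 1)) * sum(Rj^2) - 3 * N * (t_ + 1)
  crit <- stats::qchisq(1 - alpha, df = t_ - 1)
  structure(list(
    avg_ranks = tibble::tibble(algorithm = colnames(m), rank_sum = Rj,
                               avg_rank = Rj / N),
    statistic = Fr, df = t_ - 1L, critical = crit,
    p_value = stats::pchisq(Fr, df = t_ - 1L, lower.tail = FALSE),
    alpha = alpha, reject = Fr > crit,
    n_datasets = N, n_algorithms = t_),
    class = "friedman_rank_test")
}

#' @export
print.friedman_rank_test <- function(x, ...) {
  cat("Friedman rank test: F_r = ", sprintf("%.3f", x$statistic),
      " (df = ", x$df, ", critical ", sprintf("%.3f", x$critical),
      " at alpha = ", x$alpha, ") -> ",
      if (x$reject) "reject" else "retain", " the null\n", sep = "")
  print(x$avg_ranks)
  invisible(x)
}

#' @export
tidy.friedman_rank_test <- function(x, ...) x$avg_ranks

#' @export
glance.friedman_rank_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 critical = x$critical, alpha = x$alpha, reject = x$reject,
                 n_datasets = x$n_datasets, n_algorithms = x$n_algorithms)
}

#' Sign-test win/draw/loss record between two algorithms
#'
#' Per dataset, algorithm `a` scores a win (loss) over `b` when its metric is
#' higher (lower) after rounding both to `digits` decimals; equality after
#' rounding is a draw. The two-tailed binomial sign test on the win/loss
#' counts (draws excluded, success probability 1/2) annotates whether the
#' aggregate record is significant at the given confidence level.
#'
#' @param a,b Equal-length metric vectors over the same datasets.
#' @param digits Rounding used by the draw rule (default 3, the precision
#'   metric tables are conventionally printed at).
#' @param confidence Confidence level for the sign test (default 0.95).
#' @return Tibble with `win`, `draw`, `loss`, `p_value`, `significant`.
#' @export
sign_test_wdl <- function(a, b, digits = 3L, confidence = 0.95) {
  if (length(a) != length(b)) stop("vectors differ in length", call. = FALSE)
  ra <- round(a, digits); rb <- round(b, digits)
  win <- sum(ra > rb); loss <- sum(ra < rb); draw <- sum(ra == rb)
  p <- if (win + loss == 0) 1 else
    min(1, 2 * stats::pbinom(min(win, loss), win + loss, 0.5))
  tibble::tibble(win = win, draw = draw, loss = loss, p_value = p,
                 significant = p < (1 - confidence))
}
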