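# Stratified k-fold cross-validation with in-fold SMOTE. Oversampling is
# applied to the training portion of each fold only; test folds are
# never resampled and their composition is fingerprinted so leakage can
# be asserted.

#' Accuracy and F1 from predicted and true labels
#'
#' F1 uses the sick (`TRUE`) class as positive.
#'
#' @param pred,truth logical vectors.
#' @return named numeric vector `accuracy`, `f1`.
#' @export
classification_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(accuracy = mean(pred == truth), f1 = f1)
}

# stratified fold assignment: shuffle within class, deal round-robin
stratified_folds <- function(y, n_folds, seed) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    ci <- which(y == cls)
    # per-class fold counts differ by at most one; remainders land in
    # random folds rather than always the first ones
    fold[ci] <- sample(rep_len(sample.int(n_folds), length(ci)))
  }
  fold
}

fit_predict <- function(classifier, Xtr, ytr, Xte, spec) {
  if (classifier == "net") {
    fit <- msm_train(Xtr, ytr, spec)
    return(predict(fit, Xte))
  }
  # comparators get the same per-fold standardization as the network
  center <- colMeans(Xtr)
  scl <- apply(Xtr, 2, stats::sd); scl[scl == 0 | !is.finite(scl)] <- 1
  Xtr_s <- sweep(sweep(Xtr, 2, center), 2, scl, `/`)
  Xte_s <- sweep(sweep(Xte, 2, center), 2, scl, `/`)
  if (classifier == "logistic") {
    fit <- glmnet::glmnet(Xtr_s, factor(ytr), family = "binomial",
                          alpha = 0, lambda = 0.01)
    p <- stats::predict(fit, Xte_s, type = "response")
    return(as.numeric(p) > 0.5)
  }
  if (classifier == "svm") {
    fit <- e1071::svm(Xtr_s, factor(ytr), kernel = "radial",
                      scale = FALSE)
    return(as.logical(as.character(stats::predict(fit, Xte_s))))
  }
  stop("unknown classifier '", classifier, "'", call. = FALSE)
}

#' Cross-validate a classifier on a labelled dataset
#'
#' Stratified `n_folds`-fold cross-validation. When a SMOTE
#' configuration is supplied, oversampling is applied to each fold's
#' training portion only (with a fold-specific seed derived from
#' `seed`); test folds are evaluated untouched. Per-fold accuracy and
#' F1 (positive class = sick) are reported together with fold
#' assignments and a fingerprint of each test fold for leakage checks.
#'
#' @param dataset an `msm_dataset`, or any list with matrix `X` and
#'   logical `y`.
#' @param spec an `msm_net_spec`; each fold trains with seed
#'   `spec$seed + fold`.
#' @param smote_cfg optional `msm_smote_config`.
#' @param n_folds number of folds (default 10).
#' @param seed seed for the fold assignment and SMOTE.
#' @param classifier `"net"` (default), `"logistic"` or `"svm"`.
#' @return list of class `msm_cv`: `fold` assignments, `metrics` (data
#'   frame with per-fold accuracy/F1 and training-row counts),
#'   `mean_accuracy`, `mean_f1`, `fingerprints` (per-fold test-row
#'   identifiers), `classifier`, `seed`.
#' @export
cross_validate <- function(dataset, spec = net_spec(), smote_cfg = NULL,
                           n_folds = 10, seed = 1,
                           classifier = c("net", "logistic", "svm")) {
  classifier <- match.arg(classifier)
  X <- dataset$X; y <- as.logical(dataset$y)
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (nrow(X) < n_folds)
    stop("need at least n_folds = ", n_folds, " samples", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (min(table(y)) < n_folds)
    stop("smallest class has ", min(table(y)), " samples; stratified ",
         n_folds, "-fold CV needs at least ", n_folds, " per class",
         call. = FALSE)
  fold <- stratified_folds(y, n_folds, seed)
  ids <- if (!is.null(dataset$doc_ids)) dataset$doc_ids
         else as.character(seq_len(nrow(X)))
  metrics <- data.frame(fold = seq_len(n_folds), accuracy = NA_real_,
                        f1 = NA_real_, n_train = NA_integer_,
                        n_synthetic = NA_integer_)
  fingerprints <- character(n_folds)
  for (k in seq_len(n_folds)) {
    te <- which(fold == k); tr <- which(fold != k)
    fingerprints[k] <- paste(sort(ids[te]), collapse = "|")
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    n_syn <- 0L
    if (!is.null(smote_cfg)) {
      cfg <- smote_cfg
      cfg$seed <- smote_cfg$seed + 1000L * k
      aug <- smote(Xtr, ytr, cfg)
      Xtr <- aug$X; ytr <- aug$y; n_syn <- aug$n_synthetic
    }
    fspec <- spec
    fspec$seed <- spec$seed + k
    pred <- fit_predict(classifier, Xtr, ytr, X[te, , drop = FALSE], fspec)
    m <- classification_metrics(pred, y[te])
    metrics$accuracy[k] <- m["accuracy"]
    metrics$f1[k] <- m["f1"]
    metrics$n_train[k] <- length(ytr)
    metrics$n_synthetic[k] <- n_syn
  }
  structure(list(fold = fold, metrics = metrics,
                 mean_accuracy = mean(metrics$accuracy),
                 mean_f1 = mean(metrics$f1),
                 fingerprints = fingerprints,
                 classifier = classifier, seed = seed),
            class = "msm_cv")
}

#' @export
print.msm_cv <- function(x, ...) {
  cat(sprintf("<msm_cv> %s, %d folds: accuracy %.3f, F1 %.3f\n",
              x$classifier, nrow(x$metrics), x$mean_accuracy, x$mean_f1))
  invisible(x)
}

#' Run the network and both comparator classifiers on one dataset
#'
#' Identical folds (same seed) for the feedforward network, L2 logistic
#' regression and an RBF-kernel SVM, so results are directly comparable.
#'
#' @inheritParams cross_validate
#' @return named list of `msm_cv` objects (`net`, `logistic`, `svm`).
#' @export
comparators <- function(dataset, spec = net_spec(), smote_cfg = NULL,
                        n_folds = 10, seed = 1) {
  out <- lapply(c(net = "net", logistic = "logistic", svm = "svm"),
                function(cl) cross_validate(dataset, spec, smote_cfg,
                                            n_folds, seed, classifier = cl))
  out
}
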