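# Localization prediction from motif strength: features are per-miRNA scaled
# best-match scores for each significantly enriched motif, zeroed below that
# motif's optimal enrichment threshold, evaluated with random forest and
# Gaussian naive Bayes under stratified k-fold cross-validation, with pooled
# out-of-fold ROC/AUC.

POSITIVE_CLASS <- "SEV_ENRICHED"

#' Build the thresholded motif-strength feature matrix
#'
#' One row per miRNA called `SEV_ENRICHED` or `CELL_ENRICHED` (the neutral
#' class is excluded; the task is binary), one column per significant motif
#' from either enrichment direction. The value is the miRNA's scaled
#' best-match score for that motif, set to 0 when it falls below the motif's
#' optimal enrichment threshold. Columns are ordered by E-value, then motif
#' id; a motif significant in both directions contributes one column, keeping
#' the direction with the smaller E-value.
#'
#' @param scans Scan results from [scan_motifs()] covering every classified
#'   miRNA and every significant motif.
#' @param enriched One `motif_enrichment` table, or a list of them (e.g. the
#'   sEV-vs-cell and cell-vs-sEV directions); only rows with
#'   `significant == TRUE` are used.
#' @param calls A `localization_table` from [classify_localization()].
#' @return List of class `feature_matrix` with `x` (numeric matrix), `y`
#'   (factor with levels `CELL_ENRICHED`, `SEV_ENRICHED`; positive class
#'   `SEV_ENRICHED`), `mirna_ids`, `motif_ids` and `thresholds`.
#' @export
build_features <- function(scans, enriched, calls) {
  if (inherits(enriched, "data.frame")) enriched <- list(enriched)
  sig <- do.call(rbind, lapply(enriched, function(e)
    as.data.frame(e)[e$significant, , drop = FALSE]))
  if (is.null(sig) || nrow(sig) == 0)
    stop("no significantly enriched motif in either direction; ",
         "relax the E-value threshold (e_threshold) to proceed")
  sig <- sig[order(sig$e_value, sig$motif_id), ]
  sig <- sig[!duplicated(sig$motif_id), ]

  keep <- calls$call %in% c("SEV_ENRICHED", "CELL_ENRICHED")
  ids <- calls$mirna_id[keep]
  if (length(ids) == 0) stop("no miRNA called SEV_ENRICHED or CELL_ENRICHED")
  x <- matrix(0, length(ids), nrow(sig),
              dimnames = list(ids, sig$motif_id))
  for (j in seq_len(nrow(sig))) {
    sc <- scans[scans$motif_id == sig$motif_id[j], ]
    m <- match(ids, sc$mirna_id)
    if (anyNA(m))
      stop("scan results missing for miRNA(s): ",
           paste(utils::head(ids[is.na(m)], 3), collapse = ", "))
    val <- ifelse(sc$present[m], sc$best_scaled[m], 0)
    val[val < sig$threshold[j]] <- 0
    x[, j] <- val
  }
  y <- factor(ifelse(calls$call[keep] == POSITIVE_CLASS,
                     POSITIVE_CLASS, "CELL_ENRICHED"),
              levels = c("CELL_ENRICHED", POSITIVE_CLASS))
  structure(list(x = x, y = y, mirna_ids = ids, motif_ids = sig$motif_id,
                 thresholds = stats::setNames(sig$threshold, sig$motif_id)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d miRNAs (%d %s) x %d motifs\n",
              nrow(x$x), sum(x$y == POSITIVE_CLASS), POSITIVE_CLASS,
              ncol(x$x)))
  invisible(x)
}

#' Gaussian naive Bayes fit-and-predict
#'
#' Per-feature Gaussian class-conditional densities with a variance floor of
#' `1e-9` (sub-threshold features are exactly zero, so zero within-class
#' variance is common) and class priors equal to training frequencies.
#'
#' @param x_train Numeric matrix of training features.
#' @param y_train Factor of training labels (2 classes present).
#' @param x_test Numeric matrix of test features (same columns).
#' @param positive Level treated as the positive class.
#' @param var_floor Lower bound on the per-class per-feature variance.
#' @return Numeric vector: P(positive class | x) per test row.
#' @export
naive_bayes_fit_predict <- function(x_train, y_train, x_test,
                                    positive = POSITIVE_CLASS,
                                    var_floor = 1e-9) {
  y_train <- factor(y_train)
  classes <- levels(droplevels(y_train))
  if (length(classes) != 2)
    stop("training data must contain exactly 2 classes, got ",
         length(classes))
  if (!positive %in% classes) stop("positive class absent from training data")
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  loglik <- matrix(0, nrow(x_test), 2)
  for (k in 1:2) {
    xk <- x_train[y_train == classes[k], , drop = FALSE]
    mu <- colMeans(xk)
    v <- pmax(apply(xk, 2, stats::var), var_floor)
    v[is.na(v)] <- var_floor  # single-observation class
    ll <- vapply(seq_len(ncol(x_test)), function(j)
      stats::dnorm(x_test[, j], mu[j], sqrt(v[j]), log = TRUE),
      numeric(nrow(x_test)))
    ll <- matrix(ll, nrow = nrow(x_test))
    loglik[, k] <- rowSums(ll) + log(mean(y_train == classes[k]))
  }
  # posterior for the positive class via log-sum-exp
  kpos <- which(classes == positive)
  d <- loglik - apply(loglik, 1, max)
  post <- exp(d[, kpos]) / rowSums(exp(d))
  as.numeric(post)
}

#' Random forest fit-and-predict
#'
#' Bootstrap-resampled CART trees (Gini impurity, unlimited depth) with a
#' per-split random feature subset of size `mtry = floor(log2(m)) + 1`,
#' mirroring WEKA's RandomForest defaults. The returned probability is the
#' fraction of trees voting for the positive class. Seeded and reproducible.
#'
#' @inheritParams naive_bayes_fit_predict
#' @param n_trees Number of trees (default 100).
#' @param mtry Features tried per split; default `floor(log2(m)) + 1`.
#' @param seed RNG seed for the forest.
#' @return Numeric vector: P(positive class | x) per test row.
#' @export
random_forest_fit_predict <- function(x_train, y_train, x_test,
                                      positive = POSITIVE_CLASS,
                                      n_trees = 100, mtry = NULL, seed = 1) {
  y_train <- droplevels(factor(y_train))
  if (nlevels(y_train) != 2)
    stop("training data must contain exactly 2 classes")
  if (!positive %in% levels(y_train))
    stop("positive class absent from training data")
  x_train <- as.data.frame(as.matrix(x_train))
  x_test <- as.data.frame(as.matrix(x_test))
  names(x_test) <- names(x_train) <- make.names(names(x_train))
  if (is.null(mtry)) mtry <- floor(log2(ncol(x_train))) + 1
  mtry <- max(1L, min(ncol(x_train), mtry))
  set.seed(seed)
  fit <- randomForest::randomForest(x = x_train, y = y_train,
                                    ntree = n_trees, mtry = mtry)
  prob <- stats::predict(fit, x_test, type = "prob")
  as.numeric(prob[, positive])
}

#' ROC curve from scores and labels
#'
#' Sweeps every distinct score as a threshold (ties grouped), producing a
#' piecewise-linear curve from (0, 0) to (1, 1) that is non-decreasing in
#' both coordinates.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Logical (or coercible) vector; `TRUE` = positive.
#' @return `data.frame` with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)  # counts at each distinct score
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp[last] / n_neg),
             tpr = c(0, tp[last] / n_pos))
}

#' Area under a ROC curve by the trapezoidal rule
#'
#' @param roc A `data.frame` from [roc_curve()].
#' @return AUC in \[0, 1\].
#' @export
auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so folds are as balanced as possible.
stratified_folds <- function(y, k, seed) {
  y <- factor(y)
  if (any(table(y) < 2)) stop("each class needs at least 2 members")
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation with pooled ROC
#'
#' Each fold serves once as the validation set while the model trains on the
#' remaining folds; out-of-fold predicted probabilities are pooled across
#' folds and a single ROC/AUC is computed per classifier (the pooled
#' convention, as WEKA reports it).
#'
#' @param features A [build_features()] result.
#' @param k Number of folds (default 10).
#' @param seed Seed controlling fold assignment and the forest RNG.
#' @param models Character subset of `c("rf", "nb")`.
#' @param n_trees,mtry Passed to [random_forest_fit_predict()].
#' @return List of class `cv_report`: per model a list with `prob` (pooled
#'   out-of-fold P(sEV)), `roc`, `auc` and `confusion` (at probability 0.5);
#'   plus the shared `fold` assignment, `y` and `mirna_ids`.
#' @export
cross_validate <- function(features, k = 10, seed = 1,
                           models = c("rf", "nb"), n_trees = 100,
                           mtry = NULL) {
  stopifnot(inherits(features, "feature_matrix"))
  models <- match.arg(models, several.ok = TRUE)
  x <- features$x; y <- features$y
  fold <- stratified_folds(y, k, seed)
  for (f in sort(unique(fold)))
    if (nlevels(droplevels(y[fold != f])) < 2)
      stop("fold ", f, " leaves a single-class training set; reduce k")
  report <- list(fold = fold, y = y, mirna_ids = features$mirna_ids,
                 models = list())
  for (m in models) {
    prob <- rep(NA_real_, length(y))
    for (f in sort(unique(fold))) {
      tr <- fold != f; te <- fold == f
      prob[te] <- if (m == "rf")
        random_forest_fit_predict(x[tr, , drop = FALSE], y[tr],
                                  x[te, , drop = FALSE],
                                  n_trees = n_trees, mtry = mtry,
                                  seed = seed + f)
      else
        naive_bayes_fit_predict(x[tr, , drop = FALSE], y[tr],
                                x[te, , drop = FALSE])
    }
    lab <- y == POSITIVE_CLASS
    roc <- roc_curve(prob, lab)
    pred <- prob >= 0.5
    confusion <- table(predicted = factor(pred, c(FALSE, TRUE)),
                       actual = factor(lab, c(FALSE, TRUE)))
    report$models[[m]] <- list(prob = prob, roc = roc,
                               auc = auc_trapezoid(roc),
                               confusion = confusion)
  }
  class(report) <- "cv_report"
  report
}

#' Nested cross-validation with fold-internal motif enrichment
#'
#' The standard analysis determines motif significance and thresholds once on
#' the full labelled set and then cross-validates the classifiers on the
#' resulting features, so the feature definition has seen every label. This
#' nested mode instead recomputes the enrichment (both directions) within
#' each training fold and scores the held-out fold on features defined from
#' its training data alone, eliminating that leakage at the price of less
#' data per enrichment; its AUC is the conservative estimate and is expected
#' not to exceed the standard mode's on average.
#'
#' @param seqs A [sequence_set()] covering all classified miRNAs.
#' @param motifs List of [motif_model()] objects.
#' @param calls A `localization_table`.
#' @param k,seed,models,n_trees Passed as in [cross_validate()].
#' @param e_threshold,holdout_frac Passed to [sea_enrich()] inside each fold.
#' @return A `cv_report` (pooled out-of-fold probabilities, ROC, AUC).
#' @export
nested_cross_validate <- function(seqs, motifs, calls, k = 10, seed = 1,
                                  models = c("rf", "nb"), n_trees = 100,
                                  e_threshold = 0.05, holdout_frac = 0.10) {
  models <- match.arg(models, several.ok = TRUE)
  keep <- calls$call %in% c("SEV_ENRICHED", "CELL_ENRICHED")
  ids <- calls$mirna_id[keep]
  y <- factor(ifelse(calls$call[keep] == POSITIVE_CLASS, POSITIVE_CLASS,
                     "CELL_ENRICHED"),
              levels = c("CELL_ENRICHED", POSITIVE_CLASS))
  fold <- stratified_folds(y, k, seed)
  prob <- matrix(NA_real_, length(ids), length(models),
                 dimnames = list(ids, models))
  for (f in sort(unique(fold))) {
    tr_ids <- ids[fold != f]
    tr_calls <- calls[calls$mirna_id %in% tr_ids, ]
    pos <- sequence_set(unclass(seqs)[
      tr_calls$mirna_id[tr_calls$call == "SEV_ENRICHED"]])
    bg <- sequence_set(unclass(seqs)[
      tr_calls$mirna_id[tr_calls$call == "CELL_ENRICHED"]])
    e1 <- sea_enrich(pos, bg, motifs, holdout_frac = holdout_frac,
                     seed = seed + f, e_threshold = e_threshold)
    e2 <- sea_enrich(bg, pos, motifs, holdout_frac = holdout_frac,
                     seed = seed + f + 1000L, e_threshold = e_threshold)
    scans <- scan_motifs(seqs, motifs, base_frequencies(seqs))
    fm_all <- build_features(scans, list(e1, e2), calls)
    tr <- fm_all$mirna_ids %in% tr_ids
    for (m in models) {
      p <- if (m == "rf")
        random_forest_fit_predict(fm_all$x[tr, , drop = FALSE],
                                  fm_all$y[tr],
                                  fm_all$x[!tr, , drop = FALSE],
                                  n_trees = n_trees, seed = seed + f)
      else
        naive_bayes_fit_predict(fm_all$x[tr, , drop = FALSE], fm_all$y[tr],
                                fm_all$x[!tr, , drop = FALSE])
      prob[fm_all$mirna_ids[!tr], m] <- p
    }
  }
  report <- list(fold = fold, y = y, mirna_ids = ids, models = list())
  lab <- y == POSITIVE_CLASS
  for (m in models) {
    roc <- roc_curve(prob[, m], lab)
    pred <- prob[, m] >= 0.5
    report$models[[m]] <- list(
      prob = unname(prob[, m]), roc = roc, auc = auc_trapezoid(roc),
      confusion = table(predicted = factor(pred, c(FALSE, TRUE)),
                        actual = factor(lab, c(FALSE, TRUE))))
  }
  class(report) <- "cv_report"
  report
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d miRNAs, %d folds\n", length(x$y),
              length(unique(x$fold))))
  for (m in names(x$models))
    cat(sprintf("  %s: AUC = %.4f\n", m, x$models[[m]]$auc))
  invisible(x)
}

#' Write cross-validation metrics and ROC points as TSV
#'
#' @param cv A `cv_report` from [cross_validate()].
#' @param metrics_path,roc_path Output file paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_cv_report <- function(cv, metrics_path, roc_path) {
  metrics <- do.call(rbind, lapply(names(cv$models), function(m) {
    conf <- cv$models[[m]]$confusion
    data.frame(model = m, auc_roc = cv$models[[m]]$auc,
               tp = conf["TRUE", "TRUE"], fp = conf["TRUE", "FALSE"],
               fn = conf["FALSE", "TRUE"], tn = conf["FALSE", "FALSE"])
  }))
  utils::write.table(metrics, metrics_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  roc <- do.call(rbind, lapply(names(cv$models), function(m)
    cbind(model = m, cv$models[[m]]$roc)))
  utils::write.table(roc, roc_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(metrics = metrics_path, roc = roc_path))
}
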