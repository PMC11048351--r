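# A small labelled scan/enrichment fixture for feature building.
feature_fixture <- function() {
  calls <- data.frame(
    mirna_id = c("m1", "m2", "m3", "m4", "m5"),
    call = c("SEV_ENRICHED", "SEV_ENRICHED", "CELL_ENRICHED",
             "CELL_ENRICHED", "NEUTRAL"),
    stringsAsFactors = FALSE)
  scans <- expand.grid(mirna_id = calls$mirna_id,
                       motif_id = c("mA", "mB"),
                       stringsAsFactors = FALSE)
  scans$best_scaled <- c(0.9, 0.6, 0.2, 0.75, 0.5,   # mA
                         0.1, 0.3, 0.95, 0.8, 0.4)   # mB
  scans$present <- TRUE
  enriched <- data.frame(
    motif_id = c("mA", "mB"), rbp_name = c("A", "B"),
    threshold = c(0.7, 0.5), e_value = c(1e-6, 1e-3),
    significant = c(TRUE, TRUE), stringsAsFactors = FALSE)
  list(calls = calls, scans = scans, enriched = enriched)
}

test_that("features pass through above threshold and zero out below", {
  fx <- feature_fixture()
  fm <- build_features(fx$scans, fx$enriched, fx$calls)
  expect_identical(rownames(fm$x), c("m1", "m2", "m3", "m4"))  # no NEUTRAL
  expect_identical(colnames(fm$x), c("mA", "mB"))  # ordered by e-value
  expect_equal(fm$x["m1", "mA"], 0.9)   # 0.9 >= 0.7 passes through
  expect_equal(fm$x["m2", "mA"], 0)     # 0.6 < 0.7 tagged as 0
  expect_equal(fm$x["m4", "mB"], 0.8)
  expect_true(all(fm$x == 0 | fm$x >= rep(fm$thresholds, each = 4)))
  expect_identical(as.character(fm$y),
                   c("SEV_ENRICHED", "SEV_ENRICHED", "CELL_ENRICHED",
                     "CELL_ENRICHED"))

  fx$enriched$significant <- FALSE
  expect_error(build_features(fx$scans, fx$enriched, fx$calls),
               "relax the E-value threshold")
})

test_that("planted-motif features separate the classes in simulation", {
  ds <- simulate_dataset(simulation_config(seed = 13))
  loc <- classify_localization(ds$cell, ds$sev)
  sev <- sequence_set(unclass(ds$seqs)[loc$mirna_id[loc$call == "SEV_ENRICHED"]])
  cell <- sequence_set(unclass(ds$seqs)[loc$mirna_id[loc$call == "CELL_ENRICHED"]])
  e1 <- sea_enrich(sev, cell, ds$motifs, seed = 13)
  e2 <- sea_enrich(cell, sev, ds$motifs, seed = 14)
  scans <- scan_motifs(ds$seqs, ds$motifs, base_frequencies(ds$seqs))
  fm <- build_features(scans, list(e1, e2), loc)
  planted <- "planted_AGGGA"
  expect_true(planted %in% colnames(fm$x))
  expect_gt(mean(fm$x[fm$y == "SEV_ENRICHED", planted]),
            mean(fm$x[fm$y == "CELL_ENRICHED", planted]))
})

test_that("naive Bayes matches closed-form posteriors", {
  # symmetric two-point training set: equidistant test point scores 0.5
  x <- rbind(c(0, 0), c(1, 1))
  y <- factor(c("CELL_ENRICHED", "SEV_ENRICHED"))
  p <- naive_bayes_fit_predict(x, y, rbind(c(0.5, 0.5)))
  expect_equal(p, 0.5)

  # two-feature hand-worked example against direct Bayes arithmetic
  set.seed(2)
  x_sev <- matrix(rnorm(8, 1), 4)
  x_cell <- matrix(rnorm(12, 0), 6)
  xtr <- rbind(x_sev, x_cell)
  ytr <- factor(rep(c("SEV_ENRICHED", "CELL_ENRICHED"), c(4, 6)))
  test <- c(0.7, 0.2)
  got <- naive_bayes_fit_predict(xtr, ytr, rbind(test))
  want <- oracle_nb_posterior(list(x_sev, x_cell), test,
                              prior = c(0.4, 0.6))[1]
  expect_equal(got, want, tolerance = 1e-9)

  # agreement with e1071 on a non-degenerate problem
  set.seed(3)
  xtr <- matrix(rnorm(60), 30)
  ytr <- factor(rep(c("CELL_ENRICHED", "SEV_ENRICHED"), 15))
  xte <- matrix(rnorm(10), 5)
  colnames(xtr) <- colnames(xte) <- c("f1", "f2")
  got <- naive_bayes_fit_predict(xtr, ytr, xte)
  ref <- predict(e1071::naiveBayes(xtr, ytr), xte, type = "raw")
  expect_equal(got, unname(ref[, "SEV_ENRICHED"]), tolerance = 1e-6)
})

test_that("duplicating every training row leaves NB predictions unchanged", {
  set.seed(4)
  xtr <- matrix(rnorm(40), 20)
  ytr <- factor(rep(c("CELL_ENRICHED", "SEV_ENRICHED"), 10))
  xte <- matrix(rnorm(6), 3)
  p1 <- naive_bayes_fit_predict(xtr, ytr, xte)
  # duplication changes the n-1 variance denominator; compare with a
  # tolerance wide enough for that and tight enough to catch real breakage
  p2 <- naive_bayes_fit_predict(rbind(xtr, xtr), rep(ytr, 2), xte)
  expect_equal(p1, p2, tolerance = 0.02)
})

test_that("random forest is reproducible and learns separable data", {
  set.seed(6)
  n <- 60
  y <- factor(rep(c("CELL_ENRICHED", "SEV_ENRICHED"), each = n / 2))
  x <- cbind(f = ifelse(y == "SEV_ENRICHED", 1, 0) + rnorm(n, sd = 0.05),
             g = rnorm(n))
  p1 <- random_forest_fit_predict(x, y, x, seed = 9)
  p2 <- random_forest_fit_predict(x, y, x, seed = 9)
  expect_identical(p1, p2)
  expect_gte(auc_trapezoid(roc_curve(p1, y == "SEV_ENRICHED")), 0.99)
})

test_that("more trees do not hurt on the default synthetic features", {
  ds <- simulate_dataset(simulation_config(n_mirna = 120,
                                           n_sev_detected = 120,
                                           frac_sev_enriched = 0.3,
                                           frac_cell_enriched = 0.4,
                                           seed = 3))
  loc <- classify_localization(ds$cell, ds$sev)
  keep <- loc$call %in% c("SEV_ENRICHED", "CELL_ENRICHED")
  y <- factor(loc$call[keep])
  scans <- scan_motifs(ds$seqs, ds$motifs, base_frequencies(ds$seqs))
  x <- matrix(scans$best_scaled[scans$motif_id == "planted_AGGGA"][keep],
              ncol = 1, dimnames = list(NULL, "planted_AGGGA"))
  auc_for <- function(ntree, s) {
    p <- random_forest_fit_predict(x, y, x, n_trees = ntree, seed = s)
    auc_trapezoid(roc_curve(p, y == "SEV_ENRICHED"))
  }
  a1 <- mean(vapply(1:10, function(s) auc_for(1, s), numeric(1)))
  a100 <- mean(vapply(1:10, function(s) auc_for(100, s), numeric(1)))
  expect_gte(a100, a1)
})

test_that("ROC/AUC behave as the rank statistic they are", {
  # probabilities equal to labels give AUC 1
  lab <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  expect_equal(auc_trapezoid(roc_curve(as.numeric(lab), lab)), 1.0)

  set.seed(12)
  for (i in 1:50) {
    n <- sample(10:80, 1)
    sc <- round(runif(n), 2)  # coarse grid forces ties
    lab <- runif(n) < 0.4
    if (!any(lab) || all(lab)) next
    roc <- roc_curve(sc, lab)
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    auc <- auc_trapezoid(roc)
    expect_equal(auc, oracle_auc_mann_whitney(sc, lab), tolerance = 1e-12)
    # label flip mirrors the AUC
    expect_equal(auc_trapezoid(roc_curve(sc, !lab)), 1 - auc,
                 tolerance = 1e-12)
    # invariance under a strictly monotone transform of the scores
    expect_equal(auc_trapezoid(roc_curve(qlogis((sc + 1) / 3), lab)), auc,
                 tolerance = 1e-12)
    # agreement with pROC
    expect_equal(auc, as.numeric(pROC::auc(pROC::roc(lab, sc,
                                                     quiet = TRUE,
                                                     direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("cross-validation stratifies folds and pools predictions", {
  fx <- feature_fixture()
  ds <- simulate_dataset(simulation_config(seed = 19))
  loc <- classify_localization(ds$cell, ds$sev)
  sev <- sequence_set(unclass(ds$seqs)[loc$mirna_id[loc$call == "SEV_ENRICHED"]])
  cell <- sequence_set(unclass(ds$seqs)[loc$mirna_id[loc$call == "CELL_ENRICHED"]])
  e1 <- sea_enrich(sev, cell, ds$motifs, seed = 19)
  e2 <- sea_enrich(cell, sev, ds$motifs, seed = 20)
  scans <- scan_motifs(ds$seqs, ds$motifs, base_frequencies(ds$seqs))
  fm <- build_features(scans, list(e1, e2), loc)
  cv <- cross_validate(fm, k = 10, seed = 1)

  # every fold is represented in both classes as evenly as possible
  tab <- table(cv$fold, cv$y)
  expect_true(all(abs(tab[, 1] - mean(tab[, 1])) <= 1))
  expect_true(all(abs(tab[, 2] - mean(tab[, 2])) <= 1))
  expect_false(anyNA(cv$models$rf$prob))
  expect_gte(cv$models$rf$auc, 0.85)
  expect_gte(cv$models$nb$auc, 0.85)

  # same seed reproduces the report exactly
  cv2 <- cross_validate(fm, k = 10, seed = 1)
  expect_identical(cv$models$rf$prob, cv2$models$rf$prob)
})

test_that("permuted labels give chance-level AUC", {
  ds <- simulate_dataset(simulation_config(n_mirna = 150,
                                           n_sev_detected = 150,
                                           frac_sev_enriched = 0.3,
                                           frac_cell_enriched = 0.4,
                                           seed = 8))
  loc <- classify_localization(ds$cell, ds$sev)
  scans <- scan_motifs(ds$seqs, ds$motifs, base_frequencies(ds$seqs))
  sev <- sequence_set(unclass(ds$seqs)[loc$mirna_id[loc$call == "SEV_ENRICHED"]])
  cell <- sequence_set(unclass(ds$seqs)[loc$mirna_id[loc$call == "CELL_ENRICHED"]])
  e1 <- sea_enrich(sev, cell, ds$motifs, seed = 8)
  fm <- build_features(scans, e1, loc)
  aucs <- vapply(1:6, function(s) {
    set.seed(1000 + s)
    fm_perm <- fm
    fm_perm$y <- sample(fm$y)
    cv <- cross_validate(fm_perm, k = 10, seed = s, models = "nb")
    cv$models$nb$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.40)
  expect_lt(mean(aucs), 0.60)
})

test_that("nested fold-internal enrichment is no better than the standard mode", {
  aucs <- sapply(1:3, function(s) {
    ds <- simulate_dataset(simulation_config(n_mirna = 150,
                                             n_sev_detected = 150,
                                             frac_sev_enriched = 0.3,
                                             frac_cell_enriched = 0.4,
                                             n_decoy_motifs = 6, seed = s))
    loc <- classify_localization(ds$cell, ds$sev)
    sev <- sequence_set(unclass(ds$seqs)[loc$mirna_id[loc$call == "SEV_ENRICHED"]])
    cell <- sequence_set(unclass(ds$seqs)[loc$mirna_id[loc$call == "CELL_ENRICHED"]])
    e1 <- sea_enrich(sev, cell, ds$motifs, seed = s)
    e2 <- sea_enrich(cell, sev, ds$motifs, seed = s + 1)
    scans <- scan_motifs(ds$seqs, ds$motifs, base_frequencies(ds$seqs))
    fm <- build_features(scans, list(e1, e2), loc)
    standard <- cross_validate(fm, k = 5, seed = s, models = "nb")
    nested <- nested_cross_validate(ds$seqs, ds$motifs, loc, k = 5,
                                    seed = s, models = "nb")
    c(standard = standard$models$nb$auc, nested = nested$models$nb$auc)
  })
  # leakage guard: the fold-internal mode cannot beat the full-set mode on
  # average (small tolerance for Monte Carlo noise)
  expect_lte(mean(aucs["nested", ]), mean(aucs["standard", ]) + 0.02)
})
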