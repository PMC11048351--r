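# Compartment classification: which miRNAs are preferentially secreted into
# small extracellular vesicles and which are retained in the cell. Works on
# percentage compositions (a miRNA's share of the total reliably detected
# signal in its profile), compared replicate-wise between compartments with a
# pooled-variance t-test and the Benjamini-Krieger-Yekutieli two-stage FDR.

LOCALIZATION_CALLS <- c("SEV_ENRICHED", "CELL_ENRICHED", "NEUTRAL",
                        "UNDETECTED")

#' miRNAs reliably detected above background
#'
#' A miRNA counts as reliably detected in a compartment when its
#' detected-above-background (DABG) p-value is below `alpha` in every
#' replicate of that compartment (conservative reading; `rule = "any"`
#' relaxes this to a single replicate).
#'
#' @param profile An [abundance_profile()].
#' @param alpha DABG p-value threshold (default 0.05).
#' @param rule `"all"` (default) or `"any"` replicates below `alpha`.
#' @return Character vector of detected miRNA ids.
#' @export
detect_reliable <- function(profile, alpha = 0.05, rule = c("all", "any")) {
  stopifnot(inherits(profile, "abundance_profile"))
  rule <- match.arg(rule)
  below <- profile$detection_p < alpha
  keep <- if (rule == "all") rowSums(!below) == 0 else rowSums(below) > 0
  profile$mirna_ids[keep]
}

#' Per-replicate percentage composition of detected miRNAs
#'
#' Divides each detected miRNA's signal by the total signal of all reliably
#' detected miRNAs in the same replicate of the same compartment, so each
#' replicate column sums to 1.
#'
#' @param profile An [abundance_profile()].
#' @param detected Character vector of detected miRNA ids (subset of the
#'   profile's ids).
#' @return Matrix `length(detected)` x `n_replicates` of fractions.
#' @export
composition <- function(profile, detected) {
  stopifnot(inherits(profile, "abundance_profile"))
  if (!all(detected %in% profile$mirna_ids))
    stop("detected ids not present in profile: ",
         paste(setdiff(detected, profile$mirna_ids), collapse = ", "))
  sig <- profile$signals[detected, , drop = FALSE]
  tot <- colSums(sig)
  if (any(tot <= 0))
    stop("replicate ", which(tot <= 0)[1],
         " has zero total reliable signal in compartment ",
         profile$compartment)
  sweep(sig, 2, tot, "/")
}

#' Pooled-variance two-sample t-test
#'
#' Unpaired, two-tailed Student t-test assuming equal standard deviation in
#' the two groups (`df = nx + ny - 2`). Degenerate zero-variance inputs are
#' defined explicitly: equal means give `t = 0`, `p = 1`; unequal means give
#' `t = +-Inf`, `p = 0`.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return List with `t_stat` and `p_value`.
#' @export
equal_variance_ttest <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group needs at least 2 observations")
  mx <- mean(x); my <- mean(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  if (se == 0) {
    if (mx == my) return(list(t_stat = 0, p_value = 1))
    return(list(t_stat = sign(mx - my) * Inf, p_value = 0))
  }
  t_stat <- (mx - my) / se
  list(t_stat = t_stat,
       p_value = 2 * stats::pt(-abs(t_stat), df = nx + ny - 2))
}

#' Benjamini-Krieger-Yekutieli two-stage FDR
#'
#' Adaptive two-stage linear step-up procedure. Stage 1 runs
#' Benjamini-Hochberg at `q' = q / (1 + q)`; its `r1` rejections estimate the
#' number of true nulls as `m0 = m - r1`. If `r1 = 0` nothing is rejected; if
#' `r1 = m` everything is. Otherwise stage 2 runs Benjamini-Hochberg at
#' `q'' = q' * m / m0` and its rejection set is the result. Adjusted q-values
#' are defined so that `q_value <= q` exactly reproduces the rejection set at
#' the level `q` supplied here (they are calibrated to that level, not to
#' every level simultaneously).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param q Target FDR level (default 0.05).
#' @return List with `q_value` (same order as input), `rejected` (logical),
#'   and `m0` (estimated number of true nulls).
#' @export
fdr_bky_two_stage <- function(p_values, q = 0.05) {
  m <- length(p_values)
  if (m == 0)
    return(list(q_value = numeric(0), rejected = logical(0), m0 = 0L))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop("p-values must be in [0, 1] and non-missing")
  q1 <- q / (1 + q)
  bh <- stats::p.adjust(p_values, method = "BH")
  r1 <- sum(bh <= q1)
  m0 <- m - r1
  q_value <- pmin(1, bh * (1 + q) * m0 / m)
  list(q_value = q_value, rejected = q_value <= q, m0 = m0)
}

#' Classify miRNAs by compartment
#'
#' Runs the full localization procedure on a pair of aligned abundance
#' profiles: detect reliable miRNAs per compartment, compute percentage
#' compositions (a miRNA detected in only one compartment is assigned
#' composition 0 in the other), compare the replicate compositions with
#' [equal_variance_ttest()], adjust across all tested miRNAs with
#' [fdr_bky_two_stage()], and call each miRNA `SEV_ENRICHED`,
#' `CELL_ENRICHED` or `NEUTRAL` from the rejection mask and the sign of the
#' composition difference. miRNAs detected in neither compartment are
#' reported as `UNDETECTED` with `NA` statistics.
#'
#' @param cell,sev [abundance_profile()] objects with identical `mirna_ids`
#'   in identical order.
#' @param q FDR level for the class call (default 0.05).
#' @param alpha DABG detection threshold passed to [detect_reliable()].
#' @param detection_rule Passed to [detect_reliable()].
#' @return A `data.frame` of class `localization_table` with columns
#'   `mirna_id`, `mean_comp_cell`, `mean_comp_sev`, `t_stat`, `p_value`,
#'   `q_value`, `call`.
#' @export
classify_localization <- function(cell, sev, q = 0.05, alpha = 0.05,
                                  detection_rule = "all") {
  stopifnot(inherits(cell, "abundance_profile"),
            inherits(sev, "abundance_profile"))
  if (cell$compartment != "CELL" || sev$compartment != "SEV")
    stop("profiles must be passed as (cell = CELL, sev = SEV)")
  if (!identical(cell$mirna_ids, sev$mirna_ids))
    stop("profiles are not aligned: mirna_ids differ")
  ids <- cell$mirna_ids
  det_cell <- detect_reliable(cell, alpha, detection_rule)
  det_sev <- detect_reliable(sev, alpha, detection_rule)
  tested <- ids[ids %in% union(det_cell, det_sev)]

  comp_cell <- matrix(0, length(tested), ncol(cell$signals),
                      dimnames = list(tested, NULL))
  comp_sev <- matrix(0, length(tested), ncol(sev$signals),
                     dimnames = list(tested, NULL))
  if (length(det_cell) > 0)
    comp_cell[det_cell, ] <- composition(cell, det_cell)
  if (length(det_sev) > 0)
    comp_sev[det_sev, ] <- composition(sev, det_sev)

  n <- length(tested)
  t_stat <- p_value <- numeric(n)
  for (i in seq_len(n)) {
    tt <- equal_variance_ttest(comp_sev[i, ], comp_cell[i, ])
    t_stat[i] <- tt$t_stat
    p_value[i] <- tt$p_value
  }
  fdr <- fdr_bky_two_stage(p_value, q)
  mean_cell <- rowMeans(comp_cell)
  mean_sev <- rowMeans(comp_sev)
  call <- ifelse(!fdr$rejected, "NEUTRAL",
                 ifelse(mean_sev > mean_cell, "SEV_ENRICHED",
                        "CELL_ENRICHED"))

  out <- data.frame(mirna_id = ids, mean_comp_cell = NA_real_,
                    mean_comp_sev = NA_real_, t_stat = NA_real_,
                    p_value = NA_real_, q_value = NA_real_,
                    call = "UNDETECTED", stringsAsFactors = FALSE)
  idx <- match(tested, ids)
  out$mean_comp_cell[idx] <- mean_cell
  out$mean_comp_sev[idx] <- mean_sev
  out$t_stat[idx] <- t_stat
  out$p_value[idx] <- p_value
  out$q_value[idx] <- fdr$q_value
  out$call[idx] <- call
  class(out) <- c("localization_table", "data.frame")
  out
}

#' Write a localization table as TSV
#'
#' @param table A `localization_table` from [classify_localization()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_localization_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' AU content and length statistics per localization class
#'
#' For each localization class, reports the mean AU fraction (count of A and
#' U bases over sequence length) and the mean sequence length, and tests each
#' statistic between the sEV-enriched and cell-enriched classes with the
#' pooled-variance t-test. A class with fewer than two members has its
#' statistics reported but the test skipped with a notice.
#'
#' @param table A `localization_table`.
#' @param seqs A [sequence_set()] covering the classified miRNAs.
#' @return List with `class_stats` (per-class data.frame) and `tests`
#'   (SEV vs CELL comparison for AU fraction and length).
#' @export
compare_class_sequence_stats <- function(table, seqs) {
  stopifnot(inherits(seqs, "sequence_set"))
  tab <- table[table$call %in% c("SEV_ENRICHED", "CELL_ENRICHED", "NEUTRAL"), ]
  missing <- setdiff(tab$mirna_id, names(seqs))
  if (length(missing) > 0)
    stop("no sequence for classified miRNA(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  s <- unclass(seqs)[tab$mirna_id]
  len <- nchar(s)
  au <- (nchar(gsub("[^AU]", "", s))) / len

  class_stats <- do.call(rbind, lapply(split(seq_len(nrow(tab)), tab$call),
    function(i) data.frame(call = tab$call[i[1]], n = length(i),
                           mean_au_fraction = mean(au[i]),
                           mean_length = mean(len[i]))))
  rownames(class_stats) <- NULL

  one_test <- function(x, y, what) {
    if (length(x) < 2 || length(y) < 2) {
      message("class with < 2 members: ", what, " test skipped")
      return(data.frame(statistic = what, t_stat = NA_real_,
                        p_value = NA_real_, tested = FALSE))
    }
    tt <- equal_variance_ttest(x, y)
    data.frame(statistic = what, t_stat = tt$t_stat, p_value = tt$p_value,
               tested = TRUE)
  }
  i_sev <- tab$call == "SEV_ENRICHED"
  i_cell <- tab$call == "CELL_ENRICHED"
  tests <- rbind(one_test(au[i_sev], au[i_cell], "au_fraction"),
                 one_test(len[i_sev], len[i_cell], "length"))
  list(class_stats = class_stats, tests = tests)
}
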