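#' Classify one patient's localization against the reference standard
#'
#' The reference standard is the resected region set together with the
#' postoperative Engel outcome. With overlap = (predicted intersects
#' resected) and favorable = (Engel class I):
#' TP = overlap & favorable; FP = overlap & unfavorable;
#' FN = no overlap & favorable; TN = no overlap & unfavorable.
#'
#' @param predicted integer set of predicted EZ region ids (the hub or
#'   epileptogenic set of the configured metric); may be empty (treated as
#'   no overlap, with a warning).
#' @param clinical a [clinical_record].
#' @return one of `"TP"`, `"FP"`, `"TN"`, `"FN"`.
#' @export
classify_patient <- function(predicted, clinical) {
  stopifnot(inherits(clinical, "clinical_record"))
  predicted <- as.integer(predicted)
  if (length(predicted) == 0L)
    warning("empty prediction set for patient ", clinical$patient_id,
            "; treated as no overlap")
  overlap <- length(intersect(predicted, clinical$resected_regions)) > 0L
  favorable <- clinical$engel_class == "I"
  if (overlap && favorable) "TP"
  else if (overlap && !favorable) "FP"
  else if (!overlap && favorable) "FN"
  else "TN"
}

#' Contingency table of localization outcomes
#'
#' @param tp,fp,tn,fn non-negative integer patient counts (total > 0).
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("empty contingency table")
  structure(as.list(counts), class = "contingency_table")
}

#' Tally classifications into a contingency table
#' @param labels character vector of `"TP"/"FP"/"TN"/"FN"`.
#' @return A [contingency_table].
#' @export
tally_classifications <- function(labels) {
  contingency_table(sum(labels == "TP"), sum(labels == "FP"),
                    sum(labels == "TN"), sum(labels == "FN"))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1")
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Diagnostic statistics of a localization contingency table
#'
#' The six standard statistics:
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' accuracy (TP+TN)/total, PLR = sens/(1-spec), NLR = (1-sens)/spec,
#' DOR = (TP*TN)/(FP*FN). Wilson score 95\% CIs for the three
#' proportions; log-scale normal approximation for PLR/NLR/DOR. A zero
#' cell triggers the Haldane 0.5 continuity correction for the ratio
#' statistics only (flagged in `method_notes`).
#'
#' @param ct a [contingency_table].
#' @param level CI level (default 0.95).
#' @return An object of class `diagnostic_report`: per-statistic values
#'   and `ci` (rows lower/upper), plus `counts` and `method_notes`.
#' @export
diagnostics <- function(ct, level = 0.95) {
  stopifnot(inherits(ct, "contingency_table"))
  tp <- ct$tp; fp <- ct$fp; tn <- ct$tn; fn <- ct$fn
  total <- tp + fp + tn + fn
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / total
  notes <- character()

  h <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(h == 0)) {
    h <- h + 0.5
    notes <- c(notes, "Haldane 0.5 correction applied to PLR/NLR/DOR (zero cell)")
  }
  sens_h <- h["tp"] / (h["tp"] + h["fn"])
  spec_h <- h["tn"] / (h["tn"] + h["fp"])
  plr <- unname(if (spec < 1) sens / (1 - spec) else sens_h / (1 - spec_h))
  nlr <- unname(if (spec > 0) (1 - sens) / spec else (1 - sens_h) / spec_h)
  dor <- unname(if (fp > 0 && fn > 0) tp * tn / (fp * fn)
                else h["tp"] * h["tn"] / (h["fp"] * h["fn"]))

  z <- qnorm(1 - (1 - level) / 2)
  log_ci <- function(est, se) exp(log(est) + c(-1, 1) * z * se)
  se_plr <- sqrt(1 / h["tp"] - 1 / (h["tp"] + h["fn"]) +
                 1 / h["fp"] - 1 / (h["fp"] + h["tn"]))
  se_nlr <- sqrt(1 / h["fn"] - 1 / (h["tp"] + h["fn"]) +
                 1 / h["tn"] - 1 / (h["fp"] + h["tn"]))
  se_dor <- sqrt(sum(1 / h))

  ci <- rbind(
    sensitivity = wilson_ci(tp, tp + fn, level),
    specificity = wilson_ci(tn, tn + fp, level),
    accuracy = wilson_ci(tp + tn, total, level),
    plr = log_ci(plr, se_plr),
    nlr = log_ci(nlr, se_nlr),
    dor = log_ci(dor, se_dor))
  colnames(ci) <- c("lower", "upper")
  structure(list(sensitivity = sens, specificity = spec, accuracy = acc,
                 plr = plr, nlr = nlr, dor = dor, ci = ci,
                 counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 method_notes = paste(notes, collapse = "; ")),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat("<diagnostic_report>  (counts tp/fp/tn/fn:",
      paste(x$counts, collapse = "/"), ")\n")
  for (s in c("sensitivity", "specificity", "accuracy", "plr", "nlr", "dor"))
    cat(sprintf("  %-12s %6.3f  [%.3f, %.3f]\n", s, x[[s]],
                x$ci[s, 1], x$ci[s, 2]))
  if (nzchar(x$method_notes)) cat("  note:", x$method_notes, "\n")
  invisible(x)
}

#' Compare localization performance of two metrics
#'
#' Builds the 2x2 correct-vs-incorrect table (correct = TP + TN) for the
#' two metrics and applies the Pearson chi-square test when all expected
#' counts are >= 5, otherwise Fisher's exact test (two-sided).
#'
#' @param ct_a,ct_b [contingency_table]s from the same cohort.
#' @param test `"auto"` (the expected-count rule), or force `"fisher"` /
#'   `"chisq"`.
#' @return list with `statistic` (NA for Fisher), `p_value`, `test`,
#'   `table`.
#' @export
compare_metrics <- function(ct_a, ct_b, test = c("auto", "fisher",
                                                 "chisq")) {
  test <- match.arg(test)
  stopifnot(inherits(ct_a, "contingency_table"),
            inherits(ct_b, "contingency_table"))
  correct <- c(ct_a$tp + ct_a$tn, ct_b$tp + ct_b$tn)
  incorrect <- c(ct_a$fp + ct_a$fn, ct_b$fp + ct_b$fn)
  tab <- rbind(correct, incorrect)
  colnames(tab) <- c("metric_a", "metric_b")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(statistic = NA_real_, p_value = 1, test = "degenerate",
                table = tab, note = "zero margin"))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_chisq <- switch(test, auto = all(expected >= 5),
                      chisq = TRUE, fisher = FALSE)
  if (use_chisq) {
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = "chi-square", table = tab)
  } else {
    ht <- fisher.test(tab)
    list(statistic = NA_real_, p_value = ht$p.value, test = "fisher",
         table = tab)
  }
}

#' Summarize Engel outcome classes
#'
#' @param records list of [clinical_record]s.
#' @return list with `counts` (named by class) and `favorable` (fraction
#'   Engel I).
#' @export
engel_summary <- function(records) {
  if (length(records) == 0L) stop("no clinical records")
  cls <- vapply(records, function(r) r$engel_class, "")
  counts <- table(factor(cls, levels = c("I", "II", "III", "IV")))
  list(counts = counts, favorable = unname(counts["I"]) / length(cls))
}

#' Per-metric contingency tables derived from the printed cohort results
#'
#' MRI-negative cohort (n = 15): TP/FP/TN/FN counts per network metric as
#' uniquely recovered from the published diagnostic statistics and their
#' Wilson confidence bounds (the counts themselves were not printed).
#' Packaged in `extdata/printed_derived_contingency.tsv`.
#'
#' @return named list of [contingency_table]s (`si`, `dc`, `dcout`,
#'   `dcin`).
#' @export
printed_contingency <- function() {
  path <- system.file("extdata", "printed_derived_contingency.tsv",
                      package = "eznetsi", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#")
  out <- lapply(seq_len(nrow(tab)), function(i)
    contingency_table(tab$tp[i], tab$fp[i], tab$tn[i], tab$fn[i]))
  names(out) <- tab$metric
  out
}
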