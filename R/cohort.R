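# Cohort-level comparisons: patient-reweighted, tissue-stratified burden
# contrasts with bootstrap confidence intervals and rank tests; dose-response
# regression; detection-vs-treatment association tests.

#' Equal-patient sample weights
#'
#' Samples from the same patient (within one group and tissue stratum) share
#' that patient's unit weight equally, so each patient contributes equally to
#' cohort summaries. The weights of one patient's samples sum to 1 and the
#' total weight equals the number of patients.
#'
#' @param patient_id Character vector, one entry per sample.
#' @return Numeric vector of positive per-sample weights.
#' @export
patient_weights <- function(patient_id) {
  if (length(patient_id) == 0L) stop("no samples")
  1 / ave(rep(1, length(patient_id)), patient_id, FUN = sum)
}

# Per-patient mean of sample values (one observation per patient).
.collapse_patients <- function(value, patient_id) {
  tapply(value, patient_id, mean)
}

.pct_increase <- function(a, b) {
  ma <- stats::median(a)
  if (ma == 0) stop("undefined percent increase: reference group median is 0")
  (stats::median(b) - ma) / ma * 100
}

#' Compare burden between two treatment groups
#'
#' Tissue-stratified comparison of a per-sample burden metric (mutations,
#' neoantigens, expressed neoantigens, ...) between a reference group `a` and
#' a comparison group `b`. Within each stratum, samples are collapsed to
#' per-patient means so each patient contributes one observation; the estimate
#' is the percent increase of group-b median over group-a median, with a
#' percentile bootstrap confidence interval obtained by resampling patients
#' (not samples) within each group, and a two-sided Mann-Whitney test on the
#' per-patient values. A pooled row combines the stratum estimates by a
#' patient-count-weighted mean.
#'
#' @param data Data frame with columns `patient_id`, `tissue`, `group` and
#'   `value` (one row per sample).
#' @param group_a,group_b Labels in `data$group`: reference and comparison
#'   group.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Optional RNG seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame with one row per stratum plus a `"pooled"` row:
#'   `stratum`, `median_pct_increase`, `ci_low`, `ci_high`, `mw_p`,
#'   `n_patients_a`, `n_patients_b`. Strata with fewer than two patients in
#'   either group are skipped with a warning.
#' @export
compare_groups <- function(data, group_a, group_b, n_boot = 2000,
                           seed = NULL, conf_level = 0.95) {
  stopifnot(all(c("patient_id", "tissue", "group", "value") %in% names(data)))
  if (!is.null(seed)) set.seed(seed)
  alpha <- (1 - conf_level) / 2
  strata <- sort(unique(data$tissue))
  rows <- list()
  for (st in strata) {
    da <- data[data$tissue == st & data$group == group_a, , drop = FALSE]
    db <- data[data$tissue == st & data$group == group_b, , drop = FALSE]
    pa <- .collapse_patients(da$value, da$patient_id)
    pb <- .collapse_patients(db$value, db$patient_id)
    if (length(pa) < 2L || length(pb) < 2L) {
      warning("stratum ", st, " skipped: fewer than 2 patients per group")
      next
    }
    est <- .pct_increase(pa, pb)
    boot <- vapply(seq_len(n_boot), function(i) {
      ra <- pa[sample.int(length(pa), replace = TRUE)]
      rb <- pb[sample.int(length(pb), replace = TRUE)]
      ma <- stats::median(ra)
      if (ma == 0) return(NA_real_)
      (stats::median(rb) - ma) / ma * 100
    }, numeric(1))
    ci <- stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    mw <- stats::wilcox.test(pb, pa, exact = FALSE)$p.value
    rows[[st]] <- data.frame(
      stratum = st, median_pct_increase = est,
      ci_low = ci[1L], ci_high = ci[2L], mw_p = mw,
      n_patients_a = length(pa), n_patients_b = length(pb),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) stop("no stratum had at least 2 patients per group")
  out <- do.call(rbind, rows)
  w <- out$n_patients_a + out$n_patients_b
  pooled <- data.frame(
    stratum = "pooled",
    median_pct_increase = sum(out$median_pct_increase * w) / sum(w),
    ci_low = sum(out$ci_low * w) / sum(w),
    ci_high = sum(out$ci_high * w) / sum(w),
    mw_p = NA_real_,
    n_patients_a = sum(out$n_patients_a),
    n_patients_b = sum(out$n_patients_b),
    stringsAsFactors = FALSE
  )
  out <- rbind(out, pooled)
  rownames(out) <- NULL
  out
}

#' Dose-response regression of attributed mutations on treatment cycles
#'
#' Ordinary least-squares fit of per-sample chemotherapy-signature mutation
#' counts on the number of chemotherapy cycles administered, with the
#' closed-form normal-theory confidence interval for the slope and the
#' Pearson correlation.
#'
#' @param mutations Numeric vector: attributed mutation (or neoantigen)
#'   counts, one per sample.
#' @param cycles Numeric vector of cycle counts; must vary across samples.
#' @param conf_level Confidence level for the slope interval (default 0.95).
#' @return List with `slope`, `ci_low`, `ci_high`, `correlation`,
#'   `intercept`, `n`.
#' @export
dose_response <- function(mutations, cycles, conf_level = 0.95) {
  stopifnot(length(mutations) == length(cycles))
  if (length(cycles) < 3L) stop("dose-response needs at least 3 samples")
  if (stats::var(cycles) == 0) stop("cycle counts do not vary")
  fit <- stats::lm(mutations ~ cycles)
  ci <- stats::confint(fit, "cycles", level = conf_level)
  list(
    slope = unname(stats::coef(fit)["cycles"]),
    ci_low = ci[1L], ci_high = ci[2L],
    correlation = if (stats::var(mutations) == 0) NA_real_ else
      stats::cor(mutations, cycles),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    n = length(cycles)
  )
}

#' Association between signature detection and treatment exposure
#'
#' Two-sided Fisher exact test on the 2x2 table of signature detection versus
#' drug exposure across samples, with Bonferroni adjustment for the number of
#' signatures tested.
#'
#' @param detected Logical vector: signature detected in each sample.
#' @param exposed Logical vector: sample exposed to the drug.
#' @param n_signatures_tested Bonferroni factor (default 1).
#' @return List with `table` (2x2, detected x exposed), `odds_ratio`,
#'   `p_value`, `p_adjusted`.
#' @export
detection_association <- function(detected, exposed, n_signatures_tested = 1) {
  stopifnot(length(detected) == length(exposed))
  tab <- table(
    factor(detected, levels = c(TRUE, FALSE)),
    factor(exposed, levels = c(TRUE, FALSE)),
    dnn = c("detected", "exposed")
  )
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(
    table = tab,
    odds_ratio = unname(ft$estimate),
    p_value = ft$p.value,
    p_adjusted = min(1, ft$p.value * n_signatures_tested)
  )
}
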