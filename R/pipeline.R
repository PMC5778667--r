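# End-to-end orchestration: from a cohort mutation table to per-sample
# deconvolutions and signature attributions.

#' Run deconvolution and attribution across a cohort
#'
#' For every sample: merges adjacent SNVs into MNVs, applies the
#' [is_present()] read-support filter, classifies the surviving SNVs into the
#' 96 contexts, deconvolves the context counts against the catalogue, and
#' attributes mutations (and their neoantigen yields) to signatures by
#' posterior probability. Relapse samples of patients that also contributed a
#' primary sample are additionally deconvolved on the mutations unique to the
#' post-treatment timepoint ([is_unique_to_post()]); attribution of each
#' mutation then uses the deconvolution matching its uniqueness status.
#'
#' @param mutations Mutation record table for the whole cohort.
#' @param meta Sample metadata with columns `sample_id`, `patient_id`,
#'   `group` (`primary_untreated`, `primary_treated`, `relapse_treated`).
#' @param catalogue A [signature_catalogue()].
#' @param reference Named `DNAStringSet` / character contigs.
#' @param threshold Detection threshold passed to [deconvolve()].
#' @param merge_mnvs Merge adjacent SNVs first (default `TRUE`).
#' @return List with `deconvolutions` (per sample: list of `full` and
#'   possibly `post_unique` [deconvolve()] results) and `attribution` (row
#'   bind of per-sample [expected_counts()] tables). Samples with no present
#'   SNVs are skipped with a warning.
#' @export
run_cohort_attribution <- function(mutations, meta, catalogue, reference,
                                   threshold = 0.06, merge_mnvs = TRUE) {
  if (merge_mnvs) mutations <- merge_adjacent_snvs(mutations)
  mutations <- mutations[is_present(mutations$dna_alt_reads,
                                    mutations$dna_total_reads), , drop = FALSE]
  has_primary <- unique(meta$patient_id[meta$group == "primary_untreated"])
  decs <- list()
  atts <- list()
  for (sid in meta$sample_id) {
    rows <- mutations[mutations$sample_id == sid, , drop = FALSE]
    if (nrow(rows) == 0L) {
      warning("sample ", sid, " has no present mutations; skipped")
      next
    }
    snv <- rows$variant_class == "SNV"
    ctx <- rep(NA_integer_, nrow(rows))
    ctx[snv] <- as.integer(classify_contexts(
      rows$chrom[snv], rows$pos[snv], rows$ref[snv], rows$alt[snv],
      reference, quiet = TRUE
    ))
    rows$context <- ctx
    counts <- stats::setNames(numeric(96L), sbs_contexts())
    tab <- tabulate(ctx[snv][!is.na(ctx[snv])], nbins = 96L)
    counts[] <- tab
    if (sum(counts) == 0) {
      warning("sample ", sid, " has no classifiable SNVs; skipped")
      next
    }
    full <- deconvolve(counts, catalogue, threshold)

    m <- meta[meta$sample_id == sid, ]
    post_unique <- NULL
    flag <- NULL
    paired <- m$group == "relapse_treated" && m$patient_id %in% has_primary &&
      !is.null(rows$pre_total_reads)
    if (paired) {
      flag <- rep(FALSE, nrow(rows))
      flag[snv] <- is_unique_to_post(rows$pre_total_reads[snv],
                                     rows$pre_alt_reads[snv])
      u_counts <- stats::setNames(numeric(96L), sbs_contexts())
      uc <- ctx[snv & flag]
      u_counts[] <- tabulate(uc[!is.na(uc)], nbins = 96L)
      if (sum(u_counts) > 0) {
        post_unique <- deconvolve(u_counts, catalogue, threshold)
      } else {
        flag <- NULL
      }
    }
    decs[[sid]] <- list(full = full, post_unique = post_unique)
    snv_flag <- if (is.null(flag)) NULL else flag[snv]
    att <- expected_counts(
      rows, full, catalogue,
      post_unique = post_unique,
      post_unique_flag = if (is.null(post_unique)) NULL else snv_flag
    )
    atts[[sid]] <- att
  }
  list(
    deconvolutions = decs,
    attribution = do.call(rbind, lapply(atts, as.data.frame))
  )
}

#' Per-sample fraction of burden attributed to chemotherapy signatures
#'
#' Summarises an attribution table into, per sample, the fraction of SNVs,
#' neoantigens and expressed neoantigens attributed to a set of chemotherapy
#' signatures. Denominators are SNV-derived totals (the `"MNV/indel"`
#' category is excluded; `"Other SNV"` counts toward the denominator).
#'
#' @param attribution Attribution table from [run_cohort_attribution()] or
#'   row-bound [expected_counts()] results.
#' @param chemo_signatures Character vector of signature names counted as
#'   chemotherapy-associated (default [chemo_signature_names()]).
#' @return Data frame with one row per sample: `sample_id`,
#'   `chemo_snv_fraction`, `chemo_neoantigen_fraction`,
#'   `chemo_expressed_neoantigen_fraction`, `n_snvs`.
#' @export
chemo_fraction_summary <- function(attribution,
                                   chemo_signatures = chemo_signature_names()) {
  snv_rows <- attribution$category != MNV_INDEL
  frac <- function(num, den) if (den > 0) num / den else 0
  out <- lapply(split(attribution[snv_rows, , drop = FALSE],
                      attribution$sample_id[snv_rows]), function(d) {
    ch <- d$category %in% chemo_signatures
    data.frame(
      sample_id = d$sample_id[1L],
      chemo_snv_fraction = frac(sum(d$expected_snvs[ch]), sum(d$expected_snvs)),
      chemo_neoantigen_fraction = frac(sum(d$expected_neoantigens[ch]),
                                       sum(d$expected_neoantigens)),
      chemo_expressed_neoantigen_fraction =
        frac(sum(d$expected_expressed_neoantigens[ch]),
             sum(d$expected_expressed_neoantigens)),
      n_snvs = sum(d$expected_snvs),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-sample burden metrics from a mutation table
#'
#' Counts present mutations, neoantigens and expressed neoantigens per sample
#' (after optional MNV merging), for use with [compare_groups()].
#'
#' @param mutations Mutation record table.
#' @param meta Sample metadata (`sample_id`, `patient_id`, `group`,
#'   `tissue`).
#' @param merge_mnvs Merge adjacent SNVs first (default `TRUE`).
#' @return Data frame with one row per sample and columns `sample_id`,
#'   `patient_id`, `group`, `tissue`, `mutations`, `neoantigens`,
#'   `expressed_neoantigens`.
#' @export
burden_summary <- function(mutations, meta, merge_mnvs = TRUE) {
  if (merge_mnvs) mutations <- merge_adjacent_snvs(mutations)
  mutations <- mutations[is_present(mutations$dna_alt_reads,
                                    mutations$dna_total_reads), , drop = FALSE]
  expressed <- is_expressed(mutations$rna_alt_reads)
  agg <- lapply(split(seq_len(nrow(mutations)), mutations$sample_id), function(i) {
    data.frame(
      sample_id = mutations$sample_id[i[1L]],
      mutations = length(i),
      neoantigens = sum(mutations$neoantigen_count[i]),
      expressed_neoantigens =
        sum(mutations$expressed_neoantigen_count[i] * expressed[i]),
      stringsAsFactors = FALSE
    )
  })
  agg <- do.call(rbind, agg)
  out <- merge(meta[, c("sample_id", "patient_id", "group", "tissue")], agg,
               by = "sample_id", all.x = TRUE)
  num <- c("mutations", "neoantigens", "expressed_neoantigens")
  out[num] <- lapply(out[num], function(x) ifelse(is.na(x), 0, x))
  out
}
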