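# Mutation tables: construction/validation, read-support filters, and
# adjacent-SNV merging.

MUTATION_COLUMNS <- c(
  "patient_id", "sample_id", "chrom", "pos", "ref", "alt",
  "dna_alt_reads", "dna_total_reads", "rna_alt_reads",
  "neoantigen_count", "expressed_neoantigen_count", "variant_class"
)

.infer_variant_class <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  out <- rep("MNV", length(ref))
  out[nr == 1L & na == 1L] <- "SNV"
  out[na > nr] <- "INS"
  out[na < nr] <- "DEL"
  out
}

#' Build and validate a mutation record table
#'
#' A mutation record table is a plain `data.frame` with one row per somatic
#' variant and the columns `patient_id`, `sample_id`, `chrom`, `pos` (1-based),
#' `ref`, `alt`, `dna_alt_reads`, `dna_total_reads`, `rna_alt_reads`,
#' `neoantigen_count`, `expressed_neoantigen_count`, `variant_class`
#' (`"SNV"`, `"MNV"`, `"INS"` or `"DEL"`), and optionally `pre_total_reads` /
#' `pre_alt_reads` holding coverage of the site in a patient-matched
#' pre-treatment sample (`NA` where no matched sample exists).
#'
#' Missing count columns default to zero; a missing `variant_class` is inferred
#' from `ref`/`alt` lengths. Invariants enforced: counts are nonnegative,
#' `dna_alt_reads <= dna_total_reads`,
#' `expressed_neoantigen_count <= neoantigen_count`, and SNV rows have
#' single-base `ref != alt`.
#'
#' @param data A data frame with (a superset of) the columns above.
#' @return The validated data frame with canonical column order.
#' @export
mutation_records <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (col in c("rna_alt_reads", "neoantigen_count", "expressed_neoantigen_count")) {
    if (is.null(data[[col]])) data[[col]] <- 0L
  }
  if (is.null(data[["variant_class"]])) {
    data$variant_class <- .infer_variant_class(data$ref, data$alt)
  }
  missing <- setdiff(MUTATION_COLUMNS, names(data))
  if (length(missing)) {
    stop("mutation table lacks columns: ", paste(missing, collapse = ", "))
  }
  counts <- c("pos", "dna_alt_reads", "dna_total_reads", "rna_alt_reads",
              "neoantigen_count", "expressed_neoantigen_count")
  for (col in counts) {
    if (any(is.na(data[[col]])) || any(data[[col]] < 0)) {
      stop("column ", col, " must be nonnegative and non-missing")
    }
  }
  if (any(data$dna_alt_reads > data$dna_total_reads)) {
    stop("dna_alt_reads exceeds dna_total_reads")
  }
  if (any(data$expressed_neoantigen_count > data$neoantigen_count)) {
    stop("expressed_neoantigen_count exceeds neoantigen_count")
  }
  snv <- data$variant_class == "SNV"
  bad_snv <- snv & (nchar(data$ref) != 1L | nchar(data$alt) != 1L |
                      data$ref == data$alt)
  if (any(bad_snv)) stop("SNV rows must have single-base ref != alt")
  extra <- setdiff(names(data), MUTATION_COLUMNS)
  data[, c(MUTATION_COLUMNS, extra), drop = FALSE]
}

#' Read a mutation table from CSV
#'
#' Flat-file mirror of a per-cohort somatic variant listing: one row per
#' variant with patient/sample identifiers, coordinates, alleles, DNA and RNA
#' read support and neoantigen yields.
#'
#' @param path Path to the CSV file.
#' @return A validated mutation record table (see [mutation_records()]).
#' @export
read_mutations_csv <- function(path) {
  mutation_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read mutations for one sample from a VCF file
#'
#' Reads biallelic records from a standard VCF and extracts DNA read support
#' from per-sample FORMAT fields (by default `AD` for allele depths and `DP`
#' for total depth). RNA support and neoantigen yields are not part of a
#' standard VCF and default to zero unless supplied in INFO-style columns of a
#' companion table.
#'
#' @param path Path to a VCF file (one tumor sample).
#' @param patient_id,sample_id Identifiers to stamp on the records.
#' @param ad_field,dp_field FORMAT field names for allele depths / total depth.
#' @return A validated mutation record table.
#' @export
read_mutation_vcf <- function(path, patient_id, sample_id,
                              ad_field = "AD", dp_field = "DP") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF input requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = ad_field)[, 1L]
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = dp_field)[, 1L]))
  alt_reads <- suppressWarnings(
    as.integer(vapply(strsplit(ad, ","), function(x) x[length(x)], character(1)))
  )
  alt_reads[is.na(alt_reads)] <- 0L
  dp[is.na(dp)] <- 0L
  mutation_records(data.frame(
    patient_id = patient_id, sample_id = sample_id,
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    dna_alt_reads = pmin(alt_reads, dp), dna_total_reads = dp,
    stringsAsFactors = FALSE
  ))
}

#' Presence filter on DNA read support
#'
#' A mutation is considered present in a sample when more than 5% of the
#' overlapping reads and at least 6 reads support the alternate allele.
#' The VAF comparison is strict (`> 0.05`); the read-count comparison is
#' inclusive (`>= 6`). Zero total reads gives `FALSE`, not an error.
#'
#' @param dna_alt_reads,dna_total_reads Integer vectors of alternate-allele
#'   and total read counts.
#' @return Logical vector.
#' @export
is_present <- function(dna_alt_reads, dna_total_reads) {
  dna_total_reads > 0 &
    dna_alt_reads / pmax(dna_total_reads, 1) > 0.05 &
    dna_alt_reads >= 6
}

#' Expression filter on RNA read support
#'
#' A mutation counts as expressed when 3 or more RNA reads support the
#' alternate allele.
#'
#' @param rna_alt_reads Integer vector.
#' @return Logical vector.
#' @export
is_expressed <- function(rna_alt_reads) {
  rna_alt_reads >= 3
}

#' Post-treatment uniqueness filter
#'
#' In patients with a matched pre-treatment sample, a mutation is unique to
#' the post-treatment sample when the pre-treatment sample has greater than 30
#' reads of coverage at the site and no variant reads. Missing pre-treatment
#' coverage (`NA`) means the site is not assessable and yields `FALSE`.
#'
#' @param pre_total_reads,pre_alt_reads Coverage and variant reads at the site
#'   in the matched pre-treatment sample.
#' @return Logical vector.
#' @export
is_unique_to_post <- function(pre_total_reads, pre_alt_reads) {
  out <- !is.na(pre_total_reads) & !is.na(pre_alt_reads) &
    pre_total_reads > 30 & pre_alt_reads == 0
  out
}

# Merge one run of adjacent SNV rows (already ordered by position) into a
# single MNV row. Read support is the elementwise minimum (presence of the
# MNV requires presence of every constituent); neoantigen yields are summed;
# pre-treatment alt reads take the maximum so that an MNV is post-unique only
# if every constituent is.
.merge_run <- function(rows) {
  out <- rows[1L, , drop = FALSE]
  out$ref <- paste(rows$ref, collapse = "")
  out$alt <- paste(rows$alt, collapse = "")
  out$variant_class <- "MNV"
  out$dna_alt_reads <- min(rows$dna_alt_reads)
  out$dna_total_reads <- min(rows$dna_total_reads)
  out$rna_alt_reads <- min(rows$rna_alt_reads)
  out$neoantigen_count <- sum(rows$neoantigen_count)
  out$expressed_neoantigen_count <- sum(rows$expressed_neoantigen_count)
  if (!is.null(rows$pre_total_reads)) {
    out$pre_total_reads <- min(rows$pre_total_reads)
    out$pre_alt_reads <- max(rows$pre_alt_reads)
  }
  out
}

#' Merge adjacent SNVs into multinucleotide variants
#'
#' Runs of SNVs at consecutive positions on the same contig, for the same
#' patient and sample, are combined into a single MNV record with concatenated
#' alleles. MNVs are carried through burden accounting but excluded from the
#' 96-channel tabulation and deconvolution, which consider SNVs only.
#'
#' @param records Mutation record table; non-SNV rows pass through untouched.
#' @return Mutation record table with merged MNV rows, ordered by sample,
#'   contig and position.
#' @export
merge_adjacent_snvs <- function(records) {
  snv <- records[records$variant_class == "SNV", , drop = FALSE]
  other <- records[records$variant_class != "SNV", , drop = FALSE]
  if (nrow(snv) == 0L) return(records)
  snv <- snv[order(snv$patient_id, snv$sample_id, snv$chrom, snv$pos), ,
             drop = FALSE]
  n <- nrow(snv)
  new_run <- c(TRUE, snv$patient_id[-1L] != snv$patient_id[-n] |
                 snv$sample_id[-1L] != snv$sample_id[-n] |
                 snv$chrom[-1L] != snv$chrom[-n] |
                 diff(snv$pos) != 1L)
  run_id <- cumsum(new_run)
  run_len <- tabulate(run_id)
  multi <- which(run_len > 1L)
  if (length(multi) == 0L) {
    out <- rbind(snv, other)
  } else {
    in_multi <- run_id %in% multi
    merged <- do.call(rbind, lapply(
      split(snv[in_multi, , drop = FALSE], run_id[in_multi]), .merge_run
    ))
    out <- rbind(snv[!in_multi, , drop = FALSE], merged, other)
  }
  out <- out[order(out$sample_id, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write per-sample context counts to CSV
#'
#' @param counts Named 96-vector from [tabulate_contexts()].
#' @param path Output path. The file has columns `context`, `count`.
#' @export
write_context_counts <- function(counts, path) {
  utils::write.csv(
    data.frame(context = names(counts), count = as.numeric(counts)),
    path, row.names = FALSE
  )
}

#' Read per-sample context counts from CSV
#'
#' @param path CSV with columns `context`, `count` (96 rows).
#' @return Named numeric 96-vector in [sbs_contexts()] order.
#' @export
read_context_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(sbs_contexts() %in% df$context)) {
    stop("context-count file must cover all 96 contexts")
  }
  stats::setNames(df$count[match(sbs_contexts(), df$context)], sbs_contexts())
}
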