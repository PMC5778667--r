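# Per-mutation signature attribution by Bayes' rule, and aggregation into
# expected mutation / neoantigen counts per signature.
#
# For a mutation in context j of sample i, the probability that detected
# signature s generated it is
#   Pr[s | j] = H_{s,j} D_{i,s} / sum_{s'} H_{s',j} D_{i,s'}
# where D are the sample's (renormalised) deconvolution weights and H the
# catalogue. Sums of these posteriors give expected per-signature counts;
# weighting each term by the mutation's neoantigen yield gives expected
# neoantigen counts.

OTHER_SNV <- "Other SNV"
MNV_INDEL <- "MNV/indel"

#' Posterior signature probabilities for one mutation context
#'
#' Applies Bayes' rule over the sample's detected signatures. If every
#' detected signature places zero probability on the context, the mutation
#' cannot be attributed and `NULL` is returned; such mutations fall into the
#' `"Other SNV"` category during aggregation.
#'
#' @param context Channel index in `1:96` (or a context label).
#' @param weights A [deconvolve()] result for the sample.
#' @param catalogue The [signature_catalogue()] used for the deconvolution.
#' @return Named probability vector over detected signatures (sums to 1), or
#'   `NULL` when the context has zero likelihood under all detected
#'   signatures.
#' @export
posterior_signature_prob <- function(context, weights, catalogue) {
  if (is.character(context)) context <- match(context, sbs_contexts())
  stopifnot(!is.na(context), context >= 1L, context <= 96L)
  det <- names(weights$detected)[weights$detected]
  if (length(det) == 0L) return(NULL)
  num <- unclass(catalogue)[det, context] * weights$weights[det]
  s <- sum(num)
  if (s == 0) return(NULL)
  num / s
}

#' Select the deconvolution matrix for a mutation
#'
#' Treated samples with a patient-matched pre-treatment sample are deconvolved
#' twice: once on all mutations and once restricted to mutations unique to the
#' post-treatment sample. Attribution of each mutation then uses the matching
#' weights: the post-unique deconvolution when the mutation passed
#' [is_unique_to_post()] and a post-unique deconvolution exists, otherwise the
#' full-sample deconvolution.
#'
#' @param full Full-sample [deconvolve()] result.
#' @param post_unique Post-unique [deconvolve()] result, or `NULL` for
#'   unpaired samples.
#' @param post_unique_flag Logical: was the mutation unique to the
#'   post-treatment sample?
#' @return A `deconvolution` object.
#' @export
select_weight_matrix <- function(full, post_unique, post_unique_flag) {
  if (isTRUE(post_unique_flag)) {
    if (is.null(post_unique)) {
      stop("mutation flagged post-unique but no post-unique deconvolution exists")
    }
    post_unique
  } else {
    full
  }
}

# Posterior matrix (mutations x detected signatures) for a vector of context
# indices under one deconvolution. Rows with no support sum to zero.
.posterior_matrix <- function(contexts, weights, catalogue) {
  det <- names(weights$detected)[weights$detected]
  n <- length(contexts)
  if (length(det) == 0L) {
    return(matrix(0, nrow = n, ncol = 0))
  }
  H <- unclass(catalogue)[det, , drop = FALSE]
  num <- t(H[, contexts, drop = FALSE]) *
    rep(weights$weights[det], each = n)
  denom <- rowSums(num)
  pos <- denom > 0
  num[pos, ] <- num[pos, , drop = FALSE] / denom[pos]
  num[!pos, ] <- 0
  colnames(num) <- det
  num
}

#' Expected per-signature mutation and neoantigen counts for one sample
#'
#' Sums per-mutation posterior signature probabilities into the expected
#' number of SNVs attributable to each signature, and the analogous
#' neoantigen-weighted and expressed-neoantigen-weighted sums. SNVs with zero
#' likelihood under every detected signature are tallied in the
#' `"Other SNV"` category; MNV and indel records bypass attribution entirely
#' and are tallied (with their neoantigen yields) in the `"MNV/indel"`
#' category. Expressed-neoantigen sums are restricted to mutations passing
#' [is_expressed()].
#'
#' For paired post-treatment samples, pass the post-unique deconvolution via
#' `post_unique` and a logical `post_unique_flag` column (or vector); each
#' mutation then uses the weights chosen by [select_weight_matrix()].
#'
#' @param mutations Mutation record table for one sample (rows should already
#'   pass [is_present()]).
#' @param weights Full-sample [deconvolve()] result.
#' @param catalogue The [signature_catalogue()] used.
#' @param reference Reference sequences for context classification; not needed
#'   if `mutations` carries a precomputed integer `context` column.
#' @param post_unique Optional post-unique `deconvolution` for paired samples.
#' @param post_unique_flag Optional logical vector (defaults to the result of
#'   [is_unique_to_post()] on the `pre_*` columns when `post_unique` is
#'   given).
#' @return Object of class `attribution`: a data frame with one row per
#'   category (signature, `"Other SNV"`, `"MNV/indel"`) and columns
#'   `sample_id`, `category`, `expected_snvs`, `expected_neoantigens`,
#'   `expected_expressed_neoantigens`. SNVs rejected during context
#'   classification are dropped with a message and recorded in the
#'   `"n_rejected"` attribute.
#' @export
expected_counts <- function(mutations, weights, catalogue, reference = NULL,
                            post_unique = NULL, post_unique_flag = NULL) {
  sample_id <- if (nrow(mutations)) mutations$sample_id[1L] else NA_character_
  snv <- mutations$variant_class == "SNV"
  other <- mutations[!snv, , drop = FALSE]
  muts <- mutations[snv, , drop = FALSE]

  if (is.null(muts$context)) {
    if (is.null(reference)) {
      stop("either a context column or a reference is required")
    }
    muts$context <- as.integer(
      classify_contexts(muts$chrom, muts$pos, muts$ref, muts$alt, reference)
    )
  }
  n_rejected <- sum(is.na(muts$context))
  if (n_rejected > 0L) {
    message(n_rejected, " SNV(s) dropped: context unclassifiable")
    muts <- muts[!is.na(muts$context), , drop = FALSE]
  }

  if (is.null(post_unique_flag) && !is.null(post_unique)) {
    if (is.null(muts$pre_total_reads)) {
      stop("post-unique attribution needs pre_total_reads/pre_alt_reads columns")
    }
    post_unique_flag <- is_unique_to_post(muts$pre_total_reads, muts$pre_alt_reads)
  }
  if (is.null(post_unique_flag)) post_unique_flag <- rep(FALSE, nrow(muts))

  sig_names <- rownames(catalogue)
  acc <- matrix(0, nrow = length(sig_names) + 1L, ncol = 3L,
                dimnames = list(c(sig_names, OTHER_SNV),
                                c("snv", "neo", "expr_neo")))

  add_subset <- function(rows, dec) {
    if (nrow(rows) == 0L) return()
    P <- .posterior_matrix(rows$context, dec, catalogue)
    expressed <- is_expressed(rows$rna_alt_reads)
    if (ncol(P) > 0L) {
      acc[colnames(P), "snv"] <<- acc[colnames(P), "snv"] + colSums(P)
      acc[colnames(P), "neo"] <<- acc[colnames(P), "neo"] +
        colSums(P * rows$neoantigen_count)
      acc[colnames(P), "expr_neo"] <<- acc[colnames(P), "expr_neo"] +
        colSums(P * (rows$expressed_neoantigen_count * expressed))
      unattributed <- rowSums(P) == 0
    } else {
      unattributed <- rep(TRUE, nrow(rows))
    }
    if (any(unattributed)) {
      acc[OTHER_SNV, "snv"] <<- acc[OTHER_SNV, "snv"] + sum(unattributed)
      acc[OTHER_SNV, "neo"] <<- acc[OTHER_SNV, "neo"] +
        sum(rows$neoantigen_count[unattributed])
      acc[OTHER_SNV, "expr_neo"] <<- acc[OTHER_SNV, "expr_neo"] +
        sum((rows$expressed_neoantigen_count * expressed)[unattributed])
    }
  }

  flag <- as.logical(post_unique_flag)
  add_subset(muts[!flag, , drop = FALSE],
             select_weight_matrix(weights, post_unique, FALSE))
  if (any(flag)) {
    add_subset(muts[flag, , drop = FALSE],
               select_weight_matrix(weights, post_unique, TRUE))
  }

  expressed_other <- is_expressed(other$rna_alt_reads)
  out <- data.frame(
    sample_id = sample_id,
    category = c(rownames(acc), MNV_INDEL),
    expected_snvs = c(acc[, "snv"], nrow(other)),
    expected_neoantigens = c(acc[, "neo"], sum(other$neoantigen_count)),
    expected_expressed_neoantigens = c(
      acc[, "expr_neo"],
      sum(other$expressed_neoantigen_count * expressed_other)
    ),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, class = c("attribution", "data.frame"), n_rejected = n_rejected)
}

#' Write attribution results to CSV
#'
#' @param attributions A single [expected_counts()] result or a list of them
#'   (one per sample); rows are concatenated.
#' @param path Output path.
#' @export
write_attribution_csv <- function(attributions, path) {
  if (inherits(attributions, "attribution")) attributions <- list(attributions)
  utils::write.csv(do.call(rbind, lapply(attributions, as.data.frame)),
                   path, row.names = FALSE)
}
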