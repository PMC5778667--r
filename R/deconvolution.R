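# Per-sample signature deconvolution by iterated thresholded nonnegative
# least squares against a catalogue of known signatures.

#' Build and validate a signature catalogue
#'
#' A catalogue is a matrix with one row per signature and 96 columns in
#' [sbs_contexts()] order; each row is a probability vector over the
#' substitution channels. Rows are renormalised to sum to one. A warning is
#' emitted when two catalogue rows are nearly collinear (pairwise cosine
#' similarity above 0.99), since deconvolution cannot reliably separate them.
#'
#' @param x Numeric matrix (signatures in rows) with unique rownames, or a
#'   data frame in the 96-row CSV layout (a `context` column plus one column
#'   per signature).
#' @return Matrix of class `signature_catalogue`.
#' @export
signature_catalogue <- function(x) {
  if (is.data.frame(x)) {
    if (!"context" %in% names(x)) stop("data frame catalogue needs a context column")
    ord <- match(sbs_contexts(), x$context)
    if (any(is.na(ord))) stop("catalogue must cover all 96 contexts")
    x <- t(as.matrix(x[ord, setdiff(names(x), "context"), drop = FALSE]))
  }
  x <- as.matrix(x)
  if (ncol(x) != 96L) stop("a signature catalogue has 96 columns")
  if (nrow(x) < 1L) stop("a signature catalogue needs at least one signature")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    stop("signatures must have unique names (rownames)")
  }
  if (any(x < 0) || any(is.na(x))) stop("signature entries must be nonnegative")
  rs <- rowSums(x)
  if (any(rs <= 0)) stop("every signature must have positive mass")
  x <- x / rs
  colnames(x) <- sbs_contexts()
  if (nrow(x) > 1L) {
    xn <- x / sqrt(rowSums(x^2))
    cs <- tcrossprod(xn)
    diag(cs) <- 0
    if (any(cs > 0.99)) {
      pair <- which(cs == max(cs), arr.ind = TRUE)[1L, ]
      warning("nearly collinear catalogue rows: ",
              rownames(x)[pair[1L]], " and ", rownames(x)[pair[2L]],
              " (cosine > 0.99)")
    }
  }
  structure(x, class = c("signature_catalogue", "matrix", "array"))
}

#' Read / write a signature catalogue CSV
#'
#' The file layout is 96 rows (one per context) with a `context` column and
#' one numeric column per signature.
#'
#' @param path File path.
#' @return `read_catalogue_csv()` returns a `signature_catalogue`.
#' @export
read_catalogue_csv <- function(path) {
  signature_catalogue(utils::read.csv(path, check.names = FALSE,
                                      stringsAsFactors = FALSE))
}

#' @rdname read_catalogue_csv
#' @param catalogue A `signature_catalogue`.
#' @export
write_catalogue_csv <- function(catalogue, path) {
  df <- data.frame(context = sbs_contexts(), t(unclass(catalogue)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Estimate a sample's signature mixture
#'
#' Normalises the sample's 96-channel SNV counts to frequencies `f` and finds
#' nonnegative signature weights `w` minimising \eqn{\|f - H^T w\|_2} against
#' the catalogue `H` (rows are signatures). Signatures whose weight falls
#' below the detection threshold are removed and the restricted problem is
#' re-solved, repeating until every surviving weight clears the threshold.
#' The surviving weights are then renormalised to sum to one; a signature is
#' flagged as detected when its final weight is at least the threshold
#' (weights below the threshold are considered undetected).
#'
#' The default threshold of 6% of SNVs follows the detection cutoff
#' recommended for signature refitting against curated catalogues.
#'
#' @param sample Named 96-vector of SNV context counts
#'   (see [tabulate_contexts()]), or a bare numeric 96-vector in
#'   [sbs_contexts()] order. Must contain at least one SNV.
#' @param catalogue A [signature_catalogue()].
#' @param threshold Detection threshold on mixture weights (default 0.06).
#' @return Object of class `deconvolution`: list with `weights` (named,
#'   renormalised over detected signatures), `raw_weights` (final NNLS
#'   solution before renormalisation), `detected` (named logical), `residual`
#'   (L2 reconstruction error of the final fit), `n_snvs` and `threshold`.
#' @export
deconvolve <- function(sample, catalogue, threshold = 0.06) {
  stopifnot(inherits(catalogue, "signature_catalogue"))
  counts <- as.numeric(sample)
  if (length(counts) != 96L) stop("sample counts must have 96 channels")
  total <- sum(counts)
  if (total <= 0) stop("no SNVs to deconvolve")
  f <- counts / total
  H <- unclass(catalogue)
  sigs <- rownames(H)

  active <- sigs
  raw <- stats::setNames(numeric(length(sigs)), sigs)
  residual <- sqrt(sum(f^2))
  while (length(active) > 0L) {
    sol <- pracma::lsqnonneg(t(H[active, , drop = FALSE]), f)
    w <- stats::setNames(sol$x, active)
    raw[] <- 0
    raw[active] <- w
    residual <- sqrt(max(sol$resid.norm, 0))
    # inclusive threshold with a tiny relative guard against float noise
    below <- names(w)[w < threshold * (1 - 1e-9)]
    if (length(below) == 0L) break
    active <- setdiff(active, below)
  }
  if (length(active) == 0L) raw[] <- 0

  weights <- if (sum(raw) > 0) raw / sum(raw) else raw
  structure(
    list(
      weights = weights,
      raw_weights = raw,
      detected = weights >= threshold * (1 - 1e-9) & raw > 0,
      residual = residual,
      n_snvs = total,
      threshold = threshold
    ),
    class = "deconvolution"
  )
}

#' @export
print.deconvolution <- function(x, ...) {
  det <- names(x$weights)[x$detected]
  cat("<deconvolution> ", x$n_snvs, " SNVs; detected: ",
      if (length(det)) paste0(det, " (", sprintf("%.2f", x$weights[det]), ")",
                              collapse = ", ") else "none",
      "; residual ", signif(x$residual, 3), "\n", sep = "")
  invisible(x)
}

#' Detection flags for one signature across samples
#'
#' @param results Named list of [deconvolve()] results sharing one catalogue.
#' @param signature Signature name.
#' @return Named logical vector, one entry per sample.
#' @export
detection_table <- function(results, signature) {
  flags <- vapply(results, function(r) {
    if (!signature %in% names(r$detected)) {
      stop("unknown signature: ", signature)
    }
    r$detected[[signature]]
  }, logical(1))
  flags
}

#' Write per-sample deconvolution weights to CSV
#'
#' One row per sample: weights, detection flags (`detected_<name>`), residual
#' and SNV count.
#'
#' @param results Named list of [deconvolve()] results.
#' @param path Output path.
#' @export
write_deconvolution_csv <- function(results, path) {
  rows <- lapply(names(results), function(id) {
    r <- results[[id]]
    cbind(
      data.frame(sample_id = id, stringsAsFactors = FALSE),
      as.data.frame(as.list(r$weights), check.names = FALSE),
      stats::setNames(as.data.frame(as.list(as.integer(r$detected))),
                      paste0("detected_", names(r$detected))),
      data.frame(residual = r$residual, n_snvs = r$n_snvs)
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}
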