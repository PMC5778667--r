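# A synthetic signature catalogue, generated in code.
#
# The shapes are deterministic constructions that qualitatively mirror
# well-known mutational processes (CpG-deamination ageing, APOBEC, broad
# BRCA-deficiency, C>A-heavy platinum damage, ...). They are NOT the COSMIC
# reference signatures, which are external data and deliberately not bundled;
# any user-supplied catalogue in the 96-channel CSV layout can be used
# instead wherever a `signature_catalogue` is accepted.

.shape <- function(fn, floor = 0.05) {
  tab <- .CONTEXT_TABLE
  w <- fn(tab)
  w <- pmax(w, 0)
  w <- w / sum(w)
  w <- (1 - floor) * w + floor / 96
  w
}

#' A synthetic signature catalogue with known, distinguishable shapes
#'
#' Builds a catalogue of nine deterministic 96-channel signatures generated in
#' code: five background-process shapes (an ageing-like CpG C>T signature, an
#' APOBEC-like TpC signature, a broad BRCA-deficiency-like signature, a
#' C>A/C>T signature of the kind often labelled "unknown etiology", and a
#' T>C-leaning signature) and four chemotherapy shapes (a C>A-heavy cisplatin
#' signature with a 3' cytosine preference, a second cisplatin signature
#' specific for a 5' cytosine and 3' pyrimidine, a T>A + C>T cyclophosphamide
#' signature, and a near-uniform etoposide signature). Every signature keeps a
#' small uniform floor so no context has zero likelihood under a detected
#' signature.
#'
#' These synthetic shapes exist so the pipeline is testable end-to-end with
#' known ground truth; substitute a real curated catalogue via
#' [read_catalogue_csv()] for real analyses.
#'
#' @return A [signature_catalogue()] with 9 rows.
#' @export
synthetic_catalogue <- function() {
  shapes <- list(
    "Signature.1.Age" = function(t)
      (t$class == "C>T") * ifelse(t$three == "G", 8, 0.4),
    "Signature.2.APOBEC" = function(t)
      (t$class %in% c("C>T", "C>G")) * (t$five == "T") * 4,
    "Signature.3.BRCA" = function(t)
      c("C>A" = 1.6, "C>G" = 1.4, "C>T" = 0.9, "T>A" = 0.9,
        "T>C" = 0.8, "T>G" = 0.6)[t$class] *
        c(A = 1.4, C = 0.7, G = 1.1, T = 0.8)[t$three],
    "Signature.8" = function(t)
      (t$class == "C>A") * c(A = 2, C = 0.5, G = 1, T = 2)[t$three] *
        c(A = 1.5, C = 0.8, G = 0.6, T = 1.1)[t$five] +
        (t$class == "T>A") * 0.8,
    "Signature.16" = function(t)
      (t$class == "T>C") * c(A = 5, C = 1, G = 1, T = 2)[t$five],
    "Cisplatin.Gallus" = function(t)
      (t$class == "C>A") * c(A = 1, C = 4, G = 1, T = 1)[t$three] +
        (t$class == "C>T") * 0.15,
    "Cisplatin.Elegans" = function(t)
      (t$class == "C>A") * (t$five == "C") *
        c(A = 1, C = 3, G = 1, T = 3)[t$three],
    "Cyclophosphamide" = function(t)
      (t$class == "T>A") * c(A = 1, C = 2.5, G = 1, T = 1.5)[t$five] * 1.2 +
        (t$class == "C>T") * (t$three != "G") * 0.9,
    "Etoposide" = function(t)
      rep(1, nrow(t)) + 0.15 * (t$class %in% c("C>T", "T>C"))
  )
  mat <- do.call(rbind, lapply(shapes, .shape))
  colnames(mat) <- sbs_contexts()
  signature_catalogue(mat)
}

#' Chemotherapy signature names in the synthetic catalogue
#'
#' @return Character vector of the catalogue rows representing chemotherapy
#'   exposure.
#' @export
chemo_signature_names <- function() {
  c("Cisplatin.Gallus", "Cisplatin.Elegans", "Cyclophosphamide", "Etoposide")
}
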