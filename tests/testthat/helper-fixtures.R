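# Shared fixtures and independent oracles, all built in code.

# Small named reference from an explicit sequence string.
fixture_reference <- function(seq, name = "chr1") {
  out <- Biostrings::DNAStringSet(seq)
  names(out) <- name
  out
}

# Minimal mutation-record data frame with sensible read support.
fixture_records <- function(chrom, pos, ref, alt,
                            patient_id = "P1", sample_id = "S1",
                            dna_alt = 20L, dna_total = 60L, rna_alt = 0L,
                            neo = 0L, expr_neo = 0L) {
  n <- length(pos)
  r <- function(x) rep(x, length.out = n)
  mutation_records(data.frame(
    patient_id = r(patient_id), sample_id = r(sample_id),
    chrom = r(chrom), pos = pos, ref = r(ref), alt = r(alt),
    dna_alt_reads = r(dna_alt), dna_total_reads = r(dna_total),
    rna_alt_reads = r(rna_alt),
    neoantigen_count = r(neo), expressed_neoantigen_count = r(expr_neo),
    stringsAsFactors = FALSE
  ))
}

# Brute-force grid maximizer of the per-channel Poisson log-likelihood
# over (B, T) >= 0 for control counts `ctrl` and treated counts `trt`.
# Independent of the closed-form fit: scans a lattice.
grid_poisson_map <- function(ctrl, trt, step = 0.05, upper = NULL) {
  if (is.null(upper)) upper <- max(mean(ctrl), mean(trt), 1) * 2 + 2
  Bs <- seq(0, upper, by = step)
  Ts <- seq(0, upper, by = step)
  Sc <- sum(ctrl); nc <- length(ctrl)
  St <- sum(trt); nt <- length(trt)
  xlogy <- function(x, y) if (x == 0) 0 * y else x * log(y)  # x is scalar
  ll_ctrl <- xlogy(Sc, Bs) - nc * Bs              # over B
  rate <- outer(Bs, Ts, "+")
  ll <- matrix(ll_ctrl, nrow = length(Bs), ncol = length(Ts)) +
    xlogy(St, rate) - nt * rate
  best <- arrayInd(which.max(ll), dim(ll))
  c(B = Bs[best[1L]], T = Ts[best[2L]])
}

# Exhaustive hypergeometric enumeration for the two-sided Fisher exact test
# on a 2x2 table given as (a, b, c, d) row-wise.
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lo <- max(0L, c1 - (n - r1))
  hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, c1, n - c1, r1)
  sum(probs[probs <= probs[support == a] * (1 + 1e-7)])
}

# Independent per-context histogram: counts trinucleotide-context classes by
# direct string manipulation (no package internals).
naive_context_histogram <- function(chrom, pos, ref, alt, seq_str) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  labels <- sbs_contexts()
  counts <- stats::setNames(numeric(96), labels)
  for (i in seq_along(pos)) {
    tri <- substr(seq_str, pos[i] - 1, pos[i] + 1)
    r <- ref[i]; al <- alt[i]
    if (r %in% c("A", "G")) {
      tri <- paste0(comp[substr(tri, 3, 3)], comp[substr(tri, 2, 2)],
                    comp[substr(tri, 1, 1)])
      r <- comp[[r]]; al <- comp[[al]]
    }
    lab <- paste0(substr(tri, 1, 1), "[", r, ">", al, "]", substr(tri, 3, 3))
    counts[lab] <- counts[lab] + 1
  }
  counts
}

# Signature subsets of the synthetic catalogue with pairwise cosine < 0.5.
low_cosine_sets <- function() {
  list(
    c("Signature.1.Age", "Signature.2.APOBEC"),
    c("Signature.16", "Cisplatin.Gallus", "Signature.1.Age"),
    c("Signature.1.Age", "Signature.2.APOBEC", "Signature.16",
      "Cisplatin.Gallus"),
    c("Signature.8", "Signature.2.APOBEC", "Signature.16",
      "Cyclophosphamide")
  )
}
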