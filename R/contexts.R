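# Trinucleotide-context machinery for the 96 single-base-substitution channels.
#
# Channel order follows the COSMIC convention: substitution classes
# C>A, C>G, C>T, T>A, T>C, T>G; within each class the 5' flank varies first,
# then the 3' flank, both in A,C,G,T order.

SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
DNA_BASES <- c("A", "C", "G", "T")

.make_context_table <- function() {
  grid <- expand.grid(
    three = DNA_BASES, five = DNA_BASES, class = SBS_CLASSES,
    stringsAsFactors = FALSE
  )
  # expand.grid varies the first factor fastest; reorder to class > five > three
  grid <- grid[, c("class", "five", "three")]
  ref <- substr(grid$class, 1L, 1L)
  alt <- substr(grid$class, 3L, 3L)
  data.frame(
    context = paste0(grid$five, "[", grid$class, "]", grid$three),
    class = grid$class,
    five = grid$five,
    ref = ref,
    alt = alt,
    three = grid$three,
    trinuc = paste0(grid$five, ref, grid$three),
    stringsAsFactors = FALSE
  )
}

.CONTEXT_TABLE <- .make_context_table()

#' The 96 single-base-substitution context labels
#'
#' Returns the channel labels (e.g. `"A[C>A]A"`) in the fixed COSMIC order:
#' substitution classes `C>A, C>G, C>T, T>A, T>C, T>G`, and within each class
#' the 5' then the 3' flanking base in `A, C, G, T` order. All 96-channel
#' vectors in this package use this order.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs_contexts())
sbs_contexts <- function() .CONTEXT_TABLE$context

#' The 32 pyrimidine-centred trinucleotides
#'
#' Trinucleotides with a C or T centre, in alphabetical order. Genome
#' trinucleotide-frequency vectors (see [count_trinucleotide_freq()]) are
#' indexed by these labels.
#'
#' @return Character vector of length 32.
#' @export
trinucleotides_32 <- function() sort(unique(.CONTEXT_TABLE$trinuc))

#' Reference trinucleotide of each context channel
#'
#' @return Character vector of length 96 giving, for each channel of
#'   [sbs_contexts()], the pyrimidine-strand reference trinucleotide.
#' @export
context_trinucleotides <- function() .CONTEXT_TABLE$trinuc

.complement <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

#' Reverse complement of nucleotide strings
#'
#' Vectorised over `x`; works for strings of any length.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  n <- nchar(x)
  out <- character(length(x))
  short <- n == 1L
  out[short] <- .complement(x[short])
  if (any(!short)) {
    out[!short] <- vapply(
      strsplit(.complement(x[!short]), "", fixed = TRUE),
      function(b) paste(rev(b), collapse = ""),
      character(1)
    )
  }
  out
}

# Canonicalise (trinuc, ref, alt) to the pyrimidine strand and return the
# 1-based channel index (NA where the combination is invalid).
.context_index <- function(trinuc, ref, alt) {
  pur <- ref %in% c("A", "G")
  if (any(pur)) {
    trinuc[pur] <- reverse_complement(trinuc[pur])
    ref[pur] <- .complement(ref[pur])
    alt[pur] <- .complement(alt[pur])
  }
  label <- paste0(
    substr(trinuc, 1L, 1L), "[", ref, ">", alt, "]", substr(trinuc, 3L, 3L)
  )
  match(label, .CONTEXT_TABLE$context)
}

.as_seq_strings <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    out <- as.character(reference)
  } else if (is.character(reference)) {
    out <- reference
  } else {
    stop("`reference` must be a named DNAStringSet or character vector")
  }
  if (is.null(names(out))) stop("reference sequences must be named by contig")
  toupper(out)
}

#' Classify SNVs into trinucleotide-context channels
#'
#' Looks up the reference trinucleotide around each variant and maps it to one
#' of the 96 pyrimidine-strand substitution channels. Variants whose stated
#' reference base disagrees with the reference sequence, or that sit at a
#' contig edge (no flanking base), are rejected and returned as `NA`.
#'
#' @param chrom,pos,ref,alt Vectors describing SNVs: contig name, 1-based
#'   position, reference and alternate base (single characters, `ref != alt`).
#' @param reference Named `DNAStringSet` (or named character vector) of contig
#'   sequences.
#' @param quiet Suppress the message summarising rejected records.
#' @return Integer vector of channel indices in `1:96` (see [sbs_contexts()]),
#'   `NA` for rejected records, with attribute `"reason"` holding a character
#'   vector of rejection reasons (`NA` where classified).
#' @export
classify_contexts <- function(chrom, pos, ref, alt, reference, quiet = FALSE) {
  seqs <- .as_seq_strings(reference)
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n)
  ref <- toupper(ref)
  alt <- toupper(alt)
  idx <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)

  bad_chrom <- !(chrom %in% names(seqs))
  reason[bad_chrom] <- "unknown contig"
  not_snv <- nchar(ref) != 1L | nchar(alt) != 1L | ref == alt |
    !(ref %in% DNA_BASES) | !(alt %in% DNA_BASES)
  reason[!bad_chrom & not_snv] <- "not a simple SNV"

  ok <- !bad_chrom & !not_snv
  if (any(ok)) {
    len <- nchar(seqs)[match(chrom[ok], names(seqs))]
    edge <- pos[ok] <= 1L | pos[ok] >= len
    reason[ok][edge] <- "no flanking base (contig edge)"
    ok2 <- which(ok)[!edge]
    if (length(ok2)) {
      tri <- character(length(ok2))
      for (ctg in unique(chrom[ok2])) {
        sel <- chrom[ok2] == ctg
        tri[sel] <- substring(seqs[[ctg]], pos[ok2][sel] - 1L, pos[ok2][sel] + 1L)
      }
      center <- substr(tri, 2L, 2L)
      mismatch <- center != ref[ok2]
      reason[ok2][mismatch] <- "reference base mismatch"
      good <- ok2[!mismatch]
      if (length(good)) {
        idx[good] <- .context_index(tri[!mismatch], ref[good], alt[good])
      }
    }
  }
  n_rej <- sum(is.na(idx))
  if (n_rej > 0L && !quiet) {
    message(n_rej, " record(s) rejected during context classification")
  }
  structure(idx, reason = reason)
}

#' @rdname classify_contexts
#' @details `classify_context()` is the scalar form; it errors on rejection
#'   instead of returning `NA`.
#' @export
classify_context <- function(chrom, pos, ref, alt, reference) {
  idx <- classify_contexts(chrom, pos, ref, alt, reference, quiet = TRUE)
  if (is.na(idx)) {
    stop("cannot classify variant: ", attr(idx, "reason")[1L])
  }
  as.integer(idx)
}

#' Tabulate SNVs by trinucleotide context
#'
#' Counts a set of mutation records into the 96 substitution channels. Only
#' SNV records contribute; MNVs and indels are ignored (signature math is
#' SNV-only). Records rejected by [classify_contexts()] are skipped and
#' counted in the `"n_rejected"` attribute.
#'
#' @param records Mutation record data frame (see [mutation_records()]).
#' @param reference Named `DNAStringSet` or character vector of contigs.
#' @param quiet Suppress the rejection message.
#' @return Named numeric vector of length 96 (names [sbs_contexts()]), with
#'   attribute `n_rejected`.
#' @export
tabulate_contexts <- function(records, reference, quiet = FALSE) {
  records <- records[records$variant_class == "SNV", , drop = FALSE]
  counts <- stats::setNames(numeric(96L), sbs_contexts())
  if (nrow(records) == 0L) {
    attr(counts, "n_rejected") <- 0L
    return(counts)
  }
  idx <- classify_contexts(
    records$chrom, records$pos, records$ref, records$alt, reference,
    quiet = quiet
  )
  tab <- tabulate(idx[!is.na(idx)], nbins = 96L)
  counts[] <- tab
  attr(counts, "n_rejected") <- sum(is.na(idx))
  counts
}

#' Count pyrimidine-centred trinucleotides in a genome
#'
#' Tallies every trinucleotide occurrence on both strands and folds
#' purine-centred triplets onto their pyrimidine-strand reverse complements.
#' Used to build the genome-composition vectors (`h`, `m`) consumed by
#' [genome_normalize()].
#'
#' @param reference `DNAStringSet`, named character vector, or path to a FASTA
#'   file.
#' @return Named numeric vector over [trinucleotides_32()].
#' @export
count_trinucleotide_freq <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      is.null(names(reference)) && file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (!inherits(reference, "DNAStringSet")) {
    reference <- Biostrings::DNAStringSet(.as_seq_strings(reference))
  }
  freq64 <- colSums(Biostrings::trinucleotideFrequency(reference))
  out <- stats::setNames(numeric(32L), trinucleotides_32())
  for (tri in names(freq64)) {
    center <- substr(tri, 2L, 2L)
    key <- if (center %in% c("C", "T")) tri else reverse_complement(tri)
    out[key] <- out[key] + freq64[[tri]]
  }
  out
}
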