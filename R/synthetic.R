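# Synthetic data: preclinical replicate experiments and a toy tumor cohort
# with known ground truth, so every pipeline stage is testable without
# controlled-access patient data.

.derive_seed <- function(seed, k) {
  ((as.numeric(seed) * 48271 + k * 9973) %% 2147483629) + 1
}

#' Generate a random reference sequence
#'
#' Writes a single random contig with a given GC fraction; used as the genome
#' that hosts simulated mutations.
#'
#' @param length Sequence length (>= 1000).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @param name Contig name.
#' @return A named `DNAStringSet` of length 1.
#' @export
make_reference <- function(length = 1e6, gc = 0.41, seed = 1, name = "chrS") {
  stopifnot(length >= 1000, gc >= 0, gc <= 1)
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- paste(sample(names(probs), length, TRUE, prob = probs), collapse = "")
  out <- Biostrings::DNAStringSet(seq)
  names(out) <- name
  out
}

# Index every internal position of the (first) reference contig by the
# pyrimidine-strand trinucleotide it carries: `pyr` positions have a
# pyrimidine centre spelling the trinucleotide on the plus strand, `pur`
# positions spell its reverse complement.
.build_site_index <- function(reference) {
  seqs <- .as_seq_strings(reference)
  if (length(seqs) != 1L) stop("the site index expects a single-contig reference")
  b <- match(strsplit(seqs[[1L]], "", fixed = TRUE)[[1L]], DNA_BASES) - 1L
  n <- length(b)
  code <- b[1:(n - 2L)] * 16L + b[2:(n - 1L)] * 4L + b[3:n]
  center <- b[2:(n - 1L)]
  pos <- 2:(n - 1L)
  keep <- !is.na(code)
  code <- code[keep]; center <- center[keep]; pos <- pos[keep]
  # code = 16*b1 + 4*b2 + b3 maps to DNA_BASES[b1+1] DNA_BASES[b2+1] DNA_BASES[b3+1]
  decode <- function(cd) {
    paste0(DNA_BASES[cd %/% 16L + 1L], DNA_BASES[cd %/% 4L %% 4L + 1L],
           DNA_BASES[cd %% 4L + 1L])
  }
  idx <- list(pyr = list(), pur = list())
  for (tn in trinucleotides_32()) idx$pyr[[tn]] <- idx$pur[[tn]] <- integer(0)
  for (cd in unique(code)) {
    tn <- decode(cd)
    sel <- pos[code == cd]
    if (substr(tn, 2L, 2L) %in% c("C", "T")) {
      idx$pyr[[tn]] <- sel
    } else {
      idx$pur[[reverse_complement(tn)]] <- sel
    }
  }
  idx$contig <- names(seqs)[1L]
  idx
}

#' Simulate a preclinical treated/control experiment set
#'
#' Draws replicate 96-channel mutation counts from the generative model of
#' [fit_treatment_model()]: control rows are Poisson with rates `B_true`,
#' treated rows with rates `B_true + T_true`.
#'
#' @param B_true,T_true Nonnegative 96-vectors of background and treatment
#'   rates.
#' @param n_control,n_treated Replicate counts per arm.
#' @param seed RNG seed.
#' @return An [experiment_set()]; control rows come first.
#' @export
simulate_preclinical <- function(B_true, T_true, n_control, n_treated, seed = 1) {
  stopifnot(length(B_true) == 96L, length(T_true) == 96L,
            all(B_true >= 0), all(T_true >= 0))
  set.seed(seed)
  ctrl <- matrix(stats::rpois(n_control * 96L, rep(B_true, each = n_control)),
                 nrow = n_control)
  trt <- matrix(stats::rpois(n_treated * 96L, rep(B_true + T_true, each = n_treated)),
                nrow = n_treated)
  experiment_set(rbind(ctrl, trt),
                 treated = rep(c(FALSE, TRUE), c(n_control, n_treated)))
}

#' Specify a synthetic tumor cohort
#'
#' Collects the generative parameters of [simulate_cohort()]. The defaults
#' describe a desk-scale high-grade serous ovarian cancer cohort: mostly
#' untreated primary samples, a few neoadjuvant-treated primaries, and a set
#' of relapse samples (some patient-matched to a primary) whose mutation
#' burden is multiplied relative to primaries and whose SNVs carry a
#' chemotherapy-signature admixture.
#'
#' Per-sample chemotherapy fractions in relapse samples are Beta-distributed
#' with mean proportional to the sample's platinum cycle count (scaled so the
#' group mean is `relapse_chemo_fraction`), capturing both the dose-response
#' and the wide per-sample spread seen in treated cohorts.
#'
#' @param n_patients Total patients.
#' @param n_paired Patients contributing a matched primary + relapse pair.
#' @param n_primary_treated Patients with a neoadjuvant-treated primary
#'   sample (no chemotherapy-signature admixture: exposure is brief and the
#'   sampled tumor bulk predates it).
#' @param n_relapse_unpaired Patients with an unpaired relapse sample.
#' @param background_mixture Named signature mixture of the background
#'   mutational processes (must sum to 1).
#' @param relapse_chemo_fraction Mean fraction of relapse-sample SNVs drawn
#'   from the chemotherapy signature (post-unique SNVs for paired samples).
#' @param chemo_signature Catalogue row treated as the chemotherapy process.
#' @param chemo_beta_shape1 Shape1 of the per-sample Beta spread.
#' @param relapse_snv_multiplier Burden multiplier of relapse over primary
#'   samples.
#' @param post_unique_fraction Fraction of a paired relapse sample's SNVs
#'   that are unique to the post-treatment timepoint.
#' @param snvs_per_sample Mean SNV count of a primary sample.
#' @param dna_depth,rna_depth Mean sequencing depths.
#' @param vaf_shape1,vaf_shape2 Beta parameters of the variant allele
#'   fraction distribution.
#' @param neoantigens_per_snv Mean neoantigen yield per SNV.
#' @param expression_prob Probability that a mutation is expressed.
#' @param mnv_rate,indel_rate MNV / indel counts as a fraction of SNV count.
#' @param ref_length Reference length used when [simulate_cohort()] builds
#'   its own reference.
#' @param seed Master seed; all randomness (metadata and per-sample streams)
#'   derives from it deterministically.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 16,
                        n_paired = 4,
                        n_primary_treated = 2,
                        n_relapse_unpaired = 4,
                        background_mixture = c(
                          "Signature.1.Age" = 0.18,
                          "Signature.3.BRCA" = 0.40,
                          "Signature.8" = 0.22,
                          "Signature.2.APOBEC" = 0.10,
                          "Signature.16" = 0.10
                        ),
                        relapse_chemo_fraction = 0.05,
                        chemo_signature = "Cisplatin.Gallus",
                        chemo_beta_shape1 = 1.5,
                        relapse_snv_multiplier = 1.78,
                        post_unique_fraction = 0.45,
                        snvs_per_sample = 5000,
                        dna_depth = 60,
                        rna_depth = 30,
                        vaf_shape1 = 6,
                        vaf_shape2 = 14,
                        neoantigens_per_snv = 0.02,
                        expression_prob = 0.4,
                        mnv_rate = 0.01,
                        indel_rate = 0.02,
                        ref_length = 1e6,
                        seed = 1) {
  spec <- as.list(environment())
  if (abs(sum(background_mixture) - 1) > 1e-9) {
    stop("background_mixture must sum to 1")
  }
  if (relapse_chemo_fraction < 0 || relapse_chemo_fraction > 1) {
    stop("relapse_chemo_fraction must lie in [0, 1]")
  }
  if (n_paired + n_primary_treated + n_relapse_unpaired > n_patients) {
    stop("patient subgroup counts exceed n_patients")
  }
  stopifnot(snvs_per_sample > 0, dna_depth > 0, rna_depth > 0,
            post_unique_fraction >= 0, post_unique_fraction <= 1)
  structure(spec, class = "cohort_spec")
}

# Sample metadata: patients, groups, tissues, drugs and cycle counts.
.build_meta <- function(spec) {
  pt <- sprintf("PT%02d", seq_len(spec$n_patients))
  roles <- rep("primary_only", spec$n_patients)
  roles[seq_len(spec$n_paired)] <- "paired"
  roles[spec$n_paired + seq_len(spec$n_primary_treated)] <- "nact"
  roles[spec$n_paired + spec$n_primary_treated +
          seq_len(spec$n_relapse_unpaired)] <- "relapse_only"
  rows <- list()
  for (i in seq_along(pt)) {
    role <- roles[i]
    if (role == "paired") {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste0(pt[i], c("-P", "-R")), patient_id = pt[i],
        group = c("primary_untreated", "relapse_treated"),
        stringsAsFactors = FALSE
      )
    } else {
      grp <- switch(role,
                    nact = "primary_treated",
                    relapse_only = "relapse_treated",
                    "primary_untreated")
      suffix <- if (grp == "relapse_treated") "-R" else "-P"
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste0(pt[i], suffix), patient_id = pt[i],
        group = grp, stringsAsFactors = FALSE
      )
    }
  }
  meta <- do.call(rbind, rows)
  relapse <- meta$group == "relapse_treated"
  treated <- meta$group != "primary_untreated"
  meta$tissue <- ifelse(
    relapse,
    ifelse(stats::runif(nrow(meta)) < 0.8, "ascites", "solid"),
    ifelse(stats::runif(nrow(meta)) < 0.95, "solid", "ascites")
  )
  meta$drugs <- ifelse(treated, "carboplatin+paclitaxel", "")
  meta$platinum_cycles <- ifelse(treated, sample(1:6, nrow(meta), TRUE), 0L)
  cyc <- treated & stats::runif(nrow(meta)) < 0.3
  meta$cyclophosphamide_cycles <- ifelse(cyc, sample(1:4, nrow(meta), TRUE), 0L)
  meta$drugs[cyc] <- paste0(meta$drugs[cyc], "+cyclophosphamide")
  meta$days_since_last_chemo <- ifelse(treated, sample(30:400, nrow(meta), TRUE),
                                       NA_integer_)
  rownames(meta) <- NULL
  meta
}

# Draw n SNVs from a signature mixture: signature, context, genomic position
# (uniform over reference sites carrying the context's trinucleotide on
# either strand) and strand-resolved ref/alt alleles.
.draw_snvs <- function(n, mixture, catalogue, site_index) {
  if (n == 0L) {
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), signature = character(0),
                      context = integer(0), stringsAsFactors = FALSE))
  }
  mixture <- mixture[mixture > 0]
  sig <- sample(names(mixture), n, TRUE, prob = mixture)
  ctx <- integer(n)
  H <- unclass(catalogue)
  for (s in unique(sig)) {
    k <- sig == s
    ctx[k] <- sample.int(96L, sum(k), TRUE, prob = H[s, ])
  }
  tri <- context_trinucleotides()[ctx]
  alt_pyr <- .CONTEXT_TABLE$alt[ctx]
  ref_pyr <- .CONTEXT_TABLE$ref[ctx]
  pos <- integer(n)
  on_pyr <- logical(n)
  for (tn in unique(tri)) {
    k <- which(tri == tn)
    pyr <- site_index$pyr[[tn]]
    pur <- site_index$pur[[tn]]
    n_sites <- length(pyr) + length(pur)
    if (n_sites < length(k)) {
      stop("reference has too few sites for trinucleotide ", tn,
           "; use a longer reference")
    }
    pick <- sample.int(n_sites, length(k))
    sel_pyr <- pick <= length(pyr)
    pos_k <- integer(length(k))
    pos_k[sel_pyr] <- pyr[pick[sel_pyr]]
    pos_k[!sel_pyr] <- pur[pick[!sel_pyr] - length(pyr)]
    on_pyr[k] <- sel_pyr
    pos[k] <- pos_k
  }
  data.frame(
    pos = pos,
    ref = ifelse(on_pyr, ref_pyr, .complement(ref_pyr)),
    alt = ifelse(on_pyr, alt_pyr, .complement(alt_pyr)),
    signature = sig,
    context = ctx,
    stringsAsFactors = FALSE
  )
}

# DNA/RNA read support and neoantigen yields for n mutations.
.draw_reads <- function(n, spec, per_mnv = 1) {
  total <- stats::rpois(n, spec$dna_depth)
  vaf <- stats::rbeta(n, spec$vaf_shape1, spec$vaf_shape2)
  alt <- stats::rbinom(n, total, vaf)
  expressed <- stats::runif(n) < spec$expression_prob
  rna_alt <- stats::rpois(n, spec$rna_depth * vaf * expressed)
  neo <- stats::rpois(n, spec$neoantigens_per_snv * per_mnv)
  data.frame(
    dna_alt_reads = alt, dna_total_reads = total, rna_alt_reads = rna_alt,
    neoantigen_count = neo,
    expressed_neoantigen_count = ifelse(rna_alt >= 3, neo, 0L)
  )
}

.draw_other_variants <- function(n_snv, spec, seq_str, contig) {
  len <- nchar(seq_str)
  n_mnv <- stats::rpois(1L, n_snv * spec$mnv_rate)
  n_ind <- stats::rpois(1L, n_snv * spec$indel_rate)
  out <- list()
  if (n_mnv > 0L) {
    p <- sample(2:(len - 2L), n_mnv)
    ref <- substring(seq_str, p, p + 1L)
    alt <- vapply(strsplit(.complement(ref), ""), function(x)
      paste(x, collapse = ""), character(1))
    out$mnv <- data.frame(pos = p, ref = ref, alt = alt,
                          variant_class = "MNV", stringsAsFactors = FALSE)
  }
  if (n_ind > 0L) {
    p <- sample(2:(len - 4L), n_ind)
    ins <- stats::runif(n_ind) < 0.5
    ref1 <- substring(seq_str, p, p)
    ref <- ifelse(ins, ref1, substring(seq_str, p, p + 2L))
    alt <- ifelse(ins, paste0(ref1, sample(DNA_BASES, n_ind, TRUE)), ref1)
    out$ind <- data.frame(pos = p, ref = ref, alt = alt,
                          variant_class = ifelse(ins, "INS", "DEL"),
                          stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

#' Simulate a tumor cohort with known signature ground truth
#'
#' Generates per-sample somatic mutation tables, sample metadata and a
#' ground-truth ledger from a [cohort_spec()]. Each SNV draws a generating
#' signature from its sample's mixture, a trinucleotide context from that
#' signature, and a genomic position uniformly among reference sites carrying
#' the context's trinucleotide on either strand; DNA and RNA read support,
#' neoantigen yields, MNVs and indels are layered on top. Paired patients get
#' a primary sample plus a relapse sample whose post-unique mutations follow
#' the relapse mixture (background plus the chemotherapy-signature fraction)
#' and whose remaining mutations are shared with the primary; shared
#' mutations carry the primary sample's read support in the `pre_*` columns,
#' post-unique mutations carry high pre-treatment coverage with zero variant
#' reads.
#'
#' All randomness derives deterministically from `spec$seed`; the same spec
#' yields byte-identical output.
#'
#' @param spec A [cohort_spec()].
#' @param catalogue Signature catalogue containing every mixture signature
#'   and the chemotherapy signature (default [synthetic_catalogue()]).
#' @param reference Optional named single-contig reference; by default a
#'   random reference of `spec$ref_length` bases is generated from the seed.
#' @return List with `mutations` (validated mutation record table),
#'   `meta` (sample metadata including true per-sample `chemo_fraction`),
#'   `truth` (per-mutation generating signature and post-unique flag) and
#'   `reference`.
#' @export
simulate_cohort <- function(spec, catalogue = synthetic_catalogue(),
                            reference = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  need <- unique(c(names(spec$background_mixture), spec$chemo_signature))
  if (!all(need %in% rownames(catalogue))) {
    stop("catalogue lacks mixture signatures: ",
         paste(setdiff(need, rownames(catalogue)), collapse = ", "))
  }
  if (is.null(reference)) {
    reference <- make_reference(spec$ref_length, gc = 0.41,
                                seed = .derive_seed(spec$seed, 0))
  }
  seq_str <- .as_seq_strings(reference)[[1L]]
  contig <- names(.as_seq_strings(reference))[1L]
  site_index <- .build_site_index(reference)

  set.seed(.derive_seed(spec$seed, 1))
  meta <- .build_meta(spec)

  # per-sample mean chemotherapy fraction scales with platinum cycles
  relapse <- meta$group == "relapse_treated"
  meta$chemo_fraction <- 0
  if (spec$relapse_chemo_fraction > 0 && any(relapse)) {
    mu <- spec$relapse_chemo_fraction *
      meta$platinum_cycles[relapse] / mean(meta$platinum_cycles[relapse])
    mu <- pmin(pmax(mu, 1e-4), 0.3)
    a <- spec$chemo_beta_shape1
    meta$chemo_fraction[relapse] <- stats::rbeta(sum(relapse), a, a * (1 - mu) / mu)
  }

  mixture_for <- function(pi) {
    mix <- spec$background_mixture * (1 - pi)
    mix[spec$chemo_signature] <- (mix[spec$chemo_signature] %||% 0) + pi
    mix
  }

  mutations <- list()
  truth <- list()
  primary_snvs <- list()  # per patient: SNV table of the primary sample

  make_records <- function(sample_row, snvs, reads, pre_total, pre_alt) {
    n <- nrow(snvs)
    if (n == 0L) return(NULL)
    cbind(
      data.frame(patient_id = sample_row$patient_id,
                 sample_id = sample_row$sample_id,
                 chrom = contig, pos = snvs$pos, ref = snvs$ref,
                 alt = snvs$alt, stringsAsFactors = FALSE),
      reads,
      data.frame(variant_class = "SNV",
                 pre_total_reads = pre_total, pre_alt_reads = pre_alt)
    )
  }

  # primaries first so paired relapse samples can share their mutations
  ord <- order(match(meta$group, c("primary_untreated", "primary_treated",
                                   "relapse_treated")))
  for (k in ord) {
    row <- meta[k, ]
    set.seed(.derive_seed(spec$seed, 100 + k))
    paired <- relapse[k] && row$patient_id %in% names(primary_snvs)
    mult <- if (relapse[k]) spec$relapse_snv_multiplier else 1
    n_snv <- stats::rpois(1L, spec$snvs_per_sample * mult)

    if (!relapse[k]) {
      snvs <- .draw_snvs(n_snv, spec$background_mixture, catalogue, site_index)
      reads <- .draw_reads(nrow(snvs), spec)
      recs <- make_records(row, snvs, reads, NA_integer_, NA_integer_)
      primary_snvs[[row$patient_id]] <- cbind(snvs, reads)
      post_flag <- rep(FALSE, nrow(snvs))
    } else {
      mix <- mixture_for(meta$chemo_fraction[k])
      if (paired) {
        n_unique <- stats::rbinom(1L, n_snv, spec$post_unique_fraction)
        pre <- primary_snvs[[row$patient_id]]
        n_shared <- min(n_snv - n_unique, nrow(pre))
        shared <- pre[sample.int(nrow(pre), n_shared), , drop = FALSE]
        uniq <- .draw_snvs(n_unique, mix, catalogue, site_index)
        uniq <- uniq[!(uniq$pos %in% shared$pos), , drop = FALSE]
        snvs <- rbind(shared[, c("pos", "ref", "alt", "signature", "context")],
                      uniq)
        reads <- .draw_reads(nrow(snvs), spec)
        pre_total <- c(shared$dna_total_reads,
                       stats::rpois(nrow(uniq), spec$dna_depth))
        pre_alt <- c(shared$dna_alt_reads, rep(0L, nrow(uniq)))
        post_flag <- rep(c(FALSE, TRUE), c(nrow(shared), nrow(uniq)))
        recs <- make_records(row, snvs, reads, pre_total, pre_alt)
      } else {
        snvs <- .draw_snvs(n_snv, mix, catalogue, site_index)
        reads <- .draw_reads(nrow(snvs), spec)
        recs <- make_records(row, snvs, reads, NA_integer_, NA_integer_)
        post_flag <- rep(FALSE, nrow(snvs))
      }
    }

    other <- .draw_other_variants(n_snv, spec, seq_str, contig)
    if (!is.null(other)) {
      oreads <- .draw_reads(nrow(other), spec, per_mnv = 2)
      orecs <- cbind(
        data.frame(patient_id = row$patient_id, sample_id = row$sample_id,
                   chrom = contig, pos = other$pos, ref = other$ref,
                   alt = other$alt, stringsAsFactors = FALSE),
        oreads,
        data.frame(variant_class = other$variant_class,
                   pre_total_reads = NA_integer_, pre_alt_reads = NA_integer_)
      )
      recs <- rbind(recs, orecs)
    }
    mutations[[row$sample_id]] <- recs
    truth[[row$sample_id]] <- data.frame(
      sample_id = row$sample_id, chrom = contig,
      pos = c(snvs$pos, other$pos),
      signature = c(snvs$signature,
                    if (!is.null(other)) tolower(other$variant_class)),
      context = c(snvs$context, rep(NA_integer_, NROW(other))),
      post_unique = c(post_flag, rep(FALSE, NROW(other))),
      stringsAsFactors = FALSE
    )
  }

  mutations <- mutation_records(do.call(rbind, mutations))
  rownames(mutations) <- NULL
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(mutations = mutations, meta = meta, truth = truth,
       reference = reference)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
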