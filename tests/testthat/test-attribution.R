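# Build a small catalogue with prescribed values in channel 1 and the rest
# spread uniformly, plus a matching deconvolution object with given weights.
toy_catalogue <- function(channel1 = c(s1 = 0.2, s2 = 0.1)) {
  rows <- t(vapply(channel1, function(p) c(p, rep((1 - p) / 95, 95)),
                   numeric(96)))
  suppressWarnings(signature_catalogue(rows))  # rows are nearly collinear by design
}

toy_weights <- function(w, threshold = 0.06) {
  structure(
    list(weights = w, raw_weights = w,
         detected = w >= threshold, residual = 0,
         n_snvs = 100, threshold = threshold),
    class = "deconvolution"
  )
}

test_that("posterior probabilities follow Bayes' rule over detected signatures", {
  cat <- toy_catalogue(c(s1 = 0.2, s2 = 0.1))
  w <- toy_weights(c(s1 = 0.5, s2 = 0.5))
  p <- posterior_signature_prob(1L, w, cat)
  expect_equal(unname(p), c(2 / 3, 1 / 3))
  expect_equal(sum(p), 1)

  # a single detected signature takes all the probability
  w1 <- toy_weights(c(s1 = 1, s2 = 0))
  expect_equal(unname(posterior_signature_prob(1L, w1, cat)["s1"]), 1)

  # zero catalogue weight forces zero posterior regardless of D
  cat0 <- toy_catalogue(c(s1 = 0, s2 = 0.1))
  p0 <- posterior_signature_prob(1L, toy_weights(c(s1 = 0.9, s2 = 0.1)), cat0)
  expect_equal(unname(p0["s1"]), 0)

  # no support at all: mutation is unattributable
  catz <- toy_catalogue(c(s1 = 0, s2 = 0))
  expect_null(posterior_signature_prob(1L, toy_weights(c(s1 = 0.5, s2 = 0.5)),
                                       catz))
})

test_that("expected counts aggregate posteriors and neoantigen weights", {
  cat <- synthetic_catalogue()
  ref <- make_reference(20000, seed = 2)
  spec <- cohort_spec(n_patients = 1, n_paired = 0, n_primary_treated = 0,
                      n_relapse_unpaired = 0, snvs_per_sample = 10,
                      background_mixture = c("Signature.1.Age" = 1),
                      neoantigens_per_snv = 0, seed = 5, ref_length = 20000)
  sim <- simulate_cohort(spec, cat, ref)
  muts <- sim$mutations[sim$mutations$variant_class == "SNV", ]
  muts$neoantigen_count <- 2L
  muts$expressed_neoantigen_count <- 0L
  w <- toy_weights(stats::setNames(c(1, rep(0, nrow(cat) - 1)), rownames(cat)))
  att <- expected_counts(muts, w, cat, reference = sim$reference)
  expect_equal(att$expected_snvs[att$category == "Signature.1.Age"], nrow(muts))
  expect_equal(att$expected_neoantigens[att$category == "Signature.1.Age"],
               2 * nrow(muts))
  expect_equal(sum(att$expected_snvs[att$category == "MNV/indel"]), 0)

  empty <- expected_counts(muts[0, ], w, cat, reference = sim$reference)
  expect_equal(sum(empty$expected_snvs), 0)
})

test_that("expected counts match a per-mutation enumeration oracle", {
  cat <- synthetic_catalogue()
  set.seed(8)
  w <- runif(nrow(cat)); w[w < 0.3] <- 0
  w <- stats::setNames(w / sum(w), rownames(cat))
  dec <- toy_weights(w)
  n <- 300
  ctx <- sample.int(96, n, TRUE)
  neo <- rpois(n, 1)
  rna <- sample(0:6, n, TRUE)
  muts <- fixture_records("chr1", pos = seq_len(n) + 1L, ref = "C", alt = "A",
                          rna_alt = rna, neo = neo, expr_neo = neo)
  muts$context <- ctx
  att <- expected_counts(muts, dec, cat)

  exp_snv <- stats::setNames(numeric(nrow(cat)), rownames(cat))
  exp_neo <- exp_snv; exp_expr <- exp_snv
  for (i in seq_len(n)) {
    p <- posterior_signature_prob(ctx[i], dec, cat)
    exp_snv[names(p)] <- exp_snv[names(p)] + p
    exp_neo[names(p)] <- exp_neo[names(p)] + neo[i] * p
    if (rna[i] >= 3) exp_expr[names(p)] <- exp_expr[names(p)] + neo[i] * p
  }
  sig_rows <- match(rownames(cat), att$category)
  expect_equal(att$expected_snvs[sig_rows], unname(exp_snv), tolerance = 1e-9)
  expect_equal(att$expected_neoantigens[sig_rows], unname(exp_neo),
               tolerance = 1e-9)
  expect_equal(att$expected_expressed_neoantigens[sig_rows], unname(exp_expr),
               tolerance = 1e-9)
})

test_that("attribution conserves SNV and neoantigen totals exactly", {
  cat <- synthetic_catalogue()
  spec <- cohort_spec(n_patients = 4, n_paired = 1, n_primary_treated = 0,
                      n_relapse_unpaired = 1, snvs_per_sample = 600,
                      ref_length = 2e5, seed = 21)
  sim <- simulate_cohort(spec, cat)
  res <- run_cohort_attribution(sim$mutations, sim$meta, cat, sim$reference)

  merged <- merge_adjacent_snvs(sim$mutations)
  present <- merged[is_present(merged$dna_alt_reads, merged$dna_total_reads), ]
  for (sid in unique(res$attribution$sample_id)) {
    att <- res$attribution[res$attribution$sample_id == sid, ]
    rows <- present[present$sample_id == sid, ]
    snv <- rows[rows$variant_class == "SNV", ]
    snv_cat <- att$category != "MNV/indel"
    expect_equal(sum(att$expected_snvs[snv_cat]), nrow(snv), tolerance = 1e-9)
    expect_equal(sum(att$expected_neoantigens[snv_cat]),
                 sum(snv$neoantigen_count), tolerance = 1e-9)
    expect_equal(sum(att$expected_expressed_neoantigens[snv_cat]),
                 sum(snv$expressed_neoantigen_count *
                       is_expressed(snv$rna_alt_reads)), tolerance = 1e-9)
    expect_equal(sum(att$expected_snvs[!snv_cat]),
                 sum(rows$variant_class != "SNV"))
  }
})

test_that("raising a mutation's neoantigen yield never lowers any signature's total", {
  cat <- synthetic_catalogue()
  set.seed(13)
  w <- stats::setNames(rep(1 / nrow(cat), nrow(cat)), rownames(cat))
  dec <- toy_weights(w, threshold = 0.01)
  n <- 50
  muts <- fixture_records("chr1", pos = seq_len(n) + 1L, ref = "C", alt = "A",
                          neo = rpois(n, 1))
  muts$context <- sample.int(96, n, TRUE)
  base <- expected_counts(muts, dec, cat)
  bumped <- muts
  bumped$neoantigen_count[7] <- bumped$neoantigen_count[7] + 3L
  after <- expected_counts(bumped, dec, cat)
  expect_true(all(after$expected_neoantigens >= base$expected_neoantigens - 1e-12))
})

test_that("the weight matrix is selected by post-uniqueness", {
  full <- toy_weights(c(s1 = 1, s2 = 0))
  post <- toy_weights(c(s1 = 0, s2 = 1))
  expect_identical(select_weight_matrix(full, NULL, FALSE), full)
  expect_identical(select_weight_matrix(full, post, TRUE), post)
  expect_identical(select_weight_matrix(full, post, FALSE), full)
  expect_error(select_weight_matrix(full, NULL, TRUE), "post-unique")
})

test_that("attributed mixture fractions recover generating fractions", {
  cat <- synthetic_catalogue()
  sigs <- c("Signature.1.Age", "Signature.2.APOBEC", "Signature.16",
            "Cisplatin.Gallus")
  H <- unclass(cat)[sigs, ]
  errs <- numeric(0)
  for (seed in 1:20) {
    set.seed(seed)
    w_true <- runif(4, 0.10, 0.5)
    w_true <- 0.6 * w_true / sum(w_true) + 0.1  # all components >= 0.10
    f <- colSums(H * w_true)
    ctx <- sample.int(96, 5000, TRUE, prob = f)
    counts <- tabulate(ctx, nbins = 96)
    dec <- deconvolve(counts, cat)
    muts <- fixture_records("chr1", pos = seq_along(ctx) + 1L,
                            ref = "C", alt = "A")
    muts$context <- ctx
    att <- expected_counts(muts, dec, cat)
    got <- att$expected_snvs[match(sigs, att$category)] / length(ctx)
    errs <- c(errs, abs(got - w_true))
  }
  expect_lt(max(errs), 0.05)
})
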