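test_that("preclinical simulation is seeded and mean-consistent", {
  B <- runif(96, 0, 20)
  T_ <- runif(96, 0, 30)
  e1 <- simulate_preclinical(B, T_, n_control = 3, n_treated = 3, seed = 12)
  e2 <- simulate_preclinical(B, T_, n_control = 3, n_treated = 3, seed = 12)
  expect_identical(e1$counts, e2$counts)
  expect_equal(e1$treated, rep(c(FALSE, TRUE), each = 3))

  z <- simulate_preclinical(rep(0, 96), T_, n_control = 2, n_treated = 2,
                            seed = 1)
  expect_true(all(z$counts[!z$treated, ] == 0))

  # law of large numbers: treated-minus-control means approach T
  big <- simulate_preclinical(B, T_, n_control = 1000, n_treated = 1000,
                              seed = 3)
  diff_mean <- colMeans(big$counts[big$treated, ]) -
    colMeans(big$counts[!big$treated, ])
  se <- sqrt((2 * B + T_) / 1000)
  expect_true(all(abs(diff_mean - T_) < 3.5 * se + 1e-9))
})

test_that("random references honour GC content and seeding", {
  at <- make_reference(2000, gc = 0, seed = 5)
  expect_true(all(strsplit(as.character(at[[1]]), "")[[1]] %in% c("A", "T")))
  expect_identical(as.character(make_reference(5000, seed = 9)),
                   as.character(make_reference(5000, seed = 9)))
  big <- make_reference(1e6, gc = 0.41, seed = 2)
  gc <- sum(Biostrings::letterFrequency(big, c("G", "C"))) / 1e6
  expect_lt(abs(gc - 0.41), 0.01)
})

test_that("cohort simulation is byte-identical under one seed", {
  spec <- cohort_spec(n_patients = 4, n_paired = 1, n_primary_treated = 1,
                      n_relapse_unpaired = 1, snvs_per_sample = 150,
                      ref_length = 1e5, seed = 33)
  s1 <- simulate_cohort(spec)
  s2 <- simulate_cohort(spec)
  expect_identical(s1$mutations, s2$mutations)
  expect_identical(s1$meta, s2$meta)
  expect_identical(s1$truth, s2$truth)
})

test_that("generated tables satisfy record invariants and match their ledger", {
  spec <- cohort_spec(n_patients = 5, n_paired = 1, n_primary_treated = 1,
                      n_relapse_unpaired = 1, snvs_per_sample = 400,
                      ref_length = 2e5, seed = 14)
  sim <- simulate_cohort(spec)
  m <- sim$mutations
  expect_true(all(m$dna_alt_reads <= m$dna_total_reads))
  expect_true(all(m$expressed_neoantigen_count <= m$neoantigen_count))
  expect_true(all(m$pos > 1))
  # every mutation row has a ledger entry with matching class bookkeeping
  expect_equal(nrow(sim$truth), nrow(m))
  snv <- m$variant_class == "SNV"
  expect_equal(sum(!is.na(sim$truth$context)), sum(snv))

  # the simulated alleles agree with the reference at every SNV position
  seq <- as.character(sim$reference[[1]])
  refb <- substring(seq, m$pos[snv], m$pos[snv])
  expect_equal(refb, m$ref[snv])

  # ledger signature counts match the mixture within multinomial noise
  prim <- sim$meta$sample_id[sim$meta$group == "primary_untreated"]
  tr <- sim$truth[sim$truth$sample_id %in% prim &
                    !sim$truth$signature %in% c("mnv", "ins", "del"), ]
  frac <- table(tr$signature) / nrow(tr)
  mix <- spec$background_mixture
  for (s in names(mix)) {
    se <- sqrt(mix[[s]] * (1 - mix[[s]]) / nrow(tr))
    expect_lt(abs(frac[[s]] - mix[[s]]), 4 * se + 1e-9)
  }
})

test_that("a zero chemotherapy fraction leaves no chemotherapy mutations in the ledger", {
  spec <- cohort_spec(n_patients = 4, n_paired = 1, n_primary_treated = 0,
                      n_relapse_unpaired = 1, snvs_per_sample = 200,
                      relapse_chemo_fraction = 0, ref_length = 1e5, seed = 8)
  sim <- simulate_cohort(spec)
  expect_false(any(sim$truth$signature %in% chemo_signature_names()))
})

test_that("single-signature sampling converges to the signature shape", {
  cat <- synthetic_catalogue()
  spec <- cohort_spec(n_patients = 1, n_paired = 0, n_primary_treated = 0,
                      n_relapse_unpaired = 0, snvs_per_sample = 50000,
                      background_mixture = c("Cisplatin.Gallus" = 1),
                      mnv_rate = 0, indel_rate = 0,
                      ref_length = 1e6, seed = 17)
  sim <- simulate_cohort(spec, cat)
  counts <- tabulate(sim$truth$context, nbins = 96)
  expect_gt(cosine_similarity(counts, unclass(cat)["Cisplatin.Gallus", ]),
            0.99)
  # and the emitted ref/alt/position encoding reproduces those contexts
  snv <- sim$mutations[sim$mutations$variant_class == "SNV", ][1:2000, ]
  idx <- classify_contexts(snv$chrom, snv$pos, snv$ref, snv$alt,
                           sim$reference, quiet = TRUE)
  truth_idx <- sim$truth$context[match(
    paste(snv$sample_id, snv$pos),
    paste(sim$truth$sample_id, sim$truth$pos)
  )]
  expect_equal(as.integer(idx), truth_idx)
})

test_that("paired relapse samples carry assessable pre-treatment read columns", {
  spec <- cohort_spec(n_patients = 3, n_paired = 2, n_primary_treated = 0,
                      n_relapse_unpaired = 0, snvs_per_sample = 300,
                      ref_length = 1e5, seed = 27)
  sim <- simulate_cohort(spec)
  post <- sim$mutations[grepl("-R$", sim$mutations$sample_id) &
                          sim$mutations$variant_class == "SNV", ]
  expect_true(all(!is.na(post$pre_total_reads)))
  uniq <- is_unique_to_post(post$pre_total_reads, post$pre_alt_reads)
  truth_flag <- sim$truth$post_unique[match(
    paste(post$sample_id, post$pos),
    paste(sim$truth$sample_id, sim$truth$pos)
  )]
  # filter positives are overwhelmingly the mutations generated as
  # post-unique (shared mutations can pass only when the primary sample
  # happened to sample zero variant reads)
  expect_gt(mean(truth_flag[uniq]), 0.95)
  expect_gt(mean(truth_flag), 0.3)  # around the generating fraction of 0.45
})
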