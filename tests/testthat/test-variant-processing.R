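test_that("presence filter applies strict VAF and inclusive read thresholds", {
  expect_true(is_present(6, 100))    # 6% > 5% and 6 >= 6
  expect_false(is_present(5, 50))    # 10% VAF but only 5 reads
  expect_false(is_present(6, 120))   # exactly 5% is not more than 5%
  expect_false(is_present(0, 0))     # zero coverage is absent, not an error
  expect_equal(is_present(c(6, 5, 6), c(100, 50, 120)),
               c(TRUE, FALSE, FALSE))
})

test_that("expression filter needs 3 or more RNA reads", {
  expect_equal(is_expressed(c(3, 2, 0, 10)), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("post-uniqueness needs >30x pre-treatment coverage and no variant reads", {
  expect_true(is_unique_to_post(31, 0))
  expect_false(is_unique_to_post(30, 0))
  expect_false(is_unique_to_post(100, 1))
  expect_false(is_unique_to_post(NA, NA))  # not assessable
})

test_that("adjacent SNVs merge into MNVs; gaps do not", {
  recs <- fixture_records(
    chrom = "chr1", pos = c(100L, 101L),
    ref = c("C", "T"), alt = c("A", "C"),
    neo = c(1L, 2L)
  )
  merged <- merge_adjacent_snvs(recs)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$ref, "CT")
  expect_equal(merged$alt, "AC")
  expect_equal(merged$variant_class, "MNV")
  expect_equal(merged$neoantigen_count, 3L)

  gap <- fixture_records(chrom = "chr1", pos = c(100L, 102L),
                         ref = c("C", "T"), alt = c("A", "C"))
  expect_equal(merge_adjacent_snvs(gap)$variant_class, c("SNV", "SNV"))

  tri <- fixture_records(chrom = "chr1", pos = c(100L, 101L, 102L),
                         ref = c("C", "T", "G"), alt = c("A", "C", "T"))
  out <- merge_adjacent_snvs(tri)
  expect_equal(out$ref, "CTG")
  expect_equal(out$alt, "ACT")
})

test_that("merging matches a run-length oracle and conserves covered positions", {
  set.seed(7)
  for (rep in 1:10) {
    pos <- sort(sample(1:60, 25))
    recs <- fixture_records(chrom = "chr1", pos = pos,
                            ref = "C", alt = "A")
    out <- merge_adjacent_snvs(recs)
    # oracle: number of runs of consecutive integers
    n_runs <- sum(diff(pos) != 1) + 1
    expect_equal(nrow(out), n_runs)
    covered <- unlist(mapply(function(p, r) p:(p + nchar(r) - 1),
                             out$pos, out$ref))
    expect_setequal(covered, pos)
  }
})

test_that("MNV read support is conservative and samples merge independently", {
  recs <- mutation_records(data.frame(
    patient_id = "P1", sample_id = c("S1", "S1", "S2"),
    chrom = "chr1", pos = c(10L, 11L, 10L),
    ref = "C", alt = "A",
    dna_alt_reads = c(10L, 7L, 9L), dna_total_reads = c(40L, 30L, 50L),
    rna_alt_reads = c(5L, 2L, 0L),
    neoantigen_count = 0L, expressed_neoantigen_count = 0L,
    variant_class = "SNV", stringsAsFactors = FALSE
  ))
  out <- merge_adjacent_snvs(recs)
  s1 <- out[out$sample_id == "S1", ]
  expect_equal(s1$variant_class, "MNV")
  expect_equal(s1$dna_alt_reads, 7L)     # min of constituents
  expect_equal(s1$dna_total_reads, 30L)
  expect_equal(s1$rna_alt_reads, 2L)
  expect_equal(out$variant_class[out$sample_id == "S2"], "SNV")
})

test_that("context tabulation matches an independent histogram and conserves counts", {
  counts0 <- tabulate_contexts(fixture_records("chr1", integer(0),
                                               character(0), character(0)),
                               fixture_reference("ACGTACGT"))
  expect_equal(sum(counts0), 0)

  seq <- paste(rep("TACGGA", 40), collapse = "")
  ref <- fixture_reference(seq)
  ten <- fixture_records("chr1", pos = 3L + 6L * (0:9), ref = "C", alt = "T")
  c10 <- tabulate_contexts(ten, ref)
  expect_equal(sum(c10), 10)
  expect_equal(unname(c10[["A[C>T]G"]]), 10)

  set.seed(3)
  n <- 200
  pos <- sample(2:(nchar(seq) - 1), n, TRUE)
  refb <- vapply(pos, function(p) substr(seq, p, p), "")
  altb <- vapply(refb, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  recs <- fixture_records("chr1", pos = pos, ref = refb, alt = altb)
  got <- tabulate_contexts(recs, ref)
  expect_equal(as.numeric(got),
               as.numeric(naive_context_histogram("chr1", pos, refb, altb, seq)))
  expect_equal(sum(got), n)
})

test_that("mutation tables are validated on construction", {
  base <- data.frame(
    patient_id = "P1", sample_id = "S1", chrom = "chr1", pos = 5L,
    ref = "C", alt = "A", dna_alt_reads = 10L, dna_total_reads = 30L,
    stringsAsFactors = FALSE
  )
  expect_silent(mutation_records(base))
  bad <- base; bad$dna_alt_reads <- 40L
  expect_error(mutation_records(bad), "exceeds")
  bad <- base; bad$ref <- "A"; bad$alt <- "A"
  expect_error(mutation_records(bad), "SNV")
  bad <- base; bad$neoantigen_count <- 1L; bad$expressed_neoantigen_count <- 2L
  expect_error(mutation_records(bad), "expressed")
})

test_that("mutation CSV and context-count CSV round-trip", {
  recs <- fixture_records("chr1", c(5L, 9L), c("C", "T"), c("A", "G"),
                          neo = c(2L, 0L))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(recs, f, row.names = FALSE)
  back <- read_mutations_csv(f)
  expect_equal(back$pos, recs$pos)
  expect_equal(back$neoantigen_count, recs$neoantigen_count)

  counts <- stats::setNames(numeric(96), sbs_contexts())
  counts[c(3, 50)] <- c(4, 7)
  f2 <- tempfile(fileext = ".csv")
  write_context_counts(counts, f2)
  expect_equal(as.numeric(read_context_counts(f2)), as.numeric(counts))
})

test_that("VCF input yields validated records with read support", {
  skip_if_not_installed("vcfR")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR",
    "chr1\t100\t.\tC\tA\t.\tPASS\t.\tGT:AD:DP\t0/1:50,10:60",
    "chr1\t200\t.\tT\tG\t.\tPASS\t.\tGT:AD:DP\t0/1:20,7:27"
  )
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  recs <- read_mutation_vcf(f, patient_id = "P1", sample_id = "S1")
  expect_equal(recs$pos, c(100L, 200L))
  expect_equal(recs$dna_alt_reads, c(10L, 7L))
  expect_equal(recs$dna_total_reads, c(60L, 27L))
  expect_equal(recs$variant_class, c("SNV", "SNV"))
})
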