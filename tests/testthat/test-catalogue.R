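test_that("catalogue column sums conserve input mutation counts", {
  cfg <- small_scenario(divisor = 60L)
  sim <- simulate_cohort(cfg, seed = 9, emit_records = TRUE)
  cat96 <- build_catalogue(sim$records, "SBS96",
                           sample_ids = colnames(sim$catalogue$counts))
  planted_totals <- colSums(sim$catalogue$counts)
  expect_equal(colSums(cat96$counts), planted_totals)
  expect_identical(cat96$counts, sim$catalogue$counts)
  expect_equal(cat96$log$n_unclassifiable, 0L)
})

test_that("catalogue is invariant to record order and logs skipped records", {
  cfg <- small_scenario(divisor = 100L)
  sim <- simulate_cohort(cfg, seed = 10, emit_records = TRUE)
  recs <- sim$records
  set.seed(1)
  perm <- recs[sample.int(nrow(recs)), ]
  c1 <- build_catalogue(recs, "SBS96")
  c2 <- build_catalogue(perm, "SBS96", sample_ids = c1$sample_ids)
  expect_identical(c1$counts, c2$counts)
  # a DBS record is skipped under an SBS schema; an N-context SNV is
  # unclassifiable; both are logged
  extra <- data.frame(sample_id = recs$sample_id[1], chrom = "1",
                      pos = c(1L, 2L), ref = c("CT", "C"),
                      alt = c("AA", "A"), context5 = c("A", "N"),
                      context3 = c("A", "A"))
  c3 <- build_catalogue(rbind(recs, extra), "SBS96",
                        sample_ids = c1$sample_ids)
  expect_equal(c3$log$n_skipped_type, 1L)
  expect_equal(c3$log$n_unclassifiable, 1L)
  expect_equal(sum(c3$counts), sum(c1$counts))
})

test_that("empty input and three-identical-SNV examples behave per contract", {
  empty <- build_catalogue(
    data.frame(sample_id = character(0), ref = character(0),
               alt = character(0), context5 = character(0),
               context3 = character(0)),
    "SBS96", sample_ids = c("a", "b"))
  expect_equal(dim(empty$counts), c(96L, 2L))
  expect_true(all(empty$counts == 0L))
  tri <- data.frame(sample_id = "s1", ref = "C", alt = "A",
                    context5 = "A", context3 = "A")[rep(1, 3), ]
  ct <- build_catalogue(tri, "SBS96")
  expect_equal(sum(ct$counts), 3L)
  expect_equal(unname(ct$counts["A[C>A]A", "s1"]), 3L)
})

test_that("six-class profile matches brute-force summation and handles edge columns", {
  schema <- channel_schema("SBS96")
  set.seed(3)
  counts <- matrix(rpois(96 * 5, 20), 96, 5,
                   dimnames = list(schema$channels, paste0("s", 1:5)))
  counts[, 5] <- 0L
  prof <- six_class_profile(counts)
  # oracle: sum the 16 channels per class by parsing the labels
  for (cls in c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")) {
    idx <- grepl(paste0("[", cls, "]"), schema$channels, fixed = TRUE)
    expect_equal(prof[cls, 1:4],
                 colSums(counts[idx, 1:4]) / colSums(counts[, 1:4]))
  }
  expect_true(all(abs(colSums(prof[, 1:4]) - 1) < 1e-12))
  expect_true(all(is.na(prof[, 5])))
  expect_identical(attr(prof, "undefined"), "s5")
  # pure C>A sample
  pure <- matrix(0L, 96, 1, dimnames = list(schema$channels, "p"))
  pure[grepl("[C>A]", schema$channels, fixed = TRUE), 1] <- 2L
  expect_equal(unname(six_class_profile(pure)[, 1]), c(1, 0, 0, 0, 0, 0))
  # uniform column
  unif <- matrix(1L, 96, 1, dimnames = list(schema$channels, "u"))
  expect_equal(unname(six_class_profile(unif)[, 1]), rep(1 / 6, 6))
})

test_that("catalogue TSV and signatures CSV round-trip exactly", {
  cfg <- small_scenario(divisor = 100L)
  sim <- simulate_cohort(cfg, seed = 12)
  path <- tempfile(fileext = ".tsv")
  write_catalogue(sim$catalogue, path)
  back <- read_catalogue(path)
  expect_identical(back$counts, sim$catalogue$counts)
  expect_identical(back$schema$name, "SBS96")
  sp <- tempfile(fileext = ".csv")
  write_signatures(sim$signatures, sp)
  sback <- read_signatures(sp, schema = "SBS96")
  expect_equal(sback, sim$signatures, tolerance = 1e-12)
})

test_that("minimal VCF reader with FASTA context provider classifies variants", {
  fa <- tempfile(fileext = ".fa")
  seqv <- paste0(strrep("A", 30), "C", strrep("G", 30))
  writeLines(c(">chr1", seqv), fa)
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t31\t.\tC\tA,T\t.\tPASS\t.",
    "chr1\t10\t.\tAA\tA\t.\tPASS\t."), vcf)
  ctx <- fasta_context_provider(fa, flank = 10L)
  muts <- read_vcf_mutations(vcf, "s1", context_fun = ctx)
  expect_equal(nrow(muts), 3L)   # multi-allelic split
  snvs <- muts[mutation_type(muts$ref, muts$alt) == "SNV", ]
  expect_identical(classify_sbs(snvs$ref, snvs$alt, snvs$context5,
                                snvs$context3),
                   c("A[C>A]G", "A[C>T]G"))
  indel <- muts[mutation_type(muts$ref, muts$alt) == "indel", ]
  expect_identical(
    classify_indel(indel$ref, indel$alt, indel$context5, indel$context3),
    "1:Del:T:5")
})
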