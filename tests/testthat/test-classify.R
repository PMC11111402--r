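test_that("SBS-96 classification matches exhaustive enumeration of all 192 stranded contexts", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(f5 = bases, ref = bases, alt = bases, f3 = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  expect_equal(nrow(grid), 192L)
  labels <- classify_sbs(grid$ref, grid$alt, grid$f5, grid$f3)
  # every label valid, all 96 channels covered exactly twice (2-to-1 map)
  schema <- channel_schema("SBS96")
  expect_true(all(labels %in% schema$channels))
  expect_equal(sort(unique(labels)), sort(schema$channels))
  expect_true(all(table(labels) == 2L))
  # strand invariance: classifying the reverse-complemented record gives
  # the identical channel (oracle reverse complement, not the package's)
  rc_labels <- classify_sbs(rc_oracle(grid$ref), rc_oracle(grid$alt),
                            rc_oracle(grid$f3), rc_oracle(grid$f5))
  expect_identical(labels, rc_labels)
  # canonical examples
  expect_identical(classify_sbs("C", "A", "A", "A"), "A[C>A]A")
  expect_identical(classify_sbs("G", "T", "T", "T"), "A[C>A]A")
})

test_that("SBS classification errors and unclassifiable handling", {
  expect_error(classify_sbs("CC", "A", "A", "A"), "single bases")
  expect_error(classify_sbs("C", "C", "A", "A"), "differ")
  expect_true(is.na(classify_sbs("C", "A", "N", "A")))
  expect_true(is.na(classify_sbs("C", "A", "A", "N")))
})

test_that("SBS-288 labels collapse exactly to SBS-96 and carry strand", {
  expect_identical(
    classify_sbs288("C", "A", "A", "A", "transcribed"), "T:A[C>A]A")
  set.seed(7)
  bases <- c("A", "C", "G", "T")
  n <- 200
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  f5 <- sample(bases, n, replace = TRUE)
  f3 <- sample(bases, n, replace = TRUE)
  strand <- sample(c("transcribed", "untranscribed", "unknown"), n,
                   replace = TRUE)
  l288 <- classify_sbs288(ref, alt, f5, f3, strand)
  expect_identical(collapse_sbs288(l288), classify_sbs(ref, alt, f5, f3))
  expect_true(all(l288 %in% channel_schema("SBS288")$channels))
})

test_that("SBS-288 catalogue column sums equal the SBS-96 catalogue's", {
  set.seed(21)
  cfg <- small_scenario(divisor = 60L)
  sim <- simulate_cohort(cfg, seed = 5, emit_records = TRUE)
  recs <- sim$records
  recs$strand <- sample(c("transcribed", "untranscribed", "unknown"),
                        nrow(recs), replace = TRUE)
  c96 <- build_catalogue(recs, "SBS96")
  c288 <- build_catalogue(recs, "SBS288", sample_ids = c96$sample_ids)
  expect_equal(colSums(c288$counts), colSums(c96$counts))
})

test_that("DBS-78 classification covers all 144 stranded doublets 78 channels", {
  bases <- c("A", "C", "G", "T")
  dinucs <- as.vector(outer(bases, bases, paste0))
  grid <- expand.grid(ref = dinucs, alt = dinucs, stringsAsFactors = FALSE)
  keep <- substr(grid$ref, 1, 1) != substr(grid$alt, 1, 1) &
    substr(grid$ref, 2, 2) != substr(grid$alt, 2, 2)
  grid <- grid[keep, ]
  expect_equal(nrow(grid), 144L)
  labels <- classify_dbs(grid$ref, grid$alt)
  schema <- channel_schema("DBS78")
  expect_true(all(labels %in% schema$channels))
  expect_equal(sort(unique(labels)), sort(schema$channels))
  # reverse-complement pairs merge: each channel hit once or twice, with
  # the self-complementary doublets hit once (144 = 2*66 + 12)
  tab <- table(labels)
  expect_true(all(tab %in% c(1L, 2L)))
  expect_equal(sum(tab == 1L), 12L)
  # strand invariance
  rc_labels <- classify_dbs(rc_oracle(grid$ref), rc_oracle(grid$alt))
  expect_identical(labels, rc_labels)
  # canonical examples
  expect_identical(classify_dbs("CT", "AA"), "CT>AA")
  expect_identical(classify_dbs("GG", "TT"), "CC>AA")
  expect_error(classify_dbs("CT", "CA"), "both")
})

test_that("ID-83 classification agrees with the construction grid over unit length, run count and homology", {
  units <- c("A", "AC", "ACG", "ACGT", "ACGTT", "ACGTAC")
  other <- function(...) setdiff(c("A", "C", "G", "T"), unlist(list(...)))[1]
  for (u_len in 1:6) {
    u <- units[u_len]
    first <- substr(u, 1, 1)
    last <- substr(u, u_len, u_len)
    b5 <- other(last, first)
    flank5 <- strrep(b5, 11)
    anchor <- substr(flank5, 11, 11)
    c5 <- substr(flank5, 1, 10)
    for (extra in 0:7) {
      b3 <- other(first, b5)
      c3 <- paste0(strrep(u, extra), strrep(b3, 12))
      # deletion: copies in reference including the deleted one = extra + 1
      lab_del <- classify_indel(paste0(anchor, u), anchor, c5, c3)
      Lc <- min(u_len, 5L)
      exp_del <- if (u_len == 1L) {
        base <- if (u %in% c("C", "T")) u else chartr("AG", "TC", u)
        paste0("1:Del:", base, ":", min(extra + 1L, 6L) - 1L)
      } else if (extra == 0L) {
        paste0(Lc, ":Del:R:0")
      } else {
        paste0(Lc, ":Del:R:", min(extra + 1L, 6L) - 1L)
      }
      expect_identical(lab_del, exp_del)
      # insertion: copies already present = extra
      lab_ins <- classify_indel(anchor, paste0(anchor, u), c5, c3)
      exp_ins <- if (u_len == 1L) {
        base <- if (u %in% c("C", "T")) u else chartr("AG", "TC", u)
        paste0("1:Ins:", base, ":", min(extra, 5L))
      } else {
        paste0(Lc, ":Ins:R:", min(extra, 5L))
      }
      expect_identical(lab_ins, exp_ins)
    }
    # microhomology grid: partial 3' copies of length h (deletions only)
    if (u_len >= 2L) {
      for (h in 1:min(u_len - 1L, 5L)) {
        nxt <- substr(u, h + 1L, h + 1L)
        b3 <- other(nxt, first)
        c3 <- paste0(substr(u, 1, h), strrep(b3, 12))
        lab <- classify_indel(paste0(anchor, u), anchor, c5, c3)
        expect_identical(lab, paste0(min(u_len, 5L), ":Del:M:",
                                     min(h, u_len - 1L, 5L)))
      }
    }
  }
})

test_that("ID-83 handles the canonical worked examples", {
  # insertion of T next to a TTTTT run: 5+ copies present
  expect_identical(
    classify_indel("A", "AT", strrep("G", 10), "TTTTTGGGGG"),
    "1:Ins:T:5")
  # deletion of C with no adjacent C on either side: minimal category
  expect_identical(
    classify_indel("AC", "A", strrep("A", 10), "GGGGGGGGGG"),
    "1:Del:C:0")
  # deletion of TAG flanked 3' by TA: 3-bp deletion, homology 2
  expect_identical(
    classify_indel("ATAG", "A", strrep("G", 10), "TACCCCCCCC"),
    "3:Del:M:2")
  expect_error(classify_indel("AC", "AG", strrep("A", 10), strrep("A", 10)),
               "complex|unclassifiable")
  expect_error(classify_indel("AC", "A", "AAA", strrep("A", 10)),
               "context")
})
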