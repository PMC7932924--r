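# constructed rearrangement-table fixture rows
rr <- function(case_id, count, tube = "TRG", junction_class = "Vg-Jg",
               five_gene = "TRGV1", three_gene = "TRGJ1", five_del = 0L,
               ndn_length = 4L, three_del = 0L, junction_aa = "CASW",
               platform = "DNAamp", damaged = FALSE,
               productivity = "productive") {
  df <- tibble::tibble(case_id = case_id, platform = platform, tube = tube,
                       junction_class = junction_class,
                       category = immunomark:::class_category(junction_class),
                       locus_group =
                         immunomark:::class_locus_group(junction_class),
                       five_gene = five_gene, three_gene = three_gene,
                       five_del = five_del, ndn_length = ndn_length,
                       three_del = three_del, junction_aa = junction_aa,
                       productivity = productivity, damaged = damaged,
                       count = as.integer(count))
  df$key <- identity_key(df)
  df
}

test_that("the uniqueness filter removes exactly the cross-case keys", {
  # ndn_length 9 produces the same key in every case that carries it
  tbl <- dplyr::bind_rows(
    rr("A", 50), rr("A", 40, ndn_length = 9L),
    rr("B", 30, ndn_length = 9L), rr("B", 25, ndn_length = 2L),
    rr("C", 10, ndn_length = 7L))
  fl <- apply_uniqueness_filter(tbl)
  expect_equal(nrow(fl$removed), 2)
  expect_setequal(fl$removed$case_id, c("A", "B"))
  expect_equal(unique(fl$removed$shared_cases), "A,B")
  expect_equal(nrow(fl$kept), 3)
  expect_false(any(fl$kept$ndn_length == 9L))
  # idempotence
  fl2 <- apply_uniqueness_filter(fl$kept)
  expect_equal(fl2$kept, fl$kept)
  expect_equal(nrow(fl2$removed), 0)
  # single-case run: no removals
  single <- apply_uniqueness_filter(dplyr::bind_rows(rr("A", 5), rr("A", 3,
                                                     ndn_length = 1L)))
  expect_equal(nrow(single$removed), 0)
  expect_equal(nrow(single$kept), 2)
})

test_that("a key shared by three cases is removed once per case", {
  tbl <- dplyr::bind_rows(
    rr("A", 12, ndn_length = 3L), rr("B", 7, ndn_length = 3L),
    rr("C", 4, ndn_length = 3L),
    rr("A", 20), rr("B", 21, ndn_length = 1L), rr("C", 22, ndn_length = 2L))
  fl <- apply_uniqueness_filter(tbl)
  # brute-force expectation: the shared key occurs once in each of 3 cases
  shared_key <- rr("A", 1, ndn_length = 3L)$key
  expect_equal(nrow(fl$removed), sum(tbl$key == shared_key))
  expect_equal(nrow(fl$removed), 3)
  expect_setequal(fl$removed$shared_cases, "A,B,C")
  expect_equal(nrow(fl$kept), 3)
})

test_that("damaged partial keys are exempt from the uniqueness filter", {
  tbl <- dplyr::bind_rows(
    rr("A", 2, platform = "RNAseq", damaged = TRUE, junction_aa = "",
       ndn_length = NA_integer_),
    rr("B", 3, platform = "RNAseq", damaged = TRUE, junction_aa = "",
       ndn_length = NA_integer_))
  fl <- apply_uniqueness_filter(tbl)
  expect_equal(nrow(fl$removed), 0)
  expect_equal(nrow(fl$kept), 2)
})

test_that("DNAamp marker thresholds are inclusive and tube-scoped", {
  # tube total 200: 12 reads (6%) passes; 10 reads (5% exactly) passes on
  # both inclusive bounds; 9 reads at 50% of a small tube fails min_reads;
  # 11 reads at 4.4% fails min_fraction
  tbl <- dplyr::bind_rows(
    rr("A", 12, ndn_length = 1L),                  # marker
    rr("A", 10, ndn_length = 2L),                  # marker, both bounds exact
    rr("A", 178, ndn_length = 3L),                 # marker (dominant clone)
    rr("A", 9, tube = "TRD", junction_class = "Vd-(Dd)-Jd",
       five_gene = "TRDV1", three_gene = "TRDJ1", ndn_length = 4L),
    rr("A", 9, tube = "TRD", junction_class = "Vd-(Dd)-Jd",
       five_gene = "TRDV2", three_gene = "TRDJ1", ndn_length = 5L),
    rr("A", 11, tube = "IGHV-IGHD-IGHJ", junction_class = "Vh-(Dh)-Jh",
       five_gene = "IGHV1", three_gene = "IGHJ1", ndn_length = 6L),
    rr("A", 239, tube = "IGHV-IGHD-IGHJ", junction_class = "Vh-(Dh)-Jh",
       five_gene = "IGHV2", three_gene = "IGHJ1", ndn_length = 7L))
  mk <- identify_dnaamp_markers(tbl, marker_thresholds())
  expect_setequal(mk$ndn_length, c(1L, 2L, 3L, 7L))
  expect_equal(mk$tube_total[mk$ndn_length == 1L], 200L)
  expect_equal(mk$fraction[mk$ndn_length == 2L], 0.05)
  # 9/18 = 50% in the TRD tube still fails the 10-read bound
  expect_false(any(mk$tube == "TRD"))
  # fractions within a tube sum to 1 over all keys
  all_fr <- identify_dnaamp_markers(tbl, marker_thresholds(min_reads = 0,
                                                           min_fraction = 0))
  sums <- tapply(all_fr$fraction, all_fr$tube, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_error(identify_dnaamp_markers(dplyr::mutate(tbl, tube = "NOPE")),
               "unknown tube")
})

test_that("RNAseq rearrangements are kept at any abundance unless told not to", {
  tbl <- dplyr::bind_rows(
    rr("A", 1, platform = "RNAseq", tube = NA_character_),
    rr("A", 300, platform = "RNAseq", tube = NA_character_,
       ndn_length = 2L))
  off <- identify_rnaseq_rearrangements(tbl, marker_thresholds())
  expect_equal(nrow(off), 2)
  on <- identify_rnaseq_rearrangements(
    tbl, marker_thresholds(apply_to_rnaseq = TRUE))
  expect_equal(nrow(on), 1)
  expect_equal(on$count, 300L)
  expect_equal(on$locus_total, 301L)
  empty <- identify_rnaseq_rearrangements(tbl[0, ], marker_thresholds())
  expect_equal(nrow(empty), 0)
})

test_that("marker counts are monotone in both thresholds", {
  sim <- mini_sim()
  kept <- apply_uniqueness_filter(sim$rearr)$kept
  grid_reads <- c(1, 5, 10, 25)
  grid_frac <- c(0, 0.02, 0.05, 0.15)
  counts <- matrix(NA_integer_, length(grid_reads), length(grid_frac))
  for (i in seq_along(grid_reads)) {
    for (j in seq_along(grid_frac)) {
      counts[i, j] <- nrow(identify_dnaamp_markers(
        kept, marker_thresholds(grid_reads[i], grid_frac[j])))
    }
  }
  expect_true(all(apply(counts, 2, diff) <= 0))
  expect_true(all(apply(counts, 1, diff) <= 0))
})
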