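test_that("align_segment finds exact substrings and rejects noise", {
  ref <- toy_ref()
  idx <- toy_index()
  v <- ref$sequence[ref$name == "IGHV2"]
  read <- substr(v, 41, 140)
  hit <- align_segment(read, idx, "V")
  expect_equal(hit$gene, "IGHV2")
  expect_equal(hit$identity, 1)
  expect_equal(hit$read_end - hit$read_start, 100)
  expect_equal(hit$strand, "+")
  # minus-strand reads align after reverse-complementing
  hit_rc <- align_segment(immunomark:::revcomp(read), idx, "V")
  expect_equal(hit_rc$gene, "IGHV2")
  expect_equal(hit_rc$strand, "-")
  # random reads produce almost no false V/J calls and no annotations
  withr::with_seed(5, {
    rand <- vapply(1:1000, function(i) immunomark:::random_dna(150), "")
  })
  fp <- vapply(rand, function(r) nrow(align_segment(r, idx, "V")) > 0, TRUE)
  expect_lt(mean(fp), 0.01)
  assigned <- vapply(rand[1:300], function(r) {
    annotate_read(r, NA, idx)$status == "assigned"
  }, TRUE)
  expect_lt(mean(assigned), 0.01)
})

test_that("alignment ties break to the lexicographically smaller gene", {
  seqs <- immunomark:::with_seed(3, immunomark:::random_dna(120))
  ref <- tibble::tibble(
    name = c("TRGV9", "TRGV2"), locus = "TRG", segment_type = "V",
    sequence = seqs, frame_anchor = 0L)
  ref <- immunomark:::new_germline_reference(ref)
  hit <- align_segment(substr(seqs, 1, 80), ref, "V")
  expect_equal(hit$gene, "TRGV2")
})

test_that("read pairs merge on true overlaps only", {
  ref <- toy_ref()
  idx <- toy_index()
  r <- simulate_rearrangement(ref, "Vg-Jg", simulation_params(), seed = 12,
                              index = idx)
  frag <- substr(r$sequence, 1, 120)
  read1 <- substr(frag, 1, 75)
  read2 <- immunomark:::revcomp(substr(frag, 46, 120))
  m <- merge_pair(read1, read2)
  expect_true(m$merged)
  expect_equal(m$sequence, frag)
  # distant mates (no overlap) stay unmerged
  frag2 <- substr(r$sequence, 1, 300)
  m2 <- merge_pair(substr(frag2, 1, 75),
                   immunomark:::revcomp(substr(frag2, 226, 300)))
  expect_false(m2$merged)
  # conflicting overlap content (mismatches beyond the seed) stays unmerged
  r2f_bad <- paste0(substr(frag, 46, 57), strrep("A", 13),
                    substr(frag, 71, 120))
  m3 <- merge_pair(read1, immunomark:::revcomp(r2f_bad))
  expect_false(m3$merged)
})

test_that("annotation recovers truth keys and reports unassigned reasons", {
  ref <- toy_ref()
  idx <- toy_index()
  p <- simulation_params()
  withr::with_seed(55, {
    for (label in c("Vg-Jg", "Dh-Jh", "Vk-Kde", "intron-Kde", "Dd2-Jd1")) {
      r <- simulate_rearrangement(ref, label, p, index = idx)
      ann <- annotate_read(r$sequence, NA, idx)
      expect_equal(ann$status, "assigned")
      expect_equal(ann$key, r$key, label = label)
      expect_false(ann$damaged)
      # strand symmetry: the reverse complement yields the same record
      ann_rc <- annotate_read(immunomark:::revcomp(r$sequence), NA, idx)
      expect_equal(ann_rc$key, r$key, label = paste(label, "rc"))
      expect_equal(ann_rc$strand, "-")
    }
  })
  # a V-only read has no 3' partner
  v <- ref$sequence[ref$name == "IGKV1"]
  ann <- annotate_read(substr(v, 1, 120), NA, idx)
  expect_equal(ann$status, "unassigned")
  expect_equal(ann$reason, "no_3prime")
  # random sequence has no 5' anchor
  ann <- annotate_read(immunomark:::with_seed(6, immunomark:::random_dna(150)),
                       NA, idx)
  expect_equal(ann$status, "unassigned")
  expect_equal(ann$reason, "no_5prime")
})

test_that("unmerged pairs with a mid-fragment junction come back damaged", {
  ref <- toy_ref()
  idx <- toy_index()
  p <- simulation_params()
  r <- simulate_rearrangement(ref, "Vg-Jg", p, seed = 13, index = idx)
  # 250 nt fragment placed so the junction window starts 3 nt before the
  # second mate: neither 75 nt mate spans the whole window
  ctx <- paste0(immunomark:::with_seed(14, immunomark:::random_dna(200)),
                r$sequence,
                immunomark:::with_seed(15, immunomark:::random_dna(200)))
  ws0 <- r$win_start + 200
  frag <- substr(ctx, ws0 - 171, ws0 + 78)
  expect_equal(nchar(frag), 250)
  ann <- annotate_read(substr(frag, 1, 75),
                       immunomark:::revcomp(substr(frag, 176, 250)), idx)
  expect_equal(ann$status, "assigned")
  expect_true(ann$damaged)
  expect_equal(ann$junction_aa, "")
  expect_equal(ann$productivity, "unknown")
  expect_true(is.na(ann$ndn_length))
  # the damaged partial key differs from the intact key, and only the
  # intact record matches under default (exact) marker matching
  expect_false(ann$key == r$key)
  marker <- tibble::tibble(case_id = "c1", key = r$key,
                           junction_class = r$junction_class,
                           five_gene = r$five_gene,
                           three_gene = r$three_gene,
                           five_del = r$five_del,
                           ndn_length = r$ndn_length,
                           three_del = r$three_del)
  rna <- dplyr::bind_rows(
    dplyr::mutate(marker, damaged = FALSE, count = 1L),
    dplyr::mutate(marker, key = ann$key, damaged = TRUE, count = 2L,
                  ndn_length = NA_integer_))
  v_intact <- match_markers(marker, rna[1, ])
  v_damaged_only <- match_markers(marker, rna[2, ])
  expect_true(v_intact$matched)
  expect_false(v_damaged_only$matched)
})

test_that("pair annotation is symmetric under fragment strand flips", {
  sim <- mini_sim()
  idx <- toy_index()
  rna <- sim$rna
  assigned <- which(sim$arna$status == "assigned")
  for (i in assigned[seq(1, min(20, length(assigned)))]) {
    # opposite-strand sequencing of the same fragment swaps the mates
    flipped <- annotate_read(rna$sequence2[i], rna$sequence[i], idx)
    expect_equal(flipped$key, sim$arna$key[i])
    expect_equal(flipped$strand, "-")
  }
})

test_that("deduplication counts reads for DNAamp, fragments for RNAseq", {
  ref <- toy_ref()
  idx <- toy_index()
  r <- simulate_rearrangement(ref, "Vg-Jg", simulation_params(), seed = 17,
                              index = idx)
  # 5 read pairs from the same fragment collapse to one unique fragment
  frag <- substring(r$sequence, nchar(r$sequence) - 149)
  pairs <- tibble::tibble(
    read_id = paste0("p", 1:5),
    sequence = substr(frag, 1, 75),
    sequence2 = immunomark:::revcomp(substr(frag, 76, 150)),
    fragment_id = "frag1", case_id = "c1", platform = "RNAseq",
    tube = NA_character_)
  ded <- deduplicate(annotate_reads(pairs, idx))
  expect_equal(nrow(ded), 1)
  expect_equal(ded$count, 1L)
  # 5 amplicon reads with one key count as 5
  amps <- tibble::tibble(read_id = paste0("a", 1:5), sequence = r$sequence,
                         case_id = "c1", platform = "DNAamp", tube = "TRG")
  ded2 <- deduplicate(annotate_reads(amps, idx))
  expect_equal(ded2$count, 5L)
  expect_equal(ded2$key, r$key)
  # empty input stays empty
  expect_equal(nrow(deduplicate(annotate_reads(amps[0, ], idx))), 0)
})

test_that("annotation results do not depend on input order", {
  sim <- mini_sim()
  idx <- toy_index()
  rna <- sim$rna[sim$rna$case_id == "case_01", ][1:80, ]
  a1 <- deduplicate(annotate_reads(rna, idx))
  a2 <- deduplicate(annotate_reads(rna[rev(seq_len(nrow(rna))), ], idx))
  expect_equal(a1, a2)
})

test_that("truth recovery and damage agreement hold on the mini cohort", {
  sim <- mini_sim()
  tk <- setNames(sim$truth$key, sim$truth$truth_id)
  clonal_ids <- sim$truth$truth_id[sim$truth$is_clonal]
  cl <- sim$adna[sim$adna$truth_id %in% clonal_ids, ]
  expect_gte(mean(cl$key == tk[cl$truth_id]), 0.99)
  ar <- sim$arna[sim$arna$status == "assigned", ]
  expect_gte(mean(ar$damaged == ar$damaged_truth), 0.99)
})
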