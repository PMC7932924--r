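test_that("tube definitions cover the amplifiable classes only", {
  tubes <- tube_definitions()
  expect_setequal(unique(tubes$tube),
                  c("IGHV-IGHD-IGHJ", "IGHD-IGHJ", "IGKV-IGKJ/Kde",
                    "intronRSS-Kde", "TRBV-TRBD-TRBJ", "TRBD-TRBJ", "TRG",
                    "TRD"))
  # IGL and TRA-5' classes belong to no tube
  expect_length(intersect(tubes$junction_class,
                          c("Vl-Jl", "Va-Ja", "Va-Jd", "Va-Dd")), 0)
  expect_true(all(tubes$junction_class %in% junction_classes()$label))
  expect_equal(anyDuplicated(tubes$junction_class), 0)
})

test_that("single rearrangement draws honor class and degenerate settings", {
  ref <- toy_ref()
  idx <- toy_index()
  p <- simulation_params()
  r <- simulate_rearrangement(ref, "Vk-Kde", p, seed = 7, index = idx)
  expect_equal(r$junction_class, "Vk-Kde")
  expect_equal(r$productivity, "unknown")
  expect_equal(r$junction_aa, "")
  # same seed reproduces the draw
  expect_identical(r, simulate_rearrangement(ref, "Vk-Kde", p, seed = 7,
                                             index = idx))
  # no deletions and no insertions: junction equals germline abutment
  p0 <- simulation_params(deletion_max = 0, ndn_mean = 0)
  r0 <- simulate_rearrangement(ref, "Vg-Jg", p0, seed = 3, index = idx)
  expect_equal(r0$five_del, 0L)
  expect_equal(r0$ndn_length, 0L)
  expect_equal(r0$three_del, 0L)
  v_seq <- ref$sequence[ref$name == r0$five_gene]
  j_seq <- ref$sequence[ref$name == r0$three_gene]
  expect_equal(r0$sequence, paste0(v_seq, j_seq))
  expect_error(simulate_rearrangement(ref, "Vx-Jx", p, index = idx),
               "unknown junction class")
})

test_that("cases carry the clonal plan and background productivity mix", {
  ref <- toy_ref()
  idx <- toy_index()
  p <- simulation_params(background_size = 40)
  case <- suppressWarnings(simulate_case(ref, p, "caseA", seed = 9,
                                         index = idx))
  clonal <- case[case$is_clonal, ]
  expect_equal(nrow(clonal), sum(default_clonal_plan()$n))
  expect_gte(sum(clonal$junction_class == "Vh-(Dh)-Jh"), 1)
  expect_gte(sum(clonal$junction_class == "Vk-Kde"), 1)
  expect_equal(anyDuplicated(clonal$key), 0)
  expect_equal(nrow(case[!case$is_clonal, ]), 40)
  # truth annotation is self-consistent: re-annotating the full sequence
  # reproduces the identity key
  for (i in sample(nrow(case), 8)) {
    ann <- annotate_read(case$sequence[i], NA, idx)
    expect_equal(ann$key, case$key[i])
  }
  # all-productive background boundary
  p1 <- simulation_params(background_size = 60,
                          background_productive_fraction = 1)
  case1 <- simulate_case(ref, p1, "caseB", seed = 10, index = idx)
  bg_complete <- case1[!case1$is_clonal &
                         case1$category == "complete_VJ", ]
  expect_true(all(bg_complete$productivity == "productive"))
})

test_that("clonal IGH unproductive fraction tracks the plan probability", {
  ref <- toy_ref()
  idx <- toy_index()
  plan <- default_clonal_plan()
  plan <- plan[plan$junction_class == "Vh-(Dh)-Jh", ]
  p <- simulation_params(background_size = 0, clonal_plan = plan)
  draws <- dplyr::bind_rows(lapply(1:40, function(i) {
    simulate_case(ref, p, sprintf("c%02d", i), seed = 77, index = idx)
  }))
  n <- nrow(draws)
  expect_equal(n, 80)
  k <- sum(draws$productivity == "unproductive")
  # binomial 99% acceptance band around 0.7
  expect_gte(k, qbinom(0.005, n, 0.7))
  expect_lte(k, qbinom(0.995, n, 0.7))
})

test_that("amplicon reads follow tube eligibility and clonal share", {
  ref <- toy_ref()
  idx <- toy_index()
  plan <- dplyr::bind_rows(default_clonal_plan(),
                           tibble::tibble(junction_class = "Vl-Jl", n = 1L,
                                          unproductive_prob = NA))
  p <- simulation_params(background_size = 30, clonal_plan = plan,
                         dnaamp_depth_per_tube = 10000)
  truth <- suppressWarnings(simulate_case(ref, p, "caseC", seed = 21,
                                          index = idx))
  reads <- suppressWarnings(simulate_dnaamp_reads(truth, p, seed = 21))
  # an IGL clonal rearrangement appears in no tube's output
  igl_ids <- truth$truth_id[truth$junction_class == "Vl-Jl"]
  expect_length(igl_ids, 1)
  expect_false(any(reads$truth_id %in% igl_ids))
  # reads only from tube-eligible classes, never from TRA-5' classes
  tube_classes <- tube_definitions()
  read_classes <- truth$junction_class[match(reads$truth_id, truth$truth_id)]
  expect_true(all(paste(reads$tube, read_classes) %in%
                    paste(tube_classes$tube, tube_classes$junction_class)))
  # clonal share within 3 sigma of blast_fraction in the IGH V tube
  tube <- reads[reads$tube == "IGHV-IGHD-IGHJ", ]
  clonal_ids <- truth$truth_id[truth$is_clonal]
  n_clonal <- sum(tube$truth_id %in% clonal_ids)
  expect_lt(abs(n_clonal - 0.9 * nrow(tube)),
            3 * sqrt(nrow(tube) * 0.9 * 0.1) + 1)
  # zero depth gives zero reads
  p0 <- simulation_params(dnaamp_depth_per_tube = 0)
  expect_equal(nrow(suppressWarnings(
    simulate_dnaamp_reads(truth, p0, seed = 1))), 0)
})

test_that("transcription rates follow the three-tier model", {
  p <- simulation_params(sterile_rate = 0.01, incomplete_rate = 0.001)
  truth <- tibble::tibble(
    category = c("complete_VJ", "complete_VJ", "incomplete_DJ", "other"),
    productivity = c("productive", "unproductive",
                     "potentially_productive", "unknown"))
  expect_equal(expression_level(truth, p), c(1, 0.01, 0.001, 0.001))
  p0 <- simulation_params(incomplete_rate = 0)
  expect_equal(expression_level(truth, p0)[3:4], c(0, 0))
})

test_that("RNAseq fragments respect rates, coverage truth and determinism", {
  ref <- toy_ref()
  idx <- toy_index()
  # zero sterile/incomplete rates: every fragment from a productive
  # complete rearrangement
  p <- simulation_params(background_size = 20, sterile_rate = 0,
                         incomplete_rate = 0, rnaseq_fragments = 300)
  truth <- suppressWarnings(simulate_case(ref, p, "caseD", seed = 31,
                                          index = idx))
  rna <- simulate_rnaseq_reads(truth, p, seed = 31)
  src <- truth[match(rna$truth_id, truth$truth_id), ]
  expect_true(all(src$productivity == "productive" &
                    src$category == "complete_VJ"))
  # read pairs are read_length long and fragment-consistent
  expect_true(all(nchar(rna$sequence) == pmin(75, rna$frag_len)))
  # whole-transcript fragments with reads at least as long leave no
  # junction uncovered
  pf <- simulation_params(background_size = 0, rnaseq_fragments = 150,
                          context_length = 400, fragment_length_min = 400,
                          fragment_length_mean = 400, fragment_length_sd = 0,
                          read_length = 410)
  truth_f <- simulate_case(ref, pf, "caseE", seed = 32, index = idx)
  rna_f <- simulate_rnaseq_reads(truth_f, pf, seed = 32)
  expect_gt(nrow(rna_f), 0)
  expect_true(all(!rna_f$damaged_truth))
  # all-zero rates: empty output with a warning
  pz <- simulation_params(productive_rate = 0, sterile_rate = 0,
                          incomplete_rate = 0)
  expect_warning(out <- simulate_rnaseq_reads(truth, pz, seed = 1),
                 "zero")
  expect_equal(nrow(out), 0)
  # determinism: same seed, byte-identical read tables and FASTQ
  rna2 <- simulate_rnaseq_reads(truth, p, seed = 31)
  expect_identical(rna, rna2)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rna, f1)
  write_fastq(rna2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("damaged fraction rises with fragment length", {
  ref <- toy_ref()
  idx <- toy_index()
  plan <- tibble::tibble(junction_class = "Vg-Jg", n = 1L,
                         unproductive_prob = 0)
  # among junction-spanning fragments, longer fragments leave the junction
  # outside the read coverage more often
  fracs <- vapply(c(180, 250, 350), function(fm) {
    p <- simulation_params(background_size = 0, clonal_plan = plan,
                           rnaseq_fragments = 1500,
                           fragment_length_mean = fm,
                           fragment_length_sd = 0)
    truth <- simulate_case(ref, p, "caseF", seed = 41, index = idx)
    rna <- simulate_rnaseq_reads(truth, p, seed = 41)
    win_center <- (truth$win_start + truth$win_end) %/% 2L
    pad5 <- max(0L, 300L - win_center)
    ws <- truth$win_start + pad5
    we <- truth$win_end + pad5
    spans <- ws >= rna$frag_start & we <= rna$frag_start + rna$frag_len
    mean(rna$damaged_truth[spans])
  }, 0)
  expect_true(all(diff(fracs) > 0))
})

test_that("read ids and truth tables are mutually consistent", {
  sim <- mini_sim()
  expect_true(all(sim$dna$truth_id %in% sim$truth$truth_id))
  expect_true(all(sim$rna$truth_id %in% sim$truth$truth_id))
  expect_equal(anyDuplicated(sim$dna$read_id), 0)
  expect_equal(anyDuplicated(sim$rna$read_id), 0)
  # read id embeds the case and truth record
  parts <- strsplit(sim$dna$read_id, "|", fixed = TRUE)
  expect_true(all(vapply(parts, `[`, "", 1) == sim$dna$case_id))
  expect_true(all(vapply(parts, `[`, "", 3) == sim$dna$truth_id))
})
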