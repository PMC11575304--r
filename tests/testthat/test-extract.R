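test_that("Mott quality trimming keeps good reads and drops bad ones", {
  seq10 <- strrep("A", 10)
  expect_equal(quality_trim(seq10, phred_string(rep(30, 10)))$seq, seq10)
  expect_equal(quality_trim(seq10, phred_string(rep(10, 10)))$seq, "")

  # mixed-quality read: the kept window must equal the exhaustive best window
  q <- c(rep(30, 4), rep(2, 3), rep(30, 3))
  w <- mott_window_oracle(q)
  tr <- quality_trim(seq10, phred_string(q))
  expect_equal(tr$seq, substr(seq10, w[1], w[2]))
  expect_equal(nchar(tr$seq), w[2] - w[1] + 1)
})

test_that("Mott trimming equals the exhaustive-window oracle on random reads", {
  set.seed(5)
  for (i in 1:200) {
    r <- random_read()
    q <- utf8ToInt(r$qual) - 33L
    expect_equal(metacrispr:::mott_window(q), mott_window_oracle(q),
                 info = paste("read", i))
  }
})

test_that("primer prefix matching tolerates up to the mismatch budget", {
  p <- crispr_primers("CRISPR3")
  spacer <- strrep("ACGT", 6)
  expect_equal(find_and_trim_primer(paste0(p$fwd_locus, spacer), p$fwd_locus),
               spacer)

  one_mm <- p$fwd_locus
  substr(one_mm, 3, 3) <- if (substr(one_mm, 3, 3) == "A") "C" else "A"
  expect_equal(find_and_trim_primer(paste0(one_mm, spacer), p$fwd_locus),
               spacer)

  three_mm <- p$fwd_locus
  for (i in c(2, 8, 14)) {
    substr(three_mm, i, i) <- if (substr(three_mm, i, i) == "A") "C" else "A"
  }
  expect_true(is.na(find_and_trim_primer(paste0(three_mm, spacer), p$fwd_locus)))
  expect_true(is.na(find_and_trim_primer("ACGT", p$fwd_locus)))
})

test_that("pair reconciliation resolves one mismatch by quality", {
  s <- strrep("AC", 11)
  expect_equal(reconcile_pair(s, s, strrep("I", 22), strrep("I", 22))$seq, s)

  s2 <- s; substr(s2, 5, 5) <- "T"
  hi_r2 <- reconcile_pair(s, s2, phred_string(c(rep(38, 4), 12, rep(38, 17))),
                          phred_string(rep(38, 22)))
  expect_equal(substr(hi_r2$seq, 5, 5), "T")
  hi_r1 <- reconcile_pair(s, s2, phred_string(rep(38, 22)),
                          phred_string(c(rep(38, 4), 12, rep(38, 17))))
  expect_equal(hi_r1$seq, s)

  s3 <- s2; substr(s3, 9, 9) <- "G"
  expect_true(reconcile_pair(s, s3, strrep("I", 22), strrep("I", 22))$conflict)
  expect_true(reconcile_pair(s, substr(s, 1, 20), strrep("I", 22),
                             strrep("I", 20))$conflict)
})

test_that("spacer length bounds are inclusive", {
  expect_false(length_filter(strrep("A", 19)))
  expect_true(length_filter(strrep("A", 20)))
  expect_true(length_filter(strrep("A", 40)))
  expect_false(length_filter(strrep("A", 41)))
})

test_that("primer-dimer artifacts are recognized from their fragments", {
  p3 <- crispr_primers("CRISPR3")
  p1 <- crispr_primers("CRISPR1")
  # reverse complement of the reverse-tail 5' end
  expect_equal(classify_artifact("ACATCTCCGAGCCCACGAGAC", p3),
               "primer_dimer_rev_tail")
  # fragment of the CRISPR1 forward fusion primer
  expect_equal(classify_artifact("ACTCTCAAGATTTAAGTAACT", p1),
               "primer_dimer_fwd")
  # and with a single mismatch
  expect_equal(classify_artifact("ACATCTCCGTGCCCACGAGAC", p3),
               "primer_dimer_rev_tail")
  set.seed(3)
  rnd <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
  expect_equal(classify_artifact(rnd, p3), "ok")
})

test_that("noiseless amplicons are recovered exactly at every spacer length", {
  p <- crispr_primers("CRISPR3")
  for (len in c(20L, 27L, 33L, 40L)) {
    arr <- make_array(p, 1, spacer_len_range = c(len, len), seed = len)
    amplicon <- paste0(p$fwd_locus, arr$spacers, revcomp(p$rev_locus))
    pairs <- tibble::tibble(
      r1_seq = amplicon, r1_qual = strrep("D", nchar(amplicon)),
      r2_seq = revcomp(amplicon), r2_qual = strrep("D", nchar(amplicon)),
      n = 3L
    )
    ex <- extract_pairs(pairs, p, "s")
    expect_equal(ex$observations$sequence, arr$spacers)
    expect_equal(ex$observations$count, 3L)
  }
})

test_that("extraction from FASTQ files conserves reads across labels", {
  arr <- make_array("CRISPR3", 4, seed = 2)
  cfg <- sim_config(read_depth = 300L, dimer_reads_expected = 200L,
                    per_base_error_rate = 0.002, contaminant_rate = 0)
  sim <- simulate_sample(arr, 500, cfg, seed = 7, sample_id = "mix")
  f1 <- withr_tempfile(); f2 <- withr_tempfile()
  write_paired_fastq(sim, f1, f2)
  ex <- extract_sample(f1, f2, arr$primers, "mix")
  expect_equal(sum(ex$report$count), sum(sim$n))
  expect_setequal(ex$report$label,
                  c("ok", "quality_fail", "no_primer_found", "primer_dimer_fwd",
                    "primer_dimer_rev_tail", "pair_conflict", "length_fail"))
  # re-embedding extracted spacers in fresh noiseless amplicons is idempotent
  spacers <- ex$observations$sequence[ex$observations$count >
                                        0.01 * sum(ex$observations$count)]
  amplicon <- paste0(arr$primers$fwd_locus, spacers,
                     revcomp(arr$primers$rev_locus))
  redo <- extract_pairs(
    tibble::tibble(r1_seq = amplicon, r1_qual = strrep("D", nchar(amplicon)),
                   r2_seq = revcomp(amplicon),
                   r2_qual = strrep("D", nchar(amplicon)), n = 1L),
    arr$primers, "redo")
  expect_setequal(redo$observations$sequence, spacers)
})

test_that("empty input gives empty output and a zero report", {
  f1 <- withr_tempfile(); f2 <- withr_tempfile()
  file.create(f1); file.create(f2)
  ex <- extract_sample(f1, f2, crispr_primers("CRISPR3"), "empty")
  expect_equal(nrow(ex$observations), 0)
  expect_equal(sum(ex$report$count), 0)
})
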