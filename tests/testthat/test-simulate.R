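test_that("synthetic arrays are distinct, primer-free and reproducible", {
  arr <- make_array("CRISPR3", 4, seed = 1)
  expect_length(arr$spacers, 4)
  expect_equal(anyDuplicated(arr$spacers), 0)
  lens <- nchar(arr$spacers)
  expect_true(all(lens >= 20 & lens <= 40))
  amplicons <- nchar(arr$primers$fwd_locus) + lens + nchar(arr$primers$rev_locus)
  expect_true(all(amplicons >= 67 & amplicons <= 87))

  expect_identical(make_array("CRISPR3", 4, seed = 1)$spacers, arr$spacers)
  expect_false(identical(make_array("CRISPR3", 4, seed = 2)$spacers,
                         arr$spacers))
  expect_length(make_array("CRISPR1", 1, seed = 9)$spacers, 1)

  # no spacer shares a 12-mer with the fusion primers
  p <- arr$primers
  corpus <- unlist(lapply(c(p$fwd_fusion, p$rev_fusion,
                            revcomp(c(p$fwd_fusion, p$rev_fusion))),
                          metacrispr:::seq_kmers, k = 12L))
  for (sp in arr$spacers) {
    expect_false(any(metacrispr:::seq_kmers(sp, 12L) %in% corpus))
  }
})

test_that("household sharing controls repertoire overlap", {
  cfg <- sim_config(saliva_richness = 100L)

  none <- make_household(c("A", "B"), "H", "CRISPR3",
                         sim_config(saliva_richness = 100L,
                                    household_shared_fraction = 0), seed = 4)
  expect_length(intersect(names(none[[1]]$saliva_frequencies),
                          names(none[[2]]$saliva_frequencies)), 0)

  all_shared <- make_household(c("A", "B"), "H", "CRISPR3",
                               sim_config(saliva_richness = 100L,
                                          household_shared_fraction = 1), seed = 4)
  expect_setequal(names(all_shared[[1]]$saliva_frequencies),
                  names(all_shared[[2]]$saliva_frequencies))

  partial <- make_household(c("A", "B"), "H", "CRISPR3",
                            sim_config(saliva_richness = 100L,
                                       household_shared_fraction = 0.3), seed = 4)
  expect_length(intersect(names(partial[[1]]$saliva_frequencies),
                          names(partial[[2]]$saliva_frequencies)), 30)

  # frequencies sum to one; skin repertoire nested in saliva repertoire
  for (pool in partial) {
    expect_equal(sum(pool$saliva_frequencies), 1)
    expect_equal(sum(pool$skin_frequencies), 1)
    expect_true(all(names(pool$skin_frequencies) %in%
                    names(pool$saliva_frequencies)))
  }
})

test_that("simulation is deterministic per seed down to the FASTQ bytes", {
  arr <- make_array("CRISPR3", 4, seed = 1)
  cfg <- sim_config(read_depth = 500L, dimer_reads_expected = 300L)
  cfg$contaminant_spacers <- make_contaminant_pool(arr$primers, seed = 8)
  s1 <- simulate_sample(arr, 100, cfg, seed = 3, sample_id = "s")
  s2 <- simulate_sample(arr, 100, cfg, seed = 3, sample_id = "s")
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  s3 <- simulate_sample(arr, 100, cfg, seed = 4, sample_id = "s")
  expect_false(identical(as.data.frame(s1), as.data.frame(s3)))

  d <- tempfile(); dir.create(d)
  write_paired_fastq(s1, file.path(d, "a1.fq"), file.path(d, "a2.fq"))
  write_paired_fastq(s2, file.path(d, "b1.fq"), file.path(d, "b2.fq"),
                     id_prefix = "s")
  expect_identical(readLines(file.path(d, "a1.fq")),
                   readLines(file.path(d, "b1.fq")))
  expect_identical(readLines(file.path(d, "a2.fq")),
                   readLines(file.path(d, "b2.fq")))
})

test_that("no-template controls contain only dimer and contaminant reads", {
  arr <- make_array("CRISPR3", 4, seed = 1)
  cfg <- sim_config()
  cfg$contaminant_spacers <- make_contaminant_pool(arr$primers, seed = 8)
  ntc <- simulate_sample(arr, 0, cfg, seed = 6, sample_id = "ntc")
  truth <- attr(ntc, "truth")
  expect_true(all(truth$templates == 0))
  expect_true(all(truth$reads == 0))
  expect_setequal(unique(ntc$origin), c("dimer", "contaminant"))

  ex <- extract_pairs(ntc, arr$primers, "ntc")
  n_total <- sum(ntc$n)
  n_noise <- sum(ex$report$count[grepl("^primer_dimer", ex$report$label)]) +
    sum(ntc$n[ntc$origin == "contaminant"])
  expect_gt(n_noise / n_total, 0.95)
  # no true spacer survives extraction of a dimer-dominated NTC
  expect_false(any(ex$observations$sequence %in% arr$spacers))
})

test_that("noiseless replicates recover identical spacer sets", {
  arr <- make_array("CRISPR3", 4, seed = 1)
  cfg <- noiseless_config(depth = 1000L)
  sets <- lapply(1:3, function(r) {
    sim <- simulate_sample(arr, 1000, cfg, seed = 30 + r, sample_id = "s")
    ex <- extract_pairs(sim, arr$primers, "s")
    sort(collapse_errors(dereplicate(ex$observations))$sequence)
  })
  expect_equal(sets[[1]], sort(arr$spacers))
  expect_equal(sets[[2]], sets[[1]])
  expect_equal(sets[[3]], sets[[1]])
})

test_that("reproducibility degrades with template load in one experiment", {
  arr <- make_array("CRISPR3", 4, seed = 1)
  res <- dilution_experiment(arr, config = sim_config(), seed = 42)
  means <- res$distances |>
    dplyr::group_by(copies_per_ul) |>
    dplyr::summarise(m = mean(distance)) |>
    dplyr::arrange(dplyr::desc(copies_per_ul))
  expect_true(all(diff(means$m) >= -0.02))  # non-increasing in copies
  expect_true(all(res$distances$distance[res$distances$copies_per_ul == 1000] < 0.8))
  expect_gt(stats::median(res$distances$distance[res$distances$copies_per_ul == 1]),
            0.8)
})

test_that("full pipeline identifies individuals across households", {
  cfg <- sim_config()
  ok_runs <- vapply(1:20, function(run) {
    seed <- 1000L + 13L * run
    h1 <- make_household(c("A1", "A2"), "H1", "CRISPR3", cfg, seed = seed)
    h2 <- make_household(c("B1", "B2"), "H2", "CRISPR3", cfg, seed = seed + 7L)
    pools <- c(h1, h2)
    cfg$contaminant_spacers <- make_contaminant_pool(crispr_primers("CRISPR3"),
                                                     seed = seed + 5L)
    obs <- list()
    for (i in seq_along(pools)) {
      pool <- pools[[i]]
      for (tp in c("saliva", "skin")) {
        sid <- paste0(pool$individual_id, "_", tp)
        sim <- simulate_sample(pool, if (tp == "saliva") 1e5 else 1e4, cfg,
                               seed = seed + 100L * i + (tp == "skin"),
                               sample_id = sid, sample_type = tp)
        obs[[sid]] <- extract_pairs(sim, pool$primers, sid)$observations
      }
    }
    tab <- collapse_errors(dereplicate(dplyr::bind_rows(obs)))
    attr(tab, "samples") <- names(obs)
    d <- suppressWarnings(pairwise_distances(tab))
    own_ok <- all(vapply(pools, function(p) {
      dist_between(d, paste0(p$individual_id, "_skin"),
                   paste0(p$individual_id, "_saliva")) < 0.8
    }, logical(1)))
    cross_ok <- all(vapply(pools, function(p) {
      others <- setdiff(vapply(pools, `[[`, "", "individual_id"),
                        c(p$individual_id,
                          vapply(pools[vapply(pools, `[[`, "", "household_id") ==
                                         p$household_id], `[[`, "", "individual_id")))
      all(vapply(others, function(o) {
        dist_between(d, paste0(p$individual_id, "_skin"),
                     paste0(o, "_saliva")) >= 0.8
      }, logical(1)))
    }, logical(1)))
    own_ok && cross_ok
  }, logical(1))
  expect_gte(mean(ok_runs), 0.95)
})

test_that("within-individual distance falls as spacer load rises", {
  cfg <- sim_config()
  pool <- make_household("A", "H", "CRISPR3", cfg, seed = 77)[[1]]
  cfg$contaminant_spacers <- make_contaminant_pool(pool$primers, seed = 78)
  copies <- rep(c(1, 10, 100, 1e3, 1e4), each = 2)
  obs <- list(ref = local({
    sim <- simulate_sample(pool, 1e5, cfg, seed = 500, sample_id = "ref",
                           sample_type = "saliva")
    extract_pairs(sim, pool$primers, "ref")$observations
  }))
  for (i in seq_along(copies)) {
    sid <- paste0("skin", i)
    sim <- simulate_sample(pool, copies[i], cfg, seed = 600 + i,
                           sample_id = sid, sample_type = "skin")
    obs[[sid]] <- extract_pairs(sim, pool$primers, sid)$observations
  }
  tab <- collapse_errors(dereplicate(dplyr::bind_rows(obs)))
  attr(tab, "samples") <- names(obs)
  d <- suppressWarnings(pairwise_distances(tab))
  dist_to_ref <- vapply(seq_along(copies), function(i) {
    dist_between(d, paste0("skin", i), "ref")
  }, numeric(1))
  rho <- suppressWarnings(cor(copies, dist_to_ref, method = "spearman"))
  expect_lt(rho, 0)
})

test_that("simulated Cq values follow the ideal curve", {
  cq <- simulate_cq(10^(6:2), noise_sd = 0, seed = 1)
  expect_equal(diff(cq), rep(1 / log10(2), 4))
  curve <- fit_standard_curve(tibble::tibble(copies_per_ul = 10^(6:2), cq = cq))
  expect_equal(curve$efficiency_pct, 100, tolerance = 1e-6)
  expect_error(simulate_cq(c(0, 10)), "copies_per_ul > 0")
})
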