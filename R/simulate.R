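#' Simulation configuration
#'
#' Bundles the generative parameters of the synthetic amplicon model:
#' Poisson sampling of template molecules from the diluted extract,
#' per-template lognormal PCR amplification, competition of amplified
#' template mass against a fixed primer-dimer mass for sequencer output,
#' appended dimer reads dominating no-template controls, a global
#' environmental contaminant pool, and uniform per-base substitution errors.
#'
#' @param template_volume_ul Template volume per reaction in uL (default 1).
#' @param read_depth Sequencing depth budget for spacer-derived reads
#'   (default 20,000 pairs).
#' @param per_base_error_rate Per-base substitution error probability
#'   (default 0.001).
#' @param dimer_reads_expected Expected primer-dimer read pairs per library
#'   (default 15,000; no-template controls emit essentially only these).
#' @param dimer_template_equivalents Primer-dimer library mass expressed in
#'   template-molecule equivalents; amplified template mass competes against
#'   it for the read budget, so low-template libraries yield few spacer reads
#'   (default 150; 0 when `dimer_reads_expected` is 0).
#' @param contaminant_rate Fraction of the read budget drawn from the
#'   contaminant pool (default 0.001).
#' @param contaminant_spacers Optional named frequency vector for the global
#'   contaminant pool (see [make_contaminant_pool()]).
#' @param household_shared_fraction Fraction of an individual's spacer
#'   repertoire shared with household members (default 0.3).
#' @param pcr_dispersion_sigma Lognormal sigma of per-template amplification
#'   (default 0.6).
#' @param saliva_richness Spacers per individual saliva pool (default 30).
#' @param skin_subsample_fraction Fraction of the saliva repertoire present
#'   on skin (default 0.7).
#' @param abundance_jitter_sigma Lognormal sigma applied to skin frequencies
#'   relative to saliva (default 0.5).
#' @param read_quality Constant Phred score of correct simulated bases
#'   (default 35); error positions get Q20.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(template_volume_ul = 1,
                       read_depth = 20000L,
                       per_base_error_rate = 0.001,
                       dimer_reads_expected = 15000L,
                       dimer_template_equivalents = 150,
                       contaminant_rate = 0.001,
                       contaminant_spacers = NULL,
                       household_shared_fraction = 0.3,
                       pcr_dispersion_sigma = 0.6,
                       saliva_richness = 30L,
                       skin_subsample_fraction = 0.7,
                       abundance_jitter_sigma = 0.5,
                       read_quality = 35L) {
  stopifnot(read_depth > 0, template_volume_ul > 0,
            per_base_error_rate >= 0, per_base_error_rate <= 1,
            contaminant_rate >= 0, contaminant_rate <= 1,
            household_shared_fraction >= 0, household_shared_fraction <= 1,
            skin_subsample_fraction > 0, skin_subsample_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic CRISPR array
#'
#' Draws `n_spacers` distinct uniform-random spacers (rejection-sampled so no
#' spacer shares a 12-mer with the fusion primers or their reverse
#' complements), mirroring a cloned standard array. Each amplicon is
#' `fwd_locus + spacer + revcomp(rev_locus)`.
#'
#' @param primers A [primer_set()] (or locus name accepted by
#'   [crispr_primers()]).
#' @param n_spacers Number of spacers (>= 1).
#' @param spacer_len_range Inclusive length range (default the primer set's
#'   20-40 window).
#' @param seed Integer seed; identical seeds give identical arrays.
#' @return A list of class `crispr_array` with `locus_name`, `primers`,
#'   `spacers`.
#' @export
make_array <- function(primers, n_spacers, spacer_len_range = NULL, seed = 1L) {
  if (is.character(primers)) primers <- crispr_primers(primers)
  if (is.null(spacer_len_range)) {
    spacer_len_range <- c(primers$min_spacer_len, primers$max_spacer_len)
  }
  stopifnot(n_spacers >= 1, spacer_len_range[1] >= 1,
            spacer_len_range[1] <= spacer_len_range[2])
  set.seed(seed)
  forbidden <- unique(unlist(lapply(
    unique(c(primers$fwd_fusion, primers$rev_fusion,
             revcomp(c(primers$fwd_fusion, primers$rev_fusion)))),
    seq_kmers, k = 12L)))
  spacers <- character(0)
  bases <- c("A", "C", "G", "T")
  tries <- 0L
  while (length(spacers) < n_spacers) {
    tries <- tries + 1L
    if (tries > 1000L * n_spacers) abort("make_array: rejection sampling failed")
    lens <- spacer_len_range[1]:spacer_len_range[2]
    len <- lens[sample.int(length(lens), 1)]
    sp <- paste(sample(bases, len, replace = TRUE), collapse = "")
    if (sp %in% spacers) next
    if (any(seq_kmers(sp, 12L) %in% forbidden)) next
    spacers <- c(spacers, sp)
  }
  structure(list(locus_name = primers$locus_name, primers = primers,
                 spacers = spacers),
            class = "crispr_array")
}

#' @export
print.crispr_array <- function(x, ...) {
  cat("<crispr_array>", x$locus_name, "with", length(x$spacers), "spacers\n")
  invisible(x)
}

#' Global contaminant spacer pool
#'
#' Environmental contamination in low-biomass libraries looks like real
#' spacer amplicons; this builds a fixed pool of contaminant spacers with
#' Dirichlet(1) frequencies, shared across all samples of a run.
#'
#' @inheritParams make_array
#' @param n_spacers Pool size (default 20).
#' @return Named numeric vector of spacer frequencies.
#' @export
make_contaminant_pool <- function(primers, n_spacers = 20L, seed = 1L) {
  arr <- make_array(primers, n_spacers, seed = seed)
  w <- rgamma(n_spacers, 1)
  setNames(w / sum(w), arr$spacers)
}

#' Simulate a household of individuals with shared spacer repertoires
#'
#' Cohabiting individuals share `household_shared_fraction` of their spacer
#' repertoire (support-level sharing with independent frequencies); the rest
#' is private. Saliva frequencies are Dirichlet(1); the skin repertoire is a
#' random subset of the saliva repertoire with lognormal-jittered,
#' renormalized frequencies.
#'
#' @param individual_ids Character vector of individual labels.
#' @param household_id Household label.
#' @param primers A [primer_set()] or locus name.
#' @param config A [sim_config()] (richness, sharing, jitter parameters).
#' @param seed Integer seed.
#' @return A list of `individual_pool` objects.
#' @export
make_household <- function(individual_ids, household_id, primers,
                           config = sim_config(), seed = 1L) {
  if (is.character(primers)) primers <- crispr_primers(primers)
  stopifnot(length(individual_ids) >= 1)
  richness <- config$saliva_richness
  n_shared <- round(config$household_shared_fraction * richness)
  n_private <- richness - n_shared
  n_total <- n_shared + n_private * length(individual_ids)
  universe <- make_array(primers, max(n_total, 1L), seed = seed)$spacers
  set.seed(seed + 1L)
  shared <- if (n_shared > 0) universe[seq_len(n_shared)] else character()
  remaining <- setdiff(universe, shared)
  lapply(seq_along(individual_ids), function(i) {
    private <- if (n_private > 0) {
      remaining[((i - 1) * n_private + 1):(i * n_private)]
    } else character()
    support <- c(shared, private)
    w <- rgamma(length(support), 1)
    saliva <- setNames(w / sum(w), support)
    n_skin <- max(1L, ceiling(config$skin_subsample_fraction * length(support)))
    skin_support <- sample(support, n_skin)
    sw <- saliva[skin_support] * rlnorm(n_skin, 0, config$abundance_jitter_sigma)
    structure(list(individual_id = individual_ids[i],
                   household_id = household_id,
                   primers = primers,
                   saliva_frequencies = saliva,
                   skin_frequencies = sw / sum(sw)),
              class = "individual_pool")
  })
}

#' @export
print.individual_pool <- function(x, ...) {
  cat("<individual_pool>", x$individual_id, "in household", x$household_id,
      "-", length(x$saliva_frequencies), "saliva /",
      length(x$skin_frequencies), "skin spacers\n")
  invisible(x)
}

# Resolve a simulation source into (primers, named frequency vector).
source_frequencies <- function(source, sample_type = "saliva") {
  if (inherits(source, "crispr_array")) {
    list(primers = source$primers,
         freqs = setNames(rep(1 / length(source$spacers),
                              length(source$spacers)), source$spacers))
  } else if (inherits(source, "individual_pool")) {
    f <- if (sample_type == "skin") source$skin_frequencies
         else source$saliva_frequencies
    list(primers = source$primers, freqs = f)
  } else {
    abort("source must be a crispr_array or individual_pool")
  }
}

# Primer-dimer insert sequences: the fragments of the fusion primers that
# survive primer trimming in real no-template controls (a reverse-tail
# reverse complement and a forward-primer fragment).
dimer_inserts <- function(primers) {
  c(rev_tail = revcomp(substr(primers$rev_tail, 1L, 21L)),
    fwd = substr(primers$fwd_locus, 1L, min(21L, nchar(primers$fwd_locus))))
}

#' Simulate one amplicon library
#'
#' Draws `T ~ Poisson(copies_per_ul * template_volume_ul)` template
#' molecules with multinomial spacer identities, amplifies each by an
#' independent lognormal factor, and allocates
#' `read_depth * M_s / (M_s + M_d)` read pairs multinomially over the
#' amplified per-spacer mass `M_s` (the fixed dimer mass `M_d` models the
#' primer-dimer library fraction that crowds out low-template signal).
#' Poisson-distributed primer-dimer pairs and a contaminant-pool draw are
#' appended, then uniform per-base substitution errors are applied
#' independently to both mates (correct bases Q35, error positions Q20).
#'
#' @param source A [make_array()] array or [make_household()] pool.
#' @param copies_per_ul Template concentration (>= 0; 0 = no-template
#'   control).
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seed and config give identical output.
#' @param sample_id Sample label.
#' @param sample_type For individual pools: `"saliva"` or `"skin"`.
#' @return A tibble of class `sim_pairs`: run-length counted read pairs with
#'   columns `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual`, `n`, `origin`
#'   (`spacer`, `dimer` or `contaminant`), plus a `truth` attribute (tibble
#'   of true spacers and template/read counts) and a `sample_id` attribute.
#'   Expand to FASTQ with [write_paired_fastq()].
#' @export
simulate_sample <- function(source, copies_per_ul, config = sim_config(),
                            seed = 1L, sample_id = "sample",
                            sample_type = "saliva") {
  if (copies_per_ul < 0) abort("copies_per_ul must be non-negative")
  src <- source_frequencies(source, sample_type)
  primers <- src$primers
  freqs <- src$freqs
  set.seed(seed)

  n_templates <- rpois(1, copies_per_ul * config$template_volume_ul)
  tpl <- if (n_templates > 0) {
    as.vector(rmultinom(1, n_templates, freqs))
  } else {
    rep(0L, length(freqs))
  }
  mass <- vapply(tpl, function(k) {
    if (k == 0) 0 else sum(rlnorm(k, 0, config$pcr_dispersion_sigma))
  }, numeric(1))
  m_signal <- sum(mass)
  m_dimer <- if (config$dimer_reads_expected > 0) config$dimer_template_equivalents else 0
  n_signal <- if (m_signal > 0) {
    round(config$read_depth * m_signal / (m_signal + m_dimer))
  } else 0L
  sig_reads <- if (n_signal > 0) {
    as.vector(rmultinom(1, n_signal, mass))
  } else {
    rep(0L, length(freqs))
  }

  n_dimer <- if (config$dimer_reads_expected > 0) {
    rpois(1, config$dimer_reads_expected)
  } else 0L
  dimers <- dimer_inserts(primers)
  dimer_counts <- if (n_dimer > 0) {
    as.vector(rmultinom(1, n_dimer, rep(1, length(dimers))))
  } else rep(0L, length(dimers))

  contam <- config$contaminant_spacers
  n_contam <- if (!is.null(contam) && config$contaminant_rate > 0) {
    rbinom(1, config$read_depth, config$contaminant_rate)
  } else 0L
  contam_counts <- if (n_contam > 0) {
    as.vector(rmultinom(1, n_contam, contam))
  } else rep(0L, length(contam))

  inserts <- c(names(freqs), unname(dimers), names(contam))
  counts <- c(sig_reads, dimer_counts, contam_counts)
  origin <- c(rep("spacer", length(freqs)), rep("dimer", length(dimers)),
              rep("contaminant", length(contam)))
  keep <- counts > 0
  amplicon <- paste0(primers$fwd_locus, inserts[keep],
                     revcomp(primers$rev_locus))
  rows <- tibble(
    r1_seq = amplicon,
    r2_seq = revcomp(amplicon),
    n = as.integer(counts[keep]),
    origin = origin[keep]
  )
  q_char <- intToUtf8(config$read_quality + 33L)
  rows$r1_qual <- strrep(q_char, nchar(rows$r1_seq))
  rows$r2_qual <- rows$r1_qual

  rows <- inject_errors(rows, config$per_base_error_rate)
  rows <- rows[order(rows$origin, rows$r1_seq, rows$r2_seq), ]
  out <- structure(
    rows[, c("r1_seq", "r1_qual", "r2_seq", "r2_qual", "n", "origin")],
    class = c("sim_pairs", class(tibble())),
    sample_id = sample_id,
    truth = tibble(spacer = names(freqs), frequency = unname(freqs),
                   templates = tpl, reads = sig_reads)
  )
  out
}

# Uniform per-base substitution errors on a counted pair table; clean pairs
# stay aggregated, erroneous pairs are expanded individually.
inject_errors <- function(rows, e) {
  if (e <= 0 || nrow(rows) == 0) return(rows)
  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    l1 <- nchar(rows$r1_seq[i]); l2 <- nchar(rows$r2_seq[i])
    n <- rows$n[i]
    p_clean <- (1 - e)^(l1 + l2)
    n_clean <- rbinom(1, n, p_clean)
    m <- n - n_clean
    pieces <- rows[i, ]
    pieces$n <- n_clean
    if (m > 0) {
      k1 <- rbinom(m, l1, e)
      k2 <- rbinom(m, l2, e)
      z <- which(k1 + k2 == 0)
      if (length(z)) {  # condition on at least one error
        to1 <- runif(length(z)) < l1 / (l1 + l2)
        k1[z[to1]] <- 1L
        k2[z[!to1]] <- 1L
      }
      mut <- tibble(
        r1_seq = rep(rows$r1_seq[i], m), r1_qual = rep(rows$r1_qual[i], m),
        r2_seq = rep(rows$r2_seq[i], m), r2_qual = rep(rows$r2_qual[i], m),
        n = 1L, origin = rows$origin[i]
      )
      m1 <- mutate_bases(mut$r1_seq, mut$r1_qual, k1)
      m2 <- mutate_bases(mut$r2_seq, mut$r2_qual, k2)
      mut$r1_seq <- m1$seq; mut$r1_qual <- m1$qual
      mut$r2_seq <- m2$seq; mut$r2_qual <- m2$qual
      pieces <- bind_rows(pieces, mut)
    }
    out[[i]] <- pieces
  }
  res <- bind_rows(out)
  res <- res[res$n > 0, ]
  res %>%
    group_by(.data$r1_seq, .data$r1_qual, .data$r2_seq, .data$r2_qual,
             .data$origin) %>%
    summarise(n = as.integer(sum(.data$n)), .groups = "drop")
}

BASES <- c("A", "C", "G", "T")

# Apply k[i] substitution errors to read i (Q20 at error positions).
mutate_bases <- function(seqs, quals, k) {
  single <- which(k == 1L)
  if (length(single)) {
    len <- nchar(seqs[single])
    pos <- floor(runif(length(single)) * len) + 1L
    old <- substr(seqs[single], pos, pos)
    alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                  nrow = 4, byrow = TRUE, dimnames = list(BASES, NULL))
    new <- alt[cbind(match(old, BASES), sample.int(3, length(single), TRUE))]
    substr(seqs[single], pos, pos) <- new
    substr(quals[single], pos, pos) <- "5"  # Phred 20
  }
  multi <- which(k > 1L)
  for (i in multi) {
    len <- nchar(seqs[i])
    pos <- sample.int(len, min(k[i], len))
    s <- strsplit(seqs[i], "")[[1]]
    q <- strsplit(quals[i], "")[[1]]
    for (p in pos) {
      s[p] <- sample(setdiff(BASES, s[p]), 1)
      q[p] <- "5"
    }
    seqs[i] <- paste(s, collapse = "")
    quals[i] <- paste(q, collapse = "")
  }
  list(seq = seqs, qual = quals)
}

#' Expand simulated pairs to mated FASTQ files
#'
#' @param pairs A [simulate_sample()] result.
#' @param r1_path,r2_path Output FASTQ paths.
#' @param id_prefix Read id prefix (default the sample id).
#' @return Invisibly, the two paths.
#' @export
write_paired_fastq <- function(pairs, r1_path, r2_path,
                               id_prefix = attr(pairs, "sample_id") %||% "read") {
  idx <- rep(seq_len(nrow(pairs)), times = pairs$n)
  ids <- paste0(id_prefix, "_", seq_along(idx))
  write_fastq(tibble(id = paste0(ids, "/1"), seq = pairs$r1_seq[idx],
                     qual = pairs$r1_qual[idx]), r1_path)
  write_fastq(tibble(id = paste0(ids, "/2"), seq = pairs$r2_seq[idx],
                     qual = pairs$r2_qual[idx]), r2_path)
  invisible(c(r1_path, r2_path))
}

#' Run a simulated dilution series through the full pipeline
#'
#' Simulates `replicates` libraries at each concentration, extracts and
#' denoises them, and reports each library's Bray-Curtis distance to a
#' single highest-concentration reference replicate — the copy-number vs
#' reproducibility readout of the assay.
#'
#' @param array A [make_array()] standard array.
#' @param copies_list Concentrations in copies/uL (default `10^(3:0)`).
#' @param replicates Libraries per concentration (default 3).
#' @param config A [sim_config()]; a contaminant pool is generated
#'   automatically when `contaminant_rate > 0` and none is supplied.
#' @param seed Integer seed.
#' @return A list of class `dilution_result`: `distances` (tibble
#'   `copies_per_ul`, `replicate`, `sample_id`, `distance`), `asv` (the
#'   denoised [asv_table()]), `reference` (the reference sample id), and
#'   `report` (summed artifact-label counts).
#' @export
dilution_experiment <- function(array, copies_list = 10^(3:0), replicates = 3,
                                config = sim_config(), seed = 1L) {
  stopifnot(inherits(array, "crispr_array"))
  if (is.null(config$contaminant_spacers) && config$contaminant_rate > 0) {
    config$contaminant_spacers <-
      make_contaminant_pool(array$primers, seed = seed + 633L)
  }
  grid <- tidyr::expand_grid(copies_per_ul = copies_list,
                             replicate = seq_len(replicates))
  grid$sample_id <- sprintf("c%g_r%d", grid$copies_per_ul, grid$replicate)
  obs <- vector("list", nrow(grid))
  reports <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pairs <- simulate_sample(array, grid$copies_per_ul[i], config,
                             seed = seed + 97L * i,
                             sample_id = grid$sample_id[i])
    ex <- extract_pairs(pairs, array$primers, grid$sample_id[i])
    obs[[i]] <- ex$observations
    reports[[i]] <- ex$report
  }
  tab <- collapse_errors(dereplicate(bind_rows(obs)))
  attr(tab, "samples") <- grid$sample_id
  reference <- grid$sample_id[grid$copies_per_ul == max(copies_list)][1]
  dists <- pairwise_distances(tab)
  grid$distance <- vapply(grid$sample_id, function(s) {
    suppressWarnings(dist_between(dists, s, reference))
  }, numeric(1))
  report <- bind_rows(reports) %>%
    group_by(.data$label) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  structure(list(distances = as_tibble(grid), asv = tab,
                 reference = reference, report = report),
            class = "dilution_result")
}

#' @export
print.dilution_result <- function(x, ...) {
  cat("<dilution_result> reference:", x$reference, "\n")
  s <- x$distances %>%
    group_by(.data$copies_per_ul) %>%
    summarise(mean_distance = mean(.data$distance), .groups = "drop") %>%
    arrange(desc(.data$copies_per_ul))
  print(s)
  invisible(x)
}

#' Plot a dilution-series reproducibility readout
#'
#' @param result A [dilution_experiment()] result.
#' @param threshold Identity threshold drawn as a reference line (0.8).
#' @return A ggplot.
#' @export
plot_dilution_reproducibility <- function(result, threshold = 0.8) {
  ggplot2::ggplot(result$distances,
                  ggplot2::aes(x = factor(.data$copies_per_ul),
                               y = .data$distance)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "template copies/uL",
                  y = "Bray-Curtis distance to reference",
                  title = "Reproducibility vs template load")
}

#' Simulated Cq values from an ideal standard curve
#'
#' Helper for exercising the quantification module without modelling qPCR
#' chemistry: Cq is linear in log10(copies) with Gaussian noise.
#'
#' @param copies_per_ul Positive template concentrations.
#' @param slope,intercept Curve parameters (defaults: perfect doubling,
#'   Cq 36 at 1 copy/uL).
#' @param noise_sd Gaussian Cq noise (default 0.05 cycles).
#' @param seed Integer seed.
#' @return Numeric vector of Cq values.
#' @export
simulate_cq <- function(copies_per_ul, slope = -1 / log10(2),
                        intercept = 36, noise_sd = 0.05, seed = 1L) {
  stopifnot(all(copies_per_ul > 0))
  set.seed(seed)
  intercept + slope * log10(copies_per_ul) +
    stats::rnorm(length(copies_per_ul), 0, noise_sd)
}
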