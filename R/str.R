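#' Default 21-locus autosomal STR panel
#'
#' The 21 autosomal loci of the GlobalFiler amplification kit (the kit's
#' remaining markers are sex markers and are not compared).
#'
#' @return Character vector of locus names.
#' @export
str_panel_autosomal21 <- function() {
  c("D3S1358", "vWA", "D16S539", "CSF1PO", "TPOX", "D8S1179", "D21S11",
    "D18S51", "D2S441", "D19S433", "TH01", "FGA", "D22S1045", "D5S818",
    "D13S317", "D7S820", "SE33", "D10S1248", "D1S1656", "D12S391", "D2S1338")
}

#' Compare a called allele set with the reference genotype at one locus
#'
#' A locus is `correct` only under exact set equality. Losing reference
#' alleles without gaining any is `dropout_only` (or `no_call` when nothing
#' was called); extra alleles on top of the full reference are `dropin_only`;
#' anything else mixes both error types. Homozygotes are represented by a
#' single allele, so a two-allele call against a homozygous reference sharing
#' one allele counts as drop-in.
#'
#' @param called Character vector of called alleles (may be empty).
#' @param reference Character vector of reference alleles (non-empty).
#' @return One of `"correct"`, `"no_call"`, `"dropout_only"`,
#'   `"dropin_only"`, `"dropout_and_dropin"`.
#' @export
#' @examples
#' compare_locus(c("12"), c("12", "14"))
compare_locus <- function(called, reference) {
  called <- unique(called[!is.na(called) & nzchar(called)])
  reference <- unique(reference[!is.na(reference) & nzchar(reference)])
  if (length(reference) == 0) abort("compare_locus: reference genotype is empty")
  if (setequal(called, reference)) return("correct")
  if (length(called) == 0) return("no_call")
  dropout <- length(setdiff(reference, called)) > 0
  dropin <- length(setdiff(called, reference)) > 0
  if (dropout && dropin) "dropout_and_dropin"
  else if (dropout) "dropout_only"
  else "dropin_only"
}

# half-up rounding to integer percent (57.14 -> 57, 83.25 + printed tables)
round_half_up <- function(x) floor(x + 0.5)

#' Compare a called STR profile against a reference profile
#'
#' Both profiles are genotype tables: one row per locus with a
#' comma-separated allele string (empty = no call). The panels must match.
#'
#' @param called,reference Data frames with columns `locus`, `alleles`.
#' @param panel Locus panel (default [str_panel_autosomal21()]); every panel
#'   locus must appear in both profiles.
#' @return A list of class `profile_comparison`: `per_locus` tibble (locus,
#'   status), `correct_loci`, `total_loci`, `rate_pct` (half-up integer
#'   percent).
#' @export
compare_profile <- function(called, reference, panel = str_panel_autosomal21()) {
  for (nm in list(called = called, reference = reference)) {
    stopifnot(all(c("locus", "alleles") %in% names(nm)))
  }
  missing_c <- setdiff(panel, called$locus)
  missing_r <- setdiff(panel, reference$locus)
  if (length(missing_c) || length(missing_r)) {
    abort(sprintf("panel mismatch: loci missing from %s: %s",
                  if (length(missing_c)) "called profile" else "reference profile",
                  paste(c(missing_c, missing_r), collapse = ", ")))
  }
  split_alleles <- function(x) {
    if (is.na(x) || !nzchar(x)) character() else
      stringr::str_trim(strsplit(x, ",")[[1]])
  }
  status <- vapply(panel, function(loc) {
    compare_locus(split_alleles(called$alleles[match(loc, called$locus)]),
                  split_alleles(reference$alleles[match(loc, reference$locus)]))
  }, character(1))
  correct <- sum(status == "correct")
  structure(
    list(per_locus = tibble(locus = panel, status = unname(status)),
         correct_loci = correct,
         total_loci = length(panel),
         rate_pct = round_half_up(100 * correct / length(panel))),
    class = "profile_comparison"
  )
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("<profile_comparison> %d/%d loci correct (%d%%)\n",
              x$correct_loci, x$total_loci, x$rate_pct))
  invisible(x)
}

#' Correct-locus rates from correct-locus counts
#'
#' Convenience for auditing printed typing tables: converts per-sample
#' correct-locus counts into half-up integer percentages.
#'
#' @param correct_loci Integer vector of correct-locus counts.
#' @param total_loci Panel size (default 21).
#' @return Tibble with `correct_loci`, `total_loci`, `rate_pct`.
#' @export
profile_rates <- function(correct_loci, total_loci = 21L) {
  stopifnot(all(correct_loci >= 0), all(correct_loci <= total_loci))
  tibble(correct_loci = as.integer(correct_loci),
         total_loci = as.integer(total_loci),
         rate_pct = round_half_up(100 * correct_loci / total_loci))
}

#' Summarise a set of profile comparisons
#'
#' @param comparisons A list of [compare_profile()] results, or a tibble with
#'   columns `correct_loci`, `total_loci`, `rate_pct` (as from
#'   [profile_rates()]).
#' @return A one-row tibble: `n_profiles`, `full_profile_count`,
#'   `mean_rate_pct` (half-up integer).
#' @export
summarize_profiles <- function(comparisons) {
  df <- if (inherits(comparisons, "data.frame")) {
    as_tibble(comparisons)
  } else {
    purrr::map_dfr(comparisons, function(x) {
      tibble(correct_loci = x$correct_loci, total_loci = x$total_loci,
             rate_pct = x$rate_pct)
    })
  }
  if (nrow(df) == 0) abort("summarize_profiles: need at least one comparison")
  tibble(n_profiles = nrow(df),
         full_profile_count = sum(df$correct_loci == df$total_loci),
         mean_rate_pct = round_half_up(mean(df$rate_pct)))
}

#' Read an STR genotype table
#'
#' TSV/CSV with columns `sample_id`, `locus`, `alleles` (comma-separated
#' allele designations; empty for no call).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_str_profiles <- function(path) {
  tab <- read_delim_auto(path, all_character = TRUE)
  required <- c("sample_id", "locus", "alleles")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(paste0("STR profile table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  tab$alleles[is.na(tab$alleles)] <- ""
  as_tibble(tab)
}
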