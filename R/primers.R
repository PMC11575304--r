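#' Primer set for a streptococcal CRISPR locus
#'
#' A primer set bundles the locus-specific repeat-annealing primer halves and
#' the Illumina overhang tails used to build the fusion (sequencing) primers,
#' plus the spacer length window enforced downstream. Fusion primers are
#' always `tail + locus part`.
#'
#' @param locus_name Locus label, e.g. `"CRISPR3"` or `"CRISPR1"`.
#' @param fwd_locus,rev_locus Locus-specific primer halves (DNA strings) that
#'   anneal within the CRISPR repeat on either side of a spacer.
#' @param fwd_tail,rev_tail Illumina overhang sequences prepended to the locus
#'   halves in the fusion primers.
#' @param min_spacer_len,max_spacer_len Inclusive spacer length bounds in nt.
#'
#' @return An object of class `primer_set` (a named list).
#' @export
#' @examples
#' crispr_primers("CRISPR3")
primer_set <- function(locus_name, fwd_locus, rev_locus,
                       fwd_tail = ILLUMINA_FWD_TAIL,
                       rev_tail = ILLUMINA_REV_TAIL,
                       min_spacer_len = 20L, max_spacer_len = 40L) {
  stopifnot(is.character(fwd_locus), is.character(rev_locus),
            min_spacer_len > 0, min_spacer_len <= max_spacer_len)
  structure(
    list(
      locus_name = locus_name,
      fwd_locus = toupper(fwd_locus),
      rev_locus = toupper(rev_locus),
      fwd_tail = toupper(fwd_tail),
      rev_tail = toupper(rev_tail),
      fwd_fusion = paste0(toupper(fwd_tail), toupper(fwd_locus)),
      rev_fusion = paste0(toupper(rev_tail), toupper(rev_locus)),
      min_spacer_len = as.integer(min_spacer_len),
      max_spacer_len = as.integer(max_spacer_len)
    ),
    class = "primer_set"
  )
}

#' @export
print.primer_set <- function(x, ...) {
  cat("<primer_set>", x$locus_name, "\n",
      " fwd: ", x$fwd_locus, "\n",
      " rev: ", x$rev_locus, "\n",
      " spacer length: [", x$min_spacer_len, ", ", x$max_spacer_len, "]\n",
      sep = "")
  invisible(x)
}

# Illumina Nextera-style overhangs carried by both fusion primers.
ILLUMINA_FWD_TAIL <- "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG"
ILLUMINA_REV_TAIL <- "GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG"

#' Built-in primer sets for the two Streptococcus CRISPR loci
#'
#' Returns the repeat-targeting amplicon primer set for CRISPR3 or CRISPR1 of
#' *Streptococcus*, as used for metaCRISPR typing.
#'
#' @param locus `"CRISPR3"` or `"CRISPR1"`.
#' @return A [primer_set()].
#' @export
crispr_primers <- function(locus = c("CRISPR3", "CRISPR1")) {
  locus <- match.arg(locus)
  switch(locus,
    CRISPR3 = primer_set("CRISPR3",
      fwd_locus = "TCGAAACAACACAGCTCTAAAAC",
      rev_locus = "TGTTGTTTCGAATGGTTCCAAAAC"),
    CRISPR1 = primer_set("CRISPR1",
      fwd_locus = "ACTCTCAAGATTTAAGTAACTGTACAAC",
      rev_locus = "CAGTTACTTAAATCTTGAGAGTACAAAAAC")
  )
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (`A`, `C`, `G`, `T`, `N`).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- character(length(x))
  nonempty <- !is.na(x) & nzchar(x)
  if (any(nonempty)) {
    out[nonempty] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nonempty]))
    )
  }
  out[is.na(x)] <- NA_character_
  out
}

# Hamming distance between two equal-length strings (Inf if lengths differ).
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  if (a == b) return(0L)
  sum(utf8ToInt(a) != utf8ToInt(b))
}
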