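#' Read a FASTQ file into a tibble
#'
#' Parses Phred+33 FASTQ into one row per read. Quality is kept as the raw
#' quality string; use [phred_scores()] to decode to integer scores.
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @return A tibble with columns `id`, `seq`, `qual`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), f)
#' read_fastq(f)
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0) {
    return(tibble(id = character(), seq = character(), qual = character()))
  }
  if (n %% 4 != 0) {
    abort(sprintf("truncated FASTQ: %d lines is not a multiple of 4 (record %d incomplete)",
                  n, n %/% 4 + 1L))
  }
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  seq <- toupper(lines[idx + 1L])
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad_at <- !startsWith(hdr, "@")
  if (any(bad_at)) {
    abort(sprintf("malformed FASTQ record %d: header does not start with '@'",
                  which(bad_at)[1]))
  }
  bad_plus <- !startsWith(plus, "+")
  if (any(bad_plus)) {
    abort(sprintf("malformed FASTQ record %d: separator line does not start with '+'",
                  which(bad_plus)[1]))
  }
  bad_len <- nchar(seq) != nchar(qual)
  if (any(bad_len)) {
    abort(sprintf("malformed FASTQ record %d: sequence and quality lengths differ",
                  which(bad_len)[1]))
  }
  tibble(id = sub("^@", "", hdr), seq = seq, qual = qual)
}

#' Write reads to FASTQ
#'
#' Inverse of [read_fastq()]: `read_fastq(write_fastq(x, path))` recovers `x`.
#'
#' @param reads Tibble with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    abort("seq and qual lengths differ")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual)),
               con)
  }
  invisible(path)
}

#' Decode Phred+33 quality strings
#'
#' @param qual Character vector of quality strings.
#' @return A list of integer vectors of per-base Phred scores.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) if (nzchar(q)) utf8ToInt(q) - 33L else integer())
}

#' Encode integer Phred scores as a Phred+33 string
#' @param scores Integer vector of Phred scores.
#' @return A quality string.
#' @export
phred_string <- function(scores) {
  if (length(scores) == 0) return("")
  intToUtf8(as.integer(scores) + 33L)
}

#' Read mated paired-end FASTQ files
#'
#' Pairs records positionally and checks that id stems match after stripping
#' common mate suffixes (`/1`, `/2`, or a space-delimited tag).
#'
#' @param r1_path,r2_path Paths to the forward and reverse FASTQ files.
#' @return A tibble with columns `id`, `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual`.
#' @export
read_paired_fastq <- function(r1_path, r2_path) {
  r1 <- read_fastq(r1_path)
  r2 <- read_fastq(r2_path)
  if (nrow(r1) != nrow(r2)) {
    abort(sprintf("unmated FASTQ files: %d vs %d records", nrow(r1), nrow(r2)))
  }
  stem <- function(x) sub("/[12]$", "", sub("\\s.*$", "", x))
  s1 <- stem(r1$id)
  s2 <- stem(r2$id)
  bad <- s1 != s2
  if (any(bad)) {
    abort(sprintf("unmated FASTQ files: id stems differ at record %d ('%s' vs '%s')",
                  which(bad)[1], s1[which(bad)[1]], s2[which(bad)[1]]))
  }
  tibble(id = s1, r1_seq = r1$seq, r1_qual = r1$qual,
         r2_seq = r2$seq, r2_qual = r2$qual)
}

#' Read a sample metadata table
#'
#' Expects a tab- or comma-separated table with columns `sample_id`,
#' `individual`, `household`, `sample_type`, `site`, `dilution_factor`.
#' `sample_type` must be one of skin, saliva, object, NTC, standard. NTC rows
#' must carry no individual.
#'
#' @param path Path to the delimited file.
#' @return A tibble of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  meta <- read_delim_auto(path)
  required <- c("sample_id", "individual", "sample_type")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    abort(paste0("metadata is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"household" %in% names(meta)) meta$household <- NA_character_
  if (!"site" %in% names(meta)) meta$site <- NA_character_
  if (!"dilution_factor" %in% names(meta)) meta$dilution_factor <- 1
  if (anyDuplicated(meta$sample_id)) {
    abort(sprintf("duplicate sample_id in metadata: '%s'",
                  meta$sample_id[duplicated(meta$sample_id)][1]))
  }
  ok_types <- c("skin", "saliva", "object", "NTC", "standard")
  bad <- !meta$sample_type %in% ok_types
  if (any(bad)) {
    abort(sprintf("unknown sample_type '%s'", meta$sample_type[bad][1]))
  }
  ntc_named <- meta$sample_type == "NTC" & !is.na(meta$individual) & nzchar(meta$individual)
  if (any(ntc_named)) {
    abort(sprintf("NTC sample '%s' must have no individual", meta$sample_id[ntc_named][1]))
  }
  if (any(meta$dilution_factor <= 0, na.rm = TRUE)) {
    abort("dilution_factor must be positive")
  }
  as_tibble(meta)
}

#' Read a spacer copy-number table
#'
#' Parses a long-format copy table with one row per sample x locus. The
#' `copies_per_ul` column may contain numbers, numbers with a trailing `*`
#' (below the quantification limit, as footnoted in printed tables), or `ND`
#' (no amplification). `ND` becomes a missing value with `nd = TRUE`;
#' `below_loq` is true for ND rows and any value below `loq`.
#'
#' @param path Path to a tab- or comma-separated file with columns
#'   `sample_id`, `locus`, `copies_per_ul` and optionally `individual`,
#'   `site`, `sample_type`, `bacterial_dna_pg_ul`, `human_dna_pg_ul`.
#' @param loq Limit of quantification in copies/uL (lowest calibration
#'   standard; default 100).
#' @return A tibble with parsed numeric `copies_per_ul` plus `nd` and
#'   `below_loq` flags.
#' @export
read_copy_table <- function(path, loq = 100) {
  tab <- read_delim_auto(path, all_character = TRUE)
  required <- c("sample_id", "locus", "copies_per_ul")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(paste0("copy table is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  dup <- duplicated(tab[, c("sample_id", "locus")])
  if (any(dup)) {
    abort(sprintf("duplicate sample_id/locus row in copy table: '%s' / '%s'",
                  tab$sample_id[dup][1], tab$locus[dup][1]))
  }
  raw <- stringr::str_trim(tab$copies_per_ul)
  nd <- toupper(raw) == "ND"
  flagged <- grepl("\\*$", raw)
  value <- suppressWarnings(as.numeric(gsub("[,*]", "", raw)))
  bad <- !nd & is.na(value)
  if (any(bad)) {
    abort(sprintf("unparseable copies_per_ul value '%s' (sample '%s')",
                  raw[bad][1], tab$sample_id[bad][1]))
  }
  value[nd] <- NA_real_
  if (any(value < 0, na.rm = TRUE)) {
    abort("negative copies_per_ul in copy table")
  }
  out <- as_tibble(tab)
  out$copies_per_ul <- value
  out$nd <- nd
  out$below_loq <- nd | (!is.na(value) & value < loq)
  inconsistent <- flagged & !out$below_loq
  if (any(inconsistent)) {
    warn(sprintf("value footnoted below-LOQ but >= %g copies/uL (sample '%s')",
                 loq, out$sample_id[inconsistent][1]))
  }
  for (col in intersect(c("bacterial_dna_pg_ul", "human_dna_pg_ul"), names(out))) {
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }
  out
}

# Delimiter sniffing: tab if the header contains one, else comma.
read_delim_auto <- function(path, all_character = FALSE) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  col_types <- if (all_character) readr::cols(.default = readr::col_character()) else NULL
  readr::read_delim(path, delim = delim, col_types = col_types,
                    show_col_types = FALSE, progress = FALSE)
}

#' Construct an ASV count table
#'
#' The package's central object: per-sample counts of exact spacer sequences
#' (amplicon sequence variants), held in long form. Rows with the same
#' sample and sequence are not allowed; use [dereplicate()] to aggregate raw
#' observations.
#'
#' @param x A data frame with columns `sample_id`, `sequence`, `count`.
#' @return A tibble of class `asv_tbl`, ordered canonically (ASVs by
#'   descending total count then sequence; samples by first appearance).
#' @export
asv_table <- function(x) {
  stopifnot(all(c("sample_id", "sequence", "count") %in% names(x)))
  x <- as_tibble(x[, c("sample_id", "sequence", "count")])
  if (nrow(x) > 0 && any(x$count < 0)) abort("ASV counts must be non-negative")
  if (nrow(x) > 0 && any(x$count != round(x$count))) {
    abort("ASV counts must be integers")
  }
  if (anyDuplicated(paste(x$sample_id, x$sequence, sep = "\r"))) {
    abort("duplicate sample/sequence rows in ASV table")
  }
  x$count <- as.integer(round(x$count))
  structure(canonicalize_asv(x), class = c("asv_tbl", class(tibble())))
}

# Stable canonical order: ASVs by descending total count, ties lexicographic;
# samples keep first-appearance order.
canonicalize_asv <- function(x) {
  if (nrow(x) == 0) return(x)
  totals <- tapply(x$count, x$sequence, sum)
  seq_rank <- rank(-totals[x$sequence], ties.method = "min")
  ord <- order(match(x$sample_id, unique(x$sample_id)), seq_rank, x$sequence)
  x[ord, , drop = FALSE]
}

#' Widen an ASV table to a sample x sequence count matrix
#'
#' @param table An [asv_table()].
#' @param samples Optional sample ids to include (rows of all zeros are kept
#'   for samples with no ASVs).
#' @return An integer matrix, rows = samples, columns = ASV sequences.
#' @export
asv_matrix <- function(table, samples = NULL) {
  if (is.null(samples)) samples <- unique(table$sample_id)
  seqs <- unique(table$sequence)
  m <- matrix(0L, nrow = length(samples), ncol = length(seqs),
              dimnames = list(samples, seqs))
  keep <- table$sample_id %in% samples
  if (any(keep)) {
    m[cbind(match(table$sample_id[keep], samples),
            match(table$sequence[keep], seqs))] <- table$count[keep]
  }
  m
}

#' Read / write an ASV table as TSV
#'
#' Serialized wide: first column `sequence`, remaining columns per-sample
#' counts. `read_asv_table(write_asv_table(x, path))` round-trips.
#'
#' @param table An [asv_table()].
#' @param path File path.
#' @return `read_asv_table` returns an `asv_tbl`; `write_asv_table` returns
#'   `path` invisibly.
#' @export
write_asv_table <- function(table, path) {
  samples <- unique(table$sample_id)
  m <- asv_matrix(table, samples)
  wide <- tibble(sequence = colnames(m))
  for (s in samples) wide[[s]] <- unname(m[s, ])
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_asv_table
#' @export
read_asv_table <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sequence" %in% names(wide)) {
    abort("ASV table file must have a 'sequence' first column")
  }
  if (anyDuplicated(wide$sequence)) {
    abort(sprintf("duplicate ASV sequence row '%s'",
                  wide$sequence[duplicated(wide$sequence)][1]))
  }
  samples <- setdiff(names(wide), "sequence")
  if (length(samples) == 0 || nrow(wide) == 0) {
    return(asv_table(tibble(sample_id = character(), sequence = character(),
                            count = integer())))
  }
  long <- tidyr::pivot_longer(wide, -"sequence", names_to = "sample_id",
                              values_to = "count")
  if (any(long$count != round(long$count) | long$count < 0)) {
    abort("ASV counts must be non-negative integers")
  }
  # keep explicit zero rows out of the long representation, but remember
  # every sample column
  out <- asv_table(long[long$count > 0, c("sample_id", "sequence", "count")])
  attr(out, "samples") <- samples
  out
}

#' Sample ids covered by an ASV table
#'
#' Includes samples that lost every read (all-zero columns on disk).
#' @param table An `asv_tbl`.
#' @return Character vector of sample ids.
#' @export
asv_samples <- function(table) {
  union(attr(table, "samples") %||% character(), unique(table$sample_id))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
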