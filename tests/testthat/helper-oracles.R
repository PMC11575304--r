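# Independent oracles used by the property-style tests. These deliberately
# re-derive results by exhaustive search / direct formula evaluation, not by
# calling the implementation under test.

# Exhaustive O(n^2) search for the best Mott window: maximize score sum,
# ties -> longer window, then leftmost start; empty window (sum 0) allowed.
mott_window_oracle <- function(q, error_limit = 0.01) {
  score <- error_limit - 10^(-q / 10)
  n <- length(q)
  tol <- 1e-12
  best <- list(sum = 0, start = 0L, end = -1L, len = 0L)
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- sum(score[i:j])
      len <- j - i + 1L
      if (s > best$sum + tol ||
          (abs(s - best$sum) <= tol &&
           (len > best$len || (len == best$len && i < best$start)))) {
        best <- list(sum = s, start = i, end = j, len = len)
      }
    }
  }
  c(best$start, best$end)
}

random_read <- function(len_range = c(1, 60), q_range = c(2, 40)) {
  len <- sample(len_range[1]:len_range[2], 1)
  list(seq = paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
       qual = phred_string(sample(q_range[1]:q_range[2], len, TRUE)))
}

# AUC by exhaustive pair counting: P(pos < neg) + 0.5 P(pos == neg).
auc_oracle <- function(pos, neg) {
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p < n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Direct Bray-Curtis formula, written independently of bray_curtis().
bc_oracle <- function(u, v) {
  num <- 0
  for (k in seq_along(u)) num <- num + min(u[k], v[k])
  1 - 2 * num / (sum(u) + sum(v))
}

# Exhaustive merge-order search for the abundance-ratio collapse: returns
# every terminal count vector reachable by applying qualifying merges in any
# order (used on tables designed to have a unique terminal state).
collapse_all_orders <- function(counts, min_fold = 32, max_hamming = 1) {
  hamming_str <- function(a, b) {
    if (nchar(a) != nchar(b)) return(Inf)
    sum(utf8ToInt(a) != utf8ToInt(b))
  }
  nm <- names(counts)
  moves <- list()
  for (child in nm) {
    for (parent in nm) {
      if (parent != child && counts[[child]] > 0 && counts[[parent]] > 0 &&
          counts[[parent]] / counts[[child]] >= min_fold &&
          hamming_str(parent, child) <= max_hamming) {
        moves[[length(moves) + 1]] <- c(parent, child)
      }
    }
  }
  if (length(moves) == 0) return(list(counts))
  out <- list()
  for (mv in moves) {
    nxt <- counts
    nxt[[mv[1]]] <- nxt[[mv[1]]] + nxt[[mv[2]]]
    nxt[[mv[2]]] <- 0
    out <- c(out, collapse_all_orders(nxt, min_fold, max_hamming))
  }
  unique(out)
}

# Small random ASV table over near-identical sequences (provokes merges).
random_asv_table <- function(n_samples = 2, n_seq = 5, base_len = 24) {
  base <- paste(sample(c("A", "C", "G", "T"), base_len, TRUE), collapse = "")
  seqs <- vapply(seq_len(n_seq), function(i) {
    s <- strsplit(base, "")[[1]]
    k <- sample(0:2, 1)
    if (k > 0) {
      pos <- sample(base_len, k)
      s[pos] <- vapply(s[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    }
    paste(s, collapse = "")
  }, "")
  seqs <- unique(seqs)
  rows <- expand.grid(sample_id = paste0("s", seq_len(n_samples)),
                      sequence = seqs, stringsAsFactors = FALSE)
  rows$count <- sample(c(0:5, 10^(1:4)), nrow(rows), TRUE)
  rows <- rows[rows$count > 0, ]
  if (nrow(rows) == 0) return(random_asv_table(n_samples, n_seq, base_len))
  asv_table(rows)
}

withr_tempfile <- function() tempfile(fileext = ".txt")

noiseless_config <- function(depth = 1000L) {
  sim_config(read_depth = depth, per_base_error_rate = 0,
             dimer_reads_expected = 0L, contaminant_rate = 0)
}
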