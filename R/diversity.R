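#' Bray-Curtis dissimilarity between two count profiles
#'
#' `1 - 2 * sum(pmin(u, v)) / (sum(u) + sum(v))` over aligned non-negative
#' count vectors. Two all-zero profiles are defined to be maximally
#' dissimilar (distance 1, with a warning): samples that lost every read
#' occur routinely in diluted low-biomass libraries and must still compare.
#'
#' @param u,v Aligned non-negative count vectors.
#' @return Dissimilarity in `[0, 1]`.
#' @export
#' @examples
#' bray_curtis(c(2, 1, 0), c(1, 0, 1))
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) {
    abort("bray_curtis: vectors must have equal length")
  }
  if (any(u < 0) || any(v < 0)) abort("bray_curtis: counts must be non-negative")
  tot <- sum(u) + sum(v)
  if (tot == 0) {
    warn("bray_curtis: both profiles empty; returning maximal dissimilarity 1")
    return(1)
  }
  1 - 2 * sum(pmin(u, v)) / tot
}

#' Observed ASV richness
#'
#' @param counts Non-negative count vector for one sample.
#' @return Number of strictly positive entries.
#' @export
observed_otus <- function(counts) {
  sum(counts > 0)
}

#' Shannon diversity index
#'
#' `-sum(p_i * log(p_i, base))` over nonzero proportions; base 2 by default
#' (the common amplicon-pipeline convention).
#'
#' @param counts Non-negative count vector with positive total.
#' @param log_base Logarithm base (default 2).
#' @return The Shannon index.
#' @export
shannon <- function(counts, log_base = 2) {
  if (sum(counts) <= 0) abort("shannon: sample has no counts")
  unname(vegan::diversity(matrix(counts, nrow = 1), index = "shannon",
                          base = log_base)[1])
}

#' Per-sample alpha diversity of an ASV table
#'
#' @param table An [asv_table()].
#' @return Tibble with `sample_id`, `observed_otus`, `shannon` (NA for
#'   empty samples).
#' @export
alpha_diversity <- function(table) {
  m <- asv_matrix(table, asv_samples(table))
  tibble(
    sample_id = rownames(m),
    observed_otus = apply(m, 1, observed_otus),
    shannon = apply(m, 1, function(x) if (sum(x) > 0) shannon(x) else NA_real_)
  )
}

#' All pairwise Bray-Curtis distances of an ASV table
#'
#' @param table An [asv_table()] with at least 2 samples.
#' @return A tibble of class `bc_dist` with one row per unordered sample pair
#'   (`sample_a`, `sample_b`, `distance`); use [dist_matrix()] for the square
#'   form.
#' @export
pairwise_distances <- function(table) {
  samples <- asv_samples(table)
  if (length(samples) < 2) abort("pairwise_distances: need at least 2 samples")
  m <- asv_matrix(table, samples)
  empty <- rowSums(m) == 0
  if (any(empty)) {
    warn(sprintf("%d sample(s) with no counts; distances to them set to 1",
                 sum(empty)))
  }
  pairs <- utils::combn(samples, 2)
  d <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    d[k] <- if (empty[i] && empty[j]) 1
            else suppressWarnings(bray_curtis(m[i, ], m[j, ]))
  }
  structure(tibble(sample_a = pairs[1, ], sample_b = pairs[2, ], distance = d),
            class = c("bc_dist", class(tibble())), samples = samples)
}

#' Square distance matrix from pairwise distances
#'
#' @param distances A [pairwise_distances()] tibble.
#' @return A symmetric matrix with zero diagonal.
#' @export
dist_matrix <- function(distances) {
  samples <- attr(distances, "samples") %||%
    unique(c(distances$sample_a, distances$sample_b))
  m <- matrix(0, length(samples), length(samples),
              dimnames = list(samples, samples))
  i <- match(distances$sample_a, samples)
  j <- match(distances$sample_b, samples)
  m[cbind(i, j)] <- distances$distance
  m[cbind(j, i)] <- distances$distance
  m
}

#' Look up the distance between two samples
#' @param distances A [pairwise_distances()] tibble.
#' @param a,b Sample ids.
#' @return The Bray-Curtis distance.
#' @export
dist_between <- function(distances, a, b) {
  if (a == b) return(0)
  hit <- (distances$sample_a == a & distances$sample_b == b) |
         (distances$sample_a == b & distances$sample_b == a)
  if (!any(hit)) abort(sprintf("no distance recorded for '%s' vs '%s'", a, b))
  distances$distance[hit][1]
}

#' Call personal identity from a Bray-Curtis distance
#'
#' Two samples are called `same_source` when their dissimilarity is strictly
#' below the threshold (default 0.8); a distance exactly at the threshold is
#' `different_source`.
#'
#' @param distances A [pairwise_distances()] tibble (or any tibble with
#'   `sample_a`, `sample_b`, `distance`).
#' @param query,reference Sample ids to compare.
#' @param threshold Identity threshold (default 0.8).
#' @param locus Optional locus label carried into the result.
#' @return A one-row tibble: `query_sample`, `reference_sample`, `locus`,
#'   `distance`, `threshold`, `call`.
#' @export
call_identity <- function(distances, query, reference, threshold = 0.8,
                          locus = NA_character_) {
  d <- dist_between(distances, query, reference)
  tibble(query_sample = query, reference_sample = reference, locus = locus,
         distance = d, threshold = threshold,
         call = if (d < threshold) "same_source" else "different_source")
}

#' Identity calls for distances already in hand
#'
#' Vectorized strict-threshold rule for precomputed distances (e.g. printed
#' typing results).
#'
#' @param distance Numeric vector of Bray-Curtis distances.
#' @param threshold Identity threshold (default 0.8).
#' @return Character vector: `"same_source"` or `"different_source"`.
#' @export
identity_call <- function(distance, threshold = 0.8) {
  ifelse(distance < threshold, "same_source", "different_source")
}

#' ROC curve for distance-based identity calling
#'
#' The classifier "same source if distance < t" is swept over all distinct
#' observed distances plus boundary points. Sensitivity is computed over
#' same-individual pairs, specificity over different-individual pairs; AUC by
#' the trapezoid rule over (1 - specificity, sensitivity). The reported best
#' threshold maximizes sensitivity + specificity (Youden), with ties broken
#' toward higher specificity, then the lower threshold.
#'
#' @param distance Numeric vector of pairwise distances.
#' @param is_same Logical vector: `TRUE` for same-individual pairs.
#' @return An object of class `roc_result`; see [tidy()] and [glance()].
#' @export
roc_curve <- function(distance, is_same) {
  stopifnot(length(distance) == length(is_same))
  if (!any(is_same) || all(is_same)) {
    abort("roc_curve: both classes must be present")
  }
  pos <- distance[is_same]
  neg <- distance[!is_same]
  thr <- sort(unique(c(distance, -Inf, Inf, max(distance) + 1)))
  sens <- vapply(thr, function(t) mean(pos < t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (head(sens[ord], -1) + tail(sens[ord], -1)) / 2)
  youden <- sens + spec
  best <- which(youden == max(youden))
  best <- best[order(-spec[best], thr[best])][1]
  structure(
    list(thresholds = thr, sensitivity = sens, specificity = spec, auc = auc,
         best_threshold = thr[best], best_sensitivity = sens[best],
         best_specificity = spec[best],
         n_same = length(pos), n_different = length(neg)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result>\n",
      sprintf("  AUC = %.4f over %d same / %d different pairs\n",
              x$auc, x$n_same, x$n_different),
      sprintf("  best threshold %.4g (sens %.3f, spec %.3f)\n",
              x$best_threshold, x$best_sensitivity, x$best_specificity),
      sep = "")
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) {
  tibble(threshold = x$thresholds, sensitivity = x$sensitivity,
         specificity = x$specificity)
}

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, best_threshold = x$best_threshold,
         best_sensitivity = x$best_sensitivity,
         best_specificity = x$best_specificity,
         n_same = x$n_same, n_different = x$n_different)
}

#' @export
autoplot.roc_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$auc))
}

#' Compare skin-to-reference distances across relatedness groups
#'
#' Partitions skin-vs-saliva sample pairs into within-individual,
#' within-household (different individuals sharing a household) and
#' between-household groups, then applies a Kruskal-Wallis test across the
#' groups and pairwise Mann-Whitney U tests with Bonferroni correction
#' (p-values multiplied by the number of comparisons and capped at 1).
#'
#' @param distances A [pairwise_distances()] tibble.
#' @param meta Sample metadata tibble with `sample_id`, `individual`,
#'   `household`, `sample_type`.
#' @return A list of class `group_comparison`: `groups` (tibble of pair,
#'   group, distance), `kw_p`, and `pairwise` (tibble with raw and adjusted
#'   Mann-Whitney p-values).
#' @export
group_distances <- function(distances, meta) {
  stopifnot(all(c("sample_id", "individual", "household", "sample_type")
                %in% names(meta)))
  info <- function(id, col) meta[[col]][match(id, meta$sample_id)]
  df <- distances %>%
    mutate(
      type_a = info(.data$sample_a, "sample_type"),
      type_b = info(.data$sample_b, "sample_type")
    ) %>%
    filter((.data$type_a == "skin" & .data$type_b == "saliva") |
           (.data$type_a == "saliva" & .data$type_b == "skin")) %>%
    mutate(
      ind_a = info(.data$sample_a, "individual"),
      ind_b = info(.data$sample_b, "individual"),
      hh_a = info(.data$sample_a, "household"),
      hh_b = info(.data$sample_b, "household"),
      group = case_when(
        .data$ind_a == .data$ind_b ~ "within_individual",
        !is.na(.data$hh_a) & .data$hh_a == .data$hh_b ~ "within_household",
        TRUE ~ "between_household"
      )
    ) %>%
    select("sample_a", "sample_b", "group", "distance")

  groups <- split(df$distance, df$group)
  expected <- c("within_individual", "within_household", "between_household")
  present <- expected[expected %in% names(groups) &
                      vapply(expected, function(g) length(groups[[g]]) > 0,
                             logical(1))]
  kw_p <- NA_real_
  if (length(present) == length(expected)) {
    kw_p <- kruskal.test(df$distance, factor(df$group))$p.value
  } else {
    inform(paste0("group_distances: empty group(s), Kruskal-Wallis skipped (",
                  paste(setdiff(expected, present), collapse = ", "), ")"))
  }
  combos <- utils::combn(present, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(combos, function(cp) {
    p <- mwu_p(groups[[cp[1]]], groups[[cp[2]]])
    tibble(group_a = cp[1], group_b = cp[2], p_value = p)
  })
  if (nrow(pairwise) > 0) {
    pairwise$p_adjusted <- pmin(pairwise$p_value * nrow(pairwise), 1)
  }
  structure(list(groups = df, kw_p = kw_p, pairwise = pairwise),
            class = "group_comparison")
}

# Two-sided Mann-Whitney U p-value: exact for small tie-free samples,
# normal approximation with tie correction otherwise (stats::wilcox.test).
mwu_p <- function(x, y) {
  suppressWarnings(wilcox.test(x, y, exact = (length(x) <= 8 &&
                                              length(y) <= 8))$p.value)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n  Kruskal-Wallis p =", format(x$kw_p, digits = 4), "\n")
  print(x$pairwise)
  invisible(x)
}

#' Spearman correlation reported only when significant
#'
#' Rank correlation with average ranks for ties; the estimate is reported
#' only when its p-value clears `alpha`, otherwise it is suppressed (the
#' p-value is always returned). Constant input yields an undefined, hence
#' suppressed, correlation.
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @param alpha Significance level gating the report (default 0.05).
#' @return A one-row tibble: `estimate` (NA when suppressed), `p_value`,
#'   `reported`, `n`.
#' @export
spearman_gated <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) abort("spearman_gated: need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(estimate = NA_real_, p_value = NA_real_, reported = FALSE,
                  n = length(x)))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  reported <- ct$p.value < alpha
  tibble(estimate = if (reported) unname(ct$estimate) else NA_real_,
         p_value = ct$p.value, reported = reported, n = length(x))
}

#' Z-score standardize ASV abundances across samples
#'
#' Standardizes each ASV (each sequence) to mean 0, population-sd 1 across
#' samples, the transform used for abundance heatmaps.
#'
#' @param table An [asv_table()].
#' @return A tibble `sample_id`, `sequence`, `z`.
#' @export
zscore_table <- function(table) {
  m <- asv_matrix(table, asv_samples(table))
  z <- apply(m, 2, function(col) {
    s <- sqrt(mean((col - mean(col))^2))
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  tibble(sample_id = rep(rownames(m), times = ncol(m)),
         sequence = rep(colnames(m), each = nrow(m)),
         z = as.vector(z))
}

#' Binarize an ASV table to presence/absence
#'
#' Idempotent: counts become 1 (present) or are dropped (absent).
#'
#' @param table An [asv_table()].
#' @return An [asv_table()] with all counts equal to 1.
#' @export
binarize_table <- function(table) {
  out <- table
  out$count[out$count > 0] <- 1L
  drop_empty(asv_table(out))
}

#' Write / read a square distance matrix as TSV
#'
#' @param distances A [pairwise_distances()] tibble.
#' @param path File path.
#' @return `read_distance_matrix` returns the square matrix.
#' @export
write_distance_matrix <- function(distances, path) {
  m <- dist_matrix(distances)
  df <- cbind(tibble(sample_id = rownames(m)), as_tibble(m))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}
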