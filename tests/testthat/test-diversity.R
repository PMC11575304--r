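test_that("Bray-Curtis follows the count-overlap formula and its bounds", {
  expect_equal(bray_curtis(c(3, 2, 1), c(3, 2, 1)), 0)
  expect_equal(bray_curtis(c(5, 0), c(0, 7)), 1)
  expect_equal(bray_curtis(c(2, 1, 0), c(1, 0, 1)), 0.6)
  expect_warning(d <- bray_curtis(c(0, 0), c(0, 0)), "empty")
  expect_equal(d, 1)
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "length")

  set.seed(9)
  for (i in 1:50) {
    u <- rpois(6, 3); v <- rpois(6, 3)
    if (sum(u) + sum(v) == 0) next
    d <- bray_curtis(u, v)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(bray_curtis(v, u), d)            # symmetry
    expect_equal(bray_curtis(2 * u, 2 * v), d)    # joint scaling
    perm <- sample(6)
    expect_equal(bray_curtis(u[perm], v[perm]), d) # column permutation
  }
})

test_that("Bray-Curtis matches an independent implementation on random pairs", {
  set.seed(13)
  for (i in 1:200) {
    u <- rpois(8, 2); v <- rpois(8, 2)
    if (sum(u) == 0 || sum(v) == 0) next
    expect_equal(bray_curtis(u, v), bc_oracle(u, v))
    expect_equal(bray_curtis(u, v),
                 as.numeric(vegan::vegdist(rbind(u, v), method = "bray")))
  }
})

test_that("alpha diversity indices evaluate directly", {
  expect_equal(observed_otus(c(5, 0, 2)), 2)
  expect_equal(observed_otus(c(0, 0)), 0)
  expect_equal(observed_otus(rep(1, 4)), 4)

  expect_equal(shannon(rep(10, 4)), 2)
  expect_equal(shannon(c(0, 42, 0)), 0)
  p <- c(3, 1) / 4
  expect_equal(shannon(c(3, 1)), -sum(p * log2(p)))
  expect_equal(shannon(c(3, 1)), 0.8112781, tolerance = 1e-7)
  expect_error(shannon(c(0, 0)), "no counts")
})

test_that("pairwise distances are symmetric with empty samples at 1", {
  a <- strrep("A", 20); b <- strrep("C", 20)
  tab <- asv_table(tibble::tibble(
    sample_id = c("s1", "s1", "s2", "s2"),
    sequence = c(a, b, a, b), count = c(4L, 1L, 4L, 1L)))
  attr(tab, "samples") <- c("s1", "s2", "s3")  # s3 lost all reads
  expect_warning(d <- pairwise_distances(tab), "no counts")
  m <- dist_matrix(d)
  expect_equal(unname(diag(m)), c(0, 0, 0))
  expect_equal(m, t(m))
  expect_equal(m["s1", "s2"], 0)
  expect_equal(m["s1", "s3"], 1)

  f <- withr_tempfile()
  write_distance_matrix(d, f)
  expect_equal(read_distance_matrix(f), m)
})

test_that("identity calls use the strict below-threshold rule", {
  expect_equal(identity_call(0.19), "same_source")
  expect_equal(identity_call(0.86), "different_source")
  expect_equal(identity_call(0.8), "different_source")  # boundary exclusive

  a <- strrep("A", 20); b <- strrep("C", 20)
  tab <- asv_table(tibble::tibble(
    sample_id = c("q", "q", "r", "r"),
    sequence = c(a, b, a, b), count = c(9L, 1L, 8L, 2L)))
  call <- call_identity(pairwise_distances(tab), "q", "r", locus = "CRISPR3")
  expect_equal(call$call, "same_source")
  expect_error(call_identity(pairwise_distances(tab), "q", "zzz"),
               "no distance")
})

test_that("ROC analysis sweeps thresholds and matches pair-counting AUC", {
  perfect <- roc_curve(c(0.1, 0.2, 0.9, 1.0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$best_sensitivity, 1)
  expect_equal(perfect$best_specificity, 1)
  expect_gt(perfect$best_threshold, 0.2)
  expect_lte(perfect$best_threshold, 0.9)

  same <- c(0.2, 0.5, 0.8)
  chance <- roc_curve(c(same, same), rep(c(TRUE, FALSE), each = 3))
  expect_equal(chance$auc, 0.5)

  expect_error(roc_curve(c(0.1, 0.2), c(TRUE, TRUE)), "both classes")

  set.seed(17)
  for (i in 1:60) {
    n_pos <- sample(2:8, 1); n_neg <- sample(2:8, 1)
    d <- sample(seq(0, 1, by = 0.1), n_pos + n_neg, replace = TRUE)
    lab <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
    expect_equal(roc_curve(d, lab)$auc,
                 auc_oracle(d[lab], d[!lab]), info = paste("case", i))
  }
})

test_that("group comparisons partition pairs and adjust p-values", {
  meta <- tibble::tibble(
    sample_id = c("sk1", "sa1", "sa2", "sa3"),
    individual = c("I1", "I1", "I2", "I3"),
    household = c("H1", "H1", "H1", "H2"),
    sample_type = c("skin", "saliva", "saliva", "saliva")
  )
  dist_tbl <- structure(
    tibble::tibble(sample_a = c("sk1", "sk1", "sk1", "sa1", "sa1", "sa2"),
                   sample_b = c("sa1", "sa2", "sa3", "sa2", "sa3", "sa3"),
                   distance = c(0.2, 0.5, 0.95, 0.4, 0.9, 0.85)),
    samples = c("sk1", "sa1", "sa2", "sa3"))
  g <- group_distances(dist_tbl, meta)
  expect_equal(nrow(g$groups), 3)  # only skin-vs-saliva pairs survive
  expect_equal(sort(g$groups$group),
               sort(c("within_individual", "within_household",
                      "between_household")))
  expect_equal(g$pairwise$p_adjusted,
               pmin(g$pairwise$p_value * nrow(g$pairwise), 1))

  # two clearly separated groups: exact two-sided MWU p = 2 / choose(4, 2)
  expect_equal(metacrispr:::mwu_p(c(0.1, 0.2), c(0.9, 1.0)), 1 / 3,
               tolerance = 1e-9)
})

test_that("gated Spearman reports only significant correlations", {
  up <- spearman_gated(1:10, (1:10)^2)
  expect_equal(up$estimate, 1)
  expect_true(up$reported)
  down <- spearman_gated(1:10, -(1:10))
  expect_equal(down$estimate, -1)

  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  expect_equal(unname(cor(x, y, method = "spearman")), 0.8)  # rank formula
  g <- spearman_gated(x, y)
  expect_equal(g$p_value,
               suppressWarnings(cor.test(x, y, method = "spearman")$p.value))
  if (g$p_value >= 0.05) expect_false(g$reported)

  flat <- spearman_gated(rep(1, 5), 1:5)
  expect_false(flat$reported)
  expect_true(is.na(flat$estimate))
  expect_error(spearman_gated(1:2, 1:2), "at least 3")
})

test_that("z-scoring and binarization behave as table transforms", {
  a <- strrep("A", 20); b <- strrep("C", 20)
  tab <- asv_table(tibble::tibble(
    sample_id = rep(c("s1", "s2", "s3"), each = 2),
    sequence = rep(c(a, b), 3),
    count = c(5L, 1L, 9L, 1L, 1L, 1L)))
  z <- zscore_table(tab)
  for (s in c(a, b)) {
    zs <- z$z[z$sequence == s]
    expect_equal(mean(zs), 0)
    expect_equal(sqrt(mean(zs^2)), if (s == a) 1 else 0)  # population sd
  }
  bin <- binarize_table(tab)
  expect_true(all(bin$count == 1))
  expect_equal(binarize_table(bin), bin)
})
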