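## sparse fixture with controlled per-cell detected-gene and mito counts
cells_with <- function(n_genes, detected, mito_counts) {
  n_cells <- length(detected)
  gene_ids <- c("mt-1", paste0("g", seq_len(n_genes - 1)))
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (c in seq_len(n_cells)) {
    rows <- 1 + seq_len(detected[c])       # skip the mito gene
    i <- c(i, rows); j <- c(j, rep(c, length(rows)))
    x <- c(x, rep(1, length(rows)))
    if (mito_counts[c] > 0) {
      i <- c(i, 1L); j <- c(j, c); x <- c(x, mito_counts[c])
    }
  }
  m <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n_genes, n_cells))
  rownames(m) <- gene_ids
  colnames(m) <- paste0("bc", seq_len(n_cells))
  labeled_counts(m, data.frame(group = rep("A", n_cells)))
}

test_that("droplet filtering applies the three strict inequalities at their defaults", {
  ## detected (non-mito): 1600 kept; exactly 1500 removed; 11000 removed;
  ## 1600 with 20% mito removed
  lc <- cells_with(12000,
                   detected = c(1599, 1500, 11000, 1599),
                   mito_counts = c(100, 0, 0, 400))
  res <- filter_droplets(lc)
  fl <- res$report$flags
  expect_equal(fl$genes_detected, c(1600L, 1500L, 11000L, 1600L))
  expect_equal(fl$mito_fraction[1], 100 / 1699, tolerance = 1e-12)
  expect_equal(fl$mito_fraction[4], 400 / 1999, tolerance = 1e-12)
  expect_equal(fl$retained, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$report$n_retained, 1L)
  expect_equal(colnames(res$counts$counts), "bc1")
})

test_that("per-predicate removal counts match a hand count on a 10-cell fixture", {
  ## 7 clean cells, one below min genes, one above max, one mito-rich
  lc <- cells_with(100,
                   detected = c(rep(20, 7), 3, 60, 20),
                   mito_counts = c(rep(0, 7), 0, 0, 25))
  p <- qc_params(min_genes_exclusive = 5, max_genes_exclusive = 50,
                 max_mito_fraction = 0.15)
  res <- filter_droplets(lc, p)
  fl <- res$report$flags
  expect_equal(res$report$n_retained, 7L)
  expect_equal(sum(!fl$pass_min_genes), 1L)
  expect_equal(sum(!fl$pass_max_genes), 1L)
  expect_equal(sum(!fl$pass_mito), 1L)
  expect_equal(res$report$n_input,
               res$report$n_retained + res$report$n_removed)
  ## flags reproduce the retention decision exactly
  expect_equal(fl$retained,
               fl$pass_min_genes & fl$pass_max_genes & fl$pass_mito)
})

test_that("predicates compose: joint filtering equals sequential, any order", {
  lc <- cells_with(100,
                   detected = c(rep(20, 5), 3, 60, 20, 4, 55),
                   mito_counts = c(0, 0, 30, 0, 0, 0, 0, 25, 0, 0))
  joint <- qc_params(min_genes_exclusive = 5, max_genes_exclusive = 50,
                     max_mito_fraction = 0.15)
  only_min <- qc_params(min_genes_exclusive = 5, max_genes_exclusive = 1e9,
                        max_mito_fraction = 1)
  only_max <- qc_params(min_genes_exclusive = 1e-6,
                        max_genes_exclusive = 50, max_mito_fraction = 1)
  only_mito <- qc_params(min_genes_exclusive = 1e-6,
                         max_genes_exclusive = 1e9,
                         max_mito_fraction = 0.15)
  ref <- sort(filter_droplets(lc, joint)$counts$cell_info$barcode)
  for (ord in list(list(only_min, only_max, only_mito),
                   list(only_mito, only_min, only_max),
                   list(only_max, only_mito, only_min))) {
    out <- lc
    for (p in ord) out <- filter_droplets(out, p)$counts
    expect_equal(sort(out$cell_info$barcode), ref)
  }
})

test_that("missing mito annotation passes vacuously with a recorded warning", {
  m <- matrix(c(5, 1, 0, 2), 2, 2)
  lc <- make_lc(m, c("A", "A"))
  expect_false(any(lc$gene_info$mito))
  res <- filter_droplets(lc, qc_params(min_genes_exclusive = 0.5,
                                       max_genes_exclusive = 10))
  expect_match(res$report$warnings, "vacuously")
  expect_true(all(res$report$flags$pass_mito))
})

test_that("normalization removes depth and matches a hand-computed table", {
  m <- cbind(c(1, 2, 3), c(0, 4, 0), c(2, 2, 2))
  lc <- make_lc(m, c("A", "A", "A"))
  nm <- normalize_counts(lc)
  ## totals 6, 4, 6; median target 6; value = log1p(count * 6 / total)
  expected <- cbind(log1p(c(1, 2, 3)),
                    log1p(c(0, 4, 0) * 6 / 4),
                    log1p(c(2, 2, 2)))
  dimnames(expected) <- dimnames(nm$values)
  expect_equal(as.matrix(nm$values), expected, tolerance = 1e-12)

  ## all-zero gene stays zero
  m2 <- rbind(m, 0)
  nm2 <- normalize_counts(make_lc(m2, c("A", "A", "A")))
  expect_true(all(as.matrix(nm2$values)[4, ] == 0))

  ## two cells identical up to a depth factor normalize identically
  m3 <- cbind(c(1, 2, 3), c(3, 6, 9), c(5, 0, 1))
  nm3 <- normalize_counts(make_lc(m3, c("A", "A", "A")))
  v <- as.matrix(nm3$values)
  expect_equal(v[, 1], v[, 2], tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(normalize_counts(lc, method = "sct"), "arg")
})

test_that("neuron selection is strict at the threshold", {
  ## equal totals so normalized marker expression is log1p(count)
  m <- rbind(Stmn2 = c(2, 3, 9), filler = c(9, 8, 2))
  lc <- make_lc(m, rep("A", 3), gene_ids = c("Stmn2", "filler"))
  nm <- normalize_counts(lc)
  p <- qc_params(neuron_markers = "Stmn2", neuron_threshold = log1p(3))
  res <- select_neurons(nm, p)
  expect_equal(res$counts$cell_info$barcode, "bc3")
  expect_equal(res$report$flags$neuron_score, log1p(c(2, 3, 9)),
               tolerance = 1e-12)

  ## all cells below the threshold -> empty retention
  res0 <- select_neurons(nm, qc_params(neuron_markers = "Stmn2",
                                       neuron_threshold = 100))
  expect_equal(res0$report$n_retained, 0L)
  expect_equal(ncol(res0$counts$counts), 0L)

  expect_error(select_neurons(nm, qc_params(neuron_markers = "Nefl")),
               "markers")
})

test_that("the auto threshold separates planted neurons from empty contaminants", {
  cm <- generate_counts(qc_fixture_config(seed = 12))
  nm <- normalize_counts(cm)
  res <- select_neurons(nm, qc_fixture_params(neuron_threshold = "auto"))
  truth <- cm$cell_info$kind != "lowquality"  # doublets do contain a neuron
  agreement <- mean(res$report$flags$retained == truth)
  expect_gte(agreement, 0.99)
  expect_true(res$report$thresholds$auto)
  expect_true(is.finite(res$report$thresholds$neuron_threshold))
})

test_that("glial-doublet exclusion removes planted doublets and nothing else", {
  cm <- generate_counts(qc_fixture_config(seed = 13))
  keep <- cm$cell_info$kind != "lowquality"
  nm <- normalize_counts(subset_cells(cm, keep))
  res <- exclude_glial_doublets(nm, qc_fixture_params())
  truth <- nm$cell_info$kind == "cell"
  expect_equal(res$report$flags$retained, truth)

  ## infinite threshold is the identity filter
  resI <- exclude_glial_doublets(nm, qc_fixture_params(glial_threshold = Inf))
  expect_equal(resI$report$n_removed, 0L)

  ## zero glial expression everywhere -> nothing removed under auto
  m <- rbind(Plp1 = c(0, 0, 0), Stmn2 = c(5, 6, 7))
  lc0 <- make_lc(m, rep("A", 3), gene_ids = c("Plp1", "Stmn2"))
  res0 <- exclude_glial_doublets(normalize_counts(lc0),
                                 qc_params(glial_threshold = "auto"))
  expect_equal(res0$report$n_removed, 0L)
})

test_that("the bimodal threshold is invariant to order and duplication", {
  set.seed(17)
  x <- c(rnorm(300, 0.2, 0.1), rnorm(200, 3, 0.4))
  t0 <- otsu_threshold(x)
  expect_gt(t0, 0.6); expect_lt(t0, 2.5)
  expect_equal(otsu_threshold(sample(x)), t0, tolerance = 1e-12)
  expect_equal(otsu_threshold(rep(x, 3)), t0, tolerance = 1e-12)
})

test_that("the full QC chain retains exactly the planted clean neurons", {
  cm <- generate_counts(qc_fixture_config(seed = 21))
  res <- run_qc(cm, qc_fixture_params())
  truth <- sort(cm$cell_info$barcode[cm$cell_info$kind == "cell"])
  expect_equal(sort(res$counts$cell_info$barcode), truth)
  expect_equal(res$reports$filter_droplets$n_input, ncol(cm$counts))
  ## stage bookkeeping chains: output of one stage is input of the next
  expect_equal(res$reports$select_neurons$n_input,
               res$reports$filter_droplets$n_retained)
  expect_equal(res$reports$exclude_glial_doublets$n_input,
               res$reports$select_neurons$n_retained)
})
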