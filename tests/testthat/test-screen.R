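test_that("bipartition enumeration is complete, canonical and duplicate-free", {
  expect_error(enumerate_bipartitions("A"), "at least 2")
  expect_error(enumerate_bipartitions(c("A", "A")), "at least 2")

  two <- enumerate_bipartitions(c("A", "B"))
  expect_length(two, 2)
  expect_setequal(vapply(two, format, character(1)), c("A | B", "B | A"))

  four <- enumerate_bipartitions(letters[1:4])
  expect_length(four, 14)
  keys <- vapply(four, format, character(1))
  expect_false(anyDuplicated(keys) > 0)
  ## every split's complement is also enumerated
  comp <- vapply(four, function(b)
    format(bipartition(b$subset_2, letters[1:4])), character(1))
  expect_true(all(comp %in% keys))

  ## count identity over a range of group numbers
  for (g in 2:10) {
    expect_length(enumerate_bipartitions(paste0("g", 1:g)), 2^g - 2)
  }

  ## canonical encoding: mask bit i-1 set <=> group i in subset_1
  sp <- enumerate_bipartitions(groups8)
  for (k in c(1L, 5L, 100L, 254L)) {
    expect_identical(sp[[k]]$subset_1, mask_members(k, groups8))
    expect_identical(attr(sp[[k]], "mask"), k)
  }
})

test_that("binarization tabulates expressing cells per group exactly", {
  m <- rbind(c(0, 1, 2, 0), c(0, 0, 0, 0))
  lc <- make_lc(m, rep("A", 4))
  tab <- binarize_and_tabulate(lc)
  expect_equal(unname(tab$num_expr["gene1", "A"]), 2)
  expect_equal(unname(tab$prop["gene1", "A"]), 0.5)
  expect_equal(unname(tab$prop["gene2", "A"]), 0)
  expect_equal(unname(tab$ncells[["A"]]), 4L)

  ## random fixture vs per-cell brute force
  set.seed(11)
  n_cells <- 50
  grp <- sample(c("A", "B", "C"), n_cells, replace = TRUE)
  m <- matrix(rpois(20 * n_cells, 0.7), nrow = 20)
  lc <- make_lc(m, grp)
  tab <- binarize_and_tabulate(lc)
  for (g in unique(grp)) {
    for (r in 1:20) {
      brute <- sum(m[r, grp == g] >= 1)
      expect_equal(unname(tab$num_expr[paste0("gene", r), g]), brute)
      expect_equal(unname(tab$prop[paste0("gene", r), g]),
                   brute / sum(grp == g))
    }
  }
  ## identity prop * ncells = num_expr
  expect_equal(sweep(tab$prop, 2, tab$ncells, "*"), tab$num_expr)
})

test_that("unlabeled cells are reported by barcode", {
  lc <- make_lc(matrix(1, 2, 3), c("A", NA, "A"))
  expect_error(binarize_and_tabulate(lc), "bc2")
})

test_that("the split score matches the closed form and its penalty rule", {
  sp <- bipartition("A", c("A", "B"))
  ## hand evaluation: log2(-1 + 0.9 + 1) - log2(0.02 + 0) = log2(0.9) - log2(0.02)
  expect_equal(score_gene_split(c(A = 1, B = 0), sp), 5.491853096, tolerance = 1e-9)

  ## subset_1 below / at the tolerated floor forces the minimal score
  expect_identical(score_gene_split(c(A = 0.05, B = 0), sp), -Inf)
  expect_identical(score_gene_split(c(A = 0.1, B = 0), sp), -Inf)
  expect_true(is.finite(score_gene_split(c(A = 0.1001, B = 0), sp)))

  ## multi-group split against an independently coded evaluation
  g <- c("A", "B", "C", "D", "E")
  sp2 <- bipartition(c("A", "C"), g)
  p <- c(A = 0.9, B = 0.3, C = 0.55, D = 0.0, E = 0.12)
  expected <- (log2(-1 + 0.9 + 0.9) + log2(-1 + 0.9 + 0.55)) / 2 -
    (log2(0.02 + 0.3) + log2(0.02 + 0.0) + log2(0.02 + 0.12)) / 3
  expect_equal(score_gene_split(p, sp2), expected, tolerance = 1e-12)

  ## non-default parameters shift the penalty boundary with them
  prm <- score_params(eps_pos = 0.7, eps_nega = 0.1)
  expect_identical(score_gene_split(c(A = 0.3, B = 0), sp, prm), -Inf)
  expect_true(is.finite(score_gene_split(c(A = 0.31, B = 0), sp, prm)))

  expect_error(score_gene_split(c(A = 1), sp), "missing")
})

test_that("score parameter invariants are enforced", {
  expect_error(score_params(eps_nega = 0), "out of range")
  expect_error(score_params(eps_pos = 0), "out of range")
  expect_error(score_params(eps_pos = 1.2), "out of range")
  expect_silent(score_params(eps_pos = 1))
})

test_that("screen_all scores every (gene, split) and matches elementwise scoring", {
  set.seed(21)
  prop <- matrix(runif(3 * 8), nrow = 3, dimnames = list(paste0("g", 1:3),
                                                         groups8))
  tab <- proportion_table(prop, 100)
  sc <- screen_all(tab)
  expect_equal(dim(sc$scores), c(3L, 254L))

  for (gi in 1:3) {
    for (si in c(1, 37, 128, 254)) {
      expect_equal(sc$scores[gi, si],
                   score_gene_split(prop[gi, ], sc$splits[[si]]),
                   tolerance = 1e-12)
    }
  }

  ## empty gene set
  empty <- proportion_table(matrix(numeric(0), nrow = 0, ncol = 8,
                                   dimnames = list(NULL, groups8)), 10)
  expect_equal(nrow(screen_all(empty)$scores), 0L)
})

test_that("top_genes ranks, deduplicates and drops minimal scores", {
  ## gene A: 5.0 on one split, 4.0 on another -> appears once with the best
  prop <- rbind(A = c(g1 = 1, g2 = 1, g3 = 0),
                B = c(g1 = 1, g2 = 0, g3 = 0))
  tab <- proportion_table(prop, 50)
  sc <- screen_all(tab)
  ranked <- top_genes(sc, screen_config(top_k = 100, dedup = TRUE))
  expect_equal(anyDuplicated(ranked$gene), 0L)
  bestA <- max(sc$scores["A", ])
  expect_equal(ranked$score[ranked$gene == "A"], bestA)

  ## without dedup the same gene may appear several times
  ranked_all <- top_genes(sc, screen_config(top_k = 1000, dedup = FALSE))
  expect_gt(sum(ranked_all$gene == "A"), 1)

  ## nothing discriminates -> empty ranking
  dead <- proportion_table(matrix(0.05, 2, 3,
                                  dimnames = list(c("x", "y"),
                                                  c("g1", "g2", "g3"))), 50)
  expect_equal(nrow(top_genes(screen_all(dead))), 0L)

  ## brute-force oracle: sort all finite scores, keep best per gene, truncate
  set.seed(31)
  prop <- matrix(runif(100 * 5), nrow = 100,
                 dimnames = list(sprintf("g%03d", 1:100), paste0("c", 1:5)))
  tab <- proportion_table(prop, 200)
  sc <- screen_all(tab)
  ranked <- top_genes(sc, screen_config(top_k = 40))
  oracle_best <- apply(sc$scores, 1, max)
  oracle_best <- sort(oracle_best[is.finite(oracle_best)], decreasing = TRUE)
  expect_equal(ranked$score, unname(oracle_best[seq_len(nrow(ranked))]),
               tolerance = 1e-12)
  expect_equal(ranked$gene, names(oracle_best)[seq_len(nrow(ranked))])
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
})

test_that("scores.tsv serializes ranked output", {
  prop <- rbind(A = c(g1 = 1, g2 = 0))
  ranked <- top_genes(screen_all(proportion_table(prop, 10)))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_scores_tsv(ranked, path)
  back <- read.delim(path)
  expect_equal(back$gene, ranked$gene)
  expect_equal(back$score, ranked$score, tolerance = 1e-9)
})
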