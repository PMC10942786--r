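#' Score parameters for the bipartition screen
#'
#' `eps_pos` sets the hard floor on the expressing-cell fraction tolerated in
#' `subset_1`: any group whose fraction satisfies `-1 + eps_pos + prop <= 0`
#' (i.e. `prop <= 1 - eps_pos`, 10% at the default) forces the minimal
#' possible score for that split. `eps_nega` is the penalty floor for
#' `subset_2` expression; it must stay positive so that the penalty term is
#' finite at zero expression.
#'
#' @param eps_pos scalar in (0, 1], default 0.9.
#' @param eps_nega positive scalar, default 0.02.
#' @return a `score_params` list.
#' @export
score_params <- function(eps_pos = 0.9, eps_nega = 0.02) {
  stop_if_not_scalar_number(eps_pos, "eps_pos", lower = 0, upper = 1,
                            strict_lower = TRUE)
  stop_if_not_scalar_number(eps_nega, "eps_nega", lower = 0,
                            strict_lower = TRUE)
  structure(list(eps_pos = eps_pos, eps_nega = eps_nega),
            class = "score_params")
}

#' Screen output configuration
#'
#' @param top_k number of genes to keep after ranking (default 100).
#' @param dedup keep only the top-scoring split for genes that appear more
#'   than once in the ranking? Default `TRUE`.
#' @return a `screen_config` list.
#' @export
screen_config <- function(top_k = 100, dedup = TRUE) {
  stop_if_not_scalar_number(top_k, "top_k", lower = 1)
  structure(list(top_k = as.integer(top_k), dedup = isTRUE(dedup)),
            class = "screen_config")
}

#' Ordered bipartition of cell groups
#'
#' An ordered pair of disjoint, jointly exhaustive, nonempty group subsets.
#' A split and its complement are distinct objects: the score is asymmetric
#' (expression is rewarded in `subset_1` and penalized in `subset_2`).
#'
#' @param subset_1 character vector of group names on the rewarded side.
#' @param groups full ordered vector of group names; `subset_2` is the
#'   complement of `subset_1` within it.
#' @return a `bipartition` list with `subset_1`, `subset_2`, `n_S1`, `n_S2`.
#' @export
bipartition <- function(subset_1, groups) {
  groups <- as.character(groups)
  if (anyDuplicated(groups)) stop("group names must be unique", call. = FALSE)
  subset_1 <- as.character(subset_1)
  if (!all(subset_1 %in% groups)) {
    stop(sprintf("unknown group(s): %s",
                 paste(setdiff(subset_1, groups), collapse = ", ")),
         call. = FALSE)
  }
  ## canonical member order = input group order
  subset_1 <- groups[groups %in% subset_1]
  subset_2 <- setdiff(groups, subset_1)
  if (length(subset_1) == 0L || length(subset_2) == 0L) {
    stop("both sides of a bipartition must be nonempty", call. = FALSE)
  }
  structure(list(subset_1 = subset_1, subset_2 = subset_2,
                 n_S1 = length(subset_1), n_S2 = length(subset_2)),
            class = "bipartition")
}

#' @export
format.bipartition <- function(x, ...) {
  paste0(paste(x$subset_1, collapse = ";"), " | ",
         paste(x$subset_2, collapse = ";"))
}

#' @export
print.bipartition <- function(x, ...) {
  cat("<bipartition>", format(x), "\n")
  invisible(x)
}

#' Enumerate all ordered bipartitions of a set of groups
#'
#' Returns every ordered split of the groups into two nonempty complementary
#' subsets: `2^G - 2` splits for `G` groups (254 for the eight autonomic
#' groups), excluding only the two trivial all-vs-none splits. Both
#' orientations of each unordered split are present. The enumeration order is
#' canonical: split `k` (k = 1 .. 2^G-2) puts group `i` into `subset_1` iff
#' bit `i-1` of `k` is set, with bits indexed along the input group order.
#'
#' @param groups character vector of at least two distinct group names.
#' @return list of [bipartition] objects; each carries its encoding in
#'   attribute `"mask"`.
#' @export
#' @examples
#' length(enumerate_bipartitions(letters[1:8]))  # 254
enumerate_bipartitions <- function(groups) {
  groups <- as.character(groups)
  g <- length(groups)
  if (g < 2L || anyDuplicated(groups)) {
    stop("need at least 2 distinct groups", call. = FALSE)
  }
  if (g > 24L) stop("too many groups to enumerate (> 24)", call. = FALSE)
  masks <- seq_len(2L^g - 2L)
  lapply(masks, function(k) {
    members <- groups[bitwAnd(bitwShiftR(k, 0:(g - 1L)), 1L) == 1L]
    bp <- bipartition(members, groups)
    attr(bp, "mask") <- k
    bp
  })
}

#' Tabulate per-group expressing-cell proportions
#'
#' Binarizes the counts at one read (a cell "expresses" a gene when its count
#' is >= 1) and tabulates, for every gene and group, the number and fraction
#' of expressing cells.
#'
#' @param cm a [labeled_counts] object; every cell must carry a group label.
#' @return a `proportion_table`: list with `groups` (ordered identifiers),
#'   `ncells` (named per-group cell counts), `num_expr` and `prop`
#'   (genes x groups matrices).
#' @export
binarize_and_tabulate <- function(cm) {
  stopifnot(inherits(cm, "labeled_counts"))
  grp <- cm$cell_info$group
  bad <- is.na(grp) | grp == ""
  if (any(bad)) {
    stop(sprintf("unlabeled cells: %s",
                 paste(head(cm$cell_info$barcode[bad], 5), collapse = ", ")),
         call. = FALSE)
  }
  groups <- unique(grp)
  ## binarize: >= 1 read
  bin <- cm$counts
  bin@x <- rep(1, length(bin@x))
  ## genes x groups incidence via sparse group indicator
  ind <- sparseMatrix(i = seq_along(grp), j = match(grp, groups), x = 1,
                      dims = c(length(grp), length(groups)))
  num_expr <- as.matrix(bin %*% ind)
  dimnames(num_expr) <- list(rownames(cm$counts), groups)
  ncells <- as.integer(table(factor(grp, levels = groups)))
  names(ncells) <- groups
  prop <- sweep(num_expr, 2, ncells, "/")
  structure(list(groups = groups, ncells = ncells,
                 num_expr = num_expr, prop = prop),
            class = "proportion_table")
}

#' Build a proportion table directly from proportions
#'
#' Convenience constructor used for property tests and examples when the
#' per-group proportions are given rather than derived from counts.
#'
#' @param prop genes x groups matrix of expressing-cell fractions in `[0, 1]`.
#' @param ncells per-group cell counts; counts of expressing cells are
#'   reconstructed as `round(prop * ncells)`.
#' @return a `proportion_table`.
#' @export
proportion_table <- function(prop, ncells) {
  prop <- as.matrix(prop)
  if (is.null(colnames(prop))) {
    colnames(prop) <- paste0("g", seq_len(ncol(prop)))
  }
  if (is.null(rownames(prop)) && nrow(prop) > 0) {
    rownames(prop) <- paste0("gene", seq_len(nrow(prop)))
  }
  if (any(prop < 0 | prop > 1)) stop("proportions must lie in [0, 1]",
                                     call. = FALSE)
  if (length(ncells) == 1L) ncells <- rep(ncells, ncol(prop))
  ncells <- setNames(as.integer(ncells), colnames(prop))
  if (any(ncells < 1L)) stop("ncells must be >= 1", call. = FALSE)
  structure(list(groups = colnames(prop), ncells = ncells,
                 num_expr = round(sweep(prop, 2, ncells, "*")), prop = prop),
            class = "proportion_table")
}

#' Score one gene against one bipartition
#'
#' The discrimination score for a gene with per-group expressing fractions
#' `p_i` on a split (S1, S2) is
#' \deqn{\sum_{i \in S1} \frac{1}{n_{S1}} \log_2(-1 + eps_{pos} + p_i)
#'       - \sum_{j \in S2} \frac{1}{n_{S2}} \log_2(eps_{nega} + p_j)}
#' Each ganglion contributes with equal weight irrespective of its size; a
#' single `subset_1` group with `-1 + eps_pos + p <= 0` (a fraction at or
#' below 10% under the defaults) makes its log term non-finite and the gene
#' receives the minimal possible score, `-Inf`, for that split.
#'
#' @param props named per-group expressing fractions for one gene, covering
#'   at least the groups of `split`.
#' @param split a [bipartition].
#' @param params a [score_params] object.
#' @return a single extended-real score (`-Inf` permitted).
#' @export
#' @examples
#' sp <- bipartition("A", c("A", "B"))
#' score_gene_split(c(A = 1, B = 0), sp)  # log2(0.9) - log2(0.02)
score_gene_split <- function(props, split, params = score_params()) {
  stopifnot(inherits(split, "bipartition"))
  need <- c(split$subset_1, split$subset_2)
  if (!all(need %in% names(props))) {
    stop(sprintf("proportions missing for group(s): %s",
                 paste(setdiff(need, names(props)), collapse = ", ")),
         call. = FALSE)
  }
  p1 <- props[split$subset_1]
  p2 <- props[split$subset_2]
  pos <- log2_floor(p1 + params$eps_pos - 1)
  if (any(!is.finite(pos))) return(-Inf)
  sum(pos) / split$n_S1 - sum(log2(p2 + params$eps_nega)) / split$n_S2
}

#' Score every gene against every bipartition
#'
#' Vectorized screen: one score per (gene, split) for all `2^G - 2` ordered
#' bipartitions of the table's groups. Equivalent to calling
#' [score_gene_split()] elementwise.
#'
#' @param table a `proportion_table` from [binarize_and_tabulate()] or
#'   [proportion_table()].
#' @param params a [score_params] object.
#' @return a `screen_scores` list: `scores` (genes x splits matrix, `-Inf`
#'   permitted), `splits` (list of [bipartition]), `table`, `params`.
#' @export
screen_all <- function(table, params = score_params()) {
  stopifnot(inherits(table, "proportion_table"))
  splits <- enumerate_bipartitions(table$groups)
  prop <- table$prop
  g <- length(table$groups)
  n_splits <- length(splits)

  ## per-group terms, shared by all splits
  pos_term <- log2_floor(prop + params$eps_pos - 1)   # genes x groups
  neg_term <- log2(prop + params$eps_nega)
  infeasible_grp <- !is.finite(pos_term)              # prop <= 1 - eps_pos
  pos_finite <- pos_term
  pos_finite[infeasible_grp] <- 0

  ## membership weights: groups x splits
  masks <- vapply(splits, attr, integer(1), which = "mask")
  in_s1 <- vapply(masks, function(k) {
    bitwAnd(bitwShiftR(k, 0:(g - 1L)), 1L) == 1L
  }, logical(g))
  if (g == 1L) in_s1 <- matrix(in_s1, nrow = 1L)
  n_s1 <- colSums(in_s1)
  w1 <- sweep(in_s1 * 1, 2, n_s1, "/")
  w2 <- sweep((!in_s1) * 1, 2, g - n_s1, "/")

  scores <- pos_finite %*% w1 - neg_term %*% w2
  ## -Inf whenever any subset_1 group is at or below the tolerated floor
  bad <- (infeasible_grp %*% (in_s1 * 1)) > 0
  scores[bad] <- -Inf
  colnames(scores) <- vapply(splits, format, character(1))
  structure(list(scores = scores, splits = splits, table = table,
                 params = params),
            class = "screen_scores")
}

#' @export
print.screen_scores <- function(x, ...) {
  cat(sprintf("<screen_scores> %d genes x %d splits (%d groups)\n",
              nrow(x$scores), length(x$splits), length(x$table$groups)))
  invisible(x)
}

## Flatten a screen_scores object to one row per (gene, split).
flatten_scores <- function(sc) {
  n_genes <- nrow(sc$scores)
  n_splits <- length(sc$splits)
  masks <- vapply(sc$splits, attr, integer(1), which = "mask")
  data.frame(
    gene = rep(rownames(sc$scores), times = n_splits),
    split = rep(seq_len(n_splits), each = n_genes),
    mask = rep(masks, each = n_genes),
    score = as.vector(sc$scores),
    stringsAsFactors = FALSE
  )
}

#' Rank the screen and keep the top genes
#'
#' Sorts all (gene, split) scores in decreasing order, optionally keeps only
#' the top-scoring split per gene, and truncates to the `top_k` best. Entries
#' with the minimal score (`-Inf`) never rank above finite ones and are
#' dropped from the ranking: a gene that discriminates no split is not a top
#' gene. Ties are broken by the larger `subset_1`-vs-`subset_2` proportion
#' margin (min over `subset_1` minus max over `subset_2`), then by the
#' canonical split encoding, then by gene identifier.
#'
#' @param scores a `screen_scores` object from [screen_all()].
#' @param config a [screen_config] object.
#' @return data.frame with columns `gene`, `subset_1`, `subset_2`
#'   (semicolon-joined member lists), `score`, `rank`, plus the split index
#'   `split`.
#' @export
top_genes <- function(scores, config = screen_config()) {
  stopifnot(inherits(scores, "screen_scores"))
  flat <- flatten_scores(scores)
  flat <- flat[is.finite(flat$score), , drop = FALSE]
  if (nrow(flat) == 0L) {
    return(data.frame(gene = character(), subset_1 = character(),
                      subset_2 = character(), score = numeric(),
                      rank = integer(), split = integer(),
                      stringsAsFactors = FALSE))
  }
  ## tie-break margin: min subset_1 proportion - max subset_2 proportion
  prop <- scores$table$prop
  margin <- vapply(seq_len(nrow(flat)), function(r) {
    bp <- scores$splits[[flat$split[r]]]
    p <- prop[flat$gene[r], ]
    min(p[bp$subset_1]) - max(p[bp$subset_2])
  }, numeric(1))
  ord <- order(-flat$score, -margin, flat$mask, flat$gene)
  flat <- flat[ord, , drop = FALSE]
  if (config$dedup) {
    flat <- flat[!duplicated(flat$gene), , drop = FALSE]
  }
  flat <- head(flat, config$top_k)
  out <- data.frame(
    gene = flat$gene,
    subset_1 = vapply(scores$splits[flat$split], function(b)
      paste(b$subset_1, collapse = ";"), character(1)),
    subset_2 = vapply(scores$splits[flat$split], function(b)
      paste(b$subset_2, collapse = ";"), character(1)),
    score = flat$score,
    rank = seq_len(nrow(flat)),
    split = flat$split,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write a ranked screen table to TSV
#'
#' Serializes a [top_genes()] table; minimal scores would be written as the
#' string `-inf` (they do not occur in ranked output but may in the full
#' per-split matrix).
#'
#' @param ranked data.frame from [top_genes()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(ranked, path) {
  out <- ranked
  out$score <- ifelse(is.finite(out$score), format(out$score, digits = 10),
                      "-inf")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
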