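#' Group-to-role map for the autonomic pattern taxonomy
#'
#' Assigns each cell group a role — sympathetic ganglion, parasympathetic
#' ganglion, or pelvic cluster — and marks which pelvic clusters belong to
#' the cholinergic vs noradrenergic neurotransmitter phenotype. The default
#' reproduces the eight autonomic groups: stellate, coeliac and lumbar
#' (sympathetic), sphenopalatine (parasympathetic), and pelvic clusters
#' P1-P4 of which P1, P2, P4 are cholinergic and P3 noradrenergic.
#'
#' @param roles named character vector mapping every group to one of
#'   `"sympathetic"`, `"parasympathetic"`, `"pelvic_cluster"`.
#' @param cholinergic_pelvic,noradrenergic_pelvic disjoint subsets of the
#'   pelvic clusters.
#' @return a `group_role_map` list.
#' @export
group_role_map <- function(
    roles = c(sphenopalatine = "parasympathetic",
              stellate = "sympathetic",
              coeliac = "sympathetic",
              lumbar = "sympathetic",
              P1 = "pelvic_cluster", P2 = "pelvic_cluster",
              P3 = "pelvic_cluster", P4 = "pelvic_cluster"),
    cholinergic_pelvic = c("P1", "P2", "P4"),
    noradrenergic_pelvic = "P3") {
  ok <- c("sympathetic", "parasympathetic", "pelvic_cluster")
  if (is.null(names(roles)) || !all(roles %in% ok)) {
    stop("`roles` must be a named vector with values sympathetic, ",
         "parasympathetic or pelvic_cluster", call. = FALSE)
  }
  pelvic <- names(roles)[roles == "pelvic_cluster"]
  if (!all(cholinergic_pelvic %in% pelvic) ||
      !all(noradrenergic_pelvic %in% pelvic) ||
      length(intersect(cholinergic_pelvic, noradrenergic_pelvic)) > 0) {
    stop("cholinergic/noradrenergic sets must be disjoint subsets of the ",
         "pelvic clusters", call. = FALSE)
  }
  structure(list(roles = roles,
                 sympathetic = names(roles)[roles == "sympathetic"],
                 parasympathetic = names(roles)[roles == "parasympathetic"],
                 pelvic = pelvic,
                 cholinergic_pelvic = as.character(cholinergic_pelvic),
                 noradrenergic_pelvic = as.character(noradrenergic_pelvic)),
            class = "group_role_map")
}

## Fixed pattern -> consolidated category correspondence.
pattern_categories <- c(
  I = "sympathetic-and-pelvic",
  II = "parasympathetic-not-pelvic",
  III = "sympathetic-not-pelvic",
  IV = "parasympathetic-and-some-pelvic",
  V = "cholinergic",
  VI = "noradrenergic",
  VII = "pelvic-specific",
  other = "other"
)

#' Pattern levels in display order
#' @return character vector `I` ... `VII`, `other`.
#' @export
pattern_levels <- function() names(pattern_categories)

set_equal <- function(a, b) length(a) == length(b) && setequal(a, b)

#' Classify a bipartition into the expression-pattern taxonomy
#'
#' Maps the rewarded side (`subset_1`) of a split onto one of seven pattern
#' labels, or `"other"`:
#' \describe{
#'   \item{I}{all sympathetic ganglia plus pelvic clusters, no
#'     parasympathetic ("sympathetic-and-pelvic"). By default any nonempty
#'     pelvic subset qualifies; set `require_all_pelvic = TRUE` to demand the
#'     full pelvic complement.}
#'   \item{II}{exactly the parasympathetic ganglia
#'     ("parasympathetic-not-pelvic").}
#'   \item{III}{exactly the sympathetic ganglia ("sympathetic-not-pelvic").}
#'   \item{IV}{parasympathetic plus a nonempty pelvic subset different from
#'     the cholinergic complement ("parasympathetic-and-some-pelvic").}
#'   \item{V}{parasympathetic plus exactly the cholinergic pelvic clusters
#'     (the ChAT synexpression group).}
#'   \item{VI}{all sympathetic plus exactly the noradrenergic pelvic
#'     clusters (the Th synexpression group).}
#'   \item{VII}{a nonempty set of pelvic clusters by themselves, on either
#'     side of the split (expressed, or not expressed, exclusively in
#'     them).}
#' }
#' The more specific neurotransmitter patterns V and VI take precedence over
#' IV and I respectively, so every split receives exactly one label.
#' `"other"` collects the remaining splits (typically those that split the
#' sympathetic ganglia).
#'
#' @param split a [bipartition].
#' @param roles a [group_role_map] covering all groups of the split.
#' @param require_all_pelvic see pattern I above.
#' @return single character pattern label.
#' @export
#' @examples
#' groups <- c("sphenopalatine", "stellate", "coeliac", "lumbar",
#'             "P1", "P2", "P3", "P4")
#' classify_split(bipartition(c("stellate", "coeliac", "lumbar",
#'                              "P1", "P2", "P3", "P4"), groups),
#'                group_role_map())  # "I"
classify_split <- function(split, roles = group_role_map(),
                           require_all_pelvic = FALSE) {
  stopifnot(inherits(split, "bipartition"), inherits(roles, "group_role_map"))
  all_groups <- c(split$subset_1, split$subset_2)
  unknown <- setdiff(all_groups, names(roles$roles))
  if (length(unknown) > 0) {
    stop(sprintf("unknown group(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  s1 <- split$subset_1
  sym <- intersect(roles$sympathetic, all_groups)
  para <- intersect(roles$parasympathetic, all_groups)
  pelv <- intersect(roles$pelvic, all_groups)
  s1_sym <- intersect(s1, sym)
  s1_para <- intersect(s1, para)
  s1_pelv <- intersect(s1, pelv)

  has_all_sym <- set_equal(s1_sym, sym)
  has_all_para <- set_equal(s1_para, para)
  pelvic_only <- function(side) {
    length(side) > 0 && all(side %in% pelv)
  }

  ## neurotransmitter synexpression groups first: they are special cases of
  ## the broader I/IV shapes
  if (has_all_para && length(s1_sym) == 0 &&
      set_equal(s1_pelv, roles$cholinergic_pelvic)) {
    return("V")
  }
  if (has_all_sym && length(s1_para) == 0 &&
      set_equal(s1_pelv, roles$noradrenergic_pelvic)) {
    return("VI")
  }
  if (has_all_sym && length(s1_para) == 0 && length(s1_pelv) > 0 &&
      (!require_all_pelvic || set_equal(s1_pelv, pelv))) {
    return("I")
  }
  if (has_all_para && length(s1_sym) == 0 && length(s1_pelv) == 0) {
    return("II")
  }
  if (has_all_sym && length(s1_para) == 0 && length(s1_pelv) == 0) {
    return("III")
  }
  if (has_all_para && length(s1_sym) == 0 && length(s1_pelv) > 0) {
    return("IV")
  }
  if (pelvic_only(s1) || pelvic_only(split$subset_2)) {
    return("VII")
  }
  "other"
}

#' Assign patterns to a ranked gene table
#'
#' Applies [classify_split()] to the best split of every gene in a
#' [top_genes()] table.
#'
#' @param ranked data.frame from [top_genes()].
#' @param groups ordered group identifiers of the screen (to reconstruct
#'   each split).
#' @param roles a [group_role_map].
#' @param require_all_pelvic passed to [classify_split()].
#' @return `ranked` with added columns `pattern` and `category`.
#' @export
assign_patterns <- function(ranked, groups, roles = group_role_map(),
                            require_all_pelvic = FALSE) {
  pattern <- vapply(ranked$subset_1, function(s1) {
    classify_split(bipartition(strsplit(s1, ";", fixed = TRUE)[[1]], groups),
                   roles, require_all_pelvic)
  }, character(1), USE.NAMES = FALSE)
  ranked$pattern <- pattern
  ranked$category <- unname(pattern_categories[pattern])
  ranked
}

#' Tally pattern assignments by consolidated category
#'
#' Counts genes per pattern and per consolidated category, together with the
#' aggregate contrasts used to summarize the taxonomy: `I+II` (genes arguing
#' against a parasympathetic identity of the pelvic clusters), `III+IV`
#' (against a sympathetic identity), and `V+VI` (neurotransmitter-linked).
#'
#' @param assignments data.frame with a `pattern` column, e.g. from
#'   [assign_patterns()].
#' @return list with `by_pattern`, `by_category` (named integer vectors
#'   covering all levels) and `consolidated` (`against_parasympathetic`,
#'   `against_sympathetic`, `neurotransmitter`).
#' @export
tally_patterns <- function(assignments) {
  pat <- factor(assignments$pattern, levels = pattern_levels())
  by_pattern <- table(pat)
  by_category <- setNames(as.integer(by_pattern),
                          unname(pattern_categories[pattern_levels()]))
  n <- as.integer(by_pattern)
  names(n) <- pattern_levels()
  list(
    by_pattern = setNames(as.integer(by_pattern), pattern_levels()),
    by_category = by_category,
    consolidated = c(
      against_parasympathetic = unname(n["I"] + n["II"]),
      against_sympathetic = unname(n["III"] + n["IV"]),
      neurotransmitter = unname(n["V"] + n["VI"])
    ),
    total = nrow(assignments)
  )
}

#' Order genes for a pattern heatmap
#'
#' Heatmap convention: genes are grouped contiguously by pattern label in the
#' fixed order I..VII, other (not by score), and sorted by decreasing score
#' within each block.
#'
#' @param assignments data.frame with `gene`, `pattern` and `score` columns.
#' @return list with `ordering` (the reordered data.frame, plus a `block`
#'   column) and `blocks` (data.frame of per-pattern start/end row indices).
#' @export
order_for_heatmap <- function(assignments) {
  stopifnot(all(c("gene", "pattern", "score") %in% names(assignments)))
  rank_of <- match(assignments$pattern, pattern_levels())
  ord <- order(rank_of, -assignments$score, assignments$gene)
  out <- assignments[ord, , drop = FALSE]
  out$block <- out$pattern
  rownames(out) <- NULL
  idx <- which(!duplicated(out$pattern))
  blocks <- data.frame(
    pattern = out$pattern[idx],
    start = idx,
    end = c(idx[-1] - 1L, nrow(out)),
    stringsAsFactors = FALSE
  )
  list(ordering = out, blocks = blocks)
}
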