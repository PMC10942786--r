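#' Droplet quality-control parameters
#'
#' Defaults follow the screening workflow for autonomic ganglia: droplets
#' are kept when they express more than 1500 genes, fewer than 11,000 genes,
#' and have a mitochondrial fraction below 15% (all three inequalities
#' strict); neurons are cells whose mean normalized expression of the
#' pan-neuronal markers Stmn2, Stmn3, Gap43 and Tubb3 exceeds a threshold of
#' 3, and glial-containing doublets are removed with the markers Plp1,
#' Ttyh1, Fabp7, Cryab and Mal. The numeric neuron threshold is calibrated
#' to sctransform-normalized data; with other normalizations use
#' `"auto"`, which picks the threshold that best separates the bimodal
#' marker-score distribution (minimal within-class variance, Otsu's
#' criterion).
#'
#' @param min_genes_exclusive retain cells with more than this many detected
#'   genes (count >= 1).
#' @param max_genes_exclusive retain cells with fewer than this many
#'   detected genes.
#' @param max_mito_fraction retain cells with a mitochondrial fraction
#'   strictly below this (mitochondrial counts / total counts).
#' @param neuron_markers,glial_markers marker gene identifiers.
#' @param neuron_threshold,glial_threshold numeric cutoffs on the mean
#'   normalized marker expression, or `"auto"`.
#' @return a `qc_params` list.
#' @export
qc_params <- function(min_genes_exclusive = 1500,
                      max_genes_exclusive = 11000,
                      max_mito_fraction = 0.15,
                      neuron_markers = c("Stmn2", "Stmn3", "Gap43", "Tubb3"),
                      neuron_threshold = 3,
                      glial_markers = c("Plp1", "Ttyh1", "Fabp7", "Cryab",
                                        "Mal"),
                      glial_threshold = "auto") {
  stop_if_not_scalar_number(min_genes_exclusive, "min_genes_exclusive",
                            lower = 0, strict_lower = TRUE)
  stop_if_not_scalar_number(max_genes_exclusive, "max_genes_exclusive",
                            lower = min_genes_exclusive, strict_lower = TRUE)
  stop_if_not_scalar_number(max_mito_fraction, "max_mito_fraction",
                            lower = 0, upper = 1)
  check_thr <- function(x, name) {
    if (identical(x, "auto")) return(x)
    stop_if_not_scalar_number(x, name)
    x
  }
  structure(list(min_genes_exclusive = min_genes_exclusive,
                 max_genes_exclusive = max_genes_exclusive,
                 max_mito_fraction = max_mito_fraction,
                 neuron_markers = as.character(neuron_markers),
                 neuron_threshold = check_thr(neuron_threshold,
                                              "neuron_threshold"),
                 glial_markers = as.character(glial_markers),
                 glial_threshold = check_thr(glial_threshold,
                                             "glial_threshold")),
            class = "qc_params")
}

qc_report <- function(stage, flags, retained, thresholds = NULL,
                      warnings = character()) {
  n_in <- nrow(flags)
  structure(list(stage = stage,
                 n_input = n_in,
                 n_retained = sum(retained),
                 n_removed = n_in - sum(retained),
                 flags = flags,
                 thresholds = thresholds,
                 warnings = warnings),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report:%s> input %d, retained %d, removed %d\n",
              x$stage, x$n_input, x$n_retained, x$n_removed))
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Filter droplets on detected genes and mitochondrial fraction
#'
#' Retains droplets that detect strictly more than
#' `min_genes_exclusive` genes, strictly fewer than `max_genes_exclusive`
#' genes, and whose mitochondrial fraction (counts of genes flagged `mito`
#' over total counts) is strictly below `max_mito_fraction`. A gene is
#' "detected" at one read or more.
#'
#' @param cm a [labeled_counts] object.
#' @param params a [qc_params] object.
#' @return list with `counts` (the filtered [labeled_counts]) and `report`
#'   (a `qc_report` whose `flags` data.frame gives each cell's predicate
#'   outcomes). With no mitochondrial gene flagged, the mitochondrial
#'   predicate passes vacuously and a warning is recorded in the report.
#' @export
filter_droplets <- function(cm, params = qc_params()) {
  stopifnot(inherits(cm, "labeled_counts"))
  detected <- Matrix::colSums(cm$counts >= 1)
  total <- Matrix::colSums(cm$counts)
  warnings <- character()
  if (any(cm$gene_info$mito)) {
    mito_counts <- Matrix::colSums(cm$counts[cm$gene_info$mito, ,
                                             drop = FALSE])
    mito_frac <- ifelse(total > 0, mito_counts / total, 0)
    pass_mito <- mito_frac < params$max_mito_fraction
  } else {
    mito_frac <- rep(NA_real_, ncol(cm$counts))
    pass_mito <- rep(TRUE, ncol(cm$counts))
    warnings <- "no mitochondrial genes flagged; mito predicate passed vacuously"
  }
  pass_min <- detected > params$min_genes_exclusive
  pass_max <- detected < params$max_genes_exclusive
  keep <- pass_min & pass_max & pass_mito
  flags <- data.frame(barcode = cm$cell_info$barcode,
                      genes_detected = as.integer(detected),
                      mito_fraction = mito_frac,
                      pass_min_genes = pass_min,
                      pass_max_genes = pass_max,
                      pass_mito = pass_mito,
                      retained = keep,
                      stringsAsFactors = FALSE)
  list(counts = subset_cells(cm, keep),
       report = qc_report("filter_droplets", flags, keep,
                          thresholds = params[c("min_genes_exclusive",
                                                "max_genes_exclusive",
                                                "max_mito_fraction")],
                          warnings = warnings))
}

#' Depth-normalize a count matrix
#'
#' The default (and only built-in) method, `"lognorm_median"`, removes the
#' per-cell sequencing-depth effect by scaling every cell to the median
#' total count of the matrix and taking `log1p`:
#' `log1p(count / cell_total * median(cell_totals))`. Two cells identical up
#' to a depth factor map to identical profiles. This stands in for
#' regression-based normalizations (such as sctransform) upstream of marker
#' gating; the screen itself works on raw binarized counts and never sees
#' normalized values.
#'
#' @param cm a [labeled_counts] object.
#' @param method normalization method name.
#' @return a `normalized_matrix`: list with `values` (dense-free sparse
#'   genes x cells matrix of normalized expression), `cell_info`,
#'   `gene_info`, `method`, and the `counts` object it came from.
#' @export
normalize_counts <- function(cm, method = "lognorm_median") {
  stopifnot(inherits(cm, "labeled_counts"))
  method <- match.arg(method, "lognorm_median")
  total <- Matrix::colSums(cm$counts)
  target <- median(total[total > 0])
  scale <- ifelse(total > 0, target / total, 0)
  vals <- cm$counts %*% Diagonal(x = scale)
  vals@x <- log1p(vals@x)
  dimnames(vals) <- dimnames(cm$counts)
  structure(list(values = vals, cell_info = cm$cell_info,
                 gene_info = cm$gene_info, method = method, counts = cm),
            class = "normalized_matrix")
}

#' Bimodal separation threshold (Otsu's criterion)
#'
#' Picks the cutoff minimizing the within-class variance of a histogram of
#' the scores, the standard criterion for separating a bimodal distribution.
#' Invariant to the order of the scores and to duplicating all of them.
#'
#' @param x numeric scores.
#' @param n_bins histogram resolution.
#' @return single numeric threshold (midpoint of the optimal bin edge).
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("no finite scores", call. = FALSE)
  if (diff(range(x)) == 0) return(x[1])
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_tot <- mu[n_bins]
  ## maximize between-class variance == minimize within-class variance
  between <- (mu_tot * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  ## the criterion is flat across empty histogram gaps; take the midpoint of
  ## the maximizing plateau rather than its edge
  kk <- which(between >= max(between) - 1e-12)
  (breaks[min(kk) + 1] + breaks[max(kk) + 1]) / 2
}

## Data-driven marker threshold. Otsu's cutoff is accepted only when the
## resulting low class is genuinely marker-negative (its mean score well
## below the high class's): a true contaminant population lacks the markers
## rather than expressing them slightly less. Without such a split the stage
## has nothing to separate and passes every cell through.
bimodal_marker_threshold <- function(score, low_to_high_max = 0.25) {
  score <- as.numeric(score)
  if (length(score) < 2 || diff(range(score)) == 0) {
    return(list(threshold = NA_real_, separated = FALSE))
  }
  thr <- otsu_threshold(score)
  lo <- score[score <= thr]
  hi <- score[score > thr]
  if (length(lo) == 0 || length(hi) == 0) {
    return(list(threshold = NA_real_, separated = FALSE))
  }
  separated <- mean(lo) < low_to_high_max * mean(hi)
  list(threshold = if (separated) thr else NA_real_, separated = separated)
}

marker_score <- function(nm, markers, what) {
  present <- intersect(markers, rownames(nm$values))
  if (length(present) == 0) {
    stop(sprintf("none of the %s markers (%s) are present in the matrix",
                 what, paste(markers, collapse = ", ")), call. = FALSE)
  }
  Matrix::colSums(nm$values[present, , drop = FALSE]) / length(present)
}

#' Select neurons by mean marker expression
#'
#' Scores every cell by its mean normalized expression over the available
#' neuronal markers and retains cells whose score strictly exceeds the
#' threshold. With `neuron_threshold = "auto"` the cutoff is the
#' [otsu_threshold()] of the score distribution, accepted only when the low
#' class it isolates is genuinely marker-negative (mean score well below the
#' high class's); when no such population exists the stage has nothing to
#' gate out and every cell passes. The chosen threshold and the outcome of
#' the bimodality check are recorded in the report.
#'
#' @param nm a `normalized_matrix` from [normalize_counts()].
#' @param params a [qc_params] object.
#' @return list with `counts` (retained cells, raw counts) and `report`.
#' @export
select_neurons <- function(nm, params = qc_params()) {
  stopifnot(inherits(nm, "normalized_matrix"))
  score <- marker_score(nm, params$neuron_markers, "neuronal")
  auto <- identical(params$neuron_threshold, "auto")
  if (auto) {
    bi <- bimodal_marker_threshold(score)
    ## no marker-negative population detected: nothing to gate out
    thr <- if (bi$separated) bi$threshold else min(score) - 1
    separated <- bi$separated
  } else {
    thr <- params$neuron_threshold
    separated <- NA
  }
  keep <- score > thr
  flags <- data.frame(barcode = nm$cell_info$barcode,
                      neuron_score = as.numeric(score),
                      retained = keep, stringsAsFactors = FALSE)
  list(counts = subset_cells(nm$counts, keep),
       report = qc_report("select_neurons", flags, keep,
                          thresholds = list(neuron_threshold = thr,
                                            auto = auto,
                                            auto_separated = separated)))
}

#' Exclude glial-containing doublets
#'
#' Removes cells whose mean normalized expression over the glial markers
#' exceeds the threshold; with `glial_threshold = "auto"` the cutoff comes
#' from [otsu_threshold()] when the glial score splits into a
#' glial-negative and a glial-positive class, and falls back to retaining
#' everything when there is no such glial-positive population.
#'
#' @param nm a `normalized_matrix` (typically recomputed on the
#'   neuron-selected cells).
#' @param params a [qc_params] object.
#' @return list with `counts` (retained cells, raw counts) and `report`.
#' @export
exclude_glial_doublets <- function(nm, params = qc_params()) {
  stopifnot(inherits(nm, "normalized_matrix"))
  score <- marker_score(nm, params$glial_markers, "glial")
  auto <- identical(params$glial_threshold, "auto")
  if (auto) {
    bi <- bimodal_marker_threshold(score)
    ## here the glial-negative low class is the one we keep; without a
    ## separated glial-positive class no cell is removed
    thr <- if (bi$separated) bi$threshold else Inf
    separated <- bi$separated
  } else {
    thr <- params$glial_threshold
    separated <- NA
  }
  keep <- score <= thr
  flags <- data.frame(barcode = nm$cell_info$barcode,
                      glial_score = as.numeric(score),
                      retained = keep, stringsAsFactors = FALSE)
  list(counts = subset_cells(nm$counts, keep),
       report = qc_report("exclude_glial_doublets", flags, keep,
                          thresholds = list(glial_threshold = thr,
                                            auto = auto,
                                            auto_separated = separated)))
}

#' Run the full QC chain
#'
#' Droplet filtering, neuron selection and glial-doublet exclusion in
#' sequence; the normalized matrix is recomputed after droplet filtering so
#' that depth scaling reflects the retained cells only.
#'
#' @param cm a [labeled_counts] object.
#' @param params a [qc_params] object.
#' @return list with `counts` (the neuron-only matrix) and `reports` (one
#'   `qc_report` per stage).
#' @export
run_qc <- function(cm, params = qc_params()) {
  st1 <- filter_droplets(cm, params)
  nm <- normalize_counts(st1$counts)
  st2 <- select_neurons(nm, params)
  nm2 <- normalize_counts(st2$counts)
  st3 <- exclude_glial_doublets(nm2, params)
  list(counts = st3$counts,
       reports = list(filter_droplets = st1$report,
                      select_neurons = st2$report,
                      exclude_glial_doublets = st3$report))
}
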