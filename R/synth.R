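#' Specification of one labeled cell group
#'
#' @param name group identifier.
#' @param role `"sympathetic"`, `"parasympathetic"` or `"pelvic_cluster"`.
#' @param n_cells number of cells (>= 1).
#' @param batch batch identifier (the two sequencing rounds of the default
#'   design).
#' @return a `group_spec` list.
#' @export
group_spec <- function(name, role, n_cells, batch = "batch1") {
  role <- match.arg(role, c("sympathetic", "parasympathetic",
                            "pelvic_cluster"))
  stop_if_not_scalar_number(n_cells, "n_cells", lower = 1)
  structure(list(name = as.character(name), role = role,
                 n_cells = as.integer(n_cells), batch = as.character(batch)),
            class = "group_spec")
}

#' Default group design: four ganglia and four pelvic clusters
#'
#' Three sympathetic ganglia (stellate, coeliac, lumbar), one
#' parasympathetic ganglion (sphenopalatine) and four pelvic clusters
#' (P1-P4), sized after the neuron counts of the source datasets scaled down
#' fourfold to keep simulations fast while preserving the strong group-size
#' imbalance. The two batches reflect the two sequencing rounds: stellate,
#' sphenopalatine and the larger pelvic clusters in the first, coeliac,
#' lumbar and the remaining pelvic clusters in the second.
#'
#' @param scale multiplier applied to every group size (e.g. `scale = 0.25`
#'   shrinks the design a further fourfold for quick tests).
#' @return list of [group_spec] objects.
#' @export
default_groups <- function(scale = 1) {
  specs <- list(
    group_spec("sphenopalatine", "parasympathetic", 464, "batch1"),
    group_spec("stellate", "sympathetic", 672, "batch1"),
    group_spec("coeliac", "sympathetic", 59, "batch2"),
    group_spec("lumbar", "sympathetic", 231, "batch2"),
    group_spec("P1", "pelvic_cluster", 112, "batch1"),
    group_spec("P2", "pelvic_cluster", 88, "batch1"),
    group_spec("P3", "pelvic_cluster", 50, "batch2"),
    group_spec("P4", "pelvic_cluster", 56, "batch2")
  )
  lapply(specs, function(s) {
    s$n_cells <- max(1L, as.integer(round(s$n_cells * scale)))
    s
  })
}

#' A gene planted with a dichotomous expression pattern
#'
#' The gene expresses in a fraction `p_on` of the cells of every group on
#' side 1 of its split and `p_off` elsewhere; expressing cells draw a
#' positive count from a shifted negative binomial with mean `mean_on`.
#'
#' @param gene_id identifier.
#' @param subset_1 character vector: group names on the highly expressing
#'   side.
#' @param p_on expressing fraction in `subset_1` groups, in (0, 1].
#' @param p_off expressing fraction elsewhere, in `[0, 1)`; must be below
#'   `p_on`.
#' @param mean_on mean count given expression (> 0).
#' @param dispersion negative-binomial size parameter.
#' @return a `planted_gene` list.
#' @export
planted_gene <- function(gene_id, subset_1, p_on = 0.8, p_off = 0.02,
                         mean_on = 5, dispersion = 1) {
  stop_if_not_scalar_number(p_on, "p_on", lower = 0, upper = 1,
                            strict_lower = TRUE)
  stop_if_not_scalar_number(p_off, "p_off", lower = 0, upper = 1,
                            strict_upper = TRUE)
  if (p_on <= p_off) stop("`p_on` must exceed `p_off`", call. = FALSE)
  stop_if_not_scalar_number(mean_on, "mean_on", lower = 0, strict_lower = TRUE)
  structure(list(gene_id = as.character(gene_id),
                 subset_1 = as.character(subset_1),
                 p_on = p_on, p_off = p_off,
                 mean_on = mean_on, dispersion = dispersion),
            class = "planted_gene")
}

#' Simulation configuration
#'
#' Defines a complete synthetic dataset: labeled groups, background genes
#' expressed uniformly, planted dichotomous genes, mitochondrial genes driven
#' by a per-cell Beta mitochondrial fraction, neuronal and glial marker
#' genes, and two kinds of artifact droplets (low-quality debris with very
#' low library complexity and high mitochondrial content, and neuron+glia
#' doublets expressing both marker sets).
#'
#' @param groups list of [group_spec].
#' @param n_background_genes genes with the same expressing fraction
#'   everywhere.
#' @param planted list of [planted_gene].
#' @param background_p baseline expressing fraction of background genes.
#' @param background_mean,background_dispersion count law of expressing
#'   background cells.
#' @param mito_gene_count number of `mt-` genes.
#' @param mito_fraction_params Beta parameters of the per-cell mitochondrial
#'   fraction: `shape1`, `shape2` for intact cells (default mean 5%),
#'   `lowq_shape1`, `lowq_shape2` for low-quality droplets (default mean
#'   40%, reflecting the high mitochondrial content of broken cells).
#' @param neuron_marker_ids,glial_marker_ids marker gene identifiers; the
#'   defaults are the pan-neuronal set Stmn2, Stmn3, Gap43, Tubb3 and the
#'   glial set Plp1, Ttyh1, Fabp7, Cryab, Mal.
#' @param neuron_marker_mean,glial_marker_mean mean counts of expressed
#'   markers.
#' @param n_lowquality_droplets,n_glial_doublets artifact droplet counts.
#' @param lowquality_depth_factor multiplier (< 1) on every expression
#'   probability in low-quality droplets; drives their low gene detection.
#' @param batch_depth optional named multiplicative depth factor per batch
#'   applied to count means (not to expressing fractions — the screen is
#'   binarized, so depth is the relevant nuisance).
#' @param seed RNG seed; a fixed seed makes the output byte-identical.
#' @return a `sim_config` list.
#' @export
sim_config <- function(groups = default_groups(),
                       n_background_genes = 200,
                       planted = list(),
                       background_p = 0.3,
                       background_mean = 2,
                       background_dispersion = 1,
                       mito_gene_count = 10,
                       mito_fraction_params = list(shape1 = 5, shape2 = 95,
                                                   lowq_shape1 = 8,
                                                   lowq_shape2 = 12),
                       neuron_marker_ids = c("Stmn2", "Stmn3", "Gap43",
                                             "Tubb3"),
                       glial_marker_ids = c("Plp1", "Ttyh1", "Fabp7",
                                            "Cryab", "Mal"),
                       neuron_marker_mean = 20,
                       glial_marker_mean = 15,
                       n_lowquality_droplets = 0,
                       n_glial_doublets = 0,
                       lowquality_depth_factor = 0.05,
                       batch_depth = NULL,
                       seed = 1L) {
  if (inherits(groups, "group_spec")) groups <- list(groups)
  stopifnot(length(groups) >= 1, all(vapply(groups, inherits, logical(1),
                                            "group_spec")))
  gnames <- vapply(groups, `[[`, character(1), "name")
  if (anyDuplicated(gnames)) stop("group names must be unique", call. = FALSE)
  if (inherits(planted, "planted_gene")) planted <- list(planted)
  planted_ids <- vapply(planted, `[[`, character(1), "gene_id")
  for (pg in planted) {
    if (!all(pg$subset_1 %in% gnames)) {
      stop(sprintf("planted gene %s references unknown group(s): %s",
                   pg$gene_id,
                   paste(setdiff(pg$subset_1, gnames), collapse = ", ")),
           call. = FALSE)
    }
    if (length(pg$subset_1) == 0 || length(pg$subset_1) == length(gnames)) {
      stop(sprintf("planted gene %s must split the groups into two nonempty sides",
                   pg$gene_id), call. = FALSE)
    }
  }
  id_lists <- list(planted = planted_ids, neuron = neuron_marker_ids,
                   glial = glial_marker_ids)
  all_ids <- unlist(id_lists)
  if (anyDuplicated(all_ids)) {
    stop(sprintf("overlapping identifier lists: %s",
                 paste(unique(all_ids[duplicated(all_ids)]), collapse = ", ")),
         call. = FALSE)
  }
  stop_if_not_scalar_number(background_p, "background_p", lower = 0, upper = 1)
  stop_if_not_scalar_number(lowquality_depth_factor, "lowquality_depth_factor",
                            lower = 0, upper = 1, strict_lower = TRUE)
  structure(list(groups = groups,
                 n_background_genes = as.integer(n_background_genes),
                 planted = planted,
                 background_p = background_p,
                 background_mean = background_mean,
                 background_dispersion = background_dispersion,
                 mito_gene_count = as.integer(mito_gene_count),
                 mito_fraction_params = mito_fraction_params,
                 neuron_marker_ids = as.character(neuron_marker_ids),
                 glial_marker_ids = as.character(glial_marker_ids),
                 neuron_marker_mean = neuron_marker_mean,
                 glial_marker_mean = glial_marker_mean,
                 n_lowquality_droplets = as.integer(n_lowquality_droplets),
                 n_glial_doublets = as.integer(n_glial_doublets),
                 lowquality_depth_factor = lowquality_depth_factor,
                 batch_depth = batch_depth,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Shifted negative binomial: strictly positive counts with mean ~ mean_on.
## The Bernoulli gate alone determines the expressing fraction, so planted
## fractions are exactly binomial.
rpos_nb <- function(n, mean_on, dispersion) {
  if (n == 0L) return(integer(0))
  1L + rnbinom(n, size = dispersion, mu = max(mean_on - 1, 0.05))
}

#' Generate a synthetic labeled count matrix
#'
#' Draws a genes x cells unique-read count matrix under a zero-inflated
#' negative-binomial law: each (gene, cell) expresses with a
#' gene-and-group-specific probability, and expressing cells draw a strictly
#' positive overdispersed count. Group cells are neurons (high neuronal
#' marker expression, no glial expression); glial doublets express both
#' marker sets at full depth; low-quality droplets have all expression
#' probabilities scaled down by `lowquality_depth_factor` and a high
#' mitochondrial fraction. Mitochondrial counts are allocated per cell so
#' that the cell's mitochondrial fraction matches a Beta draw.
#'
#' The result is deterministic given `config$seed`; the caller's RNG state
#' is left untouched.
#'
#' @param config a [sim_config].
#' @return a [labeled_counts] whose `cell_info` carries `group`, `batch` and
#'   `kind` (`"cell"`, `"lowquality"` or `"glial_doublet"`), and whose
#'   `gene_info` carries `mito` and `marker_class`.
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_counts_impl(config))
}

generate_counts_impl <- function(config) {
  groups <- config$groups
  gnames <- vapply(groups, `[[`, character(1), "name")
  gsizes <- vapply(groups, `[[`, integer(1), "n_cells")
  gbatch <- vapply(groups, `[[`, character(1), "batch")

  n_real <- sum(gsizes)
  n_lowq <- config$n_lowquality_droplets
  n_doub <- config$n_glial_doublets
  n_cells <- n_real + n_lowq + n_doub

  ## cell bookkeeping: artifact droplets inherit a group label round-robin
  ## (they arrive in the same library as real cells)
  cell_group <- c(rep(gnames, gsizes),
                  gnames[(seq_len(n_lowq) - 1L) %% length(gnames) + 1L],
                  gnames[(seq_len(n_doub) - 1L) %% length(gnames) + 1L])
  cell_kind <- c(rep("cell", n_real), rep("lowquality", n_lowq),
                 rep("glial_doublet", n_doub))
  cell_batch <- gbatch[match(cell_group, gnames)]
  is_lowq <- cell_kind == "lowquality"
  is_doub <- cell_kind == "glial_doublet"

  depth_mult <- ifelse(is_lowq, config$lowquality_depth_factor, 1)
  mean_mult <- rep(1, n_cells)
  if (!is.null(config$batch_depth)) {
    f <- config$batch_depth[cell_batch]
    f[is.na(f)] <- 1
    mean_mult <- unname(f)
  }

  gene_ids <- c(vapply(config$planted, `[[`, character(1), "gene_id"),
                sprintf("bg%04d", seq_len(config$n_background_genes)),
                config$neuron_marker_ids,
                config$glial_marker_ids,
                if (config$mito_gene_count > 0)
                  sprintf("mt-gene%02d", seq_len(config$mito_gene_count)))
  marker_class <- c(rep("planted", length(config$planted)),
                    rep("background", config$n_background_genes),
                    rep("neuron_marker", length(config$neuron_marker_ids)),
                    rep("glial_marker", length(config$glial_marker_ids)),
                    rep("mito", config$mito_gene_count))
  n_genes <- length(gene_ids)

  counts <- matrix(0L, nrow = n_genes, ncol = n_cells,
                   dimnames = list(gene_ids, paste0("cell", sprintf(
                     "%06d", seq_len(n_cells)), "-1")))

  draw_gene <- function(p_cell, mean_on, dispersion) {
    on <- runif(n_cells) < pmin(1, p_cell * depth_mult)
    x <- integer(n_cells)
    k <- sum(on)
    if (k > 0) {
      x[on] <- as.integer(round(rpos_nb(k, mean_on, dispersion) *
                                  mean_mult[on]))
      x[on] <- pmax(x[on], 1L)   # expressing cells keep >= 1 read
    }
    x
  }

  row <- 0L
  for (pg in config$planted) {
    row <- row + 1L
    p_cell <- ifelse(cell_group %in% pg$subset_1, pg$p_on, pg$p_off)
    counts[row, ] <- draw_gene(p_cell, pg$mean_on, pg$dispersion)
  }
  for (b in seq_len(config$n_background_genes)) {
    row <- row + 1L
    counts[row, ] <- draw_gene(rep(config$background_p, n_cells),
                               config$background_mean,
                               config$background_dispersion)
  }
  for (m in seq_along(config$neuron_marker_ids)) {
    row <- row + 1L
    ## neurons and doublets both carry neuronal transcripts; low-quality
    ## droplets lose them through the shared depth multiplier
    counts[row, ] <- draw_gene(rep(0.98, n_cells),
                               config$neuron_marker_mean, 2)
  }
  for (m in seq_along(config$glial_marker_ids)) {
    row <- row + 1L
    p_cell <- ifelse(is_doub, 0.95, 0)
    counts[row, ] <- draw_gene(p_cell, config$glial_marker_mean, 2)
  }

  ## mitochondrial counts: per-cell Beta fraction f; the cell's mito total
  ## is chosen so mito / (mito + nuclear) ~ f, then spread multinomially
  if (config$mito_gene_count > 0) {
    mp <- config$mito_fraction_params
    f <- numeric(n_cells)
    ok <- !is_lowq
    f[ok] <- rbeta(sum(ok), mp$shape1, mp$shape2)
    f[!ok] <- rbeta(sum(!ok), mp$lowq_shape1, mp$lowq_shape2)
    nuclear_tot <- colSums(counts)
    mito_tot <- as.integer(round(f / (1 - f) * pmax(nuclear_tot, 1)))
    mito_rows <- row + seq_len(config$mito_gene_count)
    for (c in which(mito_tot > 0)) {
      counts[mito_rows, c] <- as.integer(
        rmultinom(1, mito_tot[c], rep(1, config$mito_gene_count)))
    }
  }

  cm <- labeled_counts(
    as(counts, "CsparseMatrix"),
    data.frame(group = cell_group, batch = cell_batch, kind = cell_kind,
               stringsAsFactors = FALSE),
    data.frame(gene_id = gene_ids, marker_class = marker_class,
               stringsAsFactors = FALSE)
  )
  cm
}

#' Ground truth for planted genes
#'
#' Returns, for every planted gene, its true split (in the canonical group
#' order) and the pattern label that [classify_split()] assigns to that
#' split, for use as recovery ground truth.
#'
#' @param config a [sim_config].
#' @param roles a [group_role_map]; the default is derived from the roles
#'   declared in `config$groups`.
#' @return data.frame with columns `gene`, `subset_1`, `subset_2`,
#'   `pattern`, `category` (zero rows when nothing is planted).
#' @export
planted_truth <- function(config, roles = NULL) {
  stopifnot(inherits(config, "sim_config"))
  gnames <- vapply(config$groups, `[[`, character(1), "name")
  if (is.null(roles)) {
    rl <- vapply(config$groups, `[[`, character(1), "role")
    roles <- group_role_map(roles = setNames(rl, gnames))
  }
  if (length(config$planted) == 0) {
    return(data.frame(gene = character(), subset_1 = character(),
                      subset_2 = character(), pattern = character(),
                      category = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(config$planted, function(pg) {
    bp <- bipartition(pg$subset_1, gnames)
    pat <- classify_split(bp, roles)
    data.frame(gene = pg$gene_id,
               subset_1 = paste(bp$subset_1, collapse = ";"),
               subset_2 = paste(bp$subset_2, collapse = ";"),
               pattern = pat,
               category = unname(pattern_categories[pat]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a simulation to disk as a CellRanger-style triplet
#'
#' Convenience wrapper: generates the counts, writes the Matrix Market
#' triplet with the label sidecar via [write_cellranger_mtx()], and stores
#' the planted truth as `truth.json`.
#'
#' @param config a [sim_config].
#' @param path output directory.
#' @param gzip compress the triplet?
#' @return `path`, invisibly.
#' @export
write_simulation <- function(config, path, gzip = FALSE) {
  cm <- generate_counts(config)
  write_cellranger_mtx(cm, path, gzip = gzip)
  truth <- planted_truth(config)
  jsonlite::write_json(truth, file.path(path, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}
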