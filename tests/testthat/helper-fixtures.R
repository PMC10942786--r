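## Shared fixtures for the test suite. Everything is built in code.

groups8 <- c("sphenopalatine", "stellate", "coeliac", "lumbar",
             "P1", "P2", "P3", "P4")

## labeled_counts from a dense matrix (genes x cells) and a group vector
make_lc <- function(m, groups, gene_ids = NULL, ...) {
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(m)))
  rownames(m) <- gene_ids
  colnames(m) <- paste0("bc", seq_len(ncol(m)))
  labeled_counts(Matrix::Matrix(m, sparse = TRUE),
                 data.frame(group = groups), ...)
}

## group design used when the real size imbalance is irrelevant
uniform_groups <- function(n_cells) {
  roles <- c(sphenopalatine = "parasympathetic", stellate = "sympathetic",
             coeliac = "sympathetic", lumbar = "sympathetic",
             P1 = "pelvic_cluster", P2 = "pelvic_cluster",
             P3 = "pelvic_cluster", P4 = "pelvic_cluster")
  lapply(names(roles), function(g)
    group_spec(g, roles[[g]], n_cells,
               batch = if (g %in% c("sphenopalatine", "stellate", "P1", "P2"))
                 "batch1" else "batch2"))
}

## subset_1 member vector for a canonical split mask over `groups`
mask_members <- function(mask, groups) {
  groups[bitwAnd(bitwShiftR(mask, 0:(length(groups) - 1L)), 1L) == 1L]
}

## QC fixture: clean neurons plus planted low-quality droplets and glial
## doublets, with thresholds far from every predicate's sampling noise
qc_fixture_config <- function(seed = 42) {
  sim_config(groups = default_groups(scale = 0.25),
             n_background_genes = 500,
             background_p = 0.3,
             n_lowquality_droplets = 25,
             n_glial_doublets = 15,
             seed = seed)
}

qc_fixture_params <- function(neuron_threshold = 0.5, glial_threshold = 0.8) {
  qc_params(min_genes_exclusive = 60, max_genes_exclusive = 5000,
            max_mito_fraction = 0.15,
            neuron_threshold = neuron_threshold,
            glial_threshold = glial_threshold)
}
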