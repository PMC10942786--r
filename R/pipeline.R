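## Pipeline driver: simulate/read -> qc -> screen -> patterns, with a
## validated config and a digest manifest for reproducibility.

default_pipeline_config <- function() {
  list(
    input = NULL,       # list(path=, labels=) for a CellRanger triplet
    simulate = NULL,    # sim_config-shaped list for synthetic input
    qc = list(),        # qc_params() overrides
    score = list(),     # score_params() overrides
    screen = list(),    # screen_config() overrides
    roles = NULL,       # named group -> role map (default group_role_map())
    cholinergic_pelvic = NULL,
    noradrenergic_pelvic = NULL,
    seed = 1L
  )
}

build_sim_config <- function(sim, seed) {
  groups <- if (is.null(sim$groups)) {
    default_groups(scale = sim$scale %||% 1)
  } else {
    lapply(sim$groups, function(g)
      group_spec(g$name, g$role, g$n_cells, g$batch %||% "batch1"))
  }
  planted <- lapply(sim$planted %||% list(), function(p)
    planted_gene(p$gene_id, unlist(p$subset_1),
                 p$p_on %||% 0.8, p$p_off %||% 0.02,
                 p$mean_on %||% 5, p$dispersion %||% 1))
  keep <- intersect(names(sim),
                    setdiff(names(formals(sim_config)),
                            c("groups", "planted", "seed")))
  do.call(sim_config, c(list(groups = groups, planted = planted,
                             seed = sim$seed %||% seed),
                        sim[keep]))
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration file, rejects unknown keys, checks
#' ranges and referenced files, and fills every default: score parameters
#' `eps_pos = 0.9`, `eps_nega = 0.02`; `top_k = 100`; droplet QC at
#' 1500/11,000 detected genes and 15% mitochondrial fraction. Exactly one of
#' `input` (a CellRanger-style triplet directory) and `simulate` (a
#' synthetic-data specification) must be set; an empty file selects a
#' default synthetic run.
#'
#' @param path configuration file, or a list already in config shape.
#' @return a `pipeline_config` list with components `counts_source`
#'   (function of no arguments producing a [labeled_counts]), `qc`,
#'   `score`, `screen`, `roles`, `sim` (or `NULL`), `seed`.
#' @export
validate_config <- function(path) {
  raw <- if (is.list(path)) {
    path
  } else {
    if (!file.exists(path)) {
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    }
    yaml::read_yaml(path) %||% list()
  }
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg <- modifyList(defaults, raw, keep.null = TRUE)
  if (!is.null(cfg$input) && !is.null(cfg$simulate)) {
    stop("set exactly one of `input` and `simulate`", call. = FALSE)
  }
  if (is.null(cfg$input) && is.null(cfg$simulate)) {
    cfg$simulate <- list(scale = 0.1)   # small default synthetic demo
  }

  seed <- as.integer(cfg$seed %||% 1L)
  sim <- NULL
  if (!is.null(cfg$input)) {
    if (is.null(cfg$input$path) || !dir.exists(cfg$input$path)) {
      stop(sprintf("input directory not found: %s",
                   cfg$input$path %||% "<unset>"), call. = FALSE)
    }
    labels <- cfg$input$labels
    if (!is.null(labels) && !file.exists(labels)) {
      stop(sprintf("labels file not found: %s", labels), call. = FALSE)
    }
    if (is.null(labels) &&
        !file.exists(file.path(cfg$input$path, "labels.tsv"))) {
      stop(sprintf("no labels.tsv in %s and no `labels` given",
                   cfg$input$path), call. = FALSE)
    }
    in_path <- cfg$input$path
    counts_source <- function() read_cellranger_mtx(in_path, labels = labels)
  } else {
    sim <- build_sim_config(cfg$simulate, seed)
    counts_source <- function() generate_counts(sim)
  }

  qc <- do.call(qc_params, cfg$qc)
  score <- do.call(score_params, cfg$score)
  screen <- do.call(screen_config, cfg$screen)
  roles <- if (is.null(cfg$roles)) {
    if (!is.null(sim)) {
      gnames <- vapply(sim$groups, `[[`, character(1), "name")
      rl <- vapply(sim$groups, `[[`, character(1), "role")
      pelvic <- gnames[rl == "pelvic_cluster"]
      group_role_map(
        roles = setNames(rl, gnames),
        cholinergic_pelvic = cfg$cholinergic_pelvic %||%
          intersect(c("P1", "P2", "P4"), pelvic),
        noradrenergic_pelvic = cfg$noradrenergic_pelvic %||%
          intersect("P3", pelvic))
    } else {
      group_role_map()
    }
  } else {
    group_role_map(
      roles = unlist(cfg$roles),
      cholinergic_pelvic = cfg$cholinergic_pelvic %||% character(),
      noradrenergic_pelvic = cfg$noradrenergic_pelvic %||% character())
  }

  structure(list(counts_source = counts_source, sim = sim, qc = qc,
                 score = score, screen = screen, roles = roles, seed = seed),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full screening pipeline
#'
#' Executes input acquisition (simulation or triplet read), quality control,
#' the bipartition screen, and pattern assignment, writing every artifact
#' under `out_dir`: `qc_report.json`, the filtered triplet under
#' `filtered/`, `scores.tsv`, `patterns.tsv`, `ordering.tsv`, `tally.json`,
#' and a `manifest.json` with an MD5 digest of each artifact. Reruns with an
#' identical configuration and seed reproduce identical digests.
#'
#' @param config a `pipeline_config` from [validate_config()], or a path to
#'   a configuration file.
#' @param out_dir output directory, created if needed.
#' @return the manifest, invisibly: list with `artifacts` (name -> md5) and
#'   `summary` (cell/gene tallies per stage).
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cm <- run_stage("input", config$counts_source())
  qc <- run_stage("qc", run_qc(cm, config$qc))

  run_stage("write_qc", {
    rep_json <- lapply(qc$reports, function(r)
      list(stage = r$stage, n_input = r$n_input, n_retained = r$n_retained,
           n_removed = r$n_removed, thresholds = r$thresholds,
           warnings = r$warnings))
    jsonlite::write_json(rep_json, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    write_cellranger_mtx(qc$counts, file.path(out_dir, "filtered"))
  })

  ranked <- run_stage("screen", {
    tab <- binarize_and_tabulate(qc$counts)
    sc <- screen_all(tab, config$score)
    top_genes(sc, config$screen)
  })
  run_stage("write_screen",
            write_scores_tsv(ranked, file.path(out_dir, "scores.tsv")))

  groups <- unique(qc$counts$cell_info$group)
  pats <- run_stage("patterns", {
    assign_patterns(ranked, groups, config$roles)
  })
  run_stage("write_patterns", {
    write.table(pats[, c("gene", "pattern", "category", "subset_1", "score")],
                file.path(out_dir, "patterns.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tally <- tally_patterns(pats)
    jsonlite::write_json(tally, file.path(out_dir, "tally.json"),
                         auto_unbox = TRUE, digits = NA)
    hm <- order_for_heatmap(pats)
    write.table(hm$ordering[, c("gene", "pattern", "category", "score",
                                "block")],
                file.path(out_dir, "ordering.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })

  artifacts <- c("qc_report.json", "scores.tsv", "patterns.tsv",
                 "ordering.tsv", "tally.json",
                 file.path("filtered", c("matrix.mtx", "features.tsv",
                                         "barcodes.tsv", "labels.tsv")))
  digests <- vapply(artifacts, function(a)
    unname(tools::md5sum(file.path(out_dir, a))), character(1))
  manifest <- list(
    artifacts = as.list(digests),
    summary = list(
      n_cells_input = ncol(cm$counts),
      n_cells_neurons = ncol(qc$counts$counts),
      n_genes = nrow(cm$counts),
      n_top_genes = nrow(ranked),
      seed = config$seed
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
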