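#' Pipeline configuration with the study's default thresholds
#'
#' Every numeric default equals the corresponding analysis threshold:
#' minimum 600 UMIs per cell, doublet score at most 0.4, 10 cells per sample
#' for pseudobulk inclusion, 40 cells per sample in lineage subsets, marker
#' Z cutoff 3, signature-derivation Z cutoff 10, 10% ligand-receptor
#' expression screen with 1,000 permutations, and top/bottom 25% survival
#' strata.
#'
#' @param input_dir Directory with an MTX bundle (`cohort.mtx`,
#'   `cohort_genes.tsv`, `cohort_cells.tsv`), or `NULL` to simulate.
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run, in dependency order.
#' @param seed Integer seed for simulation and permutations.
#' @param ... Overrides for any threshold listed above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, out_dir = tempfile("metaniche_run_"),
                            stages = c("simulate", "qc", "composition", "markers",
                                       "de", "cnv", "signature", "survival",
                                       "interactions"),
                            seed = 1L, ...) {
  cfg <- list(
    input_dir = input_dir, out_dir = out_dir, stages = stages, seed = as.integer(seed),
    min_umi = 600L, max_doublet = 0.4, min_cells = 10L, subset_min_cells = 40L,
    marker_z = 3, signature_z = 10, lr_min_fraction = 0.10, n_perm = 1000L,
    quantile = 0.25, normalize_scale = 1e4, cnv_window = 101L, cnv_clip_sd = 3
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop_mn(paste("unknown config fields:", paste(unknown, collapse = ", ")),
                               "mn_bad_config")
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

write_stage_table <- function(x, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".tsv"))
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  path
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the enabled stages in dependency order on either a simulated
#' cohort (stage `"simulate"`) or an MTX bundle read from
#' `config$input_dir`: QC filtering, composition comparison, tumor marker
#' detection, pseudobulk differential expression, CNV profiling against the
#' non-malignant reference, metastatic-signature derivation, bulk survival
#' stratification with log-rank testing, and the ligand-receptor permutation
#' test.  Skipping QC while requesting downstream stages proceeds on
#' unfiltered cells with a logged warning.  Every run writes its resolved
#' configuration and a manifest (stage outputs, input digests, seed) beside
#' the outputs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly: a list with `outputs` (named paths),
#'   `config`, `digests` and per-stage timing.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  timings <- list()
  stage_on <- function(s) s %in% config$stages
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e) {
      stop_mn(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
              "mn_stage_error")
    })
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    r
  }

  if (stage_on("simulate")) {
    sim <- tick("simulate", generate_sc_cohort(sim_config(seed = config$seed)))
    counts <- sim$counts; cells <- sim$cells; genes <- sim$genes
    outputs$simulate <- write_cohort(sim, file.path(config$out_dir, "simulated"))
  } else {
    if (is.null(config$input_dir)) {
      stop_mn("stage 'qc' needs either the simulate stage or input_dir", "mn_dependency_error")
    }
    bundle <- tick("read", read_mtx_bundle(
      file.path(config$input_dir, "cohort.mtx"),
      file.path(config$input_dir, "cohort_genes.tsv"),
      file.path(config$input_dir, "cohort_cells.tsv")
    ))
    counts <- bundle$counts; cells <- bundle$cells; genes <- bundle$genes
    sim <- NULL
  }

  if (stage_on("qc")) {
    qc <- tick("qc", filter_cells(counts, cells, config$min_umi, config$max_doublet))
    counts <- qc$counts; cells <- qc$cells
    outputs$qc_audit <- write_stage_table(qc$audit, config$out_dir, "qc_audit")
  } else if (length(setdiff(config$stages, "simulate"))) {
    rlang::warn("QC disabled: downstream stages run on unfiltered cells")
  }

  norm <- normalize_counts(counts, scale = config$normalize_scale)

  if (stage_on("composition")) {
    comp <- tick("composition",
                 composition_test(cells, "metastatic", "nonmetastatic",
                                  min_cells_per_sample = config$subset_min_cells))
    outputs$composition <- write_stage_table(comp$tests, config$out_dir, "composition_tests")
    outputs$proportions <- write_stage_table(comp$proportions, config$out_dir,
                                             "composition_proportions")
  }

  markers_tumor <- NULL
  if (stage_on("markers") || stage_on("interactions")) {
    markers_tumor <- tick("markers",
                          wilcoxon_markers(norm, cells$cell_type, "tumor"))
    outputs$markers <- write_stage_table(markers_tumor, config$out_dir, "tumor_markers")
  }

  if (stage_on("de")) {
    de <- tick("de", {
      bm <- cells$condition %in% c("metastatic", "nonmetastatic")
      ref_type <- names(sort(table(cells$cell_type[bm & cells$cell_type != "tumor"]),
                             decreasing = TRUE))[1]
      pb <- make_pseudobulk(counts[, bm, drop = FALSE], cells[bm, ], ref_type,
                            min_cells = config$min_cells)
      grp <- pb$samples$condition
      pseudobulk_de(pb$counts[, grp == "nonmetastatic", drop = FALSE],
                    pb$counts[, grp == "metastatic", drop = FALSE])
    })
    outputs$de <- write_stage_table(de$results, config$out_dir, "pseudobulk_de")
  }

  if (stage_on("cnv")) {
    cnv <- tick("cnv", {
      ref <- cells$cell_id[cells$cell_type != "tumor" &
                             cells$condition %in% c("metastatic", "nonmetastatic")]
      infer_cnv(norm, genes, ref, window = config$cnv_window, clip_sd = config$cnv_clip_sd)
    })
    outputs$cnv <- write_stage_table(
      tibble::as_tibble(as.data.frame(t(cnv$profile)), rownames = "cell_id"),
      config$out_dir, "cnv_profile")
  }

  derivation <- NULL
  if (stage_on("signature")) {
    derivation <- tick("signature", derive_signature(norm, cells, z_cutoff = config$signature_z))
    outputs$signature_provenance <- write_stage_table(derivation$provenance,
                                                      config$out_dir, "signature_provenance")
    if (length(derivation$signature$genes)) {
      outputs$signature_gmt <- write_gmt(derivation$signature,
                                         file.path(config$out_dir, "metastatic_signature.gmt"))
    }
  }

  if (stage_on("survival")) {
    if (is.null(derivation) || length(derivation$signature$genes) == 0) {
      stop_mn("stage 'survival' requires a non-empty derived signature", "mn_dependency_error")
    }
    sv <- tick("survival", {
      bulk <- generate_bulk_cohort(200, derivation$signature, hazard_ratio = 3,
                                   seed = config$seed)
      scores <- score_signature(bulk$expr, derivation$signature)
      strat <- stratify_by_score(scores, quantile = config$quantile)
      surv <- dplyr::inner_join(bulk$survival, strat, by = c(patient_id = "id")) |>
        dplyr::filter(.data$stratum != "excluded")
      list(km = km_estimate(surv), lr = logrank_test(surv, "high", "low"), table = surv)
    })
    outputs$km <- write_stage_table(sv$km, config$out_dir, "km_curves")
    outputs$logrank <- write_stage_table(sv$lr$table, config$out_dir, "logrank_table")
    outputs$survival_pvalue <- write_stage_table(
      tibble::tibble(statistic = sv$lr$statistic, p_val = sv$lr$p_val),
      config$out_dir, "logrank_summary")
  }

  if (stage_on("interactions")) {
    lr <- tick("interactions", {
      db <- generate_lr_database(50, genes, seed = config$seed)
      triples <- screen_pairs(norm, cells, db, min_fraction = config$lr_min_fraction)
      res <- lr_permutation_test(norm, cells, triples, n_perm = config$n_perm,
                                 seed = config$seed)
      flags <- flag_exclusive_ligands(markers_tumor, unique(res$ligand),
                                      z_cutoff = config$marker_z)
      dplyr::left_join(res, flags, by = "ligand")
    })
    outputs$interactions <- write_stage_table(lr, config$out_dir, "interactions")
  }

  cfg_path <- file.path(config$out_dir, "resolved_config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- unlist(outputs, use.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("metaniche")),
    seed = config$seed,
    outputs = as.list(paths),
    digests = as.list(tools::md5sum(paths[file.exists(paths) & !dir.exists(paths)])),
    timing_s = timings
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
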