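#' Simulation configuration for a synthetic single-cell cohort
#'
#' Assembles and validates the parameters of the cohort generator.  The
#' defaults emulate the study design every downstream stage expects: 8
#' metastatic and 7 nonmetastatic bone-marrow samples plus 3 primary-tumor
#' samples; tumor cells present only in metastatic and primary samples; a
#' myeloid-skewed, T-depleted composition shift in the metastatic arm; 30
#' planted genes upregulated 4-fold exclusively in metastatic tumor cells;
#' one 200-gene copy-gain and one 200-gene copy-loss segment in all tumor
#' cells; negative-binomial counts with gene-shared dispersion and log-normal
#' library sizes; and a 5% doublet rate with directly simulated doublet
#' scores.
#'
#' @param n_samples Named integer vector of samples per condition
#'   (`metastatic`, `nonmetastatic`, `primary`; a `primary` entry of 0 drops
#'   that arm).
#' @param cells_per_sample Integer range (length 2): cells drawn uniformly
#'   per sample.
#' @param n_genes Number of genes; distributed evenly over `n_chromosomes`.
#' @param n_chromosomes Number of chromosomes in the synthetic genome.
#' @param cell_type_catalog Tibble with columns `type`, `n_markers`,
#'   `marker_fold`: each non-tumor type gets `n_markers` exclusive marker
#'   genes upregulated `marker_fold`-fold; the `tumor` row defines the
#'   tumor-exclusive decoy markers.
#' @param base_composition Named positive vector: Dirichlet concentrations of
#'   the non-tumor cell types.
#' @param composition_shift Named multiplicative shift applied to
#'   `base_composition` in the metastatic condition.
#' @param tumor_fraction_metastatic,tumor_fraction_primary Expected tumor-cell
#'   fraction per sample in each condition (nonmetastatic is 0 by
#'   construction).
#' @param n_signature_genes,signature_fold Size and fold change of the gene
#'   set planted only in metastatic tumor cells.
#' @param cnv_segments Tibble (`chromosome`, `start_rank`, `end_rank`,
#'   `copy_ratio`): multiplicative copy-ratio segments applied to the
#'   expected expression of all tumor cells.
#' @param nb_dispersion Gene-shared negative-binomial dispersion (1/size).
#' @param library_size_lognormal Length-2 vector `(meanlog, sdlog)` of the
#'   per-cell expected library size.
#' @param doublet_rate Fraction of barcodes constructed as two-cell averages.
#' @param seed Integer seed; one stream drives every draw.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = c(metastatic = 8, nonmetastatic = 7, primary = 3),
                       cells_per_sample = c(150L, 250L),
                       n_genes = 2000L,
                       n_chromosomes = 8L,
                       cell_type_catalog = default_cell_type_catalog(),
                       base_composition = c(T_cell = 12, myeloid = 10, B_cell = 6, NK_cell = 4),
                       composition_shift = c(T_cell = 0.6, myeloid = 1.8, B_cell = 1, NK_cell = 0.8),
                       tumor_fraction_metastatic = 0.25,
                       tumor_fraction_primary = 0.8,
                       n_signature_genes = 30L,
                       signature_fold = 4,
                       cnv_segments = default_cnv_segments(),
                       nb_dispersion = 0.3,
                       library_size_lognormal = c(log(2500), 0.45),
                       doublet_rate = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_samples = n_samples, cells_per_sample = as.integer(cells_per_sample),
    n_genes = as.integer(n_genes), n_chromosomes = as.integer(n_chromosomes),
    cell_type_catalog = tibble::as_tibble(cell_type_catalog),
    base_composition = base_composition, composition_shift = composition_shift,
    tumor_fraction_metastatic = tumor_fraction_metastatic,
    tumor_fraction_primary = tumor_fraction_primary,
    n_signature_genes = as.integer(n_signature_genes), signature_fold = signature_fold,
    cnv_segments = tibble::as_tibble(cnv_segments),
    nb_dispersion = nb_dispersion,
    library_size_lognormal = library_size_lognormal,
    doublet_rate = doublet_rate, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

default_cell_type_catalog <- function() {
  tibble::tibble(
    type = c("tumor", "T_cell", "myeloid", "B_cell", "NK_cell"),
    n_markers = 20L,
    marker_fold = 8
  )
}

default_cnv_segments <- function() {
  tibble::tibble(
    chromosome = c("chr2", "chr3"),
    start_rank = c(26L, 26L),
    end_rank = c(225L, 225L),
    copy_ratio = c(2, 0.5)
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(all(c("metastatic", "nonmetastatic") %in% names(cfg$n_samples)))
  if (any(cfg$n_samples[c("metastatic", "nonmetastatic")] < 1)) {
    stop_mn("need at least one sample in each bone-marrow condition", "mn_bad_config")
  }
  if (length(cfg$cells_per_sample) != 2 || any(cfg$cells_per_sample < 1) ||
      cfg$cells_per_sample[1] > cfg$cells_per_sample[2]) {
    stop_mn("cells_per_sample must be a valid positive range", "mn_bad_config")
  }
  if (!all(is.finite(cfg$base_composition)) || any(cfg$base_composition <= 0)) {
    stop_mn("base_composition concentrations must be positive and finite", "mn_bad_config")
  }
  if (!setequal(names(cfg$base_composition), names(cfg$composition_shift))) {
    stop_mn("composition_shift must name the same types as base_composition", "mn_bad_config")
  }
  if (any(cfg$composition_shift < 0) || all(cfg$composition_shift * cfg$base_composition == 0)) {
    stop_mn("degenerate composition: a cell type would have zero expected cells everywhere",
            "mn_bad_config")
  }
  if (cfg$tumor_fraction_metastatic < 0 || cfg$tumor_fraction_metastatic > 1 ||
      cfg$tumor_fraction_primary < 0 || cfg$tumor_fraction_primary > 1) {
    stop_mn("tumor fractions must lie in [0, 1]", "mn_bad_config")
  }
  if (cfg$nb_dispersion <= 0) stop_mn("nb_dispersion must be positive", "mn_bad_config")
  if (cfg$doublet_rate < 0 || cfg$doublet_rate > 1) {
    stop_mn("doublet_rate must lie in [0, 1]", "mn_bad_config")
  }
  genes_per_chrom <- cfg$n_genes %/% cfg$n_chromosomes
  seg <- cfg$cnv_segments
  if (nrow(seg)) {
    ok_chrom <- seg$chromosome %in% paste0("chr", seq_len(cfg$n_chromosomes))
    if (!all(ok_chrom) || any(seg$start_rank < 1) || any(seg$end_rank > genes_per_chrom) ||
        any(seg$start_rank > seg$end_rank) || any(seg$copy_ratio <= 0)) {
      stop_mn("cnv_segments must lie within the ordered gene index of their chromosome",
              "mn_bad_config")
    }
  }
  invisible(cfg)
}

# gene universe: even split over chromosomes, ordered start coordinates
build_gene_table <- function(cfg) {
  per <- cfg$n_genes %/% cfg$n_chromosomes
  n <- per * cfg$n_chromosomes
  tibble::tibble(
    gene_id = sprintf("g%05d", seq_len(n)),
    symbol = sprintf("GENE%05d", seq_len(n)),
    chromosome = rep(paste0("chr", seq_len(cfg$n_chromosomes)), each = per),
    start = rep(seq_len(per), times = cfg$n_chromosomes) * 10000L,
    rank = rep(seq_len(per), times = cfg$n_chromosomes)
  )
}

# assign marker and signature genes: disjoint picks from the upper half of
# baseline abundance, avoiding chromosomes that carry CNV segments so the
# planted DE ground truth is unconfounded
assign_special_genes <- function(cfg, genes, baseline) {
  cnv_chroms <- unique(cfg$cnv_segments$chromosome)
  eligible <- which(!(genes$chromosome %in% cnv_chroms) & baseline >= stats::median(baseline))
  need <- sum(cfg$cell_type_catalog$n_markers) + cfg$n_signature_genes
  if (length(eligible) < need) {
    stop_mn("gene universe too small for the requested marker/signature genes", "mn_bad_config")
  }
  picks <- sample(eligible, need)
  out <- list()
  i <- 0
  for (k in seq_len(nrow(cfg$cell_type_catalog))) {
    nm <- cfg$cell_type_catalog$n_markers[k]
    out[[cfg$cell_type_catalog$type[k]]] <- picks[i + seq_len(nm)]
    i <- i + nm
  }
  out$signature <- picks[i + seq_len(cfg$n_signature_genes)]
  out
}

# expected relative expression profile (sums to 1) for a cell of given type
# and condition, given baseline and the special-gene assignment
expected_profile <- function(cfg, type, condition, baseline, special, genes) {
  w <- baseline
  cat_row <- match(type, cfg$cell_type_catalog$type)
  if (!is.na(cat_row)) {
    w[special[[type]]] <- w[special[[type]]] * cfg$cell_type_catalog$marker_fold[cat_row]
  }
  if (type == "tumor") {
    if (condition == "metastatic") {
      w[special$signature] <- w[special$signature] * cfg$signature_fold
    }
    seg <- cfg$cnv_segments
    if (nrow(seg)) {
      for (s in seq_len(nrow(seg))) {
        idx <- which(genes$chromosome == seg$chromosome[s] &
                       genes$rank >= seg$start_rank[s] & genes$rank <= seg$end_rank[s])
        w[idx] <- w[idx] * seg$copy_ratio[s]
      }
    }
  }
  w / sum(w)
}

#' Expected per-gene mean counts for a cell
#'
#' The generator's own statement of each cell's expected expression:
#' baseline x type-marker folds x (metastatic tumor only) signature folds x
#' (tumor only) CNV copy ratios, renormalized to a relative profile and
#' scaled by the expected library size.  Used by the mean-convergence
#' property tests.
#'
#' @param sim A cohort returned by [generate_sc_cohort()].
#' @param type,condition Cell type and condition of the hypothetical cell.
#' @param library_size Expected total counts of the cell.
#' @return Numeric vector of expected counts, one per gene.
#' @export
expected_cell_means <- function(sim, type, condition, library_size) {
  cfg <- sim$config
  p <- expected_profile(cfg, type, condition, sim$internal$baseline,
                        sim$internal$special, sim$genes)
  p * library_size
}

#' Generate a synthetic single-cell cohort with known ground truth
#'
#' Draws a multi-sample cohort under the configured design: per-sample cell
#' counts and Dirichlet-multinomial cell-type compositions (shifted in the
#' metastatic arm), tumor cells only in metastatic and primary samples,
#' negative-binomial counts around each cell's expected profile, log-normal
#' library sizes, and a fraction of barcodes rebuilt as two-cell doublets
#' with high simulated doublet scores.  Fully reproducible from
#' `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A list with `counts` (dgCMatrix, symbols x cells), `cells`,
#'   `genes` tibbles, `truth` (per-cell types and doublet flags, per-gene DE
#'   labels per comparison, CNV segments, signature/marker gene sets) and
#'   `config`.
#' @export
generate_sc_cohort <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, generate_sc_cohort_impl(config))
}

generate_sc_cohort_impl <- function(cfg) {
  genes <- build_gene_table(cfg)
  n_genes <- nrow(genes)
  baseline <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
  special <- assign_special_genes(cfg, genes, baseline)

  types <- names(cfg$base_composition)
  profiles <- list()
  for (tp in c(types, "tumor")) {
    for (cond in c("metastatic", "nonmetastatic", "primary")) {
      profiles[[paste(tp, cond, sep = ".")]] <-
        expected_profile(cfg, tp, cond, baseline, special, genes)
    }
  }

  conditions <- c("metastatic", "nonmetastatic", "primary")
  n_by_cond <- vapply(conditions, function(cd) {
    if (cd %in% names(cfg$n_samples)) as.integer(cfg$n_samples[[cd]]) else 0L
  }, integer(1))

  cell_rows <- list()
  count_cols <- list()
  cell_counter <- 0L
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    tf <- switch(cond,
                 metastatic = cfg$tumor_fraction_metastatic,
                 nonmetastatic = 0,
                 primary = cfg$tumor_fraction_primary)
    for (si in seq_len(n_by_cond[ci])) {
      sample_id <- sprintf("%s_s%02d", cond, si)
      n_cells <- cfg$cells_per_sample[1] +
        sample.int(cfg$cells_per_sample[2] - cfg$cells_per_sample[1] + 1L, 1) - 1L
      alpha <- cfg$base_composition
      if (cond == "metastatic") alpha <- alpha * cfg$composition_shift[names(alpha)]
      gam <- stats::setNames(stats::rgamma(length(alpha), shape = alpha), names(alpha))
      props <- (gam / sum(gam)) * (1 - tf)
      type_prob <- c(props, tumor = tf)
      cell_types <- sample(names(type_prob), n_cells, replace = TRUE, prob = type_prob)
      lib <- stats::rlnorm(n_cells, cfg$library_size_lognormal[1], cfg$library_size_lognormal[2])
      mu_mat <- vapply(seq_len(n_cells), function(j) {
        profiles[[paste(cell_types[j], cond, sep = ".")]] * lib[j]
      }, numeric(n_genes))
      cnt <- matrix(stats::rnbinom(n_genes * n_cells, size = 1 / cfg$nb_dispersion,
                                   mu = as.vector(mu_mat)),
                    nrow = n_genes)
      ids <- sprintf("%s_c%04d", sample_id, seq_len(n_cells))
      cell_rows[[sample_id]] <- tibble::tibble(
        cell_id = ids, sample_id = sample_id, condition = cond,
        cell_type = cell_types, expected_library = lib
      )
      count_cols[[sample_id]] <- cnt
      cell_counter <- cell_counter + n_cells
    }
  }
  cells <- dplyr::bind_rows(cell_rows)
  counts <- do.call(cbind, count_cols)
  colnames(counts) <- cells$cell_id
  rownames(counts) <- genes$symbol

  # doublets: replace a random subset of barcodes with the NB draw around the
  # average of two same-sample parents' expected profiles
  n_total <- nrow(cells)
  is_doublet <- logical(n_total)
  n_doub <- round(cfg$doublet_rate * n_total)
  if (n_doub > 0) {
    doub_idx <- sample(n_total, n_doub)
    is_doublet[doub_idx] <- TRUE
    for (j in doub_idx) {
      cand <- setdiff(which(cells$sample_id == cells$sample_id[j]), j)
      partner <- if (length(cand) == 0) j else if (length(cand) == 1) cand else sample(cand, 1)
      p1 <- profiles[[paste(cells$cell_type[j], cells$condition[j], sep = ".")]]
      p2 <- profiles[[paste(cells$cell_type[partner], cells$condition[partner], sep = ".")]]
      mu <- (p1 + p2) / 2 * cells$expected_library[j]
      counts[, j] <- stats::rnbinom(n_genes, size = 1 / cfg$nb_dispersion, mu = mu)
    }
  }
  doublet_score <- ifelse(is_doublet, stats::runif(n_total, 0.55, 0.95),
                          stats::runif(n_total, 0.01, 0.30))

  counts <- as_count_matrix(counts)
  cells <- cells |>
    dplyr::mutate(doublet_score = doublet_score,
                  total_umis = as.integer(Matrix::colSums(counts))) |>
    dplyr::select(-"expected_library")

  truth <- list(
    cells = tibble::tibble(cell_id = cells$cell_id, true_type = cells$cell_type,
                           is_doublet = is_doublet),
    de = dplyr::bind_rows(
      tibble::tibble(symbol = genes$symbol[special$signature],
                     comparison = "metastatic_tumor_vs_primary_tumor",
                     fold_change = cfg$signature_fold),
      purrr::map_dfr(cfg$cell_type_catalog$type, function(tp) {
        k <- match(tp, cfg$cell_type_catalog$type)
        tibble::tibble(symbol = genes$symbol[special[[tp]]],
                       comparison = paste0(tp, "_vs_rest"),
                       fold_change = cfg$cell_type_catalog$marker_fold[k])
      })
    ),
    cnv = cfg$cnv_segments,
    signature_genes = genes$symbol[special$signature],
    marker_genes = lapply(special[cfg$cell_type_catalog$type],
                          function(ix) genes$symbol[ix])
  )

  list(counts = counts, cells = cells, genes = genes, truth = truth, config = cfg,
       internal = list(baseline = baseline, special = special))
}

#' Generate a bulk expression cohort with signature-dependent survival
#'
#' Each patient receives a standardized latent signature burden; signature
#' genes gain `burden x effect_size` on the log-expression scale; survival
#' times are exponential with hazard proportional to
#' `hazard_ratio^burden`, independently uniformly censored.
#'
#' @param n_patients Number of patients (>= 4).
#' @param signature A [gene_set()] or character vector of signature genes.
#' @param hazard_ratio Hazard multiplier per unit (SD) of burden.
#' @param seed Integer seed.
#' @param n_background Background (non-signature) genes simulated.
#' @param effect_size Log-expression shift per unit burden on signature genes.
#' @param baseline_hazard Event rate at burden 0 (per study time unit).
#' @param censor_range Uniform censoring window.
#' @return A list with `expr` (genes x patients matrix of log-scale values),
#'   `survival` (tibble `patient_id`, `time`, `event`) and `truth`
#'   (per-patient burden).
#' @export
generate_bulk_cohort <- function(n_patients, signature, hazard_ratio, seed = 1L,
                                 n_background = 470L, effect_size = 1,
                                 baseline_hazard = log(2) / 36,
                                 censor_range = c(12, 120)) {
  if (n_patients < 4) stop_mn("need at least 4 patients", "mn_bad_input")
  if (inherits(signature, "gene_set")) signature <- signature$genes
  signature <- unique(as.character(signature))
  if (length(signature) == 0) stop_mn("signature must be non-empty", "mn_bad_input")
  if (hazard_ratio <= 0) stop_mn("hazard_ratio must be positive", "mn_bad_input")
  withr::with_seed(seed, {
    genes <- c(signature, sprintf("BG%04d", seq_len(n_background)))
    burden <- as.vector(scale(stats::rnorm(n_patients)))
    base <- stats::rnorm(length(genes), mean = 5, sd = 1)
    expr <- matrix(stats::rnorm(length(genes) * n_patients, sd = 0.5),
                   nrow = length(genes)) + base
    expr[seq_along(signature), ] <- expr[seq_along(signature), ] +
      rep(burden * effect_size, each = length(signature))
    rownames(expr) <- genes
    colnames(expr) <- sprintf("patient%03d", seq_len(n_patients))
    rate <- baseline_hazard * hazard_ratio^burden
    t_event <- stats::rexp(n_patients, rate = rate)
    t_cens <- stats::runif(n_patients, censor_range[1], censor_range[2])
    surv <- tibble::tibble(
      patient_id = colnames(expr),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    )
    list(expr = expr, survival = surv,
         truth = tibble::tibble(patient_id = colnames(expr), burden = burden))
  })
}

#' Generate a synthetic ligand-receptor pair table
#'
#' Stands in for a curated ligand-receptor database: draws unique
#' `(ligand, receptor)` pairs (ligand != receptor, each gene used once) from
#' the supplied gene universe, deterministically given the seed.
#'
#' @param n_pairs Number of pairs.
#' @param gene_universe Character vector of gene symbols, or a gene table
#'   with a `symbol` column.
#' @param seed Integer seed.
#' @return A tibble (`pair_id`, `ligand`, `receptor`).
#' @export
generate_lr_database <- function(n_pairs, gene_universe, seed = 1L) {
  if (is.data.frame(gene_universe)) gene_universe <- gene_universe$symbol
  gene_universe <- unique(as.character(gene_universe))
  if (n_pairs < 1) stop_mn("n_pairs must be positive", "mn_bad_input")
  if (length(gene_universe) < 2 * n_pairs) {
    stop_mn("gene universe too small for the requested number of unique pairs",
            "mn_bad_input")
  }
  withr::with_seed(seed, {
    picks <- sample(gene_universe, 2 * n_pairs)
    tibble::tibble(
      pair_id = sprintf("LR%04d", seq_len(n_pairs)),
      ligand = picks[seq_len(n_pairs)],
      receptor = picks[n_pairs + seq_len(n_pairs)]
    )
  })
}

#' Write a simulated cohort to disk
#'
#' Emits the standard triplet bundle (MTX + gene/cell tables), the ground
#' truth as delimited tables, and the configuration as JSON.
#'
#' @param sim A cohort from [generate_sc_cohort()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(sim, dir) {
  paths <- write_mtx_bundle(sim$counts, sim$genes, sim$cells, dir)
  tdir <- file.path(dir, "truth")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(sim$truth$cells, file.path(tdir, "truth_cells.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$de, file.path(tdir, "truth_de.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$cnv, file.path(tdir, "truth_cnv.tsv"), progress = FALSE)
  cfg <- sim$config
  cfg$cell_type_catalog <- as.data.frame(cfg$cell_type_catalog)
  cfg$cnv_segments <- as.data.frame(cfg$cnv_segments)
  jsonlite::write_json(unclass(cfg), file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, truth = tdir))
}
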