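# End-to-end orchestration: scenario/inputs -> quantile normalization ->
# per-condition DE gene sets -> miRNA filter/normalize/DE -> hub ranking,
# with a manifest sufficient to re-run the exact computation.

#' Pipeline configuration
#'
#' Inputs come either from files (`paths`) or from the bundled synthetic
#' generator (`scenario`, used when `paths` is NULL). All thresholds
#' default to the pipeline's canonical values: FDR < 0.1 and fold change
#' >= 1.5 for genes, raw count >= 25 in some sample and Student's t
#' p < 0.05 for miRNAs, 10,000 Monte Carlo iterations, hub significance at
#' p < 0.05.
#'
#' @param paths NULL, or a named list with expression, groups, mirna_counts,
#'   library_sizes, utrs, mirnas (file paths)
#' @param scenario a `scenario_config` used when `paths` is NULL
#' @param reference reference group label, default "naive"
#' @param conditions condition labels to test against the reference;
#'   default: every non-reference group
#' @param outdir output directory
#' @param fdr_max,fold_min gene significance gate
#' @param min_count,count_rule miRNA low-count filter
#' @param scale,pseudocount miRNA normalization and log transform
#' @param mirna_p_max miRNA significance threshold
#' @param n_iterations,alpha,site_types hub test parameters
#' @param rng_seed seed for the Monte Carlo resampling
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(paths = NULL, scenario = scenario_config(),
                            reference = "naive", conditions = NULL,
                            outdir = tempfile("mirhub_run_"),
                            fdr_max = 0.1, fold_min = 1.5,
                            min_count = 25, count_rule = "any",
                            scale = 1e6, pseudocount = 1,
                            mirna_p_max = 0.05,
                            n_iterations = 10000L, alpha = 0.05,
                            site_types = DEFAULT_SITE_TYPES,
                            rng_seed = 1L) {
  structure(list(paths = paths, scenario = scenario, reference = reference,
                 conditions = conditions, outdir = outdir,
                 fdr_max = fdr_max, fold_min = fold_min,
                 min_count = min_count, count_rule = count_rule,
                 scale = scale, pseudocount = pseudocount,
                 mirna_p_max = mirna_p_max,
                 n_iterations = as.integer(n_iterations), alpha = alpha,
                 site_types = site_types, rng_seed = rng_seed),
            class = "pipeline_config")
}

load_pipeline_inputs <- function(config) {
  if (is.null(config$paths)) {
    return(generate_hub_scenario(config$scenario))
  }
  need <- c("expression", "groups", "mirna_counts", "library_sizes",
            "utrs", "mirnas")
  miss <- setdiff(need, names(config$paths))
  if (length(miss)) stop("missing input path(s): ", paste(miss, collapse = ", "))
  absent <- !vapply(config$paths[need], file.exists, logical(1))
  if (any(absent))
    stop("input file(s) not found: ",
         paste(unlist(config$paths[need][absent]), collapse = ", "))
  groups <- read_keyed_tsv(config$paths$groups)
  lib <- read_keyed_tsv(config$paths$library_sizes, mode = "numeric")
  expr <- read_matrix_tsv(config$paths$expression)
  counts <- read_matrix_tsv(config$paths$mirna_counts)
  list(expression = expression_matrix(expr, groups),
       mirna_counts = mirna_count_table(counts, lib, groups),
       utrs = utr_set(read_fasta(config$paths$utrs)),
       mirnas = read_fasta(config$paths$mirnas),
       truth = NULL, config = NULL)
}

#' Run the full hub-identification pipeline
#'
#' Stages: load (or simulate) inputs; quantile-normalize expression; per
#' condition, t-test against the reference and gate into up/down gene sets;
#' filter, normalize and test miRNA counts; run the Monte Carlo hub test
#' pairing up-regulated miRNAs with down-regulated genes and vice versa;
#' compute the cross-condition gene-set overlap. All result tables plus a
#' manifest.json (parameters, seeds, input/output checksums; no
#' timestamps, so reruns are byte-identical) are written under
#' `config$outdir`.
#'
#' @param config a `pipeline_config`
#' @return invisibly, a list with per-condition results and the manifest
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- load_pipeline_inputs(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  log_counts <- list()

  groups <- inputs$expression$groups
  conditions <- config$conditions
  if (is.null(conditions))
    conditions <- setdiff(unique(groups), config$reference)
  if (!config$reference %in% groups)
    stop("reference group not present: ", config$reference)

  norm_expr <- quantile_normalize(inputs$expression)
  write_matrix_tsv(norm_expr$values, out("expression_normalized.tsv"), "gene_id")

  gene_sets <- list(); de_tables <- list()
  for (cond in conditions) {
    de <- differential_expression(norm_expr, cond, config$reference)
    de_tables[[cond]] <- de
    write_tsv(de, out(sprintf("de_genes_%s.tsv", cond)))
    gs <- significant_genes(de, config$fdr_max, config$fold_min, label = cond)
    gene_sets[[cond]] <- gs
    write_tsv(as.data.frame(gs), out(sprintf("gene_set_%s.tsv", cond)))
    log_counts[[paste0("genes_tested_", cond)]] <- nrow(de)
    log_counts[[paste0("genes_significant_", cond)]] <- nrow(gs)
  }

  overlap <- NULL
  if (length(conditions) >= 2L) {
    overlap <- overlap_analysis(gene_sets[[conditions[1L]]],
                                gene_sets[[conditions[2L]]])
    jsonlite::write_json(overlap, out("overlap.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  filtered <- filter_low_counts(inputs$mirna_counts, config$min_count,
                                config$count_rule)
  log_counts$mirnas_input <- nrow(inputs$mirna_counts$counts)
  log_counts$mirnas_dropped_low_count <- length(attr(filtered, "dropped"))
  cpm <- normalize_counts(filtered, config$scale)
  write_matrix_tsv(cpm, out("mirna_cpm.tsv"), "mirna_id")

  mirna_tables <- list(); hub_tables <- list()
  for (i in seq_along(conditions)) {
    cond <- conditions[i]
    md <- mirna_de(cpm, filtered$groups, cond, config$reference,
                   p_max = config$mirna_p_max,
                   pseudocount = config$pseudocount)
    mirna_tables[[cond]] <- md
    write_tsv(md, out(sprintf("mirna_de_%s.tsv", cond)))
    log_counts[[paste0("mirnas_significant_", cond)]] <- sum(md$significant)

    up <- gene_sets[[cond]][gene_sets[[cond]]$direction == "up", , drop = FALSE]
    down <- gene_sets[[cond]][gene_sets[[cond]]$direction == "down", , drop = FALSE]
    hub_cfg <- hub_test_config(
      n_iterations = config$n_iterations,
      rng_seed = if (is.null(config$rng_seed)) NULL
                 else (as.integer(config$rng_seed) + 1000L * i) %% .Machine$integer.max,
      site_types = config$site_types)
    hubs <- suppressWarnings(
      identify_hubs(md, up$gene_id, down$gene_id, inputs$utrs,
                    inputs$mirnas, hub_cfg, alpha = config$alpha))
    hub_tables[[cond]] <- hubs
    write_tsv(hubs, out(sprintf("hubs_%s.tsv", cond)))
  }

  outputs <- list.files(config$outdir, full.names = TRUE)
  manifest <- list(
    package = "mirhub",
    version = as.character(utils::packageVersion("mirhub")),
    parameters = config[setdiff(names(config),
                                c("paths", "scenario", "outdir"))],
    scenario_seed = if (is.null(config$paths)) config$scenario$rng_seed else NULL,
    inputs = if (!is.null(config$paths))
      lapply(config$paths, function(p) unname(tools::md5sum(p))) else "simulated",
    stage_counts = log_counts,
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(gene_sets = gene_sets, de_tables = de_tables,
                 overlap = overlap, mirna_de = mirna_tables,
                 hubs = hub_tables, truth = inputs$truth,
                 manifest = manifest, outdir = config$outdir))
}
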