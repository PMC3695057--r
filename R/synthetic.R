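# Synthetic-data generator with planted ground truth. Emulates the paired
# design the pipeline expects: a naive reference and two inflamed
# conditions, where condition 1 down-regulates a "hub" miRNA whose planted
# targets go up, and condition 2 up-regulates a second hub whose targets go
# down. Every generator is a pure function of (config, seed).

#' Scenario configuration for the synthetic generator
#'
#' Defaults describe the simulated world: a desk-scale gene universe
#' (2,000 genes, 50 miRNAs), 3'UTR lengths ~ Normal(800, 200) truncated at
#' 30 nt, three groups of four replicates, per-condition hubs with 40% of
#' genes as planted 8mer targets shifted by 1 log2 unit, replicate noise of
#' 0.25 log2 units, and negative-binomial miRNA counts with dispersion 0.2
#' and a 3.5 log2-unit (~11-fold) hub shift, large enough that a
#' 4-replicate Student's t reliably detects the hub despite the NB
#' dispersion, as for the most significantly regulated miRNAs
#'
#' @param n_genes number of genes (UTRs)
#' @param n_mirnas number of miRNAs
#' @param utr_length_mean,utr_length_sd UTR length distribution, nt
#' @param gc_fraction GC content of generated sequence, in [0,1]
#' @param groups named integer vector: ordered group labels -> replicate
#'   counts; the first label is the reference
#' @param hub_spec named list (one entry per non-reference condition) of
#'   lists with fields mirna_id (NULL = auto-assign), direction ("up"/"down"
#'   = the hub miRNA's own regulation), target_fraction, target_log2_effect
#'   (magnitude of the planted target shift; targets move opposite to the
#'   hub), site_type, mirna_log2fc (magnitude of the hub's count shift)
#' @param noise_sd replicate noise on the log2 expression scale
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion)
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-gene mean
#'   log2 expression
#' @param mirna_meanlog,mirna_sdlog log-normal distribution of baseline
#'   miRNA mean counts
#' @param library_size_range per-sample uniquely mapped read totals are
#'   drawn uniformly from this range
#' @param rng_seed integer seed
#' @return a `scenario_config` list
#' @export
scenario_config <- function(n_genes = 2000L, n_mirnas = 50L,
                            utr_length_mean = 800, utr_length_sd = 200,
                            gc_fraction = 0.5,
                            groups = c(naive = 4L, cond1 = 4L, cond2 = 4L),
                            hub_spec = list(
                              cond1 = list(mirna_id = NULL, direction = "down",
                                           target_fraction = 0.4,
                                           target_log2_effect = 1.0,
                                           site_type = "8mer",
                                           mirna_log2fc = 3.5),
                              cond2 = list(mirna_id = NULL, direction = "up",
                                           target_fraction = 0.4,
                                           target_log2_effect = 1.0,
                                           site_type = "8mer",
                                           mirna_log2fc = 3.5)),
                            noise_sd = 0.25, nb_dispersion = 0.2,
                            baseline_log2_mean = 8, baseline_log2_sd = 2,
                            mirna_meanlog = log(500), mirna_sdlog = 1,
                            library_size_range = c(8e5, 1.2e6),
                            rng_seed = 1L) {
  stopifnot(n_genes >= 1L, n_mirnas >= 1L, utr_length_mean >= 30)
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0,1]")
  if (any(groups < 2L)) stop("every group needs >=2 replicates")
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stop("groups must be uniquely named")
  for (cond in names(hub_spec)) {
    hs <- hub_spec[[cond]]
    if (!cond %in% names(groups)) stop("hub condition not in groups: ", cond)
    if (!hs$direction %in% c("up", "down")) stop("hub direction must be up/down")
    if (hs$target_fraction < 0 || hs$target_fraction > 1)
      stop("target_fraction must be in [0,1]")
    if (hs$target_fraction > 0 && hs$target_fraction * n_genes < 1)
      stop("target_fraction * n_genes must be >= 1")
    if (!is.finite(hs$target_log2_effect) || !is.finite(hs$mirna_log2fc))
      stop("effect sizes must be finite")
  }
  stopifnot(is.finite(noise_sd), noise_sd >= 0, nb_dispersion > 0)
  structure(list(n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
                 utr_length_mean = utr_length_mean, utr_length_sd = utr_length_sd,
                 gc_fraction = gc_fraction, groups = groups,
                 hub_spec = hub_spec, noise_sd = noise_sd,
                 nb_dispersion = nb_dispersion,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 mirna_meanlog = mirna_meanlog, mirna_sdlog = mirna_sdlog,
                 library_size_range = library_size_range,
                 rng_seed = rng_seed),
            class = "scenario_config")
}

## base sampler honouring gc_fraction
random_dna <- function(total_nt, gc_fraction) {
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  sample(DNA_BASES, total_nt, replace = TRUE, prob = p)
}

## lengths ~ round(Normal(mean, sd)), redrawn until >= min_len
sample_lengths <- function(n, mean, sd, min_len = 30L) {
  len <- round(stats::rnorm(n, mean, sd))
  while (any(len < min_len)) {
    bad <- len < min_len
    len[bad] <- round(stats::rnorm(sum(bad), mean, sd))
  }
  as.integer(len)
}

#' Generate a synthetic 3'UTR set
#'
#' One random sequence per gene; lengths ~ Normal(mean, sd) rounded and
#' truncated (by redrawing) at >= 30 nt; base composition set by
#' `gc_fraction`.
#'
#' @param config a `scenario_config`
#' @return named character vector of UTRs (gene_0001, ...)
#' @export
generate_utr_set <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$rng_seed, {
    len <- sample_lengths(config$n_genes, config$utr_length_mean,
                          config$utr_length_sd)
    bases <- random_dna(sum(len), config$gc_fraction)
    seqs <- vapply(split(bases, rep.int(seq_along(len), len)),
                   paste, "", collapse = "")
    names(seqs) <- sprintf("gene_%04d", seq_len(config$n_genes))
    seqs
  })
}

#' Generate a set of random mature miRNA sequences
#'
#' @param n number of miRNAs
#' @param length mature length, default 22 nt
#' @param rng_seed integer seed (NULL = current stream)
#' @return named character vector (mir-001, ...)
#' @export
generate_mirna_set <- function(n, length = 22L, rng_seed = NULL) {
  with_seed(rng_seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(DNA_BASES, length, replace = TRUE), collapse = ""), "")
    names(seqs) <- sprintf("mir-%03d", seq_len(n))
    seqs
  })
}

#' Plant exact seed sites into a fraction of UTRs
#'
#' A uniformly chosen fraction of genes (nearest integer, ties rounded up)
#' receives one exact site of `site_type` for `mirna` at a random position,
#' overwriting the bases there (UTR lengths are unchanged, keeping the
#' length-normalization contract clean). Chance sites arising elsewhere are
#' left as-is and not recorded.
#'
#' @param utrs named character vector of UTRs
#' @param mirna a `mirna_sequence` or mature sequence string
#' @param fraction proportion of genes to receive a site, in [0,1]
#' @param site_type planted site type, default "8mer"
#' @param rng_seed integer seed (NULL = current stream)
#' @return list: `utrs` (modified set) and `truth` (data.frame gene_id,
#'   start 0-based, site_type)
#' @export
plant_seed_sites <- function(utrs, mirna, fraction, site_type = "8mer",
                             rng_seed = NULL) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0,1]")
  site_type <- match.arg(site_type, SITE_TYPES)
  word <- site_words(mirna)[[site_type]]
  if (nchar(word) > min(nchar(utrs)))
    stop("site word longer than shortest UTR")
  n_recip <- round_half_up(fraction * length(utrs))
  truth <- data.frame(gene_id = character(), start = integer(),
                      site_type = character(), stringsAsFactors = FALSE)
  if (n_recip == 0L) return(list(utrs = utrs, truth = truth))
  with_seed(rng_seed, {
    recip <- sample(names(utrs), n_recip)
    pos <- vapply(nchar(utrs[recip]) - nchar(word) + 1L,
                  function(k) sample.int(k, 1L), integer(1))
    seqs <- utrs[recip]
    substr(seqs, pos, pos + nchar(word) - 1L) <- word
    utrs[recip] <- seqs
    list(utrs = utrs,
         truth = data.frame(gene_id = recip, start = as.integer(pos - 1L),
                            site_type = site_type, stringsAsFactors = FALSE,
                            row.names = NULL))
  })
}

#' Generate a complete hub scenario with planted ground truth
#'
#' Produces every input the pipeline consumes: a log2 expression matrix
#' (baseline Normal(mu_g, noise_sd) per replicate; planted targets shifted
#' opposite to their hub in the matching condition), a negative-binomial
#' miRNA count table with per-sample library sizes and the hub miRNAs
#' shifted in their configured direction, the UTR set with planted sites,
#' the mature miRNA set, and a truth table.
#'
#' @param config a `scenario_config`
#' @return list: `expression` (expression_matrix), `mirna_counts`
#'   (mirna_counts), `utrs`, `mirnas`, `truth` (list: hubs, targets, sites),
#'   `config`
#' @export
generate_hub_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$rng_seed, {
    mirnas <- generate_mirna_set(config$n_mirnas)
    len <- sample_lengths(config$n_genes, config$utr_length_mean,
                          config$utr_length_sd)
    bases <- random_dna(sum(len), config$gc_fraction)
    utrs <- vapply(split(bases, rep.int(seq_along(len), len)),
                   paste, "", collapse = "")
    names(utrs) <- sprintf("gene_%04d", seq_len(config$n_genes))

    # assign hub miRNAs (auto: first free miRNA per condition) and plant
    # their target sites into disjoint gene subsets
    hub_ids <- character(0)
    truth_hubs <- list(); truth_targets <- list(); truth_sites <- list()
    free_genes <- names(utrs)
    for (cond in names(config$hub_spec)) {
      hs <- config$hub_spec[[cond]]
      id <- hs$mirna_id
      if (is.null(id)) id <- setdiff(names(mirnas), hub_ids)[1L]
      if (!id %in% names(mirnas)) stop("hub miRNA not in miRNA set: ", id)
      hub_ids <- c(hub_ids, id)
      n_recip <- round_half_up(hs$target_fraction * config$n_genes)
      if (n_recip > length(free_genes)) stop("not enough genes for disjoint hub targets")
      recip <- sample(free_genes, n_recip)
      free_genes <- setdiff(free_genes, recip)
      planted <- plant_seed_sites(utrs[recip], mirnas[[id]],
                                  fraction = 1, site_type = hs$site_type)
      utrs[recip] <- planted$utrs
      truth_hubs[[cond]] <- data.frame(condition = cond, mirna_id = id,
                                       direction = hs$direction,
                                       stringsAsFactors = FALSE)
      truth_targets[[id]] <- recip
      truth_sites[[id]] <- cbind(mirna_id = id, planted$truth)
    }

    # sample layout
    groups <- rep(names(config$groups), config$groups)
    samples <- sprintf("%s_r%d", groups,
                       unlist(lapply(config$groups, seq_len)))
    names(groups) <- samples

    # expression: baseline + planted target shifts + replicate noise
    mu <- stats::rnorm(config$n_genes, config$baseline_log2_mean,
                       config$baseline_log2_sd)
    expr <- matrix(mu, nrow = config$n_genes, ncol = length(samples),
                   dimnames = list(names(utrs), samples))
    for (cond in names(config$hub_spec)) {
      hs <- config$hub_spec[[cond]]
      id <- truth_hubs[[cond]]$mirna_id
      shift <- if (hs$direction == "down") hs$target_log2_effect else -hs$target_log2_effect
      expr[truth_targets[[id]], groups == cond] <-
        expr[truth_targets[[id]], groups == cond] + shift
    }
    expr <- expr + matrix(stats::rnorm(length(expr), 0, config$noise_sd),
                          nrow = nrow(expr))

    # miRNA counts: NB around log-normal baselines, hub shifted in its
    # condition, means scaled by library size
    base_mean <- stats::rlnorm(config$n_mirnas, config$mirna_meanlog,
                               config$mirna_sdlog)
    lib <- round(stats::runif(length(samples), config$library_size_range[1L],
                              config$library_size_range[2L]))
    names(lib) <- samples
    log2fc <- matrix(0, nrow = config$n_mirnas, ncol = length(samples),
                     dimnames = list(names(mirnas), samples))
    for (cond in names(config$hub_spec)) {
      hs <- config$hub_spec[[cond]]
      id <- truth_hubs[[cond]]$mirna_id
      log2fc[id, groups == cond] <-
        if (hs$direction == "up") hs$mirna_log2fc else -hs$mirna_log2fc
    }
    mu_counts <- base_mean * 2^log2fc *
      matrix(lib / mean(lib), nrow = config$n_mirnas,
             ncol = length(samples), byrow = TRUE)
    counts <- matrix(stats::rnbinom(length(mu_counts),
                                    mu = mu_counts,
                                    size = 1 / config$nb_dispersion),
                     nrow = config$n_mirnas,
                     dimnames = dimnames(log2fc))

    list(expression = expression_matrix(expr, groups),
         mirna_counts = mirna_count_table(counts, lib, groups),
         utrs = utrs, mirnas = mirnas,
         truth = list(hubs = do.call(rbind, truth_hubs),
                      targets = truth_targets,
                      sites = do.call(rbind, truth_sites)),
         config = config)
  })
}

#' Generate synthetic promoters with planted motif occurrences
#'
#' A fraction of promoters (nearest integer, ties up) receives the PWM
#' consensus word at a random position, on a random strand (minus-strand
#' plants overwrite with the reverse complement). Positions are recorded in
#' plus-strand 0-based coordinates, matching [scan_promoter()] output.
#'
#' @param n number of promoters
#' @param length promoter length, default 1500 nt
#' @param pwm a `pwm_model` supplying the consensus word
#' @param plant_fraction proportion of promoters to receive a plant
#' @param rng_seed integer seed (NULL = current stream)
#' @param gc_fraction background GC content
#' @return list: `promoters` (named character) and `truth` (data.frame id,
#'   offset 0-based, strand)
#' @export
generate_promoter_set <- function(n, length = 1500L, pwm, plant_fraction,
                                  rng_seed = NULL, gc_fraction = 0.5) {
  if (plant_fraction < 0 || plant_fraction > 1)
    stop("plant_fraction must be in [0,1]")
  word <- pwm_consensus(pwm)
  if (nchar(word) > length) stop("PWM wider than promoter length")
  with_seed(rng_seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(random_dna(length, gc_fraction), collapse = ""), "")
    names(seqs) <- sprintf("prom_%04d", seq_len(n))
    n_plant <- round_half_up(plant_fraction * n)
    truth <- data.frame(id = character(), offset = integer(),
                        strand = character(), stringsAsFactors = FALSE)
    if (n_plant > 0L) {
      ids <- sample(names(seqs), n_plant)
      pos <- sample.int(length - nchar(word) + 1L, n_plant, replace = TRUE)
      strand <- sample(c("+", "-"), n_plant, replace = TRUE)
      ins <- ifelse(strand == "+", word, dna_revcomp(word))
      s <- seqs[ids]
      substr(s, pos, pos + nchar(word) - 1L) <- ins
      seqs[ids] <- s
      truth <- data.frame(id = ids, offset = as.integer(pos - 1L),
                          strand = strand, stringsAsFactors = FALSE,
                          row.names = NULL)
    }
    list(promoters = seqs, truth = truth)
  })
}

#' Write a scenario bundle to disk as plain-text files
#'
#' Emits utrs.fasta, mirnas.fasta, expression.tsv, groups.tsv,
#' mirna_counts.tsv, library_sizes.tsv, truth_* tables, and a metadata.json
#' sidecar recording the seed and configuration.
#'
#' @param bundle output of [generate_hub_scenario()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_fasta(bundle$utrs, p("utrs.fasta"))
  write_fasta(bundle$mirnas, p("mirnas.fasta"))
  write_matrix_tsv(bundle$expression$values, p("expression.tsv"), "gene_id")
  write_tsv(data.frame(sample = names(bundle$expression$groups),
                       group = unname(bundle$expression$groups)),
            p("groups.tsv"))
  write_matrix_tsv(bundle$mirna_counts$counts, p("mirna_counts.tsv"), "mirna_id")
  write_tsv(data.frame(sample = names(bundle$mirna_counts$library_sizes),
                       library_size = unname(bundle$mirna_counts$library_sizes)),
            p("library_sizes.tsv"))
  write_tsv(bundle$truth$hubs, p("truth_hubs.tsv"))
  write_tsv(bundle$truth$sites, p("truth_sites.tsv"))
  cfg <- bundle$config
  jsonlite::write_json(cfg[setdiff(names(cfg), "hub_spec")],
                       p("metadata.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(dir)
}
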