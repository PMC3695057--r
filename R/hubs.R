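# Monte Carlo "regulatory hub" test. For a miRNA and a differentially
# expressed gene set, the observed statistic is X = T / L, the number of
# predicted targets in the set divided by the set's mean 3'UTR length in
# kilobases (length normalization removes the bias of long UTRs carrying
# more chance sites). The null resamples equally sized gene sets from the
# universe and recomputes X; the empirical p-value is the add-one right
# tail. Up-regulated miRNAs are tested against down-regulated genes and
# vice versa, the pairing expected of a repressive regulator.

#' Configuration for the hub enrichment test
#'
#' @param n_iterations Monte Carlo resamples, default 10000
#' @param rng_seed integer seed for reproducible resampling
#' @param site_types qualifying target-site types
#' @param universe optional character vector of gene IDs used as the
#'   resampling background; defaults to every gene with a UTR
#' @param length_weighted if TRUE, null gene sets are sampled with
#'   probability proportional to UTR length instead of uniformly (an
#'   alternative way to control UTR-length bias; off by default, where the
#'   control is division of T by mean UTR length on both sides)
#' @return a `hub_test_config` list
#' @export
hub_test_config <- function(n_iterations = 10000L, rng_seed = NULL,
                            site_types = DEFAULT_SITE_TYPES,
                            universe = NULL, length_weighted = FALSE) {
  stopifnot(n_iterations >= 1L)
  structure(list(n_iterations = as.integer(n_iterations),
                 rng_seed = rng_seed, site_types = site_types,
                 universe = universe, length_weighted = length_weighted),
            class = "hub_test_config")
}

#' Observed length-normalized target count
#'
#' T = number of predicted targets of `mirna` inside `gene_ids`;
#' L = mean 3'UTR length of `gene_ids` in kb; X = T / L (targets per kb of
#' average UTR).
#'
#' @param mirna a `mirna_sequence` or mature sequence string
#' @param gene_ids gene set of interest (character vector or `gene_set`)
#' @param utrs named character vector of UTRs covering all members
#' @param site_types qualifying site types
#' @return list with `T`, `L_kb`, `X`
#' @export
observed_statistic <- function(mirna, gene_ids, utrs,
                               site_types = DEFAULT_SITE_TYPES) {
  if (inherits(gene_ids, "gene_set")) gene_ids <- gene_ids$gene_id
  if (length(gene_ids) == 0L) stop("gene set of interest is empty")
  missing_utr <- setdiff(gene_ids, names(utrs))
  if (length(missing_utr))
    stop("gene set members without a UTR: ",
         paste(utils::head(missing_utr, 10L), collapse = ", "))
  targets <- predict_targets(mirna, utrs[gene_ids], site_types = site_types)
  T_obs <- nrow(targets)
  L_kb <- mean(nchar(utrs[gene_ids])) / 1000
  list(T = T_obs, L_kb = L_kb, X = T_obs / L_kb)
}

## Internal fast path shared by null_distribution / identify_hubs:
## statistic from a precomputed target indicator + UTR lengths.
stat_from_indicator <- function(is_target, len_nt) {
  sum(is_target) / (mean(len_nt) / 1000)
}

#' Monte Carlo null distribution of the hub statistic
#'
#' Each of `n_iterations` draws samples `set_size` genes from the universe
#' without replacement and recomputes X = T / L on the drawn set — the
#' length normalization is applied to every null draw exactly as to the
#' observed set.
#'
#' @param mirna a `mirna_sequence` or mature sequence string
#' @param set_size size of each resampled gene set
#' @param utrs named character vector of UTRs (the universe lives here)
#' @param config a `hub_test_config`
#' @return numeric vector of `n_iterations` null statistics
#' @export
null_distribution <- function(mirna, set_size, utrs, config = hub_test_config()) {
  universe <- if (is.null(config$universe)) names(utrs) else config$universe
  stopifnot(all(universe %in% names(utrs)))
  if (set_size > length(universe))
    stop("set_size exceeds universe size")
  targets <- predict_targets(mirna, utrs[universe],
                             site_types = config$site_types)
  is_target <- universe %in% targets$gene_id
  len_nt <- nchar(utrs[universe])
  draw_null(is_target, len_nt, set_size, config)
}

draw_null <- function(is_target, len_nt, set_size, config) {
  n_univ <- length(is_target)
  prob <- if (isTRUE(config$length_weighted)) len_nt / sum(len_nt) else NULL
  with_seed(config$rng_seed, {
    vapply(seq_len(config$n_iterations), function(i) {
      idx <- sample.int(n_univ, set_size, replace = FALSE, prob = prob)
      stat_from_indicator(is_target[idx], len_nt[idx])
    }, numeric(1))
  })
}

#' Add-one empirical p-value (right tail)
#'
#' p = (1 + #\{r : X_r >= X\}) / (N + 1). Never zero; exactly representable
#' as (k+1)/(N+1).
#'
#' @param observed observed statistic X
#' @param null_draws numeric vector of null statistics
#' @return empirical p-value in [1/(N+1), 1]
#' @export
empirical_pvalue <- function(observed, null_draws) {
  stopifnot(length(null_draws) >= 1L)
  (1 + sum(null_draws >= observed)) / (length(null_draws) + 1)
}

#' Full hub test for one miRNA against one gene set
#'
#' @inheritParams observed_statistic
#' @param config a `hub_test_config`
#' @param keep_null keep the null draws in the result
#' @return a `hub_result` list: mirna_id, T, L_kb, X, null_mean, null_sd,
#'   empirical_p, neg_log10_p, and (optionally) null_draws
#' @export
hub_test <- function(mirna, gene_ids, utrs, config = hub_test_config(),
                     keep_null = FALSE) {
  m <- as_mirna(mirna)
  if (inherits(gene_ids, "gene_set")) gene_ids <- gene_ids$gene_id
  if (length(gene_ids) == 0L) stop("gene set of interest is empty")
  universe <- if (is.null(config$universe)) names(utrs) else config$universe
  outside <- setdiff(gene_ids, universe)
  if (length(outside))
    stop("gene set members outside the universe (no UTR available): ",
         paste(utils::head(outside, 10L), collapse = ", "))
  # one scan of the universe serves both the observed statistic and the null
  targets <- predict_targets(m, utrs[universe], site_types = config$site_types)
  is_target <- universe %in% targets$gene_id
  len_nt <- nchar(utrs[universe])
  in_set <- match(gene_ids, universe)
  T_obs <- sum(is_target[in_set])
  L_kb <- mean(len_nt[in_set]) / 1000
  X_obs <- T_obs / L_kb
  null <- draw_null(is_target, len_nt, length(gene_ids), config)
  p <- empirical_pvalue(X_obs, null)
  out <- list(mirna_id = m$id, T = T_obs, L_kb = L_kb, X = X_obs,
              null_mean = mean(null), null_sd = stats::sd(null),
              empirical_p = p, neg_log10_p = -log10(p))
  if (keep_null) out$null_draws <- null
  structure(out, class = "hub_result")
}

#' @export
print.hub_result <- function(x, ...) {
  cat(sprintf("hub_result %s: T=%d, L=%.3f kb, X=%.3f, p=%.4g (-log10 p=%.3f)\n",
              x$mirna_id, x$T, x$L_kb, x$X, x$empirical_p, x$neg_log10_p))
  invisible(x)
}

#' Identify candidate regulatory hub miRNAs
#'
#' Tests every differentially expressed miRNA against the oppositely
#' regulated gene set: up-regulated miRNAs against down-regulated genes and
#' down-regulated miRNAs against up-regulated genes. Results are ranked by
#' empirical p ascending, ties by X descending, then by miRNA ID; the
#' significance flag is p < `alpha`.
#'
#' @param de_mirnas data.frame from [mirna_de()] (or any frame with
#'   mirna_id, direction in \{up, down, ns\}); "ns" rows are skipped
#' @param genes_up,genes_down `gene_set`s (or ID vectors) of up- and
#'   down-regulated genes
#' @param utrs named character vector of 3'UTRs
#' @param mirna_set named character vector of mature miRNA sequences
#' @param config a `hub_test_config`; per-miRNA resampling seeds are derived
#'   deterministically from `config$rng_seed`
#' @param alpha significance level on the empirical p, default 0.05
#' @return data.frame ranked by evidence: mirna, direction, gene_set, T,
#'   L_kb, X, null_mean, null_sd, empirical_p, neg_log10_p, significant
#' @export
identify_hubs <- function(de_mirnas, genes_up, genes_down, utrs, mirna_set,
                          config = hub_test_config(), alpha = 0.05) {
  if (inherits(genes_up, "gene_set")) genes_up <- genes_up$gene_id
  if (inherits(genes_down, "gene_set")) genes_down <- genes_down$gene_id
  de <- de_mirnas[de_mirnas$direction %in% c("up", "down"), , drop = FALSE]
  if (nrow(de) == 0L || (length(genes_up) == 0L && length(genes_down) == 0L)) {
    warning("no differentially expressed miRNAs or genes; empty hub report")
    return(empty_hub_frame())
  }
  missing_seq <- setdiff(de$mirna_id, names(mirna_set))
  if (length(missing_seq))
    stop("no mature sequence for: ", paste(missing_seq, collapse = ", "))
  rows <- vector("list", nrow(de))
  for (i in seq_len(nrow(de))) {
    dir <- de$direction[i]
    gene_ids <- if (dir == "up") genes_down else genes_up
    if (length(gene_ids) == 0L) next
    cfg_i <- config
    if (!is.null(config$rng_seed))
      cfg_i$rng_seed <- (as.integer(config$rng_seed) + i) %% .Machine$integer.max
    res <- hub_test(mirna_sequence(de$mirna_id[i], mirna_set[[de$mirna_id[i]]]),
                    gene_ids, utrs, cfg_i)
    rows[[i]] <- data.frame(mirna = res$mirna_id, direction = dir,
                            gene_set = if (dir == "up") "down-regulated" else "up-regulated",
                            T = res$T, L_kb = res$L_kb, X = res$X,
                            null_mean = res$null_mean, null_sd = res$null_sd,
                            empirical_p = res$empirical_p,
                            neg_log10_p = res$neg_log10_p,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    warning("no testable miRNA/gene-set pairings; empty hub report")
    return(empty_hub_frame())
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$empirical_p, -out$X, out$mirna), , drop = FALSE]
  out$significant <- out$empirical_p < alpha
  rownames(out) <- NULL
  out
}

empty_hub_frame <- function() {
  data.frame(mirna = character(), direction = character(),
             gene_set = character(), T = integer(), L_kb = numeric(),
             X = numeric(), null_mean = numeric(), null_sd = numeric(),
             empirical_p = numeric(), neg_log10_p = numeric(),
             significant = logical(), stringsAsFactors = FALSE)
}
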