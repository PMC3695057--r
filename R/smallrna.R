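# miRNA read-count handling: low-count filter, library-size (CPM)
# normalization, and per-miRNA differential expression on log2(CPM + 1).

#' Construct a miRNA count table
#'
#' @param counts non-negative integer matrix, miRNAs x samples, with unique
#'   rownames and sample colnames
#' @param library_sizes uniquely mapped reads per sample (named by sample or
#'   in column order); the normalization denominator
#' @param groups sample group labels (named or in column order)
#' @return a `mirna_counts` object
#' @export
mirna_count_table <- function(counts, library_sizes, groups) {
  stopifnot(is.matrix(counts), is.numeric(counts))
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs miRNA rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("miRNA IDs must be unique")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  align <- function(v, what) {
    if (!is.null(names(v))) {
      miss <- setdiff(colnames(counts), names(v))
      if (length(miss)) stop("samples without ", what, ": ",
                             paste(miss, collapse = ", "))
      v <- v[colnames(counts)]
    } else if (length(v) != ncol(counts)) {
      stop("need one ", what, " per sample")
    }
    names(v) <- colnames(counts)
    v
  }
  library_sizes <- align(as.numeric(library_sizes), "library size")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  groups <- align(as.character(groups), "group label")
  structure(list(counts = counts, library_sizes = library_sizes,
                 groups = groups), class = "mirna_counts")
}

#' @export
print.mirna_counts <- function(x, ...) {
  cat(sprintf("mirna_counts: %d miRNAs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Drop miRNAs with uniformly low read counts
#'
#' Default rule: a miRNA is retained iff its raw count reaches `min_count`
#' in at least one sample. `rule = "total"` instead requires the summed raw
#' count across samples to reach `min_count`. Dropped IDs are attached as
#' attribute `"dropped"`.
#'
#' @param x a `mirna_counts` object
#' @param min_count retention threshold (inclusive), default 25
#' @param rule "any" (default) or "total"
#' @return filtered `mirna_counts`
#' @export
filter_low_counts <- function(x, min_count = 25, rule = c("any", "total")) {
  stopifnot(inherits(x, "mirna_counts"))
  rule <- match.arg(rule)
  keep <- switch(rule,
    any   = apply(x$counts, 1L, max) >= min_count,
    total = rowSums(x$counts) >= min_count)
  out <- x
  out$counts <- x$counts[keep, , drop = FALSE]
  attr(out, "dropped") <- rownames(x$counts)[!keep]
  out
}

#' Normalize counts by library size (counts per `scale` mapped reads)
#'
#' value_ij = raw_ij * scale / library_size_j; with the default scale of 1e6
#' this is counts per million uniquely mapped reads.
#'
#' @param x a `mirna_counts` object
#' @param scale normalization scale, default 1e6
#' @return numeric matrix of normalized abundances (same dimnames)
#' @export
normalize_counts <- function(x, scale = 1e6) {
  stopifnot(inherits(x, "mirna_counts"))
  if (any(x$library_sizes <= 0)) stop("library sizes must be positive")
  sweep(x$counts, 2L, x$library_sizes, "/") * scale
}

#' Per-miRNA differential expression on normalized counts
#'
#' Two-sided Student's t-test per miRNA on log2(normalized + pseudocount).
#' Significance is called at raw p < `p_max` (no multiple-testing gate, the
#' convention for small miRNA panels); a BH q-value column is emitted for
#' transparency. log2FC = mean(a) - mean(b) on the log scale.
#'
#' @param normalized matrix from [normalize_counts()]
#' @param groups sample group labels (named by sample or in column order)
#' @param group_a,group_b condition and reference labels
#' @param p_max significance threshold on the raw p-value, default 0.05
#' @param pseudocount added before log2, default 1
#' @param var_equal pooled-variance t (default) or Welch
#' @return data.frame: mirna_id, mean_a, mean_b, log2fc, p_value, q_value,
#'   significant, direction
#' @export
mirna_de <- function(normalized, groups, group_a, group_b, p_max = 0.05,
                     pseudocount = 1, var_equal = TRUE) {
  stopifnot(is.matrix(normalized))
  groups <- as.character(groups)
  if (!is.null(names(groups))) groups <- groups[colnames(normalized)]
  idx_a <- which(groups == group_a)
  idx_b <- which(groups == group_b)
  if (length(idx_a) < 2L || length(idx_b) < 2L)
    stop("both groups must be present with >=2 replicates")
  lg <- log2(normalized + pseudocount)
  tt <- row_t_test(lg, idx_a, idx_b, var_equal = var_equal)
  sig <- tt$p_value < p_max
  data.frame(mirna_id = rownames(normalized),
             mean_a = tt$mean_a, mean_b = tt$mean_b,
             log2fc = tt$delta, p_value = tt$p_value,
             q_value = bh_fdr(tt$p_value),
             significant = sig,
             direction = ifelse(!sig, "ns",
                                ifelse(tt$delta > 0, "up", "down")),
             stringsAsFactors = FALSE, row.names = NULL)
}
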