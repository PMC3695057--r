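# Expression-matrix handling: quantile normalization, per-gene two-sample
# t-tests, BH-FDR, the FDR/fold-change significance gate, and set overlaps.

#' Construct an expression matrix with sample group labels
#'
#' @param values numeric matrix of log2 expression, genes x samples, with
#'   unique rownames (gene IDs) and colnames (sample IDs)
#' @param groups character vector of group labels, one per sample; either
#'   named by sample ID or in column order
#' @return an `expression_matrix` object (list with `values`, `groups`)
#' @export
expression_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("gene IDs must be unique")
  if (anyNA(values)) stop("missing values in expression matrix")
  groups <- as.character(groups)
  if (!is.null(names(groups))) {
    miss <- setdiff(colnames(values), names(groups))
    if (length(miss)) stop("samples without group label: ", paste(miss, collapse = ", "))
    groups <- groups[colnames(values)]
  } else if (length(groups) != ncol(values)) {
    stop("need one group label per sample")
  }
  names(groups) <- colnames(values)
  structure(list(values = values, groups = groups), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("groups:", paste(sprintf("%s (n=%d)", names(table(x$groups)),
                               as.integer(table(x$groups))), collapse = ", "), "\n")
  invisible(x)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample to share the same empirical distribution: the
#' reference is the row-wise mean of the per-column sorted values, and each
#' value is mapped to the reference value at its within-column rank. Ties
#' within a column receive the mean of the reference values their rank range
#' spans, so the procedure is symmetric in tied entries.
#'
#' @param x an `expression_matrix` or a numeric matrix
#' @return object of the same type, normalized
#' @export
quantile_normalize <- function(x) UseMethod("quantile_normalize")

#' @export
quantile_normalize.expression_matrix <- function(x) {
  x$values <- quantile_normalize(x$values)
  x
}

#' @export
quantile_normalize.matrix <- function(x) {
  if (anyNA(x)) stop("missing values not supported")
  if (ncol(x) < 2L) stop("need >=2 samples to quantile normalize")
  ref <- rowMeans(apply(x, 2L, sort))
  cs <- c(0, cumsum(ref))
  out <- apply(x, 2L, function(col) {
    rmin <- rank(col, ties.method = "min")
    rmax <- rank(col, ties.method = "max")
    (cs[rmax + 1L] - cs[rmin]) / (rmax - rmin + 1L)
  })
  dimnames(out) <- dimnames(x)
  out
}

## Vectorized two-sample t-tests across rows of a matrix.
## Equal-variance (pooled) by default; Welch behind var_equal = FALSE.
## Degenerate-variance conventions:
##   s_pooled == 0 and equal means   -> t = 0,  p = 1
##   s_pooled == 0 and unequal means -> t = +/-Inf, p = smallest positive
##                                      double, degenerate flag set
row_t_test <- function(mat, idx_a, idx_b, var_equal = TRUE) {
  na <- length(idx_a); nb <- length(idx_b)
  if (na < 2L || nb < 2L) stop("need >=2 replicates per group")
  a <- mat[, idx_a, drop = FALSE]
  b <- mat[, idx_b, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  if (var_equal) {
    sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep.int(na + nb - 2L, nrow(mat))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
    df[!is.finite(df)] <- na + nb - 2L
  }
  delta <- ma - mb
  t <- delta / se
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se == 0
  eq <- degenerate & delta == 0
  ne <- degenerate & delta != 0
  t[eq] <- 0; p[eq] <- 1
  t[ne] <- sign(delta[ne]) * Inf
  p[ne] <- .Machine$double.xmin
  data.frame(mean_a = ma, mean_b = mb, delta = delta, t_statistic = t,
             df = df, p_value = p, degenerate = degenerate,
             row.names = rownames(mat), stringsAsFactors = FALSE)
}

#' Per-gene differential expression between two groups
#'
#' Two-sided two-sample t-test per gene (equal-variance by default, matching
#' classical microarray practice; Welch via `var_equal = FALSE`). The log2
#' fold change is mean(group_a) - mean(group_b); the linear fold change is
#' reported as sign(log2FC) * 2^|log2FC|. BH q-values are computed over all
#' genes tested.
#'
#' @param x an `expression_matrix` (log2 scale)
#' @param group_a,group_b group labels; convention: `group_a` is the
#'   condition, `group_b` the reference, so positive log2FC means "up in a"
#' @param var_equal pooled-variance t if TRUE (default), Welch otherwise
#' @return data.frame with columns gene_id, t_statistic, df, p_value,
#'   q_value, log2_fold_change, fold_change, degenerate
#' @export
differential_expression <- function(x, group_a, group_b, var_equal = TRUE) {
  stopifnot(inherits(x, "expression_matrix"))
  idx_a <- which(x$groups == group_a)
  idx_b <- which(x$groups == group_b)
  if (length(idx_a) < 2L || length(idx_b) < 2L)
    stop("both groups must be present with >=2 replicates")
  tt <- row_t_test(x$values, idx_a, idx_b, var_equal = var_equal)
  lfc <- tt$delta
  data.frame(gene_id = rownames(x$values),
             t_statistic = tt$t_statistic, df = tt$df,
             p_value = tt$p_value, q_value = bh_fdr(tt$p_value),
             log2_fold_change = lfc,
             fold_change = sign(lfc) * 2^abs(lfc),
             degenerate = tt$degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-way fixed-effects ANOVA F-test across all groups
#'
#' Companion to the pairwise t-tests: a per-gene one-way F-test over every
#' group label in the matrix. Downstream gene sets are built from the
#' pairwise condition-vs-reference t-tests; this is provided for the global
#' "is anything moving" question.
#'
#' @param x an `expression_matrix`
#' @return data.frame with gene_id, f_statistic, df1, df2, p_value, q_value
#' @export
anova_f_test <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  g <- factor(x$groups)
  k <- nlevels(g)
  n <- ncol(x$values)
  if (k < 2L) stop("need >=2 groups")
  gm <- rowMeans(x$values)
  ssb <- 0; ssw <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    m <- rowMeans(x$values[, idx, drop = FALSE])
    ssb <- ssb + length(idx) * (m - gm)^2
    ssw <- ssw + rowSums((x$values[, idx, drop = FALSE] - m)^2)
  }
  df1 <- k - 1L; df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1
  p[ssw == 0 & ssb > 0] <- .Machine$double.xmin
  data.frame(gene_id = rownames(x$values), f_statistic = f,
             df1 = df1, df2 = df2, p_value = p, q_value = bh_fdr(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up q-values
#'
#' q_(i) = min_{j >= i} p_(j) * m / j, capped at 1; order-preserving.
#'
#' @param p numeric vector of p-values in [0,1]
#' @return vector of q-values, same order as input
#' @export
bh_fdr <- function(p) {
  if (anyNA(p)) stop("NA/NaN p-values not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / seq.int(m, 1L)))
  q[order(o)]
}

#' Gate differential-expression results into a significant gene set
#'
#' A gene is significant when q < `fdr_max` (strict) and its linear fold
#' change satisfies |FC| >= `fold_min` (inclusive). Direction is the sign of
#' the log2 fold change.
#'
#' @param results data.frame from [differential_expression()]
#' @param fdr_max FDR ceiling (strict `<`), default 0.1
#' @param fold_min linear fold-change floor (inclusive `>=`), default 1.5
#' @param label optional set label
#' @return a `gene_set` data.frame (gene_id, direction) for passing genes
#' @export
significant_genes <- function(results, fdr_max = 0.1, fold_min = 1.5,
                              label = NULL) {
  stopifnot(nrow(results) > 0L)
  pass <- results$q_value < fdr_max & 2^abs(results$log2_fold_change) >= fold_min
  gene_set(results$gene_id[pass],
           direction = ifelse(results$log2_fold_change[pass] > 0, "up", "down"),
           label = label)
}

#' Construct a directed gene set
#'
#' @param gene_id character vector of member IDs (no duplicates)
#' @param direction per-member "up"/"down"
#' @param label optional label carried as an attribute
#' @return data.frame of class `gene_set`
#' @export
gene_set <- function(gene_id, direction = rep("up", length(gene_id)),
                     label = NULL) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("duplicate gene IDs in gene set")
  out <- data.frame(gene_id = gene_id, direction = as.character(direction),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_set", "data.frame")
  attr(out, "label") <- label
  out
}

#' Overlap accounting between two directed gene sets
#'
#' Reports common and unique members and how many common genes move in the
#' same direction in both sets.
#'
#' @param set_a,set_b `gene_set` objects
#' @return list with `common`, `unique_a`, `unique_b` (ID vectors) and
#'   counts `n_common`, `n_unique_a`, `n_unique_b`, `n_concordant`
#' @export
overlap_analysis <- function(set_a, set_b) {
  common <- intersect(set_a$gene_id, set_b$gene_id)
  da <- set_a$direction[match(common, set_a$gene_id)]
  db <- set_b$direction[match(common, set_b$gene_id)]
  list(common = common,
       unique_a = setdiff(set_a$gene_id, common),
       unique_b = setdiff(set_b$gene_id, common),
       n_common = length(common),
       n_unique_a = length(setdiff(set_a$gene_id, common)),
       n_unique_b = length(setdiff(set_b$gene_id, common)),
       n_concordant = sum(da == db))
}
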