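# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately avoid the code paths they check: plain substring
# enumeration instead of Biostrings matching, direct formulas instead of
# the package's vectorized implementations.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
}

## Site words derived by hand from the mature sequence (RNA or DNA).
oracle_site_words <- function(mature) {
  m <- chartr("U", "T", toupper(mature))
  seed7 <- substr(m, 2L, 8L)
  seed6 <- substr(m, 2L, 7L)
  c("8mer" = paste0(oracle_revcomp(seed7), "A"),
    "7mer-m8" = oracle_revcomp(seed7),
    "7mer-A1" = paste0(oracle_revcomp(seed6), "A"),
    "6mer" = oracle_revcomp(seed6))
}

## Exhaustive-substring seed-site finder: enumerate every occurrence of
## every site word by direct substring comparison, then resolve each seed
## core locus to its strongest type. Returns the same columns as
## find_seed_sites (gene_id omitted).
oracle_seed_sites <- function(mature, utr, site_types = names(oracle_site_words(mature))) {
  words <- oracle_site_words(mature)
  n <- nchar(utr)
  occ <- lapply(words, function(w) {
    k <- nchar(w)
    if (n < k) return(integer(0))
    which(vapply(seq_len(n - k + 1L),
                 function(i) substr(utr, i, i + k - 1L) == w, NA))
  })
  # 1-based position of the seed core (revcomp nt2-7) for each occurrence
  core_of <- list("8mer" = occ[["8mer"]] + 1L,
                  "7mer-m8" = occ[["7mer-m8"]] + 1L,
                  "7mer-A1" = occ[["7mer-A1"]],
                  "6mer" = occ[["6mer"]])
  cores <- sort(unique(unlist(core_of)))
  rows <- lapply(cores, function(cc) {
    for (ty in c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
      if (cc %in% core_of[[ty]]) {
        start1 <- if (ty %in% c("8mer", "7mer-m8")) cc - 1L else cc
        return(data.frame(start = start1 - 1L, site_type = ty,
                          word = substr(utr, start1,
                                        start1 + nchar(words[[ty]]) - 1L),
                          stringsAsFactors = FALSE))
      }
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), site_type = character(),
               word = character(), stringsAsFactors = FALSE)
  out[out$site_type %in% site_types, , drop = FALSE]
}

## Direct BH step-up formula: q_(i) = min_{j>=i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

## Exact PWM score tail by brute-force enumeration of all 4^w words.
## mat: 4 x w score matrix (any scale); bg: base probabilities.
## Returns function(s) = P(score >= s).
oracle_pwm_tail <- function(mat, bg = rep(0.25, 4)) {
  w <- ncol(mat)
  codes <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- rowSums(vapply(seq_len(w), function(j) mat[codes[, j], j],
                           numeric(nrow(codes))))
  probs <- exp(rowSums(vapply(seq_len(w), function(j) log(bg[codes[, j]]),
                              numeric(nrow(codes)))))
  function(s) vapply(s, function(si) sum(probs[scores >= si - 1e-12]),
                     numeric(1))
}

read_keyed_tsv_for_test <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2]]), df[[1]])
}

random_dna_str <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

## Small expression fixture: flat matrix with optional per-gene shifts.
make_expr_fixture <- function(n_genes = 50, groups = c(naive = 4, cond = 4),
                              noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  glab <- rep(names(groups), groups)
  samples <- sprintf("%s_r%d", glab, unlist(lapply(groups, seq_len)))
  vals <- matrix(rnorm(n_genes * length(samples), 8, noise_sd),
                 nrow = n_genes,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)), samples))
  expression_matrix(vals, stats::setNames(glab, samples))
}

## A deterministic information-rich PWM for scan tests.
toy_pwm <- function(width = 6, strength = 20, id = "toy",
                    consensus = NULL) {
  bases <- c("A", "C", "G", "T")
  if (is.null(consensus)) consensus <- paste(rep(c("A", "C", "G"),
                                                 length.out = width),
                                             collapse = "")
  m <- matrix(1, 4, width, dimnames = list(bases, NULL))
  idx <- match(strsplit(consensus, "")[[1L]], bases)
  m[cbind(idx, seq_len(width))] <- strength
  build_pwm(m, id = id)
}
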