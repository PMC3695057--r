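# Position weight matrices: TRANSFAC-format parsing, log-odds construction,
# exact score-distribution calibration by dynamic programming, and window
# scanning of promoter sequences.
#
# Calibration discretizes each log-odds cell to the nearest multiple of
# `bin_width` (default 0.01 bits) and convolves the per-column score
# distributions under the iid background; the resulting tail table is EXACT
# for the binned score, and the binned score differs from the true score by
# at most width * bin_width / 2. Window p-values are looked up on the same
# binned scale, so scanning and calibration are mutually consistent.

DNA_BASES <- c("A", "C", "G", "T")

#' Parse TRANSFAC-format count matrices
#'
#' Reads one or more matrix blocks: an ID (and optional NA name) line, a
#' `P0 A C G T` header, numbered position rows with four counts (a trailing
#' consensus letter is tolerated), and a `//` terminator.
#'
#' @param x path to a file, or a character vector of lines
#' @return list of matrices (rows A,C,G,T; one column per motif position),
#'   named by motif ID
#' @export
parse_transfac <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  out <- list()
  cur_id <- NULL; cur_name <- NULL; cur_rows <- list(); in_block <- FALSE
  col_order <- DNA_BASES
  flush <- function() {
    if (length(cur_rows) == 0L) return()
    m <- do.call(cbind, cur_rows)           # 4 x width, rows in col_order
    rownames(m) <- col_order
    m <- m[DNA_BASES, , drop = FALSE]
    id <- if (!is.null(cur_id)) cur_id
          else if (!is.null(cur_name)) cur_name else sprintf("motif_%d", length(out) + 1L)
    out[[id]] <<- m
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    toks <- strsplit(ln, "[ \t]+")[[1L]]
    key <- toupper(toks[1L])
    if (key == "//") { flush(); cur_id <- NULL; cur_name <- NULL
                       cur_rows <- list(); in_block <- FALSE; next }
    if (key == "ID") { cur_id <- toks[2L]; next }
    if (key == "NA") { cur_name <- paste(toks[-1L], collapse = " "); next }
    if (key %in% c("P0", "PO")) {
      bases <- toupper(toks[-1L])
      if (!setequal(bases, DNA_BASES))
        stop("line ", i, ": P0 header must name A C G T")
      col_order <- bases
      in_block <- TRUE
      next
    }
    if (in_block && grepl("^[0-9]+$", key)) {
      vals <- suppressWarnings(as.numeric(toks[2:5]))
      if (length(toks) < 5L || anyNA(vals))
        stop("line ", i, ": malformed count row")
      if (any(vals < 0)) stop("line ", i, ": negative count")
      cur_rows[[length(cur_rows) + 1L]] <- vals
      next
    }
    # other TRANSFAC fields (XX, BF, CC, ...) are ignored
  }
  flush()
  if (length(out) == 0L) stop("no TRANSFAC matrix blocks found")
  out
}

#' Write count matrices in TRANSFAC format
#'
#' @param matrices list of 4 x width count matrices (rows A,C,G,T)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_transfac <- function(matrices, path) {
  if (is.matrix(matrices)) matrices <- list(motif_1 = matrices)
  con <- file(path, "w"); on.exit(close(con))
  for (id in names(matrices)) {
    m <- matrices[[id]]
    writeLines(c(paste("ID", id), "P0\tA\tC\tG\tT"), con)
    for (j in seq_len(ncol(m))) {
      writeLines(sprintf("%02d\t%s", j,
                         paste(format(m[, j], trim = TRUE), collapse = "\t")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Build a log-odds PWM from a count matrix
#'
#' log-odds(b, j) = log2( (count_bj + pseudocount) /
#' (colsum_j + 4 * pseudocount) / background_b ), in bits.
#'
#' @param counts 4 x width count matrix (rows A,C,G,T)
#' @param pseudocount added to every cell, default 0.25
#' @param background base frequencies (A,C,G,T), default uniform
#' @param id motif identifier
#' @return a `pwm_model` (counts, log-odds, width, background; calibrate
#'   with [score_pvalue_table()])
#' @export
build_pwm <- function(counts, pseudocount = 0.25,
                      background = rep(0.25, 4), id = "motif") {
  stopifnot(is.matrix(counts), nrow(counts) == 4L, ncol(counts) >= 1L,
            all(counts >= 0))
  if (is.null(rownames(counts))) rownames(counts) <- DNA_BASES
  counts <- counts[DNA_BASES, , drop = FALSE]
  if (any(colSums(counts) + 4 * pseudocount <= 0))
    stop("column sums must be positive (use pseudocount > 0)")
  background <- as.numeric(background)
  stopifnot(length(background) == 4L)
  if (any(background <= 0)) stop("background frequencies must be positive")
  background <- background / sum(background)
  freq <- sweep(counts + pseudocount, 2L,
                colSums(counts) + 4 * pseudocount, "/")
  logodds <- log2(freq / background)
  rownames(logodds) <- DNA_BASES
  structure(list(id = id, width = ncol(counts), counts = counts,
                 pseudocount = pseudocount, background = background,
                 logodds = logodds, calibration = NULL),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("pwm_model %s: width %d, %scalibrated\n", x$id, x$width,
              if (is.null(x$calibration)) "not " else ""))
  invisible(x)
}

#' Consensus word of a PWM (highest-count base per position)
#'
#' Ties resolved in A,C,G,T order.
#'
#' @param pwm a `pwm_model`
#' @return consensus string
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$counts, 2L, which.max)], collapse = "")
}

#' Calibrate the exact score distribution of a PWM
#'
#' Computes the distribution of the match score of a random background word
#' by position-wise convolution of the discretized per-column score
#' distributions, and attaches a queryable tail table
#' P(score >= s) to the model. Exact for the binned score; the binning
#' error on any window score is at most width * bin_width / 2.
#'
#' @param pwm a `pwm_model`
#' @param bin_width score discretization, bits; default 0.01
#' @param max_bins guard against pathological bin counts
#' @return the `pwm_model` with a `calibration` component
#'   (bin, offset, prob, tail)
#' @export
score_pvalue_table <- function(pwm, bin_width = 0.01, max_bins = 5e6) {
  stopifnot(inherits(pwm, "pwm_model"))
  if (!all(is.finite(pwm$logodds)))
    stop("non-finite log-odds; rebuild with pseudocount > 0")
  sc <- round(pwm$logodds / bin_width)       # integer bins, 4 x width
  lo <- sum(apply(sc, 2L, min)); hi <- sum(apply(sc, 2L, max))
  if (hi - lo + 1 > max_bins)
    stop("calibration needs ", hi - lo + 1,
         " bins; increase bin_width")
  # prob[k] = P(binned score == lo + k - 1)
  prob <- 1; off <- 0                         # distribution of the empty prefix
  for (j in seq_len(pwm$width)) {
    cl <- sc[, j]
    new_off <- off + min(cl)
    new_len <- length(prob) + max(cl) - min(cl)
    acc <- numeric(new_len)
    for (b in 1:4) {
      sh <- cl[b] - min(cl)
      acc[(1 + sh):(length(prob) + sh)] <-
        acc[(1 + sh):(length(prob) + sh)] + pwm$background[b] * prob
    }
    prob <- acc; off <- new_off
  }
  tail <- rev(cumsum(rev(prob)))
  pwm$calibration <- list(bin = bin_width, offset = off, prob = prob,
                          tail = tail, score_bins = sc)
  pwm
}

#' Tail probability of a PWM score
#'
#' P(score >= s) for a random background word, from the calibrated table.
#' `s` is snapped up to the binned-score grid, so the result is exact for
#' scores produced by [scan_promoter()].
#'
#' @param pwm a calibrated `pwm_model`
#' @param s score(s), bits
#' @return tail probabilities
#' @export
pwm_tail_p <- function(pwm, s) {
  cal <- pwm$calibration
  if (is.null(cal)) stop("PWM not calibrated; run score_pvalue_table() first")
  k <- ceiling(s / cal$bin - 1e-9)            # smallest grid point >= s
  idx <- k - cal$offset + 1
  out <- numeric(length(s))
  out[idx <= 0] <- 1
  inr <- idx >= 1 & idx <= length(cal$tail)
  out[inr] <- cal$tail[idx[inr]]
  out[idx > length(cal$tail)] <- 0
  out
}

## Binned window scores along a coded sequence; NA where a window spans an
## ambiguous base. codes: integer vector (1..4, NA for N).
binned_scores <- function(codes, score_bins) {
  w <- ncol(score_bins)
  n_win <- length(codes) - w + 1L
  if (n_win < 1L) return(numeric(0))
  total <- numeric(n_win)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n_win - 1L)]
    total <- total + score_bins[cbind(cj, j)]
  }
  total
}

#' Scan a promoter for high-confidence PWM matches
#'
#' Scores every window of the sequence (and of its reverse complement when
#' `both_strands`) against the calibrated PWM and reports windows whose
#' score tail probability is below `p_max`. Minus-orientation hits are
#' reported at the offset of the window on the given (plus) sequence.
#' Windows containing N are skipped; their count is attached as attribute
#' `"n_skipped"`.
#'
#' @param pwm a calibrated `pwm_model`
#' @param promoter sequence string, or a row of [extract_promoters()] output
#' @param p_max p-value threshold (strict `<`), default 5e-6
#' @param both_strands scan both orientations, default TRUE
#' @param promoter_id ID used in the output when `promoter` is a string
#' @return data.frame sorted by offset: promoter_id, offset (0-based),
#'   strand (+/-), score (bits, binned scale), p_value
#' @export
scan_promoter <- function(pwm, promoter, p_max = 5e-6, both_strands = TRUE,
                          promoter_id = "promoter") {
  if (is.null(pwm$calibration)) stop("PWM not calibrated; run score_pvalue_table() first")
  if (is.data.frame(promoter)) {
    stopifnot(nrow(promoter) == 1L)
    promoter_id <- promoter$id
    promoter <- promoter$sequence
  }
  seq <- as_dna(promoter)
  L <- nchar(seq); w <- pwm$width
  empty <- data.frame(promoter_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  if (L < w) { warning("promoter shorter than motif"); return(empty) }
  bin <- pwm$calibration$bin
  sb <- pwm$calibration$score_bins
  codes <- match(strsplit(seq, "")[[1L]], DNA_BASES)
  hits <- list(empty)
  collect <- function(codes, strand) {
    s_bin <- binned_scores(codes, sb)
    p <- rep(1, length(s_bin))
    ok <- !is.na(s_bin)
    p[ok] <- pwm_tail_p(pwm, s_bin[ok] * bin)
    keep <- ok & p < p_max
    n_skip <- sum(!ok)
    off <- which(keep) - 1L
    if (strand == "-") off <- L - w - off     # mirror to plus coordinates
    list(df = data.frame(promoter_id = rep(promoter_id, length(off)),
                         offset = off,
                         strand = rep(strand, length(off)),
                         score = s_bin[keep] * bin,
                         p_value = p[keep], stringsAsFactors = FALSE),
         n_skipped = n_skip)
  }
  plus <- collect(codes, "+")
  n_skipped <- plus$n_skipped
  hits[[2L]] <- plus$df
  if (both_strands) {
    rc_codes <- rev(5L - codes)               # revcomp in code space (NA-safe)
    minus <- collect(rc_codes, "-")
    n_skipped <- n_skipped + minus$n_skipped
    hits[[3L]] <- minus$df
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Scan many promoters against many PWMs
#'
#' @param pwms list of calibrated `pwm_model`s
#' @param promoters named character vector of promoter sequences, or
#'   [extract_promoters()] output
#' @param ... passed to [scan_promoter()]
#' @return data.frame of hits with a `motif` column
#' @export
scan_promoters <- function(pwms, promoters, ...) {
  if (inherits(pwms, "pwm_model")) pwms <- list(pwms)
  if (is.data.frame(promoters)) {
    seqs <- stats::setNames(promoters$sequence, promoters$id)
  } else seqs <- promoters
  rows <- list()
  for (pwm in pwms) {
    for (id in names(seqs)) {
      h <- scan_promoter(pwm, seqs[[id]], promoter_id = id, ...)
      if (nrow(h)) rows[[length(rows) + 1L]] <- cbind(motif = pwm$id, h)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(motif = character(), promoter_id = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
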