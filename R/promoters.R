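# Promoter extraction around transcription start sites. Coordinates are
# 0-based half-open internally; a promoter is `upstream` bases 5' of the
# TSS plus `downstream` bases from the TSS onward, on the transcribed
# strand, so the TSS sits at offset `upstream` within the returned
# sequence.

#' Extract promoter regions around TSSs
#'
#' Plus-strand TSS t maps to the genomic interval [t - upstream,
#' t + downstream); minus-strand TSS t to [t - downstream + 1,
#' t + upstream + 1) with the slice reverse-complemented, so both read
#' 5'->3' on the transcribed strand with the TSS at offset `upstream`.
#' Intervals running off a chromosome end are truncated with a warning and
#' the realized length recorded.
#'
#' @param tss data.frame with columns id, chrom, strand (+/-), tss
#' @param genome named character vector (or DNAStringSet) of chromosome
#'   sequences
#' @param upstream bases 5' of the TSS, default 1000
#' @param downstream bases from the TSS onward, default 500
#' @param coord_base 0 (default) if `tss` coordinates are 0-based, 1 if
#'   1-based
#' @return data.frame: id, chrom, strand, start, end (0-based half-open
#'   genomic), length, truncated, sequence
#' @export
extract_promoters <- function(tss, genome, upstream = 1000L,
                              downstream = 500L, coord_base = 0L) {
  stopifnot(all(c("id", "chrom", "strand", "tss") %in% colnames(tss)),
            all(tss$strand %in% c("+", "-")), coord_base %in% c(0L, 1L))
  if (!is.character(genome)) genome <- stats::setNames(as.character(genome), names(genome))
  genome <- as_dna(genome)
  miss <- setdiff(unique(tss$chrom), names(genome))
  if (length(miss)) stop("chromosome(s) missing from genome: ",
                         paste(miss, collapse = ", "))
  t0 <- as.integer(tss$tss) - coord_base
  chrom_len <- nchar(genome)[tss$chrom]
  if (any(t0 < 0L | t0 >= chrom_len)) stop("TSS outside chromosome bounds")
  start <- ifelse(tss$strand == "+", t0 - upstream, t0 - downstream + 1L)
  end <- ifelse(tss$strand == "+", t0 + downstream, t0 + upstream + 1L)
  cl_start <- pmax(start, 0L)
  cl_end <- pmin(end, chrom_len)
  truncated <- cl_start != start | cl_end != end
  if (any(truncated))
    warning(sum(truncated), " promoter(s) truncated at chromosome ends")
  seq <- substring(genome[tss$chrom], cl_start + 1L, cl_end)
  seq <- ifelse(tss$strand == "-", dna_revcomp(seq), seq)
  data.frame(id = tss$id, chrom = tss$chrom, strand = tss$strand,
             start = as.integer(cl_start), end = as.integer(cl_end),
             length = as.integer(cl_end - cl_start),
             truncated = truncated, sequence = unname(seq),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write motif hits as BED6 (+ p-value column)
#'
#' Hit offsets are promoter-relative; combined with the promoter table the
#' output carries genomic 0-based half-open coordinates. The BED strand is
#' the hit orientation relative to the genome.
#'
#' @param hits data.frame from [scan_promoters()] (needs motif,
#'   promoter_id, offset, strand, score, p_value)
#' @param promoters data.frame from [extract_promoters()]
#' @param width motif width used for the hits
#' @param path output BED file
#' @return `path`, invisibly
#' @export
write_hits_bed <- function(hits, promoters, width, path) {
  m <- match(hits$promoter_id, promoters$id)
  if (anyNA(m)) stop("hits reference unknown promoter IDs")
  prom <- promoters[m, , drop = FALSE]
  # promoter-relative offset o on the transcribed strand -> genomic start
  gstart <- ifelse(prom$strand == "+",
                   prom$start + hits$offset,
                   prom$end - hits$offset - width)
  flip <- c("+" = "-", "-" = "+")
  gstrand <- ifelse(prom$strand == "+", hits$strand, flip[hits$strand])
  bed <- data.frame(chrom = prom$chrom,
                    start = as.integer(gstart),
                    end = as.integer(gstart + width),
                    name = paste(hits$motif, hits$promoter_id, sep = "|"),
                    score = round(hits$score, 4),
                    strand = unname(gstrand),
                    p_value = signif(hits$p_value, 6),
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
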