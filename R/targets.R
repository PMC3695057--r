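# Seed-based miRNA target prediction over 3'UTRs, using the TargetScan site
# taxonomy. A "locus" is an occurrence of the 6-nt seed core
# (revcomp of miRNA nt 2-7) in the UTR; flanking bases upgrade it to
# 7mer-m8 (match to nt 8 on the 5' side), 7mer-A1 (an A opposite miRNA
# position 1 on the 3' side) or 8mer (both). Each locus gets its single
# strongest type so one site is never counted twice.

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
DEFAULT_SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1")

#' Construct a mature miRNA sequence record
#'
#' Accepts RNA or DNA alphabet; stored as DNA. Derives the 6-nt (nt 2-7)
#' and 7-nt (nt 2-8) seeds.
#'
#' @param id miRNA identifier
#' @param seq mature sequence, 5'->3'
#' @return a `mirna_sequence` list (id, seq, seed6, seed7)
#' @export
mirna_sequence <- function(id, seq) {
  seq <- as_dna(seq)
  if (nchar(seq) < 8L) stop("mature miRNA must be >=8 nt: ", id)
  structure(list(id = as.character(id), seq = seq,
                 seed6 = substr(seq, 2L, 7L), seed7 = substr(seq, 2L, 8L)),
            class = "mirna_sequence")
}

#' Validate a 3'UTR set
#'
#' @param x named character vector of UTR sequences (gene ID -> sequence)
#' @return the canonicalized named character vector
#' @export
utr_set <- function(x) {
  x <- as_dna(x)
  if (is.null(names(x)) || !all(nzchar(names(x)))) stop("UTRs must be named by gene ID")
  if (anyDuplicated(names(x))) stop("gene IDs must be unique")
  x
}

as_mirna <- function(mirna) {
  if (inherits(mirna, "mirna_sequence")) mirna
  else mirna_sequence(if (!is.null(names(mirna))) names(mirna)[1L] else "miRNA",
                      mirna)
}

#' Target-site words for a miRNA, by site type
#'
#' Returns the mRNA-sense (5'->3', DNA alphabet) words whose presence in a
#' 3'UTR constitutes a seed match:
#' 8mer = revcomp(nt 2-8) + "A"; 7mer-m8 = revcomp(nt 2-8);
#' 7mer-A1 = revcomp(nt 2-7) + "A"; 6mer = revcomp(nt 2-7).
#'
#' @param mirna a `mirna_sequence` or a mature sequence string
#' @return named character vector over the four site types
#' @export
site_words <- function(mirna) {
  m <- as_mirna(mirna)
  if (grepl("N", m$seed7, fixed = TRUE))
    stop("ambiguous base in seed region of ", m$id)
  rc7 <- dna_revcomp(m$seed7)
  rc6 <- dna_revcomp(m$seed6)
  c("8mer" = paste0(rc7, "A"), "7mer-m8" = rc7,
    "7mer-A1" = paste0(rc6, "A"), "6mer" = rc6)
}

## Locate and classify all seed-match loci of `mirna` in a set of UTRs.
## Returns 0-based starts of the reported (type-specific) word.
seed_site_loci <- function(mirna, utrs) {
  words <- site_words(mirna)
  core <- words[["6mer"]]
  m8_base <- substr(words[["7mer-m8"]], 1L, 1L)
  subject <- Biostrings::DNAStringSet(unname(utrs))
  hits <- Biostrings::vmatchPattern(core, subject)
  sidx <- Biostrings::startIndex(hits)          # list of 1-based core starts
  n_hits <- vapply(sidx, length, integer(1))
  if (sum(n_hits) == 0L) {
    return(data.frame(gene_id = character(), start = integer(),
                      site_type = character(), word = character(),
                      stringsAsFactors = FALSE))
  }
  gi <- rep.int(seq_along(utrs), n_hits)
  s <- unlist(sidx, use.names = FALSE)
  seqs <- utrs[gi]
  len <- nchar(seqs)
  has_m8 <- s > 1L & substring(seqs, s - 1L, s - 1L) == m8_base
  has_a1 <- s + 6L <= len & substring(seqs, s + 6L, s + 6L) == "A"
  type <- ifelse(has_m8 & has_a1, "8mer",
          ifelse(has_m8, "7mer-m8",
          ifelse(has_a1, "7mer-A1", "6mer")))
  start1 <- ifelse(has_m8, s - 1L, s)            # 1-based start of reported word
  width <- c("8mer" = 8L, "7mer-m8" = 7L, "7mer-A1" = 7L, "6mer" = 6L)[type]
  data.frame(gene_id = names(utrs)[gi],
             start = as.integer(start1 - 1L),
             site_type = type,
             word = substring(seqs, start1, start1 + width - 1L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Find classified seed-match sites in one UTR
#'
#' Scans the given mRNA-sense sequence for seed matches of `mirna` and
#' assigns each locus its strongest site type
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer); only loci whose assigned type is in
#' `site_types` are reported. Matching is strand-specific: sites exist only
#' on the 5'->3' mRNA sequence as given.
#'
#' @param mirna a `mirna_sequence` or mature sequence string
#' @param utr UTR sequence (single string)
#' @param site_types site types to report
#' @param allow_overlap if FALSE, overlapping reported words are resolved
#'   greedily left-to-right
#' @param gene_id ID used in the output
#' @return data.frame: gene_id, start (0-based), site_type, word
#' @export
find_seed_sites <- function(mirna, utr, site_types = SITE_TYPES,
                            allow_overlap = TRUE, gene_id = "utr") {
  stopifnot(length(utr) == 1L, nchar(utr) > 0L)
  site_types <- match.arg(site_types, SITE_TYPES, several.ok = TRUE)
  utrs <- stats::setNames(as_dna(utr), gene_id)
  out <- seed_site_loci(as_mirna(mirna), utrs)
  out <- out[out$site_type %in% site_types, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  if (!allow_overlap && nrow(out) > 1L) {
    keep <- logical(nrow(out))
    last_end <- -1L
    for (i in seq_len(nrow(out))) {
      if (out$start[i] > last_end) {
        keep[i] <- TRUE
        last_end <- out$start[i] + nchar(out$word[i]) - 1L
      }
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Predict the target gene set of a miRNA over a UTR set
#'
#' A gene is a predicted target iff its 3'UTR carries at least one seed
#' site whose assigned type is in `site_types`. The default type set
#' {8mer, 7mer-m8, 7mer-A1} is the canonical high-confidence taxonomy;
#' 6mer-only genes are excluded by default.
#'
#' @param mirna a `mirna_sequence` or mature sequence string
#' @param utrs named character vector of UTR sequences
#' @param site_types site types that qualify a gene as a target
#' @return a `gene_set` of target gene IDs
#' @export
predict_targets <- function(mirna, utrs,
                            site_types = DEFAULT_SITE_TYPES) {
  utrs <- utr_set_allow_empty(utrs)
  empty <- !nzchar(utrs)
  if (any(empty)) {
    warning("excluding ", sum(empty), " gene(s) with empty UTR")
    utrs <- utrs[!empty]
  }
  site_types <- match.arg(site_types, SITE_TYPES, several.ok = TRUE)
  loci <- seed_site_loci(as_mirna(mirna), utrs)
  ids <- unique(loci$gene_id[loci$site_type %in% site_types])
  gene_set(ids, direction = rep(NA_character_, length(ids)),
           label = as_mirna(mirna)$id)
}

utr_set_allow_empty <- function(x) {
  x <- as_dna(x)
  if (is.null(names(x)) || !all(nzchar(names(x)))) stop("UTRs must be named by gene ID")
  if (anyDuplicated(names(x))) stop("gene IDs must be unique")
  x
}

#' Target indicator matrix for many miRNAs
#'
#' @param mirnas named character vector of mature sequences (or list of
#'   `mirna_sequence`)
#' @param utrs named character vector of UTRs
#' @param site_types qualifying site types
#' @return logical matrix, genes x miRNAs
#' @export
target_matrix <- function(mirnas, utrs, site_types = DEFAULT_SITE_TYPES) {
  utrs <- utr_set(utrs)
  if (!is.list(mirnas))
    mirnas <- mapply(mirna_sequence, names(mirnas), mirnas, SIMPLIFY = FALSE)
  out <- matrix(FALSE, nrow = length(utrs), ncol = length(mirnas),
                dimnames = list(names(utrs),
                                vapply(mirnas, `[[`, "", "id")))
  for (m in mirnas) {
    loci <- seed_site_loci(m, utrs)
    ids <- unique(loci$gene_id[loci$site_type %in% site_types])
    out[ids, m$id] <- TRUE
  }
  out
}
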