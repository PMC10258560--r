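# Read preparation: junction filtering, trimming, UMI tagging, and (for RB
# libraries) barcode extraction and error-correction clustering.
#
# All sequence matching here is substitution-only (Hamming): the library
# chemistry this package models produces substitution errors, and Hamming
# semantics keep every rule exactly testable against brute force.

#' Find the transposon terminus in forward reads
#'
#' Returns, for each sequence, the leftmost window whose Hamming distance to
#' `terminus` is at most `max_mismatches` (no indels). Offsets are 1-based;
#' `NA` means no window qualifies.
#'
#' @param seqs character vector of read sequences.
#' @param terminus terminus sequence to locate.
#' @param max_mismatches maximum substitutions permitted (default 2).
#' @return tibble with columns `offset` (1-based start, `NA` if absent),
#'   `mismatches`, and `terminus_end` (1-based last base of the match).
#' @export
match_terminus <- function(seqs, terminus = TN_TERMINUS,
                           max_mismatches = 2L) {
  stopifnot(nchar(terminus) > 0L)
  m <- cpp_hamming_search(as.character(seqs), terminus,
                          as.integer(max_mismatches))
  tibble::tibble(
    offset = m[, 1L],
    mismatches = m[, 2L],
    terminus_end = m[, 1L] + nchar(terminus) - 1L
  )
}

#' Filter read pairs for the transposon junction
#'
#' Re-pairs the two FASTQ files by read id (orphans on either side are
#' dropped and counted) and keeps only pairs whose forward read carries the
#' transposon terminus within the mismatch bound.
#'
#' @param r1_path,r2_path forward/reverse FASTQ paths (plain or gzip).
#' @param profile a [protocol_profile()].
#' @param max_mismatches substitutions permitted in the terminus match.
#' @return list with `pairs` (tibble: `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`, `terminus_offset`, `terminus_end`) and `stats` (named list:
#'   `input_r1`, `input_r2`, `paired`, `orphans`, `terminus_matched`,
#'   `kept`).
#' @export
filter_junction_pairs <- function(r1_path, r2_path, profile,
                                  max_mismatches = 2L) {
  r1 <- read_fastq(r1_path)
  r2 <- read_fastq(r2_path)
  ids1 <- sub("/1$", "", r1$read_id)
  ids2 <- sub("/2$", "", r2$read_id)
  common <- intersect(ids1, ids2)
  i1 <- match(common, ids1)
  i2 <- match(common, ids2)
  orphans <- (nrow(r1) - length(common)) + (nrow(r2) - length(common))
  mt <- match_terminus(r1$seq[i1], profile$terminus, max_mismatches)
  keep <- !is.na(mt$offset)
  pairs <- tibble::tibble(
    read_id = common[keep],
    seq1 = r1$seq[i1][keep],
    qual1 = r1$qual[i1][keep],
    seq2 = r2$seq[i2][keep],
    qual2 = r2$qual[i2][keep],
    terminus_offset = mt$offset[keep],
    terminus_end = mt$terminus_end[keep]
  )
  list(
    pairs = pairs,
    stats = list(input_r1 = nrow(r1), input_r2 = nrow(r2),
                 paired = length(common), orphans = orphans,
                 terminus_matched = sum(keep), kept = nrow(pairs))
  )
}

#' Tag UMIs and trim read pairs down to genomic sequence
#'
#' The UMI is the first `umi_len` bases of the reverse read; it is removed
#' from the sequence and appended to the read identifier after a `":"`
#' separator. In `anchor` mode the forward read is trimmed through the end
#' of its terminus match (requires the `terminus_end` column produced by
#' [filter_junction_pairs()]); in `fixed` mode exactly `fixed_offsets` bases
#' are removed from the front of each mate (the reverse-read offset applies
#' after the UMI). Pairs failing the mean-quality threshold or too short to
#' trim are dropped and counted.
#'
#' @param pairs pair tibble from [filter_junction_pairs()], or any tibble
#'   with `read_id`, `seq1`, `qual1`, `seq2`, `qual2` (plus `terminus_end`
#'   for anchor mode).
#' @param profile a [protocol_profile()].
#' @param trim_mode `"anchor"` (default) or `"fixed"`.
#' @param fixed_offsets integer vector `c(r1, r2)` of front-trim lengths for
#'   fixed mode.
#' @param min_mean_qual drop a pair when either mate's mean Phred quality is
#'   below this (default 15).
#' @return list with `fragments` (tibble: `read_id`, `genomic_seq_r1`,
#'   `genomic_seq_r2`, `umi`) and `stats` (`input`, `low_quality`,
#'   `too_short`, `kept`).
#' @export
tag_umi_and_trim <- function(pairs, profile,
                             trim_mode = c("anchor", "fixed"),
                             fixed_offsets = c(r1 = 0L, r2 = 0L),
                             min_mean_qual = 15) {
  trim_mode <- match.arg(trim_mode)
  n_in <- nrow(pairs)
  if (n_in == 0L) {
    return(list(
      fragments = tibble::tibble(read_id = character(),
                                 genomic_seq_r1 = character(),
                                 genomic_seq_r2 = character(),
                                 umi = character()),
      stats = list(input = 0L, low_quality = 0L, too_short = 0L, kept = 0L)
    ))
  }
  ok_qual <- mean_phred(pairs$qual1) >= min_mean_qual &
    mean_phred(pairs$qual2) >= min_mean_qual
  n_lowq <- sum(!ok_qual)
  pairs <- pairs[ok_qual, , drop = FALSE]

  r1_from <- if (trim_mode == "anchor") {
    if (!"terminus_end" %in% names(pairs)) {
      stop("anchor mode needs the terminus_end column from ",
           "filter_junction_pairs()", call. = FALSE)
    }
    pairs$terminus_end + 1L
  } else {
    rep(as.integer(fixed_offsets[[1L]]) + 1L, nrow(pairs))
  }
  r2_from <- profile$umi_len +
    (if (trim_mode == "fixed") as.integer(fixed_offsets[[2L]]) else 0L) + 1L

  long_enough <- nchar(pairs$seq1) >= r1_from &
    nchar(pairs$seq2) >= r2_from
  n_short <- sum(!long_enough)
  pairs <- pairs[long_enough, , drop = FALSE]
  r1_from <- r1_from[long_enough]

  umi <- substr(pairs$seq2, 1L, profile$umi_len)
  fragments <- tibble::tibble(
    read_id = paste0(pairs$read_id, ":", umi),
    genomic_seq_r1 = substr(pairs$seq1, r1_from, nchar(pairs$seq1)),
    genomic_seq_r2 = substr(pairs$seq2, r2_from, nchar(pairs$seq2)),
    umi = umi
  )
  if ("barcode_raw" %in% names(pairs)) fragments$barcode_raw <- pairs$barcode_raw
  list(fragments = fragments,
       stats = list(input = n_in, low_quality = n_lowq,
                    too_short = n_short, kept = nrow(fragments)))
}

#' Extract RB-Tn-Seq barcodes between their flanking sequences
#'
#' Locates `flank5` by its leftmost Hamming match, then `flank3` downstream
#' of it, with `max_mismatches` substitutions allowed in total across both
#' flanks. Returns the sequence strictly between the two flanks; the caller
#' applies the expected-length filter (20 bp by default in the pipeline).
#'
#' @param seqs untrimmed forward-read sequences.
#' @param flank5,flank3 flanking sequences of the barcode cassette.
#' @param max_mismatches combined substitution budget across both flanks.
#' @return character vector of barcodes (`NA` where either flank is
#'   absent).
#' @export
extract_barcode <- function(seqs, flank5 = TN_FLANK5, flank3 = TN_FLANK3,
                            max_mismatches = 4L) {
  seqs <- as.character(seqs)
  m5 <- cpp_hamming_search(seqs, flank5, as.integer(max_mismatches))
  after5 <- m5[, 1L] + nchar(flank5)
  rest <- rep(NA_character_, length(seqs))
  has5 <- !is.na(m5[, 1L])
  rest[has5] <- substr(seqs[has5], after5[has5], nchar(seqs[has5]))
  budget3 <- as.integer(max_mismatches) - m5[, 2L]
  budget3[is.na(budget3)] <- -1L
  m3 <- cpp_hamming_search(rest, flank3, budget3)
  out <- rep(NA_character_, length(seqs))
  ok <- has5 & !is.na(m3[, 1L])
  out[ok] <- substr(rest[ok], 1L, m3[ok, 1L] - 1L)
  out
}

#' Consolidate nearly identical barcodes by greedy abundance clustering
#'
#' Barcodes are visited by descending read count (ties broken
#' lexicographically); each joins the first existing cluster whose center is
#' within Hamming distance `d`, otherwise it founds a new cluster with
#' itself as center. The procedure is deterministic and conserves reads.
#'
#' @param counts named integer vector (names = barcodes) or tibble with
#'   columns `barcode`, `count`.
#' @param d maximum Hamming distance to a cluster center (default 2).
#' @return tibble with columns `barcode`, `count`, `center`, ordered as
#'   visited. `attr(, "clusters")` holds the per-cluster summary
#'   (`center`, `n_members`, `total`).
#' @export
cluster_barcodes <- function(counts, d = 2L) {
  if (is.data.frame(counts)) {
    tbl <- tibble::tibble(barcode = as.character(counts$barcode),
                          count = as.integer(counts$count))
  } else {
    tbl <- tibble::tibble(barcode = names(counts),
                          count = as.integer(counts))
  }
  if (nrow(tbl) == 0L) {
    out <- tibble::tibble(barcode = character(), count = integer(),
                          center = character())
    attr(out, "clusters") <- tibble::tibble(center = character(),
                                            n_members = integer(),
                                            total = integer())
    return(out)
  }
  if (length(unique(nchar(tbl$barcode))) != 1L) {
    stop("barcodes must all have the same length", call. = FALSE)
  }
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$count), .data$barcode)
  idx <- cpp_greedy_cluster(tbl$barcode, as.integer(d))
  out <- dplyr::mutate(tbl, center = tbl$barcode[idx])
  attr(out, "clusters") <- out %>%
    dplyr::group_by(center = .data$center) %>%
    dplyr::summarise(n_members = dplyr::n(), total = sum(.data$count),
                     .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$total), .data$center)
  out
}

#' Prepare an RB-Tn-Seq pair table: barcode extraction plus length filter
#'
#' Convenience wrapper used by the pipeline: extracts barcodes from the
#' untrimmed forward reads of junction-filtered pairs and drops pairs whose
#' barcode is absent or does not match the expected length.
#'
#' @param pairs pair tibble from [filter_junction_pairs()].
#' @param profile a [protocol_profile()].
#' @param max_mismatches combined flank mismatch budget.
#' @return list with `pairs` (input rows with a valid `barcode_raw` column
#'   added) and `stats` (`input`, `no_barcode`, `bad_length`, `kept`).
#' @export
attach_barcodes <- function(pairs, profile, max_mismatches = 4L) {
  bc <- extract_barcode(pairs$seq1, profile$flank5, profile$flank3,
                        max_mismatches)
  missing <- is.na(bc)
  badlen <- !missing & nchar(bc) != profile$barcode_len
  keep <- !missing & !badlen
  out <- pairs[keep, , drop = FALSE]
  out$barcode_raw <- bc[keep]
  list(pairs = out,
       stats = list(input = nrow(pairs), no_barcode = sum(missing),
                    bad_length = sum(badlen), kept = nrow(out)))
}
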