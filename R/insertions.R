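# Insertion spectra, promoter orientation, enriched-peak calling, and
# nearest-gene annotation.
#
# A spectrum is the per-TA-site molecule count of one sample. Junction
# positions are snapped to the nearest TA site within a small tolerance
# (mariner inserts only at TA; residual offsets come from junction
# chemistry), and molecules with no TA nearby are tracked separately.

#' Build a per-TA-site insertion spectrum from deduplicated molecules
#'
#' Each molecule's junction position is snapped to the nearest TA site
#' within `snap_tolerance` nt (ties go to the upstream site). Molecules
#' with no TA site within tolerance are reported in the `off_ta`
#' attribute and excluded from `total_mapped`.
#'
#' @param molecules deduplicated alignment tibble from [dedup_umi()].
#' @param ta_sites TA index from [index_ta_sites()].
#' @param snap_tolerance maximum snap distance in nt (default 2).
#' @param sample sample label stored on the spectrum.
#' @param genome_length genome length, stored for peak calling.
#' @return a `tn_spectrum`: tibble (`chrom`, `position`, `strand`, `count`,
#'   `fraction`) with attributes `sample`, `total_mapped`, `off_ta`
#'   (tibble), `raw` (unsnapped junction counts), `genome_length`.
#'   Fractions are counts over `total_mapped` and sum to 1.
#' @export
build_spectrum <- function(molecules, ta_sites, snap_tolerance = 2L,
                           sample = "sample1", genome_length = NULL) {
  stopifnot(length(ta_sites) > 0L)
  snapped <- snap_to_ta(molecules$junction_pos, ta_sites, snap_tolerance)
  raw <- molecules %>%
    dplyr::count(.data$chrom, .data$junction_pos, .data$strand,
                 name = "count")
  on_ta <- !is.na(snapped)
  tab <- tibble::tibble(chrom = molecules$chrom[on_ta],
                        position = snapped[on_ta],
                        strand = molecules$strand[on_ta]) %>%
    dplyr::count(.data$chrom, .data$position, .data$strand, name = "count") %>%
    dplyr::arrange(.data$chrom, .data$position, .data$strand)
  total <- sum(tab$count)
  tab$fraction <- if (total > 0L) tab$count / total else numeric(nrow(tab))
  off <- tibble::tibble(chrom = molecules$chrom[!on_ta],
                        junction_pos = molecules$junction_pos[!on_ta],
                        strand = molecules$strand[!on_ta]) %>%
    dplyr::count(.data$chrom, .data$junction_pos, .data$strand,
                 name = "count")
  structure(tab, class = c("tn_spectrum", class(tab)),
            sample = sample, total_mapped = total, off_ta = off,
            raw = raw, genome_length = genome_length)
}

# Snap positions to the nearest TA site within tolerance; ties upstream.
snap_to_ta <- function(pos, ta_sites, tolerance) {
  ta <- sort(ta_sites)
  i <- findInterval(pos, ta)
  lo <- ifelse(i >= 1L, ta[pmax(i, 1L)], NA_integer_)
  hi <- ifelse(i < length(ta), ta[pmin(i + 1L, length(ta))], NA_integer_)
  dlo <- abs(pos - lo)
  dhi <- abs(hi - pos)
  dlo[is.na(dlo)] <- .Machine$integer.max
  dhi[is.na(dhi)] <- .Machine$integer.max
  best <- ifelse(dlo <= dhi, lo, hi)  # tie -> upstream (lo)
  bestd <- pmin(dlo, dhi)
  out <- ifelse(bestd <= tolerance, best, NA_integer_)
  as.integer(out)
}

#' Infer outward-facing promoter direction per insertion site
#'
#' Junction reads accumulate on the side opposite the outward-facing
#' promoter, so the promoter points against the strand carrying the reads.
#' With reads on both strands the majority decides and the minority
#' fraction is reported; exact ties are flagged ambiguous.
#'
#' @param spectrum a [build_spectrum()] result (stranded counts).
#' @return tibble with `chrom`, `position`, `n_plus`, `n_minus`,
#'   `promoter_orientation` (`+`, `-`, or `ambiguous`), and
#'   `minority_fraction`.
#' @export
infer_orientation <- function(spectrum) {
  spectrum %>%
    tibble::as_tibble() %>%
    tidyr::pivot_wider(id_cols = c("chrom", "position"),
                       names_from = "strand", values_from = "count",
                       values_fill = 0L) %>%
    dplyr::rename_with(~ c("+" = "n_plus", "-" = "n_minus")[.x],
                       dplyr::any_of(c("+", "-"))) %>%
    add_missing_strand_cols() %>%
    dplyr::mutate(
      promoter_orientation = dplyr::case_when(
        .data$n_plus > .data$n_minus ~ "-",
        .data$n_minus > .data$n_plus ~ "+",
        TRUE ~ "ambiguous"
      ),
      minority_fraction = pmin(.data$n_plus, .data$n_minus) /
        pmax(.data$n_plus + .data$n_minus, 1L)
    )
}

add_missing_strand_cols <- function(tbl) {
  for (col in c("n_plus", "n_minus")) {
    if (!col %in% names(tbl)) tbl[[col]] <- 0L
  }
  tbl
}

#' Call insertion-enriched peaks against a local Poisson background
#'
#' Slides fixed-width windows along the genome and tests each window's
#' molecule pileup against a local background rate
#' `lambda_local = max(lambda_genome, lambda_5kb, lambda_10kb)` (the
#' genome-wide rate and the rates in 5/10-kb neighborhoods, all scaled to
#' the window width and floored at 1e-6). P-values come from the upper-tail
#' Poisson survival function, are BH-adjusted across all tested windows,
#' and adjacent significant windows are merged into peaks.
#'
#' @param spectrum a [build_spectrum()] result.
#' @param genome_length genome length; defaults to the spectrum attribute.
#' @param window window width in nt (default 200).
#' @param step window step in nt (default `window / 2`).
#' @param q_max BH-adjusted significance cutoff (default 0.01).
#' @param features optional feature table for nearest-gene annotation.
#' @return a `tn_peaks` tibble: `chrom`, `start`, `end`, `summit`,
#'   `pileup`, `fold_enrichment`, `p`, `q`, and (when `features` is given)
#'   `nearest_gene`, `distance`. `attr(, "n_windows")` records how many
#'   windows were tested.
#' @export
call_peaks <- function(spectrum, genome_length = NULL, window = 200L,
                       step = window %/% 2L, q_max = 0.01,
                       features = NULL) {
  if (is.null(genome_length)) genome_length <- attr(spectrum, "genome_length")
  if (is.null(genome_length)) {
    stop("genome_length is required (not stored on the spectrum)",
         call. = FALSE)
  }
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), summit = integer(),
                          pileup = integer(), fold_enrichment = numeric(),
                          p = numeric(), q = numeric())
  if (nrow(spectrum) == 0L) {
    return(structure(empty, class = c("tn_peaks", class(empty)),
                     n_windows = 0L))
  }
  chrom <- spectrum$chrom[1L]
  pos <- spectrum$position
  cnt <- as.numeric(spectrum$count)
  o <- order(pos)
  pos <- pos[o]; cnt <- cnt[o]
  # collapse strands (upos stays in ascending numeric order)
  upos <- unique(pos)
  ucnt <- as.numeric(tapply(cnt, factor(pos, levels = upos), sum))
  csum <- cumsum(ucnt)
  total <- csum[length(csum)]
  range_sum <- function(lo, hi) {
    hi_i <- findInterval(hi, upos)
    lo_i <- findInterval(lo - 1L, upos)
    ifelse(hi_i >= 1L, csum[pmax(hi_i, 1L)], 0) -
      ifelse(lo_i >= 1L, csum[pmax(lo_i, 1L)], 0)
  }
  starts <- seq(1L, max(1L, genome_length - window + 1L), by = step)
  ends <- pmin(starts + window - 1L, genome_length)
  pileup <- range_sum(starts, ends)
  centers <- (starts + ends) %/% 2L
  lam_genome <- total * window / genome_length
  lam_5k <- range_sum(centers - 2500L, centers + 2499L) * window / 5000
  lam_10k <- range_sum(centers - 5000L, centers + 4999L) * window / 10000
  lam_local <- pmax(lam_genome, lam_5k, lam_10k, 1e-6)
  p <- stats::ppois(pileup - 1, lam_local, lower.tail = FALSE)
  q <- bh_adjust(p)
  sig <- which(q <= q_max & pileup > 0)
  n_windows <- length(starts)
  if (length(sig) == 0L) {
    return(structure(empty, class = c("tn_peaks", class(empty)),
                     n_windows = n_windows))
  }
  # merge overlapping/adjacent significant windows
  ms <- starts[sig]; me <- ends[sig]
  brk <- c(TRUE, ms[-1L] > me[-length(me)] + 1L)
  grp <- cumsum(brk)
  peaks <- purrr::map_dfr(split(seq_along(sig), grp), function(ii) {
    w <- sig[ii]
    pstart <- min(starts[w]); pend <- max(ends[w])
    inside <- upos >= pstart & upos <= pend
    summit <- if (any(inside)) {
      cand <- upos[inside]
      cand[which.max(ucnt[inside])]
    } else pstart
    best <- w[which.max(pileup[w])]
    peak_pileup <- max(pileup[w])
    peak_fold <- peak_pileup / lam_local[best]
    peak_p <- min(p[w])
    peak_q <- min(q[w])
    tibble::tibble(
      chrom = chrom,
      start = as.integer(pstart), end = as.integer(pend),
      summit = as.integer(summit),
      pileup = as.integer(peak_pileup),
      fold_enrichment = peak_fold,
      p = peak_p, q = peak_q
    )
  })
  peaks <- dplyr::arrange(peaks, .data$start)
  if (!is.null(features)) peaks <- nearest_gene(peaks, features)
  structure(peaks, class = c("tn_peaks", setdiff(class(peaks), "tn_peaks")),
            n_windows = n_windows)
}

#' Annotate intervals with their nearest gene
#'
#' Distance is 0 for any overlap; otherwise it is the gap to the closest
#' feature edge, signed negative when the interval lies 5' of the feature
#' on the feature's coding strand. Exact ties on the unsigned distance are
#' broken by the lexicographically smallest `gene_id`.
#'
#' @param intervals tibble with `start`, `end` (1-based inclusive), e.g.
#'   peaks from [call_peaks()].
#' @param features feature tibble (`gene_id`, `start`, `end`, `strand`).
#' @return `intervals` with `nearest_gene` and `distance` columns added.
#' @export
nearest_gene <- function(intervals, features) {
  if (nrow(features) == 0L) stop("empty annotation", call. = FALSE)
  n <- nrow(intervals); m <- nrow(features)
  if (n == 0L) {
    intervals$nearest_gene <- character(0)
    intervals$distance <- integer(0)
    return(intervals)
  }
  ps <- matrix(intervals$start, n, m)
  pe <- matrix(intervals$end, n, m)
  fs <- matrix(features$start, n, m, byrow = TRUE)
  fe <- matrix(features$end, n, m, byrow = TRUE)
  gap_right <- fs - pe  # > 0 when interval entirely left of feature
  gap_left <- ps - fe   # > 0 when interval entirely right of feature
  dist_abs <- pmax(gap_right, gap_left, 0L)
  plus <- matrix(features$strand == "+", n, m, byrow = TRUE)
  upstream <- ifelse(plus, gap_right > 0L, gap_left > 0L)
  signed <- ifelse(upstream, -dist_abs, dist_abs)
  # order features by gene_id for the tie rule
  gene_rank <- rank(features$gene_id, ties.method = "first")
  pick <- vapply(seq_len(n), function(i) {
    d <- dist_abs[i, ]
    cand <- which(d == min(d))
    cand[which.min(gene_rank[cand])]
  }, integer(1))
  intervals$nearest_gene <- features$gene_id[pick]
  intervals$distance <- as.integer(signed[cbind(seq_len(n), pick)])
  intervals
}

#' Export a spectrum as bedGraph (normalized fractions)
#'
#' @param spectrum a [build_spectrum()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_bedgraph <- function(spectrum, path) {
  tbl <- spectrum %>%
    tibble::as_tibble() %>%
    dplyr::group_by(.data$chrom, .data$position) %>%
    dplyr::summarise(fraction = sum(.data$fraction), .groups = "drop") %>%
    dplyr::transmute(.data$chrom, start = .data$position - 1L,
                     end = .data$position + 1L, .data$fraction)
  readr::write_tsv(tbl, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @export
print.tn_spectrum <- function(x, ...) {
  cat("<tn_spectrum> sample=", attr(x, "sample"), ", ",
      nrow(x), " TA sites, ", attr(x, "total_mapped"),
      " molecules (", nrow(attr(x, "off_ta")), " off-TA positions)\n",
      sep = "")
  NextMethod()
}
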