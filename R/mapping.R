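# Fragment placement and molecule deduplication.
#
# The built-in placer is an exact-seed + Hamming-extension mapper with a
# unique-best requirement: it is designed for desk-scale genomes, and SAM
# import is the escape hatch for externally aligned data. Deduplication
# collapses PCR copies by (coordinate, strand, UMI) with the directional
# UMI-merging rule.

#' Build an exact k-mer seed index over a genome
#'
#' @param genome a [tn_genome].
#' @param k seed length (default 20).
#' @return an object of class `tn_index` mapping every genomic k-mer to its
#'   1-based positions.
#' @export
build_index <- function(genome, k = 20L) {
  stopifnot(inherits(genome, "tn_genome"))
  k <- as.integer(k)
  if (k > genome$length) {
    warning("k = ", k, " exceeds genome length ", genome$length,
            "; index is empty")
    lookup <- list()
  } else {
    n <- genome$length - k + 1L
    kmers <- substring(genome$sequence, seq_len(n), seq_len(n) + k - 1L)
    lookup <- split(seq_len(n), kmers)
  }
  structure(list(k = k, lookup = lookup, genome_name = genome$name,
                 genome_length = genome$length),
            class = "tn_index")
}

#' @export
print.tn_index <- function(x, ...) {
  cat("<tn_index> ", x$genome_name, ": k=", x$k, ", ",
      format(length(x$lookup), big.mark = ","), " distinct k-mers\n",
      sep = "")
  invisible(x)
}

#' Place reads on the genome by exact seed + Hamming extension
#'
#' Seeds up to `n_seeds` non-overlapping k-mers of each read (and of its
#' reverse complement) against the index, extends candidates by Hamming
#' comparison, and keeps the unique best placement. Multiple seeds make the
#' placer robust to substitution errors landing in any single seed. Ties on
#' mismatch count make a read ambiguous, and ambiguous reads are unplaced.
#'
#' @param seqs character vector of read sequences.
#' @param index a [build_index()] result.
#' @param genome the [tn_genome] the index was built on.
#' @param max_mm maximum substitutions per read (default 3).
#' @param n_seeds maximum number of non-overlapping seed k-mers per read.
#' @return tibble with one row per read: `strand` (+/-, `NA` if unplaced),
#'   `start`, `end` (1-based genomic span), `mismatches`, and `status`
#'   (`placed`, `unmapped`, `ambiguous`).
#' @keywords internal
place_reads <- function(seqs, index, genome, max_mm = 3L, n_seeds = 3L) {
  n <- length(seqs)
  res <- tibble::tibble(strand = rep(NA_character_, n),
                        start = rep(NA_integer_, n),
                        end = rep(NA_integer_, n),
                        mismatches = rep(NA_integer_, n),
                        status = rep("unmapped", n))
  if (n == 0L) return(res)
  k <- index$k
  len <- nchar(seqs)
  valid <- which(len >= k)
  if (length(valid) == 0L) return(res)
  rc <- rep(NA_character_, n)
  rc[valid] <- revcomp(seqs[valid])

  collect <- function(idx, strings) {
    out <- vector("list", n_seeds)
    for (s in seq_len(n_seeds)) {
      off <- (s - 1L) * k
      use <- idx[len[idx] >= off + k]
      if (length(use) == 0L) break
      km <- substr(strings[use], off + 1L, off + k)
      hits <- index$lookup[km]
      nh <- lengths(hits)
      out[[s]] <- tibble::tibble(
        row = rep(use, nh),
        start = unlist(hits, use.names = FALSE) - off
      )
    }
    dplyr::bind_rows(out)
  }
  fwd <- collect(valid, seqs)
  rev <- collect(valid, rc)
  cand <- dplyr::bind_rows(
    dplyr::mutate(fwd, strand = "+"),
    dplyr::mutate(rev, strand = "-")
  )
  cand <- dplyr::distinct(cand[cand$start >= 1L, , drop = FALSE])
  if (nrow(cand) == 0L) return(res)
  qseq <- ifelse(cand$strand == "+", seqs[cand$row], rc[cand$row])
  cand$mm <- cpp_mismatch_at(qseq, genome$sequence, cand$start,
                             as.integer(max_mm))
  cand <- cand[!is.na(cand$mm) & cand$mm <= max_mm, , drop = FALSE]
  if (nrow(cand) == 0L) return(res)

  cand <- cand %>%
    dplyr::group_by(.data$row) %>%
    dplyr::mutate(best = min(.data$mm), n_best = sum(.data$mm == min(.data$mm))) %>%
    dplyr::ungroup()
  amb <- unique(cand$row[cand$n_best > 1L])
  res$status[amb] <- "ambiguous"
  win <- cand[cand$mm == cand$best & !(cand$row %in% amb), , drop = FALSE]
  res$strand[win$row] <- win$strand
  res$start[win$row] <- win$start
  res$end[win$row] <- win$start + len[win$row] - 1L
  res$mismatches[win$row] <- win$mm
  res$status[win$row] <- "placed"
  res
}

#' Map tagged fragments as concordant pairs
#'
#' Places both mates with [place_reads()] and keeps pairs whose mates land
#' on opposite strands in the proper orientation with an insert no longer
#' than `max_insert`. The junction position is the 5'-most genomic base of
#' the forward read.
#'
#' @param fragments tibble from [tag_umi_and_trim()] (columns
#'   `read_id`, `genomic_seq_r1`, `genomic_seq_r2`, `umi`, optionally
#'   `barcode_raw`/`barcode_cluster`).
#' @param index a [build_index()] result.
#' @param genome the matching [tn_genome].
#' @param profile a [protocol_profile()] (for `max_insert`).
#' @param max_mm maximum substitutions per read.
#' @return list with `alignments` (tibble: `read_id`, `umi`, barcode
#'   columns if present, `chrom`, `junction_pos`, `strand`, `start`, `end`,
#'   `insert_size`) and `stats` (`input`, `unmapped`, `ambiguous`,
#'   `discordant`, `mapped`).
#' @export
map_fragments <- function(fragments, index, genome, profile, max_mm = 3L) {
  n <- nrow(fragments)
  p1 <- place_reads(fragments$genomic_seq_r1, index, genome, max_mm)
  p2 <- place_reads(fragments$genomic_seq_r2, index, genome, max_mm)

  both_placed <- p1$status == "placed" & p2$status == "placed"
  opposite <- both_placed & p1$strand != p2$strand
  span_start <- ifelse(p1$strand == "+", p1$start, p2$start)
  span_end <- ifelse(p1$strand == "+", p2$end, p1$end)
  proper <- opposite & span_end >= span_start &
    (span_end - span_start + 1L) <= profile$max_insert &
    p1$start >= span_start & p1$end <= span_end
  proper[is.na(proper)] <- FALSE

  ali <- tibble::tibble(
    read_id = fragments$read_id[proper],
    umi = fragments$umi[proper],
    chrom = genome$name,
    junction_pos = as.integer(ifelse(p1$strand[proper] == "+",
                                     p1$start[proper], p1$end[proper])),
    strand = p1$strand[proper],
    start = as.integer(span_start[proper]),
    end = as.integer(span_end[proper]),
    insert_size = as.integer(span_end[proper] - span_start[proper] + 1L)
  )
  for (col in c("barcode_raw", "barcode_cluster")) {
    if (col %in% names(fragments)) ali[[col]] <- fragments[[col]][proper]
  }
  n_unmapped <- sum(p1$status == "unmapped" | p2$status == "unmapped")
  n_amb <- sum((p1$status == "ambiguous" | p2$status == "ambiguous") &
                 p1$status != "unmapped" & p2$status != "unmapped")
  list(alignments = ali,
       stats = list(input = n, unmapped = n_unmapped, ambiguous = n_amb,
                    discordant = n - n_unmapped - n_amb - nrow(ali),
                    mapped = nrow(ali)))
}

#' Map a single tagged fragment
#'
#' Single-pair wrapper around [map_fragments()].
#'
#' @inheritParams map_fragments
#' @param fragment one-row fragment tibble.
#' @return a one-row alignment tibble, or `NULL` when the pair does not
#'   place concordantly and uniquely.
#' @export
map_pair <- function(fragment, index, genome, profile, max_mm = 3L) {
  out <- map_fragments(fragment[1L, , drop = FALSE], index, genome, profile,
                       max_mm)
  if (nrow(out$alignments) == 0L) NULL else out$alignments
}

# Reference width consumed by a CIGAR string (M/D/N/=/X).
cigar_ref_width <- function(cigar) {
  vapply(regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar)),
         function(ops) {
           n <- as.integer(sub("[MIDNSHP=X]", "", ops))
           sum(n[grepl("[MDN=X]", ops)])
         }, integer(1))
}

#' Import externally produced alignments from SAM/BAM
#'
#' Keeps proper pairs with both mates mapped and insert size within the
#' profile bound; coordinates are converted to the internal 1-based
#' convention. The UMI is recovered from the read-name suffix after the
#' last `":"`.
#'
#' @param path SAM or BAM file with paired alignments.
#' @param profile a [protocol_profile()] (for `max_insert`).
#' @return list with `alignments` (same columns as [map_fragments()]) and
#'   `stats` (`records`, `skipped_unmapped`, `skipped_improper`,
#'   `skipped_insert`, `kept`).
#' @export
import_sam <- function(path, profile) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "isize")
  )
  b <- Rsamtools::scanBam(path, param = param)[[1L]]
  flag <- b$flag
  is_r1 <- bitwAnd(flag, 64L) > 0L
  unmapped <- bitwAnd(flag, 4L) > 0L | bitwAnd(flag, 8L) > 0L
  proper <- bitwAnd(flag, 2L) > 0L
  keep <- is_r1 & !unmapped & proper
  n_r1 <- sum(is_r1)
  skipped_unmapped <- sum(is_r1 & unmapped)
  skipped_improper <- sum(is_r1 & !unmapped & !proper)

  qname <- b$qname[keep]
  no_umi <- !grepl(":", qname, fixed = TRUE)
  if (any(no_umi)) {
    stop("missing UMI suffix (no ':' in read name) in SAM record: ",
         qname[no_umi][1L], call. = FALSE)
  }
  isize <- b$isize[keep]
  pos <- b$pos[keep]
  width <- cigar_ref_width(b$cigar[keep])
  strand <- as.character(b$strand[keep])
  start <- as.integer(ifelse(isize >= 0L, pos, pos + width - 1L + isize + 1L))
  end <- as.integer(ifelse(isize >= 0L, pos + isize - 1L, pos + width - 1L))
  insert <- abs(isize)
  ok <- insert > 0L & insert <= profile$max_insert
  skipped_insert <- sum(!ok)

  ali <- tibble::tibble(
    read_id = qname[ok],
    umi = sub(".*:", "", qname[ok]),
    chrom = as.character(b$rname[keep])[ok],
    junction_pos = as.integer(ifelse(strand[ok] == "+", pos[ok],
                                     pos[ok] + width[ok] - 1L)),
    strand = strand[ok],
    start = start[ok],
    end = end[ok],
    insert_size = as.integer(insert[ok])
  )
  list(alignments = ali,
       stats = list(records = length(flag), pairs = n_r1,
                    skipped_unmapped = skipped_unmapped,
                    skipped_improper = skipped_improper,
                    skipped_insert = skipped_insert, kept = nrow(ali)))
}

# Directional UMI components within one coordinate group. `umis` and
# `counts` describe distinct UMIs; returns the index of the representative
# (cluster seed) for each UMI. Edges run from a to b when the UMIs differ
# at exactly one position and count(a) >= 2*count(b) - 1; clusters are
# grown breadth-first from the highest-count unassigned UMI.
directional_components <- function(umis, counts) {
  o <- order(-counts, umis)
  n <- length(umis)
  assigned <- integer(n)
  for (ii in seq_len(n)) {
    i <- o[ii]
    if (assigned[i] > 0L) next
    assigned[i] <- i
    queue <- i
    while (length(queue) > 0L) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      open <- which(assigned == 0L)
      if (length(open) == 0L) break
      d <- cpp_hamming_pairs(rep(umis[cur], length(open)), umis[open])
      join <- open[d == 1L & counts[cur] >= 2L * counts[open] - 1L]
      if (length(join) > 0L) {
        assigned[join] <- i
        queue <- c(queue, join)
      }
    }
  }
  assigned
}

#' Deduplicate alignments into molecules by UMI and mapping coordinate
#'
#' Reads are grouped by (chrom, fragment span, strand); within a group,
#' UMIs at Hamming distance 1 are merged by the directional rule
#' (`count(a) >= 2 * count(b) - 1`), and each connected component becomes
#' one molecule represented by its highest-count UMI and that UMI's
#' earliest read id. Output order is deterministic (coordinate, then UMI).
#'
#' @param alignments alignment tibble from [map_fragments()] or
#'   [import_sam()].
#' @return tibble with one row per molecule: `read_id`, `umi`, barcode
#'   columns if present, `chrom`, `junction_pos`, `strand`, `start`, `end`,
#'   `insert_size`, `n_reads`.
#' @export
dedup_umi <- function(alignments) {
  if (nrow(alignments) == 0L) {
    return(dplyr::mutate(alignments, n_reads = integer(0)))
  }
  bc_cols <- intersect(c("barcode_raw", "barcode_cluster"),
                       names(alignments))
  ali <- dplyr::mutate(alignments, .row = dplyr::row_number())
  umi_tbl <- ali %>%
    dplyr::group_by(.data$chrom, .data$start, .data$end, .data$strand,
                    .data$umi) %>%
    dplyr::summarise(
      n = dplyr::n(),
      .first = min(.data$.row),
      read_id = dplyr::first(.data$read_id),
      junction_pos = .data$junction_pos[1L],
      insert_size = .data$insert_size[1L],
      .groups = "drop"
    )
  # majority barcode per (coordinate, UMI) group, ties to the smaller value
  for (col in bc_cols) {
    bcm <- ali %>%
      dplyr::count(.data$chrom, .data$start, .data$end, .data$strand,
                   .data$umi, .val = .data[[col]], name = ".nn") %>%
      dplyr::arrange(dplyr::desc(.data$.nn), .data$.val) %>%
      dplyr::distinct(.data$chrom, .data$start, .data$end, .data$strand,
                      .data$umi, .keep_all = TRUE)
    names(bcm)[names(bcm) == ".val"] <- col
    umi_tbl <- dplyr::left_join(
      umi_tbl, dplyr::select(bcm, -".nn"),
      by = c("chrom", "start", "end", "strand", "umi")
    )
  }
  key <- paste(umi_tbl$chrom, umi_tbl$start, umi_tbl$end, umi_tbl$strand,
               sep = "\r")
  grp <- split(seq_len(nrow(umi_tbl)), key)
  sizes <- lengths(grp)
  singles <- unlist(grp[sizes == 1L], use.names = FALSE)
  multi <- grp[sizes > 1L]
  rows_list <- vector("list", length(multi))
  nreads_list <- vector("list", length(multi))
  for (m in seq_along(multi)) {
    g <- multi[[m]]
    comp <- directional_components(umi_tbl$umi[g], umi_tbl$n[g])
    reps <- unique(comp)
    rows_list[[m]] <- g[reps]
    nreads_list[[m]] <- vapply(reps, function(r) sum(umi_tbl$n[g[comp == r]]),
                               integer(1))
  }
  rep_rows <- c(singles, unlist(rows_list, use.names = FALSE))
  rep_nreads <- c(umi_tbl$n[singles], unlist(nreads_list, use.names = FALSE))
  out <- umi_tbl[rep_rows, , drop = FALSE]
  out$n_reads <- rep_nreads
  out <- dplyr::arrange(out, .data$chrom, .data$start, .data$end,
                        .data$strand, .data$umi)
  dplyr::select(out, "read_id", "umi", dplyr::all_of(bc_cols), "chrom",
                "junction_pos", "strand", "start", "end", "insert_size",
                "n_reads")
}
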