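# Barcode-defined lineage reconstruction: demultiplexing pooled samples,
# founder identification, cross-contamination detection, and convergent
# insertion loci across independent lineages.
#
# A lineage is the set of insertion spectra across time points that share
# one transposon barcode. Spectra are renormalized within lineage and time
# point so pooled sequencing-depth differences do not distort longitudinal
# comparisons.

#' Demultiplex molecules into barcode-defined lineages
#'
#' Every molecule with a barcode cluster is assigned to exactly one
#' lineage (its cluster center); molecules without barcodes are reported
#' separately. Per-lineage spectra are renormalized within each
#' (lineage, time point).
#'
#' @param molecules deduplicated molecule tibble with columns `sample`,
#'   `barcode_cluster`, `chrom`, `position` (TA-snapped), `strand`, and
#'   optionally `count` (default one molecule per row).
#' @param sample_manifest tibble mapping `sample` to `time_point` (and
#'   optionally `replicate`).
#' @return a `tn_lineages` tibble (`barcode`, `time_point`, `chrom`,
#'   `position`, `strand`, `count`, `fraction`) with attributes `flags`
#'   (per-lineage `ambiguous_founder` flag), `unassigned` (molecules
#'   without barcode), and `time_points` (sorted).
#' @export
demultiplex_lineages <- function(molecules, sample_manifest) {
  missing <- setdiff(unique(molecules$sample), sample_manifest$sample)
  if (length(missing) > 0L) {
    stop("sample(s) absent from manifest: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"count" %in% names(molecules)) molecules$count <- 1L
  mol <- dplyr::left_join(molecules,
                          dplyr::select(sample_manifest, "sample",
                                        "time_point"),
                          by = "sample")
  unassigned <- dplyr::filter(mol, is.na(.data$barcode_cluster))
  assigned <- dplyr::filter(mol, !is.na(.data$barcode_cluster))
  spectra <- assigned %>%
    dplyr::group_by(barcode = .data$barcode_cluster, .data$time_point,
                    .data$chrom, .data$position, .data$strand) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop") %>%
    dplyr::group_by(.data$barcode, .data$time_point) %>%
    dplyr::mutate(fraction = .data$count / sum(.data$count)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$barcode, .data$time_point, .data$position,
                   .data$strand)
  tps <- sort(unique(sample_manifest$time_point))
  flags <- spectra %>%
    dplyr::group_by(.data$barcode) %>%
    dplyr::summarise(ambiguous_founder = !(tps[1L] %in% .data$time_point),
                     .groups = "drop")
  structure(spectra, class = c("tn_lineages", class(spectra)),
            flags = flags, unassigned = unassigned, time_points = tps)
}

#' Identify founder insertion sites per lineage
#'
#' The founder site(s) of a lineage are the sites holding at least
#' `min_fraction` of the earliest time point's molecules (typically one
#' site; several can qualify for multicopy loci). Lineages with no
#' qualifying site, or absent from the earliest time point, are flagged
#' `ambiguous_founder`.
#'
#' @param lineages a [demultiplex_lineages()] result.
#' @param min_fraction founder fraction threshold (default 0.5).
#' @return tibble (`barcode`, `position`, `fraction`, `ambiguous_founder`).
#'   Flagged lineages appear with `NA` position.
#' @export
identify_founder <- function(lineages, min_fraction = 0.5) {
  tps <- attr(lineages, "time_points")
  t0 <- tps[1L]
  earliest <- lineages %>%
    tibble::as_tibble() %>%
    dplyr::filter(.data$time_point == t0) %>%
    dplyr::group_by(.data$barcode, .data$position) %>%
    dplyr::summarise(fraction = sum(.data$fraction), .groups = "drop_last")
  founders <- earliest %>%
    dplyr::filter(.data$fraction >= min_fraction) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(ambiguous_founder = FALSE)
  all_bc <- unique(lineages$barcode)
  missing <- setdiff(all_bc, founders$barcode)
  dplyr::bind_rows(
    founders,
    tibble::tibble(barcode = missing, position = NA_integer_,
                   fraction = NA_real_, ambiguous_founder = TRUE)
  ) %>%
    dplyr::arrange(.data$barcode, .data$position)
}

#' Detect cross-contamination between replicate lineages
#'
#' A replicate is flagged when at least `min_reads` end-point molecules
#' carry a barcode cluster absent from its expected founder set; when the
#' foreign barcode is another replicate's founder, that replicate is named
#' as the likely source.
#'
#' @param molecules molecule tibble with `sample`, `barcode_cluster` (and
#'   optionally `count`).
#' @param sample_manifest tibble mapping `sample` to `replicate` and
#'   `time_point`.
#' @param founder_barcodes tibble (`replicate`, `barcode`) giving each
#'   replicate's expected founder barcode set (from the earliest-time-point
#'   sequencing).
#' @param min_reads minimum foreign molecules to flag (default 10).
#' @return tibble (`replicate`, `barcode`, `n_molecules`, `flagged`,
#'   `source_replicate`); one row per foreign barcode observed.
#' @export
detect_contamination <- function(molecules, sample_manifest,
                                 founder_barcodes, min_reads = 10L) {
  missing <- setdiff(unique(molecules$sample), sample_manifest$sample)
  if (length(missing) > 0L) {
    stop("sample(s) absent from manifest: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"count" %in% names(molecules)) molecules$count <- 1L
  t_end <- max(sample_manifest$time_point)
  endpoint <- molecules %>%
    dplyr::left_join(dplyr::select(sample_manifest, "sample", "replicate",
                                   "time_point"), by = "sample") %>%
    dplyr::filter(.data$time_point == t_end,
                  !is.na(.data$barcode_cluster))
  foreign <- endpoint %>%
    dplyr::anti_join(founder_barcodes,
                     by = c("replicate", "barcode_cluster" = "barcode")) %>%
    dplyr::group_by(.data$replicate, barcode = .data$barcode_cluster) %>%
    dplyr::summarise(n_molecules = sum(.data$count), .groups = "drop")
  src <- founder_barcodes %>%
    dplyr::group_by(.data$barcode) %>%
    dplyr::summarise(source_replicate = paste(sort(unique(.data$replicate)),
                                              collapse = ","),
                     .groups = "drop")
  foreign %>%
    dplyr::left_join(src, by = "barcode") %>%
    dplyr::mutate(flagged = .data$n_molecules >= min_reads) %>%
    dplyr::arrange(.data$replicate, dplyr::desc(.data$n_molecules))
}

#' Find convergent insertion loci across lineages
#'
#' Bins each lineage's end-point spectrum into fixed windows and reports
#' windows where at least `min_lineages` independent lineages each place
#' at least `min_fraction` of their end-point molecules. Also reports,
#' per lineage, donor-site retention (the founder site still present at
#' the end point) and the multisite signature (two or more high-fraction
#' end-point sites).
#'
#' @param lineages a [demultiplex_lineages()] result.
#' @param window window width in nt (default 1000).
#' @param min_lineages minimum supporting lineages (default 2).
#' @param min_fraction minimum end-point fraction per lineage in a window
#'   (default 0.05).
#' @param founder_min_fraction threshold passed to [identify_founder()].
#' @param multisite_fraction per-site fraction defining a "high-fraction"
#'   end-point site for the multisite flag (default 0.2).
#' @return a `tn_convergence` tibble (`chrom`, `window_start`,
#'   `window_end`, `n_lineages`, `lineages`) with attributes
#'   `donor_retention` (per lineage: founder position, end fraction,
#'   `retained`) and `multisite` (per lineage: `n_high_sites`,
#'   `multisite`).
#' @export
find_convergent_loci <- function(lineages, window = 1000L,
                                 min_lineages = 2L, min_fraction = 0.05,
                                 founder_min_fraction = 0.5,
                                 multisite_fraction = 0.2) {
  tps <- attr(lineages, "time_points")
  t_end <- tps[length(tps)]
  endpoint <- lineages %>%
    tibble::as_tibble() %>%
    dplyr::filter(.data$time_point == t_end)
  binned <- endpoint %>%
    dplyr::mutate(bin = (.data$position - 1L) %/% window) %>%
    dplyr::group_by(.data$barcode, .data$chrom, .data$bin) %>%
    dplyr::summarise(fraction = sum(.data$fraction), .groups = "drop")
  conv <- binned %>%
    dplyr::filter(.data$fraction >= min_fraction) %>%
    dplyr::group_by(.data$chrom, .data$bin) %>%
    dplyr::summarise(n_lineages = dplyr::n_distinct(.data$barcode),
                     lineages = paste(sort(unique(.data$barcode)),
                                      collapse = ","),
                     .groups = "drop") %>%
    dplyr::filter(.data$n_lineages >= min_lineages) %>%
    dplyr::transmute(.data$chrom,
                     window_start = .data$bin * window + 1L,
                     window_end = (.data$bin + 1L) * window,
                     .data$n_lineages, .data$lineages) %>%
    dplyr::arrange(.data$chrom, .data$window_start)

  founders <- identify_founder(lineages, founder_min_fraction)
  end_at <- function(bc, pos) {
    hit <- endpoint$barcode == bc & endpoint$position == pos
    if (any(hit)) sum(endpoint$fraction[hit]) else 0
  }
  donor <- founders %>%
    dplyr::filter(!.data$ambiguous_founder) %>%
    dplyr::rowwise() %>%
    dplyr::mutate(end_fraction = end_at(.data$barcode, .data$position),
                  retained = .data$end_fraction >= min_fraction) %>%
    dplyr::ungroup() %>%
    dplyr::select("barcode", "position", "end_fraction", "retained")
  multisite <- endpoint %>%
    dplyr::group_by(.data$barcode, .data$position) %>%
    dplyr::summarise(fraction = sum(.data$fraction), .groups = "drop") %>%
    dplyr::group_by(.data$barcode) %>%
    dplyr::summarise(n_high_sites = sum(.data$fraction >= multisite_fraction),
                     .groups = "drop") %>%
    dplyr::mutate(multisite = .data$n_high_sites >= 2L)
  structure(conv, class = c("tn_convergence", class(conv)),
            donor_retention = donor, multisite = multisite)
}

#' @export
print.tn_convergence <- function(x, ...) {
  cat("<tn_convergence> ", nrow(x), " convergent window(s); ",
      sum(attr(x, "multisite")$multisite), " multisite lineage(s)\n",
      sep = "")
  NextMethod()
}
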