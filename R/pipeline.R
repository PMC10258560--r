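# End-to-end orchestration: simulate (optional) -> read prep -> barcode
# clustering -> mapping -> deduplication -> spectra -> peaks -> optional
# enrichment and lineage reports, with a machine-readable run manifest.
#
# Re-running with the same configuration and seed produces byte-identical
# tabular outputs.

#' Validate a pipeline configuration
#'
#' @param config a named list (see [run_pipeline()]) or a path to a YAML
#'   file holding one.
#' @return the validated config list, with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  fail <- function(...) {
    stop(errorCondition(paste0(...), class = c("tn_config_error", "error")))
  }
  if (is.null(config$mode) ||
      !config$mode %in% c("tnseq", "rbtnseq")) {
    fail("config$mode must be 'tnseq' or 'rbtnseq'")
  }
  if (is.null(config$outdir)) fail("config$outdir is required")
  sim <- !is.null(config$simulate)
  if (sim && is.null(config$seed)) {
    fail("config$seed is required when simulating")
  }
  if (!sim) {
    for (f in c("genome_fasta", "samples")) {
      if (is.null(config$inputs[[f]])) {
        fail("config$inputs$", f, " is required without simulation")
      }
    }
  }
  config$enrichment <- isTRUE(config$enrichment)
  config$lineage <- isTRUE(config$lineage) ||
    (is.null(config$lineage) && config$mode == "rbtnseq")
  if (config$enrichment && !sim && is.null(config$inputs$features)) {
    fail("enrichment is enabled but no gene annotation is configured")
  }
  prof_args <- config$profile %||% list()
  prof_args$mode <- config$mode
  config$profile_obj <- do.call(protocol_profile, prof_args)
  th <- config$thresholds %||% list()
  config$thresholds <- list(
    terminus_mismatches = th$terminus_mismatches %||% 2L,
    flank_mismatches = th$flank_mismatches %||% 4L,
    barcode_cluster_d = th$barcode_cluster_d %||% 2L,
    map_mismatches = th$map_mismatches %||% 3L,
    snap_tolerance = th$snap_tolerance %||% 2L,
    min_mean_qual = th$min_mean_qual %||% 15,
    peak_window = th$peak_window %||% 200L,
    peak_q_max = th$peak_q_max %||% 0.01,
    diff_min_total = th$diff_min_total %||% 128L,
    founder_min_fraction = th$founder_min_fraction %||% 0.5,
    convergence_window = th$convergence_window %||% 1000L,
    convergence_min_fraction = th$convergence_min_fraction %||% 0.05,
    contamination_min_reads = th$contamination_min_reads %||% 10L
  )
  config
}

#' Run the full insertion-sequencing pipeline
#'
#' Executes, as configured: simulation -> junction filtering -> barcode
#' extraction and clustering (RB mode) -> UMI tagging and trimming ->
#' mapping -> deduplication -> insertion spectra -> peak calling ->
#' differential enrichment (earliest vs latest time point) -> lineage
#' reconstruction. Stage outputs are written under `config$outdir` along
#' with `manifest.json` (package version, parameters, input checksums).
#'
#' The configuration is a named list (or YAML path) with entries:
#' \describe{
#'   \item{mode}{`"tnseq"` or `"rbtnseq"`.}
#'   \item{seed}{integer; drives every random stage.}
#'   \item{outdir}{output directory, created if needed.}
#'   \item{simulate}{optional list: `genome_length`, `n_genes`, `gc`,
#'     `n_founders`, `insertions_per_founder`, `n_molecules`,
#'     `pcr_duplication`, `error_rate`, and `samples` (tibble-like list
#'     with `sample`, `time_point`, optionally `replicate`, `founders`).}
#'   \item{inputs}{alternative to `simulate`: `genome_fasta`, `features`,
#'     and `samples` (list of `sample`, `time_point`, `r1`, `r2`).}
#'   \item{profile}{overrides passed to [protocol_profile()].}
#'   \item{thresholds}{stage thresholds; see [validate_config()].}
#'   \item{enrichment, lineage}{logical stage switches.}
#' }
#'
#' @param config configuration list or YAML path.
#' @return invisibly, a list with the genome, spectra, peaks, and (when
#'   enabled) diff/lineage results.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  profile <- config$profile_obj
  th <- config$thresholds
  input_files <- character(0)

  # --- reference ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    gsim <- simulate_genome(sim$genome_length %||% 100000L,
                            sim$n_genes %||% 20L, sim$gc %||% 0.5,
                            seed = config$seed)
    genome <- gsim$genome
    features <- gsim$features
    ta <- index_ta_sites(genome)
    truth <- simulate_population(genome, ta,
                                 sim$n_founders %||% 3L,
                                 sim$insertions_per_founder %||% 2L,
                                 seed = config$seed + 1L)
    readr::write_tsv(truth, file.path(outdir, "truth_population.tsv"),
                     progress = FALSE)
    samples <- sim$samples %||% list(list(sample = "sample1",
                                          time_point = 0))
    sample_tbl <- dplyr::bind_rows(lapply(samples, tibble::as_tibble))
    reads <- vector("list", nrow(sample_tbl))
    for (i in seq_len(nrow(sample_tbl))) {
      r1 <- file.path(outdir, paste0(sample_tbl$sample[i], "_R1.fastq.gz"))
      r2 <- file.path(outdir, paste0(sample_tbl$sample[i], "_R2.fastq.gz"))
      tt <- file.path(outdir, paste0(sample_tbl$sample[i], "_truth.tsv"))
      fnd <- if ("founders" %in% names(sample_tbl))
        strsplit(sample_tbl$founders[i], ",")[[1L]] else NULL
      simulate_reads(genome, truth, profile,
                     n_molecules = sim$n_molecules %||% 10000L,
                     pcr_duplication = sim$pcr_duplication %||% 1,
                     error_rate = sim$error_rate %||% 0,
                     seed = config$seed + 10L + i,
                     r1_path = r1, r2_path = r2, truth_path = tt,
                     sample = sample_tbl$sample[i], founders = fnd)
      reads[[i]] <- list(r1 = r1, r2 = r2)
    }
  } else {
    genomes <- read_genome_fasta(config$inputs$genome_fasta)
    genome <- genomes[[1L]]
    features <- if (!is.null(config$inputs$features)) {
      read_features(config$inputs$features, genome = genome)
    } else {
      tibble::tibble(gene_id = character(), start = integer(),
                     end = integer(), strand = character())
    }
    ta <- index_ta_sites(genome)
    sample_tbl <- dplyr::bind_rows(lapply(config$inputs$samples,
                                          tibble::as_tibble))
    reads <- lapply(seq_len(nrow(sample_tbl)), function(i) {
      list(r1 = sample_tbl$r1[i], r2 = sample_tbl$r2[i])
    })
    input_files <- c(config$inputs$genome_fasta, config$inputs$features,
                     unlist(lapply(reads, unlist)))
  }

  # --- per-sample read prep ---------------------------------------------
  index <- build_index(genome)
  prep <- vector("list", nrow(sample_tbl))
  stats <- list()
  for (i in seq_len(nrow(sample_tbl))) {
    jf <- filter_junction_pairs(reads[[i]]$r1, reads[[i]]$r2, profile,
                                th$terminus_mismatches)
    pairs <- jf$pairs
    st <- list(junction = jf$stats)
    if (config$mode == "rbtnseq") {
      ab <- attach_barcodes(pairs, profile, th$flank_mismatches)
      pairs <- ab$pairs
      st$barcode <- ab$stats
    }
    tr <- tag_umi_and_trim(pairs, profile, trim_mode = "anchor",
                           min_mean_qual = th$min_mean_qual)
    st$trim <- tr$stats
    prep[[i]] <- tr$fragments
    stats[[sample_tbl$sample[i]]] <- st
  }

  # --- barcode clustering (pooled across samples) ------------------------
  if (config$mode == "rbtnseq") {
    raw <- unlist(lapply(prep, function(f) f$barcode_raw))
    cl <- cluster_barcodes(table(raw), d = th$barcode_cluster_d)
    centers <- stats::setNames(cl$center, cl$barcode)
    for (i in seq_along(prep)) {
      prep[[i]]$barcode_cluster <- unname(centers[prep[[i]]$barcode_raw])
    }
    readr::write_tsv(tibble::as_tibble(cl),
                     file.path(outdir, "barcode_clusters.tsv"),
                     progress = FALSE)
  }

  # --- mapping, dedup, spectra, peaks ------------------------------------
  spectra <- list()
  molecules <- list()
  all_peaks <- list()
  for (i in seq_len(nrow(sample_tbl))) {
    smp <- sample_tbl$sample[i]
    mp <- map_fragments(prep[[i]], index, genome, profile,
                        th$map_mismatches)
    stats[[smp]]$mapping <- mp$stats
    mol <- dedup_umi(mp$alignments)
    stats[[smp]]$dedup <- list(reads = nrow(mp$alignments),
                               molecules = nrow(mol))
    spec <- build_spectrum(mol, ta, th$snap_tolerance, sample = smp,
                           genome_length = genome$length)
    mol$position <- snap_to_ta(mol$junction_pos, ta, th$snap_tolerance)
    mol$sample <- smp
    molecules[[smp]] <- mol
    spectra[[smp]] <- spec
    readr::write_tsv(tibble::as_tibble(spec),
                     file.path(outdir, paste0(smp, "_spectrum.tsv")),
                     progress = FALSE)
    write_spectrum_bedgraph(spec,
                            file.path(outdir, paste0(smp, ".bedgraph")))
    pk <- call_peaks(spec, genome$length, th$peak_window,
                     q_max = th$peak_q_max,
                     features = if (nrow(features)) features else NULL)
    all_peaks[[smp]] <- pk
    readr::write_tsv(tibble::as_tibble(pk),
                     file.path(outdir, paste0(smp, "_peaks.tsv")),
                     progress = FALSE)
  }

  # --- differential enrichment -------------------------------------------
  diff <- NULL
  if (config$enrichment) {
    if (nrow(features) == 0L) {
      stop(errorCondition("enrichment enabled but annotation is empty",
                          class = c("tn_config_error", "error")))
    }
    tp <- sample_tbl$time_point
    s_start <- sample_tbl$sample[which.min(tp)]
    s_end <- sample_tbl$sample[which.max(tp)]
    tab <- gene_count_table(spectra[[s_start]], spectra[[s_end]], features)
    diff <- diff_enrichment(tab, min_total = th$diff_min_total)
    readr::write_tsv(tibble::as_tibble(diff),
                     file.path(outdir, "diff_enrichment.tsv"),
                     progress = FALSE)
  }

  # --- lineage reconstruction --------------------------------------------
  lineage <- NULL
  if (config$lineage && config$mode == "rbtnseq") {
    mol_all <- dplyr::bind_rows(molecules) %>%
      dplyr::filter(!is.na(.data$position))
    lineage <- demultiplex_lineages(
      mol_all, dplyr::select(sample_tbl, "sample", "time_point")
    )
    readr::write_tsv(tibble::as_tibble(lineage),
                     file.path(outdir, "lineage_traces.tsv"),
                     progress = FALSE)
    founders <- identify_founder(lineage, th$founder_min_fraction)
    readr::write_tsv(founders, file.path(outdir, "lineage_founders.tsv"),
                     progress = FALSE)
    if (length(unique(sample_tbl$time_point)) > 1L) {
      conv <- find_convergent_loci(lineage, th$convergence_window,
                                   min_fraction =
                                     th$convergence_min_fraction,
                                   founder_min_fraction =
                                     th$founder_min_fraction)
      readr::write_tsv(tibble::as_tibble(conv),
                       file.path(outdir, "convergent_loci.tsv"),
                       progress = FALSE)
    }
  }

  manifest <- list(
    package = "tnseqr",
    version = as.character(utils::packageVersion("tnseqr")),
    mode = config$mode,
    seed = config$seed,
    thresholds = th,
    samples = sample_tbl$sample,
    input_checksums = as.list(tools::md5sum(input_files))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(stats, file.path(outdir, "stage_stats.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(genome = genome, features = features, ta_sites = ta,
                 spectra = spectra, molecules = molecules,
                 peaks = all_peaks, diff = diff, lineage = lineage,
                 stats = stats))
}
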