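# Synthetic Tn-Seq / RB-Tn-Seq data generator.
#
# The generator is first-class: it defines the ground truth (insertion
# positions on TA sites, promoter orientations, founder barcodes, molecule
# counts) that the downstream pipeline is expected to recover. Reads follow
# the amplicon structure of junction sequencing: the forward read crosses
# the transposon/genome junction (optionally preceded by the barcode
# cassette), the reverse read starts with a UMI and reads back from the
# sheared fragment end.

#' Transposon amplicon constants
#'
#' `TN_TERMINUS` is the 30-nt transposon terminus (inverted-repeat end)
#' that every forward junction read must cross; `TN_FLANK5` and
#' `TN_FLANK3` are the sequences flanking the 20-nt random barcode in the
#' RB cassette.
#'
#' @format Character scalars (DNA strings).
#' @name amplicon_constants
NULL

#' @rdname amplicon_constants
#' @export
TN_TERMINUS <- "CAGACCGGGGACTTATCAGCCAACCTGTTA"

#' @rdname amplicon_constants
#' @export
TN_FLANK5 <- "GATGTCCACGAGGTCTCT"

#' @rdname amplicon_constants
#' @export
TN_FLANK3 <- "GCCGGCCGTCGACCTGCAGCGTACG"

#' Protocol profile: amplicon geometry and read structure
#'
#' Bundles the constants that define how a sequencing library is structured:
#' the 30-nt transposon terminus (inverted-repeat end) that the forward read
#' must cross, the barcode flanking sequences of the RB cassette, barcode
#' and UMI lengths, and the insert-size bound used by the mapper.
#'
#' The UMI defaults differ by mode (9 nt for plain Tn-Seq, 8 nt for
#' RB-Tn-Seq): the ligated adapter carries 8 random bases, and the plain
#' Tn-Seq extraction consumes one extra ligation-scar base. Both are
#' configurable.
#'
#' @param mode `"tnseq"` or `"rbtnseq"`.
#' @param terminus transposon terminus sequence on the forward read.
#' @param flank5,flank3 barcode flanking sequences (RB mode only).
#' @param barcode_len expected barcode length in nt.
#' @param umi_len UMI length in nt; default 9 (tnseq) or 8 (rbtnseq).
#' @param read_len read length in nt.
#' @param max_insert maximum fragment (insert) size in nt.
#' @param frag_min minimum simulated fragment size in nt.
#' @return an object of class `tn_profile`.
#' @export
protocol_profile <- function(mode = c("tnseq", "rbtnseq"),
                             terminus = TN_TERMINUS,
                             flank5 = TN_FLANK5,
                             flank3 = TN_FLANK3,
                             barcode_len = 20L,
                             umi_len = NULL,
                             read_len = 150L,
                             max_insert = 1000L,
                             frag_min = 200L) {
  mode <- match.arg(mode)
  if (is.null(umi_len)) umi_len <- if (mode == "tnseq") 9L else 8L
  stopifnot(barcode_len > 0L, umi_len > 0L, read_len > nchar(terminus),
            frag_min <= max_insert)
  prefix_len <- nchar(terminus) +
    if (mode == "rbtnseq") nchar(flank5) + barcode_len + nchar(flank3) else 0L
  if (read_len <= prefix_len) {
    stop("read_len must exceed the forward-read prefix (", prefix_len,
         " nt)", call. = FALSE)
  }
  structure(
    list(mode = mode, terminus = terminus, flank5 = flank5, flank3 = flank3,
         barcode_len = as.integer(barcode_len), umi_len = as.integer(umi_len),
         read_len = as.integer(read_len), max_insert = as.integer(max_insert),
         frag_min = as.integer(frag_min),
         prefix_len = as.integer(prefix_len)),
    class = "tn_profile"
  )
}

#' @export
print.tn_profile <- function(x, ...) {
  cat("<tn_profile> mode=", x$mode, " read_len=", x$read_len,
      " umi_len=", x$umi_len,
      if (x$mode == "rbtnseq") paste0(" barcode_len=", x$barcode_len),
      " max_insert=", x$max_insert, "\n", sep = "")
  invisible(x)
}

#' Simulate a reference genome with non-overlapping genes
#'
#' Draws an i.i.d. genome at the requested GC content and places
#' non-overlapping genes on random strands. The genome is resampled (up to
#' 20 times) until it holds at least `length/50` TA sites, so that the
#' mariner insertion alphabet is never degenerate; infeasible settings
#' raise an error.
#'
#' @param length genome length in nt (>= 1000).
#' @param n_genes number of genes to place.
#' @param gc GC fraction in (0, 1).
#' @param seed integer seed; the output is reproducible for a fixed seed.
#' @param circular mark the genome circular?
#' @return list with `genome` (a [tn_genome]) and `features` (tibble).
#' @export
simulate_genome <- function(length, n_genes, gc = 0.5, seed,
                            circular = FALSE) {
  stopifnot(length >= 1000L, gc > 0, gc < 1, n_genes >= 0L)
  withr::with_seed(as.integer(seed), {
    prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    seq_str <- NULL
    for (attempt in seq_len(20L)) {
      cand <- paste0(sample(DNA_BASES, length, replace = TRUE, prob = prob),
                     collapse = "")
      hits <- gregexpr("(?=TA)", cand, perl = TRUE)[[1L]]
      n_ta <- if (hits[1L] == -1L) 0L else length(hits)
      if (n_ta >= length / 50) { seq_str <- cand; break }
    }
    if (is.null(seq_str)) {
      stop("could not draw a genome with >= length/50 TA sites at gc = ",
           gc, call. = FALSE)
    }
    genome <- tn_genome("sim_chr", seq_str, circular = circular)

    features <- tibble::tibble(gene_id = character(), start = integer(),
                               end = integer(), strand = character())
    if (n_genes > 0L) {
      starts <- integer(0); ends <- integer(0)
      attempts <- 0L
      while (length(starts) < n_genes) {
        attempts <- attempts + 1L
        if (attempts > 200L * n_genes) {
          stop("infeasible gene packing: ", n_genes, " genes in ", length,
               " nt", call. = FALSE)
        }
        glen <- sample(300:1200, 1L)
        gstart <- sample.int(length - glen + 1L, 1L)
        gend <- gstart + glen - 1L
        if (!any(gstart <= ends & gend >= starts)) {
          starts <- c(starts, gstart); ends <- c(ends, gend)
        }
      }
      ord <- order(starts)
      features <- tibble::tibble(
        gene_id = sprintf("gene%03d", seq_len(n_genes)),
        start = starts[ord],
        end = ends[ord],
        strand = sample(c("+", "-"), n_genes, replace = TRUE)
      )
    }
    list(genome = genome, features = features)
  })
}

#' Simulate a barcoded insertion population
#'
#' Each founder carries one 20-nt random barcode (the barcode travels with
#' the transposon, so every insertion seeded by that founder shares it).
#' Insertion positions are drawn uniformly over TA sites without
#' replacement; within-founder relative abundances come from a symmetric
#' Dirichlet.
#'
#' @param genome a [tn_genome].
#' @param ta_sites TA index from [index_ta_sites()].
#' @param n_founders number of founder lineages.
#' @param insertions_per_founder insertions per founder.
#' @param seed integer seed.
#' @param alpha Dirichlet concentration for within-founder abundances.
#' @param barcode_len barcode length in nt.
#' @return tibble (`founder`, `barcode`, `position`, `orientation`,
#'   `abundance`); `orientation` is the direction the outward-facing
#'   promoter points; abundances sum to 1 within each founder.
#' @export
simulate_population <- function(genome, ta_sites, n_founders,
                                insertions_per_founder, seed, alpha = 1,
                                barcode_len = 20L) {
  total <- n_founders * insertions_per_founder
  if (total > length(ta_sites)) {
    stop("requested ", total, " insertions but only ", length(ta_sites),
         " TA sites are available", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    repeat {
      barcodes <- random_dna(n_founders, barcode_len)
      if (!anyDuplicated(barcodes)) break
    }
    pos <- sample(ta_sites, total, replace = FALSE)
    ab <- stats::rgamma(total, shape = alpha)
    out <- tibble::tibble(
      founder = rep(sprintf("F%02d", seq_len(n_founders)),
                    each = insertions_per_founder),
      barcode = rep(barcodes, each = insertions_per_founder),
      position = as.integer(pos),
      orientation = sample(c("+", "-"), total, replace = TRUE),
      abundance = ab
    )
    dplyr::mutate(dplyr::group_by(out, .data$founder),
                  abundance = .data$abundance / sum(.data$abundance)) %>%
      dplyr::ungroup()
  })
}

#' Simulate paired-end junction-sequencing reads
#'
#' Generates `n_molecules` unique template molecules from the true insertion
#' population, then emits each one `1 + Poisson(pcr_duplication - 1)` times
#' (PCR duplication) with i.i.d. substitution errors per base.
#'
#' Read structure: the forward read is `[flank5][barcode][flank3]` (RB mode
#' only) + terminus + genomic sequence downstream of the junction, oriented
#' so that reads accumulate on the side *opposite* the outward-facing
#' promoter. The reverse read is UMI + reverse-complement genomic sequence
#' from the sheared fragment end; fragment lengths are uniform on
#' `[frag_min, max_insert]`. UMIs are drawn without replacement within each
#' insertion site (cross-site collisions can occur by chance).
#'
#' @param genome a [tn_genome].
#' @param truth insertion population from [simulate_population()].
#' @param profile a [protocol_profile()].
#' @param n_molecules number of unique template molecules to draw.
#' @param pcr_duplication mean emitted copies per molecule (>= 1).
#' @param error_rate substitution probability per base.
#' @param seed integer seed.
#' @param r1_path,r2_path output FASTQ paths (gzip if ending in `.gz`).
#' @param truth_path output TSV path for the molecule-level truth table.
#' @param sample sample label recorded in the truth table.
#' @param founders optional subset of founder ids to draw from.
#' @param low_quality_frac fraction of read pairs whose quality strings are
#'   degraded to Q2, for exercising the quality filter.
#' @return invisibly, a list with `truth` (molecule table), `n_pairs`
#'   (total emitted pairs) and the three paths.
#' @export
simulate_reads <- function(genome, truth, profile, n_molecules,
                           pcr_duplication = 1, error_rate = 0, seed,
                           r1_path, r2_path, truth_path,
                           sample = "sample1", founders = NULL,
                           low_quality_frac = 0) {
  stopifnot(nrow(truth) > 0L, pcr_duplication >= 1)
  if (!is.null(founders)) truth <- dplyr::filter(truth,
                                                 .data$founder %in% founders)
  if (nrow(truth) == 0L) stop("no insertions left after founder subset",
                              call. = FALSE)
  g1len <- profile$read_len - profile$prefix_len
  g2len <- profile$read_len - profile$umi_len
  need <- max(g1len, g2len)
  if (need > profile$max_insert) {
    stop("read_len longer than constructible fragment: need ", need,
         " nt but max_insert is ", profile$max_insert, call. = FALSE)
  }
  gseq <- genome$sequence
  L <- genome$length

  withr::with_seed(as.integer(seed), {
    w <- truth$abundance / sum(truth$abundance)
    ins <- sample.int(nrow(truth), n_molecules, replace = TRUE, prob = w)
    pos <- truth$position[ins]
    ori <- truth$orientation[ins]
    frag <- sample(seq(max(profile$frag_min, need), profile$max_insert),
                   n_molecules, replace = TRUE)
    # promoter "-": reads on + strand, junction at the TA's T, fragment
    # extends rightward; promoter "+": reads on - strand, junction at the
    # TA's A, fragment extends leftward.
    plus <- ori == "-"
    jpos <- ifelse(plus, pos, pos + 1L)
    avail <- ifelse(plus, L - jpos + 1L, jpos)
    frag <- pmin(frag, avail)
    if (any(frag < need)) {
      stop("read_len longer than constructible fragment for ",
           sum(frag < need), " molecule(s) near the genome edge",
           call. = FALSE)
    }
    r1gen <- ifelse(plus,
                    substring(gseq, jpos, jpos + g1len - 1L),
                    revcomp(substring(gseq, jpos - g1len + 1L, jpos)))
    fend <- ifelse(plus, jpos + frag - 1L, jpos - frag + 1L)
    r2gen <- ifelse(plus,
                    revcomp(substring(gseq, fend - g2len + 1L, fend)),
                    substring(gseq, fend, fend + g2len - 1L))

    # UMIs: without replacement within each insertion site
    umi <- character(n_molecules)
    for (s in unique(ins)) {
      idx <- which(ins == s)
      space <- 4L^profile$umi_len
      if (length(idx) > space) {
        stop("more molecules at one site than distinct UMIs", call. = FALSE)
      }
      umi[idx] <- int_to_dna(sample.int(space, length(idx)) - 1L,
                             profile$umi_len)
    }

    prefix <- if (profile$mode == "rbtnseq") {
      paste0(profile$flank5, truth$barcode[ins], profile$flank3,
             profile$terminus)
    } else {
      rep(profile$terminus, n_molecules)
    }
    r1 <- paste0(prefix, r1gen)
    r2 <- paste0(umi, r2gen)

    copies <- 1L + stats::rpois(n_molecules, pcr_duplication - 1)
    mol_id <- sprintf("M%07d", seq_len(n_molecules))
    rep_idx <- rep(seq_len(n_molecules), copies)
    copy_no <- sequence(copies)
    read_id <- paste0(mol_id[rep_idx], "x", copy_no)

    r1e <- mutate_seqs(r1[rep_idx], error_rate)
    r2e <- mutate_seqs(r2[rep_idx], error_rate)

    q1 <- strrep("F", nchar(r1e))
    q2 <- strrep("F", nchar(r2e))
    if (low_quality_frac > 0) {
      lowq <- stats::runif(length(r1e)) < low_quality_frac
      q1[lowq] <- strrep("#", nchar(r1e[lowq]))
      q2[lowq] <- strrep("#", nchar(r2e[lowq]))
    }

    write_fastq(tibble::tibble(read_id = paste0(read_id, " 1:N:0:1"),
                               seq = r1e, qual = q1), r1_path)
    write_fastq(tibble::tibble(read_id = paste0(read_id, " 2:N:0:1"),
                               seq = r2e, qual = q2), r2_path)

    truth_tbl <- tibble::tibble(
      molecule_id = mol_id,
      position = as.integer(pos),
      orientation = ori,
      barcode = truth$barcode[ins],
      umi = umi,
      copies = copies,
      frag_len = as.integer(frag),
      sample = sample
    )
    readr::write_tsv(truth_tbl, truth_path, progress = FALSE)
    invisible(list(truth = truth_tbl, n_pairs = sum(copies),
                   r1_path = r1_path, r2_path = r2_path,
                   truth_path = truth_path))
  })
}

#' Simulate a two-condition gene-level count table
#'
#' Draws negative-binomial molecule counts for `n_genes` genes in a paired
#' start/end design, optionally boosting `n_enriched` genes by `fold` in the
#' end-point condition. Used to study the power and error control of the
#' differential-enrichment test.
#'
#' @param n_genes number of genes.
#' @param depth expected total molecules per condition.
#' @param n_enriched number of truly enriched genes (the first `n_enriched`
#'   gene ids).
#' @param fold enrichment factor for the true genes.
#' @param dispersion negative-binomial dispersion of the counts.
#' @param seed integer seed.
#' @return a gene count table as produced by [gene_count_table()], with the
#'   true gene ids in `attr(, "enriched_genes")`.
#' @export
simulate_gene_counts <- function(n_genes = 500, depth = 1e5, n_enriched = 0,
                                 fold = 20, dispersion = 0.05, seed) {
  withr::with_seed(as.integer(seed), {
    p0 <- rep(1 / n_genes, n_genes)
    p1 <- p0
    if (n_enriched > 0) p1[seq_len(n_enriched)] <- p1[seq_len(n_enriched)] * fold
    p1 <- p1 / sum(p1)
    size <- 1 / dispersion
    cs <- stats::rnbinom(n_genes, size = size, mu = depth * p0)
    ce <- stats::rnbinom(n_genes, size = size, mu = depth * p1)
    tbl <- tibble::tibble(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      count_start = cs,
      count_end = ce
    )
    attr(tbl, "library_sizes") <- c(start = sum(cs), end = sum(ce))
    attr(tbl, "enriched_genes") <- tbl$gene_id[seq_len(n_enriched)]
    tbl
  })
}
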