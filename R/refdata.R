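# Reference genomes, gene annotations, and the TA-site insertion alphabet.
#
# mariner-family transposons insert exclusively at TA dinucleotides, so the
# sorted index of TA positions is the coordinate system every downstream
# stage (spectra, peaks, gene counts) works in. All internal coordinates are
# 1-based inclusive; BED is converted at the boundary.

#' Construct a reference genome object
#'
#' @param name contig name.
#' @param sequence DNA string over {A,C,G,T,N}; lower case and U are
#'   normalized.
#' @param circular treat the contig as circular (TA sites may span the
#'   end-start junction)?
#' @return an object of class `tn_genome` with fields `name`, `sequence`,
#'   `length`, `circular`.
#' @export
tn_genome <- function(name, sequence, circular = FALSE) {
  sequence <- chartr("U", "T", toupper(sequence))
  if (nchar(sequence) == 0L) stop("genome sequence must be non-empty",
                                  call. = FALSE)
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence),
         circular = circular),
    class = "tn_genome"
  )
}

#' @export
print.tn_genome <- function(x, ...) {
  cat("<tn_genome> ", x$name, ": ", format(x$length, big.mark = ","),
      " bp", if (x$circular) " (circular)", "\n", sep = "")
  invisible(x)
}

#' Read reference genomes from a FASTA file
#'
#' @param path path to a FASTA file, optionally gzip-compressed.
#' @param circular logical flag (recycled) marking contigs as circular.
#' @return a list of [tn_genome] objects, one per FASTA record. Sequences
#'   are uppercased and U is mapped to T.
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readr::read_lines(path, n_max = 1L, progress = FALSE)
  if (length(first) == 0L) {
    stop("FASTA format error in ", path, ": file is empty (line 1)",
         call. = FALSE)
  }
  if (!startsWith(first, ">")) {
    stop("FASTA format error in ", path,
         ": line 1 does not start with '>'", call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA format error in ", path, ": no records", call. = FALSE)
  }
  circular <- rep_len(circular, length(set))
  nm <- sub("\\s.*$", "", names(set))
  purrr::map(seq_along(set), function(i) {
    tn_genome(nm[i], as.character(set[[i]]), circular = circular[i])
  })
}

#' Read gene features from GFF3 or BED
#'
#' Features are converted to the internal 1-based inclusive convention: a
#' BED interval `[10, 20)` becomes `start = 11, end = 20`. Gene identifiers
#' come from the BED name column or from the first available GFF3 attribute
#' among `ID`, `Name`, `locus_tag`.
#'
#' @param path path to the annotation file.
#' @param format `"gff3"` or `"bed"`; guessed from the extension by default.
#' @param genome optional [tn_genome]; when given, features outside
#'   `[1, genome$length]` raise a validation error.
#' @return tibble with columns `gene_id`, `start`, `end`, `strand`.
#' @export
read_features <- function(path, format = c("auto", "gff3", "bed"),
                          genome = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3"
                            else "bed")
  md <- as.data.frame(gr)
  gene_id <- NULL
  for (col in c("name", "ID", "Name", "locus_tag", "gene_id")) {
    if (col %in% names(md) && !all(is.na(md[[col]]))) {
      gene_id <- as.character(md[[col]])
      break
    }
  }
  if (is.null(gene_id)) gene_id <- paste0("feature", seq_len(nrow(md)))
  feats <- tibble::tibble(
    gene_id = gene_id,
    start = md$start,
    end = md$end,
    strand = ifelse(as.character(md$strand) %in% c("+", "-"),
                    as.character(md$strand), "+")
  )
  validate_features(feats, genome = genome, source = path)
}

#' Validate a feature table against the internal convention
#' @keywords internal
#' @noRd
validate_features <- function(feats, genome = NULL, source = "features") {
  bad <- feats$start < 1L | feats$end < feats$start
  if (!is.null(genome)) bad <- bad | feats$end > genome$length
  if (any(bad)) {
    stop("invalid feature(s) in ", source, ": ",
         paste(utils::head(feats$gene_id[bad], 5L), collapse = ", "),
         " (empty interval or coordinate outside genome)", call. = FALSE)
  }
  if (anyDuplicated(feats$gene_id)) {
    stop("duplicated gene_id in ", source, ": ",
         feats$gene_id[duplicated(feats$gene_id)][1L], call. = FALSE)
  }
  feats
}

#' Index TA dinucleotide insertion sites
#'
#' Returns the sorted 1-based positions of the T of every TA dinucleotide.
#' Overlapping occurrences ("TATA" at 1 and 3) are all reported. For
#' circular genomes the end-to-start junction (T at the last base, A at the
#' first) is also checked. N bases never participate.
#'
#' @param genome a [tn_genome].
#' @return sorted integer vector of TA-site positions (T position).
#' @export
index_ta_sites <- function(genome) {
  stopifnot(inherits(genome, "tn_genome"))
  hits <- gregexpr("(?=TA)", genome$sequence, perl = TRUE)[[1L]]
  pos <- if (hits[1L] == -1L) integer(0) else as.integer(hits)
  if (genome$circular && genome$length >= 2L) {
    last <- substr(genome$sequence, genome$length, genome$length)
    first <- substr(genome$sequence, 1L, 1L)
    if (last == "T" && first == "A") pos <- c(pos, genome$length)
  }
  sort(unique(pos))
}

#' Export TA sites as BED (0-based half-open)
#'
#' @param ta_sites integer vector from [index_ta_sites()].
#' @param genome the [tn_genome] the sites belong to.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_ta_bed <- function(ta_sites, genome, path) {
  df <- tibble::tibble(
    chrom = genome$name,
    start = ta_sites - 1L,
    end = pmin(ta_sites + 1L, genome$length),
    name = paste0("TA_", ta_sites)
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
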