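# Shared fixture builders and independent brute-force oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force TA scan: check every dinucleotide window explicitly.
bf_ta_sites <- function(seq, circular = FALSE) {
  n <- nchar(seq)
  pos <- integer(0)
  for (i in seq_len(max(n - 1L, 0L))) {
    if (substr(seq, i, i + 1L) == "TA") pos <- c(pos, i)
  }
  if (circular && n >= 2L &&
      substr(seq, n, n) == "T" && substr(seq, 1L, 1L) == "A") {
    pos <- c(pos, n)
  }
  sort(unique(pos))
}

# Brute-force leftmost Hamming window scan for one sequence.
bf_hamming_search <- function(seq, pattern, max_mm) {
  plen <- nchar(pattern)
  pv <- strsplit(pattern, "")[[1]]
  for (off in seq_len(nchar(seq) - plen + 1L)) {
    w <- strsplit(substr(seq, off, off + plen - 1L), "")[[1]]
    if (sum(w != pv) <= max_mm) return(off)
  }
  NA_integer_
}

# Brute-force nearest gene: explicit minimum over all features.
bf_nearest_gene <- function(start, end, features) {
  best_d <- Inf
  best_g <- NA_character_
  for (i in seq_len(nrow(features))) {
    fs <- features$start[i]; fe <- features$end[i]
    d <- if (start <= fe && end >= fs) 0L else max(fs - end, start - fe)
    if (d < best_d || (d == best_d && features$gene_id[i] < best_g)) {
      best_d <- d
      best_g <- features$gene_id[i]
    }
  }
  best_g
}

# Hand-rolled BH step-up, straight from the definition.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Reverse complement without touching the package internals.
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Deterministic substitutions at fixed 1-based positions (A->C->G->T->A).
perturb_fixed <- function(seq, positions) {
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  chars <- strsplit(seq, "")[[1]]
  chars[positions] <- rot[chars[positions]]
  paste0(chars, collapse = "")
}

# TRUE for each member of `others` farther than min_d from `x` (Hamming).
hamming_gt <- function(x, others, min_d) {
  if (length(others) == 0) return(logical(0))
  xv <- strsplit(x, "")[[1]]
  vapply(strsplit(others, ""),
         function(o) sum(o != xv) > min_d, logical(1))
}

# Perturb a DNA string with exactly n substitutions.
perturb <- function(seq, n) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(chars), n)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste0(chars, collapse = "")
}

# A small simulated dataset shared by mapping/insertion tests, built once.
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- simulate_genome(20000, 5, 0.5, seed = 42)
      ta <- index_ta_sites(g$genome)
      pop <- simulate_population(g$genome, ta, 3, 2, seed = 7)
      prof <- protocol_profile("rbtnseq")
      td <- tempfile("tinysim")
      dir.create(td)
      sr <- simulate_reads(g$genome, pop, prof, n_molecules = 2000,
                           pcr_duplication = 1, error_rate = 0, seed = 9,
                           r1_path = file.path(td, "r1.fastq.gz"),
                           r2_path = file.path(td, "r2.fastq.gz"),
                           truth_path = file.path(td, "truth.tsv"))
      cache <<- list(genome = g$genome, features = g$features, ta = ta,
                     pop = pop, profile = prof, sim = sr, dir = td)
    }
    cache
  }
})

# Construct an RB-mode forward read for a given barcode and genomic tail.
rb_read <- function(profile, barcode, genomic) {
  paste0(profile$flank5, barcode, profile$flank3, profile$terminus, genomic)
}

# Build a minimal spectrum object directly from per-position counts.
make_spectrum <- function(positions, counts, strand = "+",
                          genome_length, sample = "synthetic") {
  tbl <- tibble::tibble(chrom = "chr", position = as.integer(positions),
                        strand = strand, count = as.integer(counts))
  tbl <- dplyr::arrange(tbl, position, strand)
  tbl$fraction <- tbl$count / sum(tbl$count)
  structure(tbl, class = c("tn_spectrum", class(tbl)),
            sample = sample, total_mapped = sum(tbl$count),
            off_ta = tibble::tibble(), raw = tbl,
            genome_length = genome_length)
}
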