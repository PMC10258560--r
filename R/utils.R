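# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a character vector of DNA sequences
#' @param x character vector of DNA sequences over {A,C,G,T,N}.
#' @return character vector of the same length.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Draw random DNA sequences
#' @keywords internal
#' @noRd
random_dna <- function(n, len, prob = rep(0.25, 4)) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE, prob = prob),
              nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

#' Encode integers 0..(4^len - 1) as DNA words of fixed length
#' @keywords internal
#' @noRd
int_to_dna <- function(ints, len) {
  out <- character(length(ints))
  digits <- matrix(0L, nrow = length(ints), ncol = len)
  x <- as.integer(ints)
  for (j in seq_len(len)) {
    digits[, len - j + 1L] <- x %% 4L
    x <- x %/% 4L
  }
  m <- matrix(DNA_BASES[digits + 1L], nrow = length(ints))
  apply(m, 1L, paste0, collapse = "")
}

#' Read a (possibly gzipped) FASTQ file into a tibble
#'
#' Minimal 4-line-record FASTQ reader used by the simulator round-trip and
#' the junction filter. Comments after the first whitespace in the header
#' are dropped from `read_id`.
#'
#' @param path path to a FASTQ file, plain or gzip.
#' @return tibble with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  if (length(lines) == 0L) {
    return(tibble::tibble(read_id = character(), seq = character(),
                          qual = character()))
  }
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record near line ", length(lines), " in ", path,
         call. = FALSE)
  }
  ids <- lines[seq(1L, length(lines), by = 4L)]
  if (any(substr(ids, 1L, 1L) != "@")) {
    bad <- which(substr(ids, 1L, 1L) != "@")[1L]
    stop("malformed FASTQ header at record ", bad, " in ", path,
         call. = FALSE)
  }
  tibble::tibble(
    read_id = sub("\\s.*$", "", substring(ids, 2L)),
    seq = toupper(lines[seq(2L, length(lines), by = 4L)]),
    qual = lines[seq(4L, length(lines), by = 4L)]
  )
}

#' Write a FASTQ file (gzip if the path ends in .gz)
#' @param reads tibble with `read_id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  if (nrow(reads) > 0L) {
    lines[seq(1L, length(lines), by = 4L)] <- paste0("@", reads$read_id)
    lines[seq(2L, length(lines), by = 4L)] <- reads$seq
    lines[seq(3L, length(lines), by = 4L)] <- "+"
    lines[seq(4L, length(lines), by = 4L)] <- reads$qual
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Mean Phred quality per read, exploiting repeated quality strings
#' @keywords internal
#' @noRd
mean_phred <- function(quals) {
  uq <- unique(quals)
  mq <- vapply(uq, function(q) mean(utf8ToInt(q)) - 33, numeric(1))
  unname(mq[match(quals, uq)])
}

#' Introduce i.i.d. substitution errors into DNA sequences
#'
#' Errors are uniform over the other three bases. Operates on the
#' concatenation of all sequences at once (per-base i.i.d. errors are
#' position-exchangeable, so drawing error sites globally is equivalent).
#' @keywords internal
#' @noRd
mutate_seqs <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  n_err <- stats::rbinom(1L, total, error_rate)
  if (n_err == 0L) return(seqs)
  pos <- sample.int(total, n_err)
  ints <- utf8ToInt(paste(seqs, collapse = ""))
  cur <- ints[pos]
  base_ints <- utf8ToInt(paste(DNA_BASES, collapse = ""))
  sub <- sample(base_ints, n_err, replace = TRUE)
  clash <- sub == cur
  while (any(clash)) {
    sub[clash] <- sample(base_ints, sum(clash), replace = TRUE)
    clash <- sub == cur
  }
  ints[pos] <- sub
  big <- intToUtf8(ints)
  ends <- cumsum(lens)
  substring(big, ends - lens + 1L, ends)
}
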