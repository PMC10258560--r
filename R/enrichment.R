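# Gene-level differential insertion enrichment between paired start-point
# and end-point samples.
#
# The test is an exact conditional negative-binomial test: conditioned on a
# gene's total count across the two conditions, the probability of the
# observed split is computed under NB noise with a common dispersion
# estimated across genes by the method of moments. As dispersion -> 0 the
# test degenerates to the binomial exact test, which serves as the
# verification oracle.

#' Count molecules per gene from a spectrum
#'
#' A molecule contributes to a gene iff its (snapped) TA position lies
#' within `[start, end]`. Positions falling in no gene are optionally
#' aggregated under per-interval intergenic pseudo-features.
#'
#' @param spectrum a [build_spectrum()] result.
#' @param features feature tibble (`gene_id`, `start`, `end`, `strand`).
#' @param include_intergenic report intergenic pseudo-features
#'   (`intergenic_<start>_<end>`)?
#' @return tibble (`gene_id`, `count`) covering every feature;
#'   `attr(, "library_size")` is the spectrum's `total_mapped`.
#' @export
count_per_gene <- function(spectrum, features, include_intergenic = FALSE) {
  pos <- spectrum$position
  cnt <- spectrum$count
  counts <- vapply(seq_len(nrow(features)), function(i) {
    sum(cnt[pos >= features$start[i] & pos <= features$end[i]])
  }, numeric(1))
  out <- tibble::tibble(gene_id = features$gene_id,
                        count = as.integer(counts))
  if (include_intergenic) {
    feats <- dplyr::arrange(features, .data$start)
    bounds <- c(0L, feats$end, attr(spectrum, "genome_length") %||%
                  max(pos, feats$end))
    gaps <- tibble::tibble(start = utils::head(bounds, -1L) + 1L,
                           end = c(feats$start - 1L,
                                   utils::tail(bounds, 1L))) %>%
      dplyr::filter(.data$end >= .data$start)
    gap_counts <- vapply(seq_len(nrow(gaps)), function(i) {
      in_gap <- pos >= gaps$start[i] & pos <= gaps$end[i]
      in_gene <- rep(FALSE, length(pos))
      for (j in seq_len(nrow(features))) {
        in_gene <- in_gene | (pos >= features$start[j] &
                                pos <= features$end[j])
      }
      sum(cnt[in_gap & !in_gene])
    }, numeric(1))
    out <- dplyr::bind_rows(out, tibble::tibble(
      gene_id = sprintf("intergenic_%d_%d", gaps$start, gaps$end),
      count = as.integer(gap_counts)
    ))
  }
  attr(out, "library_size") <- attr(spectrum, "total_mapped")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a two-condition gene count table
#'
#' @param spectrum_start,spectrum_end spectra for the paired start-point
#'   and end-point samples.
#' @param features feature tibble.
#' @return tibble (`gene_id`, `count_start`, `count_end`) with
#'   `attr(, "library_sizes")` = total mapped molecules per condition.
#' @export
gene_count_table <- function(spectrum_start, spectrum_end, features) {
  cs <- count_per_gene(spectrum_start, features)
  ce <- count_per_gene(spectrum_end, features)
  out <- tibble::tibble(gene_id = cs$gene_id,
                        count_start = cs$count,
                        count_end = ce$count)
  attr(out, "library_sizes") <- c(
    start = attr(cs, "library_size") %||% sum(cs$count),
    end = attr(ce, "library_size") %||% sum(ce$count)
  )
  out
}

#' Filter genes by combined count
#'
#' Keeps genes whose summed count across the two conditions reaches the
#' threshold (default 128).
#'
#' @param table a [gene_count_table()] result.
#' @param t combined-count threshold.
#' @return the filtered table (attributes preserved).
#' @export
filter_low_count <- function(table, t = 128L) {
  keep <- table$count_start + table$count_end >= t
  out <- table[keep, , drop = FALSE]
  attr(out, "library_sizes") <- attr(table, "library_sizes")
  out
}

#' Estimate a common NB dispersion across genes by method of moments
#'
#' Counts are scaled to a common library size; for each gene the moment
#' estimator `(var - mean) / mean^2` is formed from the two scaled counts,
#' and the mean across genes (floored at `floor`) is returned. The mean is
#' used rather than the median because each per-gene estimate carries a
#' single degree of freedom, whose heavily right-skewed distribution makes
#' the median biased low.
#'
#' @param table a (filtered) gene count table.
#' @param library_sizes named vector `c(start, end)`; defaults to the
#'   table attribute.
#' @param floor minimum dispersion (default 0.01).
#' @return a single dispersion estimate.
#' @export
estimate_dispersion <- function(table, library_sizes = NULL, floor = 0.01) {
  library_sizes <- library_sizes %||% attr(table, "library_sizes")
  s <- exp(mean(log(library_sizes)))
  z1 <- table$count_start * s / library_sizes[["start"]]
  z2 <- table$count_end * s / library_sizes[["end"]]
  m <- (z1 + z2) / 2
  v <- (z1 - m)^2 + (z2 - m)^2  # two-point variance, n-1 denominator
  phi <- (v - m) / m^2
  phi <- phi[is.finite(phi) & m > 0]
  est <- if (length(phi) == 0L) floor else mean(phi)
  max(est, floor)
}

#' Exact conditional negative-binomial test for one gene
#'
#' Conditions on the gene's total count `t = x_start + x_end`: under NB
#' noise with means proportional to the library sizes and common
#' dispersion, the two-sided p-value sums the probabilities of all splits
#' of `t` no more likely than the observed one. The log2 fold change uses
#' library-size-normalized counts with a pseudocount of 0.5 per condition.
#'
#' @param start_count,end_count observed molecule counts (vectorized).
#' @param start_libsize,end_libsize library sizes (total molecules).
#' @param dispersion common NB dispersion (see [estimate_dispersion()]);
#'   values near 0 recover the binomial exact test.
#' @return tibble (`log2_fold_change`, `p`).
#' @export
nb_test <- function(start_count, end_count, start_libsize, end_libsize,
                    dispersion) {
  stopifnot(start_libsize > 0, end_libsize > 0, dispersion > 0)
  n <- max(length(start_count), length(end_count))
  start_count <- rep_len(as.integer(start_count), n)
  end_count <- rep_len(as.integer(end_count), n)
  size <- 1 / dispersion
  lfc <- log2(((end_count + 0.5) / end_libsize) /
                ((start_count + 0.5) / start_libsize))
  p <- vapply(seq_len(n), function(i) {
    tt <- start_count[i] + end_count[i]
    if (tt == 0L) return(1)
    phat <- tt / (start_libsize + end_libsize)
    mu1 <- phat * start_libsize
    mu2 <- phat * end_libsize
    k <- 0:tt
    lp <- stats::dnbinom(k, size = size, mu = mu1, log = TRUE) +
      stats::dnbinom(tt - k, size = size, mu = mu2, log = TRUE)
    pr <- exp(lp - max(lp))
    pr <- pr / sum(pr)
    obs <- pr[start_count[i] + 1L]
    min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
  }, numeric(1))
  tibble::tibble(log2_fold_change = lfc, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1, with the
#' input order preserved.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Gene-level differential enrichment between start and end point
#'
#' Applies the combined-count filter, estimates a common dispersion,
#' runs the exact conditional NB test per gene, and BH-adjusts across
#' genes.
#'
#' @param table a [gene_count_table()] result.
#' @param min_total combined-count filter threshold (default 128).
#' @param dispersion optional fixed dispersion; estimated when `NULL`.
#' @param library_sizes named vector `c(start, end)`; defaults to the
#'   table attribute.
#' @return a `tn_diff` tibble (`gene_id`, `count_start`, `count_end`,
#'   `log2_fold_change`, `p`, `q`) with attributes `dispersion` and
#'   `library_sizes`.
#' @export
diff_enrichment <- function(table, min_total = 128L, dispersion = NULL,
                            library_sizes = NULL) {
  library_sizes <- library_sizes %||% attr(table, "library_sizes")
  if (is.null(library_sizes)) {
    library_sizes <- c(start = sum(table$count_start),
                       end = sum(table$count_end))
  }
  tbl <- filter_low_count(table, min_total)
  attr(tbl, "library_sizes") <- library_sizes
  if (nrow(tbl) == 0L) {
    out <- tibble::tibble(gene_id = character(), count_start = integer(),
                          count_end = integer(),
                          log2_fold_change = numeric(), p = numeric(),
                          q = numeric())
    return(structure(out, class = c("tn_diff", class(out)),
                     dispersion = NA_real_, library_sizes = library_sizes))
  }
  if (is.null(dispersion)) dispersion <- estimate_dispersion(tbl)
  res <- nb_test(tbl$count_start, tbl$count_end,
                 library_sizes[["start"]], library_sizes[["end"]],
                 dispersion)
  out <- tibble::tibble(
    gene_id = tbl$gene_id,
    count_start = tbl$count_start,
    count_end = tbl$count_end,
    log2_fold_change = res$log2_fold_change,
    p = res$p,
    q = bh_adjust(res$p)
  )
  structure(out, class = c("tn_diff", class(out)),
            dispersion = dispersion, library_sizes = library_sizes)
}

#' @export
print.tn_diff <- function(x, ...) {
  cat("<tn_diff> ", nrow(x), " genes tested, dispersion=",
      signif(attr(x, "dispersion"), 3), ", ", sum(x$q < 0.05),
      " genes at q < 0.05\n", sep = "")
  NextMethod()
}
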