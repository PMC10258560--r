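make_molecules <- function(junctions, strand = "+", umi = NULL) {
  n <- length(junctions)
  tibble::tibble(
    read_id = paste0("m", seq_len(n)),
    umi = umi %||% paste0(strrep("A", 7), c("A", "C", "G", "T"))[
      (seq_len(n) - 1L) %% 4L + 1L],
    chrom = "chr",
    junction_pos = as.integer(junctions),
    strand = rep_len(strand, n),
    start = as.integer(junctions),
    end = as.integer(junctions) + 299L,
    insert_size = 300L
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("junctions snap to the nearest TA site with upstream ties", {
  ta <- c(100L, 200L, 210L)
  mol <- make_molecules(c(100, 201, 198, 205, 150))
  spec <- build_spectrum(mol, ta, snap_tolerance = 2, genome_length = 1000)
  # 100 exact; 201 and 198 snap to 200; 205 equidistant from 200 and 210
  # (d=5) is beyond tolerance -> off-TA; 150 off-TA
  expect_equal(spec$position, c(100L, 200L))
  expect_equal(spec$count, c(1L, 2L))
  expect_equal(attr(spec, "total_mapped"), 3)
  expect_equal(sum(attr(spec, "off_ta")$count), 2)
  expect_equal(sum(spec$fraction), 1)

  # exact tie within tolerance goes upstream: TA at 203 and 207, junction 205
  spec2 <- build_spectrum(make_molecules(205), c(203L, 207L),
                          snap_tolerance = 2, genome_length = 1000)
  expect_equal(spec2$position, 203L)
})

test_that("spectrum fractions are counts over total mapped molecules", {
  mol <- make_molecules(c(rep(100, 50), rep(200, 150)))
  spec <- build_spectrum(mol, c(100L, 200L), genome_length = 1000)
  expect_equal(spec$fraction[spec$position == 100], 0.25)
  expect_equal(attr(spec, "total_mapped"), 200)
})

test_that("promoter orientation is opposite to the read strand", {
  mol <- make_molecules(rep(100, 10), strand = "+")
  spec <- build_spectrum(mol, 100L, genome_length = 1000)
  ori <- infer_orientation(spec)
  expect_equal(ori$promoter_orientation, "-")
  expect_equal(ori$minority_fraction, 0)

  mol2 <- make_molecules(rep(100, 10), strand = rep(c("+", "-"), 5))
  ori2 <- infer_orientation(build_spectrum(mol2, 100L,
                                           genome_length = 1000))
  expect_equal(ori2$promoter_orientation, "ambiguous")
  expect_equal(ori2$minority_fraction, 0.5)
})

test_that("simulated promoter orientations are recovered end-to-end", {
  ts <- tiny_sim()
  jf <- filter_junction_pairs(ts$sim$r1_path, ts$sim$r2_path, ts$profile)
  tr <- tag_umi_and_trim(jf$pairs, ts$profile)
  idx <- build_index(ts$genome)
  mp <- map_fragments(tr$fragments, idx, ts$genome, ts$profile)
  mol <- dedup_umi(mp$alignments)
  spec <- build_spectrum(mol, ts$ta, genome_length = ts$genome$length)
  ori <- infer_orientation(spec)
  m <- dplyr::inner_join(ori, ts$pop, by = "position")
  expect_equal(nrow(m), 6)
  expect_equal(m$promoter_orientation, m$orientation)
})

test_that("uniform coverage produces no peaks", {
  set.seed(61)
  pos <- sort(sample.int(50000, 2000, replace = TRUE))
  spec <- make_spectrum(unique(pos), as.integer(table(pos)),
                        genome_length = 50000)
  pk <- call_peaks(spec, 50000)
  expect_equal(nrow(pk), 0)
  expect_gt(attr(pk, "n_windows"), 400)
})

test_that("a dominant single site yields exactly one covering peak", {
  set.seed(62)
  bg_pos <- sample.int(100000, 5000, replace = TRUE)
  pos_tab <- table(c(bg_pos, rep(40001, 5000)))
  spec <- make_spectrum(as.integer(names(pos_tab)), as.integer(pos_tab),
                        genome_length = 100000)
  pk <- call_peaks(spec, 100000)
  expect_equal(nrow(pk), 1)
  expect_true(pk$start <= 40001 & pk$end >= 40001)
  expect_equal(pk$summit, 40001)
  expect_gt(pk$fold_enrichment, 10)
  # verify the window p-value against the survival-function oracle
  expect_lt(pk$p, stats::ppois(4999, 5000 * 200 / 100000 + 5000 * 200 / 5000,
                               lower.tail = FALSE) + 1e-300)
})

test_that("two distant spikes yield two separate peaks", {
  set.seed(63)
  bg <- table(sample.int(100000, 3000, replace = TRUE))
  tab <- c(as.integer(bg), 2000L, 2000L)
  pos <- c(as.integer(names(bg)), 20001L, 70001L)
  spec <- make_spectrum(pos, tab, genome_length = 100000)
  pk <- call_peaks(spec, 100000)
  expect_equal(nrow(pk), 2)
  expect_true(any(pk$start <= 20001 & pk$end >= 20001))
  expect_true(any(pk$start <= 70001 & pk$end >= 70001))
})

test_that("empty spectra give an empty peak list", {
  spec <- make_spectrum(integer(0), integer(0), genome_length = 10000)
  expect_equal(nrow(call_peaks(spec, 10000)), 0)
})

test_that("null Poisson-uniform spectra stay within BH control", {
  set.seed(64)
  n_sims <- 20
  counts <- integer(n_sims)
  n_win <- NA
  for (i in seq_len(n_sims)) {
    pos <- sample.int(50000, 5000, replace = TRUE)
    tab <- table(pos)
    spec <- make_spectrum(as.integer(names(tab)), as.integer(tab),
                          genome_length = 50000)
    pk <- call_peaks(spec, 50000)
    counts[i] <- nrow(pk)
    n_win <- attr(pk, "n_windows")
  }
  mc_sd <- stats::sd(counts) / sqrt(n_sims)
  expect_lte(mean(counts), 0.01 * n_win + 3 * max(mc_sd, 1e-6))
})

test_that("nearest-gene annotation applies the signed-distance rules", {
  features <- tibble::tibble(
    gene_id = c("geneA", "geneB", "geneX"),
    start = c(1000L, 3000L, 5000L),
    end = c(1500L, 3500L, 5800L),
    strand = c("+", "-", "+")
  )
  peaks <- tibble::tibble(start = c(5200L, 850L, 1600L, 2250L),
                          end = c(5300L, 900L, 1700L, 2250L))
  out <- nearest_gene(peaks, features)
  # inside geneX
  expect_equal(out$nearest_gene[1], "geneX")
  expect_equal(out$distance[1], 0)
  # 100 nt upstream of + strand geneA -> negative
  expect_equal(out$nearest_gene[2], "geneA")
  expect_equal(out$distance[2], -100)
  # 100 nt past geneA's end (downstream of +) -> positive
  expect_equal(out$distance[3], 100)
  # equidistant between geneA end (1500) and geneB start (3000): tie ->
  # lexicographically smallest gene_id
  expect_equal(out$nearest_gene[4], "geneA")

  expect_error(nearest_gene(peaks, features[0, ]), "empty")
})

test_that("nearest gene equals brute force for random intervals", {
  set.seed(65)
  features <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:30),
    start = sort(sample.int(90000, 30)),
    end = integer(30),
    strand = sample(c("+", "-"), 30, replace = TRUE)
  )
  features$end <- features$start + sample.int(800, 30)
  peaks <- tibble::tibble(start = sample.int(95000, 1000))
  peaks$end <- peaks$start + sample.int(500, 1000, replace = TRUE)
  out <- nearest_gene(peaks, features)
  oracle <- vapply(seq_len(nrow(peaks)), function(i) {
    bf_nearest_gene(peaks$start[i], peaks$end[i], features)
  }, character(1))
  expect_equal(out$nearest_gene, oracle)
})

test_that("round-trip: every abundant true insertion lands in a peak", {
  ts <- tiny_sim()
  jf <- filter_junction_pairs(ts$sim$r1_path, ts$sim$r2_path, ts$profile)
  tr <- tag_umi_and_trim(jf$pairs, ts$profile)
  idx <- build_index(ts$genome)
  mp <- map_fragments(tr$fragments, idx, ts$genome, ts$profile)
  mol <- dedup_umi(mp$alignments)
  spec <- build_spectrum(mol, ts$ta, genome_length = ts$genome$length)
  pk <- call_peaks(spec, ts$genome$length)
  truth_frac <- ts$pop$abundance / sum(ts$pop$abundance)
  abundant <- ts$pop$position[truth_frac >= 0.01]
  for (p in abundant) {
    expect_true(any(pk$start <= p & pk$end >= p))
  }
  # no peak without a true insertion
  for (i in seq_len(nrow(pk))) {
    expect_true(any(ts$pop$position >= pk$start[i] - 2 &
                      ts$pop$position <= pk$end[i] + 2))
  }
})

test_that("spectra export to bedGraph", {
  spec <- make_spectrum(c(10L, 50L), c(3L, 1L), genome_length = 100)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_spectrum_bedgraph(spec, f)
  bg <- readr::read_tsv(f, col_names = c("chrom", "start", "end", "frac"),
                        show_col_types = FALSE)
  expect_equal(bg$start, c(9, 49))
  expect_equal(bg$frac, c(0.75, 0.25))
})
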