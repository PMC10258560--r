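test_that("terminus matching honors the two-mismatch bound", {
  term <- TN_TERMINUS
  filler <- strrep("G", 25)
  exact <- paste0(filler, term, "ACGTACGT")
  expect_equal(match_terminus(exact)$offset, 26)

  two_mm <- term
  substr(two_mm, 3, 3) <- "A"   # C -> A
  substr(two_mm, 9, 9) <- "T"   # G -> T
  expect_equal(match_terminus(paste0(filler, two_mm))$offset, 26)
  expect_equal(match_terminus(paste0(filler, two_mm))$mismatches, 2)

  three_mm <- two_mm
  substr(three_mm, 15, 15) <- "G"  # T -> G
  expect_true(is.na(match_terminus(paste0(filler, three_mm))$offset))
})

test_that("terminus matching equals a brute-force all-window scan", {
  set.seed(17)
  pattern <- paste0(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
                    collapse = "")
  for (i in 1:40) {
    s <- paste0(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                collapse = "")
    if (i %% 2 == 0) {  # plant a perturbed copy at a random offset
      off <- sample.int(60, 1)
      substr(s, off, off + 11L) <- perturb(pattern, sample(0:3, 1))
    }
    got <- match_terminus(s, pattern, max_mismatches = 2)$offset
    expect_identical(got, bf_hamming_search(s, pattern, 2))
  }
})

test_that("junction filter keeps exactly the terminus-bearing pairs", {
  prof <- protocol_profile("tnseq")
  term <- prof$terminus
  genomic <- strrep("ACGT", 10)
  # 6 junction reads (one with exactly 2 mismatches), 4 background reads
  r1_seqs <- c(
    paste0(term, genomic), paste0(term, genomic), paste0(term, genomic),
    paste0(term, genomic), paste0(term, genomic),
    paste0(perturb_fixed(term, c(5, 20)), genomic),
    strrep("ACGT", 17), strrep("CCGG", 17), strrep("TTAA", 17),
    paste0(perturb_fixed(term, c(2, 11, 25)), genomic)
  )
  td <- withr::local_tempdir()
  ids <- sprintf("read%02d", 1:10)
  write_fastq(tibble::tibble(read_id = ids, seq = r1_seqs,
                             qual = strrep("F", nchar(r1_seqs))),
              file.path(td, "r1.fastq"))
  write_fastq(tibble::tibble(read_id = ids,
                             seq = strrep("A", rep(40, 10)),
                             qual = strrep("F", rep(40, 10))),
              file.path(td, "r2.fastq"))
  out <- filter_junction_pairs(file.path(td, "r1.fastq"),
                               file.path(td, "r2.fastq"), prof)
  expect_equal(out$stats$kept, 6)
  expect_setequal(out$pairs$read_id, ids[1:6])
})

test_that("junction filter drops and counts orphans", {
  prof <- protocol_profile("tnseq")
  td <- withr::local_tempdir()
  seqs <- paste0(prof$terminus, strrep("ACGT", 10))
  write_fastq(tibble::tibble(read_id = c("a", "b", "c"),
                             seq = rep(seqs, 3),
                             qual = strrep("F", nchar(rep(seqs, 3)))),
              file.path(td, "r1.fastq"))
  write_fastq(tibble::tibble(read_id = c("a", "c"),
                             seq = rep(strrep("A", 40), 2),
                             qual = rep(strrep("F", 40), 2)),
              file.path(td, "r2.fastq"))
  out <- filter_junction_pairs(file.path(td, "r1.fastq"),
                               file.path(td, "r2.fastq"), prof)
  expect_equal(out$stats$orphans, 1)
  expect_equal(out$stats$kept, 2)
})

test_that("junction filter on empty input yields empty output", {
  prof <- protocol_profile("tnseq")
  td <- withr::local_tempdir()
  file.create(file.path(td, "r1.fastq"), file.path(td, "r2.fastq"))
  out <- filter_junction_pairs(file.path(td, "r1.fastq"),
                               file.path(td, "r2.fastq"), prof)
  expect_equal(out$stats$kept, 0)
  expect_equal(nrow(out$pairs), 0)
})

test_that("truncated FASTQ records raise a format error", {
  f <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+"), f)
  expect_error(read_fastq(f), "truncated")
})

test_that("anchor trimming starts at the first genomic base", {
  prof <- protocol_profile("rbtnseq")
  genomic <- strrep("ACGTG", 10)
  pairs <- tibble::tibble(
    read_id = "r1",
    seq1 = rb_read(prof, strrep("T", 20), genomic),
    qual1 = strrep("F", nchar(rb_read(prof, strrep("T", 20), genomic))),
    seq2 = paste0("ACGTACGT", strrep("C", 40)),
    qual2 = strrep("F", 48),
    terminus_end = 93L
  )
  out <- tag_umi_and_trim(pairs, prof, trim_mode = "anchor")
  expect_equal(out$fragments$genomic_seq_r1, genomic)
  expect_equal(out$fragments$umi, "ACGTACGT")
  expect_equal(out$fragments$genomic_seq_r2, strrep("C", 40))
  expect_equal(out$fragments$read_id, "r1:ACGTACGT")
})

test_that("fixed-offset trimming removes the stated prefixes", {
  prof <- protocol_profile("tnseq")  # umi_len 9
  pairs <- tibble::tibble(
    read_id = "r1",
    seq1 = strrep("A", 100),
    qual1 = strrep("F", 100),
    seq2 = strrep("C", 100),
    qual2 = strrep("F", 100)
  )
  out <- tag_umi_and_trim(pairs, prof, trim_mode = "fixed",
                          fixed_offsets = c(r1 = 27L, r2 = 17L))
  expect_equal(nchar(out$fragments$genomic_seq_r1), 100 - 27)
  expect_equal(nchar(out$fragments$genomic_seq_r2), 100 - 9 - 17)
  expect_equal(out$fragments$umi, strrep("C", 9))
})

test_that("pairs too short to trim or low quality are dropped and counted", {
  prof <- protocol_profile("tnseq")
  pairs <- tibble::tibble(
    read_id = c("short_r2", "lowq"),
    seq1 = rep(strrep("A", 60), 2),
    qual1 = c(strrep("F", 60), strrep("#", 60)),
    seq2 = c("ACGT", strrep("C", 60)),
    qual2 = c("FFFF", strrep("#", 60)),
    terminus_end = c(30L, 30L)
  )
  out <- tag_umi_and_trim(pairs, prof, trim_mode = "anchor")
  expect_equal(out$stats$too_short, 1)
  expect_equal(out$stats$low_quality, 1)
  expect_equal(out$stats$kept, 0)
})

test_that("barcode extraction returns the sequence between the flanks", {
  prof <- protocol_profile("rbtnseq")
  bc <- strrep("ACGTG", 4)
  read <- rb_read(prof, bc, strrep("A", 50))
  expect_equal(extract_barcode(read), bc)

  # 19-nt insert is extracted; the caller's length filter rejects it
  short <- paste0(prof$flank5, substr(bc, 1, 19), prof$flank3,
                  prof$terminus, strrep("A", 50))
  expect_equal(nchar(extract_barcode(short)), 19)

  # flank5 absent -> none
  expect_true(is.na(extract_barcode(paste0(strrep("G", 18), bc,
                                           prof$flank3, strrep("A", 50)))))
})

test_that("the flank mismatch budget is shared across both flanks", {
  prof <- protocol_profile("rbtnseq")
  bc <- strrep("TGCAC", 4)
  f5_2mm <- perturb_fixed(prof$flank5, c(2, 9))
  f3_2mm <- perturb_fixed(prof$flank3, c(3, 12))
  f3_3mm <- perturb_fixed(prof$flank3, c(3, 12, 20))
  ok <- paste0(f5_2mm, bc, f3_2mm, prof$terminus, strrep("A", 40))
  over <- paste0(f5_2mm, bc, f3_3mm, prof$terminus, strrep("A", 40))
  expect_equal(extract_barcode(ok), bc)
  expect_true(is.na(extract_barcode(over)))
})

test_that("attach_barcodes applies the 20-bp length filter", {
  prof <- protocol_profile("rbtnseq")
  good <- rb_read(prof, strrep("AC", 10), strrep("G", 40))
  bad <- paste0(prof$flank5, strrep("A", 19), prof$flank3, prof$terminus,
                strrep("G", 40))
  pairs <- tibble::tibble(read_id = c("good", "bad"),
                          seq1 = c(good, bad),
                          qual1 = strrep("F", nchar(c(good, bad))),
                          seq2 = rep(strrep("C", 30), 2),
                          qual2 = rep(strrep("F", 30), 2),
                          terminus_end = c(93L, 92L))
  out <- attach_barcodes(pairs, prof)
  expect_equal(out$stats$bad_length, 1)
  expect_equal(out$pairs$read_id, "good")
})

test_that("barcode clustering follows the greedy abundance rule", {
  # distance 1 variant joins the dominant barcode
  out <- cluster_barcodes(c(AAAAAAAAAAAAAAAAAAAA = 100L,
                            AAAAAAAAAAAAAAAAAAAT = 5L), d = 2)
  cl <- attr(out, "clusters")
  expect_equal(nrow(cl), 1)
  expect_equal(cl$center, "AAAAAAAAAAAAAAAAAAAA")
  expect_equal(cl$total, 105L)

  # far-apart barcodes stay separate
  out <- cluster_barcodes(c(AAAAAAAAAAAAAAAAAAAA = 10L,
                            TTTTTTTTTTAAAAAAAAAA = 10L), d = 2)
  expect_equal(nrow(attr(out, "clusters")), 2)

  # equal counts, distance 1: single cluster centered on the
  # lexicographically smaller barcode
  out <- cluster_barcodes(c(AAAAAAAAAAAAAAAAAAAC = 7L,
                            AAAAAAAAAAAAAAAAAAAA = 7L), d = 2)
  cl <- attr(out, "clusters")
  expect_equal(nrow(cl), 1)
  expect_equal(cl$center, "AAAAAAAAAAAAAAAAAAAA")

  expect_error(cluster_barcodes(c(AAAA = 1L, AAAAA = 2L)), "length")
})

test_that("clustering conserves reads", {
  set.seed(23)
  bcs <- unique(replicate(300, paste0(sample(c("A", "C", "G", "T"), 12,
                                             replace = TRUE),
                                      collapse = "")))
  counts <- stats::setNames(sample.int(50, length(bcs), replace = TRUE), bcs)
  out <- cluster_barcodes(counts, d = 3)
  expect_equal(sum(attr(out, "clusters")$total), sum(counts))
  expect_equal(sum(out$count), sum(counts))
})

test_that("well-separated true barcodes absorb their error variants", {
  set.seed(29)
  d <- 2L
  truth <- character(0)
  while (length(truth) < 20) {  # pairwise Hamming distance > 2d = 4
    cand <- paste0(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                   collapse = "")
    if (all(hamming_gt(cand, truth, 2 * d))) truth <- c(truth, cand)
  }
  raw <- tibble::tibble(barcode = truth, count = 50L)
  variants <- tibble::tibble(
    barcode = vapply(rep(truth, each = 3),
                     function(b) perturb(b, sample.int(d, 1)), character(1)),
    truth = rep(truth, each = 3),
    count = 2L
  )
  out <- cluster_barcodes(dplyr::bind_rows(raw, variants[, c("barcode",
                                                             "count")]),
                          d = d)
  got <- out$center[match(variants$barcode, out$barcode)]
  expect_equal(got, variants$truth)
})
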