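test_that("the k-mer index maps words to all their positions", {
  g <- tn_genome("g", "ACGTACGTAA")
  idx <- build_index(g, k = 4)
  expect_equal(idx$lookup[["ACGT"]], c(1, 5))
  expect_equal(idx$lookup[["GTAC"]], 3)
  expect_null(idx$lookup[["TTTT"]])
})

test_that("an oversized k yields an empty index with a warning", {
  g <- tn_genome("g", "ACGT")
  expect_warning(idx <- build_index(g, k = 10), "exceeds")
  expect_length(idx$lookup, 0)
})

test_that("error-free pairs map to the true junction on both strands", {
  set.seed(31)
  gseq <- paste0(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                 collapse = "")
  g <- tn_genome("g", gseq)
  idx <- build_index(g)
  prof <- protocol_profile("tnseq", read_len = 80, frag_min = 150)

  # plus-strand junction at 1001, fragment of 300 nt
  r1 <- substr(gseq, 1001, 1060)
  r2 <- revcomp_chr(substr(gseq, 1241, 1300))
  frag <- tibble::tibble(read_id = "p", genomic_seq_r1 = r1,
                         genomic_seq_r2 = r2, umi = "AAAAAAAAA")
  ali <- map_pair(frag, idx, g, prof)
  expect_equal(ali$junction_pos, 1001)
  expect_equal(ali$strand, "+")
  expect_equal(ali$start, 1001)
  expect_equal(ali$end, 1300)
  expect_equal(ali$insert_size, 300)

  # minus-strand junction at 2000, fragment extending leftward
  r1m <- revcomp_chr(substr(gseq, 1941, 2000))
  r2m <- substr(gseq, 1701, 1760)
  fragm <- tibble::tibble(read_id = "m", genomic_seq_r1 = r1m,
                          genomic_seq_r2 = r2m, umi = "AAAAAAAAA")
  alim <- map_pair(fragm, idx, g, prof)
  expect_equal(alim$junction_pos, 2000)
  expect_equal(alim$strand, "-")
  expect_equal(alim$start, 1701)
  expect_equal(alim$end, 2000)
})

test_that("pairs violating the insert bound are dropped", {
  set.seed(37)
  gseq <- paste0(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                 collapse = "")
  g <- tn_genome("g", gseq)
  idx <- build_index(g)
  prof <- protocol_profile("tnseq", read_len = 80)
  # mates imply an insert of 1500 > 1000
  frag <- tibble::tibble(
    read_id = "far",
    genomic_seq_r1 = substr(gseq, 101, 160),
    genomic_seq_r2 = revcomp_chr(substr(gseq, 1541, 1600)),
    umi = "AAAAAAAAA"
  )
  expect_null(map_pair(frag, idx, g, prof))
})

test_that("reads matching two identical repeat copies are ambiguous", {
  set.seed(41)
  unit <- paste0(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                 collapse = "")
  spacer <- paste0(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                   collapse = "")
  gseq <- paste0(unit, spacer, unit)
  g <- tn_genome("g", gseq)
  idx <- build_index(g)
  prof <- protocol_profile("tnseq", read_len = 80)
  frag <- tibble::tibble(
    read_id = "rep",
    genomic_seq_r1 = substr(unit, 1, 60),
    genomic_seq_r2 = revcomp_chr(substr(unit, 201, 260)),
    umi = "AAAAAAAAA"
  )
  out <- map_fragments(frag, idx, g, prof)
  expect_equal(nrow(out$alignments), 0)
  expect_equal(out$stats$ambiguous, 1)
})

test_that("SAM import honors pairing flags and the insert bound", {
  sam <- withr::local_tempfile(fileext = ".sam")
  seq50 <- strrep("A", 50)
  q50 <- strrep("F", 50)
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr\tLN:5000",
    # proper pair, insert 300
    paste("ok:ACGTACGTA", 99, "chr", 101, 60, "50M", "=", 351, 300,
          seq50, q50, sep = "\t"),
    paste("ok:ACGTACGTA", 147, "chr", 351, 60, "50M", "=", 101, -300,
          seq50, q50, sep = "\t"),
    # mate unmapped
    paste("orphan:CCCCCCCCC", 73, "chr", 501, 60, "50M", "*", 0, 0,
          seq50, q50, sep = "\t"),
    # insert 1200 exceeds the bound
    paste("wide:GGGGGGGGG", 99, "chr", 1001, 60, "50M", "=", 2151, 1200,
          seq50, q50, sep = "\t"),
    paste("wide:GGGGGGGGG", 147, "chr", 2151, 60, "50M", "=", 1001, -1200,
          seq50, q50, sep = "\t")
  ), sam)
  prof <- protocol_profile("tnseq")
  out <- import_sam(sam, prof)
  expect_equal(nrow(out$alignments), 1)
  expect_equal(out$alignments$umi, "ACGTACGTA")
  expect_equal(out$alignments$start, 101)
  expect_equal(out$alignments$end, 400)
  expect_equal(out$alignments$junction_pos, 101)
  expect_equal(out$stats$skipped_unmapped, 1)
  expect_equal(out$stats$skipped_insert, 1)
})

test_that("SAM records without a UMI suffix raise an error", {
  sam <- withr::local_tempfile(fileext = ".sam")
  seq50 <- strrep("A", 50)
  q50 <- strrep("F", 50)
  writeLines(c(
    "@SQ\tSN:chr\tLN:5000",
    paste("noumi", 99, "chr", 101, 60, "50M", "=", 351, 300,
          seq50, q50, sep = "\t"),
    paste("noumi", 147, "chr", 351, 60, "50M", "=", 101, -300,
          seq50, q50, sep = "\t")
  ), sam)
  expect_error(import_sam(sam, protocol_profile("tnseq")), "noumi")
})

test_that("directional UMI dedup merges errors but not distinct molecules", {
  base <- tibble::tibble(
    chrom = "chr", strand = "+", start = 100L, end = 400L,
    junction_pos = 100L, insert_size = 301L
  )
  mk <- function(umis) {
    dplyr::bind_cols(
      tibble::tibble(read_id = paste0("r", seq_along(umis)), umi = umis),
      base[rep(1, length(umis)), ]
    )
  }
  # 10 reads of one UMI + 1 read at distance 1: merged (10 >= 2*1-1)
  out <- dedup_umi(mk(c(rep("AAAAAAAA", 10), "AAAAAAAT")))
  expect_equal(nrow(out), 1)
  expect_equal(out$umi, "AAAAAAAA")
  expect_equal(out$n_reads, 11)

  # equal counts at distance 8: two molecules
  out <- dedup_umi(mk(c(rep("AAAAAAAA", 5), rep("TTTTTTTT", 5))))
  expect_equal(nrow(out), 2)

  # equal counts at distance 1 do NOT merge (5 < 2*5-1)
  out <- dedup_umi(mk(c(rep("AAAAAAAA", 5), rep("AAAAAAAT", 5))))
  expect_equal(nrow(out), 2)

  # identical UMI at two different spans stays two molecules
  two_spans <- dplyr::bind_rows(
    mk("AAAAAAAA"),
    dplyr::mutate(mk("AAAAAAAA"), start = 200L, end = 500L,
                  junction_pos = 200L)
  )
  expect_equal(nrow(dedup_umi(two_spans)), 2)
})

test_that("dedup is idempotent and never increases the count", {
  ts <- tiny_sim()
  jf <- filter_junction_pairs(ts$sim$r1_path, ts$sim$r2_path, ts$profile)
  tr <- tag_umi_and_trim(jf$pairs, ts$profile)
  idx <- build_index(ts$genome)
  mp <- map_fragments(tr$fragments, idx, ts$genome, ts$profile)
  mol <- dedup_umi(mp$alignments)
  expect_lte(nrow(mol), nrow(mp$alignments))
  again <- dedup_umi(mol)
  expect_equal(nrow(again), nrow(mol))
  expect_equal(again$umi, mol$umi)
})

test_that("dedup recovers the exact molecule count under PCR duplication", {
  ts <- tiny_sim()
  td <- withr::local_tempdir()
  sr <- simulate_reads(ts$genome, ts$pop, ts$profile, n_molecules = 800,
                       pcr_duplication = 5, error_rate = 0, seed = 51,
                       r1_path = file.path(td, "r1.fastq.gz"),
                       r2_path = file.path(td, "r2.fastq.gz"),
                       truth_path = file.path(td, "t.tsv"))
  jf <- filter_junction_pairs(file.path(td, "r1.fastq.gz"),
                              file.path(td, "r2.fastq.gz"), ts$profile)
  tr <- tag_umi_and_trim(jf$pairs, ts$profile)
  idx <- build_index(ts$genome)
  mp <- map_fragments(tr$fragments, idx, ts$genome, ts$profile)
  mol <- dedup_umi(mp$alignments)
  expect_equal(nrow(mol), 800)
})

test_that("error-free reads recover the true junction almost always", {
  ts <- tiny_sim()
  truth <- ts$sim$truth
  jf <- filter_junction_pairs(ts$sim$r1_path, ts$sim$r2_path, ts$profile)
  tr <- tag_umi_and_trim(jf$pairs, ts$profile)
  idx <- build_index(ts$genome)
  mp <- map_fragments(tr$fragments, idx, ts$genome, ts$profile)
  ali <- mp$alignments
  mol_id <- sub("x\\d+:.*$", "", ali$read_id)
  tpos <- truth$position[match(mol_id, truth$molecule_id)]
  tori <- truth$orientation[match(mol_id, truth$molecule_id)]
  expected_junction <- ifelse(tori == "-", tpos, tpos + 1L)
  expect_gte(mean(ali$junction_pos == expected_junction), 0.999)
  expect_gte(nrow(ali) / nrow(truth), 0.999)
})
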