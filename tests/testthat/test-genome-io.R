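# Readers, region extraction, plastome partitioning and the small aligner.

test_that("GenBank parsing matches an independent parser on the mini fixture", {
  # expected values were computed with Biopython's GenBank parser and frozen
  rec <- read_genome(test_path("fixtures", "mini.gb"))
  expect_s3_class(rec, "genome_record")
  expect_equal(rec$id, "MINI0001")
  expect_equal(rec$length, 120L)
  expect_equal(substr(rec$sequence, 1, 20), "GCTAAAGACAATTACATAAC")
  expect_equal(rec$species_label, "synthetic construct")

  ann <- rec$annotations
  expect_equal(nrow(ann), 4L)  # source dropped; origin-spanning join split
  expect_equal(ann$feature_name[1], "trnH-GUG")
  expect_equal(unlist(ann[1, c("start", "end")], use.names = FALSE), c(1L, 75L))
  expect_equal(ann$strand[1], "+")
  expect_equal(ann$feature_name[2], "psbA")
  expect_equal(unlist(ann[2, c("start", "end")], use.names = FALSE), c(80L, 110L))
  expect_equal(ann$strand[2], "-")
  # join(115..120,1..5) across the origin becomes two intervals
  expect_equal(ann$start[3:4], c(115L, 1L))
  expect_equal(ann$end[3:4], c(120L, 5L))
})

test_that("FASTA reading validates sequences and reports offenders", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACGT"), tmp)
  rec <- read_genome(tmp)
  expect_equal(rec$length, 4L)
  expect_equal(nrow(rec$annotations), 0L)

  writeLines(c(">bad", "ACXT"), tmp)
  expect_error(read_genome(tmp), "non-IUPAC")
  expect_error(genome_record("r", "ACXT"), "non-IUPAC")
  writeLines("", tmp)
  expect_error(read_genome(tmp), "empty|determine")
})

test_that("extract_region uses 1-based inclusive coordinates", {
  expect_equal(extract_region("ACGTAC", 2, 4), "CGT")
  rec <- genome_record("r1", "ACGTACGTAA")
  expect_equal(extract_region(rec, 1, rec$length), rec$sequence)
  expect_error(extract_region(rec, 0, 4), "out of range")
  expect_error(extract_region(rec, 5, 11), "out of range")
  set.seed(11)
  for (i in 1:50) {
    s <- sample(1:10, 1)
    e <- s + sample.int(11 - s, 1) - 1
    expect_equal(nchar(extract_region(rec, s, e)), e - s + 1)
  }
})

test_that("alignment round-trips through FASTA and strips all-gap columns", {
  blk <- alignment_block(c(a = "AC-GT", b = "ACAGT"))
  expect_equal(blk$column_count, 5L)
  # all-gap column removed at construction
  blk2 <- alignment_block(c("AC--GT", "ACA-GT"))
  expect_equal(blk2$column_count, 5L)

  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(blk, tmp)
  back <- load_alignment(tmp)
  expect_equal(back$rows, blk$rows)
  expect_equal(back$haplotype_ids, blk$haplotype_ids)

  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTA"), tmp)
  expect_error(load_alignment(tmp), "ragged|lengths")
  writeLines(c(">a", "ACGT"), tmp)
  expect_error(load_alignment(tmp), "fewer than 2")
})

test_that("genome records round-trip through FASTA", {
  rec <- genome_record("acc1", rand_seq(500), species_label = "test taxon")
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(rec, tmp)
  back <- read_genome(tmp)
  expect_equal(back$sequence, rec$sequence)
  expect_equal(back$id, "acc1")
})

test_that("BED export converts to 0-based half-open", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_bed(data.frame(start = 1L, end = 10L, name = "r1", score = 5L), tmp)
  got <- read.delim(tmp, header = FALSE)
  expect_equal(unlist(got[1, 2:3], use.names = FALSE), c(0L, 10L))
})

test_that("align_small reproduces exhaustive-enumeration optima", {
  a <- align_small("ACGT", "ACGT")
  expect_equal(attr(a, "score"), 4)
  expect_false(any(grepl("-", a$rows)))

  a2 <- align_small("ACGTACGT", "ACGT")
  gaps <- gregexpr("-+", a2$rows[2])[[1]]
  expect_equal(attr(gaps, "match.length"), 4L)  # one 4-base gap run
  expect_equal(attr(a2, "score"), enum_align_score("ACGTACGT", "ACGT"))

  set.seed(42)
  for (i in 1:200) {
    x <- rand_seq(sample(1:6, 1)); y <- rand_seq(sample(1:6, 1))
    expect_equal(attr(align_small(x, y), "score"), enum_align_score(x, y),
                 info = paste(x, y))
  }
  expect_error(align_small(rand_seq(50001), "ACGT"), "50 kb")
})

test_that("partition_genome recovers constructed quadripartite boundaries", {
  # noise-free genomes built by the generator (which guarantees the planted
  # repeat pair is maximal), 100 replicates
  for (seed in 1:100) {
    spec <- simulation_spec(seed = seed, n_haplotypes = 2,
                            block_plan = data.frame(
                              label = c("LSC-like", "IR-like", "SSC-like", "IR-like"),
                              length = c(3000, 1200, 900, 1200),
                              rate = 0))
    g <- simulate_quartet(spec)$records[[1]]
    p <- partition_genome(g, min_ir_len = 1000)
    expect_false(p$degenerate)
    iv <- p$intervals
    expect_equal(iv$region, c("LSC", "IRa", "SSC", "IRb"))
    expect_equal(iv$start, c(1L, 3001L, 4201L, 5101L))
    expect_equal(iv$end, c(3000L, 4200L, 5100L, 6300L))
  }
})

test_that("partition invariants hold and absence of a repeat degenerates cleanly", {
  spec <- simulation_spec(seed = 7, n_haplotypes = 2,
                          block_plan = data.frame(
                            label = c("LSC-like", "IR-like", "SSC-like", "IR-like"),
                            length = c(9000, 2500, 1800, 2500),
                            rate = c(0.01, 0.001, 0.012, 0.001)))
  g <- simulate_quartet(spec)$records[[1]]
  p <- partition_genome(g, min_ir_len = 1000)
  iv <- p$intervals
  expect_equal(sum(iv$end - iv$start + 1), g$length)      # tiles the genome
  ira <- iv[iv$region == "IRa", ]; irb <- iv[iv$region == "IRb", ]
  expect_equal(ira$end - ira$start, irb$end - irb$start)  # equal lengths
  expect_gte(p$ir_identity, 0.99)

  set.seed(5)
  expect_warning(p2 <- partition_genome(rand_seq(10000), min_ir_len = 1000),
                 "no inverted repeat")
  expect_true(p2$degenerate)
  expect_equal(p2$intervals$region, "LSC")
  expect_equal(p2$intervals$end, 10000L)
})
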