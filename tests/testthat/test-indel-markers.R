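# InDel event extraction, tandem repeats, primer metrics, marker definition.

test_that("a gap run with one presence pattern forms a single event", {
  blk <- alignment_block(c("AC---GT", "ACTTAGT"))
  ev <- call_indel_events(blk)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$length, 3L)
  expect_equal(ev$inserted_seq, "TTA")
  expect_equal(ev$gapped, "hap1")
  expect_equal(nrow(call_indel_events(alignment_block(c("ACGT", "ACGT")))), 0L)
})

test_that("adjacent gap runs with different haplotype patterns stay separate", {
  # hap2 gapped over cols 3-4, hap3 gapped over cols 5-6: two events
  blk <- alignment_block(c("AATTCCGG", "AA--CCGG", "AATT--GG"))
  ev <- call_indel_events(blk)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$aln_start, c(3L, 5L))
  expect_equal(ev$gapped, c("hap2", "hap3"))
})

test_that("planted InDels are recovered exactly with zero spurious events", {
  for (seed in 1:30) {
    sim <- simulate_quartet(recovery_spec(seed))
    ev <- call_indel_events(sim$alignment)
    tr_truth <- sim$truth$events
    expect_equal(nrow(ev), nrow(tr_truth))
    o <- order(tr_truth$aln_start)
    expect_equal(ev$aln_start, as.integer(tr_truth$aln_start[o]))
    expect_equal(ev$length, as.integer(tr_truth$length[o]))
    # carriers of a deletion are gapped; non-members of an insertion are gapped
    for (k in seq_len(nrow(ev))) {
      t_ev <- tr_truth[o[k], ]
      members <- paste0("hap", strsplit(t_ev$subset, ",")[[1]])
      gapped <- strsplit(ev$gapped[k], ",")[[1]]
      if (t_ev$type == "del") {
        expect_setequal(gapped, members)
      } else {
        expect_setequal(gapped, setdiff(sim$alignment$haplotype_ids, members))
      }
    }
  }
})

test_that("event gap lengths are conserved and row order is irrelevant", {
  set.seed(8)
  sim <- simulate_quartet(recovery_spec(12))
  blk <- sim$alignment
  ev <- call_indel_events(blk)
  # per-row gap totals from events == per-row gap counts of the block
  for (h in seq_along(blk$haplotype_ids)) {
    id <- blk$haplotype_ids[h]
    from_events <- sum(ev$length[vapply(strsplit(ev$gapped, ","),
                                        function(g) id %in% g, logical(1))])
    expect_equal(from_events, sum(blk$mat[h, ] == "-"))
  }
  perm <- c(3, 1, 4, 2)
  blk2 <- alignment_block(blk$rows[perm], ids = blk$haplotype_ids[perm])
  ev2 <- call_indel_events(blk2)
  expect_equal(ev2$aln_start, ev$aln_start)
  expect_equal(ev2$length, ev$length)
  expect_equal(lapply(strsplit(ev2$gapped, ","), sort),
               lapply(strsplit(ev$gapped, ","), sort))
})

test_that("substitution noise never alters recovered event lengths", {
  base <- simulate_quartet(recovery_spec(77))
  spec_noisy <- recovery_spec(77)
  spec_noisy$block_plan$rate <- 0.01  # uniform 1% noise
  noisy <- simulate_quartet(spec_noisy)
  ev_b <- call_indel_events(base$alignment)
  ev_n <- call_indel_events(noisy$alignment)
  expect_equal(ev_n$length, ev_b$length)
  expect_equal(ev_n$aln_start, ev_b$aln_start)
})

test_that("tandem repeats are found with unit, copy number and slippage link", {
  tr <- detect_tandem_repeats("ACACACAC")
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$unit_length, 2L)
  expect_equal(tr$copies, 4L)

  # planted 23 bp unit duplicated in hap1 of a quartet
  spec <- simulation_spec(seed = 19, n_haplotypes = 2,
                          block_plan = data.frame(label = "LSC-like",
                                                  length = 4000, rate = 0),
                          tr_plan = data.frame(block = 1, unit_length = 23,
                                               copies = 2, subset = "1"))
  sim <- simulate_quartet(spec)
  ev <- call_indel_events(sim$alignment)
  trs <- detect_tandem_repeats(sim$alignment, indels = ev)
  hit <- trs[trs$haplotype == "hap1" & trs$unit_length == 23, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$copies, 2L)
  expect_equal(hit$slippage_event, ev$event[1])

  # sequences verified repeat-free by a brute-force scan stay empty
  set.seed(61)
  found <- 0L
  for (i in 1:20) {
    repeat {
      s <- rand_seq(60)
      if (!has_tandem_repeat(s)) break
    }
    found <- found + nrow(detect_tandem_repeats(s, max_unit = 30))
  }
  expect_equal(found, 0L)
})

test_that("primer metrics report GC and a length-appropriate Tm", {
  m <- primer_metrics(strrep("A", 20))
  expect_equal(m$gc, 0)
  m2 <- primer_metrics("GCGCGCGCGC")     # 10-mer: Wallace rule
  expect_equal(m2$tm, 40)
  expect_equal(m2$gc, 100)
  expect_equal(m2$method, "wallace")
  # hand count: 10 G/C among the 23 bases of the ZanID1 forward primer
  m3 <- primer_metrics("GATTCACAATCCACTGCCTTGAT")
  expect_equal(m3$gc, 100 * 10 / 23)
  expect_equal(m3$method, "nearest_neighbor")
  expect_true(m3$tm > 40 && m3$tm < 70)
  expect_error(primer_metrics("ACGTACGTNN"), "ambiguous")
  expect_error(primer_metrics("ACGT"), "length")
})

test_that("packaged primer table loads with expected product ranges", {
  pr <- default_primers()
  expect_setequal(names(pr), c("ZanID1", "ZanID2", "ZanID3", "ZanID4",
                               "trnH_psbA_universal"))
  expect_equal(pr$ZanID2$expected_range, c(547L, 662L))
  expect_null(pr$trnH_psbA_universal$expected_range)
})

test_that("markers spanning a planted InDel are diagnostic with exact ranges", {
  spec <- simulation_spec(seed = 91, n_haplotypes = 4,
                          block_plan = data.frame(label = "LSC-like",
                                                  length = 6000, rate = 0),
                          indel_plan = data.frame(block = 1, length = 50,
                                                  subset = "1,2", type = "del"),
                          species_map = c("schinifolium", "schinifolium",
                                          "piperitum", "piperitum"))
  sim <- simulate_quartet(spec)
  tr <- sim$truth$events[1, ]
  anc <- sim$truth$ancestor
  fwd <- substr(anc, tr$anc_start - 60, tr$anc_start - 39)
  rev_tmpl <- substr(anc, tr$anc_end + 39, tr$anc_end + 60)
  pp <- primer_pair("syn50", fwd, revc(rev_tmpl))
  mk <- define_marker(sim$alignment, pp, species_map = sim$truth$species_map,
                      max_mismatch = 0)
  expect_equal(length(mk$non_universal), 0L)
  expect_equal(unname(diff(mk$product_range)), 50L)
  expect_true(mk$diagnostic)
  expect_equal(nrow(mk$indel_events), 1L)
  # carriers of the deletion have the short product
  expect_equal(unname(mk$products[["hap1"]]), unname(mk$product_range[1]))
  expect_equal(unname(mk$products[["hap3"]]), unname(mk$product_range[2]))

  # per-haplotype product differences equal the planted net InDel length
  d <- outer(mk$products, mk$products, "-")
  expect_setequal(unique(as.vector(abs(d))), c(0L, 50L))

  # primers placed inside the deleted span cannot amplify the carriers
  fwd_in <- substr(anc, tr$anc_start, tr$anc_start + 21)
  pp2 <- primer_pair("broken", fwd_in, revc(rev_tmpl))
  mk2 <- define_marker(sim$alignment, pp2, species_map = sim$truth$species_map,
                       max_mismatch = 0)
  expect_setequal(mk2$non_universal, c("hap1", "hap2"))
})
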