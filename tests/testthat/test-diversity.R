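# Nucleotide diversity, the sliding-window scan, hotspot calling and
# partition averages.

test_that("pairwise p-distance handles gaps and undefined comparisons", {
  expect_equal(pairwise_p_distance("ACGT", "ACGT"),
               list(distance = 0, valid_sites = 4L))
  expect_equal(pairwise_p_distance("ACGT", "ACGA"),
               list(distance = 0.25, valid_sites = 4L))
  # hand count: gap column dropped under pairwise deletion
  expect_equal(pairwise_p_distance("AC-T", "ACGT"),
               list(distance = 0, valid_sites = 3L))
  expect_error(pairwise_p_distance("ACGT", "ACG"), "length")
  # all-gap overlap: undefined sentinel, never zero
  res <- pairwise_p_distance("--AA", "TT--")
  expect_true(is.na(res$distance))
  expect_equal(res$valid_sites, 0L)
})

test_that("pi equals brute-force pair/column counting on random blocks", {
  b <- alignment_block(rep("ACGTACGT", 4))
  expect_equal(nucleotide_diversity(b), 0)
  set.seed(100)
  s <- rand_seq(100)
  s2 <- s
  substr(s2, 1, 1) <- setdiff(BASES, substr(s, 1, 1))[1]
  expect_equal(nucleotide_diversity(alignment_block(c(s, s2))), 0.01)

  set.seed(101)
  for (i in 1:60) {
    n <- sample(c(2, 3, 4, 6), 1)
    L <- sample(20:200, 1)
    rows <- rand_block(n, L, p_gap = 0.08, p_n = 0.03)
    blk <- alignment_block(rows)
    for (pol in c("pairwise_deletion", "complete_deletion")) {
      expect_equal(nucleotide_diversity(blk, pol), brute_pi(blk$rows, pol),
                   tolerance = 1e-12)
    }
  }
})

test_that("pi is invariant to row order and column permutation", {
  set.seed(21)
  rows <- rand_block(4, 150, p_gap = 0.05)
  blk <- alignment_block(rows)
  base <- nucleotide_diversity(blk)
  expect_equal(nucleotide_diversity(alignment_block(rev(rows))), base)
  perm <- sample(blk$column_count)
  shuffled <- apply(blk$mat[, perm, drop = FALSE], 1, paste, collapse = "")
  expect_equal(nucleotide_diversity(alignment_block(shuffled)), base)
})

test_that("planting extra substitutions never decreases pi", {
  set.seed(33)
  m <- matrix(rep(strsplit(rand_seq(300), "")[[1]], each = 4), nrow = 4)
  prev <- 0
  for (step in 1:25) {
    # mutate one row at a column where all rows still agree
    mono <- which(apply(m, 2, function(col) length(unique(col)) == 1))
    j <- sample(mono, 1); i <- sample(4, 1)
    m[i, j] <- sample(setdiff(BASES, m[i, j]), 1)
    cur <- nucleotide_diversity(alignment_block(apply(m, 1, paste, collapse = "")))
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("window layout follows floor((L-w)/s)+1 with dropped partial windows", {
  set.seed(55)
  rows <- rand_block(2, 1200)
  w <- sliding_window_scan(alignment_block(rows), scan_config(600, 300))
  expect_equal(nrow(w), 3L)
  expect_equal(w$start, c(1L, 301L, 601L))
  expect_equal(w$end, c(600L, 900L, 1200L))
  expect_equal(w$midpoint, (w$start + w$end) %/% 2L)

  for (i in 1:40) {
    L <- sample(10:400, 1)
    ws <- sample(5:100, 1)
    ss <- sample(1:ws, 1)
    rows <- rand_block(2, L)
    cfg <- scan_config(ws, ss)
    if (L < ws) {
      expect_warning(out <- sliding_window_scan(alignment_block(rows), cfg))
      expect_equal(nrow(out), 0L)
    } else {
      out <- sliding_window_scan(alignment_block(rows), cfg)
      expect_equal(nrow(out), (L - ws) %/% ss + 1L)
      expect_true(all(out$end <= L))
      expect_true(all(diff(out$start) == ss))
    }
  }
})

test_that("identical sequences give zero diversity in every window", {
  rows <- rep(rand_seq(2000), 3)
  w <- sliding_window_scan(alignment_block(rows), scan_config())
  expect_true(all(w$pi == 0))
})

test_that("hotspots are maximal supra-threshold runs under a strict threshold", {
  mk_windows <- function(pi) {
    n <- length(pi)
    out <- data.frame(window_index = seq_len(n), start = 1L + (seq_len(n) - 1L) * 300L,
                      end = 600L + (seq_len(n) - 1L) * 300L,
                      midpoint = 300L + (seq_len(n) - 1L) * 300L,
                      pi = pi, valid_sites = 600L)
    class(out) <- c("window_diversity", "data.frame")
    out
  }
  cfg <- scan_config(pi_threshold = 0.025)
  hs <- detect_hotspots(mk_windows(c(0.01, 0.03, 0.04, 0.01)), cfg)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$window_first, 2L)
  expect_equal(hs$window_last, 3L)
  expect_equal(hs$max_pi, 0.04)

  expect_equal(nrow(detect_hotspots(mk_windows(rep(0.02, 6)), cfg)), 0L)
  # threshold is strict: a window exactly at 0.025 does not qualify
  expect_equal(nrow(detect_hotspots(mk_windows(c(0.025, 0.025)), cfg)), 0L)

  set.seed(77)
  for (i in 1:25) {
    pi <- round(runif(30, 0, 0.05), 3)
    hs <- detect_hotspots(mk_windows(pi), cfg)
    sup <- which(pi > cfg$pi_threshold)
    # union of member windows reproduces the supra-threshold set exactly
    members <- unlist(lapply(seq_len(nrow(hs)), function(k)
      hs$window_first[k]:hs$window_last[k]))
    expect_equal(sort(members), sup)
    if (nrow(hs) > 1) {
      expect_true(all(diff(hs$start) > 0))
      expect_true(all(hs$start[-1] > hs$end[-nrow(hs)]))
    }
  }
})

test_that("hotspots are named from flanking reference annotations", {
  set.seed(3)
  core <- rand_seq(3000)
  rows <- c(core, core)
  # make columns 1200..1400 divergent in row 2
  chars <- strsplit(rows[2], "")[[1]]
  idx <- 1200:1400
  chars[idx] <- vapply(chars[idx], function(b) sample(setdiff(BASES, b), 1), "")
  rows[2] <- paste(chars, collapse = "")
  blk <- alignment_block(rows)
  ann <- data.frame(feature_name = c("trnH", "psbA"),
                    start = c(1000, 1500), end = c(1100, 1600), strand = "+")
  w <- sliding_window_scan(blk, scan_config(), reference = 1)
  hs <- detect_hotspots(w, scan_config(), annotations = ann,
                        block = blk, reference = 1)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$name, "trnH-psbA")
})

test_that("partition averages report both zero-window conventions", {
  w <- data.frame(window_index = 1:8,
                  start = 1, end = 600, midpoint = 300,
                  pi = c(0.01, 0.02, 0, 0, 0, 0.003, 0.012, 0.008),
                  valid_sites = 600,
                  partition = c("LSC", "LSC", "IRa", "IRa", "IRb", "IRb",
                                "SSC", "SSC"))
  out <- partition_average_pi(w)
  expect_equal(out$mean_pi_all[out$region == "IRa"], 0)
  expect_true(is.na(out$mean_pi_nonzero[out$region == "IRa"]))
  expect_equal(out$mean_pi_nonzero[out$region == "IRb"], 0.003)
  expect_equal(out$headline[out$region == "IRb"], 0.003)   # nonzero convention
  expect_equal(out$headline[out$region == "LSC"], 0.015)   # all-window convention
  expect_equal(out$headline[out$region == "overall"], mean(w$pi))
  expect_error(partition_average_pi(w[, setdiff(names(w), "partition")]),
               "partition")
})

test_that("mean pairwise distance equals pi and matches ape on clean blocks", {
  b0 <- alignment_block(rep(rand_seq(80), 3))
  expect_equal(mean_pairwise_distance(b0)$mean, 0)

  set.seed(202)
  for (i in 1:20) {
    rows <- rand_block(sample(3:5, 1), sample(50:300, 1), p_gap = 0.05)
    blk <- alignment_block(rows)
    md <- mean_pairwise_distance(blk)
    expect_equal(md$mean, nucleotide_diversity(blk), tolerance = 1e-12)
    expect_true(isSymmetric(md$d))
    expect_equal(diag(md$d), setNames(rep(0, length(rows)), blk$haplotype_ids))
  }

  skip_if_not_installed("ape")
  rows <- rand_block(4, 400)
  blk <- alignment_block(rows)
  bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(rows), ""), identity)))
  d_ape <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  md <- mean_pairwise_distance(blk)
  expect_equal(unname(md$d), unname(d_ape), tolerance = 1e-12)
})
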