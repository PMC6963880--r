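# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's own code paths.

BASES <- c("A", "C", "G", "T")

revc <- function(x) {
  chartr("ACGTN-", "TGCAN-", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# random gapped block: N rows x L columns with given gap/N probabilities
rand_block <- function(n_rows, n_cols, p_gap = 0, p_n = 0) {
  rows <- vapply(seq_len(n_rows), function(i) {
    chars <- sample(BASES, n_cols, replace = TRUE)
    if (p_gap > 0) chars[runif(n_cols) < p_gap] <- "-"
    if (p_n > 0) chars[runif(n_cols) < p_n] <- "N"
    paste(chars, collapse = "")
  }, character(1))
  # guarantee no all-gap column so column count is preserved
  m <- do.call(rbind, strsplit(rows, ""))
  allgap <- colSums(m != "-") == 0
  if (any(allgap)) m[1, allgap] <- sample(BASES, sum(allgap), replace = TRUE)
  apply(m, 1, paste, collapse = "")
}

# brute-force pi: explicit loop over every pair and every column
brute_pi <- function(rows, gap_policy = "pairwise_deletion") {
  m <- do.call(rbind, strsplit(rows, ""))
  n <- nrow(m)
  keep_all <- apply(m, 2, function(col) all(col %in% BASES))
  dists <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    mm <- 0L; valid <- 0L
    for (col in seq_len(ncol(m))) {
      ok <- if (gap_policy == "complete_deletion") keep_all[col] else
        m[i, col] %in% BASES && m[j, col] %in% BASES
      if (ok) {
        valid <- valid + 1L
        if (m[i, col] != m[j, col]) mm <- mm + 1L
      }
    }
    dists <- c(dists, if (valid > 0) mm / valid else NA_real_)
  }
  if (all(is.na(dists))) NA_real_ else mean(dists, na.rm = TRUE)
}

# exhaustive enumeration of global alignments under affine run scoring:
# a gap run of length L scores gap_open + L * gap_extend
enum_align_score <- function(a, b, match = 1, mismatch = -2,
                             gap_open = -5, gap_extend = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(A) && j <= length(B)) {
      rec(i + 1, j + 1, score + if (A[i] == B[j]) match else mismatch, "d")
    }
    if (i <= length(A)) {
      rec(i + 1, j, score + gap_extend + if (state == "u") 0 else gap_open, "u")
    }
    if (j <= length(B)) {
      rec(i, j + 1, score + gap_extend + if (state == "l") 0 else gap_open, "l")
    }
  }
  rec(1, 1, 0, "d")
  best
}

# brute-force tandem repeat check: does s contain >= `copies` adjacent copies
# of any unit (1..max_unit) with total span >= min_span, exact matches only?
has_tandem_repeat <- function(s, max_unit = 30, min_copies = 2, min_span = 8) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  for (k in seq_len(min(max_unit, n %/% 2))) {
    for (st in seq_len(n - 2 * k + 1)) {
      cp <- 1
      while (st + (cp + 1) * k - 1 <= n &&
             all(chars[(st + cp * k):(st + (cp + 1) * k - 1)] ==
                 chars[st:(st + k - 1)])) {
        cp <- cp + 1
      }
      if (cp >= min_copies && cp * k >= min_span) return(TRUE)
    }
  }
  FALSE
}

# spec used by recovery tests: two hypervariable blocks (rate 0.04) on a
# conserved background (rate 0.003), planted InDels and one TR expansion
recovery_spec <- function(seed) {
  simulation_spec(
    seed = seed, n_haplotypes = 4,
    block_plan = data.frame(
      label = c("LSC-like", "LSC-like", "LSC-like", "LSC-like", "LSC-like"),
      length = c(8000, 1500, 6000, 1500, 7000),
      rate = c(0.003, 0.04, 0.003, 0.04, 0.003)),
    indel_plan = data.frame(block = c(2, 2, 4, 4),
                            length = c(12, 30, 50, 7),
                            subset = c("2", "2", "3,4", "1"),
                            type = "del"),
    tr_plan = data.frame(block = 4, unit_length = 20, copies = 2, subset = "1"),
    species_map = c("schinifolium", "piperitum", "simulans", "zsp"))
}
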