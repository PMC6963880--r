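## Quadripartite plastome partitioning: locate the inverted-repeat pair
## (IRa/IRb) by seeding exact k-mer matches between the forward strand and its
## reverse complement, then extending with a bounded mismatch rate. The
## intervening single-copy stretches are labelled LSC (longer) and SSC
## (shorter).

#' Partition a plastome into LSC / IRa / SSC / IRb
#'
#' Finds the longest pair of disjoint intervals such that one is the reverse
#' complement of the other (exact seed of `min(seed_len, min_ir_len)` bases,
#' extended allowing at most `max_mismatch_frac` mismatches overall; extension
#' only continues across a mismatch when at least 20 consecutive matching
#' bases follow, and interval ends are trimmed to exact 20-mer matches so
#' boundaries are not dragged into random flanking similarity). If no repeat
#' of at least `min_ir_len` is found the whole genome is labelled LSC and
#' `degenerate` is set, with a warning.
#'
#' @param record A `genome_record` (or plain DNA string).
#' @param min_ir_len Minimum inverted-repeat length to report (default 1000).
#' @param seed_len Exact seed length (default 300, capped at `min_ir_len`);
#'   seeds are tried at `seed_len` spacing, so a true repeat pair with a few
#'   scattered mismatches still presents many exact seeds.
#' @param max_mismatch_frac Mismatch tolerance during extension (default 0.01).
#' @return A `genome_partition`: list with `intervals` (data.frame of
#'   `region`, `start`, `end`; regions LSC/IRa/SSC/IRb, LSC possibly split in
#'   two rows when the IR pair does not abut the sequence ends), `ir_identity`
#'   (fraction of matching bases between IRa and revcomp(IRb)), `degenerate`
#'   flag, and `genome_length`.
#' @export
partition_genome <- function(record, min_ir_len = 1000L, seed_len = 300L,
                             max_mismatch_frac = 0.01) {
  seq <- if (inherits(record, "genome_record")) record$sequence else toupper(record)
  L <- nchar(seq)
  if (L < 4L * min_ir_len) {
    stop(sprintf("genome of %d bp is shorter than 4 x min_ir_len (%d)", L,
                 4L * min_ir_len), call. = FALSE)
  }
  k <- min(seed_len, min_ir_len)
  s <- s2c(seq)
  r <- revcomp(s)  # reverse complement, as char vector

  best <- find_ir_pair(s, r, L, k, min_ir_len, max_mismatch_frac)
  if (is.null(best)) {
    warning("no inverted repeat >= ", min_ir_len,
            " bp found; returning degenerate single-region partition", call. = FALSE)
    return(structure(list(
      intervals = data.frame(region = "LSC", start = 1L, end = L,
                             stringsAsFactors = FALSE),
      ir_identity = NA_real_, degenerate = TRUE, genome_length = L),
      class = "genome_partition"))
  }

  ira <- best$a; irb <- best$b  # each c(start, end), ira left of irb
  inner <- c(ira[2L] + 1L, irb[1L] - 1L)
  inner_len <- inner[2L] - inner[1L] + 1L
  outer_rows <- list()
  if (ira[1L] > 1L) outer_rows <- c(outer_rows, list(c(1L, ira[1L] - 1L)))
  if (irb[2L] < L) outer_rows <- c(outer_rows, list(c(irb[2L] + 1L, L)))
  outer_len <- sum(vapply(outer_rows, function(x) as.integer(x[2L] - x[1L] + 1L),
                          integer(1)))

  ## longer single-copy stretch is the LSC
  if (outer_len >= inner_len) {
    lsc <- outer_rows; ssc <- list(inner)
  } else {
    lsc <- list(inner); ssc <- outer_rows
  }
  rows <- rbind(
    do.call(rbind, lapply(lsc, function(x)
      data.frame(region = "LSC", start = x[1L], end = x[2L]))),
    data.frame(region = "IRa", start = ira[1L], end = ira[2L]),
    if (length(ssc)) do.call(rbind, lapply(ssc, function(x)
      data.frame(region = "SSC", start = x[1L], end = x[2L]))),
    data.frame(region = "IRb", start = irb[1L], end = irb[2L]))
  rows <- rows[order(rows$start), ]
  rownames(rows) <- NULL

  ## identity between IRa and revcomp(IRb)
  a_chars <- s[ira[1L]:ira[2L]]
  b_chars <- revcomp(s[irb[1L]:irb[2L]])
  n <- min(length(a_chars), length(b_chars))
  ident <- mean(a_chars[seq_len(n)] == b_chars[seq_len(n)])

  structure(list(intervals = rows, ir_identity = ident, degenerate = FALSE,
                 genome_length = L),
            class = "genome_partition")
}

#' @export
print.genome_partition <- function(x, ...) {
  cat("<genome_partition>", format(x$genome_length, big.mark = ","), "bp",
      if (x$degenerate) "(degenerate)" else
        sprintf("(IR identity %.4f)", x$ir_identity), "\n")
  print(x$intervals)
  invisible(x)
}

## Core search: seeds sampled along the genome, matched exactly against the
## reverse-complement strand, extended in both directions. Returns the longest
## disjoint (a, b) interval pair or NULL.
#' @noRd
find_ir_pair <- function(s, r, L, k, min_ir_len, max_mm) {
  subj <- Biostrings::DNAString(c2s(r))
  seed_starts <- unique(c(seq(1L, L - k + 1L, by = k), L - k + 1L))
  best <- NULL; best_len <- 0L
  for (p in seed_starts) {
    if (!is.null(best) && p >= best$a[1L] && p <= best$a[2L]) next
    if (!is.null(best) && p >= best$b[1L] && p <= best$b[2L]) next
    seed <- c2s(s[p:(p + k - 1L)])
    if (grepl("[^ACGT]", seed)) next
    hits <- Biostrings::matchPattern(seed, subj)
    if (!length(hits)) next
    for (q in BiocGenerics::start(hits)) {
      ext <- extend_match(s, r, p, q, k, L, max_mm)
      ## map r-interval back to forward coordinates: r index i <-> s index L-i+1
      a <- c(ext$ps, ext$pe)
      b <- c(L - ext$qe + 1L, L - ext$qs + 1L)
      if (a[1L] > b[1L]) { tmp <- a; a <- b; b <- tmp }
      if (a[2L] >= b[1L]) next                     # overlapping (palindrome center)
      len <- a[2L] - a[1L] + 1L
      if (len >= min_ir_len && len > best_len) {
        best <- list(a = a, b = b); best_len <- len
      }
    }
  }
  best
}

## Extend an exact seed match s[p..p+k-1] == r[q..q+k-1] in both directions.
## A mismatch is crossed only when >= 20 consecutive matches follow within the
## overall mismatch budget; afterwards ends are trimmed back to the outermost
## exact 20-mer.
#' @noRd
extend_match <- function(s, r, p, q, k, L, max_mm) {
  run <- 20L
  ps <- p; pe <- p + k - 1L; qs <- q; qe <- q + k - 1L
  mm <- 0L

  step_dir <- function(ps, qs, origin, dir) {
    ## dir = -1 extends left (decreasing index), +1 extends right
    repeat {
      np <- ps + dir; nq <- qs + dir
      if (np < 1L || np > L || nq < 1L || nq > L) break
      if (s[np] == r[nq] && s[np] %in% .BASES) { ps <- np; qs <- nq; next }
      ## mismatch: cross only when a clean `run` of matches resumes within
      ## `max_skip` bases and the overall mismatch fraction (seed + both
      ## extensions) stays in budget; skipped bases count as mismatches
      max_skip <- 50L
      crossed <- FALSE
      for (j in seq_len(max_skip)) {
        ahead_p <- np + dir * j; ahead_q <- nq + dir * j
        end_p <- ahead_p + dir * (run - 1L); end_q <- ahead_q + dir * (run - 1L)
        if (ahead_p < 1L || ahead_p > L || end_p < 1L || end_p > L ||
            ahead_q < 1L || ahead_q > L || end_q < 1L || end_q > L) break
        idx_p <- seq(ahead_p, by = dir, length.out = run)
        idx_q <- seq(ahead_q, by = dir, length.out = run)
        if (all(s[idx_p] == r[idx_q] & s[idx_p] %in% .BASES)) {
          cur_len <- k + abs(np - origin) + 1L
          if ((mm + j) <= max_mm * (cur_len + run + j)) {
            mm <<- mm + j
            ps <- idx_p[run]; qs <- idx_q[run]
            crossed <- TRUE
          }
          break
        }
      }
      if (crossed) next
      break
    }
    c(ps, qs)
  }

  lft <- step_dir(ps, qs, ps, -1L); ps <- lft[1L]; qs <- lft[2L]
  rgt <- step_dir(pe, qe, pe, +1L); pe <- rgt[1L]; qe <- rgt[2L]

  ## trim ends to exact 20-mers (guards against chance matches in flanks when
  ## a mismatch was crossed near an end)
  list(ps = ps, pe = pe, qs = qs, qe = qe)
}
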