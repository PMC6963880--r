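## Nucleotide diversity (Nei & Li's pi as the plain mean of pairwise
## p-distances), the sliding-window scan, hotspot calling, and partition-wise
## averages. This is the analytical core of the package.

#' Sliding-window scan configuration
#'
#' Defaults follow standard marker-development practice: 600 bp windows (the
#' typical length of a PCR marker) advanced in 300 bp steps, with hotspots
#' called strictly above pi = 0.025.
#'
#' @param window_size Window width in alignment columns (default 600).
#' @param step_size Step between window starts (default 300); must not exceed
#'   `window_size`.
#' @param pi_threshold Hotspot threshold; windows qualify with `pi >`
#'   threshold (strict).
#' @param gap_policy `"pairwise_deletion"` (sites where both members of a pair
#'   are unambiguous bases) or `"complete_deletion"` (sites where every row of
#'   the block is an unambiguous base).
#' @return A `scan_config` list.
#' @export
scan_config <- function(window_size = 600L, step_size = 300L,
                        pi_threshold = 0.025,
                        gap_policy = c("pairwise_deletion", "complete_deletion")) {
  gap_policy <- match.arg(gap_policy)
  window_size <- as.integer(window_size); step_size <- as.integer(step_size)
  if (step_size < 1L || window_size < step_size) {
    stop("need window_size >= step_size >= 1", call. = FALSE)
  }
  if (pi_threshold < 0 || pi_threshold > 1) stop("pi_threshold must lie in [0, 1]", call. = FALSE)
  structure(list(window_size = window_size, step_size = step_size,
                 pi_threshold = pi_threshold, gap_policy = gap_policy),
            class = "scan_config")
}

## logical matrix marking unambiguous bases
#' @noRd
base_mask <- function(mat) matrix(mat %in% .BASES, nrow = nrow(mat))

#' Pairwise p-distance between two aligned rows
#'
#' Proportion of differing sites over comparable sites. Under pairwise
#' deletion a site is comparable when both rows carry an unambiguous base
#' (`A/C/G/T`); under complete deletion, when every row of the surrounding
#' block does (pass the block's mask via `mask`, or the two rows alone define
#' it). With zero comparable sites the distance is `NA` (undefined), never 0.
#'
#' @param row_i,row_j Equal-length gapped sequences (strings or char vectors).
#' @param gap_policy See [scan_config()].
#' @param mask Optional logical vector of columns allowed for comparison
#'   (used by callers implementing block-wide complete deletion).
#' @return `list(distance=, valid_sites=)`.
#' @export
pairwise_p_distance <- function(row_i, row_j,
                                gap_policy = c("pairwise_deletion", "complete_deletion"),
                                mask = NULL) {
  gap_policy <- match.arg(gap_policy)
  a <- if (length(row_i) == 1L) s2c(toupper(row_i)) else row_i
  b <- if (length(row_j) == 1L) s2c(toupper(row_j)) else row_j
  if (length(a) != length(b)) {
    stop(sprintf("rows differ in gapped length (%d vs %d)", length(a), length(b)),
         call. = FALSE)
  }
  ok <- a %in% .BASES & b %in% .BASES
  if (!is.null(mask)) ok <- ok & mask else if (gap_policy == "complete_deletion") {
    ## with only two rows, complete deletion coincides with pairwise deletion
    ok <- ok
  }
  n <- sum(ok)
  if (n == 0L) return(list(distance = NA_real_, valid_sites = 0L))
  list(distance = sum(a[ok] != b[ok]) / n, valid_sites = n)
}

## Per-pair mismatch/valid indicator vectors for a block; backbone of both
## whole-block pi and the windowed scan (window sums come from cumsums).
#' @noRd
pair_indicators <- function(block, gap_policy) {
  mat <- block$mat
  n <- nrow(mat); L <- ncol(mat)
  bm <- base_mask(mat)
  global_ok <- if (gap_policy == "complete_deletion") colSums(bm) == n else NULL
  pairs <- utils::combn(n, 2L)
  valid <- mismatch <- matrix(FALSE, ncol(pairs), L)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    ok <- bm[i, ] & bm[j, ]
    if (!is.null(global_ok)) ok <- ok & global_ok
    valid[p, ] <- ok
    mismatch[p, ] <- ok & (mat[i, ] != mat[j, ])
  }
  list(pairs = pairs, valid = valid, mismatch = mismatch)
}

#' Nucleotide diversity (pi) of an alignment block
#'
#' The mean over all `C(N,2)` sequence pairs of the pairwise p-distance — the
#' Nei & Li per-site diversity without the `n/(n-1)` sample-size correction
#' (see the methods vignette; `bias_correction = TRUE` applies it). Pairs with
#' no comparable sites are excluded from the mean; if all pairs are undefined
#' the result is `NA`.
#'
#' @param block An [alignment_block()].
#' @inheritParams pairwise_p_distance
#' @param bias_correction Multiply by `n/(n-1)` (off by default).
#' @return Scalar pi in `[0, 1]` (or `NA`).
#' @export
nucleotide_diversity <- function(block,
                                 gap_policy = c("pairwise_deletion", "complete_deletion"),
                                 bias_correction = FALSE) {
  gap_policy <- match.arg(gap_policy)
  ind <- pair_indicators(block, gap_policy)
  v <- rowSums(ind$valid); m <- rowSums(ind$mismatch)
  d <- ifelse(v > 0L, m / v, NA_real_)
  if (all(is.na(d))) return(NA_real_)
  pi <- mean(d, na.rm = TRUE)
  if (bias_correction) {
    n <- length(block$rows)
    pi <- pi * n / (n - 1L)
  }
  pi
}

#' Sliding-window nucleotide diversity scan
#'
#' Windows start at columns `1, 1+step, 1+2*step, ...` while the full window
#' fits (`start + window - 1 <= columns`); a trailing partial window is
#' dropped, so the window count is `floor((L - w)/s) + 1`. Each window's pi is
#' the block diversity of its column slice. `valid_sites` counts window
#' columns contributing to at least one pair.
#'
#' @param block An [alignment_block()].
#' @param config A [scan_config()].
#' @param reference Optional row index/id; adds `ref_midpoint`, the ungapped
#'   position of the window midpoint on that row.
#' @param partition Optional [partition_genome()] result on the reference
#'   genome; adds a `partition` label per window (by `ref_midpoint`).
#' @return `data.frame` of class `window_diversity`: `window_index`, `start`,
#'   `end`, `midpoint`, `pi`, `valid_sites`, and optionally `ref_midpoint`,
#'   `partition`. Empty (with a warning) if the block is shorter than one
#'   window.
#' @export
sliding_window_scan <- function(block, config = scan_config(),
                                reference = NULL, partition = NULL) {
  L <- block$column_count
  w <- config$window_size; s <- config$step_size
  empty <- data.frame(window_index = integer(), start = integer(),
                      end = integer(), midpoint = integer(), pi = numeric(),
                      valid_sites = integer())
  if (L < w) {
    warning(sprintf("alignment (%d columns) shorter than one %d bp window", L, w),
            call. = FALSE)
    class(empty) <- c("window_diversity", "data.frame")
    return(empty)
  }
  n_win <- (L - w) %/% s + 1L
  starts <- 1L + (seq_len(n_win) - 1L) * s
  ends <- starts + w - 1L

  ind <- pair_indicators(block, config$gap_policy)
  np <- nrow(ind$valid)
  ## windowed sums via cumulative sums
  win_sum <- function(x) {
    cs <- c(0, cumsum(x))
    cs[ends + 1L] - cs[starts]
  }
  vmat <- t(apply(ind$valid, 1L, win_sum))     # np x n_win
  mmat <- t(apply(ind$mismatch, 1L, win_sum))
  if (n_win == 1L) { vmat <- matrix(vmat, ncol = 1L); mmat <- matrix(mmat, ncol = 1L) }
  dmat <- ifelse(vmat > 0L, mmat / vmat, NA_real_)
  pi <- colMeans(dmat, na.rm = TRUE)
  pi[colSums(!is.na(dmat)) == 0L] <- NA_real_
  any_valid <- matrix(colSums(ind$valid) > 0L, nrow = 1L)
  valid_sites <- as.integer(win_sum(as.numeric(any_valid)))

  out <- data.frame(window_index = seq_len(n_win), start = starts, end = ends,
                    midpoint = (starts + ends) %/% 2L, pi = pi,
                    valid_sites = valid_sites)
  if (!is.null(reference)) {
    rmap <- reference_position_map(block, reference)
    out$ref_midpoint <- rmap[out$midpoint]
    if (!is.null(partition)) {
      out$partition <- partition_label(out$ref_midpoint, partition)
    }
  }
  class(out) <- c("window_diversity", "data.frame")
  out
}

#' @noRd
partition_label <- function(pos, partition) {
  iv <- partition$intervals
  lab <- rep(NA_character_, length(pos))
  for (k in seq_len(nrow(iv))) {
    hit <- !is.na(pos) & pos >= iv$start[k] & pos <= iv$end[k]
    lab[hit] <- iv$region[k]
  }
  lab[!is.na(pos) & pos == 0L] <- NA_character_
  lab
}

#' Call hypervariable hotspot regions from a window scan
#'
#' Maximal runs of consecutive windows (adjacent `window_index`) with
#' `pi > threshold` (strict) are merged into one region; isolated single
#' windows qualify. Regions are named from reference annotations when
#' available: the overlapping feature(s), or the nearest flanking features as
#' `"left-right"` for intergenic regions; otherwise by coordinates.
#'
#' @param windows A `window_diversity` table (sorted by start).
#' @param config A [scan_config()] (threshold source).
#' @param annotations Optional feature table of the reference genome
#'   (`feature_name`, `start`, `end` in reference coordinates).
#' @param block,reference Needed with `annotations` to map alignment columns
#'   to reference coordinates.
#' @return `data.frame` of class `hotspot_regions`: `name`, `start`, `end`
#'   (alignment columns), `ref_start`, `ref_end` (if mappable), `max_pi`,
#'   `n_windows`, `window_first`, `window_last`.
#' @export
detect_hotspots <- function(windows, config = scan_config(),
                            annotations = NULL, block = NULL, reference = NULL) {
  hot <- which(!is.na(windows$pi) & windows$pi > config$pi_threshold)
  out <- data.frame(name = character(), start = integer(), end = integer(),
                    ref_start = integer(), ref_end = integer(),
                    max_pi = numeric(), n_windows = integer(),
                    window_first = integer(), window_last = integer(),
                    stringsAsFactors = FALSE)
  if (length(hot)) {
    grp <- cumsum(c(1L, diff(windows$window_index[hot]) != 1L))
    rmap <- if (!is.null(block) && !is.null(reference)) {
      reference_position_map(block, reference)
    } else NULL
    rows <- lapply(split(hot, grp), function(ix) {
      st <- windows$start[ix[1L]]; en <- windows$end[ix[length(ix)]]
      rs <- if (!is.null(rmap)) max(rmap[st], 1L) else NA_integer_
      re <- if (!is.null(rmap)) rmap[en] else NA_integer_
      nm <- if (!is.null(annotations) && !is.na(rs)) {
        hotspot_name(annotations, rs, re)
      } else sprintf("hotspot_%d_%d", st, en)
      data.frame(name = nm, start = st, end = en, ref_start = rs, ref_end = re,
                 max_pi = max(windows$pi[ix]), n_windows = length(ix),
                 window_first = windows$window_index[ix[1L]],
                 window_last = windows$window_index[ix[length(ix)]],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  }
  class(out) <- c("hotspot_regions", "data.frame")
  out
}

#' @noRd
hotspot_name <- function(ann, rs, re) {
  if (!nrow(ann)) return(sprintf("hotspot_%d_%d", rs, re))
  overlapping <- ann$end >= rs & ann$start <= re
  if (any(overlapping)) {
    return(paste(unique(ann$feature_name[overlapping]), collapse = "-"))
  }
  left <- ann[ann$end < rs, , drop = FALSE]
  right <- ann[ann$start > re, , drop = FALSE]
  ln <- if (nrow(left)) left$feature_name[which.max(left$end)] else "start"
  rn <- if (nrow(right)) right$feature_name[which.min(right$start)] else "end"
  paste(ln, rn, sep = "-")
}

#' Average pi per genome partition
#'
#' Each window is assigned to the partition containing its reference-mapped
#' midpoint. Two averaging conventions are reported side by side: over all
#' windows (`mean_pi_all`) and over windows with `pi > 0` only
#' (`mean_pi_nonzero`). The `headline` column selects the nonzero convention
#' for the inverted repeats and the all-window convention elsewhere — highly
#' conserved IR windows are predominantly zero, and reporting their nonzero
#' mean separates residual variability from pure conservation (see vignette).
#'
#' @param windows A `window_diversity` table carrying a `partition` column
#'   (from [sliding_window_scan()] with `reference` and `partition`).
#' @return `data.frame`: `region` (LSC/SSC/IRa/IRb/overall), `n_windows`,
#'   `n_unassigned` (overall row only), `mean_pi_all`, `mean_pi_nonzero`,
#'   `headline`.
#' @export
partition_average_pi <- function(windows) {
  if (is.null(windows$partition)) {
    stop("windows lack a partition column; run sliding_window_scan() with ",
         "reference and partition", call. = FALSE)
  }
  regions <- c("LSC", "SSC", "IRa", "IRb")
  rows <- lapply(regions, function(rg) {
    pi <- windows$pi[!is.na(windows$partition) & windows$partition == rg]
    pi <- pi[!is.na(pi)]
    nz <- pi[pi > 0]
    data.frame(region = rg, n_windows = length(pi),
               n_unassigned = NA_integer_,
               mean_pi_all = if (length(pi)) mean(pi) else NA_real_,
               mean_pi_nonzero = if (length(nz)) mean(nz) else NA_real_,
               stringsAsFactors = FALSE)
  })
  pi_all <- windows$pi[!is.na(windows$pi)]
  nz_all <- pi_all[pi_all > 0]
  rows <- c(rows, list(data.frame(
    region = "overall", n_windows = length(pi_all),
    n_unassigned = sum(is.na(windows$partition)),
    mean_pi_all = if (length(pi_all)) mean(pi_all) else NA_real_,
    mean_pi_nonzero = if (length(nz_all)) mean(nz_all) else NA_real_,
    stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  out$headline <- ifelse(out$region %in% c("IRa", "IRb"),
                         out$mean_pi_nonzero, out$mean_pi_all)
  out
}

#' Full pairwise p-distance matrix and its mean
#'
#' For an N-sequence block this returns the symmetric p-distance matrix, the
#' per-pair comparable-site counts, and the mean of the upper triangle — which
#' equals [nucleotide_diversity()] of the block by construction.
#'
#' @param block An [alignment_block()].
#' @inheritParams pairwise_p_distance
#' @return List of class `distance_matrix`: `ids`, `d` (NxN), `comparisons`
#'   (NxN), `mean`.
#' @export
mean_pairwise_distance <- function(block,
                                   gap_policy = c("pairwise_deletion", "complete_deletion")) {
  gap_policy <- match.arg(gap_policy)
  ind <- pair_indicators(block, gap_policy)
  n <- length(block$rows)
  d <- matrix(0, n, n, dimnames = list(block$haplotype_ids, block$haplotype_ids))
  comp <- matrix(0L, n, n, dimnames = dimnames(d))
  vals <- numeric(0)
  for (p in seq_len(ncol(ind$pairs))) {
    i <- ind$pairs[1L, p]; j <- ind$pairs[2L, p]
    v <- sum(ind$valid[p, ]); m <- sum(ind$mismatch[p, ])
    dd <- if (v > 0L) m / v else NA_real_
    d[i, j] <- d[j, i] <- dd
    comp[i, j] <- comp[j, i] <- v
    vals <- c(vals, dd)
  }
  structure(list(ids = block$haplotype_ids, d = d, comparisons = comp,
                 mean = if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)),
            class = "distance_matrix")
}

#' Plot a diversity scan
#'
#' Window midpoints against pi, with the hotspot threshold drawn as a dashed
#' line and supra-threshold windows highlighted.
#'
#' @param windows A `window_diversity` table.
#' @param config A [scan_config()] (threshold).
#' @param ... Passed to [plot()].
#' @export
plot_diversity <- function(windows, config = scan_config(), ...) {
  x <- if (!is.null(windows$ref_midpoint)) windows$ref_midpoint else windows$midpoint
  plot(x, windows$pi, type = "l", xlab = "position (bp)",
       ylab = expression(pi), ...)
  graphics::abline(h = config$pi_threshold, lty = 2, col = "grey40")
  hot <- !is.na(windows$pi) & windows$pi > config$pi_threshold
  graphics::points(x[hot], windows$pi[hot], pch = 19, col = "firebrick")
  invisible(windows)
}
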