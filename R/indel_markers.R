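## InDel event extraction, tandem-repeat detection, primer metrics and marker
## definition. An InDel event is a maximal run of alignment columns sharing an
## identical gap/base presence pattern, with gaps in at least one but not all
## rows; nested or adjacent length polymorphisms with different haplotype
## patterns therefore come out as separate events.

#' Call InDel events from a multiple alignment
#'
#' Scans columns left to right; every maximal run of columns with the same
#' gap-presence pattern (which haplotypes are gapped) and gaps in >= 1 but not
#' all haplotypes yields one event. Substitutions never affect gap patterns,
#' so event coordinates and lengths are robust to point mutation noise.
#'
#' @param block An [alignment_block()].
#' @return `data.frame` of class `indel_events`: `event`, `aln_start`,
#'   `aln_end`, `length`, `inserted_seq` (the non-gap allele, from the first
#'   ungapped row), `carriers` (comma-joined ids carrying bases),
#'   `gapped` (ids carrying the gap). Attribute `haplotype_ids` keeps row
#'   order.
#' @export
call_indel_events <- function(block) {
  mat <- block$mat
  n <- nrow(mat)
  gap <- mat == "-"
  ## per-column pattern key; all-gap columns cannot occur (stripped)
  key <- as.integer(colSums(gap * 2^(seq_len(n) - 1L)))
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values > 0L
  out <- data.frame(event = integer(), aln_start = integer(), aln_end = integer(),
                    length = integer(), inserted_seq = character(),
                    carriers = character(), gapped = character(),
                    stringsAsFactors = FALSE)
  if (any(keep)) {
    starts <- starts[keep]; ends <- ends[keep]; vals <- r$values[keep]
    ids <- block$haplotype_ids
    rows <- lapply(seq_along(starts), function(k) {
      s <- starts[k]; e <- ends[k]
      gapped_rows <- which(bitwAnd(vals[k], 2^(seq_len(n) - 1L)) > 0L)
      carrier <- setdiff(seq_len(n), gapped_rows)[1L]
      data.frame(event = k, aln_start = s, aln_end = e, length = e - s + 1L,
                 inserted_seq = paste(mat[carrier, s:e], collapse = ""),
                 carriers = paste(ids[setdiff(seq_len(n), gapped_rows)], collapse = ","),
                 gapped = paste(ids[gapped_rows], collapse = ","),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$event <- seq_len(nrow(out))
  }
  attr(out, "haplotype_ids") <- block$haplotype_ids
  class(out) <- c("indel_events", "data.frame")
  out
}

#' Detect tandem repeats in alignment haplotypes
#'
#' Each haplotype's ungapped sequence is scanned for unit lengths
#' `k = 1..max_unit` with the rolling comparison `s[i] == s[i-k]`; runs
#' spanning at least `min_copies` units qualify. One mismatch per unit copy is
#' tolerated (single-position breaks between matching runs). Overlapping calls
#' within a haplotype are resolved preferring the longer total span, then the
#' smaller unit. Repeats adjacent to or overlapping an InDel event whose
#' non-gap allele equals one unit (<= 1 mismatch) are flagged
#' `slippage_linked` — the copy-number difference explains the InDel.
#'
#' @param block An [alignment_block()] (or a single DNA string).
#' @param max_unit Largest unit length considered (default 60).
#' @param min_copies Minimum copies (default 2).
#' @param min_span Minimum total repeat span in bp (default 8); filters
#'   trivial homopolymer/dinucleotide noise.
#' @param indels Optional [call_indel_events()] table used for slippage
#'   linking.
#' @return `data.frame` of class `tandem_repeats`: `haplotype`, `start`,
#'   `end` (ungapped positions), `aln_start`, `aln_end`, `unit_length`,
#'   `copies`, `unit_seq`, `mismatches`, `slippage_event` (event id or NA).
#' @export
detect_tandem_repeats <- function(block, max_unit = 60L, min_copies = 2L,
                                  min_span = 8L, indels = NULL) {
  single <- !inherits(block, "alignment_block")
  if (single) {
    block <- list(haplotype_ids = "seq",
                  rows = toupper(block),
                  mat = NULL)
  }
  out <- list()
  for (h in seq_along(block$rows)) {
    seq_chars <- s2c(gsub("-", "", block$rows[h], fixed = TRUE))
    cand <- tr_scan_one(seq_chars, max_unit, min_copies, min_span)
    if (nrow(cand)) {
      cand$haplotype <- block$haplotype_ids[h]
      if (!single && !is.null(block$mat)) {
        ungap <- which(block$mat[h, ] != "-")
        cand$aln_start <- ungap[cand$start]
        cand$aln_end <- ungap[cand$end]
      } else {
        cand$aln_start <- cand$start; cand$aln_end <- cand$end
      }
      out[[length(out) + 1L]] <- cand
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), end = integer(), unit_length = integer(),
               copies = integer(), unit_seq = character(), mismatches = integer(),
               haplotype = character(), aln_start = integer(), aln_end = integer(),
               stringsAsFactors = FALSE)
  res$slippage_event <- rep(NA_integer_, nrow(res))
  if (nrow(res) && !is.null(indels) && nrow(indels)) {
    for (r in seq_len(nrow(res))) {
      near <- which(indels$aln_start <= res$aln_end[r] + 1L &
                      indels$aln_end >= res$aln_start[r] - 1L)
      for (ev in near) {
        ins <- indels$inserted_seq[ev]
        if (nchar(ins) == res$unit_length[r] &&
            unit_matches_rotation(ins, res$unit_seq[r])) {
          res$slippage_event[r] <- indels$event[ev]
          break
        }
      }
    }
  }
  rownames(res) <- NULL
  res <- res[, c("haplotype", "start", "end", "aln_start", "aln_end",
                 "unit_length", "copies", "unit_seq", "mismatches",
                 "slippage_event")]
  class(res) <- c("tandem_repeats", "data.frame")
  res
}

## TRUE when `ins` equals some rotation of `unit` with <= 1 mismatch (the
## reported unit of a tandem array is defined only up to rotation).
#' @noRd
unit_matches_rotation <- function(ins, unit) {
  u <- nchar(unit)
  if (nchar(ins) != u) return(FALSE)
  doubled <- s2c(paste0(unit, unit))
  ic <- s2c(ins)
  for (off in 0:(u - 1L)) {
    if (sum(ic != doubled[(off + 1L):(off + u)]) <= 1L) return(TRUE)
  }
  FALSE
}

## Rolling-comparison scan of one ungapped sequence. Long perfect match runs
## of s[i] == s[i-k] are rare, so they seed candidates which are then extended
## locally across isolated single mismatches (<= 1 per unit copy).
#' @noRd
tr_scan_one <- function(s, max_unit, min_copies, min_span) {
  n <- length(s)
  cand <- list()
  for (k in seq_len(min(max_unit, n %/% 2L))) {
    eq <- s[(k + 1L):n] == s[seq_len(n - k)]
    m <- length(eq)
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    seed_min <- max(min_span - k, k %/% 2L, 5L)
    ti <- which(r$values & r$lengths >= seed_min)
    for (x in ti) {
      lo <- starts[x]; hi <- ends[x]; mism <- 0L
      ## extend across isolated mismatches while the per-unit budget holds
      repeat {
        budget <- (hi - lo + 1L + k) %/% k
        if (hi + 2L <= m && !eq[hi + 1L] && eq[hi + 2L] && mism + 1L <= budget) {
          hi <- hi + 2L; mism <- mism + 1L
          while (hi < m && eq[hi + 1L]) hi <- hi + 1L
          next
        }
        if (lo - 2L >= 1L && !eq[lo - 1L] && eq[lo - 2L] && mism + 1L <= budget) {
          lo <- lo - 2L; mism <- mism + 1L
          while (lo > 1L && eq[lo - 1L]) lo <- lo - 1L
          next
        }
        break
      }
      span <- (hi - lo + 1L) + k
      copies <- span %/% k
      if (copies >= min_copies && copies * k >= min_span) {
        cand[[length(cand) + 1L]] <- data.frame(
          start = lo, end = lo + copies * k - 1L, unit_length = k,
          copies = copies, unit_seq = paste(s[lo:(lo + k - 1L)], collapse = ""),
          mismatches = mism, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(), end = integer(), unit_length = integer(),
                      copies = integer(), unit_seq = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  cand <- unique(do.call(rbind, cand))
  ## overlap resolution: longer span first, then smaller unit
  cand <- cand[order(-(cand$end - cand$start + 1L), cand$unit_length), ]
  kept_s <- integer(0); kept_e <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] <= kept_e & cand$end[i] >= kept_s)) {
      keep[i] <- TRUE
      kept_s <- c(kept_s, cand$start[i]); kept_e <- c(kept_e, cand$end[i])
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand[order(cand$start), , drop = FALSE]
}

## --- primers ---------------------------------------------------------------

## SantaLucia (unified) nearest-neighbor parameters: dH kcal/mol, dS cal/(mol K)
.NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
            GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)

#' Primer melting temperature and GC content
#'
#' Tm from the unified nearest-neighbor model (50 mM monovalent salt via the
#' 0.368 x ln[Na+] entropy correction, 0.25 uM primer, non-self-complementary
#' factor 4); primers shorter than 14 bases use the Wallace rule
#' `2(A+T) + 4(G+C)`. Both values are returned with the method used.
#'
#' @param seq Primer sequence, 10-40 bases, strictly `A/C/G/T`.
#' @param Na Monovalent cation concentration, mol/L (default 0.05).
#' @param conc Primer concentration, mol/L (default 2.5e-7).
#' @return `list(tm, gc, method)` — Tm in Celsius, GC in percent.
#' @export
primer_metrics <- function(seq, Na = 0.05, conc = 2.5e-7) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 10L || n > 40L) stop("primer length must be 10-40 bases", call. = FALSE)
  chars <- s2c(seq)
  if (any(!chars %in% .BASES)) {
    stop("primer contains ambiguous bases: ",
         paste(unique(chars[!chars %in% .BASES]), collapse = ", "), call. = FALSE)
  }
  gc <- 100 * sum(chars %in% c("G", "C")) / n
  if (n < 14L) {
    tm <- 2 * sum(chars %in% c("A", "T")) + 4 * sum(chars %in% c("G", "C"))
    return(list(tm = tm, gc = gc, method = "wallace"))
  }
  dinucs <- paste0(chars[-n], chars[-1L])
  dH <- sum(.NN_DH[dinucs]) + 0.2 +                      # initiation
    sum(c(0.1, 2.3)[1L + (chars[c(1L, n)] %in% c("A", "T"))])
  dS <- sum(.NN_DS[dinucs]) - 5.7 +
    sum(c(-2.8, 4.1)[1L + (chars[c(1L, n)] %in% c("A", "T"))])
  dS <- dS + 0.368 * (n - 1L) * log(Na)
  tm <- dH * 1000 / (dS + 1.987 * log(conc / 4)) - 273.15
  list(tm = tm, gc = gc, method = "nearest_neighbor")
}

#' Construct a primer pair
#'
#' @param name Pair name.
#' @param forward,reverse 5'->3' primer sequences (strict `A/C/G/T`, 15-35
#'   bases).
#' @param expected_range Optional `c(min_bp, max_bp)` product-size range.
#' @return A `primer_pair` with per-primer Tm and GC.
#' @export
primer_pair <- function(name, forward, reverse, expected_range = NULL) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  for (p in c(forward, reverse)) {
    if (nchar(p) < 15L || nchar(p) > 35L) {
      stop("primers must be 15-35 bases: ", p, call. = FALSE)
    }
  }
  structure(list(name = name, forward = forward, reverse = reverse,
                 metrics_f = primer_metrics(forward),
                 metrics_r = primer_metrics(reverse),
                 expected_range = expected_range),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s\n  F: %s (Tm %.1f C, GC %.0f%%)\n  R: %s (Tm %.1f C, GC %.0f%%)\n",
              x$name, x$forward, x$metrics_f$tm, x$metrics_f$gc,
              x$reverse, x$metrics_r$tm, x$metrics_r$gc))
  if (!is.null(x$expected_range)) {
    cat(sprintf("  expected product: %d-%d bp\n",
                x$expected_range[1L], x$expected_range[2L]))
  }
  invisible(x)
}

#' Read a primer table
#'
#' Tab-separated columns `name`, `forward`, `reverse`, and optionally
#' `min_product`, `max_product`.
#'
#' @param path TSV path.
#' @return Named list of [primer_pair()] objects.
#' @export
read_primers <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "forward", "reverse")
  if (!all(need %in% names(tab))) {
    stop("primer table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    rng <- if (all(c("min_product", "max_product") %in% names(tab)) &&
               !is.na(tab$min_product[i])) {
      c(tab$min_product[i], tab$max_product[i])
    } else NULL
    primer_pair(tab$name[i], tab$forward[i], tab$reverse[i], rng)
  })
  stats::setNames(out, tab$name)
}

#' Packaged default primer pairs
#'
#' The four ZanID marker pairs plus the universal trnH-psbA barcoding pair,
#' read from the packaged primer table (`inst/extdata/primers.tsv`).
#'
#' @return Named list of [primer_pair()] objects.
#' @export
default_primers <- function() {
  read_primers(system.file("extdata", "primers.tsv", package = "cpmarker",
                           mustWork = TRUE))
}

## --- marker definition -----------------------------------------------------

#' Define and evaluate a length-polymorphism marker
#'
#' Runs in-silico PCR ([predict_amplicons()]) of `primers` on every haplotype
#' of the block (its ungapped rows), collects the InDel and tandem-repeat
#' events falling inside the amplified span, and scores discriminability: the
#' marker is `diagnostic` when every pair of haplotypes from different
#' species differs in product size by at least `resolvable_delta` bp (gel
#' resolution model). Haplotypes the primers fail to amplify are listed in
#' `non_universal`.
#'
#' @param block An [alignment_block()].
#' @param primers A [primer_pair()].
#' @param name Marker name (defaults to the primer pair's).
#' @param species_map Named character vector mapping haplotype id to species
#'   label; defaults to each haplotype being its own species.
#' @param resolvable_delta Smallest product-size difference treated as
#'   resolvable (default 10 bp).
#' @param locus Optional locus label.
#' @param max_mismatch,anchor_len Primer-binding stringency
#'   (see [find_primer_sites()]).
#' @param events,trs Optional precomputed [call_indel_events()] /
#'   [detect_tandem_repeats()] tables for the block (computed when NULL).
#' @return A `marker_definition`: list with `name`, `locus`, `primer_pair`,
#'   `products` (named bp vector, NA where amplification failed),
#'   `product_range`, `indel_events`, `tandem_repeats`, `diagnostic`,
#'   `non_universal`, `species_map`.
#' @export
define_marker <- function(block, primers, name = primers$name,
                          species_map = NULL, resolvable_delta = 10L,
                          locus = NA_character_, max_mismatch = 2L,
                          anchor_len = 5L, events = NULL, trs = NULL) {
  ids <- block$haplotype_ids
  species_map <- species_map %||% stats::setNames(ids, ids)
  templates <- stats::setNames(gsub("-", "", block$rows, fixed = TRUE), ids)
  products <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  spans <- vector("list", length(ids)); names(spans) <- ids
  for (id in ids) {
    amp <- predict_amplicons(templates[[id]], primers,
                             max_mismatch = max_mismatch, anchor_len = anchor_len)
    if (nrow(amp)) {
      products[[id]] <- amp$length[1L]
      spans[[id]] <- c(amp$start[1L], amp$end[1L])
    }
  }
  non_universal <- names(products)[is.na(products)]

  ## events within the amplicon, in alignment coordinates: map the first
  ## amplified haplotype's span through its gap structure
  if (is.null(events)) events <- call_indel_events(block)
  if (is.null(trs)) trs <- detect_tandem_repeats(block, indels = events)
  amplified <- names(products)[!is.na(products)]
  if (length(amplified)) {
    h <- match(amplified[1L], ids)
    ungap <- which(block$mat[h, ] != "-")
    sp <- spans[[amplified[1L]]]
    a_start <- ungap[sp[1L]]; a_end <- ungap[sp[2L]]
    events <- events[events$aln_start <= a_end & events$aln_end >= a_start, , drop = FALSE]
    trs <- trs[trs$aln_start <= a_end & trs$aln_end >= a_start, , drop = FALSE]
  }

  diagnostic <- NA
  if (length(amplified) >= 2L) {
    combos <- utils::combn(amplified, 2L)
    between <- species_map[combos[1L, ]] != species_map[combos[2L, ]]
    if (any(between)) {
      diffs <- abs(products[combos[1L, between]] - products[combos[2L, between]])
      diagnostic <- all(diffs >= resolvable_delta)
    }
  }
  pr <- products[!is.na(products)]
  structure(list(name = name, locus = locus, primer_pair = primers,
                 products = products,
                 product_range = if (length(pr)) range(pr) else c(NA_integer_, NA_integer_),
                 indel_events = events, tandem_repeats = trs,
                 diagnostic = diagnostic, non_universal = non_universal,
                 resolvable_delta = resolvable_delta,
                 species_map = species_map),
            class = "marker_definition")
}

#' @export
print.marker_definition <- function(x, ...) {
  cat(sprintf("<marker_definition> %s (%s)\n", x$name,
              if (is.na(x$locus)) "unlabelled locus" else x$locus))
  cat("  products:", paste(sprintf("%s=%s", names(x$products),
                                   ifelse(is.na(x$products), "no product", x$products)),
                           collapse = ", "), "\n")
  cat(sprintf("  range %s-%s bp; %d InDel event(s), %d tandem repeat(s); diagnostic: %s\n",
              x$product_range[1L], x$product_range[2L],
              nrow(x$indel_events), nrow(x$tandem_repeats), x$diagnostic))
  if (length(x$non_universal)) {
    cat("  non-universal; no product in:", paste(x$non_universal, collapse = ", "), "\n")
  }
  invisible(x)
}
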