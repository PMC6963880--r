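## Truth-bearing synthetic data: seeded genome quartets with region-dependent
## substitution rates (conserved IR-like vs divergent single-copy blocks),
## planted InDels and slippage-style tandem-repeat insertions, plus a
## market-sample band-table simulator. Haplotypes descend independently from a
## common ancestor (star phylogeny); the generator emits both the true gapped
## alignment (from construction) and the raw ungapped sequences, together with
## a machine-readable truth record.

#' Build a simulation specification
#'
#' @param seed Integer seed; all randomness in [simulate_quartet()] derives
#'   from it (outputs are bit-reproducible for a fixed spec).
#' @param n_haplotypes Number of descendant haplotypes (default 4).
#' @param block_plan `data.frame` with columns `label` (one of `"LSC-like"`,
#'   `"IR-like"`, `"SSC-like"`), `length` (bp), `rate` (per-site substitution
#'   probability per lineage, in `[0, 0.2]`). When exactly two IR-like blocks
#'   of equal length are present, the second is the reverse complement of the
#'   first in the ancestor.
#' @param indel_plan Optional `data.frame`: `block` (index into `block_plan`),
#'   `length` (bp), `subset` (comma-joined haplotype indices carrying the
#'   variant), `type` (`"del"` — subset lacks the span — or `"ins"` — subset
#'   carries extra sequence), optional `at` (ancestral offset within the
#'   block; auto-placed when NA).
#' @param tr_plan Optional `data.frame`: `block`, `unit_length`, `copies`
#'   (total copies in the carrier subset; the ancestor has one), `subset`,
#'   optional `at`.
#' @param species_map Character vector of species labels per haplotype.
#' @param flank_protect,flank_gap Width and offset (bp) of
#'   substitution-protected windows flanking each planted event; models the
#'   conserved primer-binding flanks diagnostic markers are designed in.
#' @param min_separation Minimum bp between planted event footprints
#'   (default 80).
#' @return A validated `simulation_spec` list.
#' @export
simulation_spec <- function(seed, n_haplotypes = 4L, block_plan,
                            indel_plan = NULL, tr_plan = NULL,
                            species_map = NULL,
                            flank_protect = 40L, flank_gap = 20L,
                            min_separation = 80L) {
  stopifnot(is.data.frame(block_plan),
            all(c("label", "length", "rate") %in% names(block_plan)))
  if (any(!block_plan$label %in% c("LSC-like", "IR-like", "SSC-like"))) {
    stop("block labels must be LSC-like, IR-like or SSC-like", call. = FALSE)
  }
  if (any(block_plan$rate < 0 | block_plan$rate > 0.2)) {
    stop("substitution rates must lie in [0, 0.2]", call. = FALSE)
  }
  if (any(block_plan$length < 1L)) stop("block lengths must be >= 1", call. = FALSE)
  norm_events <- function(df, cols) {
    if (is.null(df) || !nrow(df)) return(NULL)
    if (!"at" %in% names(df)) df$at <- NA_integer_
    stopifnot(all(cols %in% names(df)))
    if (any(df$block < 1L | df$block > nrow(block_plan))) {
      stop("event refers to a block outside the plan", call. = FALSE)
    }
    df
  }
  indel_plan <- norm_events(indel_plan, c("block", "length", "subset", "type"))
  tr_plan <- norm_events(tr_plan, c("block", "unit_length", "copies", "subset"))
  if (!is.null(indel_plan) && any(indel_plan$length < 1L)) {
    stop("InDel lengths must be >= 1", call. = FALSE)
  }
  if (!is.null(tr_plan) && any(tr_plan$copies < 2L)) {
    stop("tandem repeats need copies >= 2", call. = FALSE)
  }
  species_map <- species_map %||% paste0("species", seq_len(n_haplotypes))
  if (length(species_map) != n_haplotypes) {
    stop("species_map must name every haplotype", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_haplotypes = as.integer(n_haplotypes),
                 block_plan = block_plan, indel_plan = indel_plan,
                 tr_plan = tr_plan, species_map = species_map,
                 flank_protect = as.integer(flank_protect),
                 flank_gap = as.integer(flank_gap),
                 min_separation = as.integer(min_separation)),
            class = "simulation_spec")
}

#' Default study-scale quartet specification
#'
#' Emulates the comparative setting of a four-species plastome quartet:
#' ~156 kb genomes with a large single-copy region carrying four hypervariable
#' blocks, a small single-copy region, and a conserved inverted-repeat pair.
#' Per-lineage substitution rates are set so realized pairwise diversity
#' matches typical interspecific plastome values (LSC ~0.008, SSC ~0.010,
#' IR ~0.0013, hotspots 0.028-0.055); planted InDels (3-59 bp) and tandem
#' repeats (8-40 bp units) mirror the length spectrum of diagnostic plastid
#' markers. See the methods vignette for the reasoning behind each value.
#'
#' @param seed Integer seed.
#' @return A [simulation_spec()].
#' @export
default_quartet_spec <- function(seed = 1L) {
  blocks <- data.frame(
    label = c("LSC-like", "LSC-like", "LSC-like", "LSC-like", "LSC-like",
              "LSC-like", "LSC-like", "LSC-like", "LSC-like",
              "IR-like", "SSC-like", "IR-like"),
    length = c(2000L, 1000L, 18000L, 1000L, 1500L, 1000L, 10000L, 1000L,
               49800L, 26500L, 18000L, 26500L),
    rate = c(0.004, 0.019, 0.004, 0.042, 0.004, 0.0445, 0.004, 0.024,
             0.004, 0.00065, 0.0052, 0.00065),
    stringsAsFactors = FALSE)
  blocks$hotspot <- blocks$rate > 0.0125
  indels <- data.frame(
    block = c(2L, 2L, 2L, 4L, 4L, 4L, 6L, 6L, 6L, 6L, 8L, 8L, 8L, 8L),
    length = c(11L, 3L, 6L, 19L, 28L, 5L, 19L, 28L, 39L, 6L, 32L, 6L, 59L, 50L),
    subset = c("2", "2", "1", "2", "2", "1", "2", "1", "2", "3",
               "2", "1", "2", "3,4"),
    type = "del", stringsAsFactors = FALSE)
  trs <- data.frame(
    block = c(4L, 4L, 6L, 8L),
    unit_length = c(40L, 23L, 23L, 8L),
    copies = c(2L, 2L, 2L, 3L),
    subset = "1", stringsAsFactors = FALSE)
  simulation_spec(seed = seed, n_haplotypes = 4L, block_plan = blocks,
                  indel_plan = indels, tr_plan = trs,
                  species_map = c("schinifolium", "piperitum",
                                  "simulans", "zanthoxylum_sp"))
}

#' Simulate a genome quartet with a truth record
#'
#' Draws a uniform-random ancestor block by block (a second equal-length
#' IR-like block is the reverse complement of the first, with the flanking
#' bases adjusted so the planted repeat pair is maximal — no chance
#' single-base extension), mutates each haplotype independently
#' (Jukes-Cantor-style: each site substitutes with its block's rate, to a
#' uniformly chosen different base; substitution-protected flanks around
#' planted events are skipped), then applies planted deletions, insertions
#' and tandem-repeat expansions. Deterministic for a fixed spec.
#'
#' @param spec A [simulation_spec()].
#' @return List: `records` (ungapped `genome_record`s, ids `hap1..N`),
#'   `alignment` (the true [alignment_block()]), `truth` (list: `ancestor`,
#'   `blocks` with ancestral coordinates, `events` table with ancestral and
#'   alignment coordinates, `protected` windows, `substitutions` per
#'   haplotype, `expected_pairwise` per block = `2r(1-r) + (2/3)r^2`,
#'   `species_map`, `seed`).
#' @export
simulate_quartet <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  bp <- spec$block_plan
  n_blocks <- nrow(bp)
  ends <- cumsum(bp$length)
  starts <- ends - bp$length + 1L
  La <- ends[n_blocks]

  ## ancestral sequence
  anc <- character(La)
  ir_ix <- which(bp$label == "IR-like")
  paired_ir <- length(ir_ix) == 2L && bp$length[ir_ix[1L]] == bp$length[ir_ix[2L]]
  for (b in seq_len(n_blocks)) {
    if (paired_ir && b == ir_ix[2L]) {
      anc[starts[b]:ends[b]] <- revcomp(anc[starts[ir_ix[1L]]:ends[ir_ix[1L]]])
    } else {
      anc[starts[b]:ends[b]] <- sample(.BASES, bp$length[b], replace = TRUE)
    }
  }
  ## make the planted IR pair maximal: the base just outside each repeat end
  ## must not pair with its counterpart
  if (paired_ir) {
    a1 <- starts[ir_ix[1L]]; a2 <- ends[ir_ix[1L]]
    b1 <- starts[ir_ix[2L]]; b2 <- ends[ir_ix[2L]]
    if (a1 > 1L && b2 < La) {
      forb <- complement_chars(anc[a1 - 1L])
      if (anc[b2 + 1L] == forb) anc[b2 + 1L] <- sample(setdiff(.BASES, forb), 1L)
    }
    if (b1 > 1L) {
      forb <- complement_chars(anc[a2 + 1L])
      if (anc[b1 - 1L] == forb) anc[b1 - 1L] <- sample(setdiff(.BASES, forb), 1L)
    }
  }

  ## --- place planted events in ancestral coordinates ---
  events <- plan_events(spec, starts, ends)
  ## protected flanking windows (substitutions suppressed)
  prot <- protected_windows(events, spec, La)
  prot_mask <- rep(FALSE, La)
  for (w in seq_len(nrow(prot))) prot_mask[prot$start[w]:prot$end[w]] <- TRUE

  ## --- per-haplotype substitutions ---
  n <- spec$n_haplotypes
  hap_chars <- vector("list", n)
  subs <- vector("list", n)
  for (h in seq_len(n)) {
    hc <- anc
    pos_all <- integer(0)
    for (b in seq_len(n_blocks)) {
      if (bp$rate[b] <= 0) next
      ix <- starts[b]:ends[b]
      hit <- ix[stats::runif(length(ix)) < bp$rate[b] & !prot_mask[ix]]
      if (length(hit)) {
        hc[hit] <- vapply(hc[hit], function(base)
          sample(setdiff(.BASES, base), 1L), character(1))
        pos_all <- c(pos_all, hit)
      }
    }
    hap_chars[[h]] <- hc
    subs[[h]] <- sort(pos_all)
  }

  ## --- deletions: subset rows lose the span (become gaps) ---
  dels <- events[events$type == "del", , drop = FALSE]
  for (k in seq_len(nrow(dels))) {
    for (h in subset_ids(dels$subset[k])) {
      hap_chars[[h]][dels$anc_start[k]:dels$anc_end[k]] <- "-"
    }
  }

  ## --- insertions (incl. TR expansions): spliced as extra columns ---
  ins <- events[events$type %in% c("ins", "tr"), , drop = FALSE]
  ins <- ins[order(ins$ins_after), , drop = FALSE]
  rows <- assemble_rows(hap_chars, ins, La, n)

  ## alignment coordinates of every event
  off_before <- function(x) {
    if (!nrow(ins)) return(0L)
    sum(ins$ins_len[ins$ins_after < x])
  }
  events$aln_start <- integer(nrow(events)); events$aln_end <- integer(nrow(events))
  for (k in seq_len(nrow(events))) {
    if (events$type[k] == "del") {
      events$aln_start[k] <- events$anc_start[k] + off_before(events$anc_start[k])
      events$aln_end[k] <- events$anc_end[k] + off_before(events$anc_end[k])
    } else {
      ## offsets from insertions strictly left of this one
      base <- events$ins_after[k] + off_before(events$ins_after[k])
      events$aln_start[k] <- base + 1L
      events$aln_end[k] <- base + events$ins_len[k]
    }
  }

  ids <- paste0("hap", seq_len(n))
  aln <- alignment_block(vapply(rows, c2s, character(1)), ids = ids,
                         region_name = "simulated_quartet")
  records <- lapply(seq_len(n), function(h) {
    genome_record(ids[h], gsub("-", "", c2s(rows[[h]]), fixed = TRUE),
                  species_label = spec$species_map[h])
  })

  r <- bp$rate
  truth <- list(ancestor = c2s(anc),
                blocks = cbind(bp, anc_start = starts, anc_end = ends),
                events = events, protected = prot,
                substitutions = stats::setNames(subs, ids),
                expected_pairwise = 2 * r * (1 - r) + (2 / 3) * r^2,
                species_map = stats::setNames(spec$species_map, ids),
                seed = spec$seed)
  list(records = records, alignment = aln, truth = truth)
}

#' @noRd
subset_ids <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1L]])

## Decide ancestral coordinates for every planted event; rejection-samples
## auto-placed positions away from block edges and other events.
#' @noRd
plan_events <- function(spec, starts, ends) {
  margin <- 80L
  rows <- list()
  taken <- data.frame(start = integer(), end = integer())
  place <- function(block, fp_len, at) {
    lo <- starts[block] + margin
    hi <- ends[block] - margin - fp_len + 1L
    if (!is.na(at)) {
      pos <- starts[block] + at - 1L
      if (any(taken$start <= pos + fp_len - 1L & taken$end >= pos)) {
        stop("planted events overlap at ancestral position ", pos, call. = FALSE)
      }
      return(pos)
    }
    if (hi < lo) stop("block ", block, " too short for planted event", call. = FALSE)
    for (try in seq_len(400L)) {
      pos <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      clash <- any(taken$start <= pos + fp_len - 1L + spec$min_separation &
                     taken$end >= pos - spec$min_separation)
      if (!clash) return(pos)
    }
    stop("could not place event in block ", block,
         " without overlap; reduce the plan density", call. = FALSE)
  }
  ip <- spec$indel_plan
  if (!is.null(ip)) for (k in seq_len(nrow(ip))) {
    if (ip$type[k] == "del") {
      pos <- place(ip$block[k], ip$length[k], ip$at[k])
      rows[[length(rows) + 1L]] <- data.frame(
        type = "del", block = ip$block[k], anc_start = pos,
        anc_end = pos + ip$length[k] - 1L, ins_after = NA_integer_,
        ins_len = NA_integer_, length = ip$length[k], subset = ip$subset[k],
        unit_seq = NA_character_, copies = NA_integer_, stringsAsFactors = FALSE)
      taken <- rbind(taken, data.frame(start = pos, end = pos + ip$length[k] - 1L))
    } else {
      pos <- place(ip$block[k], 1L, ip$at[k])
      rows[[length(rows) + 1L]] <- data.frame(
        type = "ins", block = ip$block[k], anc_start = pos, anc_end = pos,
        ins_after = pos, ins_len = ip$length[k], length = ip$length[k],
        subset = ip$subset[k], unit_seq = c2s(sample(.BASES, ip$length[k],
                                                     replace = TRUE)),
        copies = NA_integer_, stringsAsFactors = FALSE)
      taken <- rbind(taken, data.frame(start = pos, end = pos))
    }
  }
  tp <- spec$tr_plan
  if (!is.null(tp)) for (k in seq_len(nrow(tp))) {
    u <- tp$unit_length[k]
    pos <- place(tp$block[k], u, tp$at[k])
    rows[[length(rows) + 1L]] <- data.frame(
      type = "tr", block = tp$block[k], anc_start = pos, anc_end = pos + u - 1L,
      ins_after = pos + u - 1L, ins_len = (tp$copies[k] - 1L) * u,
      length = (tp$copies[k] - 1L) * u, subset = tp$subset[k],
      unit_seq = NA_character_, copies = tp$copies[k], stringsAsFactors = FALSE)
    taken <- rbind(taken, data.frame(start = pos, end = pos + u - 1L))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(), block = integer(), anc_start = integer(),
               anc_end = integer(), ins_after = integer(), ins_len = integer(),
               length = integer(), subset = character(), unit_seq = character(),
               copies = integer(), stringsAsFactors = FALSE)
  if (nrow(out)) out$event_id <- seq_len(nrow(out))
  out
}

#' @noRd
protected_windows <- function(events, spec, La) {
  if (!nrow(events) || spec$flank_protect <= 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  g <- spec$flank_gap; f <- spec$flank_protect
  lft <- data.frame(start = pmax(events$anc_start - g - f, 1L),
                    end = pmax(events$anc_start - g - 1L, 1L))
  rgt <- data.frame(start = pmin(events$anc_end + g + 1L, La),
                    end = pmin(events$anc_end + g + f, La))
  out <- rbind(lft, rgt)
  out[out$end >= out$start, , drop = FALSE]
}

## Interleave ancestral segments with insertion columns for every haplotype.
#' @noRd
assemble_rows <- function(hap_chars, ins, La, n) {
  if (!nrow(ins)) return(hap_chars)
  rows <- vector("list", n)
  cut_after <- ins$ins_after
  seg_start <- c(1L, cut_after + 1L)
  seg_end <- c(cut_after, La)
  for (h in seq_len(n)) {
    pieces <- vector("list", 2L * nrow(ins) + 1L)
    for (s in seq_along(seg_start)) {
      pieces[[2L * s - 1L]] <- if (seg_start[s] <= seg_end[s]) {
        hap_chars[[h]][seg_start[s]:seg_end[s]]
      } else character(0)
      if (s <= nrow(ins)) {
        carrier <- h %in% subset_ids(ins$subset[s])
        content <- if (ins$type[s] == "tr") {
          ## slippage copies replicate the haplotype's own unit, so the
          ## expanded array is perfect within its carrier
          unit <- hap_chars[[h]][ins$anc_start[s]:ins$anc_end[s]]
          rep(unit, ins$ins_len[s] %/% length(unit))
        } else s2c(ins$unit_seq[s])
        pieces[[2L * s]] <- if (carrier) content else rep("-", ins$ins_len[s])
      }
    }
    rows[[h]] <- unlist(pieces, use.names = FALSE)
  }
  rows
}

#' Simulate a market-sample band table
#'
#' Each sample is a pure species draw or (with probability
#' `mixture_fraction`) a 50:50 mixture; its per-marker observed fragment
#' lengths are the panel's expected pattern(s) with uniform integer jitter of
#' up to `jitter_bp` per band. Truth labels are returned for scoring
#' [classify_panel()].
#'
#' @param panel Marker panel (see [default_panel()]).
#' @param n_samples Number of samples (default 16).
#' @param mixture_fraction Probability a sample is a mixture (default 0.2).
#' @param jitter_bp Maximum absolute band-size jitter (default 2).
#' @param seed Integer seed.
#' @return List: `bands` (`sample_id`, `marker`, `fragments` comma-joined)
#'   and `truth` (`sample_id`, `label` in
#'   `{schinifolium, piperitum, mixture}`).
#' @export
simulate_market_panel <- function(panel = default_panel(), n_samples = 16L,
                                  mixture_fraction = 0.2, jitter_bp = 2L,
                                  seed = 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  species <- unique(unlist(lapply(panel, names)))
  bands <- list(); truth <- list()
  for (i in seq_len(n_samples)) {
    sid <- sprintf("sample%03d", i)
    mixed <- stats::runif(1L) < mixture_fraction
    label <- if (mixed) "mixture" else sample(species, 1L)
    members <- if (mixed) species else label
    for (mk in names(panel)) {
      frags <- unlist(panel[[mk]][members], use.names = FALSE)
      frags <- frags + sample(seq(-jitter_bp, jitter_bp), length(frags),
                              replace = TRUE)
      bands[[length(bands) + 1L]] <- data.frame(
        sample_id = sid, marker = mk,
        fragments = paste(frags, collapse = ","), stringsAsFactors = FALSE)
    }
    truth[[length(truth) + 1L]] <- data.frame(sample_id = sid, label = label,
                                              stringsAsFactors = FALSE)
  }
  list(bands = do.call(rbind, bands), truth = do.call(rbind, truth))
}
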