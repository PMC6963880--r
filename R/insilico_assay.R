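## In-silico PCR and restriction analysis: mismatch-tolerant primer-site
## search with an exact 3' anchor, amplicon prediction, digestion with a
## packaged enzyme catalog (Type IIS offset cutters supported), and
## fragment-pattern species classification.

#' Locate primer binding sites on a template
#'
#' Scans both strands. A site qualifies when total mismatches do not exceed
#' `max_mismatch` AND the `anchor_len` 3'-terminal primer bases match the
#' template exactly (no extension from a mismatched 3' end). IUPAC codes in
#' the primer match their expansion sets; ambiguity in the template never
#' matches.
#'
#' @param template DNA string (template forward strand).
#' @param primer 5'->3' primer sequence (IUPAC allowed).
#' @param max_mismatch Maximum non-anchor mismatches (default 2).
#' @param anchor_len Length of the exact 3' anchor (default 5).
#' @return `data.frame`: `strand` (`+`/`-`), `start`, `end` (1-based
#'   inclusive on the forward strand), `mismatches`, `three_prime_exact`
#'   (always TRUE for returned sites), sorted by `start`.
#' @export
find_primer_sites <- function(template, primer, max_mismatch = 2L, anchor_len = 5L) {
  template <- toupper(template); primer <- toupper(primer)
  m <- nchar(primer)
  if (nchar(template) < m) {
    stop("template shorter than primer", call. = FALSE)
  }
  tmpl <- Biostrings::DNAString(template)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer else revcomp(primer)
    hits <- Biostrings::matchPattern(pat, tmpl, max.mismatch = max_mismatch,
                                     fixed = "subject")
    if (!length(hits)) next
    pchars <- s2c(pat)
    for (i in seq_along(hits)) {
      st <- BiocGenerics::start(hits)[i]; en <- BiocGenerics::end(hits)[i]
      tchars <- s2c(substr(template, st, en))
      match_vec <- iupac_compatible(pchars, tchars)
      mm <- sum(!match_vec)
      if (mm > max_mismatch) next
      ## 3' anchor: last primer bases on +, first window bases on -
      anchor_ix <- if (strand == "+") (m - anchor_len + 1L):m else seq_len(anchor_len)
      if (!all(match_vec[anchor_ix])) next
      out[[length(out) + 1L]] <- data.frame(
        strand = strand, start = st, end = en, mismatches = mm,
        three_prime_exact = TRUE, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(strand = character(), start = integer(), end = integer(),
               mismatches = integer(), three_prime_exact = logical(),
               stringsAsFactors = FALSE)
  res[order(res$start), , drop = FALSE]
}

#' Predict PCR amplicons for a primer pair
#'
#' Every combination of a forward-primer site on the plus strand and a
#' reverse-primer site on the minus strand with `forward start < reverse end`
#' and product length within bounds yields an amplicon (multi-band
#' prediction). Amplicon coordinates include both full primer footprints, as
#' capillary electrophoresis measures.
#'
#' @param template DNA string (case-insensitive).
#' @param primers A [primer_pair()] (or list with `forward`/`reverse`).
#' @param min_len,max_len Product-size bounds (defaults 50 and 5000 bp).
#' @inheritParams find_primer_sites
#' @return `data.frame`: `start`, `end`, `length`, `fwd_mismatches`,
#'   `rev_mismatches`, `sequence`, sorted by length.
#' @export
predict_amplicons <- function(template, primers, min_len = 50L, max_len = 5000L,
                              max_mismatch = 2L, anchor_len = 5L) {
  template <- toupper(template)
  f <- find_primer_sites(template, primers$forward, max_mismatch, anchor_len)
  r <- find_primer_sites(template, primers$reverse, max_mismatch, anchor_len)
  f <- f[f$strand == "+", , drop = FALSE]
  r <- r[r$strand == "-", , drop = FALSE]
  out <- list()
  if (nrow(f) && nrow(r)) {
    for (i in seq_len(nrow(f))) for (j in seq_len(nrow(r))) {
      if (f$start[i] < r$end[j]) {
        len <- r$end[j] - f$start[i] + 1L
        if (len >= min_len && len <= max_len) {
          out[[length(out) + 1L]] <- data.frame(
            start = f$start[i], end = r$end[j], length = len,
            fwd_mismatches = f$mismatches[i], rev_mismatches = r$mismatches[j],
            sequence = substr(template, f$start[i], r$end[j]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), end = integer(), length = integer(),
               fwd_mismatches = integer(), rev_mismatches = integer(),
               sequence = character(), stringsAsFactors = FALSE)
  res[order(res$length), , drop = FALSE]
}

## --- restriction enzymes ---------------------------------------------------

#' Read a restriction-enzyme table
#'
#' Tab-separated columns `name`, `recognition` (IUPAC), `cut_top`,
#' `cut_bottom`: signed offsets of the cut from the 3' end of the recognition
#' site on the respective strand. The top-strand cut falls between positions
#' `site_end + cut_top` and `site_end + cut_top + 1` (so PleI, GAGTC 4/5, has
#' `cut_top = 4`; EcoRI, G^AATTC, has `cut_top = -5`). Palindromy is derived
#' from the recognition sequence.
#'
#' @param path TSV path; defaults to the packaged catalog
#'   (`inst/extdata/enzymes.tsv`).
#' @return `data.frame` with an added logical `palindromic` column.
#' @export
read_enzymes <- function(path = system.file("extdata", "enzymes.tsv",
                                            package = "cpmarker", mustWork = TRUE)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "recognition", "cut_top", "cut_bottom")
  if (!all(need %in% names(tab))) {
    stop("enzyme table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  tab$recognition <- toupper(tab$recognition)
  if (any(nchar(tab$recognition) < 4L)) {
    stop("recognition sequences must be at least 4 bases", call. = FALSE)
  }
  tab$palindromic <- vapply(tab$recognition,
                            function(x) identical(x, revcomp(x)), logical(1),
                            USE.NAMES = FALSE)
  tab
}

#' Look up an enzyme in a catalog
#'
#' @param name Enzyme name (case-insensitive).
#' @param catalog Table from [read_enzymes()].
#' @return Single-row enzyme `data.frame`.
#' @export
get_enzyme <- function(name, catalog = read_enzymes()) {
  hit <- which(tolower(catalog$name) == tolower(name))
  if (!length(hit)) {
    stop("unknown enzyme ", sQuote(name), "; packaged catalog: ",
         paste(catalog$name, collapse = ", "), call. = FALSE)
  }
  catalog[hit[1L], , drop = FALSE]
}

#' Digest an amplicon with one restriction enzyme
#'
#' Locates all occurrences of the recognition sequence (and of its reverse
#' complement, for non-palindromic enzymes) and converts them to top-strand
#' cut positions. Fragment lengths are the distances between successive
#' top-strand cuts plus the two ends, so they always sum to the amplicon
#' length; 5' overhangs of sticky-end cutters are ignored (gel-observable
#' sizes to within 1 nt). Cuts falling outside the sequence (possible for
#' offset cutters near an end) are skipped with a warning.
#'
#' @param amplicon DNA string (or one row of a [predict_amplicons()] result
#'   via its `sequence` column).
#' @param enzyme Enzyme name (looked up in `catalog`) or a single-row enzyme
#'   table.
#' @param catalog Enzyme catalog (default packaged).
#' @return List of class `digest_result`: `enzyme`, `length`,
#'   `site_positions` (recognition-site starts, both orientations),
#'   `cut_positions` (top strand; last base of the left fragment), `fragments`
#'   (decreasing bp, as read off a gel).
#' @export
digest_amplicon <- function(amplicon, enzyme, catalog = read_enzymes()) {
  if (is.character(enzyme)) enzyme <- get_enzyme(enzyme, catalog)
  seq <- toupper(amplicon)
  L <- nchar(seq)
  tmpl <- Biostrings::DNAString(seq)
  rec <- enzyme$recognition
  finds <- function(pat) {
    h <- Biostrings::matchPattern(pat, tmpl, fixed = "subject")
    BiocGenerics::start(h)
  }
  top_starts <- finds(rec)
  cut_pos <- top_starts + nchar(rec) - 1L + enzyme$cut_top
  site_pos <- top_starts
  if (!enzyme$palindromic) {
    bot_starts <- finds(revcomp(rec))
    ## recognition on the bottom strand: top-strand cut is cut_bottom + 1
    ## bases 5' of the site start (offsets measured along the bottom strand)
    cut_pos <- c(cut_pos, bot_starts - enzyme$cut_bottom - 1L)
    site_pos <- c(site_pos, bot_starts)
  }
  inside <- cut_pos >= 1L & cut_pos <= L - 1L
  if (any(!inside)) {
    warning(sprintf("%d cut(s) fall outside the %d bp amplicon and were skipped",
                    sum(!inside), L), call. = FALSE)
  }
  cuts <- sort(unique(cut_pos[inside]))
  fragments <- sort(diff(c(0L, cuts, L)), decreasing = TRUE)
  structure(list(enzyme = enzyme$name, length = L,
                 site_positions = sort(site_pos),
                 cut_positions = cuts, fragments = fragments),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("<digest_result> %s on %d bp: %d cut(s) -> fragments %s\n",
              x$enzyme, x$length, length(x$cut_positions),
              paste(x$fragments, collapse = " + ")))
  invisible(x)
}

## --- species classification ------------------------------------------------

#' Packaged default marker panel
#'
#' Expected per-species fragment patterns for the shipped assays: the
#' trnH-psbA PleI PCR-RFLP (schinifolium 436 + 107 bp; piperitum 562 bp,
#' uncut) and the psbZ-trnG product-size assay. Used by [classify_sample()]
#' and the market-panel simulator.
#'
#' @return Named list: one entry per marker, each a list of species ->
#'   numeric expected fragment lengths.
#' @export
default_panel <- function() {
  list(
    trnH_psbA_PleI = list(schinifolium = c(436, 107), piperitum = 562),
    psbZ_trnG_size = list(schinifolium = 662, piperitum = 547)
  )
}

#' Classify a sample from fragment patterns
#'
#' Per marker, the observed fragment lengths are compared with each species'
#' expected pattern: a pattern is present when each expected fragment has an
#' observed fragment within `tolerance_bp`. A marker votes for one species,
#' for `both` (both patterns present — mixture evidence, the "double band"
#' case), or for none. The final call is `mixture` if any marker votes both;
#' otherwise the unanimous species if all informative markers agree;
#' otherwise `unresolved` (including the empty-observation case).
#'
#' @param observed Named list: marker -> numeric vector of observed fragment
#'   lengths (bp).
#' @param panel Marker panel as from [default_panel()].
#' @param tolerance_bp Matching slack (default 5 bp).
#' @return List of class `species_call`: `call` (one of `schinifolium`,
#'   `piperitum`, `mixture`, `unresolved`), `votes` (per marker), `evidence`
#'   (per marker, per species logical), `reason`.
#' @export
classify_sample <- function(observed, panel = default_panel(), tolerance_bp = 5) {
  markers <- intersect(names(panel), names(observed))
  if (!length(markers) || all(!lengths(observed[markers]))) {
    return(structure(list(call = "unresolved", votes = character(),
                          evidence = list(), reason = "no observations"),
                     class = "species_call"))
  }
  votes <- character(0); evidence <- list()
  for (mk in markers) {
    obs <- observed[[mk]]
    if (!length(obs)) next
    present <- vapply(panel[[mk]], function(pat) {
      all(vapply(pat, function(fr) any(abs(obs - fr) <= tolerance_bp), logical(1)))
    }, logical(1))
    evidence[[mk]] <- present
    votes[[mk]] <- if (sum(present) >= 2L) "both" else
      if (sum(present) == 1L) names(present)[present] else "none"
  }
  informative <- votes[votes != "none"]
  call <- if (any(votes == "both")) "mixture" else
    if (length(informative) && length(unique(informative)) == 1L) unique(informative) else
      "unresolved"
  structure(list(call = call, votes = votes, evidence = evidence,
                 reason = if (call == "unresolved" && !length(informative))
                   "no marker matched any pattern" else NA_character_),
            class = "species_call")
}

#' @export
print.species_call <- function(x, ...) {
  cat(sprintf("<species_call> %s\n", x$call))
  if (length(x$votes)) {
    for (mk in names(x$votes)) cat(sprintf("  %s: %s\n", mk, x$votes[[mk]]))
  }
  invisible(x)
}

#' Classify a band table of many samples
#'
#' @param bands `data.frame` with columns `sample_id`, `marker`, `fragments`
#'   (comma-separated bp) — the format written by the market-panel simulator
#'   and accepted from manually entered gel readings.
#' @inheritParams classify_sample
#' @return `data.frame`: `sample_id`, `call`.
#' @export
classify_panel <- function(bands, panel = default_panel(), tolerance_bp = 5) {
  samples <- unique(bands$sample_id)
  calls <- vapply(samples, function(sid) {
    sub <- bands[bands$sample_id == sid, , drop = FALSE]
    obs <- stats::setNames(
      lapply(sub$fragments, function(f) as.numeric(strsplit(f, ",")[[1L]])),
      sub$marker)
    classify_sample(obs, panel, tolerance_bp)$call
  }, character(1))
  data.frame(sample_id = samples, call = calls, stringsAsFactors = FALSE,
             row.names = NULL)
}
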