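## Genome and alignment I/O: GenBank/FASTA readers, quadripartite plastome
## partitioning, region extraction, and a small global aligner for test-scale
## sequences. Coordinates are 1-based inclusive everywhere in the public
## interface (GenBank convention); BED export converts to 0-based half-open.

#' Construct a genome record
#'
#' A lightweight container for a single (plastid) genome: an accession id, a
#' free-text species label, an upper-cased IUPAC DNA sequence, and an optional
#' feature table in 1-based inclusive coordinates.
#'
#' @param id Accession-style identifier.
#' @param sequence DNA string over the IUPAC alphabet (upper-cased on entry).
#' @param species_label Free-text organism/species label.
#' @param annotations `data.frame` with columns `feature_name`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`), 1-based inclusive. Features spanning the
#'   circular origin must already be split into two linear intervals (the
#'   readers do this).
#' @param source_format `"genbank"`, `"fasta"`, or `"memory"`.
#' @return An object of class `genome_record` with fields `id`,
#'   `species_label`, `sequence`, `length`, `annotations`, `source_format`.
#' @export
genome_record <- function(id, sequence, species_label = NA_character_,
                          annotations = NULL, source_format = "memory") {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence for record ", sQuote(id), call. = FALSE)
  assert_dna(sequence, what = sprintf("record %s", sQuote(id)))
  if (is.null(annotations)) {
    annotations <- data.frame(feature_name = character(), start = integer(),
                              end = integer(), strand = character(),
                              stringsAsFactors = FALSE)
  }
  len <- nchar(sequence)
  if (nrow(annotations)) {
    bad <- annotations$start < 1L | annotations$end > len |
      annotations$start > annotations$end
    if (any(bad)) {
      stop("annotation coordinates out of range for features: ",
           paste(annotations$feature_name[bad], collapse = ", "), call. = FALSE)
    }
  }
  structure(list(id = id, species_label = species_label, sequence = sequence,
                 length = len, annotations = annotations,
                 source_format = source_format),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s)\n  %s bp, %d features, source: %s\n",
              x$id, x$species_label, format(x$length, big.mark = ","),
              nrow(x$annotations), x$source_format))
  invisible(x)
}

#' Read genome records from GenBank or FASTA
#'
#' Single-record files return a `genome_record`; multi-record files return a
#' list of them. GenBank feature tables are mapped into the record's
#' `annotations` (gene/tRNA/rRNA/CDS and other keyed features; the `gene` or
#' `product` qualifier provides the feature name, falling back to the feature
#' key). Features written as `join(a..L,1..b)` across the circular origin are
#' split into two linear intervals.
#'
#' @param path File path.
#' @param format `"auto"` (sniff first non-blank character), `"genbank"`, or
#'   `"fasta"`.
#' @return A `genome_record` or a list of them.
#' @export
read_genome <- function(path, format = c("auto", "genbank", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    head_lines <- readLines(path, n = 5L, warn = FALSE)
    head_lines <- head_lines[nzchar(trimws(head_lines))]
    if (!length(head_lines)) stop("empty file: ", path, call. = FALSE)
    format <- if (grepl("^LOCUS", head_lines[[1L]])) "genbank" else
      if (startsWith(trimws(head_lines[[1L]]), ">")) "fasta" else
        stop("cannot determine format of ", path,
             " (expected GenBank LOCUS line or FASTA '>')", call. = FALSE)
  }
  recs <- if (format == "genbank") read_genbank_file(path) else read_fasta_file(path)
  if (length(recs) == 1L) recs[[1L]] else recs
}

#' @noRd
read_fasta_file <- function(path) {
  set <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        txt <- paste(grep("^>", readLines(path, warn = FALSE),
                          invert = TRUE, value = TRUE), collapse = "")
        bad <- setdiff(unique(s2c(toupper(txt))), c(.IUPAC_CHARS, "-", "."))
        stop("FASTA file ", path, " contains non-IUPAC characters: ",
             paste(sQuote(bad), collapse = ", "), call. = FALSE)
      }
    })
  if (!length(set)) stop("no FASTA records in ", path, call. = FALSE)
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    id <- strsplit(header, "\\s+")[[1L]][1L]
    label <- sub("^\\S+\\s*", "", header)
    genome_record(id = id, sequence = as.character(set[[i]]),
                  species_label = if (nzchar(label)) label else NA_character_,
                  source_format = "fasta")
  })
}

## --- minimal GenBank flat-file parser -------------------------------------
## Handles LOCUS, DEFINITION, ORGANISM, FEATURES (simple spans, complement(),
## join() including origin-spanning joins), ORIGIN. Enough for plastome
## records; anything structurally unexpected raises an error naming the line.

#' @noRd
read_genbank_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LOCUS", lines)
  if (!length(starts)) stop("not a GenBank file (no LOCUS line): ", path, call. = FALSE)
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    parse_genbank_record(lines[starts[k]:ends[k]], path, starts[k])
  })
}

#' @noRd
parse_genbank_record <- function(lines, path, line0) {
  locus_tok <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  id <- if (length(locus_tok) >= 2L) locus_tok[[2L]] else
    stop(sprintf("malformed LOCUS line at %s:%d", path, line0), call. = FALSE)
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc)) {
    tok <- strsplit(trimws(acc[[1L]]), "\\s+")[[1L]]
    if (length(tok) >= 2L) id <- tok[[2L]]
  }
  org <- grep("^\\s{0,4}ORGANISM", lines, value = TRUE)
  species <- if (length(org)) trimws(sub("^\\s*ORGANISM\\s+", "", org[[1L]])) else NA_character_

  ## ORIGIN block -> sequence
  oi <- grep("^ORIGIN", lines)
  if (!length(oi)) stop(sprintf("no ORIGIN block in record %s (%s)", id, path), call. = FALSE)
  seq_lines <- lines[(oi[[1L]] + 1L):length(lines)]
  term <- grep("^//", seq_lines)
  if (length(term)) seq_lines <- seq_lines[seq_len(term[[1L]] - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(seq)) stop(sprintf("empty sequence in record %s (%s)", id, path), call. = FALSE)

  ## FEATURES block
  ann <- data.frame(feature_name = character(), start = integer(),
                    end = integer(), strand = character(), stringsAsFactors = FALSE)
  fi <- grep("^FEATURES", lines)
  if (length(fi)) {
    fend <- oi[[1L]] - 1L
    flines <- lines[(fi[[1L]] + 1L):fend]
    ## feature starts: exactly 5 leading spaces then a key
    fstart <- grep("^ {5}\\S", flines)
    if (length(fstart)) {
      fstop <- c(fstart[-1L] - 1L, length(flines))
      feats <- lapply(seq_along(fstart), function(k) {
        chunk <- flines[fstart[k]:fstop[k]]
        key <- sub("^ {5}(\\S+).*$", "\\1", chunk[[1L]])
        loc <- sub("^ {5}\\S+\\s+", "", chunk[[1L]])
        ## location may continue on following lines (no '/')
        cont <- chunk[-1L]
        j <- 1L
        while (j <= length(cont) && !grepl("^\\s+/", cont[[j]])) {
          loc <- paste0(loc, trimws(cont[[j]])); j <- j + 1L
        }
        name <- key
        quals <- grep("^\\s+/(gene|product)=", chunk, value = TRUE)
        if (length(quals)) {
          name <- sub('^\\s+/(gene|product)="?([^"]*)"?.*$', "\\2", quals[[1L]])
        }
        ivs <- parse_gb_location(loc, nchar(seq), id)
        if (is.null(ivs)) return(NULL)
        cbind(data.frame(feature_name = name, stringsAsFactors = FALSE), ivs)
      })
      feats <- feats[!vapply(feats, is.null, logical(1))]
      if (length(feats)) ann <- do.call(rbind, feats)
    }
  }
  if (key_is_source <- nrow(ann) > 0L) {
    ann <- ann[ann$feature_name != "source", , drop = FALSE]
    rownames(ann) <- NULL
  }
  genome_record(id = id, sequence = seq, species_label = species,
                annotations = ann, source_format = "genbank")
}

## Parse a GenBank location string into a data.frame(start, end, strand).
## Origin-spanning join(a..L,1..b) simply yields its two intervals.
#' @noRd
parse_gb_location <- function(loc, seqlen, id) {
  loc <- gsub("\\s+", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc) || grepl("^order\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  out <- lapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
    } else if (grepl("^\\d+$", p)) {
      se <- rep(as.integer(p), 2L)
    } else {
      warning(sprintf("record %s: unsupported location %s skipped", id, sQuote(p)),
              call. = FALSE)
      return(NULL)
    }
    data.frame(start = se[1L], end = se[2L], strand = strand,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Extract a subsequence in 1-based inclusive coordinates
#'
#' @param x A `genome_record` or a plain DNA string.
#' @param start,end 1-based inclusive span; `end >= start`.
#' @return Character string of length `end - start + 1`.
#' @export
extract_region <- function(x, start, end) {
  seq <- if (inherits(x, "genome_record")) x$sequence else x
  len <- nchar(seq)
  if (start < 1L || end > len || start > end) {
    stop(sprintf("region %d..%d out of range for sequence of length %d",
                 start, end, len), call. = FALSE)
  }
  substr(seq, start, end)
}

#' Write sequences to FASTA
#'
#' @param x A `genome_record`, a list of them, an `alignment_block`, or a
#'   named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  seqs <- if (inherits(x, "genome_record")) {
    stats::setNames(x$sequence, x$id)
  } else if (inherits(x, "alignment_block")) {
    stats::setNames(x$rows, x$haplotype_ids)
  } else if (is.list(x)) {
    stats::setNames(vapply(x, function(r) r$sequence, character(1)),
                    vapply(x, function(r) r$id, character(1)))
  } else x
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#'
#' Converts 1-based inclusive intervals to the BED convention
#' (`chromStart = start - 1`, `chromEnd = end`).
#'
#' @param df `data.frame` with `start`, `end` (1-based inclusive) and
#'   optionally `name` and `score`.
#' @param path Output path.
#' @param chrom Chromosome/record label used for every row.
#' @export
write_bed <- function(df, path, chrom = "plastome") {
  bed <- data.frame(chrom = chrom,
                    chromStart = as.integer(df$start) - 1L,
                    chromEnd = as.integer(df$end),
                    name = if ("name" %in% names(df)) df$name else ".",
                    score = if ("score" %in% names(df)) df$score else 0L)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## --- alignment blocks ------------------------------------------------------

#' Construct a gapped multiple-alignment block
#'
#' Rows must have identical gapped length; all-gap columns are stripped at
#' construction. At least two rows are required.
#'
#' @param rows Character vector of equal-length gapped sequences
#'   (`A/C/G/T/N/IUPAC/-`).
#' @param ids Haplotype identifiers (defaults to names of `rows` or `hap1..N`).
#' @param region_name Optional label for the aligned region.
#' @param origin_coords Optional `data.frame(record_id, start, end)` mapping
#'   each row back to its source genome (1-based inclusive, ungapped).
#' @return An `alignment_block` with fields `region_name`, `haplotype_ids`,
#'   `rows`, `column_count`, `mat` (character matrix), `origin_coords`.
#' @export
alignment_block <- function(rows, ids = NULL, region_name = "region",
                            origin_coords = NULL) {
  if (length(rows) < 2L) stop("an alignment needs at least 2 sequences", call. = FALSE)
  ids <- ids %||% (names(rows) %||% paste0("hap", seq_along(rows)))
  rows <- toupper(unname(rows))
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment rows; lengths: ",
         paste(sprintf("%s=%d", ids, lens), collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(rows)) assert_dna(rows[i], sprintf("row %s", ids[i]), allow_gap = TRUE)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  keep <- colSums(mat != "-") > 0L
  if (!all(keep)) {
    mat <- mat[, keep, drop = FALSE]
    rows <- apply(mat, 1L, paste, collapse = "")
  }
  structure(list(region_name = region_name, haplotype_ids = ids, rows = rows,
                 column_count = ncol(mat), mat = mat,
                 origin_coords = origin_coords),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("<alignment_block> %s: %d sequences x %s columns\n",
              x$region_name, length(x$rows), format(x$column_count, big.mark = ",")))
  invisible(x)
}

#' Load a multiple alignment from aligned FASTA or Clustal
#'
#' @param path Alignment file; format sniffed (`CLUSTAL` header vs FASTA).
#' @param region_name Label for the resulting block.
#' @return An [alignment_block()].
#' @export
load_alignment <- function(path, region_name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^CLUSTAL", first, ignore.case = TRUE)) {
    aln <- Biostrings::readDNAMultipleAlignment(path, format = "clustal")
    rows <- as.character(aln)
    return(alignment_block(rows, ids = names(rows), region_name = region_name))
  }
  ## aligned FASTA: read as a set so ragged rows give our own error
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) < 2L) stop("alignment file has fewer than 2 sequences: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  alignment_block(as.character(set), ids = ids, region_name = region_name)
}

#' Columns of an alignment mapped to ungapped positions of one row
#'
#' For each alignment column gives the 1-based ungapped position of `row_id`'s
#' last base at or before that column (0 before the row's first base).
#'
#' @param block An `alignment_block`.
#' @param row Row index or haplotype id.
#' @return Integer vector of length `column_count`.
#' @export
reference_position_map <- function(block, row = 1L) {
  i <- if (is.character(row)) match(row, block$haplotype_ids) else row
  if (is.na(i)) stop("unknown reference row: ", row, call. = FALSE)
  cumsum(block$mat[i, ] != "-")
}

## --- small global aligner ---------------------------------------------------

#' Global pairwise alignment with affine gaps (test-scale)
#'
#' A convenience wrapper around `Biostrings::pairwiseAlignment` for aligning
#' two short sequences without an external aligner. A gap run of length L
#' scores `gap_open + L * gap_extend`. Ambiguity codes score as mismatches to
#' everything. Whole-plastome alignment is out of scope; use an external
#' aligner and [load_alignment()].
#'
#' @param seq_a,seq_b DNA strings, each at most 50 kb.
#' @param match,mismatch,gap_open,gap_extend Scoring scheme (defaults
#'   `+1/-2/-5/-2`).
#' @param ids Haplotype ids for the resulting block.
#' @return An [alignment_block()] of the two aligned rows, with the optimal
#'   score in attribute `"score"`.
#' @export
align_small <- function(seq_a, seq_b, match = 1, mismatch = -2,
                        gap_open = -5, gap_extend = -2,
                        ids = c("seqA", "seqB")) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) > 50000L || nchar(seq_b) > 50000L) {
    stop("align_small is limited to sequences <= 50 kb; ",
         "use an external aligner (e.g. mafft) and load_alignment()", call. = FALSE)
  }
  assert_dna(seq_a, "seq_a"); assert_dna(seq_b, "seq_b")
  letters <- .IUPAC_CHARS
  sub <- matrix(mismatch, length(letters), length(letters),
                dimnames = list(letters, letters))
  diag(sub)[1:4] <- match  # only unambiguous identities score as matches
  aln <- Biostrings::pairwiseAlignment(
    pattern = seq_a, subject = seq_b, type = "global",
    substitutionMatrix = sub,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  block <- alignment_block(c(as.character(Biostrings::alignedPattern(aln)),
                             as.character(Biostrings::alignedSubject(aln))),
                           ids = ids, region_name = "pairwise")
  attr(block, "score") <- Biostrings::score(aln)
  block
}
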