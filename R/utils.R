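## Shared low-level helpers: alphabet handling, reverse complement, small
## string utilities. Nothing here is exported.

.BASES <- c("A", "C", "G", "T")

## IUPAC nucleotide codes -> the set of bases each stands for
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_CHARS <- names(.IUPAC)

## complement table covering the full IUPAC alphabet plus gap
.COMP_FROM <- "ACGTRYSWKMBDHVN-"
.COMP_TO   <- "TGCAYRSWMKVHDBN-"

#' @noRd
revcomp <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) {
    # string form
    return(chartr(.COMP_FROM, .COMP_TO,
                  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")))
  }
  # character-vector form
  rev(chartr(.COMP_FROM, .COMP_TO, x))
}

#' @noRd
complement_chars <- function(x) chartr(.COMP_FROM, .COMP_TO, x)

## TRUE when template base `t` is compatible with (possibly ambiguous)
## primer/recognition base `p`. Ambiguity in the template never matches.
#' @noRd
iupac_compatible <- function(p, t) {
  ok <- logical(length(p))
  plain <- p == t & t %in% .BASES
  ok[plain] <- TRUE
  amb <- !plain & p %in% .IUPAC_CHARS
  if (any(amb)) {
    ok[amb] <- mapply(function(pp, tt) tt %in% .IUPAC[[pp]], p[amb], t[amb])
  }
  ok
}

#' @noRd
s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' @noRd
c2s <- function(x) paste(x, collapse = "")

#' @noRd
random_dna <- function(n) c2s(sample(.BASES, n, replace = TRUE))

#' @noRd
assert_dna <- function(seq, what = "sequence", allow_gap = FALSE) {
  chars <- unique(s2c(toupper(seq)))
  allowed <- .IUPAC_CHARS
  if (allow_gap) allowed <- c(allowed, "-")
  bad <- setdiff(chars, allowed)
  if (length(bad)) {
    stop(sprintf("%s contains non-IUPAC characters: %s", what,
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
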