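#' Alignment scoring parameters
#'
#' Defaults follow common practice for nucleotide alignment of amplicons:
#' match +5, mismatch -4, affine gaps costing `gap_open + L * gap_extend`
#' for a gap of length L. With `free_end_gaps = TRUE` (the default) terminal
#' gaps are free and excluded from the identity denominator, so the identity
#' of near-full-length amplicons approximates a blastn-style percentage while
#' remaining a deterministic global computation. Internal gap columns count
#' in the denominator as mismatches.
#'
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend gap penalties (negative).
#' @param free_end_gaps logical; overlap-style alignment when `TRUE`.
#' @return A list of scoring parameters, class `cs_scoring`.
#' @export
align_scoring <- function(match = 5, mismatch = -4, gap_open = -10,
                          gap_extend = -1, free_end_gaps = TRUE) {
  structure(
    list(match = match, mismatch = mismatch, gap_open = gap_open,
         gap_extend = gap_extend, free_end_gaps = isTRUE(free_end_gaps)),
    class = "cs_scoring"
  )
}

as_bases <- function(x, what = "sequence") {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) abort(paste0(what, " must be a single record"))
    x <- x$bases
  }
  stopifnot_scalar_chr(x, what)
  toupper(x)
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch alignment with affine gap penalties and, by default,
#' free end gaps. Ties are broken deterministically: a substitution is
#' preferred over a gap in `b`, which is preferred over a gap in `a`.
#'
#' @param a,b sequences: either strings or single-row sequence tibbles.
#' @param scoring an [align_scoring()] object.
#' @return An object of class `cs_alignment`: a list with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, `identity_percent`
#'   and the match/column counts behind it.
#' @export
global_align <- function(a, b, scoring = align_scoring()) {
  res <- nw_align_cpp(as_bases(a, "a"), as_bases(b, "b"),
                      scoring$match, scoring$mismatch, scoring$gap_open,
                      scoring$gap_extend, scoring$free_end_gaps)
  structure(res, class = "cs_alignment")
}

#' @export
print.cs_alignment <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.cs_alignment <- function(x, width = 60L, ...) {
  midline <- function(a, b) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    paste(ifelse(ca == cb & ca %in% DNA_BASES, "|", " "), collapse = "")
  }
  n <- nchar(x$aligned_a)
  out <- character()
  for (s in seq(1L, n, by = width)) {
    e <- min(s + width - 1L, n)
    a <- substr(x$aligned_a, s, e)
    b <- substr(x$aligned_b, s, e)
    out <- c(out, a, midline(a, b), b, "")
  }
  c(sprintf("score %.1f, identity %.2f%% (%d/%d columns)",
            x$score, x$identity_percent, x$n_matches, x$n_core_columns),
    out)
}

#' Percent identity between two sequences
#'
#' 100 x (matching columns) / (alignment columns), where terminal-gap
#' columns are excluded from the count and internal gap columns count as
#' mismatches. This is the identity measure used by every threshold in the
#' pipeline (97% OTU clustering, <=95% / <89% novelty, >97% isolate
#' confirmation).
#'
#' @inheritParams global_align
#' @return A number in \[0, 100\].
#' @export
percent_identity <- function(a, b, scoring = align_scoring()) {
  global_align(a, b, scoring)$identity_percent
}

#' Percent identity of one query against many references
#'
#' @param query a single sequence (string or single-row tibble).
#' @param refs character vector of reference sequences.
#' @inheritParams global_align
#' @return Numeric vector of identities, one per reference.
#' @export
percent_identity_many <- function(query, refs, scoring = align_scoring()) {
  nw_identity_many_cpp(as_bases(query, "query"), toupper(refs),
                       scoring$match, scoring$mismatch, scoring$gap_open,
                       scoring$gap_extend, scoring$free_end_gaps)
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Count IUPAC-aware mismatches between a pattern and a window
#'
#' Positions where the window base is not in the allowed set of the pattern's
#' IUPAC code are counted as mismatches. An `N` in the window (an uncalled
#' base in a read) matches nothing except a literal `N` in the pattern:
#' uncalled bases never silently satisfy a primer check.
#'
#' @param pattern a string possibly containing IUPAC ambiguity codes
#'   (typically a primer).
#' @param window a read substring of the same length.
#' @return Integer mismatch count.
#' @export
iupac_mismatches <- function(pattern, window) {
  pattern <- toupper(pattern)
  window <- toupper(window)
  if (nchar(pattern) != nchar(window)) {
    abort("`pattern` and `window` must have equal length")
  }
  if (nchar(pattern) == 0L) return(0L)
  pc <- strsplit(pattern, "")[[1]]
  wc <- strsplit(window, "")[[1]]
  ok <- map2(pc, wc, function(p, w) {
    if (w == "N") return(p == "N")
    allowed <- IUPAC_SETS[[p]]
    if (is.null(allowed)) abort(paste0("unknown IUPAC code in pattern: ", p))
    w %in% allowed
  })
  sum(!unlist(ok))
}
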