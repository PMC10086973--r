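# Shared sequence helpers. All coordinates in this package are 1-based closed
# intervals; conversion to other conventions (BED) happens at I/O boundaries.

#' IUPAC nucleotide code table
#'
#' Maps each IUPAC nucleotide code to the set of concrete bases it stands for.
#' Used for PAM pattern matching and input validation.
#' @keywords internal
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_CHARS <- names(IUPAC_SETS)

#' Reverse-complement nucleotide sequences
#'
#' Vectorised reverse-complement honouring IUPAC ambiguity codes (and
#' preserving `-` gap characters).
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("TTTACG")  # "CGTAAA"
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTURYSWKMBDHVNacgturyswkmbdhvn",
                 "TGCAAYRSWMKVHDBNtgcaayrswmkvhdbn", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Convert an IUPAC pattern to a regular expression
#' @keywords internal
iupac_regex <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (is.null(set)) stop("invalid IUPAC code in pattern: ", ch, call. = FALSE)
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Test whether a concrete window matches an IUPAC pattern
#'
#' Ambiguity codes in the subject count as a mismatch: every subject position
#' must be a concrete A/C/G/T contained in the pattern's allowed set.
#' A gap anywhere in the subject is a non-match.
#' @keywords internal
iupac_window_match <- function(window, pattern) {
  if (nchar(window) != nchar(pattern)) return(FALSE)
  w <- strsplit(window, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  all(vapply(seq_along(w), function(i) {
    set <- IUPAC_SETS[[p[i]]]
    w[i] %in% c("A", "C", "G", "T") && w[i] %in% set
  }, logical(1)))
}

#' Longest homopolymer run in a sequence
#' @keywords internal
max_homopolymer_run <- function(seq) {
  if (nchar(seq) == 0L) return(0L)
  r <- rle(strsplit(seq, "")[[1]])
  max(r$lengths)
}

# Positions (1-based) of every match of an IUPAC pattern on the forward
# strand, including overlapping matches.
iupac_match_positions <- function(sequence, pattern) {
  if (nchar(sequence) < nchar(pattern)) return(integer(0))
  rx <- paste0("(?=", iupac_regex(pattern), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# Do two closed intervals [s1,e1], [s2,e2] intersect?
intervals_intersect <- function(s1, e1, s2, e2) {
  s1 <= e2 & s2 <= e1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
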