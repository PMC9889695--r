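# IUPAC degenerate nucleotide alphabet: per-position allowed-base sets, the
# complement table, and the bitmask encodings the window matcher runs on.

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

.BASE_BIT <- c(A = 1L, C = 2L, G = 4L, T = 8L)

# Subject (genome) alphabet is A/C/G/T/N. N carries its own bit so that an
# ambiguous genome base can only satisfy a pattern position allowing every
# base: we never claim a match the sequence cannot guarantee.
.SUBJECT_BIT <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 16L)

.SUBJECT_LUT <- local({
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt(paste(names(.SUBJECT_BIT), collapse = ""))] <- unname(.SUBJECT_BIT)
  lut
})

#' Parse an IUPAC degenerate consensus pattern
#'
#' Expands a consensus motif written in the 15-letter IUPAC nucleotide
#' alphabet (e.g. the E box `CANNTG`, where `N` = any base) into the set of
#' bases allowed at each position. Matching is case-insensitive.
#'
#' @param pattern A single nonempty pattern string over the IUPAC codes
#'   `A C G T R Y S W K M B D H V N`.
#' @return A list with one element per pattern position, each a character
#'   vector of allowed bases; names are the (uppercased) pattern characters.
#' @examples
#' parse_iupac("CANNTG")
#' parse_iupac("R") # list(R = c("A", "G"))
#' @export
parse_iupac <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern) ||
      !nzchar(pattern)) {
    stop("`pattern` must be a single nonempty string", call. = FALSE)
  }
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(.IUPAC_SETS))
  if (length(bad)) {
    stop(sprintf(
      "invalid IUPAC code '%s' at position %d of pattern '%s'",
      chars[bad[1]], bad[1], pattern
    ), call. = FALSE)
  }
  .IUPAC_SETS[chars]
}

#' Reverse-complement an IUPAC pattern
#'
#' Reverses the pattern and complements every position using the IUPAC
#' complement table (R<->Y, K<->M, B<->V, D<->H; S, W and N are their own
#' complements). A concrete sequence matches `pattern` if and only if its
#' reverse complement matches `reverse_complement_pattern(pattern)`, which is
#' how minus-strand scanning is implemented.
#'
#' @inheritParams parse_iupac
#' @return The reverse-complemented pattern string (uppercase).
#' @examples
#' reverse_complement_pattern("TTGACC") # "GGTCAA"
#' reverse_complement_pattern("CANNTG") # palindromic: "CANNTG"
#' @export
reverse_complement_pattern <- function(pattern) {
  parse_iupac(pattern) # validates
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  paste(rev(unname(.IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Reverse-complement concrete nucleotide sequences
#'
#' @param sequence Character vector of sequences over `A/C/G/T/N`
#'   (case preserved per character).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("TTGACC")
#' @export
reverse_complement <- function(sequence) {
  flipped <- chartr("ACGTNacgtn", "TGCANtgcan", sequence)
  vapply(
    strsplit(flipped, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  )
}

# Bitmask per pattern position; the full set (N) additionally accepts a
# subject N.
.pattern_masks <- function(pattern) {
  sets <- parse_iupac(pattern)
  masks <- vapply(sets, function(s) sum(.BASE_BIT[s]), numeric(1))
  masks <- as.integer(masks)
  masks[masks == 15L] <- 31L
  masks
}

.encode_subject <- function(sequence) {
  if (!nzchar(sequence)) {
    return(integer(0))
  }
  ints <- utf8ToInt(sequence)
  if (any(ints > 127L)) {
    stop("sequence contains non-ASCII characters", call. = FALSE)
  }
  codes <- .SUBJECT_LUT[ints]
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    stop(sprintf(
      "invalid sequence character '%s' at position %d (alphabet is A/C/G/T/N)",
      substr(sequence, bad, bad), bad
    ), call. = FALSE)
  }
  codes
}

# 0-based start offsets of all windows of `subject` satisfying `masks`.
.match_starts <- function(subject, masks) {
  len <- length(masks)
  n <- length(subject)
  if (len == 0L || n < len) {
    return(integer(0))
  }
  ok <- bitwAnd(subject[seq_len(n - len + 1L)], masks[1]) != 0L
  if (len > 1L) {
    for (j in 2:len) {
      ok <- ok & bitwAnd(subject[j:(n - len + j)], masks[j]) != 0L
    }
  }
  which(ok) - 1L
}
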