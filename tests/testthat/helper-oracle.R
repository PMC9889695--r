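# Naive window-matching oracle, kept deliberately independent of the
# package's bitmask matcher: its own IUPAC tables, per-position set
# membership via %in%, and minus-strand hits decided by reverse-complementing
# the *window* (the implementation reverse-complements the pattern instead).

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(ORACLE_COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# subject char vs pattern code: N in the subject only satisfies pattern N
oracle_char_match <- function(ch, code) {
  allowed <- ORACLE_IUPAC[[code]]
  if (ch == "N") length(allowed) == 4L else ch %in% allowed
}

oracle_window_match <- function(window, pattern) {
  wc <- strsplit(window, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  all(mapply(oracle_char_match, wc, pc))
}

# all (start, strand) hits of `pattern` in `sequence`, 0-based half-open
oracle_scan <- function(sequence, pattern, strands = "both") {
  len <- nchar(pattern)
  n <- nchar(sequence)
  hits <- list()
  if (n >= len) {
    for (s in 0:(n - len)) {
      window <- substr(sequence, s + 1, s + len)
      if (oracle_window_match(window, pattern)) {
        hits[[length(hits) + 1]] <- data.frame(
          start = s, end = s + len, strand = "+"
        )
      }
      if (strands == "both" &&
          oracle_window_match(oracle_revcomp(window), pattern)) {
        hits[[length(hits) + 1]] <- data.frame(
          start = s, end = s + len, strand = "-"
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(
      start = integer(0), end = integer(0), strand = character(0)
    ))
  }
  do.call(rbind, hits)
}

random_sequence <- function(len, p_n = 0.02) {
  paste(
    sample(c("A", "C", "G", "T", "N"), len,
      replace = TRUE,
      prob = c(rep((1 - p_n) / 4, 4), p_n)
    ),
    collapse = ""
  )
}

# concrete bases weighted up so random patterns still produce hits
random_pattern <- function(len) {
  codes <- c(rep(c("A", "C", "G", "T"), 3), names(ORACLE_IUPAC))
  paste(sample(codes, len, replace = TRUE), collapse = "")
}

# write a catalog tibble out as TSV in load_catalog()'s dialect
write_catalog_tsv <- function(catalog, path) {
  flat <- data.frame(
    cre_id = catalog$cre_id,
    display_name = catalog$display_name,
    variants = vapply(catalog$variants, paste, "", collapse = ","),
    tfs = vapply(catalog$tfs, paste, "", collapse = ","),
    tags = vapply(catalog$tags, paste, "", collapse = ",")
  )
  readr::write_tsv(flat, path, progress = FALSE)
  path
}
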