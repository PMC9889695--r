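# Exhaustive window scanning of promoters against the motif catalog, on both
# strands, reduced to a gene x CRE presence matrix.
#
# Every window of each variant's length is tested; overlapping occurrences
# are all reported (no greedy consumption) because presence/absence, not
# counts, drives the headline statistic. A minus-strand hit at [start, end)
# means the reverse complement of that forward window matches the variant;
# it is found by scanning the reverse-complemented pattern forward.

.empty_occurrences <- function() {
  tibble::tibble(
    gene_id = character(0), cre_id = character(0), variant = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    matched = character(0)
  )
}

.as_motif <- function(motif) {
  if (is.data.frame(motif)) {
    if (nrow(motif) != 1L) {
      stop("`motif` must be a single catalog row", call. = FALSE)
    }
    list(cre_id = motif$cre_id, variants = motif$variants[[1]])
  } else {
    list(
      cre_id = motif$cre_id %||% "motif",
      variants = unlist(motif$variants)
    )
  }
}

#' Scan one sequence for all occurrences of a CRE group
#'
#' @param sequence A promoter string over `A/C/G/T/N` (any case).
#' @param motif A one-row catalog tibble or a `list(cre_id =, variants =)`.
#' @param strands Scan `"both"` strands (default) or `"forward"` only.
#' @return Occurrence tibble: `cre_id`, `variant`, `start`/`end` (0-based
#'   half-open offsets in the promoter string), `strand` (relative to the
#'   promoter), `matched` (the forward-strand substring; for a `-` hit its
#'   reverse complement satisfies the variant). Sorted by start, strand
#'   (`+` before `-`), variant. Self-reverse-complementary patterns report
#'   both strands at the same window.
#' @examples
#' scan_sequence("AACATGTGAA", list(cre_id = "E_BOX", variants = "CANNTG"))
#' @export
scan_sequence <- function(sequence, motif, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  m <- .as_motif(motif)
  catalog <- tibble::tibble(
    cre_id = m$cre_id, variants = list(unique(toupper(m$variants)))
  )
  occ <- scan_promoters(
    tibble::tibble(gene_id = ".seq", sequence = sequence),
    catalog,
    strands = strands
  )
  occ$gene_id <- NULL
  occ
}

#' Scan a set of promoters against a motif catalog
#'
#' @param promoters Tibble with at least `gene_id` and `sequence` (e.g. from
#'   [extract_promoters()]); gene ids must be unique.
#' @param catalog Catalog tibble (see [load_catalog()]).
#' @inheritParams scan_sequence
#' @return Long occurrence tibble with a leading `gene_id` column (see
#'   [scan_sequence()]), ordered by promoter, then start/strand/variant.
#' @export
scan_promoters <- function(promoters, catalog, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (!all(c("gene_id", "sequence") %in% names(promoters))) {
    stop("`promoters` needs columns gene_id and sequence", call. = FALSE)
  }
  if (anyDuplicated(promoters$gene_id)) {
    stop("duplicate gene_id among promoters: ",
      promoters$gene_id[duplicated(promoters$gene_id)][1],
      call. = FALSE
    )
  }
  vt <- catalog |>
    dplyr::select("cre_id", "variants") |>
    tidyr::unnest("variants") |>
    dplyr::rename(variant = "variants") |>
    dplyr::distinct()
  vt$variant <- toupper(vt$variant)
  vt$fw_masks <- lapply(vt$variant, .pattern_masks)
  vt$rc_masks <- lapply(
    vt$variant,
    function(v) .pattern_masks(reverse_complement_pattern(v))
  )

  per_gene <- purrr::map(seq_len(nrow(promoters)), function(i) {
    seq_up <- toupper(promoters$sequence[i])
    subject <- .encode_subject(seq_up)
    hits <- purrr::map(seq_len(nrow(vt)), function(j) {
      len <- nchar(vt$variant[j])
      starts <- .match_starts(subject, vt$fw_masks[[j]])
      out <- tibble::tibble(
        cre_id = vt$cre_id[j], variant = vt$variant[j],
        start = starts, end = starts + len, strand = "+"
      )
      if (strands == "both") {
        starts_rc <- .match_starts(subject, vt$rc_masks[[j]])
        out <- dplyr::bind_rows(out, tibble::tibble(
          cre_id = vt$cre_id[j], variant = vt$variant[j],
          start = starts_rc, end = starts_rc + len, strand = "-"
        ))
      }
      out
    }) |>
      dplyr::bind_rows()
    if (nrow(hits) == 0L) {
      return(NULL)
    }
    hits$gene_id <- promoters$gene_id[i]
    hits$matched <- substring(seq_up, hits$start + 1L, hits$end)
    hits
  })
  occ <- dplyr::bind_rows(per_gene)
  if (nrow(occ) == 0L) {
    return(.empty_occurrences())
  }
  occ |>
    dplyr::relocate("gene_id") |>
    dplyr::arrange(
      match(.data$gene_id, promoters$gene_id), .data$start,
      match(.data$strand, c("+", "-")), .data$variant
    )
}

#' Reduce occurrences to a gene x CRE presence matrix
#'
#' A gene is called present for a CRE group when its promoter holds at least
#' `min_occurrences` distinct occurrence windows of any variant on either
#' strand. A palindromic pattern reporting `+` and `-` hits at the same
#' window counts as one window.
#'
#' @inheritParams scan_promoters
#' @param min_occurrences Minimum number of distinct occurrence windows for a
#'   presence call (default 1).
#' @param occurrences Optional precomputed occurrence tibble from
#'   [scan_promoters()] (skips rescanning).
#' @return A wide tibble: `gene_id` plus one logical column per catalog
#'   `cre_id`, rows in promoter order, columns in catalog order.
#' @export
build_presence_matrix <- function(promoters, catalog,
                                  strands = c("both", "forward"),
                                  min_occurrences = 1,
                                  occurrences = NULL) {
  strands <- match.arg(strands)
  if (anyDuplicated(promoters$gene_id)) {
    stop("duplicate gene_id among promoters: ",
      promoters$gene_id[duplicated(promoters$gene_id)][1],
      call. = FALSE
    )
  }
  occ <- occurrences %||% scan_promoters(promoters, catalog, strands = strands)
  counts <- occ |>
    dplyr::distinct(.data$gene_id, .data$cre_id, .data$start, .data$end) |>
    dplyr::count(.data$gene_id, .data$cre_id, name = "n_windows")
  tidyr::expand_grid(
    gene_id = promoters$gene_id, cre_id = catalog$cre_id
  ) |>
    dplyr::left_join(counts, by = c("gene_id", "cre_id")) |>
    dplyr::mutate(
      present = dplyr::coalesce(.data$n_windows, 0L) >= min_occurrences
    ) |>
    dplyr::select(-"n_windows") |>
    tidyr::pivot_wider(names_from = "cre_id", values_from = "present")
}

#' Write motif occurrences as BED6
#'
#' Promoter-relative coordinates; `name` is `cre_id:variant`, score 0.
#'
#' @param occurrences Occurrence tibble from [scan_promoters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences_bed <- function(occurrences, path) {
  bed <- tibble::tibble(
    chrom = occurrences$gene_id,
    start = occurrences$start,
    end = occurrences$end,
    name = paste0(occurrences$cre_id, ":", occurrences$variant),
    score = 0L,
    strand = occurrences$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
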