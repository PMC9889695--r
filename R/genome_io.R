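# Genome and annotation input, promoter window extraction.
#
# Coordinates are 0-based half-open internally; GFF3 (1-based inclusive) is
# converted on read and all human-facing output (FASTA headers) prints
# 1-based inclusive again.

#' Read a multi-record FASTA file into a tibble
#'
#' Sequences are uppercased, whitespace inside records is stripped, and any
#' character outside `A/C/G/T/N` is mapped to `N` with a warning.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped records).
#' @return A tibble with columns `seq_id` (first word of each header),
#'   `sequence` and `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("failed to parse FASTA file ", path, ": ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  if (length(set) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  seqs <- gsub("[[:space:]]", "", toupper(as.character(set)))
  n_bad <- sum(nchar(seqs) - nchar(gsub("[^ACGTN]", "", seqs)))
  if (n_bad > 0) {
    bad_ids <- ids[grepl("[^ACGTN]", seqs)]
    warning(sprintf(
      "mapped %d non-ACGTN character(s) to N in record(s): %s",
      n_bad, paste(bad_ids, collapse = ", ")
    ), call. = FALSE)
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  tibble::tibble(seq_id = ids, sequence = unname(seqs), length = nchar(seqs))
}

#' Read gene models from a GFF3 or BED6 annotation
#'
#' For GFF3, one gene model is built per feature of type `gene`; the anchor
#' (TSS) is the 5'-most coordinate on the `+` strand and the 3'-most file
#' coordinate on the `-` strand, converted to a 0-based position of the
#' transcription start base. For BED6 the anchor is the interval's 5' end.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"bed"` (BED6).
#' @return A tibble of gene models: `gene_id`, `chrom`, `strand` (`+`/`-`),
#'   `tss` (0-based), `label` (initialised to `"none"`; see
#'   [attach_gene_labels()]).
#' @export
read_gene_annotations <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  genes <- if (format == "gff3") .read_gff3_genes(path) else .read_bed6(path)
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad)) {
    stop(
      "unknown strand '", genes$strand[bad][1], "' for gene '",
      genes$gene_id[bad][1], "' (must be '+' or '-')",
      call. = FALSE
    )
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in annotation: ",
      genes$gene_id[duplicated(genes$gene_id)][1],
      call. = FALSE
    )
  }
  genes$label <- "none"
  genes
}

.read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df <- df[!is.na(df$type) & df$type == "gene", , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("no features of type 'gene' in ", path, call. = FALSE)
  }
  ids <- if ("ID" %in% names(df)) df$ID else rep(NA_character_, nrow(df))
  if (anyNA(ids)) {
    stop("GFF3 gene feature without an ID attribute in ", path, call. = FALSE)
  }
  strand <- as.character(df$strand)
  tibble::tibble(
    gene_id = as.character(ids),
    chrom = as.character(df$seqnames),
    strand = strand,
    # 1-based inclusive -> 0-based position of the 5'-most transcribed base
    tss = ifelse(strand == "+", df$start - 1L, df$end - 1L)
  )
}

.read_bed6 <- function(path) {
  df <- readr::read_tsv(path,
    col_names = FALSE, comment = "#", col_types = readr::cols(.default = "c"),
    progress = FALSE
  )
  if (ncol(df) < 6L) {
    stop("BED6 annotation requires 6 columns (chrom, start, end, name, ",
      "score, strand); got ", ncol(df), " in ", path,
      call. = FALSE
    )
  }
  start <- as.integer(df[[2]])
  end <- as.integer(df[[3]])
  strand <- df[[6]]
  tibble::tibble(
    gene_id = df[[4]],
    chrom = df[[1]],
    strand = strand,
    # BED is already 0-based half-open
    tss = ifelse(strand == "+", start, end - 1L)
  )
}

#' Read a two-column gene-set label TSV
#'
#' The file holds one `gene_id<TAB>label` row per labeled gene with label
#' `up` or `down`; a header row `gene_id  label` is accepted and skipped.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene_id`, `label`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) {
    stop("gene-set file not found: ", path, call. = FALSE)
  }
  df <- readr::read_tsv(path,
    col_names = c("gene_id", "label"), comment = "#",
    col_types = "cc", progress = FALSE
  )
  if (nrow(df) && df$gene_id[1] == "gene_id" && df$label[1] == "label") {
    df <- df[-1, , drop = FALSE]
  }
  if (nrow(df) == 0L) {
    stop("no gene labels in ", path, call. = FALSE)
  }
  bad <- !df$label %in% c("up", "down")
  if (any(bad)) {
    stop("invalid gene-set label '", df$label[bad][1], "' for gene '",
      df$gene_id[bad][1], "' (must be 'up' or 'down')",
      call. = FALSE
    )
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in gene-set file: ",
      df$gene_id[duplicated(df$gene_id)][1],
      call. = FALSE
    )
  }
  df
}

#' Attach up/down labels to gene models
#'
#' @param genes Gene-model tibble from [read_gene_annotations()].
#' @param gene_sets Label tibble from [read_gene_sets()] (or any data frame
#'   with `gene_id`, `label`).
#' @return `genes` with its `label` column set to `up`/`down` for listed
#'   genes and `none` otherwise.
#' @export
attach_gene_labels <- function(genes, gene_sets) {
  missing <- setdiff(gene_sets$gene_id, genes$gene_id)
  if (length(missing)) {
    warning(length(missing), " labeled gene(s) absent from the annotation: ",
      paste(utils::head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  genes |>
    dplyr::select(-dplyr::any_of("label")) |>
    dplyr::left_join(gene_sets, by = "gene_id") |>
    dplyr::mutate(label = dplyr::coalesce(.data$label, "none"))
}

#' Extract strand-aware upstream promoter windows
#'
#' For a `+` strand gene the promoter is the forward-strand window
#' `[tss - length, tss)`; for a `-` strand gene it is the forward-strand
#' window `[tss + 1, tss + 1 + length)` reported reverse-complemented, so the
#' returned string always reads 5'->3' toward the transcription start. The
#' TSS base itself is excluded. Windows are clipped at chromosome bounds and
#' flagged `truncated`; truncated genes are retained, not dropped.
#'
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `strand`, `tss`, and
#'   optionally `label`).
#' @param genome Tibble from [read_fasta()] or a named character vector of
#'   chromosome sequences.
#' @param length Window length in bases upstream of the TSS (default 3000,
#'   i.e. the 3-kb promoter).
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `window_start`/`window_end` (0-based half-open, forward strand),
#'   `sequence` (promoter orientation), `truncated`, `requested_length`, and
#'   `label` when present in `genes`.
#' @export
extract_promoters <- function(genes, genome, length = 3000) {
  if (length < 1) {
    stop("`length` must be >= 1", call. = FALSE)
  }
  seqs <- if (is.data.frame(genome)) {
    stats::setNames(genome$sequence, genome$seq_id)
  } else {
    genome
  }
  missing <- setdiff(unique(genes$chrom), names(seqs))
  if (base::length(missing)) {
    stop("chromosome(s) absent from genome: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  rows <- purrr::pmap(
    list(genes$gene_id, genes$chrom, genes$strand, genes$tss),
    function(gene_id, chrom, strand, tss) {
      chrom_seq <- seqs[[chrom]]
      clen <- nchar(chrom_seq)
      if (tss < 0 || tss >= clen) {
        stop(sprintf(
          "gene '%s': tss %d outside chromosome '%s' (length %d)",
          gene_id, tss, chrom, clen
        ), call. = FALSE)
      }
      if (strand == "+") {
        ws <- max(0, tss - length)
        we <- tss
        sequence <- substr(chrom_seq, ws + 1, we)
      } else if (strand == "-") {
        ws <- tss + 1
        we <- min(clen, tss + 1 + length)
        sequence <- reverse_complement(substr(chrom_seq, ws + 1, we))
      } else {
        stop("gene '", gene_id, "': strand must be '+' or '-'", call. = FALSE)
      }
      truncated <- nchar(sequence) < length
      if (nchar(sequence) == 0L) {
        rlang::inform(paste0(
          "gene '", gene_id, "' has a zero-length promoter window"
        ))
      }
      tibble::tibble(
        gene_id = gene_id, chrom = chrom, strand = strand,
        window_start = as.integer(ws), window_end = as.integer(we),
        sequence = sequence, truncated = truncated,
        requested_length = as.integer(length)
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  if ("label" %in% names(genes)) {
    out$label <- genes$label
    out <- dplyr::relocate(out, "label", .after = "gene_id")
  }
  out
}

#' Write promoter sequences to FASTA
#'
#' Headers have the form
#' `>gene_id window=chrom:start-end(strand) truncated={0,1}` with the window
#' printed 1-based inclusive.
#'
#' @param promoters Tibble from [extract_promoters()].
#' @param path Output file path.
#' @param wrap Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path, wrap = 70) {
  lines <- purrr::pmap(
    promoters[c(
      "gene_id", "chrom", "strand", "window_start", "window_end",
      "sequence", "truncated"
    )],
    function(gene_id, chrom, strand, window_start, window_end, sequence,
             truncated) {
      header <- sprintf(
        ">%s window=%s:%d-%d(%s) truncated=%d",
        gene_id, chrom, window_start + 1L, window_end, strand,
        as.integer(truncated)
      )
      body <- if (nzchar(sequence)) {
        starts <- seq(1, nchar(sequence), by = wrap)
        substring(sequence, starts, pmin(starts + wrap - 1, nchar(sequence)))
      } else {
        character(0)
      }
      c(header, body)
    }
  )
  writeLines(unlist(lines), path)
  invisible(path)
}
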