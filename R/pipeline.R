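# End-to-end orchestration: sequence mode (genome + annotation + labels +
# catalog -> promoters -> occurrences -> presence -> representation) and
# classification-only mode (precomputed percent table). A plain key=value
# config file mirrors every option; call-time arguments override it.

.PIPELINE_DEFAULTS <- list(
  promoter_length = 3000,
  strands = "both",
  min_occurrences = 1,
  over = 0.75,
  moderate_low = 0.50,
  drop_truncated = FALSE,
  annotation_format = NULL # inferred from the file extension when NULL
)

#' Read a plain-text pipeline configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Known numeric and
#' logical keys are coerced.
#'
#' @param path Path to the config file.
#' @return A named list of options for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad)) {
    stop("config line without '=': '", lines[bad][1], "'", call. = FALSE)
  }
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  config <- stats::setNames(as.list(vals), keys)
  numeric_keys <- c(
    "promoter_length", "min_occurrences", "over", "moderate_low", "seed"
  )
  for (k in intersect(numeric_keys, names(config))) {
    config[[k]] <- as.numeric(config[[k]])
  }
  for (k in intersect("drop_truncated", names(config))) {
    config[[k]] <- toupper(config[[k]]) %in% c("TRUE", "1", "YES")
  }
  config
}

.check_input_file <- function(path, what) {
  if (is.null(path)) {
    stop("config is missing required input: ", what, call. = FALSE)
  }
  if (!file.exists(path)) {
    stop(what, " file not found: ", path, call. = FALSE)
  }
  path
}

#' Run the promoter CRE analysis pipeline
#'
#' In sequence mode (config supplies `genome`, `annotation`, `gene_sets`,
#' `catalog`) the pipeline extracts promoters, scans them, builds the
#' presence matrix, computes per-CRE representation for the up and down gene
#' sets, compares the sets at every tier, and rolls results up by functional
#' category. In percent-table mode (config supplies `percent_table`) only
#' classification and comparison run. All result tables are written under
#' `out_dir`; timestamps appear only in the run log, so reruns on identical
#' inputs produce byte-identical tables.
#'
#' @param config A named list of options, or the path to a key=value config
#'   file (see [read_pipeline_config()]). Recognised keys: `genome`,
#'   `annotation`, `annotation_format` (`gff3`/`bed`), `gene_sets`,
#'   `catalog`, `percent_table`, `promoter_length`, `strands`,
#'   `min_occurrences`, `over`, `moderate_low`, `drop_truncated`, `out_dir`.
#'   Exactly one of `percent_table` or the sequence-mode inputs must be
#'   supplied.
#' @param ... Individual options overriding `config`.
#' @return Invisibly, a list with the `representation` object, the
#'   per-tier `comparisons`, the `files` written, and in sequence mode the
#'   intermediate `promoters`, `occurrences` and `presence` tables.
#' @export
run_pipeline <- function(config = list(), ...) {
  if (is.character(config)) {
    config <- read_pipeline_config(config)
  }
  overrides <- list(...)
  config <- utils::modifyList(config, overrides)
  config <- utils::modifyList(.PIPELINE_DEFAULTS, config)

  if (is.null(config$out_dir)) {
    stop("config must name an out_dir", call. = FALSE)
  }
  sequence_mode <- !is.null(config$genome) || !is.null(config$annotation) ||
    !is.null(config$gene_sets) || !is.null(config$catalog)
  table_mode <- !is.null(config$percent_table)
  if (sequence_mode == table_mode) {
    stop("supply either sequence-mode inputs (genome, annotation, ",
      "gene_sets, catalog) or a percent_table, not both",
      call. = FALSE
    )
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  thresholds <- representation_thresholds(
    over = config$over, moderate_low = config$moderate_low
  )
  files <- list()
  out <- function(name) file.path(config$out_dir, name)

  if (table_mode) {
    .check_input_file(config$percent_table, "percent_table")
    representation <- classify_percent_table(config$percent_table, thresholds)
    result <- list()
  } else {
    genome <- read_fasta(.check_input_file(config$genome, "genome"))
    fmt <- config$annotation_format %||%
      (if (grepl("\\.bed$", config$annotation, ignore.case = TRUE)) "bed" else "gff3")
    genes <- read_gene_annotations(
      .check_input_file(config$annotation, "annotation"),
      format = fmt
    )
    labels <- read_gene_sets(.check_input_file(config$gene_sets, "gene_sets"))
    catalog <- load_catalog(.check_input_file(config$catalog, "catalog"))
    genes <- attach_gene_labels(genes, labels)
    if (!any(genes$label %in% c("up", "down"))) {
      stop("no annotated genes carry an up/down label", call. = FALSE)
    }
    promoters <- extract_promoters(
      genes, genome,
      length = config$promoter_length
    )
    if (isTRUE(config$drop_truncated)) {
      promoters <- dplyr::filter(promoters, !.data$truncated)
    }
    occurrences <- scan_promoters(promoters, catalog,
      strands = config$strands
    )
    presence <- build_presence_matrix(promoters, catalog,
      strands = config$strands,
      min_occurrences = config$min_occurrences,
      occurrences = occurrences
    )
    representation <- analyze_representation(
      presence,
      promoters[c("gene_id", "label")],
      thresholds
    )

    files$promoters <- write_promoters_fasta(promoters, out("promoters.fasta"))
    readr::write_tsv(occurrences, out("occurrences.tsv"), progress = FALSE)
    files$occurrences <- out("occurrences.tsv")
    files$occurrences_bed <- write_occurrences_bed(
      occurrences, out("occurrences.bed")
    )
    presence_int <- dplyr::mutate(
      presence, dplyr::across(-"gene_id", as.integer)
    )
    readr::write_tsv(presence_int, out("presence_matrix.tsv"), progress = FALSE)
    files$presence <- out("presence_matrix.tsv")

    annotated <- annotate_results(representation, catalog)
    files$annotated <- write_annotated_table(annotated, out("annotated.tsv"))
    category <- summarize_categories(annotated)
    readr::write_tsv(category, out("category_summary.tsv"), progress = FALSE)
    files$category_summary <- out("category_summary.tsv")
    result <- list(
      promoters = promoters, occurrences = occurrences, presence = presence
    )
  }

  results_tbl <- tidy(representation)
  readr::write_tsv(
    dplyr::mutate(results_tbl, tier = as.character(.data$tier)),
    out("representation.tsv"),
    progress = FALSE
  )
  files$representation <- out("representation.tsv")

  comparisons <- lapply(
    stats::setNames(.TIER_LEVELS, .TIER_LEVELS),
    function(t) compare_gene_sets(representation, tier = t)
  )
  comparison_tbl <- dplyr::bind_rows(
    lapply(.TIER_LEVELS, function(t) {
      tbl <- tidy(comparisons[[t]])
      if (nrow(tbl)) tbl$tier <- t
      tbl
    })
  )
  readr::write_tsv(comparison_tbl, out("comparison.tsv"), progress = FALSE)
  files$comparison <- out("comparison.tsv")

  jsonlite::write_json(
    count_tiers(representation) |>
      dplyr::mutate(tier = as.character(.data$tier)),
    out("tier_counts.json"),
    dataframe = "rows", auto_unbox = TRUE
  )
  files$tier_counts <- out("tier_counts.json")

  log_lines <- c(
    paste0("crescan version: ", as.character(utils::packageVersion("crescan"))),
    paste0("R version: ", R.version.string),
    paste0("time: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("mode: ", if (table_mode) "percent_table" else "sequence"),
    "config:",
    paste0(
      "  ", names(config), " = ",
      vapply(config, function(v) paste(format(v), collapse = ","), character(1))
    )
  )
  writeLines(log_lines, out("run_log.txt"))
  files$run_log <- out("run_log.txt")

  invisible(c(
    list(
      representation = representation, comparisons = comparisons,
      files = files, config = config
    ),
    result
  ))
}
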