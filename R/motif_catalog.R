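# Motif catalog: named CRE groups, each a set of IUPAC consensus variants
# plus the transcription factors known to bind them and functional tags.
#
# A gene "carries" a CRE group when any variant matches its promoter on
# either strand: published CRE tables group several binding-motif variants
# (e.g. MYB1-4 under one MYB-binding-site row) under a single percent, so
# OR-over-variants is the group semantics throughout.

.CATALOG_COLUMNS <- c("cre_id", "display_name", "variants", "tfs", "tags")

#' Construct a motif catalog in code
#'
#' @param cre_id Character vector of unique CRE group identifiers.
#' @param variants List of character vectors of IUPAC consensus patterns
#'   (one vector per CRE group), or a single character vector when building
#'   a one-group catalog.
#' @param display_name Human-readable names (defaults to `cre_id`).
#' @param tfs List of character vectors of interacting TF names.
#' @param tags List of character vectors of functional category tags
#'   (`growth`/`stress`/`light` plus free hormone tags such as `ABA`, `JA`).
#' @return A validated catalog tibble with list-columns `variants`, `tfs`,
#'   `tags`.
#' @examples
#' motif_catalog("W_BOX", c("TTGACC", "TTGACT"),
#'   tfs = list("WRKY"), tags = list(c("stress", "SA"))
#' )
#' @export
motif_catalog <- function(cre_id, variants, display_name = cre_id,
                          tfs = NULL, tags = NULL) {
  if (is.character(variants)) variants <- list(variants)
  n <- length(cre_id)
  catalog <- tibble::tibble(
    cre_id = cre_id,
    display_name = display_name,
    variants = variants,
    tfs = tfs %||% rep(list(character(0)), n),
    tags = tags %||% rep(list(character(0)), n)
  )
  .validate_catalog(catalog)
}

#' Load a motif catalog from TSV
#'
#' Expects a header row and columns `cre_id`, `display_name`, `variants`,
#' `tfs`, `tags`; the last three are comma-separated within a cell. Every
#' variant must parse as an IUPAC pattern; variants shorter than 4 bases are
#' accepted with a warning (their background hit rate is high enough that a
#' presence call carries little information).
#'
#' @param path Path to the catalog TSV.
#' @return A validated catalog tibble (see [motif_catalog()]).
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) {
    stop("catalog file not found: ", path, call. = FALSE)
  }
  df <- readr::read_tsv(path,
    comment = "#", col_types = readr::cols(.default = "c"), progress = FALSE
  )
  missing <- setdiff(.CATALOG_COLUMNS, names(df))
  if (length(missing)) {
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  split_cell <- function(x) {
    purrr::map(x, function(cell) {
      if (is.na(cell) || !nzchar(cell)) {
        return(character(0))
      }
      parts <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
      parts[nzchar(parts)]
    })
  }
  catalog <- tibble::tibble(
    cre_id = df$cre_id,
    display_name = dplyr::coalesce(df$display_name, df$cre_id),
    variants = split_cell(df$variants),
    tfs = split_cell(df$tfs),
    tags = split_cell(df$tags)
  )
  .validate_catalog(catalog)
}

.validate_catalog <- function(catalog) {
  if (anyDuplicated(catalog$cre_id)) {
    stop("duplicate cre_id in catalog: ",
      catalog$cre_id[duplicated(catalog$cre_id)][1],
      call. = FALSE
    )
  }
  catalog$variants <- purrr::map2(
    catalog$variants, catalog$cre_id,
    function(vars, id) {
      vars <- unique(toupper(vars))
      if (length(vars) == 0L) {
        stop("catalog row '", id, "' has no variants", call. = FALSE)
      }
      for (v in vars) {
        tryCatch(parse_iupac(v), error = function(e) {
          stop("catalog row '", id, "': ", conditionMessage(e), call. = FALSE)
        })
      }
      short <- vars[nchar(vars) < 4]
      if (length(short)) {
        warning("catalog row '", id, "': variant(s) shorter than 4 bases (",
          paste(short, collapse = ", "),
          ") will match the background frequently",
          call. = FALSE
        )
      }
      vars
    }
  )
  catalog
}

#' Bundled example motif catalog
#'
#' A small catalog of widely used plant CRE consensus sequences (W box, GATA
#' box, E box, I box, ARR1-, Dof-, GT-1-, MYB-binding sites, ...). It is a
#' convenience fixture for examples, simulations and tests: the sequences
#' are common literature consensi and are not a transcription of any specific
#' database release.
#'
#' @return A catalog tibble (see [load_catalog()]).
#' @export
example_catalog <- function() {
  load_catalog(system.file("extdata", "example_catalog.tsv",
    package = "crescan", mustWork = TRUE
  ))
}

#' Export a catalog to minimal MEME motif format
#'
#' Each variant becomes one MEME motif named `<cre_id>.<variant>`; the
#' consensus is expanded to a letter-probability matrix with equal mass on
#' each allowed base of a position (so a concrete base gets 1.0 and `N` gets
#' 0.25 per base).
#'
#' @param catalog Catalog tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(catalog, path) {
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.25 C 0.25 G 0.25 T 0.25", ""
  )
  for (i in seq_len(nrow(catalog))) {
    for (v in catalog$variants[[i]]) {
      sets <- parse_iupac(v)
      mat <- vapply(sets, function(s) {
        p <- c(A = 0, C = 0, G = 0, T = 0)
        p[s] <- 1 / length(s)
        p
      }, numeric(4))
      lines <- c(
        lines,
        sprintf("MOTIF %s.%s", catalog$cre_id[i], v),
        sprintf(
          "letter-probability matrix: alength= 4 w= %d nsites= 1 E= 0",
          length(sets)
        ),
        apply(mat, 2, function(p) paste(sprintf("%.6f", p), collapse = " ")),
        ""
      )
    }
  }
  writeLines(lines, path)
  invisible(path)
}
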