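# Join classified CREs to their interacting transcription factors and
# functional category tags, and roll counts up per category.

#' Annotate representation results with TFs and functional tags
#'
#' @param results A `cre_representation` object or its tidy results tibble.
#' @param catalog Catalog tibble providing `display_name`, `tfs` and `tags`
#'   for every `cre_id` in the results.
#' @return The results tibble (input order preserved, representation fields
#'   untouched) with `display_name` and list-columns `tfs`, `tags` appended.
#' @export
annotate_results <- function(results, catalog) {
  res <- if (inherits(results, "cre_representation")) {
    tidy(results)
  } else {
    results
  }
  missing <- setdiff(unique(res$cre_id), catalog$cre_id)
  if (length(missing)) {
    stop("cre_id(s) missing from catalog: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  dplyr::left_join(
    res,
    dplyr::select(catalog, "cre_id", "display_name", "tfs", "tags"),
    by = "cre_id"
  )
}

#' Count CREs per functional category at one tier
#'
#' Category membership is multi-membership, not a partition: a CRE tagged
#' both `stress` and `light` contributes one count to each tag. Hence the
#' counts sum to at least the number of distinct CREs at the tier.
#'
#' @param annotated Annotated results from [annotate_results()].
#' @param tier Tier to summarize (default `"overrepresented"`).
#' @return Tibble `gene_set`, `tag`, `n_cres`; empty when no CRE sits at the
#'   tier.
#' @export
summarize_categories <- function(annotated, tier = "overrepresented") {
  tier <- match.arg(tier, .TIER_LEVELS)
  annotated |>
    dplyr::filter(.data$tier == !!tier) |>
    dplyr::select("gene_set", "cre_id", "tags") |>
    tidyr::unnest("tags") |>
    dplyr::distinct(.data$gene_set, .data$cre_id, .data$tags) |>
    dplyr::count(.data$gene_set, tag = .data$tags, name = "n_cres")
}

#' Write an annotated table in published-table shape
#'
#' One row per CRE: display name, interacting TFs, growth/stress/light
#' flags, remaining (hormone) tags, and the percent and tier per gene set.
#'
#' @param annotated Annotated results from [annotate_results()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotated_table <- function(annotated, path) {
  gsl <- c("growth", "stress", "light")
  wide <- annotated |>
    dplyr::mutate(
      tfs = purrr::map_chr(.data$tfs, paste, collapse = ","),
      G = purrr::map_lgl(.data$tags, ~ "growth" %in% .x),
      S = purrr::map_lgl(.data$tags, ~ "stress" %in% .x),
      L = purrr::map_lgl(.data$tags, ~ "light" %in% .x),
      other_tags = purrr::map_chr(
        .data$tags, ~ paste(setdiff(.x, gsl), collapse = ",")
      )
    ) |>
    dplyr::select(
      "cre_id", "display_name", "tfs", "G", "S", "L", "other_tags",
      "gene_set", "percent", "tier"
    ) |>
    tidyr::pivot_wider(
      names_from = "gene_set", values_from = c("percent", "tier")
    )
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Plot category counts per gene set
#'
#' @param category_summary Tibble from [summarize_categories()].
#' @return A ggplot bar chart of CRE counts per functional tag, faceted by
#'   gene set.
#' @export
plot_category_summary <- function(category_summary) {
  ggplot2::ggplot(
    category_summary,
    ggplot2::aes(
      x = .data$n_cres,
      y = stats::reorder(.data$tag, .data$n_cres)
    )
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~gene_set) +
    ggplot2::labs(x = "CREs carrying the tag", y = NULL) +
    ggplot2::theme_minimal()
}
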