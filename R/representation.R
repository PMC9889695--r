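# The percent-of-genes representation statistic and its three-tier
# classification: over-represented (>= 75% of promoters carry the CRE),
# moderately over-represented (50-74%) and under-represented (<= 49%).
#
# Tier boundaries are half-open intervals on the exact fraction —
# [0.75, 1] / [0.50, 0.75) / [0, 0.50) — the only partition consistent with
# the integer-percent phrasings ">=75%", "50-74%" and "<=49%". Classification
# always uses the exact rational fraction, never the rounded display percent,
# so a 74.5% fraction cannot be promoted by display rounding.

.TIER_LEVELS <- c(
  "underrepresented", "moderately_overrepresented", "overrepresented"
)

#' Representation tier thresholds
#'
#' @param over Fraction at or above which a CRE is over-represented
#'   (default 0.75).
#' @param moderate_low Lower bound of the moderately-over-represented band
#'   (default 0.50); fractions below it are under-represented.
#' @return A `representation_thresholds` object.
#' @export
representation_thresholds <- function(over = 0.75, moderate_low = 0.50) {
  if (!(moderate_low > 0 && moderate_low < over && over <= 1)) {
    stop("thresholds must satisfy 0 < moderate_low < over <= 1",
      call. = FALSE
    )
  }
  structure(
    list(over = over, moderate_low = moderate_low),
    class = "representation_thresholds"
  )
}

#' Classify presence fractions into representation tiers
#'
#' @param fraction Numeric vector of fractions in `[0, 1]`.
#' @param thresholds A [representation_thresholds()] object.
#' @return Ordered factor with levels `underrepresented <
#'   moderately_overrepresented < overrepresented`.
#' @examples
#' classify_representation(c(0.75, 0.50, 0.49))
#' @export
classify_representation <- function(fraction,
                                    thresholds = representation_thresholds()) {
  if (anyNA(fraction) || any(fraction < 0 | fraction > 1)) {
    stop("`fraction` values must lie in [0, 1]", call. = FALSE)
  }
  tier <- ifelse(
    fraction >= thresholds$over, .TIER_LEVELS[3],
    ifelse(fraction >= thresholds$moderate_low, .TIER_LEVELS[2], .TIER_LEVELS[1])
  )
  factor(tier, levels = .TIER_LEVELS, ordered = TRUE)
}

#' Percent of a gene set whose promoters carry a CRE
#'
#' @param presence Presence matrix tibble from [build_presence_matrix()].
#' @param gene_set Character vector of gene ids (must all be rows of the
#'   matrix); duplicates are dropped.
#' @param cre_id A single CRE column of the matrix.
#' @return One-row tibble: `cre_id`, `n_present`, `n_total`, `fraction`
#'   (exact), `percent` (= 100 * fraction, unrounded).
#' @export
percent_with_cre <- function(presence, gene_set, cre_id) {
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0L) {
    stop("`gene_set` is empty", call. = FALSE)
  }
  if (length(cre_id) != 1L || !cre_id %in% setdiff(names(presence), "gene_id")) {
    stop("unknown cre_id: ", cre_id, call. = FALSE)
  }
  missing <- setdiff(gene_set, presence$gene_id)
  if (length(missing)) {
    stop("gene(s) absent from presence matrix: ",
      paste(utils::head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  n_total <- length(gene_set)
  n_present <- sum(presence[[cre_id]][presence$gene_id %in% gene_set])
  tibble::tibble(
    cre_id = cre_id,
    n_present = as.integer(n_present),
    n_total = as.integer(n_total),
    fraction = n_present / n_total,
    percent = 100 * n_present / n_total
  )
}

.new_cre_representation <- function(results, thresholds, mode) {
  structure(
    list(results = results, thresholds = thresholds, mode = mode),
    class = "cre_representation"
  )
}

#' Representation analysis of up/down gene sets
#'
#' Computes, for every CRE in the presence matrix and each labeled gene set,
#' the fraction of the set's promoters carrying the CRE, and classifies it
#' into a representation tier. The denominator of each set is the full set
#' of labeled genes (truncated promoters included; drop them upstream to
#' change that).
#'
#' @param presence Presence matrix tibble from [build_presence_matrix()].
#' @param gene_labels Data frame with `gene_id` and `label`
#'   (`up`/`down`/`none`); every `up`/`down` gene must be a matrix row.
#' @param thresholds A [representation_thresholds()] object.
#' @return A `cre_representation` object; see [tidy.cre_representation()],
#'   [glance.cre_representation()], [count_tiers()], [compare_gene_sets()],
#'   [autoplot.cre_representation()].
#' @export
analyze_representation <- function(presence, gene_labels,
                                   thresholds = representation_thresholds()) {
  labs <- dplyr::filter(gene_labels, .data$label %in% c("up", "down"))
  if (nrow(labs) == 0L) {
    stop("no genes labeled 'up' or 'down'", call. = FALSE)
  }
  missing <- setdiff(labs$gene_id, presence$gene_id)
  if (length(missing)) {
    stop("labeled gene(s) absent from presence matrix: ",
      paste(utils::head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  cre_order <- setdiff(names(presence), "gene_id")
  long <- tidyr::pivot_longer(presence, -"gene_id",
    names_to = "cre_id", values_to = "present"
  )
  results <- labs |>
    dplyr::inner_join(long, by = "gene_id") |>
    dplyr::group_by(gene_set = .data$label, cre_id = .data$cre_id) |>
    dplyr::summarise(
      n_present = sum(.data$present), n_total = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(
      fraction = .data$n_present / .data$n_total,
      percent = 100 * .data$fraction,
      tier = classify_representation(.data$fraction, thresholds)
    ) |>
    dplyr::arrange(
      match(.data$cre_id, cre_order), match(.data$gene_set, c("up", "down"))
    ) |>
    dplyr::relocate("cre_id")
  .new_cre_representation(results, thresholds, mode = "sequence")
}

#' Read a precomputed percent table
#'
#' @param path TSV with header columns `cre_id`, `percent_up`,
#'   `percent_down`; a blank percent cell means the CRE is absent from that
#'   gene set's listing. Lines starting `#` are comments.
#' @return Tibble with those three columns (`NA` for blanks).
#' @export
read_percent_table <- function(path) {
  if (!file.exists(path)) {
    stop("percent table not found: ", path, call. = FALSE)
  }
  df <- readr::read_tsv(path, comment = "#", col_types = "cdd", progress = FALSE)
  needed <- c("cre_id", "percent_up", "percent_down")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("percent table is missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  df[needed]
}

#' Classify a precomputed percent table
#'
#' Classification-only mode: reanalyzes published per-CRE percent columns
#' without sequences. Blank (`NA`) cells are excluded from that gene set's
#' rows and tier counts.
#'
#' @param table A tibble with `cre_id`, `percent_up`, `percent_down`, or a
#'   path to such a TSV (see [read_percent_table()]).
#' @param thresholds A [representation_thresholds()] object.
#' @return A `cre_representation` object (with `n_present`/`n_total` unknown,
#'   `NA`).
#' @export
classify_percent_table <- function(table,
                                   thresholds = representation_thresholds()) {
  if (is.character(table) && length(table) == 1L) {
    table <- read_percent_table(table)
  }
  for (col in c("percent_up", "percent_down")) {
    vals <- table[[col]]
    bad <- !is.na(vals) & (vals < 0 | vals > 100)
    if (any(bad)) {
      stop(sprintf(
        "row '%s': %s = %s outside [0, 100]",
        table$cre_id[bad][1], col, format(vals[bad][1])
      ), call. = FALSE)
    }
  }
  results <- table |>
    tidyr::pivot_longer(c("percent_up", "percent_down"),
      names_to = "gene_set", names_prefix = "percent_", values_to = "percent"
    ) |>
    dplyr::filter(!is.na(.data$percent)) |>
    dplyr::mutate(
      n_present = NA_integer_, n_total = NA_integer_,
      fraction = .data$percent / 100,
      tier = classify_representation(.data$fraction, thresholds)
    ) |>
    dplyr::select(
      "cre_id", "gene_set", "n_present", "n_total", "fraction", "percent",
      "tier"
    )
  .new_cre_representation(results, thresholds, mode = "percent_table")
}

#' Count CREs per tier per gene set
#'
#' @param x A `cre_representation` object or its tidy results tibble.
#' @return Tibble `gene_set`, `tier`, `n` (all tier levels present, zero
#'   filled).
#' @export
count_tiers <- function(x) {
  res <- if (inherits(x, "cre_representation")) x$results else x
  res |>
    dplyr::count(.data$gene_set, .data$tier) |>
    tidyr::complete(.data$gene_set, .data$tier, fill = list(n = 0L))
}

#' Compare up and down gene sets at one tier
#'
#' @param x A `cre_representation` object (or tidy tibble) holding both gene
#'   sets classified with the same thresholds.
#' @param tier Which tier to compare (default `"overrepresented"`).
#' @return A `cre_comparison` object with sorted CRE id vectors `common`,
#'   `up_only`, `down_only` (pairwise disjoint).
#' @export
compare_gene_sets <- function(x, tier = "overrepresented") {
  tier <- match.arg(tier, .TIER_LEVELS)
  res <- if (inherits(x, "cre_representation")) x$results else x
  at_tier <- function(set) {
    sort(unique(res$cre_id[res$gene_set == set & res$tier == tier]))
  }
  up <- at_tier("up")
  down <- at_tier("down")
  structure(
    list(
      tier = tier,
      common = intersect(up, down),
      up_only = setdiff(up, down),
      down_only = setdiff(down, up)
    ),
    class = "cre_comparison"
  )
}

#' @export
print.cre_comparison <- function(x, ...) {
  cat("CRE gene-set comparison at tier:", x$tier, "\n")
  cat(sprintf(
    "  common: %d | up only: %d | down only: %d\n",
    length(x$common), length(x$up_only), length(x$down_only)
  ))
  if (length(x$common)) {
    cat("  common CREs:", paste(x$common, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname compare_gene_sets
#' @param ... Unused.
#' @method tidy cre_comparison
#' @export
tidy.cre_comparison <- function(x, ...) {
  tibble::tibble(
    cre_id = c(x$common, x$up_only, x$down_only),
    status = rep(
      c("common", "up_only", "down_only"),
      c(length(x$common), length(x$up_only), length(x$down_only))
    )
  ) |>
    dplyr::arrange(.data$cre_id)
}

#' Tidy a representation analysis
#'
#' @param x A `cre_representation` object.
#' @param ... Unused.
#' @return The per-CRE, per-gene-set results tibble: `cre_id`, `gene_set`,
#'   `n_present`, `n_total`, `fraction`, `percent`, `tier`.
#' @method tidy cre_representation
#' @export
tidy.cre_representation <- function(x, ...) {
  x$results
}

#' One-row summary of a representation analysis
#'
#' @inheritParams tidy.cre_representation
#' @return One-row tibble: `n_cre` plus a `<set>_<tier>` count column per
#'   gene set and tier.
#' @method glance cre_representation
#' @export
glance.cre_representation <- function(x, ...) {
  wide <- count_tiers(x) |>
    tidyr::pivot_wider(
      names_from = c("gene_set", "tier"), values_from = "n", names_sep = "_"
    )
  dplyr::bind_cols(
    tibble::tibble(n_cre = dplyr::n_distinct(x$results$cre_id)), wide
  )
}

#' @export
print.cre_representation <- function(x, ...) {
  cat(sprintf(
    "CRE representation analysis (%s mode): %d CREs x %d gene set(s)\n",
    x$mode, dplyr::n_distinct(x$results$cre_id),
    dplyr::n_distinct(x$results$gene_set)
  ))
  cat(sprintf(
    "thresholds: over >= %.2f, moderate >= %.2f\n",
    x$thresholds$over, x$thresholds$moderate_low
  ))
  ct <- count_tiers(x)
  print(tidyr::pivot_wider(ct, names_from = "tier", values_from = "n"))
  invisible(x)
}

#' Plot per-CRE percentages colored by tier
#'
#' @param object A `cre_representation` object.
#' @param ... Unused.
#' @return A ggplot: percent of genes carrying each CRE, faceted by gene
#'   set, with dashed lines at the tier thresholds.
#' @method autoplot cre_representation
#' @export
autoplot.cre_representation <- function(object, ...) {
  res <- object$results
  ggplot2::ggplot(
    res,
    ggplot2::aes(
      x = .data$percent,
      y = stats::reorder(.data$cre_id, .data$percent),
      fill = .data$tier
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(
      xintercept = 100 * c(object$thresholds$moderate_low, object$thresholds$over),
      linetype = "dashed", colour = "grey30"
    ) +
    ggplot2::facet_wrap(~gene_set) +
    ggplot2::labs(
      x = "% of genes whose promoter carries the CRE", y = NULL,
      fill = "tier"
    ) +
    ggplot2::theme_minimal()
}
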