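# Synthetic promoter sets and genomes with motif instances planted at known
# per-gene probabilities, so scanning and the representation statistic can be
# checked against ground truth without any external data.
#
# One synthetic chromosome per gene avoids promoter-overlap bookkeeping, and
# strands alternate so both extraction branches are exercised. Later plants
# may overwrite earlier ones at overlapping offsets; the recorded truth is
# what is actually present after all planting (each intended site is
# re-checked against its pattern), so recovery tests are exact.

.DEFAULT_SEED <- 20230131L

.check_composition <- function(composition) {
  if (is.null(names(composition)) ||
      !all(names(composition) %in% c("A", "C", "G", "T", "N"))) {
    stop("`composition` must be named with bases among A/C/G/T/N",
      call. = FALSE
    )
  }
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9) {
    stop("`composition` probabilities must be >= 0 and sum to 1",
      call. = FALSE
    )
  }
  invisible(composition)
}

.with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Generate an i.i.d. background sequence
#'
#' @param length Number of bases (>= 0).
#' @param composition Named base-probability vector summing to 1.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A nucleotide string of `length` bases.
#' @examples
#' generate_background(5, c(A = 1)) # "AAAAA"
#' @export
generate_background <- function(length,
                                composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                                seed = NULL) {
  if (length < 0) {
    stop("`length` must be nonnegative", call. = FALSE)
  }
  .check_composition(composition)
  .with_seed_maybe(seed, {
    if (length == 0) {
      ""
    } else {
      paste(
        sample(names(composition), length, replace = TRUE, prob = composition),
        collapse = ""
      )
    }
  })
}

#' Plant a concrete motif instance into a sequence
#'
#' Replaces the window starting at (0-based) `position` with an instance
#' sampled uniformly from the pattern's allowed bases per position, so the
#' returned sequence matches `pattern` at `position`.
#'
#' @param sequence Host nucleotide string.
#' @param pattern IUPAC consensus pattern to instantiate.
#' @param position 0-based offset; `position + nchar(pattern)` must not
#'   exceed `nchar(sequence)`.
#' @param seed Optional integer seed for the instance draw.
#' @return The modified sequence.
#' @export
plant_motif <- function(sequence, pattern, position, seed = NULL) {
  sets <- parse_iupac(pattern)
  len <- length(sets)
  if (position < 0 || position + len > nchar(sequence)) {
    stop(sprintf(
      "position %d out of range for pattern of length %d in sequence of length %d",
      position, len, nchar(sequence)
    ), call. = FALSE)
  }
  instance <- .with_seed_maybe(seed, {
    paste(
      vapply(sets, function(s) sample(s, 1), character(1)),
      collapse = ""
    )
  })
  paste0(
    substr(sequence, 1, position),
    instance,
    substr(sequence, position + len + 1, nchar(sequence))
  )
}

# does `sequence` satisfy `pattern` at 0-based `position`?
.matches_at <- function(sequence, pattern, position) {
  window <- substr(sequence, position + 1, position + nchar(pattern))
  if (nchar(window) < nchar(pattern)) {
    return(FALSE)
  }
  length(.match_starts(.encode_subject(window), .pattern_masks(pattern))) > 0
}

.default_plant_probs <- function(catalog, prob_up = 0.85, prob_down = 0.55) {
  tibble::tibble(
    cre_id = catalog$cre_id, prob_up = prob_up, prob_down = prob_down
  )
}

#' Simulate labeled promoter sets with planted motifs
#'
#' For every gene and every catalog CRE, a Bernoulli draw at that gene set's
#' planting probability decides whether one concrete instance of a (uniformly
#' chosen) variant is planted at a uniform random offset. Defaults mirror the
#' study conditions: 61 up-regulated and 54 down-regulated genes with 3-kb
#' promoters.
#'
#' @param catalog Catalog tibble; every variant must fit in
#'   `promoter_length`.
#' @param n_up,n_down Gene counts per set.
#' @param promoter_length Promoter length in bases.
#' @param composition Background base composition.
#' @param plant_probs Tibble `cre_id`, `prob_up`, `prob_down`; defaults to
#'   0.85/0.55 for every catalog entry.
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @return List with `promoters` (tibble `gene_id`, `label`, `sequence`),
#'   `truth` (tibble `gene_id`, `cre_id`, `planted`, `positions` list-column
#'   of surviving 0-based plant offsets), and the `plant_probs` used.
#' @export
simulate_promoter_set <- function(catalog,
                                  n_up = 61, n_down = 54,
                                  promoter_length = 3000,
                                  composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                                  plant_probs = NULL,
                                  seed = .DEFAULT_SEED) {
  .check_composition(composition)
  plant_probs <- plant_probs %||% .default_plant_probs(catalog)
  if (!all(catalog$cre_id %in% plant_probs$cre_id)) {
    stop("`plant_probs` must cover every catalog cre_id", call. = FALSE)
  }
  max_len <- max(nchar(unlist(catalog$variants)))
  if (promoter_length < max_len) {
    stop(sprintf(
      "promoter_length %d shorter than the longest catalog variant (%d)",
      promoter_length, max_len
    ), call. = FALSE)
  }
  gene_ids <- c(
    sprintf("up_%03d", seq_len(n_up)),
    sprintf("down_%03d", seq_len(n_down))
  )
  labels <- rep(c("up", "down"), c(n_up, n_down))
  probs <- plant_probs[match(catalog$cre_id, plant_probs$cre_id), ]

  .with_seed_maybe(seed, {
    per_gene <- purrr::map(seq_along(gene_ids), function(i) {
      seq <- generate_background(promoter_length, composition)
      p_col <- if (labels[i] == "up") probs$prob_up else probs$prob_down
      intents <- list()
      for (j in seq_len(nrow(catalog))) {
        if (stats::runif(1) < p_col[j]) {
          variant <- sample(catalog$variants[[j]], 1)
          pos <- sample.int(promoter_length - nchar(variant) + 1L, 1L) - 1L
          seq <- plant_motif(seq, variant, pos)
          intents[[length(intents) + 1L]] <- list(
            cre_id = catalog$cre_id[j], variant = variant, position = pos
          )
        }
      }
      # post-hoc ground truth: keep only plants still intact after overwrites
      surviving <- purrr::keep(
        intents, ~ .matches_at(seq, .x$variant, .x$position)
      )
      truth <- tibble::tibble(
        gene_id = gene_ids[i],
        cre_id = catalog$cre_id,
        planted = catalog$cre_id %in%
          purrr::map_chr(surviving, "cre_id"),
        positions = purrr::map(catalog$cre_id, function(id) {
          as.integer(sort(unlist(
            purrr::map(
              purrr::keep(surviving, ~ .x$cre_id == id), "position"
            )
          )))
        })
      )
      list(
        promoter = tibble::tibble(
          gene_id = gene_ids[i], label = labels[i], sequence = seq
        ),
        truth = truth
      )
    })
    list(
      promoters = dplyr::bind_rows(purrr::map(per_gene, "promoter")),
      truth = dplyr::bind_rows(purrr::map(per_gene, "truth")),
      plant_probs = probs
    )
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Builds one synthetic chromosome per gene — background padding, the
#' simulated promoter immediately upstream of a single gene feature
#' (strands alternate `+`/`-`), the gene body, and trailing padding — and
#' writes the same dialects the readers consume: `genome.fa`, `genes.gff3`,
#' `gene_sets.tsv` and `truth.tsv`. Byte-identical across reruns with the
#' same seed.
#'
#' @inheritParams simulate_promoter_set
#' @param dir Output directory (created if needed).
#' @param gene_length Length of the gene body placed downstream of the TSS.
#' @param upstream_pad Extra background upstream of the promoter window
#'   (total upstream span is `promoter_length + upstream_pad`).
#' @param downstream_pad Background downstream of the gene body.
#' @return Invisibly, a list with the four file `paths` and the in-memory
#'   `promoters`, `genes` and `truth` tables.
#' @export
generate_dataset <- function(dir,
                             catalog = example_catalog(),
                             n_up = 61, n_down = 54,
                             promoter_length = 3000,
                             composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                             plant_probs = NULL,
                             seed = .DEFAULT_SEED,
                             gene_length = 300,
                             upstream_pad = 100,
                             downstream_pad = 50) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(seed, {
    sim <- simulate_promoter_set(
      catalog,
      n_up = n_up, n_down = n_down, promoter_length = promoter_length,
      composition = composition, plant_probs = plant_probs, seed = NULL
    )
    strands <- rep(c("+", "-"), length.out = nrow(sim$promoters))
    chroms <- paste0("chr_", sim$promoters$gene_id)
    rows <- purrr::map(seq_len(nrow(sim$promoters)), function(i) {
      prom <- sim$promoters$sequence[i]
      body <- generate_background(gene_length, composition)
      up_pad <- generate_background(upstream_pad, composition)
      down_pad <- generate_background(downstream_pad, composition)
      if (strands[i] == "+") {
        chrom_seq <- paste0(up_pad, prom, body, down_pad)
        tss0 <- upstream_pad + promoter_length
        gff_start <- tss0 + 1L
        gff_end <- tss0 + gene_length
      } else {
        chrom_seq <- paste0(down_pad, body, reverse_complement(prom), up_pad)
        gff_start <- downstream_pad + 1L
        gff_end <- downstream_pad + gene_length
      }
      list(
        chrom_seq = chrom_seq,
        gff = sprintf(
          "%s\tcrescan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
          chroms[i], gff_start, gff_end, strands[i],
          sim$promoters$gene_id[i]
        )
      )
    })

    paths <- list(
      genome = file.path(dir, "genome.fa"),
      annotation = file.path(dir, "genes.gff3"),
      gene_sets = file.path(dir, "gene_sets.tsv"),
      truth = file.path(dir, "truth.tsv")
    )
    fasta <- unlist(purrr::map2(chroms, rows, function(chrom, row) {
      seq <- row$chrom_seq
      starts <- seq(1, nchar(seq), by = 70)
      c(
        paste0(">", chrom),
        substring(seq, starts, pmin(starts + 69, nchar(seq)))
      )
    }))
    writeLines(fasta, paths$genome)
    writeLines(
      c("##gff-version 3", purrr::map_chr(rows, "gff")),
      paths$annotation
    )
    readr::write_tsv(
      sim$promoters[c("gene_id", "label")], paths$gene_sets,
      progress = FALSE
    )
    truth_flat <- sim$truth |>
      dplyr::mutate(
        planted = as.integer(.data$planted),
        positions = purrr::map_chr(.data$positions, paste, collapse = ",")
      )
    readr::write_tsv(truth_flat, paths$truth, progress = FALSE)

    genes <- tibble::tibble(
      gene_id = sim$promoters$gene_id,
      chrom = chroms,
      strand = strands,
      tss = purrr::map2_int(rows, strands, function(row, st) {
        if (st == "+") {
          upstream_pad + as.integer(promoter_length)
        } else {
          downstream_pad + as.integer(gene_length) - 1L
        }
      }),
      label = sim$promoters$label
    )
    invisible(list(
      paths = paths, promoters = sim$promoters, genes = genes,
      truth = sim$truth
    ))
  })
}
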