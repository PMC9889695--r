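toy_presence <- tibble::tibble(
  gene_id = c("g1", "g2", "g3", "g4"),
  CRE_A = c(TRUE, TRUE, TRUE, FALSE),
  CRE_B = c(TRUE, TRUE, TRUE, TRUE)
)

test_that("percent_with_cre computes the exact presence fraction", {
  res <- percent_with_cre(toy_presence, paste0("g", 1:4), "CRE_A")
  expect_equal(res$n_present, 3L)
  expect_equal(res$n_total, 4L)
  expect_equal(res$fraction, 0.75)
  expect_equal(res$percent, 75)
  expect_equal(percent_with_cre(toy_presence, paste0("g", 1:4), "CRE_B")$percent, 100)
  expect_error(percent_with_cre(toy_presence, character(0), "CRE_A"), "empty")
  expect_error(percent_with_cre(toy_presence, "g1", "CRE_Z"), "unknown cre_id")
  expect_error(percent_with_cre(toy_presence, c("g1", "gX"), "CRE_A"), "absent")
})

test_that("percent_with_cre ignores gene order and genes outside the set", {
  base <- percent_with_cre(toy_presence, c("g1", "g2", "g3"), "CRE_A")
  shuffled <- percent_with_cre(toy_presence, c("g3", "g1", "g2"), "CRE_A")
  expect_equal(base, shuffled)
  extra <- dplyr::bind_rows(
    toy_presence,
    tibble::tibble(gene_id = "g9", CRE_A = TRUE, CRE_B = TRUE)
  )
  expect_equal(base, percent_with_cre(extra, c("g1", "g2", "g3"), "CRE_A"))
})

test_that("tier boundaries follow the half-open interval convention", {
  expect_equal(as.character(classify_representation(0.75)), "overrepresented")
  expect_equal(
    as.character(classify_representation(0.50)), "moderately_overrepresented"
  )
  expect_equal(as.character(classify_representation(0.49)), "underrepresented")
  # non-integer boundary cases resolve downward (exact fraction, half-open)
  expect_equal(
    as.character(classify_representation(0.749)), "moderately_overrepresented"
  )
  expect_equal(as.character(classify_representation(0.495)), "underrepresented")
  expect_equal(as.character(classify_representation(c(0, 1))),
    c("underrepresented", "overrepresented"))
  expect_error(classify_representation(1.2), "\\[0, 1\\]")
  expect_error(classify_representation(-0.1), "\\[0, 1\\]")
})

test_that("classification uses the exact fraction, not the rounded percent", {
  # 74.5% would round to 75 in a report but stays moderate
  expect_equal(
    as.character(classify_representation(0.745)), "moderately_overrepresented"
  )
})

test_that("tiers partition [0,1] and are monotone in the fraction", {
  withr::with_seed(1, {
    f <- sort(c(runif(1000), 0, 0.5, 0.75, 1))
    tiers <- classify_representation(f)
    expect_false(anyNA(tiers))           # every fraction gets exactly one tier
    expect_true(all(diff(as.integer(tiers)) >= 0)) # monotone non-decreasing
  })
})

test_that("thresholds are validated and configurable", {
  expect_error(representation_thresholds(0.5, 0.75), "moderate_low < over")
  t2 <- representation_thresholds(over = 0.9, moderate_low = 0.6)
  expect_equal(as.character(classify_representation(0.8, t2)),
    "moderately_overrepresented")
})

test_that("analyze_representation summarises per gene set with full denominators", {
  labels <- tibble::tibble(
    gene_id = paste0("g", 1:4),
    label = c("up", "up", "down", "none")
  )
  res <- analyze_representation(toy_presence, labels)
  tbl <- tidy(res)
  expect_equal(nrow(tbl), 4) # 2 CREs x 2 sets
  up_a <- tbl[tbl$cre_id == "CRE_A" & tbl$gene_set == "up", ]
  expect_equal(up_a$n_total, 2L)
  expect_equal(up_a$percent, 100)
  down_a <- tbl[tbl$cre_id == "CRE_A" & tbl$gene_set == "down", ]
  expect_equal(down_a$n_total, 1L)
  expect_equal(as.character(down_a$tier), "overrepresented")
  expect_error(
    analyze_representation(
      toy_presence, tibble::tibble(gene_id = "g1", label = "none")
    ),
    "no genes labeled"
  )
  g <- glance(res)
  expect_equal(g$n_cre, 2L)
  expect_equal(g$up_overrepresented, 2L)
})

test_that("classify_percent_table skips blanks and validates ranges", {
  tab <- tibble::tibble(
    cre_id = c("A", "B", "C"),
    percent_up = c(80, 60, NA),
    percent_down = c(NA, 40, 75)
  )
  res <- classify_percent_table(tab)
  tbl <- tidy(res)
  expect_equal(nrow(tbl), 4) # blanks excluded
  expect_equal(
    as.character(tbl$tier[tbl$cre_id == "A" & tbl$gene_set == "up"]),
    "overrepresented"
  )
  expect_equal(
    as.character(tbl$tier[tbl$cre_id == "B" & tbl$gene_set == "down"]),
    "underrepresented"
  )
  bad <- tibble::tibble(cre_id = "A", percent_up = 120, percent_down = NA)
  expect_error(classify_percent_table(bad), "'A'.*outside")
})

test_that("compare_gene_sets partitions CREs into disjoint sets", {
  tab <- tibble::tibble(
    cre_id = c("A", "B", "C"),
    percent_up = c(80, 90, 40),
    percent_down = c(85, 30, 90)
  )
  cmp <- compare_gene_sets(classify_percent_table(tab))
  expect_equal(cmp$common, "A")
  expect_equal(cmp$up_only, "B")
  expect_equal(cmp$down_only, "C")
  expect_length(intersect(cmp$common, cmp$up_only), 0)
  tbl <- tidy(cmp)
  expect_equal(tbl$cre_id, c("A", "B", "C")) # sorted

  # identical sets: nothing exclusive
  same <- tibble::tibble(cre_id = "A", percent_up = 80, percent_down = 80)
  cmp2 <- compare_gene_sets(classify_percent_table(same))
  expect_length(cmp2$up_only, 0)
  expect_length(cmp2$down_only, 0)

  # disjoint toy results: empty intersection
  disj <- tibble::tibble(
    cre_id = c("A", "B"), percent_up = c(80, 10), percent_down = c(10, 80)
  )
  expect_length(compare_gene_sets(classify_percent_table(disj))$common, 0)
})

test_that("autoplot returns a ggplot of percents by tier", {
  tab <- tibble::tibble(
    cre_id = c("A", "B"), percent_up = c(80, 55), percent_down = c(20, 90)
  )
  p <- autoplot(classify_percent_table(tab))
  expect_s3_class(p, "ggplot")
})
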