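write_lines_tmp <- function(lines, ext) {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_fasta parses, normalizes and validates records", {
  p <- write_lines_tmp(c(">chr1", "ACGT"), ".fa")
  expect_equal(read_fasta(p)$sequence, "ACGT")

  # case-folding, whitespace stripping, non-ACGTN -> N with warning
  p <- write_lines_tmp(c(">a", "acg t", "n", ">b desc", "AXGT"), ".fa")
  expect_warning(fa <- read_fasta(p), "non-ACGTN")
  expect_equal(fa$seq_id, c("a", "b"))
  expect_equal(fa$sequence, c("ACGTN", "ANGT"))

  p <- write_lines_tmp(c(">a", "AC", ">a", "GG"), ".fa")
  expect_error(read_fasta(p), "duplicate")
  p <- write_lines_tmp(character(0), ".fa")
  expect_error(read_fasta(p), "empty|parse")
  expect_error(read_fasta("/nonexistent.fa"), "not found")
})

test_that("read_gene_annotations converts GFF3 genes to 0-based TSS anchors", {
  gff <- c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=g1",
    "chr1\tsrc\tgene\t1001\t2000\t.\t-\t.\tID=g2",
    "chr1\tsrc\texon\t1001\t1100\t.\t+\t.\tID=e1"
  )
  genes <- read_gene_annotations(write_lines_tmp(gff, ".gff3"), "gff3")
  expect_equal(nrow(genes), 2) # exon ignored
  expect_equal(genes$tss[genes$gene_id == "g1"], 1000) # 5' end, 0-based
  expect_equal(genes$tss[genes$gene_id == "g2"], 1999) # minus-strand 5' end
  expect_equal(genes$label, c("none", "none"))
})

test_that("read_gene_annotations rejects bad BED input", {
  bed <- "chr1\t100\t200\tg1\t0\t."
  expect_error(
    read_gene_annotations(write_lines_tmp(bed, ".bed"), "bed"),
    "strand"
  )
  bed3 <- "chr1\t100\t200"
  expect_error(
    read_gene_annotations(write_lines_tmp(bed3, ".bed"), "bed"),
    "6 columns"
  )
  bed6 <- c("chr1\t100\t200\tg1\t0\t+", "chr1\t300\t400\tg2\t0\t-")
  genes <- read_gene_annotations(write_lines_tmp(bed6, ".bed"), "bed")
  expect_equal(genes$tss, c(100, 399)) # BED already 0-based
})

test_that("gene-set labels parse and attach", {
  p <- write_lines_tmp(c("gene_id\tlabel", "g1\tup", "g2\tdown"), ".tsv")
  labs <- read_gene_sets(p)
  expect_equal(labs$label, c("up", "down"))
  expect_error(
    read_gene_sets(write_lines_tmp("g1\tsideways", ".tsv")),
    "invalid gene-set label"
  )
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), chrom = "c", strand = "+", tss = 1,
    label = "none"
  )
  labeled <- attach_gene_labels(genes, labs)
  expect_equal(labeled$label, c("up", "down", "none"))
  expect_warning(
    attach_gene_labels(genes, tibble::tibble(gene_id = "gX", label = "up")),
    "absent"
  )
})

test_that("extract_promoters obeys the strand-aware window convention", {
  chrom <- withr::with_seed(
    11, paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  )
  genome <- c(chr1 = chrom)
  genes <- tibble::tibble(
    gene_id = c("plus", "minus", "clipped"),
    chrom = "chr1",
    strand = c("+", "-", "+"),
    tss = c(5000, 5000, 1000)
  )
  pr <- extract_promoters(genes, genome, length = 3000)

  # + strand: forward window [tss-3000, tss), TSS base excluded
  expect_equal(pr$sequence[1], substr(chrom, 2001, 5000))
  expect_equal(c(pr$window_start[1], pr$window_end[1]), c(2000, 5000))
  expect_false(pr$truncated[1])
  # last promoter base is genome[tss-1] (0-based)
  expect_equal(substr(pr$sequence[1], 3000, 3000), substr(chrom, 5000, 5000))

  # - strand: reverse complement of forward window [tss+1, tss+1+3000)
  expect_equal(pr$sequence[2], reverse_complement(substr(chrom, 5002, 8001)))

  # clipping at the chromosome start
  expect_equal(nchar(pr$sequence[3]), 1000)
  expect_true(pr$truncated[3])
  expect_equal(c(pr$window_start[3], pr$window_end[3]), c(0, 1000))

  # sequence length + clipped bases always equals the request
  expect_equal(nchar(pr$sequence) + (3000 - nchar(pr$sequence)),
    rep(3000, 3))

  expect_error(
    extract_promoters(
      tibble::tibble(gene_id = "g", chrom = "nope", strand = "+", tss = 10),
      genome
    ),
    "absent from genome"
  )
})

test_that("zero-length promoter at tss=0 is kept and flagged", {
  genes <- tibble::tibble(gene_id = "g0", chrom = "c", strand = "+", tss = 0)
  expect_message(
    pr <- extract_promoters(genes, c(c = "ACGTACGT"), length = 5),
    "zero-length"
  )
  expect_equal(pr$sequence, "")
  expect_true(pr$truncated)
})

test_that("promoter extraction is invariant under genome mirroring", {
  # extracting from the reverse-complemented genome with the mirrored gene
  # model must give the identical promoter string
  withr::with_seed(99, {
    for (i in 1:3) {
      clen <- 400
      chrom <- paste(sample(c("A", "C", "G", "T"), clen, TRUE), collapse = "")
      tss <- sample(50:(clen - 50), 1)
      strand <- sample(c("+", "-"), 1)
      g1 <- tibble::tibble(
        gene_id = "g", chrom = "c", strand = strand, tss = tss
      )
      mirrored_strand <- if (strand == "+") "-" else "+"
      g2 <- tibble::tibble(
        gene_id = "g", chrom = "c", strand = mirrored_strand,
        tss = clen - 1 - tss
      )
      p1 <- extract_promoters(g1, c(c = chrom), length = 30)$sequence
      p2 <- extract_promoters(
        g2, c(c = reverse_complement(chrom)), length = 30
      )$sequence
      expect_identical(p1, p2)
    }
  })
})

test_that("promoter FASTA round-trips with 1-based headers", {
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", strand = "+", tss = 120
  )
  chrom <- strrep("ACGT", 50)
  pr <- extract_promoters(genes, c(chr1 = chrom), length = 100)
  path <- withr::local_tempfile(fileext = ".fa")
  write_promoters_fasta(pr, path)
  lines <- readLines(path)
  expect_equal(lines[1], ">g1 window=chr1:21-120(+) truncated=0")
  expect_equal(read_fasta(path)$sequence, pr$sequence)
})
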