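gff3_lines <- function(genes) {
  c("##gff-version 3",
    sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            genes$chromosome, genes$start, genes$end, genes$strand, genes$gene_id))
}

test_that("GFF3 gene records are read and sorted per chromosome", {
  g <- tibble::tibble(
    gene_id = c("gA", "gB", "gC", "gD", "gE"),
    chromosome = c("chr2", "chr1", "chr1", "chr2", "chr1"),
    start = c(500L, 900L, 100L, 10L, 400L),
    end = c(700L, 980L, 250L, 40L, 450L),
    strand = c("+", "-", "+", "+", "-")
  )
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff3_lines(g), path)
  ann <- read_genome_annotation(path)
  expect_s3_class(ann, "qtg_annotation")
  expect_equal(nrow(ann), 5)
  expect_equal(ann$gene_id, c("gC", "gE", "gB", "gD", "gA"))
})

test_that("empty GFF3 yields an empty annotation", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", path)
  ann <- read_genome_annotation(path)
  expect_equal(nrow(ann), 0)
})

test_that("start > end is an error citing the line", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tgene\t100\t200\t.\t+\t.\tID=ok",
               "chr1\ttest\tgene\t500\t300\t.\t+\t.\tID=bad"), path)
  expect_error(read_genome_annotation(path), "line 3")
})

test_that("QTL membership is inclusive-overlap and matches a brute-force scan", {
  ann <- as_genome_annotation(tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    chromosome = "chr1",
    start = c(100L, 300L, 600L),
    end = c(200L, 400L, 700L)
  ))
  # gene spanning exactly the left marker position is included
  region <- list(chromosome = "chr1", left_marker_pos = 200, right_marker_pos = 250)
  expect_equal(genes_in_qtl(ann, region), "g1")
  # region strictly between two genes
  region2 <- list(chromosome = "chr1", left_marker_pos = 450, right_marker_pos = 550)
  expect_equal(genes_in_qtl(ann, region2), character(0))
  expect_error(genes_in_qtl(ann, list(chromosome = "chrX",
                                      left_marker_pos = 1, right_marker_pos = 2)),
               "chrX")

  # random regions vs the O(n) oracle
  fx <- generate_fixture(small_fixture_spec(seed = 5))
  withr::with_seed(99, {
    for (i in 1:50) {
      chrom <- sample(unique(fx$annotation$chromosome), 1)
      a <- sample.int(max(fx$annotation$end), 1)
      b <- sample.int(max(fx$annotation$end), 1)
      region <- list(chromosome = chrom,
                     left_marker_pos = min(a, b), right_marker_pos = max(a, b))
      expect_equal(genes_in_qtl(fx$annotation, region),
                   brute_genes_in_qtl(fx$annotation, region))
    }
  })
})

test_that("flanking genes are symmetric in the middle and borrow at ends", {
  ann <- as_genome_annotation(tibble::tibble(
    gene_id = sprintf("g%03d", 1:401),
    chromosome = "chr1",
    start = seq(1L, by = 1000L, length.out = 401),
    end = seq(500L, by = 1000L, length.out = 401)
  ))
  mid <- flanking_genes(ann, "g201", 200)
  expect_equal(mid, sprintf("g%03d", c(101:200, 202:301)))
  first <- flanking_genes(ann, "g001", 200)
  expect_equal(first, sprintf("g%03d", 2:201))
  last <- flanking_genes(ann, "g401", 200)
  expect_equal(last, sprintf("g%03d", 201:400))
  expect_false("g201" %in% mid)
  expect_error(flanking_genes(ann, "nope", 10), "unknown gene")

  # oracle: k nearest by gene-order distance, never exceeding k
  withr::with_seed(3, {
    for (i in 1:20) {
      k <- sample(0:50, 1)
      g <- sample(ann$gene_id, 1)
      res <- flanking_genes(ann, g, k)
      expect_lte(length(res), k)
      expect_false(g %in% res)
      pos <- match(g, ann$gene_id)
      dist <- abs(match(res, ann$gene_id) - pos)
      # no excluded gene is strictly closer than every included gene
      excluded <- setdiff(ann$gene_id, c(res, g))
      if (length(res) && length(excluded)) {
        expect_gte(min(abs(match(excluded, ann$gene_id) - pos)), max(dist) - 1)
      }
    }
  })
})

test_that("edge lists collapse duplicate undirected pairs by summing", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    gene_a = c("a", "b", "a", "c"),
    gene_b = c("b", "a", "b", "c"),
    weight = c(0.5, 0.2, 0.3, 1.0)
  ), path)
  el <- read_edge_list(path)
  expect_equal(nrow(el), 2)
  expect_equal(el$weight[el$gene_a == "a" & el$gene_b == "b"], 1.0)
  expect_error(as_edge_list(tibble::tibble(gene_a = "a", gene_b = "b", weight = -1)),
               "negative")
})

test_that("causal-gene catalogs validate trait categories and unique ids", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene_id = c("a", "b"),
                                  trait_category = c("development", "space travel")),
                   path)
  expect_error(read_causal_genes(path), "space travel")
  readr::write_tsv(tibble::tibble(gene_id = c("a", "a"),
                                  trait_category = c("development", "other")),
                   path)
  expect_error(read_causal_genes(path), "duplicate")
})
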