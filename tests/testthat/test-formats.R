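test_that("read_fasta parses records, wraps lines, and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT"), f)
  r <- read_fasta(f)
  expect_equal(r$id, "a")
  expect_equal(r$sequence, "ACGT")

  writeLines(c(">a desc here", "AC", "GT"), f)
  r <- read_fasta(f)
  expect_equal(r$sequence, "ACGT")
  expect_equal(r$description, "desc here")

  writeLines("ACGT", f)
  expect_error(read_fasta(f), "line 1")

  writeLines(character(), f)
  expect_error(read_fasta(f), "empty file")
})

test_that("fasta round-trips through write_fasta", {
  f <- withr::local_tempfile(fileext = ".fa")
  recs <- data.frame(id = c("x", "y"), description = c("", "d"),
                     sequence = c(random_protein(143), random_protein(7)))
  write_fasta(recs, f)
  expect_equal(read_fasta(f), recs)
})

gff_text <- function(lines) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), f)
  f
}

test_that("read_gff3 builds gene models with strand-aware cds_start", {
  f <- gff_text(c(
    "chr1\ts\tgene\t100\t500\t.\t+\t.\tID=g1",
    "chr1\ts\tmRNA\t100\t500\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\ts\texon\t100\t200\t.\t+\t.\tParent=m1",
    "chr1\ts\texon\t300\t500\t.\t+\t.\tParent=m1",
    "chr1\ts\tCDS\t150\t200\t.\t+\t0\tParent=m1",
    "chr1\ts\tCDS\t300\t400\t.\t+\t2\tParent=m1",
    "chr1\ts\tgene\t600\t900\t.\t-\t.\tID=g2",
    "chr1\ts\tmRNA\t600\t900\t.\t-\t.\tID=m2;Parent=g2",
    "chr1\ts\texon\t600\t900\t.\t-\t.\tParent=m2",
    "chr1\ts\tCDS\t650\t700\t.\t-\t0\tParent=m2",
    "chr1\ts\tCDS\t800\t900\t.\t-\t0\tParent=m2"))
  cat <- read_gff3(f)
  expect_equal(cat$genes[["g1"]]$cds_start, 150)
  expect_equal(cat$genes[["g2"]]$cds_start, 900)  # maximum CDS coord on '-'
  expect_equal(cat$order$chr1, c("g1", "g2"))
  # minus-strand two-segment convention from a hand-worked case
  f2 <- gff_text(c(
    "chr1\ts\tgene\t100\t500\t.\t-\t.\tID=g1",
    "chr1\ts\tmRNA\t100\t500\t.\t-\t.\tID=m1;Parent=g1",
    "chr1\ts\tCDS\t150\t200\t.\t-\t0\tParent=m1",
    "chr1\ts\tCDS\t300\t400\t.\t-\t0\tParent=m1"))
  expect_equal(read_gff3(f2)$genes[["g1"]]$cds_start, 400)
})

test_that("read_gff3 rejects malformed files", {
  expect_error(read_gff3(gff_text(
    "chr1\ts\tgene\t500\t100\t.\t+\t.\tID=g1")), "format error")
  f <- gff_text(c(
    "chr1\ts\tgene\t100\t500\t.\t+\t.\tID=g1",
    "chr1\ts\tCDS\t150\t200\t.\t+\t0\tParent=nosuch"))
  expect_error(read_gff3(f), "Parent|parent")
})

test_that("read_bed converts 0-based half-open to 1-based inclusive", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tte1", "chr1\t99\t100\tte2"), f)
  te <- read_bed(f)
  expect_equal(te$start, c(1, 100))
  expect_equal(te$end, c(100, 100))
  expect_equal(te$end[2] - te$start[2] + 1, 1)  # half-open arithmetic
  writeLines("chr1\t-5\t100\tte1", f)
  expect_error(read_bed(f), "format error")
})

test_that("BED round-trip is the inverse conversion on random intervals", {
  set.seed(41)
  start1 <- sort(sample(1:10000, 20))
  end1 <- start1 + sample(0:500, 20, replace = TRUE)
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste("chrZ", start1 - 1L, end1, paste0("t", 1:20), sep = "\t"), f)
  te <- read_bed(f)
  expect_equal(te$start, start1)
  expect_equal(te$end, end1)
})

test_that("read_matrix validates shape, labels and numeric cells", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g2\t3.5\t0"), f)
  m <- read_matrix(f)
  expect_equal(dim(m), c(2, 2))
  expect_equal(m["g2", "s1"], 3.5)
  expect_equal(colnames(m), c("s1", "s2"))

  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), f)
  expect_error(read_matrix(f), "duplicate gene id")
  writeLines(c("gene\ts1\ts2", "g1\t1\tNA?"), f)
  expect_error(read_matrix(f), "g1.*s2")
  writeLines(c("gene\ts1\ts2", "g1\t1"), f)
  expect_error(read_matrix(f), "ragged")
})

test_that("write_newick emits valid Newick and round-trips via ape", {
  expect_equal(write_newick("A"), "A:0.0;")
  D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nwk <- write_newick(upgma(D))
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, c("A", "B", "C"))
  cd <- ape::cophenetic.phylo(ph)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(cd, D, tolerance = 1e-9)

  # random tree: topology and branch lengths recovered to 1e-9
  set.seed(7)
  Dr <- random_ultrametric(8)
  tr <- upgma(Dr)
  ph <- ape::read.tree(text = write_newick(tr))
  cd <- ape::cophenetic.phylo(ph)[tr$labels, tr$labels]
  expect_equal(unname(cd), unname(tree_cophenetic(tr)), tolerance = 1e-9)

  bad <- upgma(matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "A"), c("A", "A"))))
  expect_error(write_newick(bad), "duplicate leaf labels")
})
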