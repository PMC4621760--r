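mk_cat <- function(models, fam = NULL) {
  gene_catalog(models, family_ids = if (is.null(fam))
    vapply(models, `[[`, "", "gene_id") else fam)
}

test_that("promoters are extracted strand-aware with truncation flags", {
  set.seed(44)
  chrom <- random_dna_str(2000)
  genome <- c(chr1 = chrom)
  gplus <- list(gene_id = "p", chromosome = "chr1", start = 1001, end = 1400,
                strand = "+", exons = cbind(1001, 1400), cds_start = 1001)
  gminus <- list(gene_id = "m", chromosome = "chr1", start = 200, end = 500,
                 strand = "-", exons = cbind(200, 500), cds_start = 500)
  gshort <- list(gene_id = "s", chromosome = "chr1", start = 301, end = 700,
                 strand = "+", exons = cbind(301, 700), cds_start = 301)
  pr <- extract_promoters(genome, mk_cat(list(gplus, gminus, gshort)))
  p <- pr[pr$gene_id == "p", ]
  expect_equal(p$sequence, substr(chrom, 1, 1000))
  expect_false(p$truncated)
  m <- pr[pr$gene_id == "m", ]
  expect_equal(m$sequence, auxiaa:::revcomp(substr(chrom, 501, 1500)))
  s <- pr[pr$gene_id == "s", ]
  expect_equal(nchar(s$sequence), 300)
  expect_true(s$truncated)

  gedge <- list(gene_id = "e", chromosome = "chr1", start = 1, end = 300,
                strand = "+", exons = cbind(1, 300), cds_start = 1)
  expect_error(extract_promoters(genome, mk_cat(list(gedge))), "empty promoter")
})

test_that("IUPAC element scanning reports both strands at forward coordinates", {
  lib1 <- data.frame(element_id = "E", name = "e", pattern = "CANNTG")
  h <- scan_elements(c(g = "GGCACGTGTT"), lib1)
  expect_equal(h$position[h$strand == "+"], 3)
  expect_equal(h$position[h$strand == "-"], 3)

  hn <- scan_elements(c(g = "ACGT"),
                      data.frame(element_id = "N", name = "n", pattern = "N"))
  expect_equal(hn$position[hn$strand == "+"], 1:4)
  expect_equal(hn$position[hn$strand == "-"], 1:4)

  none <- scan_elements(c(g = "GGGGGG"),
                        data.frame(element_id = "A", name = "a", pattern = "ACGT"))
  expect_equal(nrow(none), 0)

  expect_error(scan_elements(c(g = "ACGT"),
                             data.frame(element_id = "Q", name = "q",
                                        pattern = "AXGT")), "IUPAC")
})

test_that("scanner equals brute-force IUPAC expansion on random sequences", {
  set.seed(53)
  pats <- c("TGTCTC", "RCCGAC", "CANNTG", "RTTTTTR", "YAACKG")
  for (rep in 1:40) {
    s <- random_dna_str(200)
    for (p in pats) {
      lib <- data.frame(element_id = "E", name = "e", pattern = p)
      got <- scan_elements(c(g = s), lib)
      want <- iupac_brute(s, p)
      expect_equal(got$position[got$strand == "+"], want$fwd, info = p)
      expect_equal(got$position[got$strand == "-"], want$rev, info = p)
    }
  }
})

test_that("minus-strand scanning equals plus-strand scanning of the revcomp", {
  set.seed(59)
  lib <- default_element_library()
  for (rep in 1:10) {
    s <- random_dna_str(300)
    rc <- auxiaa:::revcomp(s)
    h_fwd <- scan_elements(c(g = s), lib)
    h_rc <- scan_elements(c(g = rc), lib)
    for (el in unique(lib$element_id)) {
      minus <- h_fwd$position[h_fwd$element_id == el & h_fwd$strand == "-"]
      plus_rc <- h_rc$position[h_rc$element_id == el & h_rc$strand == "+"]
      len <- nchar(lib$pattern[lib$element_id == el])
      expect_setequal(minus, sort(nchar(s) - plus_rc - len + 2))
    }
  }
})

test_that("presence table zero-fills and sums to per-gene hit totals", {
  lib <- data.frame(element_id = c("E1", "E2"), name = c("a", "b"),
                    pattern = c("TGTCTC", "GAAAAA"))
  hits <- data.frame(gene_id = c("g1", "g1", "g2"),
                     element_id = c("E1", "E1", "E2"),
                     position = c(5, 20, 7), strand = "+")
  tab <- element_presence_table(hits, c("g1", "g2", "g3"), lib)
  expect_equal(tab["g1", "E1"], 2L)
  expect_equal(tab["g3", ], c(E1 = 0L, E2 = 0L))
  expect_equal(unname(rowSums(tab)), c(2L, 1L, 0L))
})
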