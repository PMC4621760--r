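test_that("Nei-Gojobori site counts match enumerated cases", {
  expect_equal(ng_site_counts("TTT"), c(s = 1/3, n = 8/3))
  expect_equal(ng_site_counts("ATG"), c(s = 0, n = 3))
  # TGG: both third-position stop neighbours excluded by renormalization
  expect_equal(ng_site_counts("TGG"), c(s = 0, n = 3))
  expect_error(ng_site_counts("TAA"), "stop")
  for (cd in sense_codons) {
    expect_equal(sum(ng_site_counts(cd)), 3, info = cd)
  }
})

test_that("codon differences follow pathway averaging", {
  expect_equal(unclass(ng_codon_diff("TTT", "TTC"))[1:2], c(sd = 1, nd = 0))
  expect_equal(unclass(ng_codon_diff("TTT", "TTA"))[1:2], c(sd = 0, nd = 1))
  expect_equal(unclass(ng_codon_diff("TTT", "TCA"))[1:2], c(sd = 0.5, nd = 1.5))
  expect_equal(unclass(ng_codon_diff("AAA", "AAA"))[1:2], c(sd = 0, nd = 0))
  d <- ng_codon_diff("TTT", "TCA")
  expect_equal(sum(d), 2)  # total differences preserved
})

test_that("codon differences equal brute-force enumeration on sampled pairs", {
  set.seed(61)
  pick <- sample(sense_codons, 20)
  for (a in pick) for (b in sample(sense_codons, 10)) {
    got <- ng_codon_diff(a, b)
    expect_equal(unname(unclass(got)[1:2]), ng_diff_brute(a, b),
                 info = paste(a, b))
  }
})

test_that("back_translate maps residue columns to codon columns", {
  al <- list(aligned_a = "MA", aligned_b = "MA")
  ca <- back_translate(al, "ATGGCT", "ATGGCA")
  expect_equal(ca$codons_a, c("ATG", "GCT"))
  expect_equal(ca$codons_b, c("ATG", "GCA"))

  alg <- list(aligned_a = "M-A", aligned_b = "MKA")
  cag <- back_translate(alg, "ATGGCT", "ATGAAAGCA")
  expect_equal(cag$codons_a, c("ATG", "---", "GCT"))
  expect_equal(cag$codons_b, c("ATG", "AAA", "GCA"))

  expect_error(back_translate(al, "ATGGCTA", "ATGGCA"), "3 x protein length")
  expect_error(back_translate(al, "ATGTGA", "ATGGCA"), "stop|translate")
  expect_error(back_translate(al, "ATGAAA", "ATGGCA"), "translate")
})

test_that("ng_kaks reproduces hand-computed values and degenerate cases", {
  same <- list(codons_a = rep("GCT", 5), codons_b = rep("GCT", 5))
  k0 <- ng_kaks(same)
  expect_equal(k0$Ka, 0)
  expect_equal(k0$Ks, 0)
  expect_true(is.na(k0$ratio))
  expect_equal(k0$S + k0$N, 3 * 5)

  # 11 Phe codons, one synonymous difference: hand-worked NG + JC arithmetic
  ca <- list(codons_a = rep("TTT", 11), codons_b = c(rep("TTT", 10), "TTC"))
  k <- ng_kaks(ca)
  S <- 11 / 3
  pS <- 1 / S
  expect_equal(k$S, S)
  expect_equal(k$Sd, 1)
  expect_equal(k$Ks, -0.75 * log(1 - 4 * pS / 3))
  expect_equal(k$Ka, 0)

  # the Jukes-Cantor correction itself: p = 0.3 -> d = 0.3831
  expect_equal(-0.75 * log(1 - 4 * 0.3 / 3), 0.3831, tolerance = 1e-4)

  sat <- list(codons_a = c("TTT"), codons_b = c("TTC"))
  expect_error(ng_kaks(sat), "saturation")
  expect_error(ng_kaks(list(codons_a = "---", codons_b = "---")), "ungapped")
})

test_that("divergence time is the linear dating formula", {
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(0.122), 10)
  expect_equal(divergence_time(1.22), 100)
  ks <- runif(20, 0, 3)
  expect_equal(divergence_time(2 * ks), 2 * divergence_time(ks))
  expect_error(divergence_time(-0.1), "negative")
})

test_that("WGD event bins are monotone with closed legume boundaries", {
  expect_equal(assign_wgd_event(0.25), "glycine_wgd")
  expect_equal(assign_wgd_event(0.7), "legume_wgd")
  expect_equal(assign_wgd_event(1.5), "gamma_wgt")
  expect_equal(assign_wgd_event(c(0.3, 1.3)), c("legume_wgd", "legume_wgd"))
  ks <- sort(runif(50, 0, 3))
  ev <- factor(assign_wgd_event(ks),
               levels = c("glycine_wgd", "legume_wgd", "gamma_wgt"))
  expect_true(all(diff(as.integer(ev)) >= 0))
})

test_that("collinear block chaining finds monotone anchor chains", {
  mk <- function(oa, ob) data.frame(
    gene_a = paste0("a", seq_along(oa)), gene_b = paste0("b", seq_along(ob)),
    chrom_a = "c1", chrom_b = "c2", order_a = oa, order_b = ob,
    stringsAsFactors = FALSE)
  same <- detect_collinear_blocks(mk(1:5, 1:5))
  expect_equal(nrow(same$blocks), 1)
  expect_equal(same$blocks$orientation, "same")
  expect_true(all(!is.na(same$anchors$block_id)))

  inv <- detect_collinear_blocks(mk(1:5, 5:1))
  expect_equal(inv$blocks$orientation, "inverted")
  expect_equal(inv$blocks$n_anchors, 5)

  few <- detect_collinear_blocks(mk(1:4, 1:4))
  expect_equal(nrow(few$blocks), 0)

  gap <- detect_collinear_blocks(mk(c(1:4, 40), c(1:4, 40)))
  expect_equal(nrow(gap$blocks), 0)  # index gap > 25 breaks the chain
})

test_that("TE flanking test is two-sided within the window", {
  g <- list(gene_id = "g", chromosome = "chr1", start = 50000, end = 52000,
            strand = "+", exons = cbind(50000, 52000), cds_start = 50000)
  te2 <- data.frame(chromosome = "chr1", start = c(48500, 53000),
                    end = c(49000, 53400), te_id = c("u", "d"))
  expect_true(flanking_te_test(g, te2)$flag)
  expect_false(flanking_te_test(g, te2[1, ])$flag)   # one side only
  expect_false(flanking_te_test(g, te2[2, ])$flag)   # chromosome-start edge
  far <- transform(te2, start = start - 20000, end = end - 20000)
  expect_false(flanking_te_test(g, far)$flag)
})

test_that("duplication-mode precedence is block > cluster > TE > dispersed", {
  models <- lapply(1:10, function(i)
    list(gene_id = sprintf("g%02d", i), chromosome = "chr1",
         start = i * 3000, end = i * 3000 + 900, strand = "+",
         exons = cbind(i * 3000, i * 3000 + 900), cds_start = i * 3000))
  cat <- gene_catalog(models, family_ids = c("g02", "g03", "g06", "g10"))
  anchors <- data.frame(gene_a = c("g02", paste0("x", 1:4)),
                        gene_b = c("gZ", paste0("y", 1:4)),
                        chrom_a = "chr1", chrom_b = "chrZ",
                        order_a = 1:5, order_b = 1:5)
  blocks <- detect_collinear_blocks(anchors)
  clusters <- detect_tandem_clusters(cat)   # g02,g03 adjacent
  te <- data.frame(chromosome = "chr1", start = c(14000, 19500),
                   end = c(14400, 19900), te_id = c("t1", "t2"))
  modes <- classify_duplication_mode(cat, blocks, clusters, te)
  got <- structure(modes$mode, names = modes$gene_id)
  expect_equal(got[["g02"]], "wgd_segmental")  # block wins over its cluster
  expect_equal(got[["g03"]], "tandem")
  expect_equal(got[["g06"]], "transposed")     # flanked by t1/t2
  expect_equal(got[["g10"]], "dispersed")
  expect_equal(sort(unique(table(modes$gene_id))), 1L)  # exactly one mode each
})

test_that("evolved codon pairs recover their divergence parameters", {
  set.seed(71)
  anc <- paste(sample(sense_codons[!sense_codons %in% c("ATG")],
                      400, replace = TRUE), collapse = "")
  ev <- evolve_codon_pair(anc, dS_target = 0.4, omega = 0.3, seed = 72)
  al <- list(aligned_a = auxiaa:::translate_cds(ev$cds_a),
             aligned_b = auxiaa:::translate_cds(ev$cds_b))
  k <- ng_kaks(back_translate(al, ev$cds_a, ev$cds_b))
  expect_lt(abs(k$Ks - 0.4) / 0.4, 0.2)  # within 20% at 400 codons
  expect_lt(k$ratio, 1)

  # omega = 0: proteins identical; the Ka estimate is not exactly zero
  # because pathway averaging between endpoint codons that each took a
  # synonymous first-position and a synonymous third-position step (six-fold
  # degenerate Leu/Arg boxes) passes through nonsynonymous intermediates,
  # but it must be negligible next to Ks
  ev0 <- evolve_codon_pair(anc, dS_target = 0.3, omega = 0, seed = 73)
  al0 <- list(aligned_a = auxiaa:::translate_cds(ev0$cds_a),
              aligned_b = auxiaa:::translate_cds(ev0$cds_b))
  expect_identical(al0$aligned_a, al0$aligned_b)
  k0 <- ng_kaks(back_translate(al0, ev0$cds_a, ev0$cds_b))
  expect_lt(k0$Ka, 0.01)
  expect_lt(k0$Ka, k0$Ks / 20)
  expect_gt(k0$Ks, 0)

  evid <- evolve_codon_pair(anc, dS_target = 0, omega = 0.5, seed = 74)
  expect_identical(evid$cds_a, evid$cds_b)
  expect_error(evolve_codon_pair(anc, 0.8, 0.2), "0.75")
})
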