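mk_gene <- function(id, chr, start, len = 1000, strand = "+", exons = NULL) {
  end <- start + len - 1
  if (is.null(exons)) exons <- cbind(start = start, end = end)
  list(gene_id = id, chromosome = chr, start = start, end = end,
       strand = strand, exons = exons,
       cds_start = if (strand == "+") start else end)
}

# independent run scan implementing the tandem adjacency rule directly
tandem_brute <- function(catalog, max_intervening = 1, max_gap = 1e5) {
  out <- list()
  for (chr in names(catalog$order)) {
    ids <- catalog$order[[chr]]
    fidx <- which(ids %in% catalog$family_ids)
    if (length(fidx) < 2) next
    grp <- 1; groups <- rep(NA, length(fidx)); groups[1] <- 1
    for (k in 2:length(fidx)) {
      prev <- catalog$genes[[ids[fidx[k - 1]]]]
      cur <- catalog$genes[[ids[fidx[k]]]]
      ok <- (fidx[k] - fidx[k - 1] - 1) <= max_intervening &&
        (cur$start - prev$end) <= max_gap
      if (!ok) grp <- grp + 1
      groups[k] <- grp
    }
    for (g in unique(groups)) {
      mem <- ids[fidx[groups == g]]
      if (length(mem) >= 2) out[[length(out) + 1]] <- paste(mem, collapse = ",")
    }
  }
  unlist(out)
}

random_catalog <- function(n_genes = 30, p_family = 0.3) {
  starts <- cumsum(sample(c(500, 2000, 60000, 150000), n_genes, replace = TRUE))
  models <- lapply(seq_len(n_genes), function(i)
    mk_gene(sprintf("g%02d", i), "chr1", starts[i], len = 400))
  names(models) <- vapply(models, `[[`, "", "gene_id")
  fam <- names(models)[runif(n_genes) < p_family]
  gene_catalog(models, family_ids = fam)
}

test_that("chromosome distribution counts family genes and lists empties", {
  models <- list(mk_gene("a", "chr1", 100), mk_gene("b", "chr1", 5000),
                 mk_gene("c", "chr2", 100), mk_gene("d", "chr3", 100))
  cat <- gene_catalog(models, family_ids = c("a", "b", "c"))
  d <- chromosome_distribution(cat)
  expect_equal(d$counts, c(chr1 = 2L, chr2 = 1L))
  expect_equal(d$absent, "chr3")
  expect_equal(sum(d$counts), length(cat$family_ids))
  empty <- chromosome_distribution(gene_catalog(models, character()))
  expect_equal(length(empty$counts), 0)
})

test_that("tandem clusters follow the adjacency rule", {
  # three adjacent family genes -> one cluster of 3
  models <- lapply(1:7, function(i) mk_gene(paste0("g", i), "chr1", i * 3000, 400))
  cat <- gene_catalog(models, family_ids = c("g3", "g4", "g5"))
  cl <- detect_tandem_clusters(cat)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$members, "g3,g4,g5")
  expect_equal(cl$n, 3)

  # separated by 3 non-family genes -> no cluster under the default rule
  cat2 <- gene_catalog(models, family_ids = c("g1", "g5"))
  expect_equal(nrow(detect_tandem_clusters(cat2)), 0)

  # adjacent by order but beyond the bp gap -> no cluster
  far <- list(mk_gene("a", "chr1", 1000, 400), mk_gene("b", "chr1", 500000, 400))
  cat3 <- gene_catalog(far, family_ids = c("a", "b"))
  expect_equal(nrow(detect_tandem_clusters(cat3)), 0)
  expect_equal(nrow(detect_tandem_clusters(cat3, max_gap = 1e6)), 1)
})

test_that("cluster detection matches a brute-force run scan on random catalogs", {
  set.seed(19)
  for (rep in 1:20) {
    cat <- random_catalog()
    if (length(cat$family_ids) < 2) next
    got <- detect_tandem_clusters(cat)
    expect_equal(sort(got$members), sort(tandem_brute(cat)))
  }
})

test_that("clusters are maximal and disjoint", {
  set.seed(23)
  for (rep in 1:10) {
    cat <- random_catalog(40)
    cl <- detect_tandem_clusters(cat)
    if (nrow(cl) == 0) next
    mems <- unlist(strsplit(cl$members, ","))
    expect_false(anyDuplicated(mems) > 0)
    # every cluster's genes are consecutive family members on the chromosome
    for (i in seq_len(nrow(cl))) {
      ids <- catalogs_order <- cat$order[[cl$chromosome[i]]]
      fam_in_order <- ids[ids %in% cat$family_ids]
      m <- strsplit(cl$members[i], ",")[[1]]
      expect_equal(fam_in_order[seq(match(m[1], fam_in_order),
                                    length.out = length(m))], m)
    }
  }
})

test_that("intron structure is the gaps between exons", {
  g <- mk_gene("g", "chr1", 1, exons = cbind(c(1, 201), c(100, 300)))
  s <- intron_structure(g)
  expect_equal(unname(s$introns), cbind(101, 200), ignore_attr = TRUE)
  expect_equal(s$n_introns, 1)

  g1 <- mk_gene("g", "chr1", 1, exons = cbind(1, 500))
  expect_equal(intron_structure(g1)$n_introns, 0)

  ex4 <- cbind(c(1, 301, 601, 901), c(100, 400, 700, 1100))
  s4 <- intron_structure(mk_gene("g", "chr1", 1, exons = ex4))
  expect_equal(s4$n_introns, 3)
  span <- max(ex4[, 2]) - min(ex4[, 1]) + 1
  expect_equal(s4$intron_bp, span - s4$exon_bp)

  bad <- mk_gene("g", "chr1", 1, exons = cbind(c(1, 50), c(100, 200)))
  expect_error(intron_structure(bad), "overlapping exons")
})
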