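test_that("global alignment reproduces hand-worked cases", {
  al <- global_align(c(a = "AAA"), c(b = "AAA"))
  expect_equal(al$score, 3 * blosum62["A", "A"])
  expect_equal(al$percent_identity, 100)

  al1 <- global_align(c(a = "A"), c(b = "A"))
  expect_equal(al1$aligned_a, "A")
  expect_equal(al1$aligned_b, "A")

  al2 <- global_align(c(a = "AC"), c(b = "AGC"))
  expect_equal(nchar(al2$aligned_a), 3)
  expect_equal(sum(strsplit(paste0(al2$aligned_a, al2$aligned_b), "")[[1]] == "-"), 1)
  expect_equal(al2$score,
               blosum62["A", "A"] + blosum62["C", "C"] - 11)

  expect_error(global_align(c(a = ""), c(b = "A")), "empty")
})

test_that("alignment ungaps back to its inputs", {
  set.seed(5)
  for (rep in 1:10) {
    a <- random_protein(sample(5:40, 1)); b <- random_protein(sample(5:40, 1))
    al <- global_align(c(a = a), c(b = b))
    expect_equal(gsub("-", "", al$aligned_a), a)
    expect_equal(gsub("-", "", al$aligned_b), b)
    expect_equal(nchar(al$aligned_a), nchar(al$aligned_b))
  }
})

test_that("NW score equals brute-force enumeration for short sequences", {
  set.seed(31)
  for (rep in 1:12) {
    a <- random_protein(sample(1:5, 1)); b <- random_protein(sample(1:5, 1))
    al <- global_align(c(a = a), c(b = b))
    expect_equal(al$score, nw_brute(a, b, blosum62), info = paste(a, b))
  }
})

test_that("NW score agrees with Biostrings::pairwiseAlignment", {
  set.seed(37)
  for (rep in 1:8) {
    a <- random_protein(sample(10:60, 1)); b <- random_protein(sample(10:60, 1))
    al <- global_align(c(a = a), c(b = b))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
      type = "global", scoreOnly = TRUE)
    expect_equal(al$score, ref, info = paste(a, b))
  }
})

test_that("distance matrix is 1 - fractional identity and complete", {
  alns <- align_all_pairs(c(x = "MKLV", y = "MKLV", z = "WWWW"))
  D <- distance_matrix(alns)
  expect_equal(D["x", "y"], 0)
  expect_true(isSymmetric(D))
  expect_equal(diag(D), c(x = 0, y = 0, z = 0))
  expect_error(distance_matrix(alns[1:2]), "missing pair")
  half <- global_align(c(a = "AADD"), c(b = "AAKK"))
  expect_equal(1 - half$percent_identity / 100, 0.5)
})

test_that("progressive MSA merges profiles and preserves sequences", {
  msa <- progressive_msa(c(a = "MKLVDD", b = "MKLVDD"))
  expect_false(any(grepl("-", msa)))

  seqs <- c(a = "MKLVAADD", b = "MKLVADD", c = "MKLVADD")
  msa3 <- progressive_msa(seqs)
  expect_equal(unique(nchar(msa3)), 8)
  expect_equal(sum(vapply(strsplit(msa3, ""), function(x) sum(x == "-"), 0)), 2)
  for (id in names(seqs)) expect_equal(gsub("-", "", msa3[[id]]), seqs[[id]])

  bad_guide <- upgma(matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "q"), c("a", "q"))))
  expect_error(progressive_msa(seqs, guide = bad_guide), "guide")
})

test_that("UPGMA reproduces the classic worked example with its tie rule", {
  D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(D)
  expect_equal(tr$height, c(1, 3))
  expect_equal(sort(tr$labels[-tr$merge[1, ]]), c("A", "B"))

  # equidistant taxa: deterministic (A,B) first
  De <- matrix(4, 3, 3, dimnames = list(c("C", "A", "B"), c("C", "A", "B")))
  diag(De) <- 0
  tre <- upgma(De)
  expect_equal(sort(tre$labels[-tre$merge[1, ]]), c("A", "B"))
  expect_equal(tre$height, c(2, 2))

  two <- upgma(matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(two$height, 0.5)
  expect_error(upgma(matrix(0, 1, 1, dimnames = list("A", "A"))), "at least 2")
})

test_that("UPGMA recovers generating ultrametric trees and matches hclust", {
  set.seed(13)
  for (rep in 1:15) {
    n <- sample(4:9, 1)
    D <- random_ultrametric(n)
    tr <- upgma(D)
    expect_equal(tree_cophenetic(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
    # heights are monotone (ultrametric output)
    expect_true(all(diff(tr$height) >= -1e-12))
    # independent route: average-linkage hclust cophenetic distances
    hc <- hclust(as.dist(D), method = "average")
    expect_equal(as.matrix(cophenetic(hc))[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
  }
})

test_that("UPGMA agrees with phangorn on random (non-ultrametric) matrices", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 7
    M <- matrix(runif(n * n, 0.1, 1), n)
    D <- (M + t(M)) / 2; diag(D) <- 0
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    tr <- upgma(D)
    ph <- phangorn::upgma(as.dist(D))
    expect_equal(tree_cophenetic(tr)[ph$tip.label, ph$tip.label],
                 ape::cophenetic.phylo(ph), tolerance = 1e-9)
  }
})

test_that("bootstrap support is 1 for unambiguous splits and lies in [0,1]", {
  msa <- c(a = "AAAAAAAAKK", b = "AAAAAAAAKR",
           c = "WWWWWWWWKK", d = "WWWWWWWWKR")
  tr <- bootstrap_support(msa, n_replicates = 200, seed = 99)
  expect_true(all(tr$support >= 0 & tr$support <= 1))
  keys <- vapply(seq_len(nrow(tr$merge)), function(k) {
    grab <- function(v) if (v < 0) tr$labels[-v] else NULL
    paste(sort(c(grab(tr$merge[k, 1]), grab(tr$merge[k, 2]))), collapse = ",")
  }, "")
  expect_equal(tr$support[keys == "a,b"], 1)
  expect_equal(tr$support[keys == "c,d"], 1)
})

test_that("bootstrap support is reproducible across seeds within sampling error", {
  set.seed(3)
  seqs <- vapply(1:6, function(i) random_protein(60), "")
  names(seqs) <- paste0("s", 1:6)
  msa <- progressive_msa(seqs)
  s1 <- bootstrap_support(msa, 1000, seed = 1)$support
  s2 <- bootstrap_support(msa, 1000, seed = 2)$support
  expect_true(all(abs(s1 - s2) <= 0.05))
})

test_that("sister pairs are the cherries, classed by species prefix", {
  D <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3,
              dimnames = list(c("GmIAA1", "CaIAA2", "GmIAA3"),
                              c("GmIAA1", "CaIAA2", "GmIAA3")))
  sp <- extract_sister_pairs(upgma(D))
  expect_equal(nrow(sp), 1)
  expect_setequal(c(sp$id_a, sp$id_b), c("GmIAA1", "CaIAA2"))
  expect_equal(sp$pair_class, "ortholog")

  # caterpillar of 4: exactly one cherry
  Dc <- matrix(c(0, 1, 4, 8,
                 1, 0, 4, 8,
                 4, 4, 0, 8,
                 8, 8, 8, 0), 4,
               dimnames = list(paste0("Gm", 1:4), paste0("Gm", 1:4)))
  spc <- extract_sister_pairs(upgma(Dc))
  expect_equal(nrow(spc), 1)
  expect_equal(spc$pair_class, "paralog")
  # disjoint leaf sets across pairs on a larger random tree
  set.seed(8)
  Dr <- random_ultrametric(10, labels = paste0("Gm", 1:10))
  spr <- extract_sister_pairs(upgma(Dr))
  expect_false(anyDuplicated(c(spr$id_a, spr$id_b)) > 0)
})
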