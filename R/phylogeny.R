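# Pairwise and progressive protein alignment, distance matrices, UPGMA trees
# with bootstrap support, sister-pair extraction.

# residue <-> integer code (0-based, for the C++ aligner); 20 = gap
aa_encode <- function(seq) {
  res <- strsplit(seq, "")[[1L]]
  codes <- match(res, c(AA20, "-")) - 1L
  if (anyNA(codes)) stop("unknown residue letter '",
                         res[is.na(codes)][1L], "' in sequence")
  codes
}

aa_decode <- function(codes) {
  paste(c(AA20, "-")[codes + 1L], collapse = "")
}

#' Substitution matrix in the package residue order
#'
#' @param name Matrix name available in Biostrings (default BLOSUM62) or a
#'   20x20 numeric matrix with residue dimnames.
#' @return 20x20 numeric matrix ordered like the package alphabet.
#' @keywords internal
resolve_submat <- function(name = "BLOSUM62") {
  if (is.matrix(name)) {
    return(name[AA20, AA20])
  }
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)[AA20, AA20]
}

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment: a gap of length k costs
#' `gap_open + k * gap_extend` (penalties given as positive magnitudes).
#' Percent identity is identities over alignment columns; percent similarity
#' additionally counts non-identical residue pairs with a positive
#' substitution score.
#'
#' @param a,b Amino-acid sequences (character scalars, optionally named) or
#'   one-row [read_fasta()] records.
#' @param substitution_matrix Matrix name or 20x20 matrix (default BLOSUM62).
#' @param gap_open,gap_extend Positive gap penalties (defaults 10 and 1).
#' @return A `pairwise_alignment` list: `id_a`, `id_b`, `aligned_a`,
#'   `aligned_b`, `score`, `percent_identity`, `percent_similarity`.
#' @export
global_align <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 1) {
  grab <- function(x, default) {
    if (is.data.frame(x)) list(id = x$id[1L], seq = x$sequence[1L])
    else list(id = names(x)[1L] %||% default, seq = unname(x[1L]))
  }
  ra <- grab(a, "a"); rb <- grab(b, "b")
  if (!nzchar(ra$seq) || !nzchar(rb$seq)) stop("empty sequence")
  S <- resolve_submat(substitution_matrix)
  res <- .nw_align_cpp(aa_encode(ra$seq), aa_encode(rb$seq), S,
                       gap_open, gap_extend)
  ca <- res$aligned_a; cb <- res$aligned_b
  ncol_aln <- length(ca)
  both <- ca >= 0L & cb >= 0L
  ident <- sum(both & ca == cb)
  mism <- which(both & ca != cb)
  simpos <- sum(S[cbind(ca[mism] + 1L, cb[mism] + 1L)] > 0)
  structure(list(
    id_a = ra$id, id_b = rb$id,
    aligned_a = aa_decode(ifelse(ca < 0L, 20L, ca)),
    aligned_b = aa_decode(ifelse(cb < 0L, 20L, cb)),
    score = res$score,
    percent_identity = 100 * ident / ncol_aln,
    percent_similarity = 100 * (ident + simpos) / ncol_aln
  ), class = "pairwise_alignment")
}

#' All-against-all pairwise alignments
#'
#' @param sequences Named character vector or [read_fasta()] data.frame.
#' @param ... Passed to [global_align()].
#' @return List of `pairwise_alignment` objects covering every unordered
#'   pair.
#' @export
align_all_pairs <- function(sequences, ...) {
  seqs <- as_named_seqs(sequences)
  ids <- names(seqs)
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      out[[length(out) + 1L]] <-
        global_align(seqs[i], seqs[j], ...)
    }
  }
  out
}

as_named_seqs <- function(sequences) {
  if (is.data.frame(sequences)) {
    structure(sequences$sequence, names = sequences$id)
  } else {
    if (is.null(names(sequences))) stop("sequences must be named")
    sequences
  }
}

#' Distance matrix from pairwise alignments
#'
#' Distance is `1 - fractional identity`. Every unordered pair of labels must
#' be covered.
#'
#' @param alignments List of `pairwise_alignment` objects.
#' @return Symmetric numeric matrix with zero diagonal and label dimnames.
#' @export
distance_matrix <- function(alignments) {
  labs <- unique(unlist(lapply(alignments, function(x) c(x$id_a, x$id_b))))
  D <- matrix(NA_real_, length(labs), length(labs), dimnames = list(labs, labs))
  diag(D) <- 0
  for (al in alignments) {
    d <- 1 - al$percent_identity / 100
    D[al$id_a, al$id_b] <- d
    D[al$id_b, al$id_a] <- d
  }
  if (anyNA(D)) {
    idx <- which(is.na(D), arr.ind = TRUE)[1L, ]
    stop("missing pair: ", labs[idx[1L]], " / ", labs[idx[2L]])
  }
  D
}

#' UPGMA clustering of a distance matrix
#'
#' Classic UPGMA: iteratively merge the closest pair of clusters; the new
#' cluster's distance to the rest is the size-weighted arithmetic mean, and
#' each node sits at height d/2 (so the tree is ultrametric). Ties are broken
#' deterministically by the lexicographically smallest merged-label pair
#' (cluster label = smallest leaf label it contains).
#'
#' @param D Symmetric distance matrix with label dimnames (or `dist`).
#' @return An `upgma_tree`: `merge` (hclust convention), `height` (node
#'   heights, distance units), `labels`, `support` (NULL until
#'   [bootstrap_support()] fills it).
#' @export
upgma <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 2L) stop("UPGMA needs at least 2 taxa")
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  stopifnot(isTRUE(all.equal(D, t(D))), all(diag(D) == 0))
  active <- seq_len(n)                    # indices into bookkeeping vectors
  node_of <- -seq_len(n)                  # hclust code of each active cluster
  size <- rep(1L, n)
  clab <- labels                          # smallest leaf label per cluster
  W <- D
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    sub <- W[active, active, drop = FALSE]
    dmin <- min(sub[upper.tri(sub)])
    cand <- which(upper.tri(sub) & sub <= dmin + 1e-15, arr.ind = TRUE)
    keys <- apply(cand, 1L, function(rc) {
      l1 <- clab[active[rc[1L]]]; l2 <- clab[active[rc[2L]]]
      paste(min(l1, l2), max(l1, l2), sep = "\001")
    })
    pick <- cand[order(keys)[1L], ]
    ia <- active[pick[1L]]; ib <- active[pick[2L]]
    merge[step, ] <- sort(c(node_of[ia], node_of[ib]))
    height[step] <- W[ia, ib] / 2
    # weighted-mean update into slot ia
    others <- setdiff(active, c(ia, ib))
    if (length(others)) {
      W[ia, others] <- (size[ia] * W[ia, others] + size[ib] * W[ib, others]) /
        (size[ia] + size[ib])
      W[others, ia] <- W[ia, others]
    }
    size[ia] <- size[ia] + size[ib]
    clab[ia] <- min(clab[ia], clab[ib])
    node_of[ia] <- step
    active <- setdiff(active, ib)
  }
  structure(list(merge = merge, height = height, labels = labels,
                 support = NULL),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree:", length(x$labels), "leaves, root height",
      format(max(x$height)), "\n")
  invisible(x)
}

# leaf-label set per internal node, as canonical keys
clade_keys <- function(merge, labels) {
  sets <- vector("list", nrow(merge))
  for (k in seq_len(nrow(merge))) {
    grab <- function(v) if (v < 0L) labels[-v] else sets[[v]]
    sets[[k]] <- sort(c(grab(merge[k, 1L]), grab(merge[k, 2L])))
  }
  vapply(sets, paste, "", collapse = "\r")
}

# MSA (named character vector of gapped rows, or character matrix) to
# integer code matrix
msa_to_codes <- function(msa) {
  if (is.matrix(msa) && is.integer(msa)) return(msa)
  rows <- as_named_seqs(msa)
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) stop("MSA rows have unequal lengths")
  codes <- t(vapply(rows, aa_encode, integer(lens[1L])))
  rownames(codes) <- names(rows)
  codes
}

#' Pairwise p-distances from a multiple alignment
#'
#' Mismatch fraction over columns where both rows carry residues (pairwise
#' deletion of gap columns).
#'
#' @param msa Named character vector of equal-length gapped rows.
#' @return Symmetric distance matrix.
#' @export
msa_distances <- function(msa) {
  codes <- msa_to_codes(msa)
  D <- .msa_pdist_cpp(codes)
  dimnames(D) <- list(rownames(codes), rownames(codes))
  D
}

#' Progressive multiple sequence alignment along a guide tree
#'
#' Profiles are merged in guide-tree merge order by profile-profile global
#' alignment (column score = mean pairwise substitution score, affine gap
#' penalties at the profile level). When `guide` is NULL it is built by UPGMA
#' on all-pairs global-alignment distances.
#'
#' @param sequences Named character vector or [read_fasta()] data.frame
#'   (>= 2 sequences).
#' @param guide Optional `upgma_tree` whose leaves equal the sequence ids.
#' @param substitution_matrix,gap_open,gap_extend See [global_align()].
#' @return Named character vector of gapped rows (all equal length), in
#'   input order.
#' @export
progressive_msa <- function(sequences, guide = NULL,
                            substitution_matrix = "BLOSUM62",
                            gap_open = 10, gap_extend = 1) {
  seqs <- as_named_seqs(sequences)
  if (length(seqs) < 2L) stop("progressive MSA needs >= 2 sequences")
  if (is.null(guide)) {
    guide <- upgma(distance_matrix(
      align_all_pairs(seqs, substitution_matrix = substitution_matrix,
                      gap_open = gap_open, gap_extend = gap_extend)))
  }
  if (!setequal(guide$labels, names(seqs))) {
    stop("guide tree leaves do not match sequence ids")
  }
  S <- resolve_submat(substitution_matrix)
  leaf_profile <- function(id) {
    m <- matrix(aa_encode(seqs[[id]]), nrow = 1L)
    rownames(m) <- id
    m
  }
  profiles <- vector("list", nrow(guide$merge))
  for (k in seq_len(nrow(guide$merge))) {
    grab <- function(v) if (v < 0L) leaf_profile(guide$labels[-v]) else profiles[[v]]
    A <- grab(guide$merge[k, 1L]); B <- grab(guide$merge[k, 2L])
    ids <- c(rownames(A), rownames(B))
    M <- .profile_align_cpp(A, B, S, gap_open, gap_extend)
    rownames(M) <- ids
    profiles[[k]] <- M
  }
  final <- profiles[[nrow(guide$merge)]]
  out <- apply(final, 1L, aa_decode)
  out[names(seqs)]
}

#' Bootstrap support for the clades of a UPGMA tree
#'
#' Columns of the MSA are resampled with replacement; each replicate's
#' distance matrix (MSA p-distances) is re-clustered by UPGMA (average
#' linkage via [stats::hclust()], the same agglomeration) and each clade of
#' the full-data tree is scored by the fraction of replicates containing the
#' same leaf set.
#'
#' @param msa Named character vector of gapped rows.
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Optional RNG seed for reproducibility.
#' @param tree Optional full-data `upgma_tree` (computed from `msa` if NULL).
#' @return The full-data `upgma_tree` with `support` filled (fractions in
#'   [0, 1] per internal node, in merge order).
#' @export
bootstrap_support <- function(msa, n_replicates = 1000L, seed = NULL,
                              tree = NULL) {
  codes <- msa_to_codes(msa)
  if (ncol(codes) < 2L) stop("MSA must have >= 2 columns")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree)) {
    D <- .msa_pdist_cpp(codes)
    dimnames(D) <- list(rownames(codes), rownames(codes))
    tree <- upgma(D)
  }
  labels <- tree$labels
  ref_keys <- clade_keys(tree$merge, labels)
  hits <- numeric(length(ref_keys))
  L <- ncol(codes)
  for (r in seq_len(n_replicates)) {
    idx <- sample.int(L, L, replace = TRUE)
    Dr <- .msa_pdist_cpp(codes[, idx, drop = FALSE])
    dimnames(Dr) <- list(rownames(codes), rownames(codes))
    hc <- hclust(as.dist(Dr), method = "average")
    rep_keys <- clade_keys(hc$merge, hc$labels)
    hits <- hits + (ref_keys %in% rep_keys)
  }
  tree$support <- hits / n_replicates
  tree
}

#' Extract sister pairs (cherries) from a tree
#'
#' Every two-leaf internal node is reported; a pair is a paralog pair when
#' both leaves map to the same species, otherwise an ortholog pair.
#'
#' @param tree An `upgma_tree` (or an hclust-style list with `merge` and
#'   `labels`).
#' @param species_of Named character vector (id -> species) or a function of
#'   the leaf id. Default: leading letters of the id (e.g. "GmIAA7" -> "Gm").
#' @return data.frame with `id_a`, `id_b`, `species_a`, `species_b`,
#'   `pair_class`.
#' @export
extract_sister_pairs <- function(tree, species_of = NULL) {
  if (is.null(species_of)) {
    species_of <- function(id) sub("^([A-Za-z]{2}).*$", "\\1", id)
  }
  spp <- if (is.function(species_of)) species_of else function(id) unname(species_of[id])
  m <- tree$merge
  cherries <- which(m[, 1L] < 0L & m[, 2L] < 0L)
  if (!length(cherries)) {
    return(data.frame(id_a = character(), id_b = character(),
                      species_a = character(), species_b = character(),
                      pair_class = character(), stringsAsFactors = FALSE))
  }
  id_a <- tree$labels[-m[cherries, 1L]]
  id_b <- tree$labels[-m[cherries, 2L]]
  sa <- vapply(id_a, spp, ""); sb <- vapply(id_b, spp, "")
  data.frame(id_a = id_a, id_b = id_b, species_a = unname(sa),
             species_b = unname(sb),
             pair_class = ifelse(sa == sb, "paralog", "ortholog"),
             stringsAsFactors = FALSE)
}
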