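# Duplication analysis: collinearity-chain detection, duplication-mode
# classification, Nei-Gojobori Ka/Ks, synonymous-rate dating and WGD event
# binning.

genetic_code <- function() Biostrings::GENETIC_CODE

translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L) stop("CDS length not a multiple of 3")
  codons <- substring(cds, seq(1, nchar(cds), 3L), seq(3, nchar(cds), 3L))
  aa <- unname(genetic_code()[codons])
  if (anyNA(aa)) stop("invalid codon '", codons[is.na(aa)][1L], "'")
  paste(aa, collapse = "")
}

# Nei-Gojobori synonymous/nonsynonymous site counts for one sense codon.
# Per position: fraction of single-base changes preserving the amino acid,
# among changes that do not create a stop codon (stop-excluded
# renormalization).
ng_sites_one <- function(codon) {
  gc <- genetic_code()
  aa <- gc[[codon]]
  if (is.null(aa) || aa == "*") stop("stop or invalid codon: ", codon)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1L]]
  s <- 0
  for (p in 1:3) {
    syn <- 0L; valid <- 0L
    for (b in setdiff(bases, chars[p])) {
      alt <- chars; alt[p] <- b
      aa2 <- gc[[paste(alt, collapse = "")]]
      if (aa2 == "*") next
      valid <- valid + 1L
      if (aa2 == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

.ng_site_cache <- new.env(parent = emptyenv())

#' Nei-Gojobori site counts for a codon
#'
#' @param codon Sense codon (3 letters over ACGT).
#' @return Named numeric vector `c(s, n)` with `s + n == 3`.
#' @export
ng_site_counts <- function(codon) {
  codon <- toupper(codon)
  hit <- .ng_site_cache[[codon]]
  if (!is.null(hit)) return(hit)
  out <- ng_sites_one(codon)
  assign(codon, out, envir = .ng_site_cache)
  out
}

perms_of <- function(k) {
  if (k == 1L) return(list(1L))
  if (k == 2L) return(list(c(1L, 2L), c(2L, 1L)))
  list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L), c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L))
}

#' Nei-Gojobori synonymous/nonsynonymous differences between two codons
#'
#' Zero differences give (0, 0); one difference is classified directly;
#' multi-base differences are averaged over all orderings of single-base
#' steps, excluding pathways that pass through a stop codon. If every pathway
#' is blocked, the average is taken over all pathways with steps through
#' stops counted as nonsynonymous, and the result is flagged
#' (`attr(., "blocked")`).
#'
#' @param codon_a,codon_b Sense codons.
#' @return Named numeric vector `c(sd, nd)`; attribute `blocked` (logical).
#' @export
ng_codon_diff <- function(codon_a, codon_b) {
  gc <- genetic_code()
  a <- strsplit(toupper(codon_a), "")[[1L]]
  b <- strsplit(toupper(codon_b), "")[[1L]]
  if (is.null(gc[[codon_a]]) || gc[[codon_a]] == "*" ||
      is.null(gc[[codon_b]]) || gc[[codon_b]] == "*") {
    stop("sense codons required")
  }
  diffs <- which(a != b)
  if (length(diffs) == 0L) {
    return(structure(c(sd = 0, nd = 0), blocked = FALSE))
  }
  valid <- list(); fallback <- list()
  for (ord in perms_of(length(diffs))) {
    cur <- a; sd <- 0; nd <- 0; hit_stop <- FALSE
    for (p in diffs[ord]) {
      prev_aa <- gc[[paste(cur, collapse = "")]]
      cur[p] <- b[p]
      cur_aa <- gc[[paste(cur, collapse = "")]]
      if (cur_aa == "*") hit_stop <- TRUE
      if (prev_aa != "*" && cur_aa != "*" && prev_aa == cur_aa) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
    }
    fallback[[length(fallback) + 1L]] <- c(sd, nd)
    if (!hit_stop) valid[[length(valid) + 1L]] <- c(sd, nd)
  }
  use <- if (length(valid)) valid else fallback
  avg <- Reduce(`+`, use) / length(use)
  structure(c(sd = avg[1L], nd = avg[2L]), blocked = length(valid) == 0L)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each residue column becomes the corresponding codon column; gap residues
#' become `"---"` markers. The CDS must be exactly 3x the ungapped protein
#' length and translate to it under the standard code, with no internal stop.
#'
#' @param alignment `pairwise_alignment`, or list with `aligned_a`,
#'   `aligned_b` gapped protein strings.
#' @param cds_a,cds_b Coding sequences for the two proteins.
#' @return List of class `codon_alignment` with `codons_a`, `codons_b`
#'   (character vectors, `"---"` marking gaps).
#' @export
back_translate <- function(alignment, cds_a, cds_b) {
  row_codons <- function(aligned, cds) {
    prot <- gsub("-", "", aligned)
    cds <- toupper(cds)
    if (nchar(cds) != 3L * nchar(prot)) {
      stop("CDS length ", nchar(cds), " != 3 x protein length ", nchar(prot))
    }
    codons <- substring(cds, seq(1, nchar(cds), 3L), seq(3, nchar(cds), 3L))
    aa <- unname(genetic_code()[codons])
    if (any(aa == "*")) stop("internal stop codon in CDS")
    if (paste(aa, collapse = "") != prot) {
      stop("CDS does not translate to the aligned protein")
    }
    out <- character(nchar(aligned))
    res <- strsplit(aligned, "")[[1L]]
    out[res == "-"] <- "---"
    out[res != "-"] <- codons
    out
  }
  structure(list(codons_a = row_codons(alignment$aligned_a, cds_a),
                 codons_b = row_codons(alignment$aligned_b, cds_b)),
            class = "codon_alignment")
}

#' Nei-Gojobori Ka/Ks for a codon alignment
#'
#' Site counts are averaged between the two sequences; proportions
#' `pN = Nd/N`, `pS = Sd/S` are Jukes-Cantor corrected,
#' `d = -(3/4) log(1 - (4/3) p)`. The ratio is defined only when `Ks > 0`.
#'
#' @param codon_alignment A `codon_alignment` from [back_translate()], or a
#'   list with `codons_a`, `codons_b`.
#' @return List: `Ka`, `Ks`, `ratio` (NA when Ks == 0), `S`, `N`, `Sd`, `Nd`,
#'   `codons` (ungapped columns used), `blocked_pathways` (count).
#' @export
ng_kaks <- function(codon_alignment) {
  ca <- codon_alignment$codons_a
  cb <- codon_alignment$codons_b
  use <- ca != "---" & cb != "---"
  ca <- ca[use]; cb <- cb[use]
  if (length(ca) == 0L) stop("no ungapped codon columns")
  sites_a <- vapply(ca, ng_site_counts, c(s = 0, n = 0))
  sites_b <- vapply(cb, ng_site_counts, c(s = 0, n = 0))
  S <- (sum(sites_a["s", ]) + sum(sites_b["s", ])) / 2
  N <- (sum(sites_a["n", ]) + sum(sites_b["n", ])) / 2
  Sd <- 0; Nd <- 0; blocked <- 0L
  for (i in seq_along(ca)) {
    d <- ng_codon_diff(ca[i], cb[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
    if (isTRUE(attr(d, "blocked"))) blocked <- blocked + 1L
  }
  jc <- function(p, what) {
    if (p >= 3 / 4) stop("saturation: ", what, " proportion ", format(p),
                         " >= 3/4, Jukes-Cantor distance undefined")
    -0.75 * log(1 - 4 * p / 3)
  }
  pS <- Sd / S; pN <- Nd / N
  Ks <- jc(pS, "synonymous"); Ka <- jc(pN, "nonsynonymous")
  list(Ka = Ka, Ks = Ks, ratio = if (Ks > 0) Ka / Ks else NA_real_,
       S = S, N = N, Sd = Sd, Nd = Nd, codons = length(ca),
       blocked_pathways = blocked)
}

#' Dating parameters for duplication-event assignment
#'
#' @param rate Synonymous substitution rate (substitutions/site/year).
#' @param glycine_max_ks Ks below which a pair postdates the Glycine WGD.
#' @param gamma_min_ks Ks above which a pair predates the legume WGD
#'   (gamma whole-genome triplication).
#' @return List of parameters.
#' @export
dating_params <- function(rate = 6.1e-9, glycine_max_ks = 0.3,
                          gamma_min_ks = 1.3) {
  stopifnot(rate > 0, glycine_max_ks > 0, glycine_max_ks < gamma_min_ks)
  list(rate = rate, glycine_max_ks = glycine_max_ks,
       gamma_min_ks = gamma_min_ks)
}

#' Divergence time from a synonymous distance
#'
#' `T = Ks / (2 * rate) * 1e-6` million years.
#'
#' @param ks Synonymous substitutions per site (>= 0).
#' @param params See [dating_params()].
#' @return Divergence time in Mya (vectorized).
#' @export
divergence_time <- function(ks, params = dating_params()) {
  if (any(ks < 0)) stop("negative Ks")
  ks / (2 * params$rate) * 1e-6
}

#' Assign a duplicate pair to a whole-genome duplication event by Ks
#'
#' Ks below `glycine_max_ks` postdates the Glycine WGD; Ks above
#' `gamma_min_ks` postdates only the gamma WGT; the closed interval between
#' them is assigned to the legume WGD.
#'
#' @param ks Synonymous distance(s), >= 0.
#' @param params See [dating_params()].
#' @return Character vector over `c("glycine_wgd", "legume_wgd",
#'   "gamma_wgt")`.
#' @export
assign_wgd_event <- function(ks, params = dating_params()) {
  if (any(ks < 0)) stop("negative Ks")
  ifelse(ks < params$glycine_max_ks, "glycine_wgd",
         ifelse(ks <= params$gamma_min_ks, "legume_wgd", "gamma_wgt"))
}

#' Detect collinear (syntenic) blocks by anchor chaining
#'
#' Per chromosome pair, maximal chains of anchors are found by dynamic
#' programming over anchors sorted by `order_a`: `order_b` must be strictly
#' monotone (increasing = `same` orientation, decreasing = `inverted`) and
#' gene-order index gaps bounded by `max_index_gap` on both genomes. Chains
#' are extracted greedily (longest first); each anchor belongs to at most one
#' block and chains shorter than `min_anchors` are dropped.
#'
#' @param anchors data.frame with columns `gene_a`, `gene_b`, `chrom_a`,
#'   `chrom_b`, `order_a`, `order_b`.
#' @param min_anchors Minimum anchors per reported block.
#' @param max_index_gap Maximum gene-order gap between consecutive anchors.
#' @return List with `blocks` (data.frame: `block_id`, `chrom_a`, `chrom_b`,
#'   `orientation`, `n_anchors`) and `anchors` (input rows plus `block_id`,
#'   NA when unassigned).
#' @export
detect_collinear_blocks <- function(anchors, min_anchors = 5L,
                                    max_index_gap = 25L) {
  need <- c("gene_a", "gene_b", "chrom_a", "chrom_b", "order_a", "order_b")
  stopifnot(all(need %in% names(anchors)))
  anchors$block_id <- rep(NA_character_, nrow(anchors))
  blocks <- list()
  grp <- paste(anchors$chrom_a, anchors$chrom_b, sep = "\001")
  next_id <- 1L
  for (g in unique(grp)) {
    idx <- which(grp == g)
    repeat {
      avail <- idx[is.na(anchors$block_id[idx])]
      if (length(avail) < min_anchors) break
      oa <- anchors$order_a[avail]; ob <- anchors$order_b[avail]
      ord <- order(oa, ob)
      avail <- avail[ord]; oa <- oa[ord]; ob <- ob[ord]
      best_chain <- NULL; best_dir <- NA_character_
      for (dir in c("same", "inverted")) {
        k <- length(avail)
        len <- rep(1L, k); prev <- rep(0L, k)
        for (i in seq_len(k)) {
          for (j in seq_len(i - 1L)) {
            if (oa[i] <= oa[j]) next
            if (oa[i] - oa[j] > max_index_gap) next
            okb <- if (dir == "same") {
              ob[i] > ob[j] && ob[i] - ob[j] <= max_index_gap
            } else {
              ob[i] < ob[j] && ob[j] - ob[i] <= max_index_gap
            }
            if (okb && len[j] + 1L > len[i]) {
              len[i] <- len[j] + 1L; prev[i] <- j
            }
          }
        }
        top <- which.max(len)
        if (is.null(best_chain) || len[top] > length(best_chain)) {
          chain <- integer(); i <- top
          while (i != 0L) { chain <- c(i, chain); i <- prev[i] }
          best_chain <- avail[chain]; best_dir <- dir
        }
      }
      if (length(best_chain) < min_anchors) break
      id <- paste0("B", next_id); next_id <- next_id + 1L
      anchors$block_id[best_chain] <- id
      blocks[[id]] <- data.frame(
        block_id = id,
        chrom_a = anchors$chrom_a[best_chain[1L]],
        chrom_b = anchors$chrom_b[best_chain[1L]],
        orientation = best_dir, n_anchors = length(best_chain),
        stringsAsFactors = FALSE)
    }
  }
  blocks_df <- if (length(blocks)) do.call(rbind, unname(blocks)) else
    data.frame(block_id = character(), chrom_a = character(),
               chrom_b = character(), orientation = character(),
               n_anchors = integer(), stringsAsFactors = FALSE)
  list(blocks = blocks_df, anchors = anchors)
}

#' Two-sided transposable-element flanking test
#'
#' TRUE when at least one TE lies wholly upstream within `window` bp of the
#' gene start AND at least one lies wholly downstream within `window` bp of
#' the gene end, on the gene's chromosome.
#'
#' @param gene Gene model.
#' @param te_annotations data.frame from [read_bed()].
#' @param window Flanking window in bp (default 10 kb).
#' @return List: `flag`, `upstream` and `downstream` TE ids.
#' @export
flanking_te_test <- function(gene, te_annotations, window = 10000L) {
  te <- te_annotations[te_annotations$chromosome == gene$chromosome, , drop = FALSE]
  up <- te[te$end < gene$start & gene$start - te$end <= window, , drop = FALSE]
  down <- te[te$start > gene$end & te$start - gene$end <= window, , drop = FALSE]
  list(flag = nrow(up) > 0L && nrow(down) > 0L,
       upstream = up$te_id, downstream = down$te_id)
}

#' Classify the duplication mode of every family gene
#'
#' Precedence per gene: (1) participates in an anchor assigned to a collinear
#' block -> `wgd_segmental`; (2) member of a tandem cluster -> `tandem`;
#' (3) has a family homolog elsewhere (family size > 1), is outside all
#' blocks/clusters, and passes the two-sided TE flanking test ->
#' `transposed`; (4) otherwise `dispersed`. Exactly one mode per gene.
#'
#' @param catalog A `gene_catalog`.
#' @param blocks Result of [detect_collinear_blocks()].
#' @param clusters Result of [detect_tandem_clusters()].
#' @param te_annotations data.frame from [read_bed()] (may be empty).
#' @param window TE flanking window, see [flanking_te_test()].
#' @return data.frame with `gene_id`, `mode`, `evidence`.
#' @export
classify_duplication_mode <- function(catalog, blocks, clusters,
                                      te_annotations = NULL,
                                      window = 10000L) {
  fam <- catalog$family_ids
  anch <- blocks$anchors
  in_block <- function(g) {
    hit <- anch$block_id[(anch$gene_a == g | anch$gene_b == g) & !is.na(anch$block_id)]
    if (length(hit)) hit[1L] else NA_character_
  }
  cluster_members <- strsplit(clusters$members, ",")
  in_cluster <- function(g) {
    hit <- which(vapply(cluster_members, function(m) g %in% m, TRUE))
    if (length(hit)) clusters$cluster_id[hit[1L]] else NA_character_
  }
  rows <- lapply(fam, function(g) {
    b <- in_block(g)
    if (!is.na(b)) {
      return(data.frame(gene_id = g, mode = "wgd_segmental",
                        evidence = b, stringsAsFactors = FALSE))
    }
    cl <- in_cluster(g)
    if (!is.na(cl)) {
      return(data.frame(gene_id = g, mode = "tandem", evidence = cl,
                        stringsAsFactors = FALSE))
    }
    if (length(fam) > 1L && !is.null(te_annotations) && nrow(te_annotations)) {
      ft <- flanking_te_test(catalog$genes[[g]], te_annotations, window)
      if (ft$flag) {
        return(data.frame(
          gene_id = g, mode = "transposed",
          evidence = paste(c(ft$upstream[1L], ft$downstream[1L]), collapse = ","),
          stringsAsFactors = FALSE))
      }
    }
    data.frame(gene_id = g, mode = "dispersed", evidence = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ka/Ks, dating and event assignment for duplicate gene pairs
#'
#' For each pair: global protein alignment, back-translation to codons,
#' Nei-Gojobori Ka/Ks, divergence time and WGD-event bin.
#'
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @param proteins Named character vector of protein sequences.
#' @param cds Named character vector of coding sequences.
#' @param params See [dating_params()].
#' @param ... Passed to [global_align()].
#' @return data.frame: pair ids, `Ka`, `Ks`, `ratio`, `S`, `N`, `T_mya`,
#'   `event`.
#' @export
kaks_table <- function(pairs, proteins, cds, params = dating_params(), ...) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    al <- global_align(structure(proteins[ga], names = ga),
                       structure(proteins[gb], names = gb), ...)
    res <- ng_kaks(back_translate(al, cds[[ga]], cds[[gb]]))
    data.frame(gene_a = ga, gene_b = gb, Ka = res$Ka, Ks = res$Ks,
               ratio = res$ratio, S = res$S, N = res$N,
               T_mya = divergence_time(res$Ks, params),
               event = assign_wgd_event(res$Ks, params),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
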