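# Synthetic-data generation: complete fixture worlds (proteome, genome +
# annotation, TEs, anchors, promoters with planted cis-elements, codon pairs
# at target divergence, expression matrices) that encode the packaged family
# catalogs, so the whole pipeline can be validated label-by-label.

DNA4 <- c("A", "C", "G", "T")

# concrete instances used when planting motifs into family proteins
MOTIF_INSTANCES <- c(I = "LRLGLS", II = "GWPPV",
                     III = "VKVSMDGAPYLRK", IV = "GDVPWEMFVDSCKRLR")

syn_codon_table <- function() {
  gc <- genetic_code()
  split(names(gc), gc)
}

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
random_dna <- function(n) paste(sample(DNA4, n, replace = TRUE), collapse = "")

# random back-translation: one codon per residue, uniform over synonyms
back_translate_random <- function(protein) {
  tab <- syn_codon_table()
  res <- strsplit(protein, "")[[1L]]
  paste(vapply(res, function(a) {
    opts <- tab[[a]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, ""), collapse = "")
}

#' Simulation configuration defaults
#'
#' Defaults encode the study conditions the fixtures emulate: 1 kb promoters,
#' a two-sided 10 kb TE window, tandem neighbours strictly adjacent, WGD pair
#' ages concentrated in the recent (Glycine) Ks bin with a legume-aged
#' minority, purifying selection at omega = 0.2, deep single-library RNA-seq
#' per tissue (gamma-Poisson, size 80), and paralog latent-profile
#' correlations 0.95 (conserved) / 0.2 (diverged).
#'
#' @param ... Named overrides of any default.
#' @return Named list of generator parameters.
#' @export
sim_config <- function(...) {
  cfg <- list(
    intergenic_bp = 1500L, promoter_bp = 1000L, tail_bp = 15000L,
    decoy_lead = 2L, decoy_between = 3L, decoy_trail = 2L, decoy_empty = 4L,
    bg_ranges = list(c(15L, 40L), c(20L, 50L), c(20L, 50L), c(15L, 40L),
                     c(10L, 30L)),
    decoy_aa = c(120L, 250L),
    exons_family = c(2L, 5L), exons_decoy = c(1L, 3L),
    intron_bp = c(100L, 400L),
    te_dist = c(2000L, 6000L), te_len = c(300L, 800L),
    ds_tandem = c(0.02, 0.08), ds_glycine = c(0.08, 0.28),
    ds_legume = c(0.35, 0.60), p_glycine = 0.75, omega = 0.2,
    n_plant = c(2L, 4L),
    expr_sd_profile = 2.5, expr_base_log2 = 5, expr_base_sd = 1,
    expr_nb_size = 80, expr_libsize = 2e7,
    rho_high = 0.95, rho_low = 0.2,
    stress_reps = 3L, stress_de_frac = 0.3, stress_de_lfc = 2
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

# ---------------------------------------------------------------------------
# codon-pair evolution

ng_total_syn_sites <- function(codons) {
  sum(vapply(codons, function(cd) ng_site_counts(cd)[["s"]], 0))
}

split_codons <- function(cds) {
  substring(cds, seq(1, nchar(cds), 3L), seq(3, nchar(cds), 3L))
}

evolve_branch <- function(codons, dS_branch, omega, frozen = integer()) {
  gc <- genetic_code()
  L <- length(codons)
  S0 <- ng_total_syn_sites(codons)
  target <- round(dS_branch * S0)
  if (target == 0L) return(codons)
  syn_done <- 0L
  it <- 0L
  cap <- 2000L * target + 20000L
  while (syn_done < target) {
    it <- it + 1L
    if (it > cap) stop("unreachable dS target before iteration cap")
    ci <- sample.int(L, 1L)
    pos <- sample.int(3L, 1L)
    chars <- strsplit(codons[ci], "")[[1L]]
    newb <- sample(setdiff(DNA4, chars[pos]), 1L)
    alt <- chars; alt[pos] <- newb
    alt_codon <- paste(alt, collapse = "")
    aa_old <- gc[[codons[ci]]]
    aa_new <- gc[[alt_codon]]
    if (aa_new == "*") next
    if (aa_new == aa_old) {
      codons[ci] <- alt_codon
      syn_done <- syn_done + 1L
    } else {
      if (ci %in% frozen) next
      if (runif(1) < omega) codons[ci] <- alt_codon
    }
  }
  codons
}

#' Evolve a duplicate codon-sequence pair from an ancestor
#'
#' Random single-base substitutions are applied independently along two
#' branches (dS_target/2 each): synonymous changes are always accepted,
#' nonsynonymous changes with relative probability `omega`, and changes
#' creating a stop codon never. Substitution stops when the accumulated
#' synonymous changes per ancestral synonymous site reach the branch target,
#' so the pair's expected synonymous divergence is `dS_target`.
#'
#' @param ancestor_cds Sense-codon coding sequence (no internal stops).
#' @param dS_target Target synonymous divergence of the pair (< 0.75).
#' @param omega Relative fixation probability of nonsynonymous changes.
#' @param seed Optional RNG seed.
#' @param frozen_codons Codon indices where nonsynonymous changes are
#'   rejected regardless of `omega` (used to protect planted motifs).
#' @return List with `cds_a`, `cds_b`.
#' @export
evolve_codon_pair <- function(ancestor_cds, dS_target, omega, seed = NULL,
                              frozen_codons = integer()) {
  if (dS_target < 0) stop("negative dS target")
  if (dS_target >= 0.75) stop("dS target must be < 0.75 (Jukes-Cantor saturation)")
  if (!is.null(seed)) set.seed(seed)
  codons <- split_codons(toupper(ancestor_cds))
  gc <- genetic_code()
  aa <- unname(gc[codons])
  if (anyNA(aa) || any(aa == "*")) stop("ancestor must be sense codons")
  list(cds_a = paste(evolve_branch(codons, dS_target / 2, omega, frozen_codons),
                     collapse = ""),
       cds_b = paste(evolve_branch(codons, dS_target / 2, omega, frozen_codons),
                     collapse = ""))
}

# ---------------------------------------------------------------------------
# family protein/CDS construction

# one family protein with planted motif blocks; motif II included iff
# canonical slot. Returns protein, cds, and per-motif codon ranges.
make_family_cds <- function(cfg, with_motif_II = TRUE) {
  bg <- vapply(cfg$bg_ranges, function(r) sample(r[1L]:r[2L], 1L), 0L)
  parts <- list(random_aa(bg[1L]), MOTIF_INSTANCES[["I"]], random_aa(bg[2L]))
  motif_pos <- c(I = bg[1L] + 1L)
  cursor <- bg[1L] + nchar(MOTIF_INSTANCES[["I"]]) + bg[2L]
  if (with_motif_II) {
    parts <- c(parts, MOTIF_INSTANCES[["II"]])
    motif_pos[["II"]] <- cursor + 1L
    cursor <- cursor + nchar(MOTIF_INSTANCES[["II"]])
  }
  parts <- c(parts, random_aa(bg[3L]), MOTIF_INSTANCES[["III"]])
  motif_pos[["III"]] <- cursor + bg[3L] + 1L
  cursor <- cursor + bg[3L] + nchar(MOTIF_INSTANCES[["III"]])
  parts <- c(parts, random_aa(bg[4L]), MOTIF_INSTANCES[["IV"]])
  motif_pos[["IV"]] <- cursor + bg[4L] + 1L
  parts <- c(parts, random_aa(bg[5L]))
  protein <- paste(unlist(parts), collapse = "")
  frozen <- unlist(lapply(names(motif_pos), function(m) {
    seq(motif_pos[[m]], motif_pos[[m]] + nchar(MOTIF_INSTANCES[[m]]) - 1L)
  }))
  list(protein = protein, cds = back_translate_random(protein),
       motif_pos = motif_pos, frozen = frozen)
}

# remove every motif II (degron) occurrence from a CDS except an allowed
# span, by swapping the W codon for an alanine codon (GWPPx -> GAPPx)
scrub_motif_II <- function(cds, keep_start = NA_integer_) {
  pat <- "GWPP[VI]"
  repeat {
    prot <- translate_cds(cds)
    m <- gregexpr(gsub("x", ".", pat), prot, perl = TRUE)[[1L]]
    hits <- as.integer(m[m != -1L])
    hits <- hits[is.na(keep_start) | hits != keep_start]
    if (!length(hits)) return(cds)
    w_res <- hits[1L] + 1L                       # the W residue
    codon_at <- (w_res - 1L) * 3L + 1L
    substr(cds, codon_at, codon_at + 2L) <- "GCT" # Ala
  }
}

# knock out the degron of a non-canonical gene copy: GWPPV -> GAPPV
knockout_motif_II <- function(cds, motif_II_res) {
  w_res <- motif_II_res + 1L
  codon_at <- (w_res - 1L) * 3L + 1L
  substr(cds, codon_at, codon_at + 2L) <- "GCT"
  cds
}

draw_pair_ds <- function(pair_type, cfg) {
  if (pair_type == "tandem") {
    runif(1, cfg$ds_tandem[1L], cfg$ds_tandem[2L])
  } else if (runif(1) < cfg$p_glycine) {
    runif(1, cfg$ds_glycine[1L], cfg$ds_glycine[2L])
  } else {
    runif(1, cfg$ds_legume[1L], cfg$ds_legume[2L])
  }
}

# build CDS + protein for every family gene, respecting pair ancestry and
# per-gene canonical status
build_family_sequences <- function(catalog, cfg) {
  genes <- catalog$genes
  pairs <- catalog$pairs
  cds <- list(); motif_pos <- list()
  seq_pairs <- pairs[pairs$pair_type %in% c("wgd", "tandem"), , drop = FALSE]
  for (i in seq_len(nrow(seq_pairs))) {
    a <- seq_pairs$gene_a[i]; b <- seq_pairs$gene_b[i]
    ds <- draw_pair_ds(seq_pairs$pair_type[i], cfg)
    have_a <- !is.null(cds[[a]]); have_b <- !is.null(cds[[b]])
    if (!have_a && !have_b) {
      anc <- make_family_cds(cfg, with_motif_II = TRUE)
      # residue indices equal codon indices (one codon per residue)
      ev <- evolve_codon_pair(anc$cds, ds, cfg$omega,
                              frozen_codons = anc$frozen)
      cds[[a]] <- ev$cds_a; cds[[b]] <- ev$cds_b
      motif_pos[[a]] <- anc$motif_pos; motif_pos[[b]] <- anc$motif_pos
    } else {
      src <- if (have_a) a else b
      dst <- if (have_a) b else a
      frozen <- unlist(lapply(names(motif_pos[[src]]), function(m) {
        seq(motif_pos[[src]][[m]],
            motif_pos[[src]][[m]] + nchar(MOTIF_INSTANCES[[m]]) - 1L)
      }))
      cds[[dst]] <- paste(
        evolve_branch(split_codons(cds[[src]]), ds, cfg$omega, frozen),
        collapse = "")
      motif_pos[[dst]] <- motif_pos[[src]]
    }
  }
  for (g in genes$gene_id) {
    if (is.null(cds[[g]])) {
      one <- make_family_cds(cfg, with_motif_II = genes$canonical[genes$gene_id == g])
      cds[[g]] <- one$cds
      motif_pos[[g]] <- one$motif_pos
    }
  }
  # enforce per-gene degron status and scrub spurious degrons
  for (g in genes$gene_id) {
    canon <- genes$canonical[genes$gene_id == g]
    ii <- motif_pos[[g]]["II"]
    has_slot <- !is.na(ii)
    if (!canon && has_slot) {
      cds[[g]] <- knockout_motif_II(cds[[g]], as.integer(ii))
      has_slot <- FALSE
    }
    cds[[g]] <- scrub_motif_II(cds[[g]],
                               keep_start = if (has_slot) as.integer(ii) else NA_integer_)
  }
  proteins <- vapply(cds, translate_cds, "")
  list(cds = unlist(cds), proteins = proteins, motif_pos = motif_pos)
}

make_decoy_cds <- function(cfg) {
  n <- sample(cfg$decoy_aa[1L]:cfg$decoy_aa[2L], 1L)
  cds <- scrub_motif_II(back_translate_random(random_aa(n)))
  cds
}

# ---------------------------------------------------------------------------
# promoter assembly with planted cis-elements

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

iupac_to_regex <- function(pattern) {
  paste(vapply(strsplit(pattern, "")[[1L]], function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, ""), collapse = "")
}

# all match starts of an IUPAC pattern in seq, forward and (as '-' strand,
# forward coordinates) reverse complement; overlapping matches included
iupac_hits <- function(seq, pattern) {
  find <- function(p) {
    m <- gregexpr(paste0("(?=", iupac_to_regex(p), ")"), seq, perl = TRUE)[[1L]]
    as.integer(m[m != -1L])
  }
  list(fwd = find(pattern), rev = find(revcomp(pattern)))
}

instantiate_iupac <- function(pattern) {
  paste(vapply(strsplit(pattern, "")[[1L]],
               function(ch) { s <- IUPAC_SETS[[ch]]
                 if (length(s) == 1L) s else sample(s, 1L) }, ""),
        collapse = "")
}

# instance must not itself contain a match of any library pattern other than
# the intended one at offset 1
clean_instance <- function(pattern, library, tries = 50L) {
  for (t in seq_len(tries)) {
    inst <- instantiate_iupac(pattern)
    ok <- TRUE
    for (i in seq_len(nrow(library))) {
      h <- iupac_hits(inst, library$pattern[i])
      pos <- c(h$fwd, h$rev)
      if (library$pattern[i] == pattern) {
        pos <- setdiff(pos, 1L)  # intended plant (either strand)
      }
      if (length(pos)) { ok <- FALSE; break }
    }
    if (ok) return(inst)
  }
  stop("could not instantiate a clean element instance for ", pattern)
}

# build one promoter: plant chosen elements, then mutate away every
# background match of any library element
build_promoter <- function(len, plants, library, max_iter = 500L) {
  lib_len <- structure(nchar(library$pattern), names = library$element_id)
  seqv <- sample(DNA4, len, replace = TRUE)
  spans <- integer(0)   # positions covered by planted instances
  for (i in seq_len(nrow(plants))) {
    inst <- strsplit(plants$instance[i], "")[[1L]]
    at <- plants$position[i]
    seqv[at:(at + length(inst) - 1L)] <- inst
    spans <- c(spans, at:(at + length(inst) - 1L))
  }
  planted_ok <- function(el, from, to) {
    any(plants$element_id == el &
          plants$position <= to &
          plants$position + nchar(plants$instance) - 1L >= from)
  }
  for (iter in seq_len(max_iter)) {
    seqs <- paste(seqv, collapse = "")
    dirty <- FALSE
    for (i in seq_len(nrow(library))) {
      el <- library$element_id[i]
      h <- iupac_hits(seqs, library$pattern[i])
      for (pos in unique(c(h$fwd, h$rev))) {
        to <- pos + lib_len[[el]] - 1L
        if (planted_ok(el, pos, to)) next
        mut <- setdiff(pos:to, spans)
        if (!length(mut)) {
          stop("spurious element hit nested inside planted spans")
        }
        p <- mut[sample.int(length(mut), 1L)]
        seqv[p] <- sample(setdiff(DNA4, seqv[p]), 1L)
        dirty <- TRUE
      }
      if (dirty) break
    }
    if (!dirty) return(paste(seqv, collapse = ""))
  }
  stop("promoter scrub did not converge")
}

plan_plants <- function(gene_id, library, cfg) {
  n <- sample(cfg$n_plant[1L]:cfg$n_plant[2L], 1L)
  els <- sample(seq_len(nrow(library)), n)
  # spaced, non-overlapping positions
  pos <- sort(sample(seq(15L, cfg$promoter_bp - 30L, by = 30L), n))
  data.frame(gene_id = gene_id,
             element_id = library$element_id[els],
             pattern = library$pattern[els],
             position = pos,
             instance = vapply(library$pattern[els], clean_instance, "",
                               library = library),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# genome layout

# per-chromosome ordered entries (family ids and fresh decoy ids)
layout_chromosomes <- function(catalog, cfg) {
  genes <- catalog$genes
  n_chrom <- catalog$n_chromosomes
  decoy_n <- 0L
  new_decoys <- function(k) {
    ids <- sprintf("dec%04d", decoy_n + seq_len(k))
    decoy_n <<- decoy_n + k
    ids
  }
  layouts <- list()
  for (ci in seq_len(n_chrom)) {
    chr <- paste0("chr", ci)
    fam <- genes[genes$chromosome == chr, , drop = FALSE]
    fam <- fam[order(fam$chrom_index), , drop = FALSE]
    entries <- character()
    if (nrow(fam) == 0L) {
      entries <- new_decoys(cfg$decoy_empty)
    } else {
      entries <- new_decoys(cfg$decoy_lead)
      prev_cluster <- ""
      for (k in seq_len(nrow(fam))) {
        cl <- fam$cluster_id[k]
        contiguous <- nzchar(cl) && cl == prev_cluster
        if (!contiguous) entries <- c(entries, new_decoys(cfg$decoy_between))
        entries <- c(entries, fam$gene_id[k])
        prev_cluster <- cl
      }
      entries <- c(entries, new_decoys(cfg$decoy_trail))
    }
    layouts[[chr]] <- entries
  }
  layouts
}

# anchors: for each anchored family pair, map two decoys on each side of
# gene_a onto two decoys on each side of gene_b (inverted mapping when the
# pair runs against the group's direction), so each pair sits inside a
# >= 5-anchor monotone chain
build_anchors <- function(catalog, layouts) {
  genes <- catalog$genes
  fam_ids <- genes$gene_id
  pos_of <- list(); chrom_of <- list()
  for (chr in names(layouts)) {
    for (k in seq_along(layouts[[chr]])) {
      id <- layouts[[chr]][k]
      pos_of[[id]] <- k
      chrom_of[[id]] <- chr
    }
  }
  flank_decoys <- function(id) {
    chr <- chrom_of[[id]]
    lay <- layouts[[chr]]
    k <- pos_of[[id]]
    is_dec <- !(lay %in% fam_ids)
    pre <- rev(lay[seq_len(k - 1L)][is_dec[seq_len(k - 1L)]])[1:2]
    post <- lay[(k + 1L):length(lay)][is_dec[(k + 1L):length(lay)]][1:2]
    list(pre = rev(pre), post = post)   # pre in increasing order
  }
  ap <- catalog$pairs[catalog$pairs$anchor, , drop = FALSE]
  if (nrow(ap) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      chrom_a = character(), chrom_b = character(),
                      order_a = integer(), order_b = integer(),
                      stringsAsFactors = FALSE))
  }
  ap$chrom_a <- vapply(ap$gene_a, function(g) chrom_of[[g]], "")
  ap$chrom_b <- vapply(ap$gene_b, function(g) chrom_of[[g]], "")
  ap$order_a <- vapply(ap$gene_a, function(g) pos_of[[g]], 0L)
  ap$order_b <- vapply(ap$gene_b, function(g) pos_of[[g]], 0L)
  grp <- paste(ap$chrom_a, ap$chrom_b, sep = "\001")
  rows <- list()
  for (g in unique(grp)) {
    sub <- ap[grp == g, , drop = FALSE]
    sub <- sub[order(sub$order_a), , drop = FALSE]
    # one orientation per chromosome pair: follow the partner-order trend so
    # all of a group's segments chain consistently
    inverted <- nrow(sub) > 1L &&
      stats::cor(sub$order_a, sub$order_b, method = "kendall") < 0
    for (i in seq_len(nrow(sub))) {
      fa <- flank_decoys(sub$gene_a[i])
      fb <- flank_decoys(sub$gene_b[i])
      pa <- c(fa$pre, sub$gene_a[i], fa$post)
      pb <- if (inverted) c(rev(fb$post), sub$gene_b[i], rev(fb$pre))
            else c(fb$pre, sub$gene_b[i], fb$post)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = pa, gene_b = pb, stringsAsFactors = FALSE)
    }
  }
  anch <- unique(do.call(rbind, rows))
  anch$chrom_a <- vapply(anch$gene_a, function(x) chrom_of[[x]], "")
  anch$chrom_b <- vapply(anch$gene_b, function(x) chrom_of[[x]], "")
  anch$order_a <- vapply(anch$gene_a, function(x) pos_of[[x]], 0L)
  anch$order_b <- vapply(anch$gene_b, function(x) pos_of[[x]], 0L)
  rownames(anch) <- NULL
  anch
}

# ---------------------------------------------------------------------------
# full world

#' Simulate a complete survey fixture world
#'
#' Builds, deterministically under `seed`, everything the pipeline consumes:
#' family and decoy proteins/CDS (pair ancestry at target dS, degron
#' knockouts per catalog), chromosome sequences with exon-intron gene models,
#' 1 kb promoters carrying planted (and otherwise scrubbed) cis-elements,
#' TE annotations flanking transposed-labeled genes, collinearity anchors
#' realizing the catalog's WGD pairs, and tissue expression counts with the
#' catalog's paralog correlation structure.
#'
#' @param catalog A `published_catalog` from [load_published_catalog()].
#' @param config See [sim_config()].
#' @param seed Integer seed; fixes all outputs.
#' @return List with `proteome`, `cds` (data.frames id/sequence), `genome`
#'   (named chromosome sequences), `gene_models` (list), `gff_lines`,
#'   `te` (data.frame), `anchors`, `planted`, `expression` (list: counts,
#'   lengths, libsizes, stress_counts), `catalog`, `config`, `seed`.
#' @export
sim_world <- function(catalog, config = sim_config(), seed = 1L) {
  cfg <- config
  set.seed(seed)
  lib <- default_element_library()
  fam <- build_family_sequences(catalog, cfg)
  layouts <- layout_chromosomes(catalog, cfg)
  fam_ids <- catalog$genes$gene_id
  # decoy sequences
  all_ids <- unlist(layouts, use.names = FALSE)
  decoy_ids <- setdiff(all_ids, fam_ids)
  decoy_cds <- vapply(decoy_ids, function(i) make_decoy_cds(cfg), "")
  cds_all <- c(fam$cds, decoy_cds)
  prot_all <- c(fam$proteins, vapply(decoy_cds, translate_cds, ""))
  # promoters (family genes only)
  planted <- lapply(fam_ids, function(g) plan_plants(g, lib, cfg))
  names(planted) <- fam_ids
  promoters <- vapply(fam_ids, function(g) {
    build_promoter(cfg$promoter_bp, planted[[g]], lib)
  }, "")
  # chromosome assembly
  strand_of <- structure(sample(c("+", "-"), length(all_ids), replace = TRUE),
                         names = all_ids)
  gene_models <- list()
  chrom_seqs <- character(0)
  te_rows <- list()
  transposed <- catalog$genes$gene_id[catalog$genes$mode == "transposed"]
  for (chr in names(layouts)) {
    chunks <- list()
    cursor <- 0L
    add <- function(s) {
      chunks[[length(chunks) + 1L]] <<- s
      cursor <<- cursor + nchar(s)
    }
    for (id in layouts[[chr]]) {
      add(random_dna(cfg$intergenic_bp))
      is_fam <- id %in% fam_ids
      strand <- strand_of[[id]]
      if (is_fam && strand == "+") add(promoters[[id]])
      # exon-intron structure
      cds <- cds_all[[id]]
      n_ex_rng <- if (is_fam) cfg$exons_family else cfg$exons_decoy
      n_ex <- sample(n_ex_rng[1L]:n_ex_rng[2L], 1L)
      n_codons <- nchar(cds) / 3L
      n_ex <- min(n_ex, n_codons)
      cuts <- if (n_ex > 1L) sort(sample(seq_len(n_codons - 1L), n_ex - 1L)) else integer()
      bounds <- c(0L, cuts, n_codons) * 3L
      pieces <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
      introns <- if (n_ex > 1L) {
        vapply(seq_len(n_ex - 1L),
               function(i) random_dna(sample(cfg$intron_bp[1L]:cfg$intron_bp[2L], 1L)),
               "")
      } else character()
      tx <- pieces[1L]
      t_bounds <- matrix(c(1L, nchar(pieces[1L])), ncol = 2L)
      if (n_ex > 1L) for (i in seq_len(n_ex - 1L)) {
        tx <- paste0(tx, introns[i], pieces[i + 1L])
        t_bounds <- rbind(t_bounds,
                          c(nchar(tx) - nchar(pieces[i + 1L]) + 1L, nchar(tx)))
      }
      Lg <- nchar(tx)
      gstart <- cursor + 1L
      if (strand == "+") {
        exons <- t_bounds + cursor
        add(tx)
      } else {
        exons <- cbind(gstart + Lg - t_bounds[, 2L], gstart + Lg - t_bounds[, 1L])
        exons <- exons[order(exons[, 1L]), , drop = FALSE]
        add(revcomp(tx))
      }
      gend <- cursor
      gene_models[[id]] <- list(gene_id = id, chromosome = chr,
                                start = gstart, end = gend, strand = strand,
                                exons = exons,
                                cds_start = if (strand == "+") gstart else gend)
      if (is_fam && strand == "-") add(revcomp(promoters[[id]]))
      if (is_fam && id %in% transposed) {
        for (side in c("up", "down")) {
          d <- sample(cfg$te_dist[1L]:cfg$te_dist[2L], 1L)
          len <- sample(cfg$te_len[1L]:cfg$te_len[2L], 1L)
          if (side == "up") {
            e <- gstart - d; s <- max(1L, e - len + 1L)
          } else {
            s <- gend + d; e <- s + len - 1L
          }
          te_rows[[length(te_rows) + 1L]] <- data.frame(
            chromosome = chr, start = s, end = e,
            te_id = paste0("TE_", id, "_", side), stringsAsFactors = FALSE)
        }
      }
    }
    add(random_dna(cfg$tail_bp))
    # two background TEs in the tail, > 10 kb past the last gene
    tail_at <- cursor - cfg$tail_bp + 12000L
    for (k in 0:1) {
      te_rows[[length(te_rows) + 1L]] <- data.frame(
        chromosome = chr, start = tail_at + k * 1200L,
        end = tail_at + k * 1200L + 499L,
        te_id = paste0("TE_", chr, "_tail", k + 1L), stringsAsFactors = FALSE)
    }
    chrom_seqs[[chr]] <- paste(unlist(chunks), collapse = "")
  }
  anchors <- build_anchors(catalog, layouts)
  expression <- sim_expression_internal(catalog, cfg,
    gene_lengths = vapply(fam_ids, function(g) nchar(cds_all[[g]]), 0L))
  list(
    proteome = data.frame(id = names(prot_all), description = "",
                          sequence = unname(prot_all), stringsAsFactors = FALSE),
    cds = data.frame(id = names(cds_all), description = "",
                     sequence = unname(cds_all), stringsAsFactors = FALSE),
    genome = chrom_seqs,
    gene_models = gene_models,
    gff_lines = gff_lines_for(gene_models),
    te = do.call(rbind, te_rows),
    anchors = anchors,
    planted = do.call(rbind, planted),
    expression = expression,
    catalog = catalog, config = cfg, seed = seed
  )
}

gff_lines_for <- function(gene_models) {
  lines <- "##gff-version 3"
  ord <- order(vapply(gene_models, `[[`, "", "chromosome"),
               vapply(gene_models, `[[`, 0, "start"))
  for (g in gene_models[ord]) {
    at <- function(type, s, e, attrs, phase = ".") {
      paste(g$chromosome, "auxiaa_sim", type, s, e, ".", g$strand, phase,
            attrs, sep = "\t")
    }
    tid <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
               at("gene", g$start, g$end, paste0("ID=", g$gene_id)),
               at("mRNA", g$start, g$end, paste0("ID=", tid, ";Parent=", g$gene_id)))
    ex <- g$exons
    # CDS phase in translation order
    tr_order <- if (g$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
    phase <- integer(nrow(ex)); cum <- 0L
    for (k in tr_order) {
      phase[k] <- (3L - (cum %% 3L)) %% 3L
      cum <- cum + (ex[k, 2L] - ex[k, 1L] + 1L)
    }
    for (k in seq_len(nrow(ex))) {
      lines <- c(lines,
                 at("exon", ex[k, 1L], ex[k, 2L], paste0("Parent=", tid)),
                 at("CDS", ex[k, 1L], ex[k, 2L], paste0("Parent=", tid),
                    phase = phase[k]))
    }
  }
  lines
}

# ---------------------------------------------------------------------------
# expression simulation

TISSUES_CHICKPEA <- c("GS", "R", "S", "ST", "ML", "YL", "SAM",
                      paste0("FB", 1:4), paste0("FL", 1:5), "YP")
TISSUES_SOYBEAN <- c("GloEP", "EmSCP", "GloS", "Gs", "Hs", "Cs", "Es", "Ds",
                     "R", "ST", "L", "FB", "WS", "CoM", "CoL", "CoS",
                     "EcoEm", "EmEA", "EmSC")

sim_expression_internal <- function(catalog, cfg, gene_lengths) {
  genes <- catalog$genes$gene_id
  tissues <- if (catalog$species == "chickpea") TISSUES_CHICKPEA else TISSUES_SOYBEAN
  nt <- length(tissues)
  # latent log2 tissue profiles with pair correlation structure
  z <- matrix(rnorm(length(genes) * nt, sd = cfg$expr_sd_profile),
              length(genes), nt, dimnames = list(genes, tissues))
  ep <- catalog$pairs[catalog$pairs$expr_class %in% c("conserved", "diverged"), ,
                      drop = FALSE]
  for (i in seq_len(nrow(ep))) {
    rho <- if (ep$expr_class[i] == "conserved") cfg$rho_high else cfg$rho_low
    za <- z[ep$gene_a[i], ]
    z[ep$gene_b[i], ] <- rho * za + sqrt(1 - rho^2) *
      rnorm(nt, sd = cfg$expr_sd_profile)
  }
  base <- rnorm(length(genes), cfg$expr_base_log2, cfg$expr_base_sd)
  rpkm_latent <- 2^(z + base)
  libsizes <- structure(round(cfg$expr_libsize * runif(nt, 0.8, 1.2)),
                        names = tissues)
  len_kb <- gene_lengths[genes] / 1000
  counts <- matrix(0L, length(genes), nt, dimnames = list(genes, tissues))
  size <- cfg$expr_nb_size
  for (j in seq_len(nt)) {
    mu <- rpkm_latent[, j] * len_kb * libsizes[j] / 1e6
    counts[, j] <- rpois(length(mu), rgamma(length(mu), shape = size,
                                            scale = mu / size))
  }
  # stress experiment: control vs stress with replicates
  reps <- cfg$stress_reps
  snames <- c(paste0("CTR", seq_len(reps)), paste0("DS", seq_len(reps)))
  slib <- structure(round(cfg$expr_libsize * runif(2 * reps, 0.8, 1.2)),
                    names = snames)
  de <- runif(length(genes)) < cfg$stress_de_frac
  lfc <- ifelse(de, sample(c(-1, 1), length(genes), replace = TRUE) *
                  cfg$stress_de_lfc, 0)
  base_stress <- 2^(base + rnorm(length(genes), 0, 0.5))
  stress <- matrix(0L, length(genes), 2 * reps,
                   dimnames = list(genes, snames))
  for (j in seq_len(2 * reps)) {
    mu <- base_stress * (if (j > reps) 2^lfc else 1) * len_kb * slib[j] / 1e6
    stress[, j] <- rpois(length(mu), rgamma(length(mu), shape = size,
                                            scale = mu / size))
  }
  list(counts = counts, lengths = structure(gene_lengths[genes], names = genes),
       libsizes = c(libsizes, slib), stress_counts = stress,
       stress_de = structure(de, names = genes))
}

# ---------------------------------------------------------------------------
# public generator surface

#' Simulate a proteome fixture
#'
#' Family proteins carry motif blocks I, III and IV, plus the motif II degron
#' iff the catalog marks the gene canonical; decoys carry at most an
#' incidental motif I. Deterministic under `seed`.
#'
#' @inheritParams sim_world
#' @return data.frame of sequence records (as from [read_fasta()]).
#' @export
simulate_proteome <- function(catalog, config = sim_config(), seed = 1L) {
  sim_world(catalog, config, seed)$proteome
}

#' Simulate a genome fixture (sequence, annotation, TEs, anchors)
#'
#' @inheritParams sim_world
#' @return List with `genome`, `gff_lines`, `te`, `anchors`, `planted`,
#'   `gene_models` (see [sim_world()]).
#' @export
simulate_genome <- function(catalog, config = sim_config(), seed = 1L) {
  w <- sim_world(catalog, config, seed)
  w[c("genome", "gff_lines", "te", "anchors", "planted", "gene_models")]
}

#' Simulate an expression count matrix fixture
#'
#' Latent tissue profiles per gene; catalog pairs labeled conserved share
#' profiles at correlation `rho_high`, diverged pairs at `rho_low`; counts
#' are over-dispersed (gamma-mixed Poisson) integers. Deterministic under
#' `seed`.
#'
#' @inheritParams sim_world
#' @param gene_lengths Optional named lengths (bp); drawn if missing.
#' @return List: `counts`, `lengths`, `libsizes`, `stress_counts`,
#'   `stress_de`.
#' @export
simulate_expression <- function(catalog, config = sim_config(), seed = 1L,
                                gene_lengths = NULL) {
  set.seed(seed)
  if (is.null(gene_lengths)) {
    gene_lengths <- structure(
      sample(600:1800, nrow(catalog$genes), replace = TRUE),
      names = catalog$genes$gene_id)
  }
  sim_expression_internal(catalog, config, gene_lengths)
}

#' Write a complete survey fixture directory
#'
#' Runs [sim_world()] and writes: `genome.fa`, `proteome.fa`, `cds.fa`,
#' `genes.gff3`, `te.bed`, `anchors.tsv`, `elements.tsv`, `counts.tsv`,
#' `lengths.tsv`, `libsizes.tsv`, `stress_counts.tsv`, `expr_pairs.tsv`,
#' `catalog.tsv`, `planted_elements.tsv`, `config.yaml`.
#'
#' @param species `"chickpea"` or `"soybean"`.
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed.
#' @param config See [sim_config()].
#' @return `outdir`, invisibly; the world object as attribute `"world"`.
#' @export
simulate_survey <- function(species, outdir, seed = 1L, config = sim_config()) {
  catalog <- load_published_catalog(species)
  w <- sim_world(catalog, config, seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_fasta(data.frame(id = names(w$genome), description = "",
                         sequence = unname(unlist(w$genome))), p("genome.fa"))
  write_fasta(w$proteome, p("proteome.fa"))
  write_fasta(w$cds, p("cds.fa"))
  writeLines(w$gff_lines, p("genes.gff3"))
  bed <- w$te
  writeLines(paste(bed$chromosome, bed$start - 1L, bed$end, bed$te_id,
                   sep = "\t"), p("te.bed"))
  write_tsv(w$anchors[, c("gene_a", "gene_b")], p("anchors.tsv"))
  file.copy(system.file("extdata", "cis_elements.tsv", package = "auxiaa"),
            p("elements.tsv"), overwrite = TRUE)
  cm <- data.frame(gene_id = rownames(w$expression$counts),
                   w$expression$counts, check.names = FALSE)
  write_tsv(cm, p("counts.tsv"))
  sm <- data.frame(gene_id = rownames(w$expression$stress_counts),
                   w$expression$stress_counts, check.names = FALSE)
  write_tsv(sm, p("stress_counts.tsv"))
  write_tsv(data.frame(gene_id = names(w$expression$lengths),
                       length_bp = unname(w$expression$lengths)),
            p("lengths.tsv"))
  write_tsv(data.frame(sample = names(w$expression$libsizes),
                       library_size = unname(w$expression$libsizes)),
            p("libsizes.tsv"))
  ep <- catalog$pairs[catalog$pairs$expr_class %in% c("conserved", "diverged"),
                      c("gene_a", "gene_b", "expr_class"), drop = FALSE]
  write_tsv(ep, p("expr_pairs.tsv"))
  write_tsv(catalog$genes, p("catalog.tsv"))
  write_tsv(w$planted[, c("gene_id", "element_id", "position", "instance")],
            p("planted_elements.tsv"))
  yaml::write_yaml(c(list(species = species, seed = seed),
                     w$config[vapply(w$config, function(x)
                       !is.list(x), TRUE)]),
                   p("config.yaml"))
  out <- outdir
  attr(out, "world") <- w
  invisible(out)
}
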