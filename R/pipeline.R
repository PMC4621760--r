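# End-to-end survey pipeline: identify -> organize -> phylo -> duplication ->
# promoter -> expression, with TSV outputs and a run summary.

#' Build a pipeline configuration
#'
#' All method constants are surfaced as named parameters with their standard
#' defaults (synonymous rate 6.1e-9/site/year, Ks event bins 0.3/1.3, 1000 bp
#' promoters, 2-fold / P <= 0.05 DE rule, 1000 bootstrap replicates, ...).
#'
#' @param inputs Named list of input paths: `proteome`, `genome`, `gff`,
#'   `te_bed`, `cds`, `elements`, `anchors`, `counts`, `lengths`,
#'   `libsizes`; optional `stress_counts`, `expr_pairs`.
#' @param outdir Report directory.
#' @param ... Parameter overrides (see defaults in the function body).
#' @return Config list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs, outdir, ...) {
  cfg <- list(
    inputs = inputs, outdir = outdir,
    seed = 1L,
    membership_min_motifs = 2L,
    max_intervening = 1L, max_gap = 100000L,
    min_anchors = 5L, max_index_gap = 25L,
    te_window = 10000L,
    rate = 6.1e-9, glycine_max_ks = 0.3, gamma_min_ks = 1.3,
    promoter_length = 1000L,
    bootstrap_replicates = 1000L,
    gap_open = 10, gap_extend = 1, substitution_matrix = "BLOSUM62",
    fold_threshold = 2, p_threshold = 0.05,
    r_threshold = 0.8,
    de_control_prefix = "CTR", de_treatment_prefix = "DS"
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Pipeline configuration for a simulated survey directory
#'
#' @param dir Directory written by [simulate_survey()].
#' @param outdir Report directory (default `file.path(dir, "report")`).
#' @param ... Overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
survey_config <- function(dir, outdir = file.path(dir, "report"), ...) {
  pipeline_config(
    inputs = list(
      proteome = file.path(dir, "proteome.fa"),
      genome = file.path(dir, "genome.fa"),
      gff = file.path(dir, "genes.gff3"),
      te_bed = file.path(dir, "te.bed"),
      cds = file.path(dir, "cds.fa"),
      elements = file.path(dir, "elements.tsv"),
      anchors = file.path(dir, "anchors.tsv"),
      counts = file.path(dir, "counts.tsv"),
      lengths = file.path(dir, "lengths.tsv"),
      libsizes = file.path(dir, "libsizes.tsv"),
      stress_counts = file.path(dir, "stress_counts.tsv"),
      expr_pairs = file.path(dir, "expr_pairs.tsv")
    ),
    outdir = outdir, ...)
}

#' Run the full gene-family survey pipeline
#'
#' Stages: identify (motif scan, membership, degron status, physicochemical
#' profiles) -> organize (chromosome distribution, tandem clusters, gene
#' structure) -> phylo (alignments, UPGMA tree with bootstrap, sister pairs)
#' -> duplication (collinear blocks, duplication modes, Ka/Ks, dating,
#' event bins) -> promoter (1 kb extraction, cis-element scan) -> expression
#' (RPKM, clustering, paralog divergence, stress DE). Every stage's tables
#' are written to `config$outdir`, plus a `summary.yaml`. Missing inputs
#' abort with a named error before any stage runs.
#'
#' @param config A `pipeline_config` (or a path to a YAML file with the same
#'   fields).
#' @return Invisibly, a list with all stage results and the summary.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    y <- yaml::read_yaml(config)
    config <- do.call(pipeline_config,
                      c(list(inputs = y$inputs, outdir = y$outdir),
                        y[setdiff(names(y), c("inputs", "outdir"))]))
  }
  cfg <- config
  required <- c("proteome", "genome", "gff", "te_bed", "cds", "elements",
                "anchors", "counts", "lengths", "libsizes")
  for (nm in required) {
    path <- cfg$inputs[[nm]]
    if (is.null(path) || !file.exists(path)) {
      stop("missing input '", nm, "': ", if (is.null(path)) "(not set)" else path)
    }
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$outdir, f)
  log <- character()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    dt <- proc.time()[["elapsed"]] - t0
    log <<- c(log, sprintf("%s: %.1fs", name, dt))
    message(sprintf("[auxiaa] %s done in %.1fs", name, dt))
    res
  }
  set.seed(cfg$seed)

  ## identify
  proteome <- read_fasta(cfg$inputs$proteome)
  models <- default_motif_models()
  rule <- function(hits) {
    sum(vapply(hits[intersect(c("II", "III", "IV"), names(hits))],
               function(h) length(h) > 0L, TRUE)) >= cfg$membership_min_motifs
  }
  identify <- stage("identify", {
    calls <- scan_proteome(proteome, models, rule)
    members <- calls$protein_id[calls$is_family_member]
    profs <- profile_table(proteome[proteome$id %in% members, , drop = FALSE])
    profs$canonical_status <-
      calls$canonical_status[match(profs$protein_id, calls$protein_id)]
    write_tsv(calls, out("family_calls.tsv"))
    write_tsv(profs, out("profiles.tsv"))
    list(calls = calls, members = members, profiles = profs)
  })

  ## organize
  organize <- stage("organize", {
    catalog <- read_gff3(cfg$inputs$gff, family_ids = identify$members)
    dist <- chromosome_distribution(catalog)
    clusters <- detect_tandem_clusters(catalog, cfg$max_intervening, cfg$max_gap)
    structure_df <- do.call(rbind, lapply(catalog$family_ids, function(g) {
      s <- intron_structure(catalog$genes[[g]])
      data.frame(gene_id = g, n_exons = s$n_exons, n_introns = s$n_introns,
                 exon_bp = s$exon_bp, intron_bp = s$intron_bp,
                 stringsAsFactors = FALSE)
    }))
    write_tsv(data.frame(chromosome = names(dist$counts),
                         n_family_genes = unname(dist$counts)),
              out("distribution.tsv"))
    write_tsv(clusters, out("tandem_clusters.tsv"))
    write_tsv(structure_df, out("gene_structure.tsv"))
    list(catalog = catalog, distribution = dist, clusters = clusters,
         structure = structure_df)
  })
  catalog <- organize$catalog

  ## phylo
  fam_seqs <- structure(proteome$sequence, names = proteome$id)[identify$members]
  phylo <- stage("phylo", {
    alns <- align_all_pairs(fam_seqs,
                            substitution_matrix = cfg$substitution_matrix,
                            gap_open = cfg$gap_open, gap_extend = cfg$gap_extend)
    D <- distance_matrix(alns)
    tree <- upgma(D)
    msa <- progressive_msa(fam_seqs, guide = tree,
                           substitution_matrix = cfg$substitution_matrix,
                           gap_open = cfg$gap_open, gap_extend = cfg$gap_extend)
    tree <- bootstrap_support(msa, cfg$bootstrap_replicates,
                              seed = cfg$seed, tree = tree)
    sisters <- extract_sister_pairs(tree)
    writeLines(write_newick(tree), out("tree.nwk"))
    sim <- do.call(rbind, lapply(alns, function(a) data.frame(
      id_a = a$id_a, id_b = a$id_b, percent_identity = a$percent_identity,
      percent_similarity = a$percent_similarity, stringsAsFactors = FALSE)))
    write_tsv(sim, out("similarity.tsv"))
    write_tsv(sisters, out("sister_pairs.tsv"))
    list(tree = tree, msa = msa, sisters = sisters, similarity = sim)
  })

  ## duplication
  dup <- stage("duplication", {
    anchors <- read.delim(cfg$inputs$anchors, stringsAsFactors = FALSE)
    ord <- gene_order_index(catalog)
    chrom <- vapply(catalog$genes, `[[`, "", "chromosome")
    anchors$chrom_a <- chrom[anchors$gene_a]
    anchors$chrom_b <- chrom[anchors$gene_b]
    anchors$order_a <- ord[anchors$gene_a]
    anchors$order_b <- ord[anchors$gene_b]
    blocks <- detect_collinear_blocks(anchors, cfg$min_anchors, cfg$max_index_gap)
    te <- read_bed(cfg$inputs$te_bed)
    modes <- classify_duplication_mode(catalog, blocks, organize$clusters,
                                       te, cfg$te_window)
    fam <- catalog$family_ids
    anch <- blocks$anchors
    fam_pairs <- anch[anch$gene_a %in% fam & anch$gene_b %in% fam &
                        !is.na(anch$block_id), c("gene_a", "gene_b")]
    # tandem-mode neighbours within clusters
    tand <- modes$gene_id[modes$mode == "tandem"]
    for (i in seq_len(nrow(organize$clusters))) {
      mem <- strsplit(organize$clusters$members[i], ",")[[1L]]
      mem <- mem[mem %in% tand]
      if (length(mem) >= 2L) {
        fam_pairs <- rbind(fam_pairs,
                           data.frame(gene_a = mem[-length(mem)],
                                      gene_b = mem[-1L],
                                      stringsAsFactors = FALSE))
      }
    }
    fam_pairs <- unique(fam_pairs)
    cds_rec <- read_fasta(cfg$inputs$cds)
    cds <- structure(cds_rec$sequence, names = cds_rec$id)
    kk <- kaks_table(fam_pairs, fam_seqs, cds,
                     dating_params(cfg$rate, cfg$glycine_max_ks, cfg$gamma_min_ks),
                     substitution_matrix = cfg$substitution_matrix,
                     gap_open = cfg$gap_open, gap_extend = cfg$gap_extend)
    kk$mode_a <- modes$mode[match(kk$gene_a, modes$gene_id)]
    write_tsv(blocks$blocks, out("blocks.tsv"))
    write_tsv(blocks$anchors, out("anchors_assigned.tsv"))
    write_tsv(modes, out("duplication_modes.tsv"))
    write_tsv(kk, out("kaks.tsv"))
    list(blocks = blocks, modes = modes, kaks = kk, te = te)
  })

  ## promoter
  promoter <- stage("promoter", {
    genome <- read_fasta(cfg$inputs$genome)
    proms <- extract_promoters(genome, catalog, cfg$promoter_length)
    library <- read.delim(cfg$inputs$elements, stringsAsFactors = FALSE,
                          colClasses = "character")
    hits <- scan_all_promoters(proms, library)
    presence <- element_presence_table(hits, catalog$family_ids, library)
    write_fasta(data.frame(id = proms$gene_id, description = "",
                           sequence = proms$sequence), out("promoters.fa"))
    write_tsv(hits, out("element_hits.tsv"))
    write_tsv(data.frame(gene_id = rownames(presence), presence,
                         check.names = FALSE), out("element_presence.tsv"))
    list(promoters = proms, hits = hits, presence = presence)
  })

  ## expression
  expression <- stage("expression", {
    counts <- read_matrix(cfg$inputs$counts)
    lengths_df <- read.delim(cfg$inputs$lengths, stringsAsFactors = FALSE)
    libsizes_df <- read.delim(cfg$inputs$libsizes, stringsAsFactors = FALSE)
    gl <- structure(lengths_df$length_bp, names = lengths_df$gene_id)
    ls <- structure(libsizes_df$library_size, names = libsizes_df$sample)
    expr <- rpkm(counts, gl, ls)
    z <- zscore_rows(log2(expr + 1))
    ord <- hclust_order(z)
    div <- NULL
    if (!is.null(cfg$inputs$expr_pairs) && file.exists(cfg$inputs$expr_pairs)) {
      ep <- read.delim(cfg$inputs$expr_pairs, stringsAsFactors = FALSE)
      div <- divergence_table(ep, expr, cfg$r_threshold)
    }
    de <- NULL
    if (!is.null(cfg$inputs$stress_counts) &&
        file.exists(cfg$inputs$stress_counts)) {
      sc <- read_matrix(cfg$inputs$stress_counts)
      se <- rpkm(sc, gl, ls[colnames(sc)])
      ctrl <- grep(paste0("^", cfg$de_control_prefix), colnames(se), value = TRUE)
      trt <- grep(paste0("^", cfg$de_treatment_prefix), colnames(se), value = TRUE)
      if (length(ctrl) >= 2L && length(trt) >= 2L) {
        de <- de_table(se, ctrl, trt, fold_threshold = cfg$fold_threshold,
                       p_threshold = cfg$p_threshold)
        write_tsv(de, out("de_results.tsv"))
      }
    }
    write_tsv(data.frame(gene_id = rownames(expr), round(expr, 4),
                         check.names = FALSE), out("rpkm.tsv"))
    write_tsv(data.frame(gene_id = ord$labels), out("cluster_order.tsv"))
    if (!is.null(div)) write_tsv(div, out("paralog_divergence.tsv"))
    list(rpkm = expr, z = z, order = ord, divergence = div, de = de)
  })

  ## summary
  mode_counts <- table(dup$modes$mode)
  summary <- list(
    n_proteins_scanned = nrow(proteome),
    n_family = length(identify$members),
    n_canonical = sum(identify$calls$canonical_status == "canonical",
                      na.rm = TRUE),
    n_non_canonical = sum(identify$calls$canonical_status == "non_canonical",
                          na.rm = TRUE),
    chromosomes_with_family = length(organize$distribution$counts),
    chromosomes_absent = organize$distribution$absent,
    distribution = as.list(structure(as.integer(organize$distribution$counts),
                                     names = names(organize$distribution$counts))),
    n_tandem_clusters = nrow(organize$clusters),
    n_sister_pairs = nrow(phylo$sisters),
    mode_counts = as.list(structure(as.integer(mode_counts),
                                    names = names(mode_counts))),
    wgd_percent = 100 * sum(dup$modes$mode == "wgd_segmental") /
      nrow(dup$modes),
    kaks_all_below_one = all(dup$kaks$ratio < 1, na.rm = TRUE),
    mean_ks = mean(dup$kaks$Ks),
    event_counts = as.list(table(dup$kaks$event)),
    n_element_hits = nrow(promoter$hits),
    n_conserved_pairs = if (!is.null(expression$divergence))
      sum(expression$divergence$verdict == "conserved") else NA,
    n_diverged_pairs = if (!is.null(expression$divergence))
      sum(expression$divergence$verdict == "diverged") else NA,
    n_de_genes = if (!is.null(expression$de)) sum(expression$de$is_de) else NA,
    stage_timing = log,
    parameters = cfg[setdiff(names(cfg), c("inputs", "outdir"))]
  )
  yaml::write_yaml(summary, out("summary.yaml"))
  invisible(list(identify = identify, organize = organize, phylo = phylo,
                 duplication = dup, promoter = promoter,
                 expression = expression, summary = summary, config = cfg))
}
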