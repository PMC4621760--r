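# Strand-aware promoter extraction and degenerate (IUPAC) cis-element
# scanning on both strands.

IUPAC_LETTERS <- c("A","C","G","T","R","Y","S","W","K","M","B","D","H","V","N")

#' Packaged cis-regulatory element library
#'
#' A small PLACE-style library (element id, name, IUPAC pattern) covering the
#' element classes commonly reported for auxin-repressor promoters: AuxRE,
#' DRE/CRT, sugar, GA, MYC/dehydration, salt, circadian and seed/endosperm
#' motifs. Patterns follow public nomenclature and are package conventions;
#' a full user library can be supplied instead.
#'
#' @return data.frame with columns `element_id`, `name`, `pattern`.
#' @export
default_element_library <- function() {
  path <- system.file("extdata", "cis_elements.tsv", package = "auxiaa")
  read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract upstream promoter regions from a genome
#'
#' For a `+` strand gene the promoter is the `length` bases immediately
#' upstream of the first coding base (`cds_start`); for a `-` strand gene the
#' reverse complement of the `length` bases downstream. Promoters truncated
#' by a chromosome end carry a flag; position 1 of the returned sequence is
#' the farthest-upstream base (5' -> 3' relative to the gene).
#'
#' @param genome Named character vector of chromosome sequences, or a
#'   [read_fasta()] data.frame.
#' @param catalog A `gene_catalog`; promoters are extracted for its
#'   `family_ids`.
#' @param length Promoter length in bp (default 1000).
#' @return data.frame: `gene_id`, `sequence`, `chromosome`, `start`, `end`
#'   (genomic interval), `strand`, `truncated`.
#' @export
extract_promoters <- function(genome, catalog, length = 1000L) {
  chrs <- as_named_seqs(genome)
  rows <- lapply(catalog$family_ids, function(gid) {
    g <- catalog$genes[[gid]]
    if (!g$chromosome %in% names(chrs)) {
      stop("chromosome ", g$chromosome, " of gene ", gid, " absent from genome")
    }
    chrom <- chrs[[g$chromosome]]
    L <- nchar(chrom)
    if (g$strand == "-") {
      lo <- g$cds_start + 1L
      hi <- min(g$cds_start + length, L)
      if (lo > L) stop("empty promoter: gene ", gid,
                       " has no sequence downstream of cds_start")
      seq <- revcomp(substr(chrom, lo, hi))
    } else {
      hi <- g$cds_start - 1L
      lo <- max(g$cds_start - length, 1L)
      if (hi < 1L) stop("empty promoter: gene ", gid,
                        " has cds_start at chromosome position 1")
      seq <- substr(chrom, lo, hi)
    }
    data.frame(gene_id = gid, sequence = seq, chromosome = g$chromosome,
               start = lo, end = hi, strand = g$strand,
               truncated = nchar(seq) < length, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Scan a promoter for degenerate cis-elements on both strands
#'
#' Every position where the IUPAC pattern matches the forward sequence is a
#' `+` hit; every position where it matches the reverse complement is a `-`
#' hit, reported at the forward coordinate of the match start. Overlapping
#' matches are all reported. Matching uses
#' [Biostrings::matchPattern()] with IUPAC codes interpreted in the pattern
#' only.
#'
#' @param promoter Promoter sequence (character scalar) or a one-row result
#'   of [extract_promoters()].
#' @param library data.frame of elements (`element_id`, `pattern`); defaults
#'   to [default_element_library()].
#' @return data.frame: `gene_id`, `element_id`, `position` (1-based within
#'   the promoter), `strand`.
#' @export
scan_elements <- function(promoter, library = default_element_library()) {
  if (is.data.frame(promoter)) {
    gid <- promoter$gene_id[1L]; seq <- promoter$sequence[1L]
  } else {
    gid <- names(promoter)[1L] %||% "promoter"; seq <- unname(promoter[1L])
  }
  subj <- Biostrings::DNAString(toupper(seq))
  rows <- list()
  for (i in seq_len(nrow(library))) {
    pat <- toupper(library$pattern[i])
    if (!all(strsplit(pat, "")[[1L]] %in% IUPAC_LETTERS)) {
      stop("invalid IUPAC letter in pattern '", pat, "' (",
           library$element_id[i], ")")
    }
    p <- Biostrings::DNAString(pat)
    if (length(p) > length(subj)) next
    fwd <- Biostrings::start(Biostrings::matchPattern(p, subj, fixed = "subject"))
    rev <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::reverseComplement(p), subj, fixed = "subject"))
    if (length(fwd)) rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gid, element_id = library$element_id[i], position = fwd,
      strand = "+", stringsAsFactors = FALSE)
    if (length(rev)) rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gid, element_id = library$element_id[i], position = rev,
      strand = "-", stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(), element_id = character(),
                      position = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$element_id, out$position, out$strand), , drop = FALSE]
}

#' Scan many promoters for cis-elements
#'
#' @param promoters data.frame from [extract_promoters()].
#' @param library Element library.
#' @return Combined hit data.frame (see [scan_elements()]).
#' @export
scan_all_promoters <- function(promoters, library = default_element_library()) {
  hits <- lapply(seq_len(nrow(promoters)),
                 function(i) scan_elements(promoters[i, ], library))
  do.call(rbind, hits)
}

#' Gene-by-element hit count table
#'
#' Zero-filled counts of element hits per gene.
#'
#' @param hits data.frame of hits (see [scan_elements()]).
#' @param genes Character vector of gene ids (table rows).
#' @param library Element library (table columns).
#' @return Integer matrix genes x elements.
#' @export
element_presence_table <- function(hits, genes, library = default_element_library()) {
  tab <- matrix(0L, length(genes), nrow(library),
                dimnames = list(genes, library$element_id))
  if (nrow(hits)) {
    agg <- table(factor(hits$gene_id, levels = genes),
                 factor(hits$element_id, levels = library$element_id))
    tab[] <- as.integer(agg)
  }
  tab
}
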