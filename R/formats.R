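# File format readers/writers. Internal coordinates are 1-based inclusive
# (GFF3 convention) everywhere; BED input is converted on read.

#' Read a FASTA file into a sequence record table
#'
#' Parsing is delegated to [Biostrings::readBStringSet()] after a light
#' pre-validation pass so that malformed input fails with an error naming the
#' offending line. Sequences are uppercased and whitespace-stripped; records
#' are returned in file order.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `description` (text after the first
#'   whitespace in the header, `""` if none) and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("FASTA format error in ", path, ": empty file")
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("FASTA format error in ", path, " at line ", first,
         ": expected '>' header, got '", substr(lines[first], 1, 30), "'")
  }
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  if (any(!nzchar(ids))) {
    stop("FASTA format error in ", path, ": empty header")
  }
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  if (any(!nzchar(seqs))) {
    bad <- ids[!nzchar(seqs)][1L]
    stop("FASTA format error in ", path, ": empty sequence for record '", bad, "'")
  }
  id <- sub("[[:space:]].*$", "", ids)
  desc <- ifelse(grepl("[[:space:]]", ids), sub("^[^[:space:]]+[[:space:]]+", "", ids), "")
  data.frame(id = id, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequence records as FASTA
#'
#' @param records data.frame with `id` and `sequence` columns (optionally
#'   `description`), or a named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), description = "",
                          sequence = unname(records), stringsAsFactors = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[i]
    if (!is.null(records$description) && nzchar(records$description[i])) {
      hdr <- paste(hdr, records$description[i])
    }
    s <- records$sequence[i]
    chunks <- substring(s, seq(1, nchar(s), width), pmin(seq(1, nchar(s), width) + width - 1L, nchar(s)))
    writeLines(c(paste0(">", hdr), chunks), con)
  }
  invisible(path)
}

#' Read a GFF3 file into a gene catalog
#'
#' Builds one gene model per `gene` feature: coordinates, strand, sorted
#' non-overlapping exons, and `cds_start`, the chromosomal coordinate of the
#' first coding base (minimum CDS coordinate on `+`, maximum on `-`). Genes
#' are sorted by start within each chromosome (ties broken by gene id), which
#' defines the gene-order index used by the duplication analyses.
#'
#' @param path Path to a GFF3 file with gene/mRNA/exon/CDS features.
#' @param family_ids Optional character vector of gene ids to mark as family
#'   members in the catalog.
#' @return A `gene_catalog` list with elements `genes` (named list of gene
#'   models), `order` (named list: chromosome -> ordered gene ids) and
#'   `family_ids`.
#' @export
read_gff3 <- function(path, family_ids = character()) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 format error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$Parent <- vapply(df$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  cdss  <- df[df$type == "CDS",  , drop = FALSE]
  if (nrow(genes) == 0L) stop("GFF3 format error in ", path, ": no gene features")
  mrna2gene <- structure(mrnas$Parent, names = mrnas$ID)
  to_gene <- function(parent) {
    out <- ifelse(parent %in% genes$ID, parent, unname(mrna2gene[parent]))
    if (anyNA(out)) stop("GFF3 format error in ", path,
                         ": feature with Parent not resolvable to a gene")
    out
  }
  exon_gene <- if (nrow(exons)) to_gene(exons$Parent) else character()
  cds_gene  <- if (nrow(cdss))  to_gene(cdss$Parent)  else character()
  if (nrow(cdss) && any(!cds_gene %in% genes$ID)) {
    stop("GFF3 format error in ", path, ": CDS without parent gene")
  }
  models <- vector("list", nrow(genes))
  names(models) <- genes$ID
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    ex <- exons[exon_gene == gid, c("start", "end"), drop = FALSE]
    if (nrow(ex) == 0L) ex <- genes[i, c("start", "end"), drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)])) {
      stop("GFF3 format error in ", path, ": overlapping exons in gene ", gid)
    }
    cd <- cdss[cds_gene == gid, c("start", "end"), drop = FALSE]
    strand <- as.character(genes$strand[i])
    cds_start <- if (nrow(cd) == 0L) {
      if (strand == "-") genes$end[i] else genes$start[i]
    } else if (strand == "-") max(cd$end) else min(cd$start)
    models[[i]] <- list(
      gene_id = gid,
      chromosome = as.character(genes$seqnames[i]),
      start = genes$start[i], end = genes$end[i],
      strand = strand,
      exons = as.matrix(ex),
      cds_start = cds_start
    )
  }
  gene_catalog(models, family_ids = family_ids)
}

#' Construct a gene catalog from gene models
#'
#' @param models Named list of gene models (see [read_gff3()]).
#' @param family_ids Gene ids belonging to the surveyed family.
#' @return A `gene_catalog` object.
#' @export
gene_catalog <- function(models, family_ids = character()) {
  stopifnot(length(models) > 0L)
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- vapply(models, `[[`, "", "gene_id")
  }
  bad <- setdiff(family_ids, names(models))
  if (length(bad)) stop("family ids absent from catalog: ", paste(bad, collapse = ", "))
  chroms <- vapply(models, `[[`, "", "chromosome")
  starts <- vapply(models, `[[`, 0, "start")
  ids <- names(models)
  order_list <- lapply(split(seq_along(models), chroms), function(idx) {
    idx <- idx[order(starts[idx], ids[idx])]
    ids[idx]
  })
  structure(list(genes = models, order = order_list,
                 family_ids = family_ids),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("gene_catalog:", length(x$genes), "genes on", length(x$order),
      "chromosomes;", length(x$family_ids), "family members\n")
  invisible(x)
}

#' Gene-order index within a chromosome
#'
#' Rank of each gene by start coordinate within its chromosome (ties broken
#' by gene id), the index space used by collinearity chaining and tandem
#' detection.
#'
#' @param catalog A `gene_catalog`.
#' @return Named integer vector over all genes.
#' @export
gene_order_index <- function(catalog) {
  out <- integer(length(catalog$genes))
  names(out) <- names(catalog$genes)
  for (ids in catalog$order) out[ids] <- seq_along(ids)
  out
}

#' Read a BED file of transposable-element annotations
#'
#' BED is 0-based half-open; coordinates are converted to 1-based inclusive
#' on read (`start + 1`, `end`) via [rtracklayer::import()].
#'
#' @param path Path to a BED file with at least 3 columns.
#' @return data.frame with columns `chromosome`, `start`, `end`, `te_id`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("BED format error in ", path, ": fewer than 3 columns")
  if (!is.numeric(raw[[2L]]) || !is.numeric(raw[[3L]]) ||
      any(raw[[2L]] != floor(raw[[2L]])) || any(raw[[3L]] != floor(raw[[3L]]))) {
    stop("BED format error in ", path, ": non-integer coordinates")
  }
  if (any(raw[[2L]] < 0)) stop("BED format error in ", path, ": negative start")
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("BED format error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  te_id <- if ("name" %in% names(df) && !all(is.na(df$name))) as.character(df$name)
           else paste0("te", seq_len(nrow(df)))
  data.frame(chromosome = as.character(df$seqnames), start = df$start,
             end = df$end, te_id = te_id, stringsAsFactors = FALSE)
}

#' Read a labeled numeric gene-by-sample matrix from TSV
#'
#' First column holds gene ids, header row holds sample names. Any missing,
#' ragged or non-numeric cell is an error (no silent `NA`), as is a duplicate
#' gene id.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  fields <- count.fields(path, sep = "\t", quote = "")
  if (length(unique(fields)) != 1L) {
    stop("matrix format error in ", path, ": ragged rows (line ",
         which(fields != fields[1L])[1L], ")")
  }
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (anyDuplicated(df[[1L]])) {
    stop("matrix format error in ", path, ": duplicate gene id '",
         df[[1L]][duplicated(df[[1L]])][1L], "'")
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("matrix format error in ", path, ": non-numeric or missing value for gene '",
         df[[1L]][idx[1L]], "', sample '", colnames(vals)[idx[2L]], "'")
  }
  dimnames(num) <- list(df[[1L]], colnames(vals))
  num
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize an ultrametric tree as Newick text
#'
#' Produces a rooted Newick string with branch lengths, terminated by `;`.
#' Internal-node labels carry bootstrap support when present.
#'
#' @param tree An `upgma_tree` (see [upgma()]), or a single leaf label.
#' @return Newick string.
#' @export
write_newick <- function(tree) {
  if (is.character(tree) && length(tree) == 1L) {
    return(paste0(tree, ":0.0;"))
  }
  stopifnot(inherits(tree, "upgma_tree"))
  labels <- tree$labels
  if (anyDuplicated(labels)) stop("duplicate leaf labels: ",
                                  labels[duplicated(labels)][1L])
  n <- length(labels)
  if (n == 1L) return(paste0(labels, ":0.0;"))
  heights <- tree$height
  supports <- tree$support
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  node_str <- function(k) { # k<0: leaf -k ; k>0: internal row k
    if (k < 0L) list(str = labels[-k], h = 0)
    else {
      a <- node_str(tree$merge[k, 1L]); b <- node_str(tree$merge[k, 2L])
      lab <- if (!is.null(supports) && !is.na(supports[k])) fmt(supports[k]) else ""
      list(str = paste0("(", a$str, ":", fmt(heights[k] - a$h), ",",
                        b$str, ":", fmt(heights[k] - b$h), ")", lab),
           h = heights[k])
    }
  }
  paste0(node_str(nrow(tree$merge))$str, ";")
}
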