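# Genomic organization of family genes: chromosome distribution, tandem
# cluster detection, exon-intron structure.

#' Family gene counts per chromosome
#'
#' Counts are over family members only. Chromosomes present in the catalog
#' but carrying no family gene are returned in a companion `absent` vector
#' rather than as zero counts.
#'
#' @param catalog A `gene_catalog`.
#' @return List with `counts` (named integer vector, chromosomes with >= 1
#'   family gene) and `absent` (chromosome names with none).
#' @export
chromosome_distribution <- function(catalog) {
  fam <- catalog$family_ids
  chroms <- vapply(catalog$genes[fam], `[[`, "", "chromosome")
  counts <- table(chroms)
  counts <- structure(as.integer(counts), names = names(counts))
  all_chr <- names(catalog$order)
  list(counts = counts, absent = setdiff(all_chr, names(counts)))
}

#' Detect tandemly duplicated family gene clusters
#'
#' A cluster is a maximal run of family genes on one chromosome in which
#' consecutive family members are separated by at most `max_intervening`
#' non-family genes (by gene-order index) and by at most `max_gap` bp
#' (distance between the end of one gene and the start of the next).
#' Singletons are not reported. The adjacency rule is a package convention
#' (both parameters exposed); published surveys report clusters without
#' defining one.
#'
#' @param catalog A `gene_catalog`.
#' @param max_intervening Maximum number of intervening non-family genes.
#' @param max_gap Maximum inter-gene distance in bp.
#' @return data.frame with one row per cluster: `cluster_id`, `chromosome`,
#'   `members` (comma-joined, in order), `n`, `span_start`, `span_end`.
#' @export
detect_tandem_clusters <- function(catalog, max_intervening = 1L,
                                   max_gap = 100000L) {
  fam <- catalog$family_ids
  out <- list()
  for (chr in names(catalog$order)) {
    ids <- catalog$order[[chr]]
    fidx <- which(ids %in% fam)
    if (length(fidx) < 2L) next
    run <- list(fidx[1L])
    for (k in seq_along(fidx)[-1L]) {
      prev <- run[[length(run)]][length(run[[length(run)]])]
      cur <- fidx[k]
      g_prev <- catalog$genes[[ids[prev]]]
      g_cur <- catalog$genes[[ids[cur]]]
      gap_bp <- g_cur$start - g_prev$end
      if ((cur - prev - 1L) <= max_intervening && gap_bp <= max_gap) {
        run[[length(run)]] <- c(run[[length(run)]], cur)
      } else {
        run[[length(run) + 1L]] <- cur
      }
    }
    for (r in run) {
      if (length(r) < 2L) next
      members <- ids[r]
      starts <- vapply(catalog$genes[members], `[[`, 0, "start")
      ends <- vapply(catalog$genes[members], `[[`, 0, "end")
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chr, members = paste(members, collapse = ","),
        n = length(members), span_start = min(starts), span_end = max(ends),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(cluster_id = character(), chromosome = character(),
                      members = character(), n = integer(),
                      span_start = integer(), span_end = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  cbind(cluster_id = paste0("TC", seq_len(nrow(res))), res,
        stringsAsFactors = FALSE)
}

#' Exon-intron structure of a gene model
#'
#' Introns are the gaps between consecutive exons; a single-exon gene has
#' none.
#'
#' @param gene A gene model (element of `catalog$genes`).
#' @return List with `introns` (matrix of start/end, 0 rows if none),
#'   `n_exons`, `n_introns`, `exon_bp`, `intron_bp`.
#' @export
intron_structure <- function(gene) {
  ex <- gene$exons
  ex <- ex[order(ex[, 1L]), , drop = FALSE]
  if (nrow(ex) > 1L && any(ex[-1L, 1L] <= ex[-nrow(ex), 2L])) {
    stop("overlapping exons in gene ", gene$gene_id)
  }
  if (nrow(ex) < 2L) {
    introns <- matrix(numeric(), ncol = 2L,
                      dimnames = list(NULL, c("start", "end")))
  } else {
    introns <- cbind(start = ex[-nrow(ex), 2L] + 1L, end = ex[-1L, 1L] - 1L)
  }
  list(introns = introns, n_exons = nrow(ex), n_introns = nrow(introns),
       exon_bp = sum(ex[, 2L] - ex[, 1L] + 1L),
       intron_bp = if (nrow(introns)) sum(introns[, 2L] - introns[, 1L] + 1L) else 0L)
}
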