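# Packaged family catalogs: published per-gene facts (chromosome, tandem
# cluster, degron status, duplication mode, paralog pairing, expression
# divergence) transcribed into tables that drive the synthetic-data
# generator and anchor the end-to-end tests.

#' Load a packaged family catalog
#'
#' Returns the per-gene catalog for the requested species together with its
#' paralog-pair table. Every published invariant the catalog must satisfy is
#' re-validated on load (family size, per-chromosome counts, tandem-cluster
#' composition, non-canonical membership, duplication-mode totals, paralog
#' pair classes); a corrupted table fails loudly.
#'
#' @param species `"chickpea"` or `"soybean"`.
#' @return List of class `published_catalog`: `species`, `genes` (data.frame:
#'   `gene_id`, `chromosome`, `chrom_index`, `canonical`, `cluster_id`,
#'   `mode`), `pairs` (data.frame: `gene_a`, `gene_b`, `pair_type`,
#'   `anchor`, `expr_class`), `n_chromosomes` (chromosome complement of the
#'   genome).
#' @export
load_published_catalog <- function(species = c("chickpea", "soybean")) {
  species <- match.arg(species)
  genes <- read.delim(system.file("extdata",
                                  paste0("catalog_", species, ".tsv"),
                                  package = "auxiaa"),
                      stringsAsFactors = FALSE)
  pairs <- read.delim(system.file("extdata",
                                  paste0("pairs_", species, ".tsv"),
                                  package = "auxiaa"),
                      stringsAsFactors = FALSE)
  n_chrom <- if (species == "chickpea") 8L else 20L
  val <- function(ok, what) {
    if (!ok) stop("packaged catalog for ", species,
                  " failed validation: ", what)
  }
  counts <- table(genes$chromosome)
  if (species == "chickpea") {
    val(nrow(genes) == 22L, "expected 22 genes")
    expected <- c(chr1 = 1, chr2 = 1, chr3 = 3, chr4 = 8, chr5 = 1,
                  chr6 = 2, chr7 = 5, chr8 = 1)
    val(identical(as.integer(counts[names(expected)]),
                  as.integer(expected)), "per-chromosome counts")
    val(setequal(genes$gene_id[!genes$canonical],
                 paste0("CaIAA", c(5, 11, 12, 16, 17, 19))),
        "non-canonical list")
    val(setequal(genes$gene_id[genes$cluster_id != ""],
                 c("CaIAA3", "CaIAA4")), "tandem cluster list")
  } else {
    val(nrow(genes) == 63L, "expected 63 genes")
    val(length(counts) == 16L, "expected genes on 16 chromosomes")
    val(!any(paste0("chr", c(11, 12, 16, 18)) %in% names(counts)),
        "chromosomes 11/12/16/18 must be empty")
    expected <- c(chr10 = 9, chr13 = 8, chr2 = 6, chr3 = 5, chr8 = 5,
                  chr19 = 5, chr7 = 4, chr15 = 4, chr20 = 4, chr1 = 3,
                  chr4 = 2, chr6 = 2, chr9 = 2, chr17 = 2, chr5 = 1,
                  chr14 = 1)
    val(identical(as.integer(counts[names(expected)]),
                  as.integer(expected)), "per-chromosome counts")
    val(setequal(genes$gene_id[!genes$canonical],
                 paste0("GmIAA", c(5, 6, 13, 23, 31, 35, 37, 39, 40, 42,
                                   53, 58, 60))), "non-canonical list")
    cl <- split(genes$gene_id[genes$cluster_id != ""],
                genes$cluster_id[genes$cluster_id != ""])
    val(length(cl) == 8L, "expected 8 tandem clusters")
    val(any(vapply(cl, setequal, TRUE, paste0("GmIAA", 6:8))),
        "cluster GmIAA6/7/8")
    for (pair in list(c(10, 11), c(32, 33), c(37, 38), c(46, 47),
                      c(49, 50), c(55, 56), c(61, 62))) {
      val(any(vapply(cl, setequal, TRUE, paste0("GmIAA", pair))),
          paste("cluster", paste(pair, collapse = "/")))
    }
    val(sum(genes$mode == "wgd_segmental") == 57L, "57 WGD/segmental genes")
    val(setequal(genes$gene_id[genes$mode == "tandem"],
                 c("GmIAA6", "GmIAA7")), "tandem mode genes")
    val(sum(pairs$expr_class == "conserved") == 16L, "16 conserved pairs")
    val(sum(pairs$expr_class == "diverged") == 8L, "8 diverged pairs")
    anchored <- unique(c(pairs$gene_a[pairs$anchor], pairs$gene_b[pairs$anchor]))
    val(setequal(anchored, genes$gene_id[genes$mode == "wgd_segmental"]),
        "anchor pairs must cover exactly the WGD genes")
  }
  val(!anyDuplicated(genes$gene_id), "duplicate gene ids")
  structure(list(species = species, genes = genes, pairs = pairs,
                 n_chromosomes = n_chrom),
            class = "published_catalog")
}

#' @export
print.published_catalog <- function(x, ...) {
  cat("published_catalog (", x$species, "): ", nrow(x$genes), " genes, ",
      sum(!x$genes$canonical), " non-canonical, ",
      nrow(x$pairs), " pair records\n", sep = "")
  invisible(x)
}
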