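# Expression analysis: RPKM normalization, row standardization and
# clustering, differential-expression calls, paralog expression divergence.

#' RPKM normalization of a count matrix
#'
#' `rpkm = count * 1e9 / (library_size * gene_length_bp)` (reads per kilobase
#' of transcript per million mapped reads).
#'
#' @param counts Non-negative gene x sample matrix with dimnames.
#' @param gene_lengths Named vector of transcript lengths in bp (> 0),
#'   covering all rows.
#' @param library_sizes Named vector of total mapped reads per sample (> 0),
#'   covering all columns.
#' @return Numeric matrix of RPKM values with the same dimnames.
#' @export
rpkm <- function(counts, gene_lengths, library_sizes) {
  stopifnot(all(counts >= 0))
  gl <- gene_lengths[rownames(counts)]
  ls <- library_sizes[colnames(counts)]
  if (anyNA(gl)) stop("missing gene length for: ",
                      rownames(counts)[is.na(gl)][1L])
  if (anyNA(ls)) stop("missing library size for: ",
                      colnames(counts)[is.na(ls)][1L])
  if (any(gl <= 0)) stop("gene lengths must be positive")
  if (any(ls <= 0)) stop("library sizes must be positive")
  sweep(sweep(counts * 1e9, 2L, ls, "/"), 1L, gl, "/")
}

#' Row-wise Z-score standardization
#'
#' Each row is centred and scaled by its sample (n-1) standard deviation;
#' constant rows map to all zeros.
#'
#' @param matrix Numeric matrix with >= 2 columns.
#' @return Standardized matrix.
#' @export
zscore_rows <- function(matrix) {
  stopifnot(ncol(matrix) >= 2L)
  mu <- rowMeans(matrix)
  sdev <- apply(matrix, 1L, sd)
  out <- (matrix - mu) / ifelse(sdev == 0, 1, sdev)
  out[sdev == 0, ] <- 0
  out
}

#' Hierarchical clustering of matrix rows
#'
#' Agglomerative clustering via [stats::hclust()] on row distances
#' (Euclidean by default) with complete linkage by default, matching the
#' usual expression-heatmap setup. `stats::hclust` breaks ties by the
#' smallest row index.
#'
#' @param matrix Numeric matrix (>= 2 rows).
#' @param linkage Linkage method (default `"complete"`).
#' @param metric Distance metric for [stats::dist()] (default
#'   `"euclidean"`).
#' @return List: `dendrogram` (hclust object), `order` (leaf order, row
#'   indices), `labels`.
#' @export
hclust_order <- function(matrix, linkage = "complete", metric = "euclidean") {
  stopifnot(nrow(matrix) >= 2L)
  hc <- hclust(dist(matrix, method = metric), method = linkage)
  list(dendrogram = hc, order = hc$order,
       labels = rownames(matrix)[hc$order])
}

#' Differential-expression call for one gene
#'
#' Fold change is the pseudo-counted ratio of group means
#' (`(mean_treat + eps) / (mean_control + eps)`); significance is a
#' two-sided two-sample t test (Welch by default; set `pooled = TRUE` for the
#' classical equal-variance test). A gene is differentially expressed when
#' the fold change is >= `fold_threshold` or <= 1/`fold_threshold` AND
#' `p <= p_threshold`.
#'
#' @param control,treatment Numeric replicate vectors (>= 2 each).
#' @param fold_threshold Fold-change cutoff (default 2).
#' @param p_threshold P-value cutoff (default 0.05).
#' @param eps Pseudo-count on the expression scale (default 1).
#' @param pooled Use pooled-variance t test instead of Welch.
#' @return List: `fold_change`, `p_value`, `is_de`.
#' @export
call_de <- function(control, treatment, fold_threshold = 2,
                    p_threshold = 0.05, eps = 1, pooled = FALSE) {
  stopifnot(length(control) >= 2L, length(treatment) >= 2L)
  fold <- (mean(treatment) + eps) / (mean(control) + eps)
  if (all(control == 0) && all(treatment == 0)) {
    return(list(fold_change = 1, p_value = 1, is_de = FALSE))
  }
  p <- if (sd(control) == 0 && sd(treatment) == 0) {
    if (mean(control) == mean(treatment)) 1 else 0
  } else {
    t.test(treatment, control, var.equal = pooled)$p.value
  }
  list(fold_change = fold, p_value = p,
       is_de = (fold >= fold_threshold || fold <= 1 / fold_threshold) &&
         p <= p_threshold)
}

#' Differential-expression table for a matrix with two replicate groups
#'
#' @param matrix Gene x sample expression matrix.
#' @param control_cols,treatment_cols Column names or indices of the two
#'   groups.
#' @param ... Passed to [call_de()].
#' @return data.frame: `gene_id`, `fold_change`, `p_value`, `is_de`.
#' @export
de_table <- function(matrix, control_cols, treatment_cols, ...) {
  rows <- lapply(rownames(matrix), function(g) {
    r <- call_de(matrix[g, control_cols], matrix[g, treatment_cols], ...)
    data.frame(gene_id = g, fold_change = r$fold_change,
               p_value = r$p_value, is_de = r$is_de, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Expression-divergence verdict for a paralog pair
#'
#' Pearson correlation of the two genes' `log2(RPKM + 1)` profiles across
#' samples; the pair is `conserved` when the correlation reaches
#' `r_threshold`, otherwise `diverged`. A zero-variance profile makes the
#' correlation undefined: the verdict is
#' `diverged` with `undefined = TRUE`.
#'
#' @param gene_a,gene_b Gene ids (rows of `expr`).
#' @param expr RPKM matrix (>= 3 samples).
#' @param r_threshold Correlation threshold for conservation (default 0.8).
#' @return List: `gene_a`, `gene_b`, `pearson_r`, `verdict`, `undefined`.
#' @export
paralog_divergence <- function(gene_a, gene_b, expr, r_threshold = 0.8) {
  stopifnot(ncol(expr) >= 3L)
  if (!gene_a %in% rownames(expr)) stop("gene absent from matrix: ", gene_a)
  if (!gene_b %in% rownames(expr)) stop("gene absent from matrix: ", gene_b)
  xa <- log2(expr[gene_a, ] + 1)
  xb <- log2(expr[gene_b, ] + 1)
  if (sd(xa) == 0 || sd(xb) == 0) {
    return(list(gene_a = gene_a, gene_b = gene_b, pearson_r = NA_real_,
                verdict = "diverged", undefined = TRUE))
  }
  r <- cor(xa, xb)
  list(gene_a = gene_a, gene_b = gene_b, pearson_r = r,
       verdict = if (r >= r_threshold) "conserved" else "diverged",
       undefined = FALSE)
}

#' Expression-divergence table for paralog pairs
#'
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @param expr RPKM matrix.
#' @param r_threshold See [paralog_divergence()].
#' @return data.frame: pair ids, `pearson_r`, `verdict`.
#' @export
divergence_table <- function(pairs, expr, r_threshold = 0.8) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- paralog_divergence(pairs$gene_a[i], pairs$gene_b[i], expr, r_threshold)
    data.frame(gene_a = r$gene_a, gene_b = r$gene_b, pearson_r = r$pearson_r,
               verdict = r$verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
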