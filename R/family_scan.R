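# Family identification by degenerate protein-motif models, degron
# (canonical/non-canonical) classification, and physicochemical profiling.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# average residue masses (Da); peptide MW = sum(residues) + one water
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0513,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

#' Default motif models for Aux/IAA family scanning
#'
#' Motif I is the LxLxLx repressor motif and motif II the GWPPV/GWPPI degron
#' recognized by TIR1/AFB F-box proteins; motifs III and IV stand for the
#' PB1-type dimerization region and are supplied as package conventions
#' (configurable), since only descriptions of them are conventional, not
#' consensus strings. Patterns use fixed residues, `x` wildcards and bracket
#' residue classes.
#'
#' @return data.frame with columns `motif_id`, `pattern`.
#' @export
default_motif_models <- function() {
  path <- system.file("extdata", "motif_models.tsv", package = "auxiaa")
  read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

# compile "GWPP[VI]" -> list of per-position allowed-residue sets
compile_motif <- function(pattern) {
  chars <- strsplit(pattern, "")[[1L]]
  sets <- list(); i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars)) stop("unterminated bracket class in motif pattern: ", pattern)
      cls <- chars[(i + 1L):(j - 1L)]
      if (!all(cls %in% AA20)) stop("invalid residue in motif class: ", pattern)
      sets[[length(sets) + 1L]] <- cls
      i <- j + 1L
    } else if (ch == "x") {
      sets[[length(sets) + 1L]] <- AA20
      i <- i + 1L
    } else if (ch %in% AA20) {
      sets[[length(sets) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("invalid character '", ch, "' in motif pattern: ", pattern)
    }
  }
  if (length(sets) == 0L) stop("empty motif pattern")
  sets
}

#' Scan a protein for degenerate motif models
#'
#' Reports every 1-based match start per motif; `x` matches any residue and a
#' bracket class any listed residue. Overlapping matches are all reported.
#'
#' @param protein Amino-acid sequence (character scalar) or a one-row record
#'   from [read_fasta()].
#' @param models data.frame of motif models (`motif_id`, `pattern`); defaults
#'   to [default_motif_models()].
#' @return A `motif_call` list: `protein_id`, `hits` (named list motif_id ->
#'   integer positions), and placeholders for membership/canonical status.
#' @export
scan_motifs <- function(protein, models = default_motif_models()) {
  if (is.data.frame(protein)) {
    id <- protein$id[1L]; seq <- protein$sequence[1L]
  } else {
    id <- names(protein)[1L] %||% "protein"; seq <- unname(protein[1L])
  }
  res <- strsplit(seq, "")[[1L]]
  if (!all(res %in% AA20)) {
    stop("unknown residue letter '", setdiff(res, AA20)[1L], "' in protein ", id)
  }
  hits <- lapply(seq_len(nrow(models)), function(i) {
    sets <- compile_motif(models$pattern[i])
    m <- length(sets); n <- length(res)
    if (n < m) return(integer())
    ok <- rep(TRUE, n - m + 1L)
    for (p in seq_len(m)) {
      ok <- ok & res[seq.int(p, n - m + p)] %in% sets[[p]]
    }
    which(ok)
  })
  names(hits) <- models$motif_id
  structure(list(protein_id = id, hits = hits,
                 is_family_member = NA, canonical_status = NA_character_),
            class = "motif_call")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify family membership from motif hits
#'
#' The default rule calls a protein a family member when at least two of
#' motifs II, III and IV are present, so that degron-less (motif-II-free)
#' members remain callable. The rule is a pluggable predicate over the hit
#' list.
#'
#' @param result A `motif_call` from [scan_motifs()].
#' @param rule Function taking the named hits list and returning a flag.
#' @return The `motif_call` with `is_family_member` set.
#' @export
classify_family_member <- function(result, rule = NULL) {
  stopifnot(inherits(result, "motif_call"))
  if (is.null(rule)) {
    rule <- function(hits) {
      sum(vapply(hits[intersect(c("II", "III", "IV"), names(hits))],
                 function(h) length(h) > 0L, TRUE)) >= 2L
    }
  }
  result$is_family_member <- isTRUE(rule(result$hits))
  result
}

#' Classify a family member as canonical or non-canonical
#'
#' Non-canonical members are family members whose motif II (degron) hit list
#' is empty; they escape TIR1/AFB-mediated degradation.
#'
#' @param result A `motif_call` with membership decided.
#' @return The `motif_call` with `canonical_status` in
#'   `c("canonical", "non_canonical")`.
#' @export
classify_canonical <- function(result) {
  stopifnot(inherits(result, "motif_call"))
  if (!isTRUE(result$is_family_member)) {
    stop("canonical status is only defined for family members (",
         result$protein_id, ")")
  }
  result$canonical_status <-
    if (length(result$hits[["II"]]) == 0L) "non_canonical" else "canonical"
  result
}

#' Scan a whole proteome and classify members
#'
#' @param proteome data.frame from [read_fasta()].
#' @param models Motif models.
#' @param rule Membership rule (see [classify_family_member()]).
#' @return data.frame with one row per protein: `protein_id`,
#'   `is_family_member`, `canonical_status` (`NA` for non-members) and one
#'   logical column per motif.
#' @export
scan_proteome <- function(proteome, models = default_motif_models(), rule = NULL) {
  rows <- lapply(seq_len(nrow(proteome)), function(i) {
    r <- classify_family_member(scan_motifs(proteome[i, ], models), rule)
    if (r$is_family_member) r <- classify_canonical(r)
    c(list(protein_id = r$protein_id,
           is_family_member = r$is_family_member,
           canonical_status = r$canonical_status),
      lapply(r$hits, function(h) length(h) > 0L))
  })
  do.call(rbind, lapply(rows, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
}

#' Default pKa table for isoelectric-point calculation
#'
#' EMBOSS-style values for the N-terminus, C-terminus and ionizable side
#' chains. The table is an input so other value sets (e.g. the ExPASy ones)
#' can be substituted.
#'
#' @return Named numeric vector with entries `Nterm`, `Cterm`, `K`, `R`, `H`,
#'   `D`, `E`, `C`, `Y`.
#' @export
default_pka_table <- function() {
  c(Nterm = 8.6, Cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
    D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum: positive groups (N-terminus, K, R, H)
#' contribute `1/(1 + 10^(pH - pKa))`, negative groups (C-terminus, D, E, C,
#' Y) contribute `-1/(1 + 10^(pKa - pH))`. Strictly decreasing in pH.
#'
#' @param sequence Amino-acid sequence (standard 20 residues).
#' @param pH pH value(s).
#' @param pka_table Named pKa vector, see [default_pka_table()].
#' @return Net charge (vectorized over `pH`).
#' @export
net_charge <- function(sequence, pH, pka_table = default_pka_table()) {
  res <- strsplit(sequence, "")[[1L]]
  if (!all(res %in% AA20)) {
    stop("nonstandard residue '", setdiff(res, AA20)[1L], "' in sequence")
  }
  counts <- table(factor(res, levels = AA20))
  pos <- c(Nterm = 1, K = unname(counts["K"]), R = unname(counts["R"]),
           H = unname(counts["H"]))
  neg <- c(Cterm = 1, D = unname(counts["D"]), E = unname(counts["E"]),
           C = unname(counts["C"]), Y = unname(counts["Y"]))
  vapply(pH, function(p) {
    sum(pos / (1 + 10^(p - pka_table[names(pos)]))) -
      sum(neg / (1 + 10^(pka_table[names(neg)] - p)))
  }, 0)
}

#' Physicochemical profile of a protein
#'
#' Molecular weight is the sum of average residue masses plus one water;
#' the isoelectric point is found by bisection on the net-charge curve to
#' `|charge| < tol` (the curve is strictly decreasing in pH, so the root is
#' unique).
#'
#' @param protein Amino-acid sequence or one-row [read_fasta()] record.
#' @param pka_table Named pKa vector.
#' @param tol Charge tolerance for the bisection stop rule.
#' @return List with `protein_id`, `length` (residues), `molecular_weight`
#'   (Da), `isoelectric_point` (pH units), `pka_table`.
#' @export
physicochemical_profile <- function(protein, pka_table = default_pka_table(),
                                    tol = 1e-4) {
  if (is.data.frame(protein)) {
    id <- protein$id[1L]; seq <- protein$sequence[1L]
  } else {
    id <- names(protein)[1L] %||% "protein"; seq <- unname(protein[1L])
  }
  res <- strsplit(seq, "")[[1L]]
  if (length(res) < 1L) stop("empty sequence")
  if (!all(res %in% AA20)) {
    stop("nonstandard residue '", setdiff(res, AA20)[1L], "' in protein ", id)
  }
  mw <- sum(AA_MASS[res]) + WATER_MASS
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid, pka_table)
    if (abs(q) < tol || (hi - lo) < 1e-12) break
    if (q > 0) lo <- mid else hi <- mid
  }
  list(protein_id = id, length = length(res), molecular_weight = mw,
       isoelectric_point = mid, pka_table = pka_table)
}

#' Physicochemical profile table for a set of proteins
#'
#' @param proteome data.frame from [read_fasta()].
#' @param pka_table Named pKa vector.
#' @return data.frame with `protein_id`, `length`, `molecular_weight`,
#'   `isoelectric_point`.
#' @export
profile_table <- function(proteome, pka_table = default_pka_table()) {
  rows <- lapply(seq_len(nrow(proteome)), function(i) {
    p <- physicochemical_profile(proteome[i, ], pka_table)
    data.frame(protein_id = p$protein_id, length = p$length,
               molecular_weight = p$molecular_weight,
               isoelectric_point = p$isoelectric_point,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
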