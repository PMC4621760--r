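# Independent brute-force oracles used to validate the package's optimized
# implementations. These deliberately share no code with the package paths
# they check.

AA20H <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
DNAH <- c("A", "C", "G", "T")

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

# exhaustive global-alignment score: enumerate all alignments recursively,
# affine gap of length k costs open + k * ext
nw_brute <- function(a, b, S, open = 10, ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      best <- max(best, S[a[i], b[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(a)) {
      pen <- if (state == "X") ext else open + ext
      best <- max(best, -pen + rec(i + 1, j, "X"))
    }
    if (j <= length(b)) {
      pen <- if (state == "Y") ext else open + ext
      best <- max(best, -pen + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "M")
}

# exhaustive Nei-Gojobori pathway enumeration for a codon pair
gcode <- Biostrings::GENETIC_CODE
ng_diff_brute <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  diffs <- which(av != bv)
  if (!length(diffs)) return(c(0, 0))
  paths_ok <- list(); paths_all <- list()
  walk <- function(cur, remaining, sd, nd, stopped) {
    if (!length(remaining)) {
      paths_all[[length(paths_all) + 1]] <<- c(sd, nd)
      if (!stopped) paths_ok[[length(paths_ok) + 1]] <<- c(sd, nd)
      return(invisible())
    }
    for (k in seq_along(remaining)) {
      p <- remaining[k]
      nxt <- cur; nxt[p] <- bv[p]
      aa1 <- gcode[[paste(cur, collapse = "")]]
      aa2 <- gcode[[paste(nxt, collapse = "")]]
      syn <- aa1 != "*" && aa2 != "*" && aa1 == aa2
      walk(nxt, remaining[-k], sd + syn, nd + !syn,
           stopped || aa2 == "*")
    }
  }
  walk(av, diffs, 0, 0, FALSE)
  use <- if (length(paths_ok)) paths_ok else paths_all
  Reduce(`+`, use) / length(use)
}

iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

revcomp_chr <- function(s) {
  chartr("ACGTRYKMBVDHSWN", "TGCAYRMKVBHDSWN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# position-by-position degenerate matcher (both strands)
iupac_brute <- function(seq, pattern) {
  sv <- strsplit(seq, "")[[1]]
  match_at <- function(pat) {
    pv <- strsplit(pat, "")[[1]]
    m <- length(pv); n <- length(sv)
    if (n < m) return(integer())
    out <- integer()
    for (i in seq_len(n - m + 1)) {
      ok <- TRUE
      for (p in seq_len(m)) {
        if (!sv[i + p - 1] %in% iupac_sets[[pv[p]]]) { ok <- FALSE; break }
      }
      if (ok) out <- c(out, i)
    }
    out
  }
  list(fwd = match_at(pattern), rev = match_at(revcomp_chr(pattern)))
}

# protein motif matcher mirroring the pattern language (x + bracket classes)
motif_brute <- function(seq, pattern) {
  sets <- list()
  chars <- strsplit(pattern, "")[[1]]
  i <- 1
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- which(chars[(i + 1):length(chars)] == "]")[1] + i
      sets[[length(sets) + 1]] <- chars[(i + 1):(j - 1)]
      i <- j + 1
    } else {
      sets[[length(sets) + 1]] <- if (chars[i] == "x") AA20H else chars[i]
      i <- i + 1
    }
  }
  sv <- strsplit(seq, "")[[1]]
  out <- integer()
  for (s in seq_len(length(sv) - length(sets) + 1)) {
    if (all(vapply(seq_along(sets),
                   function(p) sv[s + p - 1] %in% sets[[p]], TRUE))) {
      out <- c(out, s)
    }
  }
  out
}

# random ultrametric tree -> cophenetic distance matrix (for UPGMA recovery)
random_ultrametric <- function(n, labels = paste0("t", seq_len(n))) {
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  clusters <- as.list(seq_len(n))
  h <- 0
  while (length(clusters) > 1) {
    h <- h + runif(1, 0.5, 2)
    pick <- sample(length(clusters), 2)
    for (i in clusters[[pick[1]]]) for (j in clusters[[pick[2]]]) {
      D[i, j] <- D[j, i] <- 2 * h
    }
    clusters[[pick[1]]] <- c(clusters[[pick[1]]], clusters[[pick[2]]])
    clusters[[pick[2]]] <- NULL
  }
  D
}

# cophenetic matrix of an upgma_tree
tree_cophenetic <- function(tree) {
  n <- length(tree$labels)
  D <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  sets <- vector("list", nrow(tree$merge))
  for (k in seq_len(nrow(tree$merge))) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    a <- grab(tree$merge[k, 1]); b <- grab(tree$merge[k, 2])
    for (i in a) for (j in b) D[i, j] <- D[j, i] <- 2 * tree$height[k]
    sets[[k]] <- c(a, b)
  }
  D
}

random_protein <- function(n) paste(sample(AA20H, n, replace = TRUE), collapse = "")
random_dna_str <- function(n) paste(sample(DNAH, n, replace = TRUE), collapse = "")

sense_codons <- names(gcode)[gcode != "*"]
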