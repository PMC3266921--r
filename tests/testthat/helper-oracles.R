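# Independent brute-force oracles used to check the package implementations.
# These deliberately share no code with the package internals.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Expand an IUPAC pattern to every literal ACGT word it denotes.
iupac_expand <- function(pattern) {
  sets <- IUPAC_SETS[strsplit(pattern, "")[[1]]]
  words <- Reduce(function(acc, s) {
    as.vector(outer(acc, s, paste0))
  }, sets, accumulate = FALSE, init = "")
  words
}

# All (overlapping) 1-based start positions of any literal word in seq.
naive_site_scan <- function(seq, words) {
  k <- nchar(words[1])
  L <- nchar(seq)
  if (L < k) return(integer(0))
  starts <- seq_len(L - k + 1L)
  subs <- substring(seq, starts, starts + k - 1L)
  starts[subs %in% words]
}

# Sliding-window mismatch counting under IUPAC semantics; N in the subject
# matches everything.
naive_primer_sites <- function(seq, pattern, max_mismatch = 0,
                               orientation = "forward") {
  if (orientation == "reverse") pattern <- revcomp_chr(pattern)
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  k <- length(p); L <- length(s)
  if (L < k) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(L - k + 1L)) {
    win <- s[i:(i + k - 1L)]
    mm <- 0L
    for (q in seq_len(k)) {
      if (win[q] == "N") next
      if (!(win[q] %in% IUPAC_SETS[[p[q]]])) mm <- mm + 1L
    }
    if (mm <= max_mismatch) hits <- c(hits, i)
  }
  hits
}

# Dice via explicit set operations on index sets.
set_dice <- function(a, b) {
  A <- which(a); B <- which(b)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

# 1-D single-linkage group count by union-find over the <= tol adjacency.
sl_group_count_1d <- function(x, tol) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(x[i] - x[j]) <= tol) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, 0L)))
}

# Canonical form of a partition labelling (label-permutation invariant).
partition_canon <- function(labels) match(labels, unique(labels))

# Short synthetic template: forward 27F realisation + middle + revcomp 1492R.
FWD27 <- "AGAGTTTGATCATGGCTCAG"
RC1492 <- revcomp_chr("GGTTACCTTGTTACGACTT")
make_template <- function(middle, pad5 = "", pad3 = "") {
  paste0(pad5, FWD27, middle, RC1492, pad3)
}

# Random additive distance matrix from a random 5-taxon tree; returns both.
random_additive <- function(n = 5) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
  tr <- ape::unroot(tr)
  d <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(d))
  list(tree = tr, d = d[ord, ord])
}
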