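# Clone-library analysis: Jukes-Cantor distances (pairwise gap deletion),
# furthest-neighbour (complete-linkage) OTU clustering at a divergence
# threshold, and analytic rarefaction of OTU abundances.

GAP_CHARS <- c("-", ".", "N")

.jc_from_p <- function(p) {
  if (p >= 0.75) return(Inf)
  -0.75 * log(1 - 4 * p / 3)
}

#' Jukes-Cantor distance between two aligned sequences
#'
#' Sites where either sequence is gapped (or `N`) are excluded pairwise;
#' with mismatch fraction `p` over the remaining sites the distance is
#' `-(3/4) * log(1 - 4p/3)`. Saturated pairs (`p >= 3/4`) return `Inf`.
#'
#' @param row_a,row_b equal-length gapped DNA strings (or character vectors
#'   of single residues).
#' @return Non-negative distance, or `Inf` when saturated.
#' @export
jc_distance <- function(row_a, row_b) {
  a <- if (length(row_a) == 1L) strsplit(toupper(row_a), "")[[1]] else toupper(row_a)
  b <- if (length(row_b) == 1L) strsplit(toupper(row_b), "")[[1]] else toupper(row_b)
  if (length(a) != length(b)) trflp_error("aligned rows differ in length")
  ok <- !(a %in% GAP_CHARS) & !(b %in% GAP_CHARS)
  if (!any(ok)) trflp_error("no comparable (pairwise ungapped) sites")
  .jc_from_p(mean(a[ok] != b[ok]))
}

# Distances from a pre-built character matrix (rows = sequences).
.jc_matrix <- function(m) {
  n <- nrow(m)
  ok <- !(m %in% GAP_CHARS)
  dim(ok) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      if (!any(comp)) trflp_error("no comparable sites for a sequence pair")
      d[i, j] <- d[j, i] <- .jc_from_p(mean(m[i, comp] != m[j, comp]))
    }
  }
  d
}

#' Jukes-Cantor distance matrix for an alignment
#'
#' @param aln named character vector of equal-length gapped DNA strings, a
#'   character matrix, or a `DNAStringSet`.
#' @return Symmetric distance matrix with zero diagonal; saturated pairs
#'   carry an `Inf` sentinel.
#' @export
jc_distance_matrix <- function(aln) {
  .jc_matrix(aln_matrix(aln))
}

#' Furthest-neighbour OTU clustering
#'
#' Complete-linkage agglomeration: at each step the pair of clusters with
#' the smallest complete-linkage (maximum pairwise) distance is merged,
#' while that distance does not exceed `threshold` — so the maximum
#' intra-cluster distance never exceeds the threshold. Ties are broken
#' deterministically by the lexicographically smallest member id. Pairs at
#' infinite distance never merge.
#'
#' @param d symmetric distance matrix with ids as dimnames.
#' @param threshold divergence threshold (e.g. `0.05` for the conventional
#'   5% OTU definition).
#' @return Object of class `otu_assignment`: list with `threshold` and
#'   `assignment`, a named integer vector of contiguous cluster labels
#'   (1-based, ordered by first appearance).
#' @export
cluster_otus <- function(d, threshold = 0.05) {
  d <- as.matrix(d)
  ids <- rownames(d) %||% sprintf("seq%03d", seq_len(nrow(d)))
  n <- nrow(d)
  if (n == 0L) trflp_error("empty distance matrix")
  members <- as.list(seq_len(n))        # clusters hold original indices
  Dc <- d
  diag(Dc) <- NA
  active <- rep(TRUE, n)
  while (sum(active) > 1L) {
    idx <- which(active)
    sub <- Dc[idx, idx, drop = FALSE]
    finite <- is.finite(sub)
    if (!any(finite)) break
    mn <- min(sub[finite])
    if (mn > threshold) break
    cand <- which(sub == mn, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(r) {
      m1 <- min(ids[members[[idx[r[1]]]]])
      m2 <- min(ids[members[[idx[r[2]]]]])
      paste(sort(c(m1, m2)), collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- idx[pick[1]]; j <- idx[pick[2]]
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
    # Lance-Williams update for complete linkage
    newrow <- pmax(Dc[i, ], Dc[j, ])
    newrow[i] <- NA
    Dc[i, ] <- newrow
    Dc[, i] <- newrow
  }
  clusters <- members[active]
  first <- vapply(clusters, min, 0L)
  clusters <- clusters[order(first)]
  assignment <- integer(n)
  for (k in seq_along(clusters)) assignment[clusters[[k]]] <- k
  names(assignment) <- ids
  structure(list(threshold = threshold, assignment = assignment),
            class = "otu_assignment")
}

#' OTU abundances from an assignment
#' @param otus an [cluster_otus()] result.
#' @return Integer vector of cluster sizes, named by cluster label.
#' @export
otu_abundances <- function(otus) {
  stopifnot(inherits(otus, "otu_assignment"))
  tab <- table(otus$assignment)
  stats::setNames(as.integer(tab), names(tab))
}

#' Analytic rarefaction curve
#'
#' Expected OTU richness in random subsamples of `n` clones drawn without
#' replacement from a library with OTU abundances `N_i` (total `N`):
#' `E[S(n)] = sum_i (1 - choose(N - N_i, n) / choose(N, n))`, evaluated for
#' `n = 1..N` via log binomial coefficients.
#'
#' @param otu_abundances positive integer abundances, one per OTU.
#' @return Data frame of class `rarefaction_curve` with columns `n` and
#'   `expected_richness`; non-decreasing, ending at the observed OTU count.
#' @export
rarefaction <- function(otu_abundances) {
  ab <- as.numeric(otu_abundances)
  if (length(ab) < 1L || any(!is.finite(ab)) || any(ab < 1) ||
      any(ab != round(ab))) {
    trflp_error("OTU abundances must be positive integers")
  }
  N <- sum(ab)
  n <- seq_len(N)
  # absent_i(n) = C(N - N_i, n) / C(N, n)
  absent <- vapply(n, function(k) {
    sum(exp(lchoose(N - ab, k) - lchoose(N, k)))
  }, 0)
  out <- data.frame(n = n, expected_richness = length(ab) - absent)
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

#' Write a rarefaction curve as TSV
#' @param curve a [rarefaction()] result.
#' @param path output path.
#' @export
write_rarefaction <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
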