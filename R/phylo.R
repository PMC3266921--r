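# Distance-based phylogenetics: neighbour-joining on (Jukes-Cantor)
# distance matrices, bootstrap support by column resampling, and newick
# round-tripping. Trees are `ape` "phylo" objects throughout.

.fmt_len <- function(x) sprintf("%.12g", x)

#' Neighbour-joining tree
#'
#' Standard agglomerative neighbour joining with the rate-corrected Q
#' criterion. Negative branch-length estimates are clamped to zero (a
#' message reports how many). Two taxa yield a single edge of total length
#' `d`; three taxa are resolved by the closed-form three-point formulas.
#'
#' @param d symmetric finite distance matrix with taxon ids as dimnames.
#' @return An unrooted tree of class `phylo`.
#' @export
neighbor_joining <- function(d) {
  D <- as.matrix(d)
  ids <- rownames(D) %||% sprintf("t%03d", seq_len(nrow(D)))
  n <- nrow(D)
  if (n < 2L) trflp_error("need at least 2 taxa")
  if (any(!is.finite(D))) {
    bad <- which(!is.finite(D) & upper.tri(D), arr.ind = TRUE)
    pairs <- apply(bad, 1, function(r) paste(ids[r[1]], ids[r[2]], sep = "/"))
    trflp_error(sprintf("non-finite distances for pairs: %s",
                        paste(pairs, collapse = ", ")),
                "trflp_infinite_distance")
  }
  n_clamped <- 0L
  clamp <- function(x) {
    if (x < 0) n_clamped <<- n_clamped + 1L
    max(0, x)
  }
  if (n == 2L) {
    txt <- sprintf("(%s:%s,%s:%s);", ids[1], .fmt_len(clamp(D[1, 2] / 2)),
                   ids[2], .fmt_len(clamp(D[1, 2] / 2)))
    return(ape::read.tree(text = txt))
  }
  labs <- ids
  while (length(labs) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    w <- which(Q == min(Q), arr.ind = TRUE)
    w <- w[w[, 1] < w[, 2], , drop = FALSE]
    i <- w[1, 1]; j <- w[1, 2]
    dij <- D[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- dij - bi
    newlab <- sprintf("(%s:%s,%s:%s)", labs[i], .fmt_len(clamp(bi)),
                      labs[j], .fmt_len(clamp(bj)))
    dnew <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    labs <- c(labs[keep], newlab)
    dimnames(D) <- NULL
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 labs[1], .fmt_len(clamp(b1)),
                 labs[2], .fmt_len(clamp(b2)),
                 labs[3], .fmt_len(clamp(b3)))
  if (n_clamped > 0L) {
    message(sprintf("neighbor_joining: %d negative branch length(s) clamped to 0",
                    n_clamped))
  }
  ape::read.tree(text = txt)
}

# Star tree (single multifurcation) for degenerate all-zero distances.
.star_tree <- function(ids) {
  txt <- sprintf("(%s);", paste(sprintf("%s:0", ids), collapse = ","))
  ape::read.tree(text = txt)
}

#' Neighbour-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement (`n_replicates` times,
#' seeded), rebuilds the NJ tree for each pseudo-alignment, and reports for
#' every internal node of the reference tree the percentage of replicates
#' whose tree contains the same bipartition (counted unrooted via
#' `ape::prop.clades`). Supports are stored in `node.label`.
#'
#' An alignment of identical sequences has no resolvable bipartitions; the
#' reference collapses to a star tree with an empty support set.
#'
#' @param aln named character vector of equal-length aligned sequences.
#' @param n_replicates number of bootstrap replicates.
#' @param seed RNG seed (column resampling only).
#' @return A `phylo` with per-internal-node support in `[0, 100]`.
#' @export
bootstrap_support <- function(aln, n_replicates = 100, seed = 1) {
  if (n_replicates < 1L) trflp_error("n_replicates must be >= 1")
  m <- aln_matrix(aln)
  if (is.null(rownames(m))) rownames(m) <- sprintf("t%03d", seq_len(nrow(m)))
  D <- .jc_matrix(m)
  if (max(D) == 0) {
    tr <- .star_tree(rownames(m))
    attr(tr, "bipartition_support") <- numeric(0)
    return(tr)
  }
  ref <- neighbor_joining(D)
  set.seed(seed)
  reps <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    reps[[b]] <- tryCatch(
      suppressMessages(neighbor_joining(.jc_matrix(m[, cols, drop = FALSE]))),
      error = function(e) NULL)
  }
  ok <- !vapply(reps, is.null, TRUE)
  trees <- reps[ok]
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supp <- 100 * counts / n_replicates
  ref$node.label <- .fmt_len(supp)
  attr(ref, "bipartition_support") <- supp
  ref
}

# Cheap structural scan so parse failures report a position.
.check_newick_text <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        trflp_error(sprintf("newick parse error: unbalanced ')' at position %d", k),
                    "trflp_parse")
      }
    }
  }
  if (depth != 0L) {
    trflp_error(sprintf("newick parse error: %d unclosed '(' at end of input", depth),
                "trflp_parse")
  }
  if (!grepl(";", text, fixed = TRUE)) {
    trflp_error(sprintf("newick parse error: missing ';' terminator at position %d",
                        nchar(text)), "trflp_parse")
  }
}

#' Write / read trees in newick format
#'
#' Round-trips topology, branch lengths, tip labels and node-label supports.
#'
#' @param tree a `phylo`.
#' @param path file path; for `read_newick`, a path or a literal newick
#'   string.
#' @return `read_newick`: a `phylo`. `write_newick`: the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  text <- if (length(path) == 1L && file.exists(path)) {
    paste(readLines(path, warn = FALSE), collapse = "")
  } else {
    paste(path, collapse = "")
  }
  .check_newick_text(text)
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                 error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    trflp_error("newick parse error: not a valid tree", "trflp_parse")
  }
  tr
}
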