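# Correspondence analysis of the samples x fragment-bins table:
# chi-square standardisation of the indicator matrix, singular value
# decomposition, principal coordinates for rows (samples) and columns
# (bins). "Inertia" (chi-square / grand total) plays the role of variance.

#' Correspondence analysis of a presence/absence table
#'
#' By default the analysis runs on presence/absence, matching the
#' peak-counting similarity analysis; set `weights = "height"` together with
#' a numeric matrix to ordinate height-weighted abundances instead.
#'
#' Axis signs are fixed deterministically: per axis, the first sample with a
#' non-zero score is made positive.
#'
#' @param m a `presence_matrix` or a numeric/logical matrix (samples x bins)
#'   with no all-zero row or column.
#' @param weights `"presence"` (default; values coerced to 0/1) or
#'   `"height"` (values used as supplied).
#' @return Object of class `ca_result`: `sample_scores`, `bin_scores`
#'   (principal coordinates), `eigenvalues` (non-increasing),
#'   `percent_inertia` (sums to 100 over retained axes), `total_inertia`.
#' @export
correspondence_analysis <- function(m, weights = c("presence", "height")) {
  weights <- match.arg(weights)
  X <- if (inherits(m, "presence_matrix")) m$values + 0 else as.matrix(m) + 0
  if (weights == "presence") X <- (X > 0) + 0
  if (nrow(X) < 2L || ncol(X) < 2L) trflp_error("need at least 2 rows and 2 columns")
  if (any(X < 0)) trflp_error("table entries must be non-negative")
  if (any(rowSums(X) == 0)) {
    trflp_error(sprintf("all-zero row: '%s'",
                        rownames(X)[which(rowSums(X) == 0)[1]] %||% "?"))
  }
  if (any(colSums(X) == 0)) trflp_error("all-zero column in table")
  if (is.null(rownames(X))) rownames(X) <- sprintf("row%d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("col%d", seq_len(ncol(X)))
  N <- sum(X)
  P <- X / N
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  k <- min(nrow(X), ncol(X)) - 1L
  dvals <- sv$d[seq_len(k)]
  total <- sum(sv$d^2)
  if (total < 1e-12) {
    trflp_error("no variation: all rows have the same profile",
                "trflp_no_variation")
  }
  Frow <- sweep(sv$u[, seq_len(k), drop = FALSE], 1, sqrt(r), "/") %*% diag(dvals, k)
  Gcol <- sweep(sv$v[, seq_len(k), drop = FALSE], 1, sqrt(cc), "/") %*% diag(dvals, k)
  # deterministic sign: first non-zero sample score positive per axis
  for (a in seq_len(k)) {
    nz <- which(abs(Frow[, a]) > 1e-9)
    if (length(nz) && Frow[nz[1], a] < 0) {
      Frow[, a] <- -Frow[, a]
      Gcol[, a] <- -Gcol[, a]
    }
  }
  dimnames(Frow) <- list(rownames(X), sprintf("axis%d", seq_len(k)))
  dimnames(Gcol) <- list(colnames(X), sprintf("axis%d", seq_len(k)))
  eig <- dvals^2
  structure(list(sample_scores = Frow, bin_scores = Gcol,
                 eigenvalues = eig,
                 percent_inertia = 100 * eig / total,
                 total_inertia = total),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  k <- min(4L, length(x$eigenvalues))
  cat(sprintf("correspondence analysis: %d samples, %d bins, total inertia %.4f\n",
              nrow(x$sample_scores), nrow(x$bin_scores), x$total_inertia))
  cat(sprintf("  axis %d: %.2f%%\n", seq_len(k), x$percent_inertia[seq_len(k)]),
      sep = "")
  invisible(x)
}

#' Percent of inertia explained by the leading axes
#'
#' @param res a [correspondence_analysis()] result.
#' @param k number of leading axes.
#' @return List with `percent` (length-`k` vector) and `cumulative` (their
#'   sum).
#' @export
variance_explained <- function(res, k) {
  stopifnot(inherits(res, "ca_result"))
  if (k < 1L || k > length(res$eigenvalues)) {
    trflp_error(sprintf("k must be in 1..%d", length(res$eigenvalues)))
  }
  p <- res$percent_inertia[seq_len(k)]
  list(percent = p, cumulative = sum(p))
}

#' Cluster samples in the ordination plane
#'
#' Complete-linkage clustering of the sample scores on the leading axes.
#' The cut is configurable: give `k` (number of clusters) or `h` (height).
#' With a design and neither, `k` defaults to the number of levels of the
#' chosen factor; without a design the tree is cut at half its maximum
#' merge height.
#'
#' @param res a [correspondence_analysis()] result.
#' @param design optional [sample_design()]; enables purity scoring.
#' @param n_axes number of leading axes used.
#' @param factor design factor used for the default `k` and for purity.
#' @param k,h optional cut: number of clusters or cut height.
#' @return Object of class `cluster_report`: `assignments` (data frame
#'   `sample_id`, `cluster`, plus design columns), `clusters` (per-cluster
#'   size, dominant label, purity) and `overall_purity` (`NA` without a
#'   design).
#' @export
cluster_report <- function(res, design = NULL, n_axes = 2,
                           factor = c("host_plant", "location", "diet"),
                           k = NULL, h = NULL) {
  factor <- match.arg(factor)
  stopifnot(inherits(res, "ca_result"))
  if (n_axes < 1L) trflp_error("n_axes must be >= 1")
  sc <- res$sample_scores[, seq_len(min(n_axes, ncol(res$sample_scores))),
                          drop = FALSE]
  ids <- rownames(sc)
  labels <- if (!is.null(design)) {
    design[[factor]][match(ids, design$sample_id)]
  } else {
    NULL
  }
  if (nrow(sc) == 1L) {
    memb <- stats::setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::dist(sc), method = "complete")
    if (is.null(k) && is.null(h)) {
      if (!is.null(labels)) k <- length(unique(labels)) else h <- max(hc$height) / 2
    }
    memb <- if (!is.null(k)) stats::cutree(hc, k = k) else stats::cutree(hc, h = h)
  }
  assignments <- data.frame(sample_id = ids, cluster = as.integer(memb),
                            stringsAsFactors = FALSE)
  if (!is.null(labels)) assignments[[factor]] <- labels
  cl_ids <- sort(unique(assignments$cluster))
  clusters <- do.call(rbind, lapply(cl_ids, function(cl) {
    inb <- assignments$cluster == cl
    if (!is.null(labels)) {
      tab <- sort(table(labels[inb]), decreasing = TRUE)
      data.frame(cluster = cl, n = sum(inb),
                 dominant_label = names(tab)[1],
                 purity = as.numeric(tab[1]) / sum(inb),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(cluster = cl, n = sum(inb), dominant_label = NA_character_,
                 purity = NA_real_, stringsAsFactors = FALSE)
    }
  }))
  overall <- if (!is.null(labels)) {
    sum(clusters$n * clusters$purity) / sum(clusters$n)
  } else {
    NA_real_
  }
  structure(list(assignments = assignments, clusters = clusters,
                 factor = factor, overall_purity = overall),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("cluster report (%d clusters", nrow(x$clusters)))
  if (!is.na(x$overall_purity)) {
    cat(sprintf(", purity %.2f by %s", x$overall_purity, x$factor))
  }
  cat(")\n")
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Write CA outputs as TSV
#'
#' `write_ca_scores` writes the sample principal coordinates;
#' `write_ca_eigen` the eigenvalue / percent-inertia table.
#'
#' @param res a `ca_result`.
#' @param path output path.
#' @export
write_ca_scores <- function(res, path) {
  df <- data.frame(sample = rownames(res$sample_scores), res$sample_scores,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ca_scores
#' @export
write_ca_eigen <- function(res, path) {
  df <- data.frame(axis = seq_along(res$eigenvalues),
                   eigenvalue = res$eigenvalues,
                   percent_inertia = res$percent_inertia)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
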