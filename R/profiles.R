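# Electropherogram peak processing: I/O, size-window and height filtering,
# replicate-consensus alignment (only peaks reproduced in both replicate
# runs are retained), and single-linkage binning of fragment sizes across
# samples into a presence/absence matrix.

#' Construct a peak profile
#'
#' One capillary-electrophoresis run: a sample/replicate identifier plus a
#' table of (fragment size in bp, peak height) pairs, kept sorted by size.
#'
#' @param sample_id,replicate_id identifiers.
#' @param peaks data frame with numeric columns `size_bp` (> 0) and
#'   `height` (>= 0).
#' @return An object of class `peak_profile`.
#' @export
peak_profile <- function(sample_id, replicate_id, peaks) {
  if (is.null(peaks) || nrow(peaks) == 0L) {
    peaks <- data.frame(size_bp = numeric(0), height = numeric(0))
  }
  if (!all(c("size_bp", "height") %in% names(peaks))) {
    trflp_error("peaks need columns size_bp and height")
  }
  peaks <- data.frame(size_bp = as.numeric(peaks$size_bp),
                      height = as.numeric(peaks$height))
  if (any(!is.finite(peaks$size_bp)) || any(peaks$size_bp <= 0)) {
    trflp_error("peak sizes must be finite and positive")
  }
  if (any(!is.finite(peaks$height)) || any(peaks$height < 0)) {
    trflp_error("peak heights must be finite and non-negative")
  }
  peaks <- peaks[order(peaks$size_bp), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(sample_id = as.character(sample_id),
                 replicate_id = as.character(replicate_id),
                 peaks = peaks),
            class = "peak_profile")
}

#' @export
print.peak_profile <- function(x, ...) {
  cat(sprintf("peak_profile %s/%s: %d peaks\n",
              x$sample_id, x$replicate_id, nrow(x$peaks)))
  invisible(x)
}

#' Read a peak table
#'
#' Delimited text (TSV or CSV, auto-detected from the header line) with
#' columns `sample`, `replicate`, `size_bp`, `height`. Rows are grouped into
#' one [peak_profile()] per (sample, replicate).
#'
#' @param path input file.
#' @return List of `peak_profile`s, in order of first appearance.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) trflp_error(sprintf("no such file: %s", path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample", "replicate", "size_bp", "height")
  if (!all(need %in% names(df))) {
    trflp_error(sprintf("peak table must have columns %s",
                        paste(need, collapse = ", ")), "trflp_parse")
  }
  size <- suppressWarnings(as.numeric(df$size_bp))
  height <- suppressWarnings(as.numeric(df$height))
  bad <- which(is.na(size) | is.na(height) | size <= 0 | height < 0 |
                 !nzchar(df$sample) | !nzchar(df$replicate))
  if (length(bad)) {
    trflp_error(sprintf("malformed peak table row at line %d", bad[1] + 1L),
                "trflp_parse")
  }
  df$size_bp <- size
  df$height <- height
  key <- paste(df$sample, df$replicate, sep = "\r")
  out <- lapply(unique(key), function(k) {
    rows <- df[key == k, , drop = FALSE]
    peak_profile(rows$sample[1], rows$replicate[1],
                 rows[, c("size_bp", "height")])
  })
  out
}

#' Write peak profiles to a delimited table
#' @param profiles list of `peak_profile`s.
#' @param path output path (TSV).
#' @export
write_peak_table <- function(profiles, path) {
  if (inherits(profiles, "peak_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    if (nrow(p$peaks) == 0L) return(NULL)
    data.frame(sample = p$sample_id, replicate = p$replicate_id,
               size_bp = p$peaks$size_bp, height = p$peaks$height,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(sample = character(0), replicate = character(0),
                     size_bp = numeric(0), height = numeric(0))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter peaks by height and size window
#'
#' Retains peaks with `height >= min_height` and
#' `size_window[1] <= size_bp <= size_window[2]`. Defaults reflect a 500-bp
#' internal size standard (GeneScan 500LIZ-type): fragments below 35 bp sit
#' in the primer/dye front and fragments above 500 bp are not sized.
#'
#' @param p a `peak_profile`.
#' @param min_height detection threshold in fluorescence units.
#' @param size_window numeric `c(lo, hi)` in bp, `lo < hi`.
#' @return Filtered `peak_profile`.
#' @export
filter_peaks <- function(p, min_height = 50, size_window = c(35, 500)) {
  stopifnot(inherits(p, "peak_profile"))
  if (length(size_window) != 2L || size_window[1] >= size_window[2]) {
    trflp_error("size_window must be c(lo, hi) with lo < hi")
  }
  keep <- p$peaks$height >= min_height &
    p$peaks$size_bp >= size_window[1] & p$peaks$size_bp <= size_window[2]
  peak_profile(p$sample_id, p$replicate_id, p$peaks[keep, , drop = FALSE])
}

# Greedy nearest-first one-to-one matching of two sorted peak lists.
# Returns a 2-column index matrix (i in s1, j in s2). Ties broken
# deterministically by smaller size so matching is symmetric in its inputs.
.match_peaks <- function(s1, s2, tol) {
  cand <- which(abs(outer(s1, s2, "-")) <= tol, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(cand)
  d <- abs(s1[cand[, 1]] - s2[cand[, 2]])
  lo <- pmin(s1[cand[, 1]], s2[cand[, 2]])
  hi <- pmax(s1[cand[, 1]], s2[cand[, 2]])
  cand <- cand[order(d, lo, hi), , drop = FALSE]
  used1 <- logical(length(s1)); used2 <- logical(length(s2))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!used1[i] && !used2[j]) {
      keep[r] <- TRUE
      used1[i] <- TRUE; used2[j] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

#' Consensus of two replicate profiles
#'
#' Only peaks reproduced in both replicate runs are considered reliable:
#' peaks are matched greedily nearest-first within `match_tolerance_bp`
#' (one-to-one), consensus size and height are the means of each matched
#' pair, and unmatched peaks are discarded.
#'
#' @param p1,p2 `peak_profile`s of the same sample.
#' @param match_tolerance_bp maximum size difference for a match.
#' @return A consensus `peak_profile` with `replicate_id = "consensus"`.
#' @export
replicate_consensus <- function(p1, p2, match_tolerance_bp = 1) {
  stopifnot(inherits(p1, "peak_profile"), inherits(p2, "peak_profile"))
  if (p1$sample_id != p2$sample_id) {
    trflp_error("replicate profiles belong to different samples")
  }
  mt <- .match_peaks(p1$peaks$size_bp, p2$peaks$size_bp, match_tolerance_bp)
  if (nrow(mt) == 0L) {
    return(peak_profile(p1$sample_id, "consensus", NULL))
  }
  peaks <- data.frame(
    size_bp = (p1$peaks$size_bp[mt[, 1]] + p2$peaks$size_bp[mt[, 2]]) / 2,
    height = (p1$peaks$height[mt[, 1]] + p2$peaks$height[mt[, 2]]) / 2)
  peak_profile(p1$sample_id, "consensus", peaks)
}

#' Pair replicates and build consensus profiles
#'
#' Convenience wrapper: groups a flat list of profiles by sample and forms
#' the [replicate_consensus()] of each pair.
#'
#' @param profiles list of `peak_profile`s, exactly two per sample.
#' @param match_tolerance_bp passed to [replicate_consensus()].
#' @return List of consensus `peak_profile`s, one per sample.
#' @export
consensus_profiles <- function(profiles, match_tolerance_bp = 1) {
  ids <- vapply(profiles, function(p) p$sample_id, "")
  lapply(unique(ids), function(s) {
    pair <- profiles[ids == s]
    if (length(pair) != 2L) {
      trflp_error(sprintf("sample '%s' has %d replicates, expected 2",
                          s, length(pair)))
    }
    replicate_consensus(pair[[1]], pair[[2]], match_tolerance_bp)
  })
}

#' Bin fragment sizes across samples into a presence/absence matrix
#'
#' Pooled peak sizes are clustered by single linkage at `bin_tolerance_bp`
#' (fragments chained within the tolerance co-migrate); each cluster is one
#' bin with centre equal to the mean size, and a cell is `TRUE` when the
#' sample contributed at least one peak to the bin.
#'
#' @param profiles list of `peak_profile`s (typically consensus profiles).
#' @param bin_tolerance_bp single-linkage merge tolerance in bp.
#' @return An object of class `presence_matrix`: list with `sample_ids`,
#'   `bin_centers_bp` (strictly increasing) and logical `values`
#'   (samples x bins).
#' @export
bin_profiles <- function(profiles, bin_tolerance_bp = 0.5) {
  if (inherits(profiles, "peak_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) trflp_error("need at least one profile")
  ids <- vapply(profiles, function(p) p$sample_id, "")
  if (anyDuplicated(ids)) {
    trflp_error("profiles must be one per sample (build a consensus first)")
  }
  sizes <- unlist(lapply(profiles, function(p) p$peaks$size_bp))
  owner <- rep(ids, vapply(profiles, function(p) nrow(p$peaks), 0L))
  if (length(sizes) == 0L) {
    return(structure(list(sample_ids = ids, bin_centers_bp = numeric(0),
                          values = matrix(FALSE, length(ids), 0,
                                          dimnames = list(ids, NULL))),
                     class = "presence_matrix"))
  }
  ord <- order(sizes)
  sizes <- sizes[ord]; owner <- owner[ord]
  bin <- cumsum(c(1, diff(sizes) > bin_tolerance_bp))
  centers <- as.numeric(tapply(sizes, bin, mean))
  values <- matrix(FALSE, length(ids), length(centers),
                   dimnames = list(ids, sprintf("bin_%.2f", centers)))
  values[cbind(match(owner, ids), bin)] <- TRUE
  structure(list(sample_ids = ids, bin_centers_bp = centers, values = values),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d samples x %d bins\n",
              length(x$sample_ids), length(x$bin_centers_bp)))
  invisible(x)
}

#' Export a presence/absence matrix as TSV (samples x bins, 0/1)
#' @param pm a `presence_matrix`.
#' @param path output path.
#' @export
write_presence_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "presence_matrix"))
  df <- data.frame(sample = pm$sample_ids,
                   pm$values + 0L, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
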