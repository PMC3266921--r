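# Pairwise community similarity. The unit statistic is the Dice (Sorensen)
# coefficient S_ab = 2*N_ab / (N_a + N_b), where N_a and N_b are the peak
# counts of two profiles and N_ab the number of peaks they share. Group
# summaries aggregate the pairwise matrix within and between levels of a
# design factor (host plant, location, diet).

#' Dice (Sorensen) similarity of two presence vectors
#'
#' @param row_a,row_b logical vectors of equal length (presence/absence over
#'   the same fragment bins).
#' @return `2 * N_ab / (N_a + N_b)` in `[0, 1]`.
#' @examples
#' dice(c(TRUE, TRUE, TRUE), c(TRUE, TRUE, FALSE)) # 2*2/(3+2)
#' @export
dice <- function(row_a, row_b) {
  row_a <- as.logical(row_a); row_b <- as.logical(row_b)
  if (length(row_a) != length(row_b)) {
    trflp_error("presence vectors differ in length")
  }
  na <- sum(row_a); nb <- sum(row_b)
  if (na + nb == 0L) {
    trflp_error("similarity undefined: both profiles are empty",
                "trflp_undefined_similarity")
  }
  2 * sum(row_a & row_b) / (na + nb)
}

#' Pairwise Dice similarity matrix
#'
#' @param m a [bin_profiles()] `presence_matrix` or a logical matrix with
#'   sample row names.
#' @return Symmetric matrix of class `similarity_matrix` with unit diagonal.
#' @export
similarity_matrix <- function(m) {
  v <- if (inherits(m, "presence_matrix")) m$values else as.matrix(m)
  mode(v) <- "logical"
  if (nrow(v) < 2L) trflp_error("need at least 2 samples")
  empty <- rowSums(v) == 0L
  if (any(empty)) {
    trflp_error(sprintf("sample '%s' has an empty profile",
                        rownames(v)[which(empty)[1]]),
                "trflp_undefined_similarity")
  }
  n <- nrow(v)
  s <- diag(1, n)
  dimnames(s) <- list(rownames(v), rownames(v))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s[i, j] <- s[j, i] <- dice(v[i, ], v[j, ])
    }
  }
  class(s) <- c("similarity_matrix", class(s))
  s
}

#' Sample design table
#'
#' @param sample_id,host_plant,location,diet character vectors of equal
#'   length; `diet` must be `"field"` or `"artificial"`.
#' @return A data frame of class `sample_design`.
#' @export
sample_design <- function(sample_id, host_plant, location, diet = "field") {
  df <- data.frame(sample_id = as.character(sample_id),
                   host_plant = as.character(host_plant),
                   location = as.character(location),
                   diet = as.character(diet),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) trflp_error("duplicate sample ids in design")
  if (!all(df$diet %in% c("field", "artificial"))) {
    trflp_error("diet must be 'field' or 'artificial'")
  }
  class(df) <- c("sample_design", "data.frame")
  df
}

.design_levels <- function(sim, design, factor) {
  ids <- rownames(sim)
  idx <- match(ids, design$sample_id)
  if (anyNA(idx)) {
    trflp_error(sprintf("sample '%s' missing from design", ids[which(is.na(idx))[1]]))
  }
  design[[factor]][idx]
}

#' Within- and between-group similarity summary
#'
#' Mirrors the usual pairwise-comparison table layout: for each level of the
#' chosen design factor the mean of all off-diagonal similarities among its
#' samples ("coefficient within group"), and for each level pair the mean
#' over all cross pairs ("coefficient between groups"). A singleton group
#' has no within-group pairs and reports `NA`.
#'
#' @param sim a [similarity_matrix()].
#' @param design a [sample_design()] covering all samples of `sim`.
#' @param factor one of `"host_plant"`, `"location"`, `"diet"`.
#' @return Object of class `group_summary`: list with `factor`, `within`
#'   (data frame `group`, `n`, `mean_similarity`) and `between` (groups x
#'   groups matrix, `NA` diagonal), groups in label order.
#' @export
group_summary <- function(sim, design,
                          factor = c("host_plant", "location", "diet")) {
  factor <- match.arg(factor)
  stopifnot(inherits(sim, "similarity_matrix"))
  g <- .design_levels(sim, design, factor)
  levels <- sort(unique(g))
  within <- data.frame(group = levels, n = NA_integer_,
                       mean_similarity = NA_real_, stringsAsFactors = FALSE)
  between <- matrix(NA_real_, length(levels), length(levels),
                    dimnames = list(levels, levels))
  for (a in seq_along(levels)) {
    ia <- which(g == levels[a])
    within$n[a] <- length(ia)
    if (length(ia) >= 2L) {
      sub <- sim[ia, ia, drop = FALSE]
      within$mean_similarity[a] <- mean(sub[upper.tri(sub)])
    }
    for (b in seq_along(levels)) {
      if (a == b) next
      ib <- which(g == levels[b])
      between[a, b] <- mean(sim[ia, ib, drop = FALSE])
    }
  }
  structure(list(factor = factor, within = within, between = between),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Similarity summary by %s\n", x$factor))
  w <- x$within
  b <- round(x$between, digits)
  b[upper.tri(b, diag = TRUE)] <- NA
  out <- data.frame(group = w$group, n = w$n,
                    within = round(w$mean_similarity, digits),
                    b, check.names = FALSE)
  print(out, row.names = FALSE, na.print = "")
  invisible(x)
}

#' Write a group summary in the lower-triangle table layout
#'
#' One row per group: sample count, within-group coefficient, then the
#' between-group coefficients for the groups listed before it.
#'
#' @param gs a [group_summary()].
#' @param path output TSV path.
#' @export
write_group_summary <- function(gs, path) {
  stopifnot(inherits(gs, "group_summary"))
  b <- gs$between
  b[upper.tri(b, diag = TRUE)] <- NA
  df <- data.frame(group = gs$within$group, n = gs$within$n,
                   coefficient_within_group = gs$within$mean_similarity,
                   b, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a similarity matrix as TSV
#' @param sim a `similarity_matrix`.
#' @param path output path.
#' @export
write_similarity_matrix <- function(sim, path) {
  df <- data.frame(sample = rownames(sim), unclass(sim), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
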