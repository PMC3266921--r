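# Recovery scoring against the generator's ground truth: replicate
# reproducibility, design-effect contrasts on the similarity matrix, and
# core-taxon ubiquity in consensus profiles. Used by the test suite and the
# acceptance script, and handy for power analyses of the workflow itself.

#' Dice similarity of two replicate runs
#'
#' Peaks are matched greedily one-to-one within `match_tolerance_bp`; the
#' Dice coefficient is `2 * matched / (n1 + n2)`.
#'
#' @param p1,p2 `peak_profile`s of the same sample.
#' @param match_tolerance_bp size tolerance for a shared peak.
#' @return Similarity in `[0, 1]`.
#' @export
replicate_dice <- function(p1, p2, match_tolerance_bp = 1) {
  stopifnot(inherits(p1, "peak_profile"), inherits(p2, "peak_profile"))
  n1 <- nrow(p1$peaks); n2 <- nrow(p2$peaks)
  if (n1 + n2 == 0L) {
    trflp_error("similarity undefined: both runs are empty",
                "trflp_undefined_similarity")
  }
  m <- nrow(.match_peaks(p1$peaks$size_bp, p2$peaks$size_bp, match_tolerance_bp))
  2 * m / (n1 + n2)
}

#' Mean within-sample replicate reproducibility
#'
#' @param profiles flat list of `peak_profile`s, two replicates per sample
#'   (e.g. from [simulate_electropherograms()], after [filter_peaks()]).
#' @param match_tolerance_bp passed to [replicate_dice()].
#' @return Mean replicate Dice across samples.
#' @export
mean_replicate_dice <- function(profiles, match_tolerance_bp = 1) {
  ids <- vapply(profiles, function(p) p$sample_id, "")
  vals <- vapply(unique(ids), function(s) {
    pair <- profiles[ids == s]
    if (length(pair) != 2L) {
      trflp_error(sprintf("sample '%s' needs exactly 2 replicates", s))
    }
    replicate_dice(pair[[1]], pair[[2]], match_tolerance_bp)
  }, 0)
  mean(vals)
}

.pair_sets <- function(sim, design) {
  ids <- rownames(sim)
  idx <- match(ids, design$sample_id)
  list(plant = design$host_plant[idx], loc = design$location[idx],
       diet = design$diet[idx], ids = ids)
}

#' Host-plant vs location similarity contrast
#'
#' Among field samples, compares the mean Dice similarity of same-plant /
#' different-location pairs against different-plant / same-location pairs —
#' the quantity that decides whether host plant or location structures the
#' communities more strongly.
#'
#' @param sim a [similarity_matrix()].
#' @param design a [sample_design()].
#' @return List with `same_plant_cross_location`,
#'   `cross_plant_same_location` (mean similarities) and `difference`.
#' @export
plant_location_contrast <- function(sim, design) {
  g <- .pair_sets(sim, design)
  field <- which(g$diet == "field")
  s1 <- c(); s2 <- c()
  for (a in field) {
    for (b in field) {
      if (b <= a) next
      same_p <- g$plant[a] == g$plant[b]
      same_l <- g$loc[a] == g$loc[b]
      if (same_p && !same_l) s1 <- c(s1, sim[a, b])
      if (!same_p && same_l) s2 <- c(s2, sim[a, b])
    }
  }
  list(same_plant_cross_location = mean(s1),
       cross_plant_same_location = mean(s2),
       difference = mean(s1) - mean(s2))
}

#' Artificial-diet vs field-diet similarity contrast
#'
#' @inheritParams plant_location_contrast
#' @return List with `diet_vs_crop` (mean similarity of artificial/field
#'   pairs), `crop_vs_crop` (mean over field/field pairs from different
#'   larvae) and `difference`.
#' @export
diet_contrast <- function(sim, design) {
  g <- .pair_sets(sim, design)
  n <- nrow(sim)
  dvc <- c(); cvc <- c()
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      art <- (g$diet[a] == "artificial") + (g$diet[b] == "artificial")
      if (art == 1L) dvc <- c(dvc, sim[a, b])
      if (art == 0L) cvc <- c(cvc, sim[a, b])
    }
  }
  list(diet_vs_crop = mean(dvc), crop_vs_crop = mean(cvc),
       difference = mean(dvc) - mean(cvc))
}

#' Fraction of consensus profiles containing each core taxon's fragment
#'
#' A core fragment counts as present in a profile when some peak lies
#' within `tol_bp` of the taxon's true terminal-fragment length. With the
#' default generator every core fragment should appear in every profile
#' (ubiquity = 1).
#'
#' @param truth a [assemble_communities()] result.
#' @param consensus list of consensus `peak_profile`s (one per sample).
#' @param tol_bp size tolerance.
#' @return List with `per_taxon` (named presence fractions) and `overall`
#'   (mean over core taxa and profiles).
#' @export
core_trf_presence <- function(truth, consensus, tol_bp = 0.5) {
  stopifnot(inherits(truth, "synthetic_truth"))
  core <- truth$roles$taxon_id[truth$roles$role == "core"]
  if (length(core) == 0L) trflp_error("no core taxa in truth")
  frac <- vapply(core, function(id) {
    t_len <- truth$trf_bp[[id]]
    mean(vapply(consensus, function(p) {
      any(abs(p$peaks$size_bp - t_len) <= tol_bp)
    }, TRUE))
  }, 0)
  list(per_taxon = frac, overall = mean(frac))
}
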