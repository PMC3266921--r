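# Ground-truthed synthetic data generator. Emulates the statistical
# structure the analysis chain assumes: a pool of 16S-like sequences derived
# from a common root and carrying conserved 27F/1492R priming sites; a
# host-plant x location sampling design with two larvae per cell and an
# optional artificial-diet group; occupancy-driven community membership with
# a ubiquitous core; and a capillary-electrophoresis noise layer (size
# jitter, peak dropout for subdominant taxa, spurious peaks) on terminal
# fragments within the size-standard window.

.default_plants <- c("chickpea", "cotton", "tomato", "sorghum",
                     "sunflower", "castor", "redgram", "ladyfinger")
.default_locations <- c("Pachora", "Delhi", "Bangalore", "Coimbatore")

#' Synthetic community generator configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: a 4 plants x 4 locations x 2 larvae field design with duplicate
#' electropherogram runs per larva, a 2-taxon ubiquitous core, plant-driven
#' occupancy stronger than location-driven occupancy, and noise calibrated
#' so duplicate-run reproducibility (replicate Dice) sits near 0.91.
#'
#' @param n_taxa size of the taxon pool.
#' @param root_length_bp length of the root 16S-like sequence.
#' @param substitution_rate per-site substitution probability applied to
#'   each taxon outside the priming sites; must be `< 0.25` (Jukes-Cantor
#'   distances saturate beyond that), `0` gives a degenerate pool identical
#'   to the root.
#' @param n_plants,n_locations,larvae_per_cell field sampling design.
#' @param core_taxa number of taxa present in every sample (the ubiquitous
#'   dominant phylotypes).
#' @param taxa_per_plant,taxa_per_location taxa assigned to each plant /
#'   location; remaining non-core taxa are background.
#' @param plant_effect,location_effect occurrence probability of a
#'   factor-specific taxon in a matching sample.
#' @param baseline_occupancy occurrence probability everywhere else.
#' @param size_jitter_sd_bp SD of Gaussian fragment-size measurement error.
#' @param dropout_prob per-replicate detection failure probability for a
#'   subdominant (non-core) taxon's peak.
#' @param core_dropout_prob detection failure probability for core-taxon
#'   peaks; 0 by default because dominant populations yield peaks far above
#'   the detection threshold.
#' @param spurious_peak_rate Poisson mean of spurious peaks per run.
#' @param artificial_diet add an artificial-diet group (modelled as an
#'   extra "plant" level reared in the lab, matching no field taxa)?
#' @param diet_member_loss probability that a non-core member is absent
#'   from an artificial-diet larva (impoverished diet).
#' @param amplicon_length_bp length of the 27F..1492R amplicon.
#' @param trf_grid candidate terminal-fragment lengths (bp) assigned to
#'   taxa; spaced so fragments do not co-migrate.
#' @param plant_names,location_names optional level names.
#' @param seed RNG seed; every generator stage derives its stream from it.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_taxa = 36, root_length_bp = 1500,
                             substitution_rate = 0.10,
                             n_plants = 4, n_locations = 4,
                             larvae_per_cell = 2, core_taxa = 2,
                             taxa_per_plant = 5, taxa_per_location = 2,
                             plant_effect = 0.9, location_effect = 0.3,
                             baseline_occupancy = 0.15,
                             size_jitter_sd_bp = 0.15, dropout_prob = 0.05,
                             core_dropout_prob = 0,
                             spurious_peak_rate = 0.5,
                             artificial_diet = TRUE, diet_member_loss = 0.75,
                             amplicon_length_bp = 1460,
                             trf_grid = seq(60, 476, by = 4),
                             plant_names = NULL, location_names = NULL,
                             seed = 1) {
  cfg <- list(n_taxa = as.integer(n_taxa),
              root_length_bp = as.integer(root_length_bp),
              substitution_rate = substitution_rate,
              n_plants = as.integer(n_plants),
              n_locations = as.integer(n_locations),
              larvae_per_cell = as.integer(larvae_per_cell),
              core_taxa = as.integer(core_taxa),
              taxa_per_plant = as.integer(taxa_per_plant),
              taxa_per_location = as.integer(taxa_per_location),
              plant_effect = plant_effect,
              location_effect = location_effect,
              baseline_occupancy = baseline_occupancy,
              size_jitter_sd_bp = size_jitter_sd_bp,
              dropout_prob = dropout_prob,
              core_dropout_prob = core_dropout_prob,
              spurious_peak_rate = spurious_peak_rate,
              artificial_diet = isTRUE(artificial_diet),
              diet_member_loss = diet_member_loss,
              amplicon_length_bp = as.integer(amplicon_length_bp),
              trf_grid = trf_grid,
              plant_names = plant_names, location_names = location_names,
              seed = as.integer(seed))
  if (cfg$substitution_rate < 0 || cfg$substitution_rate >= 0.25) {
    trflp_error("substitution_rate must lie in [0, 0.25): Jukes-Cantor distances saturate",
                "trflp_config")
  }
  probs <- c(plant_effect = cfg$plant_effect,
             location_effect = cfg$location_effect,
             baseline_occupancy = cfg$baseline_occupancy,
             dropout_prob = cfg$dropout_prob,
             core_dropout_prob = cfg$core_dropout_prob,
             diet_member_loss = cfg$diet_member_loss)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad)) {
    trflp_error(sprintf("probabilities out of [0,1]: %s",
                        paste(bad, collapse = ", ")), "trflp_config")
  }
  if (cfg$core_taxa > cfg$n_taxa) trflp_error("core_taxa exceeds n_taxa", "trflp_config")
  used <- cfg$core_taxa + cfg$n_plants * cfg$taxa_per_plant +
    cfg$n_locations * cfg$taxa_per_location
  if (used > cfg$n_taxa) {
    trflp_error("core + plant + location taxa exceed n_taxa", "trflp_config")
  }
  if (cfg$n_taxa > length(cfg$trf_grid)) {
    trflp_error("trf_grid too small for n_taxa", "trflp_config")
  }
  if (cfg$size_jitter_sd_bp < 0 || cfg$spurious_peak_rate < 0) {
    trflp_error("noise parameters must be non-negative", "trflp_config")
  }
  if (is.null(cfg$plant_names)) {
    cfg$plant_names <- if (cfg$n_plants <= length(.default_plants)) {
      .default_plants[seq_len(cfg$n_plants)]
    } else {
      sprintf("plant%02d", seq_len(cfg$n_plants))
    }
  }
  if (is.null(cfg$location_names)) {
    cfg$location_names <- if (cfg$n_locations <= length(.default_locations)) {
      .default_locations[seq_len(cfg$n_locations)]
    } else {
      sprintf("loc%02d", seq_len(cfg$n_locations))
    }
  }
  structure(cfg, class = "generator_config")
}

.BASES <- c("A", "C", "G", "T")

# Break every CTAG-type recognition hit upstream of the target cut, then
# plant the recognition site so the first cut sits exactly at `target`
# (amplicon coordinates). `s` is the full-genome character vector.
.force_trf <- function(s, target, amp_start, amp_len, protected, recog = "CTAG") {
  g0 <- amp_start - 1L                       # genome offset of amplicon pos 0
  site <- g0 + target + seq_len(nchar(recog)) - 1L
  s[site] <- strsplit(recog, "")[[1]]
  for (iter in 1:25) {
    amp <- paste(s[g0 + seq_len(amp_len)], collapse = "")
    hits <- gregexpr(recog, amp, fixed = TRUE)[[1]]
    hits <- hits[hits > 0 & hits < target]
    if (length(hits) == 0L) break
    for (h in hits) {
      pos <- g0 + h + seq_len(nchar(recog)) - 1L
      pos <- setdiff(pos, c(protected, site))
      if (length(pos) == 0L) next
      p <- pos[1]
      s[p] <- sample(setdiff(.BASES, s[p]), 1L)
    }
  }
  s
}

#' Generate the synthetic taxon pool
#'
#' Builds a random root sequence with the 27F site planted at position 11
#' and the (reverse-complemented) 1492R site closing a
#' `amplicon_length_bp`-long amplicon. Each taxon is derived by independent
#' per-site substitutions outside the priming sites, then a handful of
#' directed edits place its first BfaI cut at a taxon-specific fragment
#' length from `trf_grid`, guaranteeing in-window, non-comigrating terminal
#' fragments. With `substitution_rate = 0` all taxa are identical to the
#' root (degenerate control). Deterministic given `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @return Object of class `taxon_pool`: `sequences` (named character),
#'   `alignment` (gap-free, identical to `sequences`), `trf_bp` (assigned
#'   fragment lengths), `root`, `config`.
#' @export
generate_taxon_pool <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  L <- cfg$root_length_bp
  fwd <- strsplit("AGAGTTTGATCATGGCTCAG", "")[[1]]   # 27F, M resolved to A
  rev_rc <- strsplit("AAGTCGTAACAAGGTAACC", "")[[1]] # revcomp of 1492R
  amp_start <- 11L
  amp_len <- cfg$amplicon_length_bp
  rev_start <- amp_start - 1L + amp_len - length(rev_rc) + 1L
  if (rev_start + length(rev_rc) - 1L > L) {
    trflp_error("root_length_bp too short for the amplicon", "trflp_config")
  }
  root <- sample(.BASES, L, replace = TRUE)
  root[amp_start + seq_along(fwd) - 1L] <- fwd
  root[rev_start + seq_along(rev_rc) - 1L] <- rev_rc
  protected <- c(amp_start + seq_along(fwd) - 1L,
                 rev_start + seq_along(rev_rc) - 1L)
  free <- setdiff(seq_len(L), protected)
  ids <- sprintf("t%02d", seq_len(cfg$n_taxa))
  targets <- sample(cfg$trf_grid, cfg$n_taxa)
  seqs <- character(cfg$n_taxa)
  rate <- cfg$substitution_rate
  for (i in seq_len(cfg$n_taxa)) {
    if (rate == 0) {
      seqs[i] <- paste(root, collapse = "")
      next
    }
    s <- root
    mut <- free[stats::runif(length(free)) < rate]
    if (length(mut)) {
      s[mut] <- vapply(s[mut],
                       function(b) sample(setdiff(.BASES, b), 1L), "")
    }
    s <- .force_trf(s, targets[i], amp_start, amp_len, protected)
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- ids
  structure(list(sequences = seqs, alignment = seqs,
                 trf_bp = stats::setNames(targets, ids),
                 root = paste(root, collapse = ""), config = cfg),
            class = "taxon_pool")
}

.synth_design <- function(cfg) {
  grid <- expand.grid(larva = seq_len(cfg$larvae_per_cell),
                      location = cfg$location_names,
                      plant = cfg$plant_names,
                      stringsAsFactors = FALSE)
  df <- data.frame(sample_id = sprintf("%s_%s_L%d", grid$plant, grid$location,
                                       grid$larva),
                   host_plant = grid$plant, location = grid$location,
                   diet = "field", stringsAsFactors = FALSE)
  if (cfg$artificial_diet) {
    extra <- data.frame(
      sample_id = sprintf("artificial_diet_lab_L%d", seq_len(cfg$larvae_per_cell)),
      host_plant = "artificial_diet", location = "lab", diet = "artificial",
      stringsAsFactors = FALSE)
    df <- rbind(df, extra)
  }
  sample_design(df$sample_id, df$host_plant, df$location, df$diet)
}

.taxon_roles <- function(cfg) {
  ids <- sprintf("t%02d", seq_len(cfg$n_taxa))
  role <- rep("background", cfg$n_taxa)
  plant <- rep(NA_character_, cfg$n_taxa)
  location <- rep(NA_character_, cfg$n_taxa)
  role[seq_len(cfg$core_taxa)] <- "core"
  at <- cfg$core_taxa
  if (cfg$taxa_per_plant > 0) {
    for (p in cfg$plant_names) {
      idx <- at + seq_len(cfg$taxa_per_plant)
      role[idx] <- "plant"; plant[idx] <- p
      at <- at + cfg$taxa_per_plant
    }
  }
  if (cfg$taxa_per_location > 0) {
    for (l in cfg$location_names) {
      idx <- at + seq_len(cfg$taxa_per_location)
      role[idx] <- "location"; location[idx] <- l
      at <- at + cfg$taxa_per_location
    }
  }
  data.frame(taxon_id = ids, role = role, plant = plant, location = location,
             stringsAsFactors = FALSE)
}

#' Assemble communities: design, membership and ground truth
#'
#' Core taxa occur in every sample. A plant-assigned taxon occurs in a
#' sample with probability `plant_effect` when the plants match and
#' `baseline_occupancy` otherwise; location taxa likewise; background taxa
#' at baseline everywhere. Artificial-diet samples match no field taxa and
#' additionally lose each non-core member with probability
#' `diet_member_loss`. All draws are independent and seeded.
#'
#' @param cfg a [generator_config()].
#' @param pool a [generate_taxon_pool()] result.
#' @param enzyme fingerprinting enzyme used to compute true fragment
#'   lengths via the digestion machinery.
#' @return Object of class `synthetic_truth`: `config`, `pool`, `design`,
#'   logical `membership` (samples x taxa), `roles`, `trf_bp` (realised
#'   fragment lengths, from in-silico digestion), `enzyme`.
#' @export
assemble_communities <- function(cfg, pool, enzyme = bfai()) {
  stopifnot(inherits(cfg, "generator_config"), inherits(pool, "taxon_pool"))
  set.seed(cfg$seed + 1L)
  design <- .synth_design(cfg)
  roles <- .taxon_roles(cfg)
  ns <- nrow(design); nt <- nrow(roles)
  p <- matrix(cfg$baseline_occupancy, ns, nt,
              dimnames = list(design$sample_id, roles$taxon_id))
  for (j in seq_len(nt)) {
    if (roles$role[j] == "core") p[, j] <- 1
    if (roles$role[j] == "plant") {
      p[design$host_plant == roles$plant[j], j] <- cfg$plant_effect
    }
    if (roles$role[j] == "location") {
      p[design$location == roles$location[j], j] <- cfg$location_effect
    }
  }
  membership <- matrix(stats::runif(ns * nt) < p, ns, nt,
                       dimnames = dimnames(p))
  if (cfg$artificial_diet && cfg$diet_member_loss > 0) {
    diet_rows <- which(design$diet == "artificial")
    noncore <- roles$role != "core"
    for (i in diet_rows) {
      drop <- noncore & membership[i, ] &
        stats::runif(nt) < cfg$diet_member_loss
      membership[i, drop] <- FALSE
    }
  }
  trf <- vapply(roles$taxon_id, function(id) {
    amp <- extract_amplicon(pool$sequences[[id]], id = id)
    terminal_fragment(amp, enzyme)$length_bp
  }, 0L)
  structure(list(config = cfg, pool = pool, design = design,
                 membership = membership, roles = roles,
                 trf_bp = trf, enzyme = enzyme),
            class = "synthetic_truth")
}

#' Simulate noisy duplicate electropherograms
#'
#' For each sample and each of two replicate runs, every member taxon's
#' terminal fragment is emitted unless it drops out (`dropout_prob` for
#' subdominant taxa, `core_dropout_prob` for core taxa), with size = true
#' length + Gaussian jitter truncated to the size-standard window, and a
#' log-normal height (core taxa higher). A Poisson number of spurious peaks
#' is added uniformly across the window. Seeded and deterministic.
#'
#' @param truth an [assemble_communities()] result.
#' @param cfg configuration; defaults to the one embedded in `truth`.
#' @param window detectable size window in bp.
#' @return List of [peak_profile()]s (two per sample, replicates "R1"/"R2")
#'   with a `provenance` attribute tracing every peak to a member taxon or
#'   a spurious-peak record.
#' @export
simulate_electropherograms <- function(truth, cfg = truth$config,
                                       window = c(35, 500)) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(cfg$seed + 2L)
  design <- truth$design
  roles <- truth$roles
  is_core <- roles$role == "core"
  profiles <- list()
  prov <- list()
  for (i in seq_len(nrow(design))) {
    sid <- design$sample_id[i]
    members <- which(truth$membership[i, ])
    for (rep_i in 1:2) {
      drop_p <- ifelse(is_core[members], cfg$core_dropout_prob, cfg$dropout_prob)
      kept <- members[stats::runif(length(members)) >= drop_p]
      size <- truth$trf_bp[kept] + stats::rnorm(length(kept), 0, cfg$size_jitter_sd_bp)
      size <- pmin(pmax(size, window[1]), window[2])
      height <- ifelse(is_core[kept],
                       stats::rlnorm(length(kept), log(1500), 0.35),
                       stats::rlnorm(length(kept), log(600), 0.5))
      ns <- stats::rpois(1, cfg$spurious_peak_rate)
      sp_size <- stats::runif(ns, window[1], window[2])
      sp_height <- stats::rlnorm(ns, log(150), 0.4)
      peaks <- data.frame(size_bp = c(size, sp_size),
                          height = c(height, sp_height))
      rid <- sprintf("R%d", rep_i)
      profiles[[length(profiles) + 1L]] <- peak_profile(sid, rid, peaks)
      npk <- nrow(peaks)
      prov[[length(prov) + 1L]] <- data.frame(
        sample = rep(sid, npk), replicate = rep(rid, npk),
        size_bp = c(size, sp_size),
        origin = c(roles$taxon_id[kept], rep("spurious", ns)),
        stringsAsFactors = FALSE)
    }
  }
  attr(profiles, "provenance") <- do.call(rbind, prov)
  profiles
}

#' Draw a clone library from one sample
#'
#' Clones are sampled from the sample's member taxa with log-normal
#' abundance weights; core taxa get a strong weight boost, mirroring the
#' dominance of the ubiquitous phylotypes in real libraries. The default
#' library size of 90 clones matches a typical single-sample 16S cloning
#' effort.
#'
#' @param truth an [assemble_communities()] result.
#' @param sample_id which sample to draw from.
#' @param n_clones library size.
#' @param seed RNG seed (defaults to a stream derived from the config).
#' @param core_weight multiplicative abundance boost for core taxa.
#' @return Object of class `clone_library`: `sequences` (named character,
#'   one entry per clone), `taxon_counts`, `weights`, `sample_id`.
#' @export
generate_clone_library <- function(truth, sample_id, n_clones = 90,
                                   seed = truth$config$seed + 3L,
                                   core_weight = 20) {
  stopifnot(inherits(truth, "synthetic_truth"))
  i <- match(sample_id, truth$design$sample_id)
  if (is.na(i)) trflp_error(sprintf("no such sample: %s", sample_id))
  members <- which(truth$membership[i, ])
  if (length(members) == 0L) {
    trflp_error(sprintf("sample '%s' has no member taxa", sample_id))
  }
  set.seed(seed)
  ids <- truth$roles$taxon_id[members]
  w <- stats::rlnorm(length(members), 0, 1)
  w[truth$roles$role[members] == "core"] <-
    w[truth$roles$role[members] == "core"] * core_weight
  counts <- as.integer(stats::rmultinom(1, n_clones, w))
  clone_taxon <- rep(ids, counts)
  clone_ids <- sprintf("clone%03d_%s", seq_len(n_clones), clone_taxon)
  seqs <- stats::setNames(unname(truth$pool$sequences[clone_taxon]), clone_ids)
  structure(list(sequences = seqs,
                 taxon_counts = stats::setNames(counts, ids),
                 weights = stats::setNames(w, ids),
                 sample_id = sample_id),
            class = "clone_library")
}

#' Export the generator's ground truth as JSON
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- unclass(truth$config)
  members <- apply(truth$membership, 1, function(r) {
    truth$roles$taxon_id[r]
  }, simplify = FALSE)
  out <- list(config = cfg,
              design = truth$design,
              roles = truth$roles,
              trf_bp = as.list(truth$trf_bp),
              membership = members,
              enzyme = unclass(truth$enzyme))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
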