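# End-to-end orchestration: synthetic community generation (or a supplied
# peak table), peak processing, similarity and group summaries, clone
# library OTU/rarefaction analysis, neighbour-joining tree with bootstrap,
# and correspondence analysis. Every artifact is written to the output
# directory and listed in a manifest with content digests, so repeated runs
# with the same seed are verifiably byte-identical.

#' Validate a pipeline configuration
#'
#' Range and consistency checks; violations are returned as data, not
#' raised, so a caller can report them all at once.
#'
#' @param cfg a [generator_config()] (possibly edited, hence re-checked).
#' @param min_height,size_window,bin_tolerance_bp,match_tolerance_bp,
#'   otu_threshold analysis parameters.
#' @param peak_table optional path to a peak table (checked for existence).
#' @param enzyme_name,enzyme_table optional enzyme lookup: `enzyme_name`
#'   must appear in the table at `enzyme_table` (default shipped table).
#' @return Character vector of violations; empty when valid.
#' @export
validate_config <- function(cfg, min_height = 50, size_window = c(35, 500),
                            bin_tolerance_bp = 0.5, match_tolerance_bp = 1,
                            otu_threshold = 0.05, peak_table = NULL,
                            enzyme_name = NULL, enzyme_table = NULL) {
  v <- character(0)
  probs <- c(plant_effect = cfg$plant_effect,
             location_effect = cfg$location_effect,
             baseline_occupancy = cfg$baseline_occupancy,
             dropout_prob = cfg$dropout_prob,
             core_dropout_prob = cfg$core_dropout_prob %||% 0,
             diet_member_loss = cfg$diet_member_loss)
  for (nm in names(probs)) {
    if (!is.finite(probs[[nm]]) || probs[[nm]] < 0 || probs[[nm]] > 1) {
      v <- c(v, sprintf("%s = %s outside [0, 1]", nm, format(probs[[nm]])))
    }
  }
  if (!is.finite(cfg$substitution_rate) || cfg$substitution_rate < 0 ||
      cfg$substitution_rate >= 0.25) {
    v <- c(v, "substitution_rate outside [0, 0.25)")
  }
  if (cfg$spurious_peak_rate < 0) v <- c(v, "spurious_peak_rate negative")
  if (cfg$size_jitter_sd_bp < 0) v <- c(v, "size_jitter_sd_bp negative")
  if (length(size_window) != 2L || size_window[1] >= size_window[2]) {
    v <- c(v, "size_window must be c(lo, hi) with lo < hi")
  }
  if (min_height < 0) v <- c(v, "min_height negative")
  if (bin_tolerance_bp <= 0) v <- c(v, "bin_tolerance_bp must be positive")
  if (match_tolerance_bp <= 0) v <- c(v, "match_tolerance_bp must be positive")
  if (otu_threshold <= 0 || otu_threshold >= 1) {
    v <- c(v, "otu_threshold must lie in (0, 1)")
  }
  if (!is.null(peak_table) && !file.exists(peak_table)) {
    v <- c(v, sprintf("peak table not found: %s", peak_table))
  }
  if (!is.null(enzyme_name)) {
    tab_path <- enzyme_table %||% system.file("extdata", "enzymes.tsv",
                                              package = "trflpr")
    enz <- tryCatch(read_enzyme_table(tab_path), error = function(e) NULL)
    if (is.null(enz)) {
      v <- c(v, sprintf("enzyme table unreadable: %s", tab_path))
    } else if (!enzyme_name %in% names(enz)) {
      v <- c(v, sprintf("enzyme '%s' not found in table %s", enzyme_name, tab_path))
    }
  }
  v
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    trflp_error(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                "trflp_stage_error")
  })
}

#' Run the full fingerprinting pipeline
#'
#' With the default arguments the pipeline generates a synthetic dataset
#' from `cfg`, processes the electropherograms (filter, replicate
#' consensus, binning), computes the Dice similarity matrix and group
#' summaries by host plant / location / diet, draws a clone library from
#' one sample for OTU clustering, rarefaction and a bootstrapped
#' neighbour-joining tree, and ordinates the presence matrix by
#' correspondence analysis with a design-labelled cluster report. When
#' `peak_table` is supplied the peak data are read from file instead and
#' the truth-dependent stages (clone library, tree) are skipped.
#'
#' @param cfg a [generator_config()].
#' @param out_dir output directory (created if needed).
#' @param enzyme fingerprinting [enzyme()].
#' @param min_height,size_window peak filter settings.
#' @param match_tolerance_bp replicate consensus tolerance.
#' @param bin_tolerance_bp cross-sample binning tolerance.
#' @param otu_threshold OTU divergence threshold.
#' @param n_bootstrap bootstrap replicates for the tree.
#' @param clone_sample sample id for the clone library (default: first).
#' @param n_clones clone library size.
#' @param peak_table optional path to an existing peak table.
#' @param design required with `peak_table`: a [sample_design()].
#' @return Invisibly, a list with the `manifest` data frame (artifact,
#'   path, md5, bytes), a `summary` list of headline statistics, and the
#'   in-memory results.
#' @export
run_pipeline <- function(cfg = generator_config(), out_dir,
                         enzyme = bfai(), min_height = 50,
                         size_window = c(35, 500), match_tolerance_bp = 1,
                         bin_tolerance_bp = 0.5, otu_threshold = 0.05,
                         n_bootstrap = 100, clone_sample = NULL,
                         n_clones = 90, peak_table = NULL, design = NULL) {
  viol <- validate_config(cfg, min_height, size_window, bin_tolerance_bp,
                          match_tolerance_bp, otu_threshold,
                          peak_table = peak_table)
  if (length(viol)) {
    trflp_error(paste(c("invalid configuration:", viol), collapse = "\n  "),
                "trflp_config")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  put <- function(name, path) {
    artifacts[[name]] <<- path
    path
  }
  truth <- NULL
  if (is.null(peak_table)) {
    synth <- .stage("synth", {
      pool <- generate_taxon_pool(cfg)
      truth <- assemble_communities(cfg, pool, enzyme)
      profiles <- simulate_electropherograms(truth, cfg, window = size_window)
      write_fasta(pool$sequences, put("taxa_fasta", file.path(out_dir, "taxa.fasta")))
      write_fasta(pool$alignment, put("aligned_fasta", file.path(out_dir, "aligned.fasta")))
      utils::write.table(truth$design,
                         put("design_tsv", file.path(out_dir, "design.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_peak_table(profiles, put("peaks_tsv", file.path(out_dir, "peaks.tsv")))
      write_truth_json(truth, put("truth_json", file.path(out_dir, "truth.json")))
      list(truth = truth, profiles = profiles)
    })
    truth <- synth$truth
    profiles <- synth$profiles
    design <- truth$design
  } else {
    profiles <- .stage("profiles", read_peak_table(peak_table))
    if (is.null(design)) {
      trflp_error("a sample design is required when reading an external peak table",
                  "trflp_config")
    }
  }
  proc <- .stage("profiles", {
    filtered <- lapply(profiles, filter_peaks, min_height = min_height,
                       size_window = size_window)
    consensus <- consensus_profiles(filtered, match_tolerance_bp)
    pm <- bin_profiles(consensus, bin_tolerance_bp)
    write_presence_matrix(pm, put("presence_tsv", file.path(out_dir, "presence.tsv")))
    list(filtered = filtered, consensus = consensus, pm = pm)
  })
  sim <- .stage("similarity", {
    s <- similarity_matrix(proc$pm)
    write_similarity_matrix(s, put("similarity_tsv", file.path(out_dir, "similarity.tsv")))
    for (f in c("host_plant", "location", "diet")) {
      gs <- group_summary(s, design, f)
      write_group_summary(gs, put(paste0("summary_", f),
                                  file.path(out_dir, sprintf("summary_%s.tsv", f))))
    }
    s
  })
  otu_res <- NULL; tree <- NULL; clib <- NULL
  if (!is.null(truth)) {
    otu_res <- .stage("otu", {
      sid <- clone_sample %||% design$sample_id[1]
      clib <- generate_clone_library(truth, sid, n_clones)
      d <- jc_distance_matrix(clib$sequences)
      otus <- cluster_otus(d, otu_threshold)
      curve <- rarefaction(otu_abundances(otus))
      write_rarefaction(curve, put("rarefaction_tsv",
                                   file.path(out_dir, "rarefaction.tsv")))
      list(otus = otus, curve = curve, library = clib)
    })
    clib <- otu_res$library
    tree <- .stage("tree", {
      members <- unique(sub("^clone[0-9]+_", "", names(clib$sequences)))
      aln <- truth$pool$alignment[members]
      tr <- bootstrap_support(aln, n_replicates = n_bootstrap, seed = cfg$seed + 4L)
      write_newick(tr, put("tree_newick", file.path(out_dir, "tree.nwk")))
      tr
    })
  }
  ca <- .stage("ca", {
    res <- correspondence_analysis(proc$pm)
    write_ca_scores(res, put("ca_scores_tsv", file.path(out_dir, "ca_scores.tsv")))
    write_ca_eigen(res, put("ca_eigen_tsv", file.path(out_dir, "ca_eigen.tsv")))
    # recovery of a g-level factor needs up to g-1 ordination dimensions
    g <- length(unique(design$host_plant))
    rep <- cluster_report(res, design, n_axes = max(2L, g - 1L),
                          factor = "host_plant")
    utils::write.table(rep$assignments,
                       put("cluster_report_tsv", file.path(out_dir, "cluster_report.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(res = res, report = rep)
  })
  manifest <- data.frame(artifact = names(artifacts),
                         path = unname(unlist(artifacts)),
                         md5 = unname(tools::md5sum(unlist(artifacts))),
                         bytes = unname(file.size(unlist(artifacts))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    n_samples = length(proc$consensus),
    n_bins = length(proc$pm$bin_centers_bp),
    mean_replicate_dice = mean_replicate_dice(proc$filtered, match_tolerance_bp),
    ca_axis1_percent = ca$res$percent_inertia[1],
    ca_axis2_percent = ca$res$percent_inertia[2],
    plant_cluster_purity = ca$report$overall_purity)
  if (!is.null(otu_res)) {
    summary$n_otus <- max(otu_res$otus$assignment)
  }
  invisible(list(manifest = manifest, summary = summary, truth = truth,
                 profiles = profiles, consensus = proc$consensus,
                 presence = proc$pm, similarity = sim, otu = otu_res,
                 tree = tree, ca = ca))
}
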