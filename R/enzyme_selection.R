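# Restriction-enzyme screening: which enzyme's terminal fragments best
# discriminate the taxa of a clone library. Two fragments are treated as
# indistinguishable when they would co-migrate in capillary electrophoresis,
# i.e. merge under single linkage at the binning tolerance.

#' Tabulate terminal fragments for taxa x enzymes
#'
#' Each sequence must yield exactly one amplicon under the primer pair; the
#' amplicon is then digested with every candidate enzyme and the terminal
#' fragment length recorded.
#'
#' @param seqs named character vector (or `DNAStringSet`) of full-length
#'   template sequences.
#' @param enzymes list of [enzyme()] objects (e.g. [default_enzymes()]).
#' @param fwd,rev primer pair.
#' @return An object of class `trf_table`: list with `taxa`, `enzymes`,
#'   integer matrix `lengths` and logical matrix `cut_flags`.
#' @export
build_trf_table <- function(seqs, enzymes, fwd = primer_27f(),
                            rev = primer_1492r()) {
  seqs <- as_dna_chr(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    trflp_error("sequences must carry unique names")
  }
  if (inherits(enzymes, "trflp_enzyme")) enzymes <- list(enzymes)
  enz_names <- vapply(enzymes, function(e) e$name, "")
  if (anyDuplicated(enz_names)) trflp_error("duplicate enzyme names")
  taxa <- names(seqs)
  amps <- lapply(taxa, function(id) {
    tryCatch(extract_amplicon(seqs[[id]], fwd, rev, id = id),
             trflp_error = function(e) {
               trflp_error(sprintf("taxon '%s': %s", id, conditionMessage(e)),
                           class(e)[1])
             })
  })
  lengths <- matrix(NA_integer_, length(taxa), length(enzymes),
                    dimnames = list(taxa, enz_names))
  flags <- matrix(NA, length(taxa), length(enzymes),
                  dimnames = list(taxa, enz_names))
  for (j in seq_along(enzymes)) {
    for (i in seq_along(taxa)) {
      trf <- terminal_fragment(amps[[i]], enzymes[[j]])
      lengths[i, j] <- trf$length_bp
      flags[i, j] <- trf$cut_found
    }
  }
  structure(list(taxa = taxa, enzymes = enz_names,
                 lengths = lengths, cut_flags = flags),
            class = "trf_table")
}

#' Number of taxon groups an enzyme can distinguish
#'
#' Fragments within `bin_tolerance_bp` of each other are merged by single
#' linkage (transitively); the score is the number of resulting groups, at
#' most the number of taxa.
#'
#' @param table a [build_trf_table()] result.
#' @param enzyme_name enzyme to score.
#' @param bin_tolerance_bp co-migration tolerance in base pairs.
#' @return Integer group count.
#' @export
discrimination_score <- function(table, enzyme_name, bin_tolerance_bp = 0.5) {
  stopifnot(inherits(table, "trf_table"))
  if (!enzyme_name %in% table$enzymes) {
    trflp_error(sprintf("enzyme '%s' not in table", enzyme_name), "trflp_lookup")
  }
  x <- sort(table$lengths[, enzyme_name])
  if (length(x) == 0L) return(0L)
  sum(diff(x) > bin_tolerance_bp) + 1L
}

#' Rank enzymes by discriminatory power
#'
#' @inheritParams discrimination_score
#' @return A data frame with columns `enzyme`, `score`, `distinguishes_all`,
#'   sorted by score (descending) then enzyme name (ascending).
#' @export
pick_enzymes <- function(table, bin_tolerance_bp = 0.5) {
  stopifnot(inherits(table, "trf_table"))
  if (length(table$taxa) == 0L) trflp_error("empty TRF table")
  score <- vapply(table$enzymes, discrimination_score, integer(1),
                  table = table, bin_tolerance_bp = bin_tolerance_bp)
  out <- data.frame(enzyme = table$enzymes, score = as.integer(score),
                    distinguishes_all = score == length(table$taxa),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$enzyme), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enzyme ranking report
#' @param ranking result of [pick_enzymes()].
#' @param path output TSV path.
#' @export
write_enzyme_report <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
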