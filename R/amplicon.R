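# In-silico PCR and restriction digestion: primer site location, amplicon
# extraction, cut-site prediction and terminal restriction fragments (T-RFs).
#
# Conventions: all sequence positions are 1-based (R convention). A digestion
# cut position is reported as the number of bases 5' of the cut on the top
# strand, i.e. a cut value of 4 separates the 4-base prefix from the rest;
# this is also the length of the terminal fragment when the cut is the first
# one downstream of the labelled primer.

#' Define a PCR primer
#'
#' @param name primer name, e.g. `"27F"`.
#' @param pattern IUPAC DNA pattern (degenerate bases allowed), length >= 10.
#' @param max_mismatch maximum number of mismatching positions tolerated when
#'   locating the primer on a template.
#' @return An object of class `trflp_primer`.
#' @examples
#' primer("27F", "AGAGTTTGATCMTGGCTCAG")
#' @export
primer <- function(name, pattern, max_mismatch = 0L) {
  pattern <- toupper(pattern)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    trflp_error("primer name must be a non-empty string")
  }
  if (nchar(pattern) < 10L) trflp_error("primer pattern must be >= 10 bases")
  if (!is_iupac(pattern)) trflp_error("primer pattern must be IUPAC DNA")
  max_mismatch <- as.integer(max_mismatch)
  if (is.na(max_mismatch) || max_mismatch < 0L) {
    trflp_error("max_mismatch must be a non-negative integer")
  }
  structure(list(name = name, pattern = pattern, max_mismatch = max_mismatch),
            class = "trflp_primer")
}

#' Canonical bacterial 16S primers 27F and 1492R
#'
#' The near-universal 16S rRNA gene primer pair delimiting the ~1.46 kb
#' amplicon used for community fingerprinting. 27F carries the fluorescent
#' label, so the forward end defines the detected terminal fragment.
#'
#' @param max_mismatch mismatches tolerated at the priming site.
#' @return A `trflp_primer`.
#' @export
primer_27f <- function(max_mismatch = 0L) {
  primer("27F", "AGAGTTTGATCMTGGCTCAG", max_mismatch)
}

#' @rdname primer_27f
#' @export
primer_1492r <- function(max_mismatch = 0L) {
  primer("1492R", "GGTTACCTTGTTACGACTT", max_mismatch)
}

#' Read a primer configuration file
#'
#' Parses a simple `key = value` file with keys `forward`, `reverse` and
#' optionally `max_mismatch`. Lines starting with `#` are ignored.
#'
#' @param path path to the configuration file.
#' @return A list with elements `fwd` and `rev`, both `trflp_primer`s.
#' @export
read_primer_config <- function(path) {
  if (!file.exists(path)) trflp_error(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad)) {
    trflp_error(sprintf("malformed primer config line %d: '%s'", bad[1], lines[bad[1]]),
                "trflp_parse")
  }
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  cfg <- stats::setNames(as.list(vals), keys)
  if (is.null(cfg$forward) || is.null(cfg$reverse)) {
    trflp_error("primer config must define 'forward' and 'reverse'", "trflp_parse")
  }
  mm <- as.integer(cfg$max_mismatch %||% 0L)
  list(fwd = primer("forward", cfg$forward, mm),
       rev = primer("reverse", cfg$reverse, mm))
}

#' Define a restriction enzyme
#'
#' @param name enzyme name, e.g. `"BfaI"`.
#' @param recognition IUPAC recognition pattern.
#' @param cut_offset bases 3' of the recognition start (top strand) at which
#'   the backbone is cut; `0 <= cut_offset <= nchar(recognition)`.
#' @return An object of class `trflp_enzyme`.
#' @examples
#' enzyme("BfaI", "CTAG", 1) # C^TAG
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (!nzchar(recognition) || !is_iupac(recognition)) {
    trflp_error("recognition site must be a non-empty IUPAC DNA string")
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(recognition)) {
    trflp_error("cut_offset must lie within the recognition site")
  }
  structure(list(name = name, recognition = recognition, cut_offset = cut_offset),
            class = "trflp_enzyme")
}

#' BfaI (C^TAG)
#'
#' The four-cutter used for 16S community fingerprinting in this package's
#' reference workflow; its CTAG site is its own reverse complement.
#' @return A `trflp_enzyme`.
#' @export
bfai <- function() enzyme("BfaI", "CTAG", 1L)

#' Read an enzyme definition table
#'
#' Tab-separated file with columns `name`, `recognition`, `cut_offset`.
#'
#' @param path path to the TSV. Defaults to the table shipped with the
#'   package (`inst/extdata/enzymes.tsv`).
#' @return A list of `trflp_enzyme` objects, named by enzyme.
#' @export
read_enzyme_table <- function(path = system.file("extdata", "enzymes.tsv",
                                                 package = "trflpr")) {
  if (!file.exists(path)) trflp_error(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "recognition", "cut_offset")
  if (!all(need %in% names(df))) {
    trflp_error("enzyme table must have columns name, recognition, cut_offset",
                "trflp_parse")
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    enzyme(df$name[i], df$recognition[i], df$cut_offset[i])
  })
  stats::setNames(out, df$name)
}

#' Default enzyme panel
#' @return Named list of `trflp_enzyme`s read from the shipped table.
#' @export
default_enzymes <- function() read_enzyme_table()

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings returning plain named character vectors,
#' the sequence representation used throughout this package.
#'
#' @param path file path.
#' @param seqs named character vector of DNA sequences.
#' @return `read_fasta`: a named character vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) trflp_error(sprintf("no such file: %s", path))
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.check_seq <- function(seq) {
  seq <- as_dna_chr(seq)
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    trflp_error("sequence must be a single non-empty DNA string")
  }
  if (!is_dna(seq)) trflp_error("sequence alphabet restricted to A, C, G, T, N")
  seq
}

#' Locate primer binding sites
#'
#' Matches under IUPAC semantics: a sequence residue matches a pattern
#' position when it belongs to the pattern's IUPAC set; an `N` in the
#' sequence matches everything. Up to `primer$max_mismatch` mismatching
#' positions are tolerated. For `orientation = "reverse"` the reverse
#' complement of the primer is searched on the given (top) strand.
#'
#' @param seq a DNA string (character or `DNAString`).
#' @param primer a [primer()].
#' @param orientation `"forward"` or `"reverse"`.
#' @return Sorted integer vector of 1-based match start positions.
#' @examples
#' find_primer_sites("AGAGTTTGATCATGGCTCAGTTTT", primer_27f()) # 1
#' @export
find_primer_sites <- function(seq, primer,
                              orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  seq <- .check_seq(seq)
  stopifnot(inherits(primer, "trflp_primer"))
  if (nchar(primer$pattern) > nchar(seq)) {
    trflp_error("primer pattern longer than sequence")
  }
  pat <- Biostrings::DNAString(primer$pattern)
  if (orientation == "reverse") pat <- Biostrings::reverseComplement(pat)
  m <- Biostrings::matchPattern(pat, Biostrings::DNAString(seq),
                                max.mismatch = primer$max_mismatch,
                                fixed = FALSE)
  sort(Biostrings::start(m))
}

#' Extract the PCR amplicon delimited by a primer pair
#'
#' Requires exactly one forward and one reverse priming site, with the
#' forward site upstream. The amplicon runs from the forward match start
#' through the 3' end of the reverse-complemented reverse-primer site and is
#' labelled at the forward 5' end (the detected end in T-RFLP).
#'
#' @param seq template DNA string.
#' @param fwd,rev forward and reverse [primer()]s.
#' @param id template identifier carried through to the amplicon.
#' @return An object of class `trflp_amplicon` with fields `source_id`,
#'   `start`, `end` (1-based inclusive), `residues`, `labeled_end`.
#' @export
extract_amplicon <- function(seq, fwd = primer_27f(), rev = primer_1492r(),
                             id = "seq") {
  seq <- .check_seq(seq)
  fs <- find_primer_sites(seq, fwd, "forward")
  rs <- find_primer_sites(seq, rev, "reverse")
  rlen <- nchar(rev$pattern)
  if (length(fs) > 1L || length(rs) > 1L) {
    trflp_error(sprintf("ambiguous amplicon for '%s': %d forward / %d reverse sites",
                        id, length(fs), length(rs)),
                "trflp_ambiguous_amplicon")
  }
  if (length(fs) == 0L || length(rs) == 0L || rs + rlen - 1L <= fs) {
    trflp_error(sprintf("no amplicon for '%s': missing or misordered primer sites", id),
                "trflp_no_amplicon")
  }
  a <- fs
  b <- rs + rlen - 1L
  structure(list(source_id = id, start = a, end = b,
                 residues = substr(seq, a, b),
                 labeled_end = "forward-5prime"),
            class = "trflp_amplicon")
}

#' Predict restriction cut positions
#'
#' One cut per top-strand occurrence of the recognition pattern (IUPAC
#' semantics, overlapping occurrences included), at
#' `match_start - 1 + cut_offset`. Cut positions are prefix lengths: a cut
#' value `k` falls between residues `k` and `k + 1`.
#'
#' @param residues DNA string to digest.
#' @param enzyme a [enzyme()].
#' @return Sorted integer vector of cut positions (possibly empty).
#' @examples
#' digest_positions("AAACTAGAAA", bfai()) # 4
#' @export
digest_positions <- function(residues, enzyme) {
  residues <- .check_seq(residues)
  stopifnot(inherits(enzyme, "trflp_enzyme"))
  if (nchar(enzyme$recognition) > nchar(residues)) return(integer(0))
  m <- Biostrings::matchPattern(Biostrings::DNAString(enzyme$recognition),
                                Biostrings::DNAString(residues),
                                fixed = FALSE)
  sort(Biostrings::start(m) - 1L + enzyme$cut_offset)
}

#' Terminal restriction fragment of a labelled amplicon
#'
#' The detected fragment runs from the labelled 5' end to the first cut.
#' When the enzyme does not cut, the full amplicon length is reported with
#' `cut_found = FALSE` (such fragments fall beyond the size-standard window
#' and are excluded from profiles by default).
#'
#' @param amp a `trflp_amplicon` or a plain DNA string.
#' @param enzyme a [enzyme()].
#' @param taxon_id identifier recorded on the fragment (defaults to the
#'   amplicon's `source_id`).
#' @return An object of class `trflp_trf` with fields `taxon_id`,
#'   `enzyme_name`, `length_bp`, `cut_found`.
#' @export
terminal_fragment <- function(amp, enzyme, taxon_id = NULL) {
  if (inherits(amp, "trflp_amplicon")) {
    taxon_id <- taxon_id %||% amp$source_id
    residues <- amp$residues
  } else {
    taxon_id <- taxon_id %||% "seq"
    residues <- .check_seq(amp)
  }
  cuts <- digest_positions(residues, enzyme)
  cuts <- cuts[cuts >= 1L]  # a cut at position 0 releases no labelled fragment
  if (length(cuts)) {
    len <- min(cuts)
    found <- TRUE
  } else {
    len <- nchar(residues)
    found <- FALSE
  }
  structure(list(taxon_id = taxon_id, enzyme_name = enzyme$name,
                 length_bp = as.integer(len), cut_found = found),
            class = "trflp_trf")
}
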