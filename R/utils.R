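# Internal helpers shared across modules.

# Signal a classed condition so callers can distinguish error kinds
# (e.g. "trflp_no_amplicon" vs "trflp_ambiguous_amplicon").
trflp_error <- function(msg, class = "trflp_input") {
  stop(errorCondition(msg, class = c(class, "trflp_error", "error")))
}

IUPAC_CHARS <- "ACGTRYSWKMBDHVN"

is_dna <- function(x) grepl("^[ACGTN]+$", x)
is_iupac <- function(x) grepl(sprintf("^[%s]+$", IUPAC_CHARS), x)

# Accept character, DNAString or DNAStringSet; return plain character.
as_dna_chr <- function(x) {
  if (inherits(x, c("DNAString", "DNAStringSet", "XStringSet"))) {
    x <- as.character(x)
  }
  toupper(x)
}

# Equal-length gapped alignment as a character matrix (rows = sequences).
aln_matrix <- function(aln) {
  aln <- as_dna_chr(aln)
  if (is.matrix(aln)) return(aln)
  if (length(aln) < 2) trflp_error("alignment needs at least 2 sequences")
  if (length(unique(nchar(aln))) != 1L) {
    trflp_error("alignment rows must all have the same length")
  }
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
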