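# In-silico PCR and digestion.

test_that("primer sites are found under IUPAC semantics", {
  # M matches A at the degenerate position
  expect_equal(find_primer_sites("AGAGTTTGATCATGGCTCAGTTTT", primer_27f()), 1L)
  expect_error(find_primer_sites("TTTT", primer_27f()),
               "longer than sequence")
  expect_error(find_primer_sites("", primer_27f()), "non-empty")
})

test_that("mismatch-tolerant search matches the sliding-window oracle", {
  set.seed(41)
  pat <- "AGAGTTTGATCMTGGCTCAG"
  for (rep in 1:5) {
    s <- strsplit(rand_dna(200), "")[[1]]
    # plant an exact copy at 58 and a single-mismatch copy at 131 (1-based)
    exact <- strsplit(FWD27, "")[[1]]
    s[58:77] <- exact
    mm1 <- exact; mm1[7] <- setdiff(BASES, mm1[7])[1]
    s[131:150] <- mm1
    seq <- paste(s, collapse = "")
    got <- find_primer_sites(seq, primer("27F", pat, max_mismatch = 1))
    expect_equal(got, naive_primer_sites(seq, pat, 1))
    expect_true(all(c(58L, 131L) %in% got))
  }
})

test_that("reverse-orientation search finds the reverse complement", {
  seq <- make_template(rand_dna(50))
  r <- find_primer_sites(seq, primer_1492r(), "reverse")
  expect_equal(r, naive_primer_sites(seq, "GGTTACCTTGTTACGACTT", 0, "reverse"))
  expect_length(r, 1L)
})

test_that("amplicon extraction spans primer to reverse-complement end", {
  seq <- make_template(rand_dna(100), pad5 = rand_dna(10), pad3 = rand_dna(7))
  amp <- extract_amplicon(seq, id = "tx")
  expect_s3_class(amp, "trflp_amplicon")
  expect_equal(amp$start, 11L)
  expect_equal(nchar(amp$residues), 20 + 100 + 19)
  expect_equal(amp$end - amp$start + 1L, nchar(amp$residues))
  expect_true(startsWith(amp$residues, FWD27))
  expect_identical(amp$labeled_end, "forward-5prime")
})

test_that("generator taxa yield the canonical 1.46 kb amplicon", {
  pool <- generate_taxon_pool(generator_config(seed = 3))
  amp <- extract_amplicon(pool$sequences[[1]], id = "t01")
  expect_equal(nchar(amp$residues), 1460L)
  expect_equal(amp$start, 11L)
})

test_that("missing and duplicated primer sites raise distinct errors", {
  no_rev <- paste0(rand_dna(5), FWD27, rand_dna(60))
  expect_error(extract_amplicon(no_rev), class = "trflp_no_amplicon")
  two_fwd <- paste0(FWD27, rand_dna(30), FWD27, rand_dna(30), RC1492)
  expect_error(extract_amplicon(two_fwd), class = "trflp_ambiguous_amplicon")
})

test_that("digestion reports one cut per occurrence, overlapping included", {
  expect_equal(digest_positions("AAACTAGAAA", bfai()), 4L)
  expect_equal(digest_positions("AAAAAA", bfai()), integer(0))
  expect_equal(digest_positions("CTAGCTAGG", bfai()), c(1L, 5L))
})

test_that("digestion equals the IUPAC-expanded substring-scan oracle", {
  set.seed(42)
  enzymes <- list(bfai(), enzyme("HinfI", "GANTC", 1), enzyme("RsaI", "GTAC", 2))
  words <- lapply(enzymes, function(e) iupac_expand(e$recognition))
  for (rep in 1:150) {
    seq <- rand_dna(300)
    for (k in seq_along(enzymes)) {
      e <- enzymes[[k]]
      expect_identical(digest_positions(seq, e),
                       as.integer(naive_site_scan(seq, words[[k]]) - 1L + e$cut_offset))
    }
  }
})

test_that("terminal fragment is the distance to the first cut", {
  trf <- terminal_fragment("AAACTAGAAA", bfai())
  expect_equal(trf$length_bp, 4L)
  expect_true(trf$cut_found)

  uncut <- terminal_fragment(paste(rep("A", 1460), collapse = ""), bfai())
  expect_equal(uncut$length_bp, 1460L)
  expect_false(uncut$cut_found)

  multi <- terminal_fragment("AAACTAGAACTAGA", bfai())
  expect_equal(multi$length_bp, min(digest_positions("AAACTAGAACTAGA", bfai())))
})

test_that("terminal fragment never exceeds the amplicon length", {
  set.seed(7)
  for (rep in 1:50) {
    seq <- rand_dna(120)
    trf <- terminal_fragment(seq, bfai())
    expect_lte(trf$length_bp, nchar(seq))
    expect_identical(trf$length_bp == nchar(seq) &&
                       length(digest_positions(seq, bfai())) == 0, !trf$cut_found)
  }
})

test_that("palindromic digestion is reverse-complement invariant", {
  # A palindromic site occurs at mirrored positions on the two strands, so
  # the site count is strand-independent; the inter-cut fragment multiset
  # is additionally invariant when the cut sits at the centre of the site
  # (RsaI, GT^AC). BfaI's off-centre top-strand cut (C^TAG) shifts single
  # fragments by the 2-base overhang, so only its site count is compared.
  set.seed(8)
  rsai <- enzyme("RsaI", "GTAC", 2)
  frag_lengths <- function(seq, e) {
    diff(c(0, digest_positions(seq, e), nchar(seq)))
  }
  for (rep in 1:25) {
    seq <- rand_dna(400)
    rc <- revcomp_chr(seq)
    expect_equal(sort(frag_lengths(seq, rsai)), sort(frag_lengths(rc, rsai)))
    expect_equal(length(digest_positions(seq, bfai())),
                 length(digest_positions(rc, bfai())))
  }
})

test_that("enzyme and primer configuration files round-trip", {
  enz <- default_enzymes()
  expect_true("BfaI" %in% names(enz))
  expect_equal(enz$BfaI$recognition, "CTAG")
  expect_equal(enz$BfaI$cut_offset, 1L)
  pr <- read_primer_config(system.file("extdata", "primers.conf",
                                       package = "trflpr"))
  expect_equal(pr$fwd$pattern, "AGAGTTTGATCMTGGCTCAG")
  expect_equal(pr$rev$pattern, "GGTTACCTTGTTACGACTT")
})
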