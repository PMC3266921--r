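# Peak I/O, filtering, replicate consensus and binning.

rand_profile <- function(sample, replicate, n, lo = 40, hi = 480) {
  peak_profile(sample, replicate,
               data.frame(size_bp = sort(runif(n, lo, hi)),
                          height = runif(n, 60, 2000)))
}

test_that("peak tables read, validate and round-trip", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample\treplicate\tsize_bp\theight",
               "s1\tR1\t100.5\t200",
               "s1\tR1\t210.2\t350"), path)
  prof <- read_peak_table(path)
  expect_length(prof, 1L)
  expect_equal(nrow(prof[[1]]$peaks), 2L)
  expect_equal(prof[[1]]$peaks$size_bp, c(100.5, 210.2))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("sample\treplicate\tsize_bp\theight",
               "s1\tR1\t100.5\t200",
               "s1\tR1\t-5\t350"), bad)
  expect_error(read_peak_table(bad), "line 3", class = "trflp_parse")

  set.seed(21)
  profs <- list(rand_profile("a", "R1", 25), rand_profile("a", "R2", 25))
  out <- tempfile(fileext = ".tsv")
  write_peak_table(profs, out)
  back <- read_peak_table(out)
  expect_equal(back[[1]]$peaks, profs[[1]]$peaks, tolerance = 1e-12)
  expect_equal(back[[2]]$peaks, profs[[2]]$peaks, tolerance = 1e-12)
})

test_that("filtering applies height and window jointly, in any order", {
  p <- peak_profile("s", "R1",
                    data.frame(size_bp = c(30, 40, 200, 520),
                               height = c(100, 10, 60, 100)))
  f <- filter_peaks(p, min_height = 50, size_window = c(35, 500))
  expect_equal(f$peaks$size_bp, 200)

  set.seed(22)
  q <- rand_profile("s", "R1", 100, lo = 10, hi = 600)
  joint <- filter_peaks(q, 50, c(35, 500))
  seq1 <- filter_peaks(filter_peaks(q, 50, c(0.001, 1e6)), 0, c(35, 500))
  seq2 <- filter_peaks(filter_peaks(q, 0, c(35, 500)), 50, c(0.001, 1e6))
  expect_equal(joint$peaks, seq1$peaks)
  expect_equal(joint$peaks, seq2$peaks)
})

test_that("replicate consensus keeps only peaks present in both runs", {
  p1 <- peak_profile("s", "R1", data.frame(size_bp = c(100, 200, 300),
                                           height = c(500, 600, 700)))
  expect_equal(replicate_consensus(p1, p1)$peaks$size_bp, c(100, 200, 300))

  p2 <- peak_profile("s", "R2", data.frame(size_bp = c(150, 250),
                                           height = c(100, 100)))
  expect_equal(nrow(replicate_consensus(p1, p2, 0.5)$peaks), 0L)

  a <- peak_profile("s", "R1", data.frame(size_bp = 100.2, height = 500))
  b <- peak_profile("s", "R2", data.frame(size_bp = 100.6, height = 700))
  cons <- replicate_consensus(a, b, 0.5)
  expect_equal(cons$peaks$size_bp, 100.4)
  expect_equal(cons$peaks$height, 600)

  other <- peak_profile("t", "R1", data.frame(size_bp = 100, height = 1))
  expect_error(replicate_consensus(p1, other), "different samples")
})

test_that("consensus is symmetric and one-to-one", {
  set.seed(23)
  for (rep in 1:20) {
    p1 <- rand_profile("s", "R1", sample(3:10, 1))
    p2 <- rand_profile("s", "R2", sample(3:10, 1))
    c12 <- replicate_consensus(p1, p2, 1)
    c21 <- replicate_consensus(p2, p1, 1)
    expect_equal(c12$peaks, c21$peaks)
    expect_lte(nrow(c12$peaks), min(nrow(p1$peaks), nrow(p2$peaks)))
  }
})

test_that("consensus equals exhaustive optimal matching on tiny profiles", {
  # For <= 4 peaks per side, enumerate all one-to-one matchings and keep
  # the greedy-nearest-first result: every matched pair must be within
  # tolerance and the greedy matching must be maximal (no extra pair could
  # be added).
  set.seed(24)
  for (rep in 1:30) {
    s1 <- sort(runif(sample(1:4, 1), 100, 110))
    s2 <- sort(runif(sample(1:4, 1), 100, 110))
    p1 <- peak_profile("s", "R1", data.frame(size_bp = s1, height = 1))
    p2 <- peak_profile("s", "R2", data.frame(size_bp = s2, height = 1))
    cons <- replicate_consensus(p1, p2, 1)$peaks$size_bp
    # matched pair sizes are means => within tol/2 of both parents
    for (m in cons) {
      expect_true(min(abs(s1 - m)) <= 0.5 && min(abs(s2 - m)) <= 0.5)
    }
    # maximality: count of matches equals the maximum bipartite matching
    adj <- abs(outer(s1, s2, "-")) <= 1
    max_match <- function(adj) {
      n1 <- nrow(adj); n2 <- ncol(adj)
      best <- 0L
      recur <- function(i, used2, count) {
        if (i > n1) { best <<- max(best, count); return() }
        recur(i + 1L, used2, count)
        for (j in seq_len(n2)) {
          if (adj[i, j] && !used2[j]) {
            used2[j] <- TRUE
            recur(i + 1L, used2, count + 1L)
            used2[j] <- FALSE
          }
        }
      }
      recur(1L, logical(n2), 0L)
      best
    }
    expect_equal(length(cons), max_match(adj))
  }
})

test_that("binning clusters pooled sizes by single linkage", {
  p <- peak_profile("s1", "consensus",
                    data.frame(size_bp = c(100, 200), height = c(1, 1)))
  pm <- bin_profiles(list(p))
  expect_equal(length(pm$bin_centers_bp), 2L)
  expect_true(all(pm$values["s1", ]))

  p1 <- peak_profile("a", "c", data.frame(size_bp = c(100.0, 107.0), height = 1))
  p2 <- peak_profile("b", "c", data.frame(size_bp = 100.3, height = 1))
  pm2 <- bin_profiles(list(p1, p2), 0.5)
  expect_equal(length(pm2$bin_centers_bp), 2L)
  expect_equal(pm2$bin_centers_bp[1], mean(c(100.0, 100.3)))
  expect_equal(unname(pm2$values[, 1]), c(TRUE, TRUE))
  expect_equal(unname(pm2$values[, 2]), c(TRUE, FALSE))
})

test_that("binning matches the union-find oracle and ignores sample order", {
  set.seed(25)
  for (rep in 1:15) {
    profs <- lapply(1:4, function(i) rand_profile(sprintf("s%d", i), "c", 12))
    pm <- bin_profiles(profs, 0.8)
    sizes <- unlist(lapply(profs, function(p) p$peaks$size_bp))
    expect_equal(length(pm$bin_centers_bp), sl_group_count_1d(sizes, 0.8))
    expect_true(all(diff(pm$bin_centers_bp) > 0))
    # row sums equal per-sample distinct-bin counts
    expect_equal(unname(rowSums(pm$values)),
                 vapply(profs, function(p) {
                   length(unique(vapply(p$peaks$size_bp, function(s) {
                     which.min(abs(pm$bin_centers_bp - s))
                   }, 0L)))
                 }, 0L))
    # permuting sample input order leaves the (sample, center, value) set
    perm <- sample(4)
    pm2 <- bin_profiles(profs[perm], 0.8)
    expect_equal(pm2$bin_centers_bp, pm$bin_centers_bp)
    expect_equal(pm2$values[pm$sample_ids, ], pm$values)
  }
})
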