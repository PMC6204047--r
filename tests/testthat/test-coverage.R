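# Interval index queries and the sliding-window support profile.

test_that("containment counting honours exact boundaries", {
  idx0 <- build_interval_index(random_molecules(0L, 1000L))
  expect_warning(n0 <- count_spanning(idx0, "nope", 0L, 10L), "no molecules")
  expect_equal(n0, 0L)

  one <- data.table::data.table(contig = "c", start = 0L, end = 1000L,
                                barcode = "b", read_count = 5L)
  idx <- build_interval_index(one)
  expect_equal(count_spanning(idx, "c", 0L, 1000L), 1L)
  expect_equal(count_spanning(idx, "c", 0L, 1001L), 0L)

  m <- data.table::data.table(contig = "c", start = c(100L, 101L),
                              end = 5000L, barcode = c("a", "b"),
                              read_count = 5L)
  idx2 <- build_interval_index(m)
  # window [100, 1100): molecule starting at 100 contains it, at 101 does not
  expect_equal(count_spanning(idx2, "c", 100L, 1100L), 1L)
})

test_that("profile equals the brute-force O(n*L) recomputation and per-window index queries", {
  set.seed(31)
  for (rep in 1:20) {
    L <- sample(300:2500, 1L)
    w <- sample(c(40L, 100L, 250L), 1L)
    n <- sample(1:120, 1L)
    mols <- random_molecules(n, L, min_len = 20L, max_len = L)
    idx <- build_interval_index(mols)
    prof <- compute_support_profile(idx, "ctg", L, scan_params(w, 5L))
    expect_equal(prof$counts,
                 oracle_spanning_counts(mols$start, mols$end, L, w))
    # spot-check the same numbers through the interval-index query route
    for (i in sample.int(max(L - w + 1L, 1L), 10L, replace = TRUE) - 1L) {
      expect_equal(prof$counts[i + 1L], count_spanning(idx, "ctg", i, i + w))
    }
  }
})

test_that("contigs shorter than the window yield an empty profile", {
  idx <- build_interval_index(random_molecules(10L, 500L))
  prof <- compute_support_profile(idx, "ctg", 500L, scan_params(1000L, 20L))
  expect_length(prof$well_covered, 0L)
  expect_equal(length(find_cut_points(prof, scan_params(1000L, 20L))$cuts), 0L)
})

test_that("uniform deep tiling is fully well-covered", {
  L <- 5000L
  w <- 500L
  # 25 molecules covering the whole contig with margin beyond every window
  mols <- data.table::data.table(contig = "ctg", start = 0L, end = L,
                                 barcode = sprintf("b%02d", 1:25),
                                 read_count = 10L)
  prof <- compute_support_profile(build_interval_index(mols), "ctg", L,
                                  scan_params(w, 20L))
  expect_true(all(prof$well_covered))
})

test_that("a coverage break where all molecules stop is poorly covered (repeat scenario)", {
  # all left molecules end at 5000, a disjoint set starts at 5000: point
  # coverage looks continuous but no molecule spans the boundary
  L <- 10000L
  w <- 1000L
  left <- data.table::data.table(contig = "ctg", start = 0L, end = 5000L,
                                 barcode = sprintf("l%02d", 1:30),
                                 read_count = 10L)
  right <- data.table::data.table(contig = "ctg", start = 5000L, end = 10000L,
                                  barcode = sprintf("r%02d", 1:30),
                                  read_count = 10L)
  prof <- compute_support_profile(build_interval_index(rbind(left, right)),
                                  "ctg", L, scan_params(w, 20L))
  ws <- seq_len(length(prof$well_covered)) - 1L
  overlaps_break <- ws < 5000L & ws + w > 5000L
  expect_true(all(!prof$well_covered[overlaps_break]))
  expect_true(all(prof$well_covered[!overlaps_break]))
})

test_that("well-covered sets shrink as span or window increase", {
  set.seed(32)
  for (rep in 1:10) {
    L <- sample(500:3000, 1L)
    mols <- random_molecules(sample(10:150, 1L), L, min_len = 30L)
    idx <- build_interval_index(mols)
    w <- sample(c(50L, 120L), 1L)
    s <- sample(2:10, 1L)
    base <- compute_support_profile(idx, "ctg", L, scan_params(w, s))
    stricter <- compute_support_profile(idx, "ctg", L, scan_params(w, s + 3L))
    expect_true(all(which(stricter$well_covered) %in% which(base$well_covered)))
    wider <- compute_support_profile(idx, "ctg", L, scan_params(w + 40L, s))
    # compare on the window starts both scans evaluate
    common <- seq_len(length(wider$well_covered))
    expect_true(all(wider$counts[common] <= base$counts[common]))
    expect_true(all(which(wider$well_covered) %in% which(base$well_covered)))
  }
})

test_that("the spanning-count track exports as run-length bedGraph", {
  mols <- data.table::data.table(contig = "c", start = c(0L, 0L), end = c(60L, 100L),
                                 barcode = c("a", "b"), read_count = 5L)
  prof <- compute_support_profile(build_interval_index(mols), "c", 100L,
                                  scan_params(10L, 1L))
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  write_spanning_bedgraph(prof, bg)
  lines <- readLines(bg)
  got <- do.call(rbind, strsplit(lines, "\t"))
  # reconstructed per-position counts must equal the profile
  rebuilt <- integer(length(prof$counts))
  for (k in seq_len(nrow(got))) {
    rebuilt[(as.integer(got[k, 2L]) + 1L):as.integer(got[k, 3L])] <-
      as.integer(got[k, 4L])
  }
  expect_equal(rebuilt, prof$counts)
})
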