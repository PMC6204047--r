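# Synthetic scenario generator and the precision/recall evaluator.

test_that("scenario structure: junctions strictly inside contigs, zero-junction draft equals the genome", {
  p0 <- unclass(small_sim_params())
  p0$n_junctions <- 0L
  sc0 <- simulate_scenario(do.call(sim_params, p0))
  expect_equal(nrow(sc0$truth$junctions), 0L)
  # with no junctions the draft is the true genome partitioned into contigs
  expect_identical(paste(sc0$draft, collapse = ""),
                   unname(sc0$true_genome[["genome"]]))

  sc <- simulate_scenario(small_sim_params())
  jn <- sc$truth$junctions
  expect_equal(nrow(jn), 4L)
  lens <- sc$truth$contig_lengths
  expect_true(all(jn$pos > 0L & jn$pos < lens[jn$contig]))
  expect_equal(sum(lens), sc$params$genome_length)
  # every junction at least min_segment_length from the contig ends
  expect_true(all(jn$pos >= sc$params$min_segment_length))
  expect_true(all(lens[jn$contig] - jn$pos >= sc$params$min_segment_length))
  # the draft is a permutation of true-genome segments, none truly adjacent
  seg <- sc$segments[order(sc$segments$contig, sc$segments$draft_start), ]
  same_contig <- seg$contig[-1L] == seg$contig[-nrow(seg)]
  truly_adjacent <- seg$true_start[-1L] == seg$true_end[-nrow(seg)]
  expect_false(any(same_contig & truly_adjacent))
})

test_that("the seed fully determines scenario and alignments", {
  a <- simulate_scenario(small_sim_params(seed = 9L))
  b <- simulate_scenario(small_sim_params(seed = 9L))
  expect_identical(a[names(a) != "params"], b[names(b) != "params"])
  ra <- simulate_molecule_alignments(a)
  rb <- simulate_molecule_alignments(b)
  expect_identical(ra, rb)
  c_ <- simulate_scenario(small_sim_params(seed = 10L))
  expect_false(identical(a$draft, c_$draft))
})

test_that("a molecule crossing a junction splits into draft-local molecules that stop at the junction", {
  sc <- simulate_scenario(small_sim_params(seed = 3L))
  al <- simulate_molecule_alignments(sc)
  mols <- al$molecules
  boundaries <- sc$segments[, c("contig", "draft_start", "draft_end")]
  # no simulated molecule extends across any internal draft boundary
  jn <- sc$truth$junctions
  for (k in seq_len(nrow(jn))) {
    on_contig <- mols[mols$contig == jn$contig[k], ]
    expect_false(any(on_contig$start < jn$pos[k] & on_contig$end > jn$pos[k]))
  }
  # multi-segment molecules exist and their pieces abut segment boundaries
  multi <- mols[, .N, by = "barcode"][N > 1L, ]
  expect_gt(nrow(multi), 0L)
  pieces <- mols[mols$barcode %in% multi$barcode, ]
  at_boundary <- pieces$start %in% boundaries$draft_start |
    pieces$end %in% boundaries$draft_end
  expect_true(all(at_boundary))
})

test_that("molecule coverage at random non-junction points matches the calibration", {
  sc <- simulate_scenario(small_sim_params(seed = 5L))
  al <- simulate_molecule_alignments(sc)
  idx <- build_interval_index(al$molecules)
  set.seed(55)
  pts <- data.table::data.table(
    contig = sample(names(sc$truth$contig_lengths), 1000L, TRUE))
  pts$pos <- vapply(pts$contig, function(cn)
    sample.int(sc$truth$contig_lengths[[cn]] - 1L, 1L), integer(1L))
  # keep points clear of junctions and contig ends, where extents truncate
  margin <- 5000L
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    jp <- sc$truth$junctions$pos[sc$truth$junctions$contig == pts$contig[i]]
    L <- sc$truth$contig_lengths[[pts$contig[i]]]
    pts$pos[i] > margin && pts$pos[i] < L - margin &&
      (length(jp) == 0L || min(abs(jp - pts$pos[i])) > margin)
  }, logical(1L))
  pts <- pts[keep, ]
  counts <- vapply(seq_len(nrow(pts)), function(i)
    count_spanning(idx, pts$contig[i], pts$pos[i], pts$pos[i] + 1L),
    integer(1L))
  cov <- sc$params$molecule_coverage
  # nearby points share molecules, so the effective number of independent
  # observations is about one per molecule length of genome, not one per point
  n_indep <- sc$params$genome_length / sc$params$molecule_mean_length
  se <- stats::sd(counts) / sqrt(min(length(counts), n_indep))
  expect_lt(abs(mean(counts) - cov), 3 * se + 1)
})

test_that("precision and recall follow the greedy nearest-match definition", {
  truth <- list(junctions = data.frame(contig = "c", pos = (1:10) * 10000L))
  exact <- data.frame(contig = "c", pos = (1:10) * 10000L)
  ev <- evaluate_cuts(exact, truth, tolerance = 1000L)
  expect_equal(ev$precision, 1.0)
  expect_equal(ev$recall, 1.0)
  # no detections: warning, precision reported 1.0, recall 0
  expect_warning(ev0 <- evaluate_cuts(list(), truth, tolerance = 1000L),
                 "no detected cuts")
  expect_equal(ev0$precision, 1.0)
  expect_equal(ev0$recall, 0.0)
  # truth plus 5 spurious cuts far from any junction: precision 10/15
  spur <- rbind(exact, data.frame(contig = "c", pos = (1:5) * 10000L + 5000L))
  ev2 <- evaluate_cuts(spur, truth, tolerance = 1000L)
  expect_equal(ev2$precision, 10 / 15)
  expect_equal(ev2$recall, 1.0)
  # cuts on the wrong contig never match
  wrong <- data.frame(contig = "d", pos = 10000L)
  ev3 <- evaluate_cuts(wrong, truth, tolerance = 1000L)
  expect_equal(ev3$precision, 0.0)
  expect_equal(ev3$recall, 0.0)
})

test_that("emitted SAM and BED re-parse to the in-memory tables", {
  sc <- simulate_scenario(small_sim_params(seed = 6L))
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "reads.sam")
  bed <- file.path(dir, "molecules.bed")
  al <- simulate_molecule_alignments(sc, sam_path = sam, bed_path = bed)
  back <- parse_barcoded_alignments(sam)
  data.table::setorder(back, contig, start, qname)
  expect_equal(as.data.frame(back), as.data.frame(al$reads))
  expect_equal(as.data.frame(read_molecule_bed(bed)),
               as.data.frame(al$molecules))
  # scenario files round-trip through the FASTA writers
  paths <- write_scenario(sc, dir)
  draft <- Biostrings::readBStringSet(paths[["draft"]])
  expect_identical(as.character(draft), sc$draft)
})
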