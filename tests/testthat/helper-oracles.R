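# Independent oracles and fixture builders shared by the tests. These
# deliberately use naive algorithms and different control flow from the
# package implementation.

# O(n * L) brute force: for every window start, count molecules whose
# extent contains the whole window (0-based half-open).
oracle_spanning_counts <- function(start, end, contig_length, window) {
  n_pos <- contig_length - window + 1L
  if (n_pos < 1L) return(integer(0L))
  vapply(seq_len(n_pos) - 1L,
         function(i) sum(start <= i & end >= i + window),
         integer(1L))
}

# Position-scan reimplementation of the cut rule: walk the boolean vector,
# locate maximal FALSE runs with TRUE on both sides, cut after the last
# base of the preceding well-covered window and before the first base of
# the following one.
oracle_cut_points <- function(well, window) {
  n <- length(well)
  cuts <- integer(0L)
  i <- 1L
  while (i <= n) {
    if (!well[i]) {
      j <- i
      while (j < n && !well[j + 1L]) j <- j + 1L
      if (i > 1L && j < n) {
        p0 <- i - 1L   # 0-based first index of the run
        q0 <- j - 1L   # 0-based last index of the run
        cuts <- c(cuts, (p0 - 1L) + window, q0 + 1L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  sort(unique(cuts))
}

# Random molecule table on a single contig.
random_molecules <- function(n, contig_length, contig = "ctg",
                             min_len = 50L, max_len = NULL) {
  if (is.null(max_len)) max_len <- max(min_len + 1L, contig_length %/% 2L)
  len <- sample(min_len:max_len, n, replace = TRUE)
  start <- sample.int(max(contig_length - min_len, 1L), n, replace = TRUE) - 1L
  end <- pmin(start + len, contig_length)
  data.table::data.table(contig = contig, start = start, end = end,
                         barcode = sprintf("BX%05d-1", seq_len(n)),
                         read_count = sample(4:80, n, replace = TRUE))
}

# A reads table row builder with sane defaults.
make_reads <- function(contig, start, barcode, read_length = 150L,
                       mismatches = 0L, align_score = read_length,
                       mapq = 60L, end = start + read_length) {
  n <- max(length(contig), length(start), length(barcode),
           length(read_length), length(mismatches), length(align_score),
           length(mapq))
  data.table::data.table(
    qname = sprintf("q%04d", seq_len(n)),
    contig = rep_len(contig, n), start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(end, n)),
    barcode = rep_len(barcode, n),
    read_length = as.integer(rep_len(read_length, n)),
    mismatches = as.integer(rep_len(mismatches, n)),
    align_score = as.integer(rep_len(align_score, n)),
    mapq = as.integer(rep_len(mapq, n)))
}

# A support_profile built directly from a boolean vector, bypassing the
# scan, for exercising the cut logic on constructed cases.
profile_from_logical <- function(well, window = 1000L, contig = "ctg",
                                 min_spanning = 20L) {
  structure(list(contig = contig,
                 contig_length = length(well) + window - 1L,
                 window = as.integer(window),
                 min_spanning = as.integer(min_spanning),
                 counts = ifelse(well, min_spanning, 0L),
                 well_covered = as.logical(well)),
            class = "support_profile")
}

# Small simulation parameter set used where the full default scenario
# would be slow. Everything is scaled down together: 15 kbp molecules on a
# 300 kbp genome with 12 kbp minimum segments; pipeline runs on this
# scenario should use a molecule-grouping distance below the segment size
# (see small_pipeline_config).
small_sim_params <- function(seed = 7L, ...) {
  sim_params(genome_length = 300000L, n_junctions = 4L, n_contigs = 2L,
             molecule_mean_length = 15000L, molecule_coverage = 60,
             reads_per_molecule_mean = 25, min_segment_length = 12000L,
             seed = seed, ...)
}

small_pipeline_config <- function() {
  pipeline_config(molecule = molecule_params(max_read_gap = 10000L))
}
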