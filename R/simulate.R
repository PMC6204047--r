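# Desk-scale synthetic scenarios: a true genome, a misassembled draft,
# molecules with barcoded reads aligned to the draft, and a precision/
# recall evaluator against the injected truth.

#' Synthetic scenario parameters
#'
#' The generator emulates a linked-read experiment on a misassembled draft:
#' a random true genome is partitioned into segments; the draft is built by
#' concatenating segments so that no two segments adjacent in the true
#' genome are adjacent in a draft contig, making every internal draft
#' boundary a true misassembly junction. Molecules are placed uniformly on
#' the (circularised) true genome, so no simulated molecule can span a
#' junction on the draft -- reproducing the spanning-coverage dropout the
#' detector keys on.
#'
#' @param genome_length True genome length in bp (default 1 Mbp).
#' @param n_junctions Number of misassembly junctions to inject (default 10).
#' @param n_contigs Number of draft contigs (default 2).
#' @param molecule_mean_length Mean molecule length in bp (default 60 kbp;
#'   lengths are `min_molecule_length` plus an exponential, so the minimum
#'   matches the downstream small-molecule filter).
#' @param molecule_coverage Mean number of molecules whose true extent
#'   contains a given genome position (default 100).
#' @param reads_per_molecule_mean Mean read count of a molecule of mean
#'   length (default 60; counts are Poisson, proportional to molecule
#'   length, matching the ~1 read pair per kbp of real linked-read data).
#' @param read_length Read length in bp (default 150).
#' @param noise_read_frac Fraction of reads emitted with elevated edit
#'   distance (NM = 7) and depressed score (AS = 0.3 * l) so the per-read
#'   filters are exercised (default 0.05). Clean reads carry NM = 0,
#'   AS = l.
#' @param min_molecule_length Lower truncation of molecule lengths (default
#'   2000 bp).
#' @param min_segment_length Minimum segment length (default 55 kbp, i.e.
#'   longer than the default 50 kbp molecule-grouping distance). Junctions
#'   are then at least this far from contig ends and from one another, and
#'   the draft-local pieces of a barcode split at a junction can never be
#'   re-chained across an intervening segment, so each injected junction is
#'   detectable in principle.
#' @param seed Integer seed; the seed fully determines all outputs.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(genome_length = 1000000L, n_junctions = 10L,
                       n_contigs = 2L, molecule_mean_length = 60000L,
                       molecule_coverage = 100, reads_per_molecule_mean = 60,
                       read_length = 150L, noise_read_frac = 0.05,
                       min_molecule_length = 2000L,
                       min_segment_length = 55000L, seed = 1L) {
  p <- list(genome_length = as.integer(genome_length),
            n_junctions = as.integer(n_junctions),
            n_contigs = as.integer(n_contigs),
            molecule_mean_length = as.numeric(molecule_mean_length),
            molecule_coverage = as.numeric(molecule_coverage),
            reads_per_molecule_mean = as.numeric(reads_per_molecule_mean),
            read_length = as.integer(read_length),
            noise_read_frac = as.numeric(noise_read_frac),
            min_molecule_length = as.integer(min_molecule_length),
            min_segment_length = as.integer(min_segment_length),
            seed = as.integer(seed))
  stopifnot(p$genome_length > 0L, p$n_junctions >= 0L, p$n_contigs >= 1L,
            p$molecule_mean_length > p$min_molecule_length,
            p$molecule_coverage > 0, p$reads_per_molecule_mean > 0,
            p$read_length > 0L, p$noise_read_frac >= 0, p$noise_read_frac <= 1,
            p$min_molecule_length > 0L, p$min_segment_length > 0L)
  if (p$genome_length < 10 * p$molecule_mean_length) {
    stop("genome_length must be at least 10 * molecule_mean_length")
  }
  structure(p, class = "sim_params")
}

#' Simulate a true genome and a misassembled draft
#'
#' Partitions a random true genome into `n_junctions + n_contigs` segments
#' (each at least `min_segment_length` bp) and deals them into `n_contigs`
#' draft contigs in a permuted order rejected until no two true-adjacent
#' segments are joined, so that every internal boundary of a draft contig
#' is a misassembly junction. With `n_junctions = 0` the draft is the true
#' genome partitioned into contigs. Deterministic given `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `sim_scenario` with elements `true_genome`
#'   (named character vector of one sequence), `draft` (named character
#'   vector of contig sequences), `truth` (list: `contig_lengths`, named
#'   integer; `junctions`, data.table of `contig`, `pos`), `segments`
#'   (the true-to-draft coordinate map) and `params`.
#' @export
simulate_scenario <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  G <- params$genome_length
  S <- params$n_junctions + params$n_contigs
  if (S * params$min_segment_length > G) {
    stop("infeasible: ", S, " segments of >= ", params$min_segment_length,
         " bp do not fit in a ", G, " bp genome")
  }
  # a junction must join segments DISTANT in (circular) true-genome space:
  # a molecule whose true extent reaches from inside one joined segment to
  # inside the other has read pieces abutting the junction from both sides
  # on the draft, and those same-barcode pieces would re-chain into a fake
  # junction-spanning molecule. Requiring the true-space separation to be
  # at least 3 mean molecule lengths makes such bridging molecules
  # vanishingly rare, emulating misassemblies that join distant loci.
  min_true_sep <- 3 * params$molecule_mean_length
  found <- FALSE
  for (attempt in 1:500) {
    # segment lengths: minimum plus a random share of the slack
    share <- runif(S)
    extra <- floor(share / sum(share) * (G - S * params$min_segment_length))
    seg_len <- as.integer(params$min_segment_length + extra)
    seg_len[S] <- seg_len[S] + (G - sum(seg_len))
    true_end <- cumsum(seg_len)
    true_start <- true_end - seg_len
    # deal segments into contigs (each contig >= 1 segment)
    sizes <- rep(1L, params$n_contigs)
    if (S > params$n_contigs) {
      sizes <- sizes + tabulate(sample.int(params$n_contigs,
                                           S - params$n_contigs,
                                           replace = TRUE),
                                nbins = params$n_contigs)
    }
    contig_of_slot <- rep(seq_len(params$n_contigs), sizes)
    ok_perm <- function(perm) {
      same <- contig_of_slot[-1L] == contig_of_slot[-S]
      a <- perm[-S][same]
      b <- perm[-1L][same]
      if (length(a) == 0L) return(TRUE)
      fwd <- (true_start[b] - true_end[a]) %% G
      bwd <- (true_start[a] - true_end[b]) %% G
      all(pmin(fwd, bwd) >= min_true_sep)
    }
    perm <- seq_len(S)
    if (params$n_junctions == 0L) {
      found <- TRUE
      break
    }
    for (try in 1:500) {
      perm <- sample.int(S)
      if (ok_perm(perm)) {
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  if (!found) {
    stop("infeasible: could not join segments at a true-genome-space ",
         "separation of >= 3 molecule_mean_length; use fewer junctions ",
         "or a larger genome")
  }
  true_seq <- paste(sample(c("A", "C", "G", "T"), G, replace = TRUE),
                    collapse = "")
  contig_names <- sprintf("ctg%02d", seq_len(params$n_contigs))
  segments <- data.table::data.table(
    seg = perm, true_start = true_start[perm], true_end = true_end[perm],
    contig = contig_names[contig_of_slot])
  segments[, len := true_end - true_start]
  segments[, draft_start := cumsum(c(0L, len[-.N])), by = contig]
  segments[, draft_end := draft_start + len]
  draft <- vapply(contig_names, function(cn) {
    s <- segments[segments$contig == cn, ]
    paste(substring(true_seq, s$true_start + 1L, s$true_end), collapse = "")
  }, character(1L))
  contig_lengths <- vapply(contig_names, function(cn) {
    sum(segments$len[segments$contig == cn])
  }, integer(1L))
  jn <- segments[, list(pos = draft_end[-.N]), by = contig]
  junctions <- data.table::data.table(contig = jn$contig,
                                      pos = as.integer(jn$pos))
  data.table::setorder(junctions, contig, pos)
  # order the coordinate map by true position for fast read lookup
  data.table::setorder(segments, true_start)
  structure(list(true_genome = c(genome = true_seq), draft = draft,
                 truth = list(contig_lengths = contig_lengths,
                              junctions = junctions),
                 segments = segments, params = params),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("sim_scenario: %d bp genome -> %d draft contig(s), %d junction(s), seed %d\n",
              x$params$genome_length, length(x$draft),
              nrow(x$truth$junctions), x$params$seed))
  invisible(x)
}

#' Write a scenario's FASTA and truth files to a directory
#'
#' Writes `true.fa`, `draft.fa` and `truth.bed` (one zero-length BED record
#' per junction).
#'
#' @param scenario A [simulate_scenario()] object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "sim_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(true = file.path(dir, "true.fa"),
             draft = file.path(dir, "draft.fa"),
             truth = file.path(dir, "truth.bed"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(scenario$true_genome),
                              paths[["true"]], width = 60L)
  Biostrings::writeXStringSet(Biostrings::BStringSet(scenario$draft),
                              paths[["draft"]], width = 60L)
  jn <- scenario$truth$junctions
  writeLines(sprintf("%s\t%d\t%d", jn$contig, jn$pos, jn$pos),
             paths[["truth"]])
  invisible(paths)
}

#' Simulate molecules and barcoded read alignments on the draft
#'
#' Molecules are placed uniformly on the circularised true genome with
#' lengths `min_molecule_length + Exponential(molecule_mean_length -
#' min_molecule_length)`, each carrying a unique barcode and a Poisson
#' number of uniformly placed reads. Every read coordinate is mapped
#' through the segment map onto the draft; a molecule crossing a segment
#' boundary in true-genome space therefore yields reads at discontiguous
#' draft loci (one draft-local molecule per segment overlapped), so no
#' simulated molecule spans a junction on the draft. Reads straddling a
#' segment boundary (which a real aligner would clip or split) are dropped.
#'
#' A `noise_read_frac` fraction of reads carries NM = 7 and AS = 0.3 * l
#' and is removed by the default per-read filters; clean reads carry
#' NM = 0, AS = l, MAPQ 60. Deterministic given `params$seed` (an
#' RNG stream separate from [simulate_scenario()]'s is derived from it).
#'
#' @param scenario A [simulate_scenario()] object.
#' @param sam_path Optional path: write the alignments as SAM (valid
#'   all-match records with BX tags, exercising the real parser).
#' @param bed_path Optional path: write the true draft-local molecule
#'   extents as BED6 (name = barcode, score = reads in the extent).
#' @return List with `reads` (a reads table as from
#'   [parse_barcoded_alignments()]) and `molecules` (true draft-local
#'   molecule extents: `contig`, `start`, `end`, `barcode`, `read_count`).
#' @export
simulate_molecule_alignments <- function(scenario, sam_path = NULL,
                                         bed_path = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  params <- scenario$params
  set.seed(params$seed + 1L)
  G <- params$genome_length
  rl <- params$read_length
  seg <- scenario$segments        # ordered by true_start
  n_mol <- as.integer(round(params$molecule_coverage * G /
                              params$molecule_mean_length))
  mol_len <- pmin(as.integer(params$min_molecule_length +
                               round(rexp(n_mol, 1 / (params$molecule_mean_length -
                                                        params$min_molecule_length)))),
                  G - 1L)
  mol_start <- sample.int(G, n_mol, replace = TRUE) - 1L
  barcode <- sprintf("BX%07d-1", seq_len(n_mol))
  n_reads <- rpois(n_mol, params$reads_per_molecule_mean * mol_len /
                     params$molecule_mean_length)
  mol_idx <- rep.int(seq_len(n_mol), n_reads)
  offset <- floor(runif(length(mol_idx)) *
                    rep.int(pmax(mol_len - rl + 1L, 1L), n_reads))
  tpos <- (rep.int(mol_start, n_reads) + as.integer(offset)) %% G
  # map reads to the draft; drop reads crossing a segment (or genome) boundary
  si <- findInterval(tpos, seg$true_start)
  inside <- tpos + rl <= seg$true_end[si]
  si <- si[inside]; tpos <- tpos[inside]; mol_idx <- mol_idx[inside]
  nn <- length(tpos)
  noise <- runif(nn) < params$noise_read_frac
  reads <- data.table::data.table(
    qname = sprintf("r%08d", seq_len(nn)),
    contig = seg$contig[si],
    start = as.integer(seg$draft_start[si] + (tpos - seg$true_start[si])),
    barcode = barcode[mol_idx],
    read_length = rl,
    mismatches = ifelse(noise, 7L, 0L),
    align_score = ifelse(noise, as.integer(floor(0.3 * rl)), rl),
    mapq = 60L)
  reads[, end := start + rl]
  data.table::setcolorder(reads, c("qname", "contig", "start", "end",
                                   "barcode"))
  data.table::setorder(reads, contig, start, qname)
  # true draft-local molecule extents: molecule arcs clipped to segments
  arc <- data.table::data.table(
    mol = c(seq_len(n_mol), which(mol_start + mol_len > G)),
    a = c(mol_start, rep(0L, sum(mol_start + mol_len > G))),
    b = c(pmin(mol_start + mol_len, G),
          (mol_start + mol_len - G)[mol_start + mol_len > G]))
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = arc$a + 1L, end = arc$b),
    IRanges::IRanges(start = seg$true_start + 1L, end = seg$true_end))
  qa <- S4Vectors::queryHits(hits); sa <- S4Vectors::subjectHits(hits)
  cs <- pmax(arc$a[qa], seg$true_start[sa])
  ce <- pmin(arc$b[qa], seg$true_end[sa])
  mols <- data.table::data.table(
    contig = seg$contig[sa],
    start = as.integer(seg$draft_start[sa] + (cs - seg$true_start[sa])),
    end = as.integer(seg$draft_start[sa] + (ce - seg$true_start[sa])),
    barcode = barcode[arc$mol[qa]])
  rc <- reads[, .N, by = list(barcode, contig)]
  mols <- merge(mols, rc, by = c("barcode", "contig"), all.x = TRUE)
  mols[is.na(N), N := 0L]
  data.table::setnames(mols, "N", "read_count")
  data.table::setcolorder(mols, c("contig", "start", "end", "barcode",
                                  "read_count"))
  data.table::setorder(mols, contig, start, end, barcode)
  if (!is.null(sam_path)) {
    write_alignments_sam(reads, scenario$truth$contig_lengths, sam_path)
  }
  if (!is.null(bed_path)) write_molecule_bed(mols, bed_path)
  list(reads = reads[], molecules = mols[])
}

#' Score detected cuts against injected truth
#'
#' A truth junction is recovered when at least one detected cut lies within
#' `tolerance` bp of it on the same contig. Each detected cut is matched to
#' its nearest junction (at most one); a cut is a true positive when that
#' distance is within tolerance, so both cuts flanking one junction count
#' as matched. Precision = matched cuts / total cuts; recall = recovered
#' junctions / total junctions.
#'
#' @param detected Detected cuts: a list of cut plans, a breakpoints BED
#'   path, or a data.frame (see [cut_positions()]).
#' @param truth A truth list as in `scenario$truth` (needs `$junctions`).
#' @param tolerance Maximum distance in bp for a match (>= 0); use the scan
#'   window size.
#' @return List with `precision`, `recall`, `n_cuts`, `n_matched`,
#'   `n_junctions`, `n_recovered`, `tolerance`. With zero detected cuts,
#'   precision is reported as 1.0 with a warning (recall 0 when junctions
#'   exist, 1 when there is nothing to recover).
#' @export
evaluate_cuts <- function(detected, truth, tolerance = 1000L) {
  stopifnot(tolerance >= 0)
  cuts <- cut_positions(detected)
  jn <- data.table::as.data.table(truth$junctions)
  n_cuts <- nrow(cuts)
  n_junctions <- nrow(jn)
  res <- function(n_matched, n_recovered) {
    list(precision = if (n_cuts > 0L) n_matched / n_cuts else 1.0,
         recall = if (n_junctions > 0L) n_recovered / n_junctions else 1.0,
         n_cuts = n_cuts, n_matched = n_matched,
         n_junctions = n_junctions, n_recovered = n_recovered,
         tolerance = as.integer(tolerance))
  }
  if (n_cuts == 0L) {
    warning("no detected cuts; precision reported as 1.0")
    return(res(0L, 0L))
  }
  if (n_junctions == 0L) return(res(0L, 0L))
  nearest <- function(p, q) {
    # for each p, distance to nearest q (Inf when q empty)
    if (length(q) == 0L) return(rep(Inf, length(p)))
    vapply(p, function(x) min(abs(x - q)), numeric(1L))
  }
  n_matched <- 0L
  n_recovered <- 0L
  for (cn in unique(c(cuts$contig, jn$contig))) {
    cp <- cuts$pos[cuts$contig == cn]
    jp <- jn$pos[jn$contig == cn]
    n_matched <- n_matched + sum(nearest(cp, jp) <= tolerance)
    n_recovered <- n_recovered + sum(nearest(jp, cp) <= tolerance)
  }
  res(n_matched, n_recovered)
}
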