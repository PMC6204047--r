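# Orchestration: molecule inference -> window scan -> cut -> FASTA split.

#' Pipeline configuration
#'
#' Bundles the per-stage parameter objects with the defaults
#' nm = 5, as-ratio = 0.65, mapq = 0, dist = 50000, minsize = 2000,
#' min-reads = 4, window = 1000, span = 20.
#'
#' @param filter A [read_filter_params()] object.
#' @param molecule A [molecule_params()] object.
#' @param scan A [scan_params()] object.
#' @param bx_tag Barcode tag name in the alignments (default "BX").
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = read_filter_params(),
                            molecule = molecule_params(),
                            scan = scan_params(),
                            bx_tag = "BX") {
  stopifnot(inherits(filter, "read_filter_params"),
            inherits(molecule, "molecule_params"),
            inherits(scan, "scan_params"))
  structure(list(filter = filter, molecule = molecule, scan = scan,
                 bx_tag = bx_tag),
            class = "pipeline_config")
}

config_comment <- function(config) {
  sprintf(paste0("linkcut %s nm=%d as-ratio=%g mapq=%d bx-tag=%s dist=%d ",
                 "minsize=%d min-reads=%d window=%d span=%d"),
          as.character(utils::packageVersion("linkcut")),
          config$filter$max_mismatches, config$filter$min_score_ratio,
          config$filter$min_mapq, config$bx_tag,
          config$molecule$max_read_gap, config$molecule$min_molecule_size,
          config$molecule$min_reads_per_molecule,
          config$scan$window, config$scan$min_spanning)
}

#' Infer molecules from alignments and write the molecule BED
#'
#' Parses the barcoded alignments, applies the per-read filters, groups
#' same-barcode reads into molecules, filters the molecules, and writes
#' them as BED6. A summary (reads in/retained, molecules before/after
#' filtering) is logged via `message()`.
#'
#' @param alignments Path to SAM/BAM alignments of linked reads to the
#'   draft.
#' @param out_bed Output molecule BED path.
#' @param config A [pipeline_config()] object.
#' @return The filtered molecule table, invisibly.
#' @export
run_molecule <- function(alignments, out_bed, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  reads <- parse_barcoded_alignments(alignments, bx_tag = config$bx_tag)
  kept <- filter_reads(reads, config$filter)
  if (nrow(kept) == 0L) {
    warning("no reads passed the filters",
            if (nrow(reads) > 0L && all(is.na(reads$barcode)))
              " (no read carried a barcode tag)" else "")
  }
  mols <- group_into_molecules(kept, config$molecule)
  mols_kept <- filter_molecules(mols, config$molecule)
  message(sprintf("%s: %d reads in, %d retained; %d molecules, %d after size/read-count filter",
                  alignments, nrow(reads), nrow(kept), nrow(mols),
                  nrow(mols_kept)))
  write_molecule_bed(mols_kept, out_bed, comments = config_comment(config))
  invisible(mols_kept)
}

#' Detect unsupported regions and cut the draft assembly
#'
#' Reads the molecule BED and the draft FASTA, builds the interval index,
#' computes the support profile of every contig (in FASTA order), derives
#' cut plans, and writes the breakpoints BED and the corrected FASTA.
#'
#' @param draft Path to the draft FASTA.
#' @param molecule_bed Path to the molecule BED from [run_molecule()].
#' @param out_fasta Output corrected FASTA path.
#' @param out_bed Output breakpoints BED path.
#' @param config A [pipeline_config()] object.
#' @param bedgraph Optional path: also export the per-contig spanning-count
#'   track as bedGraph.
#' @return The list of cut plans (one per contig, FASTA order), invisibly.
#' @export
run_cut <- function(draft, molecule_bed, out_fasta, out_bed,
                    config = pipeline_config(), bedgraph = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  mols <- read_molecule_bed(molecule_bed)
  seqs <- Biostrings::readBStringSet(draft)
  ids <- sub("\\s.*$", "", names(seqs))
  unknown <- setdiff(unique(mols$contig), ids)
  if (length(unknown)) {
    stop("molecule BED references contig(s) absent from the FASTA: ",
         paste(unknown, collapse = ", "))
  }
  index <- build_interval_index(mols)
  lens <- Biostrings::width(seqs)
  plans <- vector("list", length(ids))
  if (!is.null(bedgraph)) writeLines(character(), bedgraph)
  for (i in seq_along(ids)) {
    profile <- compute_support_profile(index, ids[i], lens[i], config$scan)
    plans[[i]] <- find_cut_points(profile, config$scan)
    if (!is.null(bedgraph)) {
      write_spanning_bedgraph(profile, bedgraph, append = TRUE)
    }
    message(sprintf("%s: %d bp, %d cut(s)", ids[i], lens[i],
                    length(plans[[i]]$cuts)))
  }
  names(plans) <- ids
  write_breakpoints_bed(plans, out_bed, comments = config_comment(config))
  apply_cuts(seqs, plans, out_fasta)
  invisible(plans)
}

#' Run the full correction pipeline
#'
#' Runs [run_molecule()] then [run_cut()], persisting the stage artifacts
#' (`molecule.bed`, `breakpoints.bed`, `corrected.fa`) in `out_dir` so any
#' stage can be rerun in isolation. An optional `post_hook` shell command
#' (e.g. a scaffolder invocation) is run on completion with the corrected
#' FASTA path appended.
#'
#' @param alignments Path to SAM/BAM barcoded alignments.
#' @param draft Path to the draft FASTA.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()] object.
#' @param post_hook Optional shell command string run after the pipeline.
#' @return Named character vector of output paths, invisibly.
#' @export
run_all <- function(alignments, draft, out_dir,
                    config = pipeline_config(), post_hook = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(molecule_bed = file.path(out_dir, "molecule.bed"),
             breakpoints_bed = file.path(out_dir, "breakpoints.bed"),
             corrected_fasta = file.path(out_dir, "corrected.fa"))
  run_molecule(alignments, paths[["molecule_bed"]], config)
  run_cut(draft, paths[["molecule_bed"]], paths[["corrected_fasta"]],
          paths[["breakpoints_bed"]], config)
  if (!is.null(post_hook)) {
    status <- system(paste(post_hook, shQuote(paths[["corrected_fasta"]])))
    if (status != 0L) stop("post hook failed with exit status ", status)
  }
  invisible(paths)
}
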