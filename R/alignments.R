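# Barcoded alignment parsing and per-read quality filters.

#' Per-read alignment filter parameters
#'
#' Thresholds applied to each primary mapped alignment before molecule
#' inference. A read is retained when its edit distance is strictly below
#' `max_mismatches` (default: keep NM < 5), its aligner score is at least
#' `min_score_ratio` times the read length (default: keep AS >= 0.65 * l,
#' inclusive at the threshold), its mapping quality is at least `min_mapq`
#' (default 0, i.e. no MAPQ filter), and -- when `require_barcode` is TRUE --
#' it carries a barcode.
#'
#' @param max_mismatches Integer, reject reads with NM >= this value.
#' @param min_score_ratio Fraction in \[0, 1\]; keep AS >= ratio * read length.
#' @param min_mapq Minimum mapping quality (0 disables the filter).
#' @param require_barcode Drop reads without a barcode tag?
#' @return A list of class `read_filter_params`.
#' @export
#' @examples
#' read_filter_params(max_mismatches = 5, min_score_ratio = 0.65)
read_filter_params <- function(max_mismatches = 5L, min_score_ratio = 0.65,
                               min_mapq = 0L, require_barcode = TRUE) {
  max_mismatches <- as.integer(max_mismatches)
  stopifnot(max_mismatches >= 0L,
            min_score_ratio >= 0, min_score_ratio <= 1,
            min_mapq >= 0, isTRUE(require_barcode) || isFALSE(require_barcode))
  structure(list(max_mismatches = max_mismatches,
                 min_score_ratio = min_score_ratio,
                 min_mapq = as.integer(min_mapq),
                 require_barcode = require_barcode),
            class = "read_filter_params")
}

#' Parse barcoded linked-read alignments from SAM/BAM
#'
#' Reads a SAM or BAM file and returns one row per primary mapped record.
#' Unmapped, secondary, supplementary and duplicate records are excluded
#' before any filtering: only primary alignments may contribute to molecule
#' extents, so no read is counted twice. SAM input is converted to BAM
#' internally via [Rsamtools::asBam()].
#'
#' Coordinates are converted to 0-based half-open: `start = POS - 1`,
#' `end = start +` reference-space width of the CIGAR. `read_length` is the
#' query-space width of the CIGAR (the aligned read's length, symbol l in
#' the score filter AS >= 0.65 * l).
#'
#' @param path Path to a SAM (`.sam`) or BAM file whose header names all
#'   reference contigs.
#' @param bx_tag Name of the auxiliary string tag holding the barcode
#'   (default `"BX"`; other linked-read dialects may differ).
#' @return A `data.table` with columns `qname`, `contig`, `start`, `end`,
#'   `barcode` (NA when the tag is absent), `read_length`, `mismatches`
#'   (NM, NA if absent), `align_score` (AS, NA if absent), `mapq`.
#' @export
parse_barcoded_alignments <- function(path, bx_tag = "BX") {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  stopifnot(is.character(bx_tag), length(bx_tag) == 1L, nzchar(bx_tag))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    # htslib silently demotes records naming an unknown contig to unmapped;
    # make that an error instead
    lines <- readLines(path)
    is_header <- startsWith(lines, "@")
    sn <- sub("\\t.*$", "", sub("^.*\\tSN:", "", lines[startsWith(lines, "@SQ")]))
    rname <- vapply(strsplit(lines[!is_header], "\t", fixed = TRUE),
                    function(f) if (length(f) >= 3L) f[3L] else NA_character_,
                    character(1L))
    bad <- !is.na(rname) & rname != "*" & !(rname %in% sn)
    if (any(bad)) {
      stop("malformed SAM file '", path, "': record ", which(bad)[1L],
           " names contig '", rname[which(bad)[1L]],
           "' absent from the header")
    }
    bam <- tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("malformed SAM file '", path, "': ",
                               conditionMessage(e), call. = FALSE))
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = unique(c(bx_tag, "NM", "AS")),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE))
  x <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(x$pos)
  tag_or_na <- function(tag, mode) {
    v <- x$tag[[tag]]
    if (is.null(v)) v <- rep(as.vector(NA, mode = mode), n)
    v
  }
  reads <- data.table::data.table(
    qname = x$qname,
    contig = as.character(x$rname),
    start = x$pos - 1L,
    end = x$pos - 1L +
      GenomicAlignments::cigarWidthAlongReferenceSpace(x$cigar),
    barcode = tag_or_na(bx_tag, "character"),
    read_length = GenomicAlignments::cigarWidthAlongQuerySpace(x$cigar),
    mismatches = as.integer(tag_or_na("NM", "integer")),
    align_score = as.integer(tag_or_na("AS", "integer")),
    mapq = as.integer(x$mapq))
  reads[]
}

#' Test reads against the per-read alignment filters
#'
#' Pure vectorised predicate: TRUE iff `mismatches < max_mismatches` AND
#' `align_score >= min_score_ratio * read_length` AND `mapq >= min_mapq`
#' AND (barcode present or `require_barcode` is FALSE). A missing NM or AS
#' value fails the corresponding comparison: a read whose quality cannot be
#' assessed is not trusted to delimit a molecule.
#'
#' @param reads A reads table as returned by [parse_barcoded_alignments()].
#' @param params A [read_filter_params()] object.
#' @return Logical vector, one element per read.
#' @export
passes_filters <- function(reads, params = read_filter_params()) {
  stopifnot(inherits(params, "read_filter_params"))
  nm_ok <- !is.na(reads$mismatches) & reads$mismatches < params$max_mismatches
  # small epsilon keeps the >= comparison inclusive despite floating-point
  # representation of the ratio (0.65 * 100 is slightly above 65)
  as_ok <- !is.na(reads$align_score) &
    reads$align_score >= params$min_score_ratio * reads$read_length - 1e-6
  mq_ok <- !is.na(reads$mapq) & reads$mapq >= params$min_mapq
  bx_ok <- !params$require_barcode | !is.na(reads$barcode)
  nm_ok & as_ok & mq_ok & bx_ok
}

#' Subset a reads table to the reads passing the filters
#'
#' @inheritParams passes_filters
#' @param verbose Emit a message with retained/dropped counts?
#' @return The retained rows, input order preserved.
#' @export
filter_reads <- function(reads, params = read_filter_params(),
                         verbose = FALSE) {
  keep <- passes_filters(reads, params)
  if (verbose) {
    message(sprintf("reads: %d in, %d retained, %d dropped (%d lacked a barcode)",
                    nrow(reads), sum(keep), sum(!keep),
                    sum(is.na(reads$barcode))))
  }
  reads[keep, ]
}

#' Write a reads table back to SAM
#'
#' Emits one primary mapped record per read with an all-match-compatible
#' CIGAR reconstructed from `read_length` and the reference span (a trailing
#' D or I operation reconciles the two when they differ), `SEQ`/`QUAL`
#' omitted (`*`), and NM/AS/BX auxiliary tags when present. Used by the
#' simulator and for round-trip testing; the output re-parses to the same
#' read table.
#'
#' @param reads A reads table (see [parse_barcoded_alignments()]).
#' @param contig_lengths Named integer vector of reference lengths covering
#'   every contig that appears in `reads`.
#' @param path Output SAM path.
#' @param bx_tag Barcode tag name to emit.
#' @return `path`, invisibly.
#' @export
write_alignments_sam <- function(reads, contig_lengths, path, bx_tag = "BX") {
  stopifnot(!is.null(names(contig_lengths)),
            all(reads$contig %in% names(contig_lengths)))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                      as.integer(contig_lengths)))
  if (nrow(reads) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  ref_span <- reads$end - reads$start
  cigar <- ifelse(ref_span == reads$read_length,
                  sprintf("%dM", reads$read_length),
           ifelse(ref_span > reads$read_length,
                  sprintf("%dM%dD", reads$read_length,
                          ref_span - reads$read_length),
                  sprintf("%dM%dI", ref_span, reads$read_length - ref_span)))
  opt <- paste0(
    ifelse(is.na(reads$mismatches), "", sprintf("\tNM:i:%d", reads$mismatches)),
    ifelse(is.na(reads$align_score), "", sprintf("\tAS:i:%d", reads$align_score)),
    ifelse(is.na(reads$barcode), "", sprintf("\t%s:Z:%s", bx_tag, reads$barcode)))
  rec <- sprintf("%s\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*%s",
                 reads$qname, reads$contig, reads$start + 1L, reads$mapq,
                 cigar, opt)
  writeLines(c(header, rec), path)
  invisible(path)
}
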