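# Grouping same-barcode reads into inferred molecules; molecule BED I/O.

#' Molecule inference parameters
#'
#' @param max_read_gap Maximum distance (bp) between the start coordinates
#'   of consecutive same-barcode reads on one contig for them to belong to
#'   the same molecule. Default 50000 (50 kbp), the partitioning distance
#'   also used by the 10x Long Ranger / Lariat tools.
#' @param min_molecule_size Molecules shorter than this (bp) are considered
#'   spurious and removed. Default 2000.
#' @param min_reads_per_molecule Molecules composed of fewer reads than this
#'   are removed; near-singleton "molecules" are alignment noise. Default 4.
#' @return A list of class `molecule_params`.
#' @export
molecule_params <- function(max_read_gap = 50000L, min_molecule_size = 2000L,
                            min_reads_per_molecule = 4L) {
  p <- list(max_read_gap = as.integer(max_read_gap),
            min_molecule_size = as.integer(min_molecule_size),
            min_reads_per_molecule = as.integer(min_reads_per_molecule))
  stopifnot(p$max_read_gap > 0L, p$min_molecule_size > 0L,
            p$min_reads_per_molecule > 0L)
  structure(p, class = "molecule_params")
}

#' Group filtered same-barcode reads into molecules
#'
#' Within each (barcode, contig) group, reads sorted by position are chained
#' while the distance between the start coordinates of consecutive reads is
#' at most `max_read_gap`; each maximal chain becomes one molecule whose
#' extent runs from its leftmost read start to its rightmost read end.
#' Molecules never extend across contigs; a barcode seen on two contigs
#' yields (at least) one molecule per contig. The result is independent of
#' the input row order.
#'
#' @param reads A reads table whose rows all carry barcodes and passed the
#'   per-read filters (see [filter_reads()]).
#' @param params A [molecule_params()] object.
#' @return A `data.table` with columns `contig`, `start`, `end`, `barcode`,
#'   `read_count`, sorted by (contig, start, end, barcode).
#' @export
group_into_molecules <- function(reads, params = molecule_params()) {
  stopifnot(inherits(params, "molecule_params"))
  if (anyNA(reads$barcode))
    stop("reads without a barcode cannot be grouped; filter them first")
  dt <- data.table::as.data.table(reads)[
    , list(contig, start, end, barcode)]
  if (nrow(dt) == 0L) {
    return(data.table::data.table(contig = character(), start = integer(),
                                  end = integer(), barcode = character(),
                                  read_count = integer()))
  }
  data.table::setorder(dt, barcode, contig, start, end)
  new_chain <- c(TRUE, dt$barcode[-1L] != dt$barcode[-nrow(dt)] |
                   dt$contig[-1L] != dt$contig[-nrow(dt)] |
                   dt$start[-1L] - dt$start[-nrow(dt)] > params$max_read_gap)
  dt[, mol_id := cumsum(new_chain)]
  mols <- dt[, list(contig = contig[1L], start = min(start), end = max(end),
                    barcode = barcode[1L], read_count = .N),
             by = mol_id][, mol_id := NULL]
  data.table::setorder(mols, contig, start, end, barcode)
  mols[]
}

#' Filter molecules by size and read count
#'
#' Retains molecules whose extent is at least `min_molecule_size` bp
#' (a molecule of exactly the threshold length is kept: "shorter than" is
#' strict) and which are composed of at least `min_reads_per_molecule`
#' reads. Order is preserved.
#'
#' @param mols A molecule table from [group_into_molecules()].
#' @param params A [molecule_params()] object.
#' @return The retained rows.
#' @export
filter_molecules <- function(mols, params = molecule_params()) {
  stopifnot(inherits(params, "molecule_params"))
  mols[(mols$end - mols$start) >= params$min_molecule_size &
         mols$read_count >= params$min_reads_per_molecule, ]
}

#' Write molecules as BED6
#'
#' One line per molecule: contig, start, end, name = barcode,
#' score = read count, strand = ".". Coordinates 0-based half-open.
#' Optional `#`-prefixed comment lines record provenance; they are skipped
#' on re-reading, so the round-trip is lossless.
#'
#' @param mols A molecule table sorted by (contig, start).
#' @param path Output path.
#' @param comments Character vector of comment lines to prepend (without
#'   the leading `"# "`).
#' @return `path`, invisibly.
#' @export
write_molecule_bed <- function(mols, path, comments = NULL) {
  lines <- character()
  if (length(comments)) lines <- paste0("# ", comments)
  if (nrow(mols)) {
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t%d\t.", mols$contig,
                              as.integer(mols$start), as.integer(mols$end),
                              mols$barcode, as.integer(mols$read_count)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a molecule BED6 file
#'
#' Inverse of [write_molecule_bed()]. Lines starting with `#`, `track` or
#' `browser` are skipped. Malformed lines raise an error naming the line
#' number.
#'
#' @param path Path to a BED file.
#' @return A molecule `data.table` (`contig`, `start`, `end`, `barcode`,
#'   `read_count`).
#' @export
read_molecule_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(fields) == 0L) {
    return(data.table::data.table(contig = character(), start = integer(),
                                  end = integer(), barcode = character(),
                                  read_count = integer()))
  }
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    stop("malformed BED line ", lineno[which(nf < 5L)[1L]],
         " in '", path, "': expected >= 5 tab-separated fields")
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:5)), ncol = 5L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  score <- suppressWarnings(as.integer(m[, 5L]))
  bad <- is.na(start) | is.na(end) | is.na(score) | start < 0L | end < start
  if (any(bad)) {
    stop("malformed BED line ", lineno[which(bad)[1L]], " in '", path,
         "': non-numeric or inconsistent coordinates")
  }
  data.table::data.table(contig = m[, 1L], start = start, end = end,
                         barcode = m[, 4L], read_count = score)
}
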