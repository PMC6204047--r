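# Molecule interval index and the sliding-window spanning-coverage scan.

#' Sliding-window scan parameters
#'
#' @param window Window size in bp (default 1000). The scan slides this
#'   window along each contig with a step of 1 bp. The published human-scale
#'   evaluation of the method used window = 2000.
#' @param min_spanning Minimum number of molecules that must contain a
#'   window for it to count as well-covered (default 20).
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(window = 1000L, min_spanning = 20L) {
  p <- list(window = as.integer(window),
            min_spanning = as.integer(min_spanning))
  stopifnot(p$window >= 1L, p$min_spanning >= 1L)
  structure(p, class = "scan_params")
}

#' Build a per-contig interval index of molecule extents
#'
#' The index answers containment-count queries: how many molecule intervals
#' contain a given window \[a, b), i.e. have `start <= a` and `end >= b`.
#' Queries are served by [IRanges::countOverlaps()] with
#' `type = "within"` over a per-contig [IRanges::IRanges] of the molecule
#' extents.
#'
#' @param mols A filtered molecule table (see [filter_molecules()]).
#' @return An object of class `interval_index`.
#' @export
build_interval_index <- function(mols) {
  by_contig <- split(mols[, c("start", "end")], mols$contig)
  idx <- lapply(by_contig, function(d) {
    list(start = as.integer(d$start), end = as.integer(d$end),
         ranges = IRanges::IRanges(start = as.integer(d$start) + 1L,
                                   end = as.integer(d$end)))
  })
  structure(list(contigs = idx, n_molecules = nrow(mols)),
            class = "interval_index")
}

#' @export
print.interval_index <- function(x, ...) {
  cat("interval_index:", x$n_molecules, "molecules on",
      length(x$contigs), "contig(s)\n")
  invisible(x)
}

#' Count molecules spanning a window
#'
#' A molecule spans a window when its extent contains the whole window:
#' `molecule.start <= win_start` and `molecule.end >= win_end` (both
#' boundaries inclusive). Molecule extents are delimited by read
#' alignments, so a molecule containing the window necessarily has a read
#' at or left of `win_start` and a read at or right of `win_end` -- the
#' molecule-extent analogue of a molecule spanning a point with reads on
#' both sides.
#'
#' @param index An [build_interval_index()] object.
#' @param contig Contig name.
#' @param win_start,win_end Window in 0-based half-open coordinates.
#' @return Integer count. An unknown contig yields 0 with a warning
#'   (assembly contigs with no aligned molecules are legal).
#' @export
count_spanning <- function(index, contig, win_start, win_end) {
  stopifnot(inherits(index, "interval_index"),
            win_start >= 0, win_start < win_end)
  ci <- index$contigs[[contig]]
  if (is.null(ci)) {
    warning("contig '", contig, "' has no molecules in the index")
    return(0L)
  }
  IRanges::countOverlaps(
    IRanges::IRanges(start = as.integer(win_start) + 1L,
                     end = as.integer(win_end)),
    ci$ranges, type = "within")
}

#' Compute the per-position window support profile of a contig
#'
#' Slides a `window`-bp window along the contig with a step of 1 bp and
#' records, for every window start position `i` in `0 ... contig_length -
#' window`, the number of molecules containing \[i, i + window) and whether
#' that count reaches `min_spanning`. A contig shorter than the window
#' yields an empty profile (such a contig is never cut).
#'
#' The scan is evaluated with a difference vector over window-start
#' positions (a molecule \[s, e) contains windows starting in
#' \[max(s, 0), e - window\]) followed by a cumulative sum, equivalent to
#' querying the interval index at every position but O(n + L) per contig.
#'
#' @param index An [build_interval_index()] object.
#' @param contig Contig name (need not be present in the index).
#' @param contig_length Length of the contig in bp (from the FASTA or the
#'   alignment header).
#' @param params A [scan_params()] object.
#' @return An object of class `support_profile`: a list with `contig`,
#'   `contig_length`, `window`, `min_spanning`, integer vector `counts` and
#'   logical vector `well_covered`, both indexed by window start + 1.
#' @export
compute_support_profile <- function(index, contig, contig_length,
                                    params = scan_params()) {
  stopifnot(inherits(index, "interval_index"), inherits(params, "scan_params"),
            contig_length >= 0)
  contig_length <- as.integer(contig_length)
  w <- params$window
  n_pos <- contig_length - w + 1L
  if (n_pos < 1L) {
    counts <- integer(0L)
  } else {
    ci <- index$contigs[[contig]]
    if (is.null(ci) || length(ci$start) == 0L) {
      counts <- integer(n_pos)
    } else {
      lo <- pmax(ci$start, 0L)            # first window start contained
      hi <- pmin(ci$end - w, n_pos - 1L)  # last window start contained
      ok <- hi >= lo & lo <= n_pos - 1L
      add <- tabulate(lo[ok] + 1L, nbins = n_pos + 1L)
      sub <- tabulate(hi[ok] + 2L, nbins = n_pos + 1L)
      counts <- cumsum(add - sub)[seq_len(n_pos)]
    }
  }
  structure(list(contig = contig, contig_length = contig_length,
                 window = w, min_spanning = params$min_spanning,
                 counts = counts,
                 well_covered = counts >= params$min_spanning),
            class = "support_profile")
}

#' @export
print.support_profile <- function(x, ...) {
  cat(sprintf("support_profile: %s (%d bp), window %d, span %d: %d/%d windows well-covered\n",
              x$contig, x$contig_length, x$window, x$min_spanning,
              sum(x$well_covered), length(x$well_covered)))
  invisible(x)
}

#' Export the spanning-count track of a profile as bedGraph
#'
#' Writes runs of equal spanning counts as bedGraph records over window
#' start positions, for inspection in a genome browser.
#'
#' @param profile A [compute_support_profile()] object.
#' @param path Output path; opened in append mode when `append = TRUE` so
#'   several contigs can share one file.
#' @param append Append to an existing file?
#' @return `path`, invisibly.
#' @export
write_spanning_bedgraph <- function(profile, path, append = FALSE) {
  stopifnot(inherits(profile, "support_profile"))
  lines <- character()
  if (length(profile$counts)) {
    r <- rle(profile$counts)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    lines <- sprintf("%s\t%d\t%d\t%d", profile$contig, starts, ends, r$values)
  }
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}
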