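# Converting a support profile into cut points; breakpoints BED I/O.

#' Find cut points from a support profile
#'
#' For every maximal run of poorly-covered windows that has a well-covered
#' window on BOTH sides, the contig is cut after the last base of the
#' preceding well-covered window and again before the first base of the
#' following well-covered window. With the run occupying window-start
#' indices `p ... q` (0-based), those positions are `(p - 1) + window` and
#' `q + 1`. Runs touching a contig end (including an all-poor profile)
#' produce no cuts: molecule coverage necessarily decays at sequence ends,
#' and cutting there would discard sequence without evidence of
#' misassembly.
#'
#' When the poor run is shorter than `window - 1` windows the two positions
#' invert (`q + 1 < (p - 1) + window`); both cuts are still emitted, in
#' sorted order. When the two positions coincide (run of exactly
#' `window - 1` poor windows, the signature of a sharp junction) they
#' collapse to a single cut. Duplicate positions across runs are removed.
#'
#' @param profile A [compute_support_profile()] object.
#' @param params The [scan_params()] used to compute the profile; a window
#'   mismatch is an error.
#' @return An object of class `cut_plan`: list with `contig`,
#'   `contig_length`, `window`, sorted integer vector `cuts` (0-based
#'   positions strictly inside the contig) and a data.table `regions` with
#'   one row per poor run (`start`, `end`; `start == end` marks a collapsed
#'   single-position cut).
#' @export
find_cut_points <- function(profile, params = scan_params()) {
  stopifnot(inherits(profile, "support_profile"),
            inherits(params, "scan_params"))
  if (profile$window != params$window) {
    stop("profile was computed with window = ", profile$window,
         " but params specify window = ", params$window)
  }
  v <- profile$well_covered
  w <- profile$window
  empty <- data.table::data.table(start = integer(), end = integer())
  plan <- function(cuts, regions) {
    structure(list(contig = profile$contig,
                   contig_length = profile$contig_length,
                   window = w, cuts = cuts, regions = regions),
              class = "cut_plan")
  }
  if (length(v) == 0L || !any(v) || all(v)) return(plan(integer(), empty))
  r <- rle(as.logical(v))
  run_end <- cumsum(r$lengths)               # 1-based inclusive
  run_start <- run_end - r$lengths + 1L
  interior <- !r$values & seq_along(r$values) > 1L &
    seq_along(r$values) < length(r$values)
  if (!any(interior)) return(plan(integer(), empty))
  p <- run_start[interior] - 1L              # 0-based window-start indices
  q <- run_end[interior] - 1L
  cut_after <- (p - 1L) + w                  # after last base of window p-1
  cut_before <- q + 1L                       # before first base of window q+1
  regions <- data.table::data.table(start = pmin(cut_after, cut_before),
                                    end = pmax(cut_after, cut_before))
  plan(sort(unique(c(cut_after, cut_before))), regions)
}

#' @export
print.cut_plan <- function(x, ...) {
  cat(sprintf("cut_plan: %s (%d bp): %d cut(s) from %d poorly-covered run(s)\n",
              x$contig, x$contig_length, length(x$cuts), nrow(x$regions)))
  invisible(x)
}

#' Write cut plans as a breakpoints BED
#'
#' One BED3 record per poorly-supported region that generated a cut pair
#' (0-based half-open); collapsed cut pairs appear as single-position
#' records with `start == end`. Records are grouped per contig in the order
#' the plans are given (input FASTA order in the pipeline).
#'
#' @param plans A list of [find_cut_points()] plans (a single plan is
#'   accepted).
#' @param path Output path.
#' @param comments Optional comment lines (prefixed `"# "`).
#' @return `path`, invisibly.
#' @export
write_breakpoints_bed <- function(plans, path, comments = NULL) {
  if (inherits(plans, "cut_plan")) plans <- list(plans)
  lines <- character()
  if (length(comments)) lines <- paste0("# ", comments)
  for (pl in plans) {
    stopifnot(inherits(pl, "cut_plan"))
    if (nrow(pl$regions)) {
      lines <- c(lines, sprintf("%s\t%d\t%d", pl$contig, pl$regions$start,
                                pl$regions$end))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a breakpoints BED
#'
#' @param path Path to a BED3(+) file as written by
#'   [write_breakpoints_bed()]; comment/track lines are skipped.
#' @return A `data.table` with columns `contig`, `start`, `end`.
#' @export
read_breakpoints_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(fields) == 0L) {
    return(data.table::data.table(contig = character(), start = integer(),
                                  end = integer()))
  }
  if (any(lengths(fields) < 3L)) {
    stop("malformed BED line ", lineno[which(lengths(fields) < 3L)[1L]],
         " in '", path, "'")
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:3)), ncol = 3L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  bad <- is.na(start) | is.na(end) | start < 0L | end < start
  if (any(bad)) {
    stop("malformed BED line ", lineno[which(bad)[1L]], " in '", path, "'")
  }
  data.table::data.table(contig = m[, 1L], start = start, end = end)
}

#' Extract cut positions from plans or a breakpoints BED
#'
#' Normalises the detected-cut representation used by [evaluate_cuts()]:
#' a list of cut plans, a breakpoints BED path, or a data.frame with
#' `contig` and either `pos` or `start`/`end` columns. For BED regions the
#' two boundaries are both cut positions; zero-length records contribute
#' one.
#'
#' @param x Cut plans, BED path, or data.frame.
#' @return A `data.table` with columns `contig`, `pos`, unique rows.
#' @export
cut_positions <- function(x) {
  if (inherits(x, "cut_plan")) x <- list(x)
  if (is.list(x) && length(x) && all(vapply(x, inherits, logical(1L), "cut_plan"))) {
    out <- data.table::rbindlist(lapply(x, function(pl) {
      data.table::data.table(contig = rep(pl$contig, length(pl$cuts)),
                             pos = pl$cuts)
    }))
  } else if (is.character(x) && length(x) == 1L) {
    bed <- read_breakpoints_bed(x)
    out <- data.table::data.table(contig = rep(bed$contig, 2L),
                                  pos = c(bed$start, bed$end))
  } else if (is.data.frame(x)) {
    if ("pos" %in% names(x)) {
      out <- data.table::data.table(contig = x$contig, pos = as.integer(x$pos))
    } else {
      out <- data.table::data.table(contig = rep(x$contig, 2L),
                                    pos = c(as.integer(x$start),
                                            as.integer(x$end)))
    }
  } else if (is.list(x) && length(x) == 0L) {
    out <- data.table::data.table(contig = character(), pos = integer())
  } else {
    stop("cannot interpret detected cuts of class ", class(x)[1L])
  }
  unique(out[order(contig, pos)])
}
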