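# Splitting draft sequences at planned cut points.

#' Split draft-assembly sequences at cut points
#'
#' Each contig with k cuts yields k + 1 segments that tile the parent
#' exactly: concatenating a parent's segments reproduces the parent
#' sequence byte-for-byte (lowercase/softmasked bases preserved verbatim;
#' sequences are handled as [Biostrings::BStringSet] for this reason).
#' Contigs with no cuts pass through with unchanged name and sequence;
#' output order follows input FASTA order. Segments are named
#' `"<parent>-<ordinal>"` with a `"<parent>:<start>-<end>"` description
#' (0-based half-open parent coordinates).
#'
#' All plans are validated (contig present, length matching, cuts strictly
#' inside the contig) before any output is produced.
#'
#' @param fasta Path to the draft FASTA (optionally gzipped) or an
#'   [Biostrings::XStringSet].
#' @param plans List of [find_cut_points()] plans (plans with no cuts may
#'   be omitted).
#' @param out_path Optional output FASTA path, written with fixed 60-column
#'   line wrapping for reproducible diffs.
#' @return The corrected sequences as a [Biostrings::BStringSet],
#'   invisibly when `out_path` is given.
#' @export
apply_cuts <- function(fasta, plans, out_path = NULL) {
  seqs <- if (inherits(fasta, "XStringSet")) {
    Biostrings::BStringSet(fasta)
  } else {
    Biostrings::readBStringSet(fasta)
  }
  full_names <- names(seqs)
  ids <- sub("\\s.*$", "", full_names)
  if (inherits(plans, "cut_plan")) plans <- list(plans)
  by_contig <- list()
  for (pl in plans) {
    stopifnot(inherits(pl, "cut_plan"))
    i <- match(pl$contig, ids)
    if (is.na(i)) stop("cut plan references unknown contig '", pl$contig, "'")
    len <- Biostrings::width(seqs)[i]
    if (pl$contig_length != len) {
      stop("cut plan for '", pl$contig, "' expects length ", pl$contig_length,
           " but FASTA sequence has length ", len)
    }
    if (length(pl$cuts) && (any(pl$cuts <= 0L) || any(pl$cuts >= len))) {
      stop("cut position outside (0, ", len, ") for contig '", pl$contig, "'")
    }
    by_contig[[pl$contig]] <- sort(unique(c(by_contig[[pl$contig]], pl$cuts)))
  }
  out_seq <- list()
  out_name <- character()
  for (i in seq_along(seqs)) {
    cuts <- by_contig[[ids[i]]]
    if (is.null(cuts) || length(cuts) == 0L) {
      out_seq[[length(out_seq) + 1L]] <- seqs[[i]]
      out_name <- c(out_name, full_names[i])
      next
    }
    len <- Biostrings::width(seqs)[i]
    starts <- c(0L, cuts)
    ends <- c(cuts, len)
    for (k in seq_along(starts)) {
      out_seq[[length(out_seq) + 1L]] <-
        Biostrings::subseq(seqs[[i]], starts[k] + 1L, ends[k])
      out_name <- c(out_name, sprintf("%s-%d %s:%d-%d", ids[i], k, ids[i],
                                      starts[k], ends[k]))
    }
  }
  out <- Biostrings::BStringSet(out_seq)
  names(out) <- out_name
  if (!is.null(out_path)) {
    Biostrings::writeXStringSet(out, out_path, width = 60L)
    return(invisible(out))
  }
  out
}
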