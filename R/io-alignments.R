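#' Read mapped-read alignments from BED6 or SAM
#'
#' Ingests the output of an upstream short-read mapper as a tibble of aligned
#' intervals. BED6 half-open coordinates are converted to 1-based inclusive;
#' SAM records are restricted to the subset an ungapped 35 nt mapper emits
#' (FLAG 0/4/16, CIGAR M and S operations). Unmapped SAM records are skipped
#' and counted in the `n_skipped` attribute of the result.
#'
#' @param path Path to the alignment file.
#' @param dialect `"bed"` or `"sam"`.
#' @param library Library number (1 = primary-transcript enriched,
#'   2 = whole small transcriptome).
#' @param known_seqnames Optional character vector of valid reference names;
#'   records referencing other names are an error.
#' @return Tibble with columns `seqname`, `strand`, `start`, `end`,
#'   `library`; the 5'-most aligned base is `start` on "+" and `end` on "-".
#' @export
read_alignments <- function(path, dialect = c("bed", "sam"), library = 1L,
                            known_seqnames = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    aln <- tibble(
      seqname = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      library = as.integer(library)
    )
    n_skipped <- 0L
  } else {
    bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(bam))
    rec <- Rsamtools::scanBam(
      bam,
      param = Rsamtools::ScanBamParam(
        what = c("flag", "rname", "strand", "pos", "cigar")
      )
    )[[1]]
    mapped <- !bitwAnd(rec$flag, 4L)
    n_skipped <- sum(!mapped)
    ref_width <- vapply(rec$cigar[mapped], cigar_ref_width, integer(1),
                        USE.NAMES = FALSE)
    aln <- tibble(
      seqname = as.character(rec$rname[mapped]),
      strand = as.character(rec$strand[mapped]),
      start = rec$pos[mapped],
      end = rec$pos[mapped] + ref_width - 1L,
      library = as.integer(library)
    )
  }
  check_strand(aln$strand)
  if (!is.null(known_seqnames) && !all(aln$seqname %in% known_seqnames)) {
    stop("alignment(s) reference unknown sequence name(s): ",
         paste(setdiff(unique(aln$seqname), known_seqnames), collapse = ", "),
         call. = FALSE)
  }
  attr(aln, "n_skipped") <- n_skipped
  aln
}

# Reference-space width of a CIGAR string restricted to M/S (and =/X) ops.
cigar_ref_width <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[A-Z=]", cigar))[[1]]
  if (length(ops) == 0) stop("malformed CIGAR: ", cigar, call. = FALSE)
  len <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  if (!all(op %in% c("M", "S", "=", "X"))) {
    stop("unsupported CIGAR operation in: ", cigar, call. = FALSE)
  }
  sum(len[op %in% c("M", "=", "X")])
}

#' Write alignments as BED6
#'
#' Converts 1-based inclusive intervals back to BED half-open coordinates.
#'
#' @param aln Alignment tibble as returned by [read_alignments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments_bed <- function(aln, path) {
  lines <- paste(aln$seqname, aln$start - 1L, aln$end,
                 paste0("r", seq_len(nrow(aln))), 0L, aln$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
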