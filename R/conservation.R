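# Post-processing of structure-conservation windows (RNAz-style screening
# output) and their intersection with trans-encoded sRNAs.

#' Read a structure-conservation window table
#'
#' @param path Tab-delimited file with header columns `start`, `end`,
#'   `strand`, `p` (RNA-class probability) and `mpi` (mean pairwise
#'   identity, percent).
#' @return Tibble of windows.
#' @export
read_conservation_windows <- function(path) {
  w <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("start", "end", "strand", "p", "mpi") %in% names(w)))
  stopifnot(all(w$p >= 0 & w$p <= 1), all(w$end >= w$start))
  check_strand(w$strand)
  w
}

#' Merge conservation windows into conserved loci
#'
#' Keeps windows with RNA-class probability at least `p_min` and mean
#' pairwise identity strictly above `mpi_min` percent, removes windows
#' overlapping an annotated rRNA/tRNA gene (these are trivially conserved),
#' and unions the remaining overlapping same-strand windows into loci,
#' recording the maximum probability of each merged locus.
#'
#' @param windows Window tibble (see [read_conservation_windows()]).
#' @param p_min Minimum RNA-class probability (inclusive).
#' @param mpi_min Minimum mean pairwise identity in percent (exclusive).
#' @param annotation Optional annotation tibble; rRNA/tRNA rows are used for
#'   exclusion (any-strand overlap).
#' @return Tibble of loci: `start`, `end`, `strand`, `p_max`, `n_windows`.
#' @export
merge_windows <- function(windows, p_min = 0.5, mpi_min = 60,
                          annotation = NULL) {
  w <- windows[windows$p >= p_min & windows$mpi > mpi_min, , drop = FALSE]
  if (!is.null(annotation)) {
    excl <- annotation[annotation$type %in% c("rRNA", "tRNA"), , drop = FALSE]
    if (nrow(excl) > 0 && nrow(w) > 0) {
      ov <- IRanges::overlapsAny(IRanges::IRanges(w$start, w$end),
                                 IRanges::IRanges(excl$start, excl$end))
      w <- w[!ov, , drop = FALSE]
    }
  }
  if (nrow(w) == 0) {
    return(tibble(start = integer(), end = integer(), strand = character(),
                  p_max = numeric(), n_windows = integer()))
  }
  out <- lapply(c("+", "-"), function(str) {
    ws <- w[w$strand == str, , drop = FALSE]
    if (nrow(ws) == 0) return(NULL)
    ir <- IRanges::IRanges(ws$start, ws$end)
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    p_max <- vapply(seq_along(red), function(k) {
      max(ws$p[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == k]])
    }, numeric(1))
    nwin <- tabulate(S4Vectors::subjectHits(ov), nbins = length(red))
    tibble(start = IRanges::start(red), end = IRanges::end(red),
           strand = str, p_max = p_max, n_windows = nwin)
  })
  arrange(bind_rows(out), .data$start)
}

#' Overlap conserved loci with trans-encoded sRNAs
#'
#' A trans-encoded region is matched when it shares at least one nt, on the
#' same strand by default, with a conserved locus whose maximum RNA-class
#' probability reaches `p_threshold`.
#'
#' @param loci [merge_windows()] output.
#' @param trans_regions Region tibble restricted to the trans-encoded class.
#' @param p_threshold Minimum locus `p_max`.
#' @param ignore_strand Overlap regardless of strand.
#' @return List: `matched` (subset of `trans_regions` with a `p_max` column),
#'   `n_matched`, `n_total`, `fraction` (NA when there are no trans regions).
#' @export
overlap_with_trans <- function(loci, trans_regions, p_threshold = 0.5,
                               ignore_strand = FALSE) {
  n_total <- nrow(trans_regions)
  loci <- loci[loci$p_max >= p_threshold, , drop = FALSE]
  if (n_total == 0 || nrow(loci) == 0) {
    matched <- trans_regions[0, , drop = FALSE]
    matched$p_max <- numeric(0)
    return(list(matched = matched, n_matched = 0L, n_total = n_total,
                fraction = if (n_total == 0) NA_real_ else 0))
  }
  lo <- pmin(trans_regions$tss, trans_regions$three_prime)
  hi <- pmax(trans_regions$tss, trans_regions$three_prime)
  ov <- IRanges::findOverlaps(IRanges::IRanges(lo, hi),
                              IRanges::IRanges(loci$start, loci$end))
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  if (!ignore_strand) {
    same <- trans_regions$strand[q] == loci$strand[s]
    q <- q[same]; s <- s[same]
  }
  if (length(q) == 0) {
    matched <- trans_regions[0, , drop = FALSE]
    matched$p_max <- numeric(0)
    return(list(matched = matched, n_matched = 0L, n_total = n_total,
                fraction = 0))
  }
  best <- tapply(loci$p_max[s], q, max)
  idx <- as.integer(names(best))
  matched <- trans_regions[idx, , drop = FALSE]
  matched$p_max <- as.numeric(best)
  list(matched = matched, n_matched = length(idx), n_total = n_total,
       fraction = length(idx) / n_total)
}
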