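#' Build strand-specific read-start and coverage profiles
#'
#' For one sequencing library, counts for every genomic position and strand
#' how many alignments have their 5'-most base there (`read starts`) and how
#' many alignments cover the position (`coverage`). Read starts drive TSS
#' calling on the primary-transcript library; coverage depth drives 3'-end
#' calling on the whole-transcriptome library.
#'
#' @param aln Alignment tibble (see [read_alignments()]).
#' @param genome_length Length of the chromosome in nt.
#' @param library Which library to profile (matched against `aln$library`).
#' @return An object of class `srna_profiles`: integer read-start and coverage
#'   vectors per strand plus the genome length and library number.
#' @export
build_profiles <- function(aln, genome_length, library = 1L) {
  aln <- aln[aln$library == library, , drop = FALSE]
  if (nrow(aln) > 0 &&
      (min(aln$start) < 1L || max(aln$end) > genome_length)) {
    stop("alignment(s) outside genome bounds [1, ", genome_length, "]",
         call. = FALSE)
  }
  starts <- list()
  coverage <- list()
  for (str in c("+", "-")) {
    sub <- aln[aln$strand == str, , drop = FALSE]
    fp <- if (nrow(sub) > 0) five_prime_of(sub$start, sub$end, sub$strand)
          else integer(0)
    starts[[str]] <- tabulate(fp, nbins = genome_length)
    cov <- IRanges::coverage(IRanges::IRanges(sub$start, sub$end),
                             width = genome_length)
    coverage[[str]] <- as.integer(cov)
  }
  structure(
    list(genome_length = as.integer(genome_length),
         library = as.integer(library),
         starts = starts, coverage = coverage),
    class = "srna_profiles"
  )
}

#' @export
print.srna_profiles <- function(x, ...) {
  cat("<srna_profiles> library", x$library, "over", x$genome_length, "nt;",
      sum(x$starts[["+"]]) + sum(x$starts[["-"]]), "read starts\n")
  invisible(x)
}

#' @describeIn build_profiles Tidy a profile into a long per-position tibble,
#'   optionally restricted to a window.
#' @param x An `srna_profiles` object.
#' @param from,to Window bounds (default: whole genome).
#' @param ... Unused.
#' @method tidy srna_profiles
#' @export
tidy.srna_profiles <- function(x, from = 1L, to = x$genome_length, ...) {
  pos <- seq.int(from, to)
  bind_rows(lapply(c("+", "-"), function(str) {
    tibble(position = pos, strand = str,
           read_starts = x$starts[[str]][pos],
           coverage = x$coverage[[str]][pos])
  }))
}

#' Assign reads to annotation categories
#'
#' Reproduces the library accounting of a dRNA-Seq experiment: every read is
#' assigned to exactly one category by the position of its 5' base, with
#' precedence rRNA > tRNA > mRNA (CDS, sense) > cis-antisense (CDS,
#' antisense) > unannotated. rRNA/tRNA overlap is counted irrespective of
#' strand; CDS sense/antisense is strand-aware.
#'
#' @param aln Alignment tibble for one library.
#' @param annotation Annotation tibble (see [read_annotation_gff3()]).
#' @return Tibble with columns `category`, `reads`, `pct` (percent of total,
#'   one decimal, half-up); total reads in the `total` attribute.
#' @export
summarize_categories <- function(aln, annotation) {
  fp <- five_prime_of(aln$start, aln$end, aln$strand)
  category <- rep("unannotated", nrow(aln))
  in_type <- function(type, strand_aware = FALSE, same_strand = TRUE) {
    feats <- annotation[annotation$type == type, , drop = FALSE]
    if (nrow(feats) == 0) return(rep(FALSE, nrow(aln)))
    hit <- rep(FALSE, nrow(aln))
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(fp, fp),
      IRanges::IRanges(feats$start, feats$end)
    )
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    if (strand_aware) {
      same <- aln$strand[q] == feats$strand[s]
      q <- if (same_strand) q[same] else q[!same]
    }
    hit[unique(q)] <- TRUE
    hit
  }
  category[in_type("CDS", strand_aware = TRUE, same_strand = FALSE)] <-
    "cis_antisense"
  category[in_type("CDS", strand_aware = TRUE, same_strand = TRUE)] <-
    "mRNA_sense"
  category[in_type("tRNA")] <- "tRNA"
  category[in_type("rRNA")] <- "rRNA"
  counts <- vapply(
    c("rRNA", "tRNA", "mRNA_sense", "cis_antisense", "unannotated"),
    function(k) sum(category == k), integer(1)
  )
  category_table(counts)
}

#' Category percentages from raw read counts
#'
#' The display layer of [summarize_categories()]: turns per-category read
#' counts into a percentage table (one decimal, half-up rounding). Exposed
#' separately so published count tables can be fed through the identical
#' arithmetic.
#'
#' @param counts Named integer vector of per-category read counts.
#' @return Tibble `category`, `reads`, `pct`; attribute `total`.
#' @export
category_table <- function(counts) {
  total <- sum(counts)
  out <- tibble(
    category = names(counts),
    reads = as.integer(counts),
    pct = if (total > 0) unname(round_half_up(100 * counts / total, 1))
          else NA_real_
  )
  attr(out, "total") <- total
  out
}

#' Sum sub-counts into category totals
#'
#' The reporting layer used by the pipeline log: given per-context sub-counts
#' (for example promoter-validated TSS split into cis-antisense versus
#' unannotated contexts), returns the per-category totals. The partition
#' identity (totals equal the sum of their parts) holds by construction.
#'
#' @param tbl Tibble with columns `category`, `subcategory`, `n`.
#' @return Tibble `category`, `total`, ordered as first encountered.
#' @export
partition_summary <- function(tbl) {
  stopifnot(all(c("category", "n") %in% names(tbl)))
  tbl |>
    mutate(category = factor(.data$category, levels = unique(.data$category))) |>
    group_by(category = .data$category) |>
    summarise(total = sum(.data$n), .groups = "drop") |>
    mutate(category = as.character(.data$category))
}
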