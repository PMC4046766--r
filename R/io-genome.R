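#' Read a genome FASTA file
#'
#' Reads one or more DNA sequences, uppercases them and converts U to T, so
#' downstream code can assume an A/C/G/T alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one entry per record.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">chr", "acgtacgt"), f)
#' read_genome_fasta(f)
#' @export
read_genome_fasta <- function(path) {
  stopifnot(file.exists(path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) {
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  }
  nms <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nms)) {
    stop("duplicated FASTA record name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(raw))
  seqs <- chartr("U", "T", seqs)
  iupac <- "ACGTRYSWKMBDHVN"
  for (i in seq_along(seqs)) {
    bad <- regmatches(seqs[i], regexpr(paste0("[^", iupac, "]"), seqs[i]))
    if (length(bad) > 0) {
      stop("record '", nms[i], "' contains non-IUPAC character '", bad,
           "'", call. = FALSE)
    }
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nms
  out
}

#' Read gene annotation from GFF3
#'
#' Imports CDS (and optionally rRNA/tRNA) rows of a GFF3 file as a tibble.
#' Rows with start greater than end are rejected with a warning; a missing
#' locus_tag/ID attribute or a duplicated CDS locus tag is an error.
#'
#' @param path Path to a GFF3 file.
#' @param types Feature types to keep (default CDS, rRNA, tRNA).
#' @return A tibble with columns `seqname`, `type`, `locus_tag`, `strand`,
#'   `start`, `end` (1-based inclusive) and `product`, sorted by start.
#' @export
read_annotation_gff3 <- function(path, types = c("CDS", "rRNA", "tRNA")) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  ok_len <- vapply(fields, length, integer(1)) == 9L
  if (any(!ok_len)) {
    warning(sum(!ok_len), " malformed GFF3 row(s) skipped")
    body <- body[ok_len]
    fields <- fields[ok_len]
  }
  starts <- as.integer(vapply(fields, `[[`, "", 4L))
  ends <- as.integer(vapply(fields, `[[`, "", 5L))
  bad <- !is.na(starts) & !is.na(ends) & starts > ends
  if (any(bad)) {
    warning(sum(bad), " GFF3 row(s) with start > end rejected")
    body <- body[!bad]
  }
  tmp <- tempfile(fileext = ".gff3")
  on.exit(unlink(tmp))
  writeLines(c("##gff-version 3", body), tmp)
  gr <- rtracklayer::import(tmp, format = "gff3")
  gr <- gr[as.character(gr$type) %in% types]
  if (length(gr) == 0) {
    return(tibble(seqname = character(), type = character(),
                  locus_tag = character(), strand = character(),
                  start = integer(), end = integer(), product = character()))
  }
  meta <- S4Vectors::mcols(gr)
  tag <- if ("locus_tag" %in% names(meta)) meta$locus_tag else NULL
  id <- if ("ID" %in% names(meta)) meta$ID else NULL
  locus_tag <- tag %||% id
  if (is.null(locus_tag)) {
    stop("GFF3 features carry neither a locus_tag nor an ID attribute",
         call. = FALSE)
  }
  if (!is.null(tag) && !is.null(id)) locus_tag <- ifelse(is.na(tag), id, tag)
  if (any(is.na(locus_tag))) {
    stop("GFF3 feature(s) without locus_tag or ID attribute", call. = FALSE)
  }
  ann <- tibble(
    seqname = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    locus_tag = as.character(locus_tag),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    product = if ("product" %in% names(meta)) as.character(meta$product)
              else NA_character_
  )
  cds_tags <- ann$locus_tag[ann$type == "CDS"]
  if (anyDuplicated(cds_tags)) {
    stop("duplicated CDS locus_tag(s): ",
         paste(unique(cds_tags[duplicated(cds_tags)]), collapse = ", "),
         call. = FALSE)
  }
  check_strand(ann$strand)
  arrange(ann, .data$start)
}

#' Write features to GFF3
#'
#' Deterministic GFF3 writer (no date or version stamps) so that repeated
#' pipeline runs produce byte-identical output files.
#'
#' @param tbl Tibble with columns `seqname`, `type`, `start`, `end`, `strand`,
#'   and optionally `score` and `attributes`.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(tbl, path, source = "srnascan") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(tbl) > 0) {
    score <- if ("score" %in% names(tbl)) {
      ifelse(is.na(tbl$score), ".", format(tbl$score, trim = TRUE))
    } else rep(".", nrow(tbl))
    attrs <- if ("attributes" %in% names(tbl)) tbl$attributes
             else rep(".", nrow(tbl))
    writeLines(paste(tbl$seqname, source, tbl$type, tbl$start, tbl$end,
                     score, tbl$strand, ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}
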