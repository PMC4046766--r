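# Small-ORF detection within sRNA regions: 3-frame scan on the transcript
# sense strand, ribosome-binding-site matching, leaderless calls and
# homopolymeric residue runs (attenuator leader-peptide signatures).

START_CODONS <- c("ATG", "GTG", "TTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate an open reading frame
#'
#' Standard bacterial genetic code; when `init = TRUE` the first codon is
#' translated as methionine regardless of which start codon it is. The stop
#' codon, if present, is dropped.
#'
#' @param dna Character DNA sequence, a whole number of codons.
#' @param init Treat the first codon as an initiator.
#' @return Amino-acid string.
#' @export
translate_orf <- function(dna, init = TRUE) {
  n <- nchar(dna)
  stopifnot(n %% 3 == 0)
  codons <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  if (length(codons) > 0 && codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
  }
  aa <- vapply(codons, function(cd) {
    Biostrings::GENETIC_CODE[[cd]]
  }, character(1), USE.NAMES = FALSE)
  if (init && length(aa) > 0) aa[1] <- "M"
  paste(aa, collapse = "")
}

#' Find small open reading frames in a transcript sequence
#'
#' Scans all three frames of the sense strand for ORFs that begin with
#' ATG/GTG/TTG, end at the first in-frame stop (TAA/TAG/TGA), and whose
#' nucleotide length including the stop codon lies within
#' `[min_nt, max_nt]` — the default 48 nt minimum corresponds to a 15-residue
#' peptide plus stop.
#'
#' @param sequence Character DNA of the region, 5' to 3' on the transcript
#'   strand.
#' @param min_nt,max_nt ORF length bounds in nt, stop codon included.
#' @return Tibble `start`, `end` (1-based within the sequence, end = last
#'   base of the stop codon), `nt_len`, `peptide`.
#' @export
find_small_orfs <- function(sequence, min_nt = 48L, max_nt = 249L) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  codon_at <- function(p) substr(sequence, p, p + 2L)
  out <- list()
  starts <- which(vapply(seq_len(max(0L, n - 2L)), function(p)
    codon_at(p) %in% START_CODONS, logical(1)))
  for (p in starts) {
    q <- p
    repeat {
      q <- q + 3L
      if (q + 2L > n) {
        q <- NA_integer_
        break
      }
      if (codon_at(q) %in% STOP_CODONS) break
    }
    if (is.na(q)) next
    len <- q + 2L - p + 1L
    if (len < min_nt || len > max_nt) next
    orf <- substr(sequence, p, q + 2L)
    out[[length(out) + 1L]] <- tibble(
      start = p, end = q + 2L, nt_len = len,
      peptide = translate_orf(orf)
    )
  }
  if (length(out) == 0) {
    return(tibble(start = integer(), end = integer(), nt_len = integer(),
                  peptide = character()))
  }
  bind_rows(out)
}

# Best match of the RBS motif inside a window; a match needs at least
# `min_ident` identities over the motif length.
best_rbs_match <- function(window, motif = "AGGAG", min_ident = 4L) {
  nw <- nchar(window)
  nm <- nchar(motif)
  if (nw < nm) return(NULL)
  mv <- strsplit(motif, "")[[1]]
  best <- NULL
  for (p in seq_len(nw - nm + 1L)) {
    ident <- sum(strsplit(substr(window, p, p + nm - 1L), "")[[1]] == mv)
    if (ident >= min_ident && (is.null(best) || ident > best$ident)) {
      best <- list(pos = p, ident = ident,
                   match = substr(window, p, p + nm - 1L))
    }
  }
  best
}

# Homopolymeric amino-acid runs of at least `min_run` residues.
residue_runs <- function(peptide, min_run = 3L) {
  r <- rle(strsplit(peptide, "")[[1]])
  keep <- r$lengths >= min_run
  tibble(residue = r$values[keep], run = r$lengths[keep])
}

#' Call small mRNAs among sRNA regions
#'
#' Extracts each region's strand-aware sequence, finds small ORFs
#' ([find_small_orfs()]) and keeps those with translation-initiation
#' evidence: either a ribosome-binding-site match (at least 4 of the 5
#' `AGGAG` positions identical) within the `rbs_window` nt upstream of the
#' start codon, or a leaderless arrangement in which the start codon
#' coincides with the region TSS (within `leaderless_slack` nt). Homopolymer
#' residue runs of 3 or more are reported to support attenuator
#' leader-peptide reading (e.g. three consecutive tryptophans, four
#' consecutive leucines).
#'
#' @param regions Region tibble (`id`, `strand`, `tss`, `three_prime`).
#' @param genome DNAString(Set).
#' @param rbs_motif RBS consensus (Shine-Dalgarno core).
#' @param rbs_window Upstream search window in nt.
#' @param leaderless_slack Allowed offset between TSS and start codon for a
#'   leaderless call (default 0 = exact).
#' @param min_nt,max_nt ORF length bounds (see [find_small_orfs()]).
#' @return Tibble `region_id`, `orf_start`, `orf_end` (genomic), `nt_len`,
#'   `peptide`, `rbs` (matched motif or `NA`), `rbs_pos` (offset of the match
#'   5' of the start codon), `leaderless`, `runs` (list column of
#'   residue-run tibbles).
#' @export
call_small_mrnas <- function(regions, genome, rbs_motif = "AGGAG",
                             rbs_window = 15L, leaderless_slack = 0L,
                             min_nt = 48L, max_nt = 249L) {
  genome <- as_dnastring(genome)
  L <- length(genome)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    str <- regions$strand[i]
    tss <- regions$tss[i]
    tp <- regions$three_prime[i]
    lo <- min(tss, tp); hi <- max(tss, tp)
    seq_region <- extract_oriented(genome, lo, hi, str)
    orfs <- find_small_orfs(seq_region, min_nt, max_nt)
    for (j in seq_len(nrow(orfs))) {
      p <- orfs$start[j]
      leaderless <- abs(p - 1L) <= leaderless_slack
      # upstream window may extend past the region 5' end into the genome
      if (str == "+") {
        wfrom <- tss + p - 1L - rbs_window
        wto <- tss + p - 2L
        ok <- wfrom >= 1L
      } else {
        wfrom <- tss - p + 2L
        wto <- tss - p + 1L + rbs_window
        ok <- wto <= L
      }
      rbs_hit <- if (ok && wto >= wfrom) {
        best_rbs_match(extract_oriented(genome, wfrom, wto, str), rbs_motif)
      } else NULL
      if (is.null(rbs_hit) && !leaderless) next
      g_start <- if (str == "+") tss + p - 1L else tss - p + 1L
      g_end <- if (str == "+") tss + orfs$end[j] - 1L else tss - orfs$end[j] + 1L
      out[[length(out) + 1L]] <- tibble(
        region_id = regions$id[i],
        orf_start = g_start, orf_end = g_end, nt_len = orfs$nt_len[j],
        peptide = orfs$peptide[j],
        rbs = if (is.null(rbs_hit)) NA_character_ else rbs_hit$match,
        rbs_pos = if (is.null(rbs_hit)) NA_integer_ else
          as.integer(rbs_window - rbs_hit$pos + 1L),
        leaderless = leaderless,
        runs = list(residue_runs(orfs$peptide[j]))
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(region_id = character(), orf_start = integer(),
                  orf_end = integer(), nt_len = integer(),
                  peptide = character(), rbs = character(),
                  rbs_pos = integer(), leaderless = logical(),
                  runs = list()))
  }
  bind_rows(out)
}
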