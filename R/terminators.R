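# Rho-independent terminator detection: exhaustive stem-loop enumeration
# followed by a U-rich-tail score, combined into a logistic confidence.

# Pair weights on the DNA level (RNA hairpin equivalents): G:C = 3, A:T = 2,
# G:T wobble = 1, anything else is a mismatch.
PAIR_WEIGHTS <- local({
  W <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  W["G", "C"] <- W["C", "G"] <- 3
  W["A", "T"] <- W["T", "A"] <- 2
  W["G", "T"] <- W["T", "G"] <- 1
  W
})

# Logistic confidence constants. Calibrated once so that a canonical strong
# terminator (8 bp all-GC stem + 8 nt poly-U tail) scores > 0.9 while random
# background sequence stays < 0.5 in almost all windows.
TERM_CONF_A <- 0.3   # stem_score coefficient
TERM_CONF_B <- 0.8   # tail_score coefficient
TERM_CONF_C <- -9    # intercept

# Positional weights of the 15 nt tail: a U close to the hairpin counts more.
tail_weights <- function(tail_len = 15L) (tail_len:1) / tail_len

#' Find Rho-independent terminator hairpins in a sequence window
#'
#' Exhaustively enumerates stem-loop structures (stem 4-15 bp with at most
#' one mismatched pair, loop 3-10 nt) and scores the 15 nt downstream tail
#' for thymine content with positional weights. The confidence is
#' `plogis(0.3 * stem_score + 0.8 * tail_score - 9)`, where the stem score
#' sums pair weights (G:C = 3, A:T = 2, G:T = 1) and hits below the
#' confidence threshold are suppressed.
#'
#' @param sequence Character DNA sequence of the search window (sense strand
#'   of the transcript).
#' @param min_stem,max_stem Stem length bounds in bp.
#' @param min_loop,max_loop Loop length bounds in nt.
#' @param max_mismatch Maximum number of non-pairing stem positions.
#' @param tail_len Tail length in nt.
#' @param conf_threshold Minimum reported confidence (strictly greater).
#' @return Tibble with window-relative `hairpin_start`, `hairpin_end`,
#'   `stem_len`, `loop_len`, `mismatches`, `stem_score`, `tail_score`,
#'   `confidence`, sorted by decreasing confidence.
#' @export
find_terminators <- function(sequence, min_stem = 4L, max_stem = 15L,
                             min_loop = 3L, max_loop = 10L,
                             max_mismatch = 1L, tail_len = 15L,
                             conf_threshold = 0.75) {
  n <- nchar(sequence)
  if (n < 30) {
    warning("terminator search window shorter than 30 nt; no search")
    return(empty_terminator_hits())
  }
  s <- encode_dna(sequence)
  isT <- as.numeric(s == 4L)
  tw <- tail_weights(tail_len)
  hits <- list()
  for (k in min_stem:max_stem) {
    for (l in min_loop:max_loop) {
      span <- 2L * k + l
      if (span > n) next
      p <- seq_len(n - span + 1L)
      sc <- numeric(length(p))
      mism <- integer(length(p))
      for (i in seq_len(k)) {
        w <- PAIR_WEIGHTS[cbind(s[p + i - 1L], s[p + 2L * k + l - i])]
        sc <- sc + w
        mism <- mism + (w == 0)
      }
      hp_end <- p + span - 1L
      ts <- numeric(length(p))
      for (j in seq_len(tail_len)) {
        pos <- hp_end + j
        ok <- pos <= n
        ts[ok] <- ts[ok] + tw[j] * isT[pos[ok]]
      }
      conf <- plogis(TERM_CONF_A * sc + TERM_CONF_B * ts + TERM_CONF_C)
      keep <- mism <= max_mismatch & conf > conf_threshold
      if (any(keep)) {
        hits[[length(hits) + 1L]] <- tibble(
          hairpin_start = p[keep], hairpin_end = hp_end[keep],
          stem_len = k, loop_len = l, mismatches = mism[keep],
          stem_score = sc[keep], tail_score = ts[keep],
          confidence = conf[keep]
        )
      }
    }
  }
  if (length(hits) == 0) return(empty_terminator_hits())
  arrange(bind_rows(hits), dplyr::desc(.data$confidence))
}

empty_terminator_hits <- function() {
  tibble(hairpin_start = integer(), hairpin_end = integer(),
         stem_len = integer(), loop_len = integer(), mismatches = integer(),
         stem_score = numeric(), tail_score = numeric(),
         confidence = numeric())
}

#' Scan around region 3' ends for terminator hairpins
#'
#' Extracts the strand-aware sequence around each region's 3' end (hairpins
#' may begin upstream of the 3' end and must end within `window` nt of it),
#' runs [find_terminators()] and maps hits back to genomic coordinates.
#'
#' @param genome DNAString(Set).
#' @param regions Region tibble with `id`, `strand`, `three_prime`.
#' @param window Association window in nt around the 3' end.
#' @param upstream_reach How far upstream of the 3' end a hairpin may start.
#' @param ... Passed to [find_terminators()].
#' @return Tibble of hits with genomic `hairpin_end` (position of the last
#'   paired base in transcript orientation) and a `region_id` column.
#' @export
scan_terminators <- function(genome, regions, window = 60L,
                             upstream_reach = 45L, ...) {
  genome <- as_dnastring(genome)
  L <- length(genome)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    tp <- regions$three_prime[i]
    str <- regions$strand[i]
    if (str == "+") {
      from <- max(1L, tp - upstream_reach)
      to <- min(L, tp + window + 15L)
    } else {
      from <- max(1L, tp - window - 15L)
      to <- min(L, tp + upstream_reach)
    }
    if (to - from + 1L < 30L) next
    wseq <- extract_oriented(genome, from, to, str)
    hits <- suppressWarnings(find_terminators(wseq, ...))
    if (nrow(hits) == 0) next
    g_end <- if (str == "+") from + hits$hairpin_end - 1L
             else to - hits$hairpin_end + 1L
    g_start <- if (str == "+") from + hits$hairpin_start - 1L
               else to - hits$hairpin_start + 1L
    hits$hairpin_start <- g_start
    hits$hairpin_end <- g_end
    hits$region_id <- regions$id[i]
    out[[length(out) + 1L]] <- hits
  }
  if (length(out) == 0) {
    h <- empty_terminator_hits()
    h$region_id <- character()
    return(h)
  }
  bind_rows(out)
}

#' Attach the best terminator hit to each region
#'
#' The highest-confidence hit whose hairpin end lies within `window` nt of
#' the region 3' end (either side) is attached; regions without such a hit
#' keep `terminator = FALSE` — most bacterial sRNAs are not followed by a
#' Rho-independent terminator, so absence is a normal outcome.
#'
#' @param regions Region tibble (`id`, `strand`, `three_prime`, ...).
#' @param hits [scan_terminators()] output (genomic coordinates).
#' @param window Maximum distance from the 3' end in nt.
#' @return `regions` with columns `terminator` (logical),
#'   `terminator_confidence`, `terminator_end`.
#' @export
associate_terminator <- function(regions, hits, window = 60L) {
  regions$terminator <- FALSE
  regions$terminator_confidence <- NA_real_
  regions$terminator_end <- NA_integer_
  if (nrow(hits) == 0 || nrow(regions) == 0) return(regions)
  for (i in seq_len(nrow(regions))) {
    h <- hits[hits$region_id == regions$id[i] &
              abs(hits$hairpin_end - regions$three_prime[i]) <= window, ,
              drop = FALSE]
    if (nrow(h) == 0) next
    k <- which.max(h$confidence)
    regions$terminator[i] <- TRUE
    regions$terminator_confidence[i] <- h$confidence[k]
    regions$terminator_end[i] <- h$hairpin_end[k]
  }
  regions
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: permutes a sequence while preserving its exact
#' dinucleotide composition, the standard negative control for
#' structure-dependent signals such as terminator hairpins.
#'
#' @param sequence Character DNA sequence.
#' @param seed Optional integer seed.
#' @return Shuffled sequence (same length, same dinucleotide counts).
#' @export
dinucleotide_shuffle <- function(sequence, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  if (n < 3) return(sequence)
  verts <- unique(s)
  last <- s[n]
  edges <- split(s[-1], factor(s[-n], levels = verts))
  for (attempt in seq_len(1000)) {
    last_edge <- list()
    for (v in verts) {
      if (v == last || length(edges[[v]]) == 0) next
      last_edge[[v]] <- sample(edges[[v]], 1)
    }
    # chosen last edges must lead every vertex to the terminal vertex
    reaches <- function(v) {
      seen <- character(0)
      while (v != last) {
        if (v %in% seen || is.null(last_edge[[v]])) return(FALSE)
        seen <- c(seen, v)
        v <- last_edge[[v]]
      }
      TRUE
    }
    if (all(vapply(verts[verts != last], reaches, logical(1)))) break
    if (attempt == 1000) stop("dinucleotide shuffle failed to converge")
  }
  pools <- list()
  for (v in verts) {
    e <- edges[[v]]
    if (!is.null(last_edge[[v]])) {
      e <- e[-match(last_edge[[v]], e)]
      pools[[v]] <- c(if (length(e) > 1) sample(e) else e, last_edge[[v]])
    } else {
      pools[[v]] <- if (length(e) > 1) sample(e) else e
    }
  }
  used <- setNames(rep(0L, length(verts)), verts)
  out <- character(n)
  out[1] <- s[1]
  for (i in 2:n) {
    v <- out[i - 1]
    used[v] <- used[v] + 1L
    out[i] <- pools[[v]][used[v]]
  }
  paste(out, collapse = "")
}
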