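#' Detect transcription start sites from read-start profiles
#'
#' A position i is a TSS candidate when the number of read starts x_i on a
#' strand exceeds the background threshold `T` and either the
#' transcription-upstream neighbour has zero starts or the ratio
#' x_i / x_prev exceeds `R`. Both inequalities are strict. The upstream
#' neighbour is position i-1 on "+" and i+1 on "-". A stack rising from a
#' zero-count neighbour is the strongest possible 5' edge and always passes
#' the ratio condition.
#'
#' @param profiles `srna_profiles` of the primary-transcript library
#'   (see [build_profiles()]).
#' @param T Background threshold on read starts (default 19, i.e. at least
#'   20 read starts).
#' @param R Ratio threshold (default 5).
#' @param edge_margin No-call margin at the chromosome ends in nt; the
#'   chromosome is treated as linear, so candidates within the margin are
#'   suppressed rather than wrapped around the origin.
#' @return Tibble `position`, `strand`, `x_i`, `x_prev`, `ratio`
#'   (Inf when `x_prev` is 0), sorted by position within strand.
#' @export
detect_tss <- function(profiles, T = 19, R = 5, edge_margin = 0L) {
  stopifnot(inherits(profiles, "srna_profiles"))
  L <- profiles$genome_length
  out <- lapply(c("+", "-"), function(str) {
    x <- profiles$starts[[str]]
    xp <- if (str == "+") c(0L, x[-L]) else c(x[-1], 0L)
    keep <- x > T & (xp == 0L | x / xp > R)
    pos <- which(keep)
    if (edge_margin > 0) {
      pos <- pos[pos > edge_margin & pos <= L - edge_margin]
    }
    tibble(position = pos, strand = str, x_i = x[pos], x_prev = xp[pos],
           ratio = ifelse(xp[pos] == 0L, Inf, x[pos] / xp[pos]))
  })
  bind_rows(out)
}

#' Collapse clusters of nearby TSS
#'
#' Promoter-bearing TSS candidates closer than `window` nt on the same strand
#' usually represent a single start observed at slightly different positions.
#' Within every chain of candidates whose successive distances are at most
#' `window`, only the candidate with the largest read-start count survives;
#' ties go to the upstream-most position (favouring the longer transcript).
#'
#' @param candidates Tibble with at least `position`, `strand`, `x_i`
#'   (typically [detect_tss()] output annotated with promoter hits).
#' @param window Maximum distance in nt for two candidates to be merged
#'   (default 3).
#' @return Tibble of the surviving candidates, same columns as the input.
#' @export
collapse_nearby_tss <- function(candidates, window = 3L) {
  if (nrow(candidates) == 0) return(candidates)
  picked <- candidates |>
    group_by(.data$strand) |>
    arrange(.data$position, .by_group = TRUE) |>
    mutate(cluster = cumsum(c(1L, diff(.data$position) > window))) |>
    group_by(.data$strand, .data$cluster) |>
    filter({
      best <- .data$x_i == max(.data$x_i)
      at <- if (dplyr::first(.data$strand) == "+") {
        min(.data$position[best])
      } else {
        max(.data$position[best])
      }
      .data$position == at
    }) |>
    ungroup() |>
    select(-"cluster")
  arrange(picked, .data$strand, .data$position)
}
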