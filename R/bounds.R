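# Transcript 3'-end calling and multi-TSS region merging.

#' Call the 3' end of a transcript from whole-transcriptome coverage
#'
#' Walks downstream (strand-aware) from the TSS along the library-2 coverage
#' profile; the 3' end is the last position with coverage at or above
#' `cutoff` before the first position that falls below it. If that walk
#' yields a transcript shorter than `min_len` (one read length), the end is
#' placed at `min_len` nt and the call is flagged as low-support: shorter
#' calls are unresolvable with 35 nt reads. With `use_starts = TRUE` the walk
#' follows per-position read starts instead of coverage depth.
#'
#' @param tss TSS position.
#' @param strand `"+"` or `"-"`.
#' @param profiles `srna_profiles` of library 2.
#' @param cutoff Minimum coverage (default 10).
#' @param min_len Minimum transcript length in nt (default 35).
#' @param use_starts Walk on read starts instead of coverage depth.
#' @return List with `three_prime` (genomic nt), `length`, `low_support`,
#'   `truncated` (ran into the chromosome end).
#' @export
call_three_prime_end <- function(tss, strand, profiles, cutoff = 10L,
                                 min_len = 35L, use_starts = FALSE) {
  stopifnot(inherits(profiles, "srna_profiles"))
  L <- profiles$genome_length
  prof <- if (use_starts) profiles$starts[[strand]]
          else profiles$coverage[[strand]]
  truncated <- FALSE
  if (strand == "+") {
    seg <- prof[tss:L]
    below <- which(seg < cutoff)
    if (length(below) == 0) {
      end <- L
      truncated <- TRUE
      warning("3'-end walk from TSS ", tss, "+ reached the chromosome end")
    } else {
      end <- tss + below[1] - 2L
    }
    len <- end - tss + 1L
    low <- len < min_len
    if (low) {
      end <- min(L, tss + min_len - 1L)
      len <- end - tss + 1L
    }
  } else {
    seg <- prof[tss:1]
    below <- which(seg < cutoff)
    if (length(below) == 0) {
      end <- 1L
      truncated <- TRUE
      warning("3'-end walk from TSS ", tss, "- reached the chromosome start")
    } else {
      end <- tss - below[1] + 2L
    }
    len <- tss - end + 1L
    low <- len < min_len
    if (low) {
      end <- max(1L, tss - min_len + 1L)
      len <- tss - end + 1L
    }
  }
  list(three_prime = as.integer(end), length = as.integer(len),
       low_support = low, truncated = truncated)
}

#' Build bounded regions from promoter-validated TSS
#'
#' Calls a 3' end for every TSS and assembles the region table used by all
#' downstream stages.
#'
#' @param tss_tbl Promoter-annotated TSS tibble (`position`, `strand`, `x_i`,
#'   promoter columns); one row per TSS x sigma hit is collapsed to one
#'   region per TSS, keeping all sigma labels.
#' @param profiles Library-2 `srna_profiles`.
#' @inheritParams call_three_prime_end
#' @return Region tibble: `id`, `strand`, `tss`, `tss_all` (list column),
#'   `three_prime`, `length`, `low_support`, `sigma` (comma-joined),
#'   `via_extended10`, `x_i`.
#' @export
build_regions <- function(tss_tbl, profiles, cutoff = 10L, min_len = 35L,
                          use_starts = FALSE) {
  if (nrow(tss_tbl) == 0) {
    return(tibble(id = character(), strand = character(), tss = integer(),
                  tss_all = list(), three_prime = integer(),
                  length = integer(), low_support = logical(),
                  sigma = character(), via_extended10 = logical(),
                  x_i = integer()))
  }
  per_tss <- tss_tbl |>
    group_by(.data$position, .data$strand) |>
    summarise(x_i = dplyr::first(.data$x_i),
              sigma = paste(sort(unique(.data$sigma)), collapse = ","),
              via_extended10 = all(.data$via_extended10),
              .groups = "drop")
  rows <- lapply(seq_len(nrow(per_tss)), function(i) {
    tp <- call_three_prime_end(per_tss$position[i], per_tss$strand[i],
                               profiles, cutoff, min_len, use_starts)
    tibble(strand = per_tss$strand[i], tss = per_tss$position[i],
           tss_all = list(per_tss$position[i]),
           three_prime = tp$three_prime, length = tp$length,
           low_support = tp$low_support, sigma = per_tss$sigma[i],
           via_extended10 = per_tss$via_extended10[i],
           x_i = per_tss$x_i[i])
  })
  out <- bind_rows(rows) |> arrange(.data$strand, .data$tss)
  out$id <- sprintf("region_%04d", seq_len(nrow(out)))
  select(out, "id", dplyr::everything())
}

#' Merge regions with multiple nearby starts and a shared 3' end
#'
#' Same-strand regions whose TSS lie within `window` bp of each other and
#' whose 3' ends are identical represent one transcription unit with multiple
#' promoters; they are collapsed into a single region carrying all TSS, with
#' the outermost (most 5') TSS as the representative start. The operation is
#' idempotent.
#'
#' @param regions [build_regions()] output.
#' @param window Maximum 5'-end distance in bp (default 100).
#' @return Region tibble with merged rows; `n_tss` gives the number of
#'   merged starts.
#' @export
merge_multi_tss <- function(regions, window = 100L) {
  if (nrow(regions) == 0) {
    regions$n_tss <- integer(0)
    return(regions)
  }
  merged <- regions |>
    group_by(.data$strand, .data$three_prime) |>
    arrange(.data$tss, .by_group = TRUE) |>
    mutate(grp = cumsum(c(1L, diff(.data$tss) > window))) |>
    group_by(.data$strand, .data$three_prime, .data$grp) |>
    summarise(
      id = dplyr::first(.data$id),
      tss_all = list(sort(unique(unlist(.data$tss_all)))),
      low_support = any(.data$low_support),
      sigma = paste(sort(unique(unlist(strsplit(.data$sigma, ",")))),
                    collapse = ","),
      via_extended10 = all(.data$via_extended10),
      x_i = max(.data$x_i),
      .groups = "drop"
    ) |>
    mutate(
      tss = purrr::map2_int(.data$tss_all, .data$strand,
                            ~ if (.y == "+") min(.x) else max(.x)),
      n_tss = lengths(.data$tss_all),
      length = abs(.data$three_prime - .data$tss) + 1L
    ) |>
    select("id", "strand", "tss", "tss_all", "n_tss", "three_prime",
           "length", "low_support", "sigma", "via_extended10", "x_i") |>
    arrange(.data$strand, .data$tss)
  merged
}
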