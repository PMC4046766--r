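# Positional classification of sRNA regions relative to annotated CDS,
# locus-tag assignment, and per-class length statistics.

CLASS_LEVELS <- c("mRNA_leader", "asRNA", "as5UTR", "as3UTR", "trans_encoded")

# All positional labels a region qualifies for, in precedence order.
qualifying_labels <- function(tss, three_prime, strand, cds,
                              leader_dist = 100L, as5_dist = 100L,
                              as3_dist = 60L) {
  labs <- character(0)
  same <- cds[cds$strand == strand, , drop = FALSE]
  opp <- cds[cds$strand != strand, , drop = FALSE]
  lo <- min(tss, three_prime)
  hi <- max(tss, three_prime)

  # (1) mRNA leader: same-strand CDS start downstream of the region 3' end at
  # a distance strictly below leader_dist, or the region overlaps the CDS 5'
  # end.
  if (nrow(same) > 0) {
    cds5 <- ifelse(same$strand == "+", same$start, same$end)
    d <- if (strand == "+") cds5 - three_prime else three_prime - cds5
    overlap5 <- cds5 >= lo & cds5 <= hi
    if (any((d > 0 & d < leader_dist) | overlap5)) labs <- c(labs, "mRNA_leader")
  }
  if (nrow(opp) > 0) {
    o5 <- ifelse(opp$strand == "+", opp$start, opp$end)
    o3 <- ifelse(opp$strand == "+", opp$end, opp$start)
    # (2) asRNA: TSS inside an opposite-strand CDS
    if (any(tss >= opp$start & tss <= opp$end)) labs <- c(labs, "asRNA")
    # (3) as5'-UTR: TSS within as5_dist upstream (in the opposing gene's
    # orientation) of an opposite-strand CDS 5' end
    d5 <- ifelse(opp$strand == "+", o5 - tss, tss - o5)
    if (any(d5 >= 1 & d5 <= as5_dist)) labs <- c(labs, "as5UTR")
    # (4) as3'-UTR: TSS within as3_dist beyond an opposite-strand CDS 3' end
    d3 <- ifelse(opp$strand == "+", tss - o3, o3 - tss)
    if (any(d3 >= 1 & d3 <= as3_dist)) labs <- c(labs, "as3UTR")
  }
  c(labs, "trans_encoded")
}

#' Classify regions by position relative to annotated CDS
#'
#' Assigns each region one primary positional class with the decision order
#' mRNA leader > asRNA > as5'-UTR > as3'-UTR > trans-encoded:
#' a region whose 3' end lies less than `leader_dist` nt before a same-strand
#' CDS start (strict) or which overlaps that start is an mRNA leader; a TSS
#' inside an opposite-strand CDS makes an asRNA; a TSS within `as5_dist` nt
#' upstream of an opposite-strand CDS 5' end (inclusive) an antisense 5'-UTR;
#' within `as3_dist` nt beyond an opposite-strand CDS 3' end (inclusive) an
#' antisense 3'-UTR; everything else is trans-encoded. The documented dual
#' memberships (as5UTR also qualifying as3UTR; mRNA leader also qualifying
#' as5UTR) are recorded in `secondary`.
#'
#' @param regions Region tibble (`tss`, `three_prime`, `strand`, ...).
#' @param annotation Annotation tibble; only CDS rows are used.
#' @param leader_dist,as5_dist,as3_dist Distance thresholds in nt.
#' @return `regions` with `class` and `secondary` columns.
#' @export
classify_regions <- function(regions, annotation, leader_dist = 100L,
                             as5_dist = 100L, as3_dist = 60L) {
  cds <- annotation[annotation$type == "CDS", , drop = FALSE]
  cls <- character(nrow(regions))
  sec <- character(nrow(regions))
  dual_ok <- list(c("as5UTR", "as3UTR"), c("mRNA_leader", "as5UTR"))
  for (i in seq_len(nrow(regions))) {
    labs <- qualifying_labels(regions$tss[i], regions$three_prime[i],
                              regions$strand[i], cds,
                              leader_dist, as5_dist, as3_dist)
    labs <- CLASS_LEVELS[CLASS_LEVELS %in% labs]
    cls[i] <- labs[1]
    sec[i] <- ""
    for (pair in dual_ok) {
      if (cls[i] == pair[1] && pair[2] %in% labs) sec[i] <- pair[2]
    }
  }
  regions$class <- cls
  regions$secondary <- sec
  regions
}

#' Assign locus tags to antisense and trans-encoded regions
#'
#' Implements the trailing-zero nomenclature: an annotated CDS `cg0010` owns
#' the tag `cgb_00100`, and the freed last digit numbers novel features that
#' lie between consecutive CDS, ordered by genomic position (a single feature
#' between `cg0010` and the next CDS becomes `cgb_00105`). Only antisense
#' classes and trans-encoded regions receive tags; mRNA leaders stay
#' untagged.
#'
#' @param regions Classified region tibble.
#' @param annotation Annotation tibble; CDS locus tags must end in a number
#'   (e.g. `cg0010`).
#' @param prefix New-nomenclature prefix.
#' @return `regions` with a `locus_tag` column (`NA` for untagged classes).
#' @export
assign_locus_tags <- function(regions, annotation, prefix = "cgb_") {
  cds <- annotation[annotation$type == "CDS", , drop = FALSE] |>
    arrange(.data$start)
  nums <- suppressWarnings(as.integer(sub("^\\D*", "", cds$locus_tag)))
  if (anyNA(nums)) {
    stop("CDS locus tags must carry a numeric part", call. = FALSE)
  }
  width <- max(nchar(sub("^\\D*", "", cds$locus_tag)), 4L)
  regions$locus_tag <- NA_character_
  taggable <- which(regions$class %in% c("asRNA", "as5UTR", "as3UTR",
                                         "trans_encoded"))
  if (length(taggable) == 0) return(regions)
  # anchor every taggable region at the nearest CDS starting at or before its
  # 5'-most coordinate (positions before the first CDS anchor at number 0)
  pos5 <- pmin(regions$tss[taggable], regions$three_prime[taggable])
  anchor_idx <- findInterval(pos5, cds$start)
  anchor_num <- ifelse(anchor_idx == 0, 0L, nums[pmax(anchor_idx, 1L)])
  for (a in unique(anchor_num)) {
    grp <- taggable[anchor_num == a]
    grp <- grp[order(pmin(regions$tss[grp], regions$three_prime[grp]))]
    k <- length(grp)
    if (k > 9) {
      stop("more than 9 novel features after CDS number ", a,
           "; assign tags manually", call. = FALSE)
    }
    digits <- floor(seq_len(k) * 10 / (k + 1))
    regions$locus_tag[grp] <- paste0(
      prefix, formatC(a, width = width, flag = "0"), digits
    )
  }
  regions
}

#' Locus tag of an annotated CDS under the new nomenclature
#'
#' @param old_tag Old-style tag (e.g. `"cg0001"`).
#' @param prefix New-nomenclature prefix.
#' @return New tag with a trailing zero (e.g. `"cgb_00010"`).
#' @export
renumber_cds_tag <- function(old_tag, prefix = "cgb_") {
  num <- sub("^\\D*", "", old_tag)
  paste0(prefix, formatC(num, width = max(nchar(num), 4L), flag = "0"), "0")
}

#' Per-class transcript length statistics
#'
#' @param regions Classified region tibble with `class` and `length`.
#' @return Tibble per primary class: `n`, `mean`, `median`, `q25`, `q75`
#'   (statistics `NA` for empty classes).
#' @export
length_stats <- function(regions) {
  base <- tibble(class = CLASS_LEVELS)
  got <- regions |>
    group_by(class = .data$class) |>
    summarise(n = dplyr::n(),
              mean = mean(.data$length),
              median = median(.data$length),
              q25 = unname(quantile(.data$length, 0.25)),
              q75 = unname(quantile(.data$length, 0.75)),
              .groups = "drop")
  out <- left_join(base, got, by = "class")
  out$n[is.na(out$n)] <- 0L
  out
}
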