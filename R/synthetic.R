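# Synthetic dRNA-Seq worlds: a random genome with annotated CDS, planted sRNA
# regions of every positional class (each with a promoter sampled from a
# sigma-factor model), planted terminators and conservation windows, and
# simulated library-1/library-2 alignments with the statistical structure the
# detection rules assume.

#' Configuration for a synthetic dRNA-Seq world
#'
#' The defaults are the study conditions used throughout the test suite:
#' a 200 kb chromosome at GC 0.54 with 50 planted sRNA regions, TSS stacks of
#' mean height 30 in the primary library over a Poisson background of rate 1
#' read start per position and strand, and mean transcript-body coverage 40
#' in the whole-transcriptome library (whose background is matched in
#' coverage, i.e. a start rate of `background_rate / read_length`). Class
#' length means follow typical bacterial observations (asRNA ~55 nt,
#' trans-encoded ~90 nt, log-normal).
#'
#' @param genome_length Chromosome length in nt.
#' @param gc GC fraction of the background sequence.
#' @param n_cds Number of annotated CDS (default scales with genome length,
#'   about one per 2.5 kb; must be at least the number of host CDS the
#'   planted antisense/leader classes require).
#' @param counts Named planted-region counts per class
#'   (`leader`, `asRNA`, `as5UTR`, `as3UTR`, `trans`).
#' @param length_means Named mean transcript lengths per class in nt.
#' @param length_sdlog Log-normal sd (log scale) of transcript lengths.
#' @param min_region_length Shortest planted transcript in nt.
#' @param tss_height Mean library-1 read starts at a planted TSS.
#' @param background_rate Library-1 background read-start rate per position
#'   and strand; library 2 uses the coverage-matched rate
#'   `background_rate / read_length`.
#' @param library2_depth Target mean body coverage of library 2.
#' @param primary_fraction Fraction of library-2 reads of a transcript that
#'   anchor at its TSS (untreated libraries retain intact primary
#'   transcripts).
#' @param read_length Read length in nt.
#' @param terminator_fraction Fraction of trans-encoded regions followed by a
#'   planted Rho-independent terminator.
#' @param conserved_fraction Fraction of trans-encoded regions covered by a
#'   planted high-probability conservation window.
#' @param n_inactive Number of trans regions flagged inactive (condition
#'   off), excluded from read simulation and truth-based scoring.
#' @param n_rrna,n_trna Planted rRNA/tRNA genes.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(genome_length = 200000L, gc = 0.54,
                             n_cds = NULL,
                             counts = c(leader = 10L, asRNA = 15L,
                                        as5UTR = 5L, as3UTR = 5L,
                                        trans = 15L),
                             length_means = c(leader = 150, asRNA = 55,
                                              as5UTR = 70, as3UTR = 70,
                                              trans = 90),
                             length_sdlog = 0.25,
                             min_region_length = 40L,
                             tss_height = 30, background_rate = 1,
                             library2_depth = 40, primary_fraction = 0.3,
                             read_length = 35L,
                             terminator_fraction = 0.5,
                             conserved_fraction = 0.5,
                             n_inactive = 0L,
                             n_rrna = 2L, n_trna = 4L) {
  hosts <- sum(counts[c("leader", "asRNA", "as5UTR", "as3UTR")])
  if (is.null(n_cds)) {
    n_cds <- max(hosts, as.integer(round(genome_length / 2500)))
  }
  if (n_cds < hosts) {
    stop("n_cds must cover the ", hosts, " host CDS the planted classes need",
         call. = FALSE)
  }
  structure(
    list(genome_length = as.integer(genome_length), gc = gc,
         n_cds = as.integer(n_cds), counts = counts,
         length_means = length_means, length_sdlog = length_sdlog,
         min_region_length = as.integer(min_region_length),
         tss_height = tss_height, background_rate = background_rate,
         library2_depth = library2_depth,
         primary_fraction = primary_fraction,
         read_length = as.integer(read_length),
         terminator_fraction = terminator_fraction,
         conserved_fraction = conserved_fraction,
         n_inactive = as.integer(n_inactive),
         n_rrna = as.integer(n_rrna), n_trna = as.integer(n_trna)),
    class = "synthetic_config"
  )
}

sample_bases <- function(n, gc) {
  sample(BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

sample_from_pwm <- function(pwm) {
  paste(vapply(seq_len(ncol(pwm)),
               function(j) sample(BASES, 1, prob = pwm[, j]),
               character(1)), collapse = "")
}

# Canonical strong terminator: GC-rich 8 bp stem, 4 nt loop, 8 nt poly-T
# tail. `jitter` substitutes one stem pair with an A:T pair.
canonical_terminator <- function(jitter = FALSE) {
  stem <- c("G", "C", "C", "G", "C", "C", "G", "C")
  if (jitter) stem[3] <- "A"
  left <- paste(stem, collapse = "")
  right <- revcomp(left)
  paste0(left, "TTCG", right, "TTTTTTTT")
}

#' Generate a synthetic world
#'
#' Deterministically (per seed) builds a genome, places non-overlapping CDS
#' with generous intergenic margins, plants sRNA regions of every positional
#' class with promoter sequences sampled from `promoter_model` (re-sampled
#' until the scanner recovers them — planting and detection are closed over
#' the same model), plants terminators downstream of a fraction of
#' trans-encoded regions, and fabricates a structure-conservation window
#' table with known truth. The planted class of every region is verified
#' against [classify_regions()] at generation time.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param promoter_model Model used to plant and validate promoters (default
#'   a calibrated SigA consensus model).
#' @return An `srna_world`: `genome` (DNAString), `annotation`,
#'   `truth_regions`, `truth_terminators`, `truth_windows`, `config`,
#'   `promoter_model`, `seed`.
#' @export
generate_world <- function(config = synthetic_config(), seed = 1L,
                           promoter_model = NULL) {
  set.seed(derive_seed(seed, 11L))
  if (is.null(promoter_model)) {
    promoter_model <- consensus_promoter_model("SigA", gc = config$gc,
                                               seed = derive_seed(seed, 12L))
  }
  L <- config$genome_length
  genome <- sample_bases(L, config$gc)

  sample_len <- function(class) {
    m <- config$length_means[[class]]
    max(config$min_region_length,
        as.integer(round(stats::rlnorm(1, log(m) - config$length_sdlog^2 / 2,
                                       config$length_sdlog))))
  }

  counts <- config$counts
  jobs <- c(
    rep("leader", counts[["leader"]]), rep("asRNA", counts[["asRNA"]]),
    rep("as5UTR", counts[["as5UTR"]]), rep("as3UTR", counts[["as3UTR"]]),
    rep("trans", counts[["trans"]]),
    rep("cds", config$n_cds -
          sum(counts[c("leader", "asRNA", "as5UTR", "as3UTR")])),
    rep("rRNA", config$n_rrna), rep("tRNA", config$n_trna)
  )
  jobs <- sample(jobs)

  M <- 150L  # intra-block margin isolating features from neighbours
  cds_rows <- list()
  region_rows <- list()
  pos <- 300L
  for (job in jobs) {
    pos <- pos + sample(40:120, 1)
    b <- pos
    if (job == "cds") {
      Lc <- sample(600:1200, 1)
      cds_rows[[length(cds_rows) + 1L]] <-
        tibble(type = "CDS", strand = sample(c("+", "-"), 1),
               start = b + 30L, end = b + 29L + Lc)
      width <- 60L + Lc
    } else if (job %in% c("rRNA", "tRNA")) {
      Lc <- if (job == "rRNA") 1200L else 80L
      cds_rows[[length(cds_rows) + 1L]] <-
        tibble(type = job, strand = sample(c("+", "-"), 1),
               start = b + 30L, end = b + 29L + Lc)
      width <- 60L + Lc
    } else {
      len <- sample_len(job)
      str <- sample(c("+", "-"), 1)
      host <- NULL
      if (job == "leader") {
        Lc <- sample(600:1200, 1)
        d <- sample(20:80, 1)
        if (str == "+") {
          tss <- b + M; tp <- tss + len - 1L
          host <- c(tp + d, tp + d + Lc - 1L)
        } else {
          host <- c(b + M, b + M + Lc - 1L)
          tp <- host[2] + d; tss <- tp + len - 1L
        }
        width <- M + len + d + Lc + M
      } else if (job == "asRNA") {
        Lc <- len + 300L
        host <- c(b + M, b + M + Lc - 1L)
        if (str == "+") {
          tss <- host[1] + 120L; tp <- tss + len - 1L
        } else {
          tss <- host[2] - 120L; tp <- tss - len + 1L
        }
        width <- M + Lc + M
      } else if (job == "as5UTR") {
        Lc <- 700L
        d <- sample(10:90, 1)
        if (str == "+") {
          host <- c(b + M, b + M + Lc - 1L)
          tss <- host[2] + d; tp <- tss + len - 1L
        } else {
          tp <- b + M; tss <- tp + len - 1L
          host <- c(tss + d, tss + d + Lc - 1L)
        }
        width <- M + Lc + d + len + M
      } else if (job == "as3UTR") {
        Lc <- len + 300L
        d <- sample(5:55, 1)
        if (str == "+") {
          host <- c(b + M + 60L, b + M + 59L + Lc)
          tss <- host[1] - d; tp <- tss + len - 1L
        } else {
          host <- c(b + M, b + M + Lc - 1L)
          tss <- host[2] + d; tp <- tss - len + 1L
        }
        width <- M + Lc + 60L + M
      } else {  # trans
        tss <- if (str == "+") b + M else b + M + len - 1L
        tp <- if (str == "+") tss + len - 1L else b + M
        width <- M + len + M
      }
      if (!is.null(host)) {
        cds_rows[[length(cds_rows) + 1L]] <-
          tibble(type = "CDS",
                 strand = if (job == "leader") str else
                   if (str == "+") "-" else "+",
                 start = host[1], end = host[2])
      }
      region_rows[[length(region_rows) + 1L]] <-
        tibble(class = ifelse(job == "trans", "trans_encoded",
                              ifelse(job == "leader", "mRNA_leader", job)),
               strand = str, tss = tss, three_prime = tp, length = len)
    }
    pos <- pos + width
    if (pos > L - 300L) {
      stop("infeasible packing: ", length(jobs), " features do not fit in ",
           L, " nt", call. = FALSE)
    }
  }

  annotation <- bind_rows(cds_rows) |> arrange(.data$start)
  is_cds <- annotation$type == "CDS"
  tags <- character(nrow(annotation))
  tags[is_cds] <- sprintf("cg%04d", seq_len(sum(is_cds)))
  tags[!is_cds] <- sprintf("%s_%02d", tolower(annotation$type[!is_cds]),
                           seq_len(sum(!is_cds)))
  annotation$locus_tag <- tags
  annotation$seqname <- "chr"
  annotation$product <- NA_character_
  annotation <- select(annotation, "seqname", "type", "locus_tag", "strand",
                       "start", "end", "product")

  truth <- bind_rows(region_rows) |> arrange(.data$tss)
  truth$id <- sprintf("srna_%03d", seq_len(nrow(truth)))
  truth <- select(truth, "id", dplyr::everything())

  # plant promoters; re-sample weak draws until the scanner recovers them
  for (i in seq_len(nrow(truth))) {
    ok <- FALSE
    for (try in seq_len(120L)) {
      genome <- plant_promoter(genome, truth$tss[i], truth$strand[i],
                               promoter_model, config$gc)
      # verify on a local window around the TSS (scan geometry unchanged)
      lo <- max(1L, truth$tss[i] - 130L)
      hi <- min(L, truth$tss[i] + 130L)
      local <- Biostrings::DNAString(paste(genome[lo:hi], collapse = ""))
      hit <- suppressWarnings(
        scan_promoter(promoter_model, local, truth$tss[i] - lo + 1L,
                      truth$strand[i])
      )
      if (nrow(hit) == 1) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("failed to plant a detectable promoter at region ",
                  truth$id[i], call. = FALSE)
  }

  # terminators downstream of a fraction of trans regions
  trans_idx <- which(truth$class == "trans_encoded")
  n_term <- round(config$terminator_fraction * length(trans_idx))
  term_idx <- if (n_term > 0) trans_idx[seq_len(n_term)] else integer(0)
  term_rows <- list()
  for (i in term_idx) {
    tseq <- canonical_terminator()
    tl <- nchar(tseq)
    tp <- truth$three_prime[i]
    if (truth$strand[i] == "+") {
      from <- tp + 3L
      genome[from:(from + tl - 1L)] <- strsplit(tseq, "")[[1]]
      hp_end <- from + 20L - 1L  # last paired base (stem+loop+stem = 20 nt)
    } else {
      to <- tp - 3L
      genome[(to - tl + 1L):to] <- strsplit(revcomp(tseq), "")[[1]]
      hp_end <- to - 20L + 1L
    }
    term_rows[[length(term_rows) + 1L]] <-
      tibble(region_id = truth$id[i], hairpin_end = hp_end,
             strand = truth$strand[i])
  }
  truth$terminator <- truth$id %in%
    vapply(term_rows, function(r) r$region_id, character(1))
  truth_terminators <- if (length(term_rows)) bind_rows(term_rows) else
    tibble(region_id = character(), hairpin_end = integer(),
           strand = character())

  # condition flags: the last n_inactive trans regions are switched off
  truth$active <- TRUE
  if (config$n_inactive > 0 && length(trans_idx) > 0) {
    off <- tail(trans_idx, min(config$n_inactive, length(trans_idx)))
    truth$active[off] <- FALSE
  }

  # conservation windows: high-p windows over a fraction of trans regions,
  # plus low-p / low-mpi decoys elsewhere
  cons_idx <- if (length(trans_idx) > 0) {
    trans_idx[seq_len(round(config$conserved_fraction * length(trans_idx)))]
  } else integer(0)
  win_rows <- list()
  for (i in cons_idx) {
    lo <- min(truth$tss[i], truth$three_prime[i])
    hi <- max(truth$tss[i], truth$three_prime[i])
    win_rows[[length(win_rows) + 1L]] <-
      tibble(start = lo - sample(0:20, 1), end = hi + sample(0:20, 1),
             strand = truth$strand[i],
             p = round(runif(1, 0.9, 0.99), 2),
             mpi = round(runif(1, 65, 95), 1), truth_region = truth$id[i])
  }
  n_decoy <- 20L
  for (k in seq_len(n_decoy)) {
    st <- sample(L - 400L, 1)
    win_rows[[length(win_rows) + 1L]] <-
      tibble(start = st, end = st + sample(100:200, 1),
             strand = sample(c("+", "-"), 1),
             p = round(runif(1, 0, 0.45), 2),
             mpi = round(runif(1, 30, 95), 1), truth_region = NA_character_)
  }
  truth_windows <- bind_rows(win_rows)
  truth$conserved <- truth$id %in% truth_windows$truth_region

  world <- structure(
    list(genome = Biostrings::DNAString(paste(genome, collapse = "")),
         annotation = annotation, truth_regions = truth,
         truth_terminators = truth_terminators,
         truth_windows = truth_windows, config = config,
         promoter_model = promoter_model, seed = as.integer(seed)),
    class = "srna_world"
  )

  # closing the loop: planted geometry must classify as planted
  chk <- classify_regions(truth, annotation)
  if (!all(chk$class == truth$class)) {
    stop("internal error: planted region(s) classify differently than ",
         "planted: ",
         paste(truth$id[chk$class != truth$class], collapse = ", "),
         call. = FALSE)
  }
  world
}

# Overwrite the sequence upstream of a TSS with a promoter sampled from the
# model: [-35][spacer, last 8 nt from the extended -10][-10][gap 5-8 nt].
plant_promoter <- function(genome, tss, strand, model, gc) {
  s <- sample(model$spacer_range[1]:model$spacer_range[2], 1)
  g <- sample(5:8, 1)
  box35 <- sample_from_pwm(model$pwm35)
  box10 <- sample_from_pwm(model$pwm10)
  spacer <- paste(sample_bases(s, gc), collapse = "")
  if (!is.null(model$pwm_ext10)) {
    ext <- sample_from_pwm(model$pwm_ext10)
    substr(spacer, s - 7L, s) <- ext
  }
  gap <- paste(sample_bases(g, gc), collapse = "")
  prom <- paste0(box35, spacer, box10, gap)
  n <- nchar(prom)
  chars <- strsplit(prom, "")[[1]]
  if (strand == "+") {
    genome[(tss - n):(tss - 1L)] <- chars
  } else {
    # transcript-orientation promoter maps to the reverse complement on the
    # plus strand, box -35 furthest from the TSS
    genome[(tss + 1L):(tss + n)] <- strsplit(revcomp(prom), "")[[1]]
  }
  genome
}

#' @export
print.srna_world <- function(x, ...) {
  cat("<srna_world>", length(x$genome), "nt,",
      sum(x$annotation$type == "CDS"), "CDS,",
      nrow(x$truth_regions), "planted sRNA regions\n")
  invisible(x)
}

#' Simulate dRNA-Seq libraries from a synthetic world
#'
#' Library 1 (primary-transcript enriched): read starts at each active truth
#' TSS are Poisson with mean `tss_height`, plus Poisson background starts at
#' `background_rate` per position and strand. Library 2 (whole small
#' transcriptome): each transcript receives `library2_depth x length /
#' read_length` reads on average, a `primary_fraction` of which anchor at
#' the TSS while the rest start uniformly within the transcript; background
#' start rate is `background_rate / read_length` so that background coverage
#' matches `background_rate`. All reads are `read_length` nt, truncated at
#' the transcript 3' end (the molecule ends there) and at the chromosome
#' ends.
#'
#' @param world An `srna_world`.
#' @param seed Integer seed.
#' @return Alignment tibble (`seqname`, `strand`, `start`, `end`, `library`)
#'   for both libraries.
#' @export
simulate_libraries <- function(world, seed = 1L) {
  config <- world$config
  set.seed(derive_seed(seed, 21L))
  L <- length(world$genome)
  rl <- config$read_length
  truth <- world$truth_regions[world$truth_regions$active, , drop = FALSE]
  rows <- list()

  clamp_read <- function(p5, strand, stop_at) {
    # read from its 5' position, truncated at stop_at (transcript 3' end)
    if (strand == "+") {
      tibble(start = p5, end = pmin(p5 + rl - 1L, stop_at))
    } else {
      tibble(start = pmax(p5 - rl + 1L, stop_at), end = p5)
    }
  }

  # library 1: TSS stacks
  for (i in seq_len(nrow(truth))) {
    n <- rpois(1, config$tss_height)
    if (n == 0) next
    r <- clamp_read(rep(truth$tss[i], n), truth$strand[i],
                    truth$three_prime[i])
    rows[[length(rows) + 1L]] <-
      tibble(seqname = "chr", strand = truth$strand[i], start = r$start,
             end = r$end, library = 1L)
  }
  # library 1 background
  for (str in c("+", "-")) {
    n <- rpois(1, config$background_rate * L)
    if (n == 0) next
    p5 <- sample.int(L, n, replace = TRUE)
    stop_at <- if (str == "+") L else 1L
    r <- clamp_read(p5, str, stop_at)
    rows[[length(rows) + 1L]] <-
      tibble(seqname = "chr", strand = str, start = r$start, end = r$end,
             library = 1L)
  }

  # library 2: transcript bodies
  for (i in seq_len(nrow(truth))) {
    len <- truth$length[i]
    n <- rpois(1, config$library2_depth * len / rl)
    if (n == 0) next
    n_primary <- rbinom(1, n, config$primary_fraction)
    offs <- c(rep(0L, n_primary),
              sample.int(len, n - n_primary, replace = TRUE) - 1L)
    p5 <- if (truth$strand[i] == "+") truth$tss[i] + offs
          else truth$tss[i] - offs
    r <- clamp_read(p5, truth$strand[i], truth$three_prime[i])
    rows[[length(rows) + 1L]] <-
      tibble(seqname = "chr", strand = truth$strand[i], start = r$start,
             end = r$end, library = 2L)
  }
  # library 2 background (coverage-matched)
  for (str in c("+", "-")) {
    n <- rpois(1, config$background_rate / rl * L)
    if (n == 0) next
    p5 <- sample.int(L, n, replace = TRUE)
    stop_at <- if (str == "+") L else 1L
    r <- clamp_read(p5, str, stop_at)
    rows[[length(rows) + 1L]] <-
      tibble(seqname = "chr", strand = str, start = r$start, end = r$end,
             library = 2L)
  }
  aln <- bind_rows(rows)
  aln$start <- pmax(1L, aln$start)
  aln$end <- pmin(L, aln$end)
  aln
}

#' Score pipeline calls against planted truth
#'
#' Matches called TSS to truth TSS (exact by default), then scores 3'-end
#' agreement, class labels and terminator attachment on the matched regions.
#'
#' @param called_regions Classified region tibble from the pipeline.
#' @param world The `srna_world` the reads were simulated from.
#' @param tolerance_tss Maximum |called - truth| TSS distance to match
#'   (default 0 = exact).
#' @param tolerance_3p 3'-end agreement tolerance in nt (default 10).
#' @return A `recovery_report`: tibble with one row per stage (`tss`,
#'   `three_prime`, `class`, `terminator`) and columns `precision`, `recall`,
#'   `n`; matched pairs in the `pairs` attribute.
#' @export
evaluate_against_truth <- function(called_regions, world, tolerance_tss = 0L,
                                   tolerance_3p = 10L) {
  truth <- world$truth_regions[world$truth_regions$active, , drop = FALSE]
  called_tss <- called_regions |>
    select("id", "strand", "tss_all") |>
    tidyr::unnest_longer("tss_all") |>
    rename(tss = "tss_all")
  match_of <- function(tss, strand) {
    cand <- which(truth$strand == strand &
                  abs(truth$tss - tss) <= tolerance_tss)
    if (length(cand) == 0) NA_integer_ else cand[1]
  }
  called_tss$truth_idx <- purrr::map2_int(called_tss$tss, called_tss$strand,
                                          match_of)
  n_called <- nrow(called_tss)
  matched_truth <- unique(called_tss$truth_idx[!is.na(called_tss$truth_idx)])
  tss_precision <- if (n_called > 0) {
    sum(!is.na(called_tss$truth_idx)) / n_called
  } else NA_real_
  tss_recall <- if (nrow(truth) > 0) {
    length(matched_truth) / nrow(truth)
  } else NA_real_

  # region-level pairs: one called region per matched truth region
  pair_rows <- list()
  for (ti in matched_truth) {
    cr <- called_tss$id[which(called_tss$truth_idx == ti)[1]]
    reg <- called_regions[called_regions$id == cr, , drop = FALSE]
    pair_rows[[length(pair_rows) + 1L]] <- tibble(
      truth_id = truth$id[ti], called_id = cr,
      d3 = abs(reg$three_prime[1] - truth$three_prime[ti]),
      class_ok = identical(reg$class[1], truth$class[ti]),
      truth_term = truth$terminator[ti],
      called_term = isTRUE(reg$terminator[1])
    )
  }
  pairs <- if (length(pair_rows)) bind_rows(pair_rows) else
    tibble(truth_id = character(), called_id = character(), d3 = integer(),
           class_ok = logical(), truth_term = logical(),
           called_term = logical())

  frac3 <- if (nrow(pairs) > 0) mean(pairs$d3 <= tolerance_3p) else NA_real_
  frac_class <- if (nrow(pairs) > 0) mean(pairs$class_ok) else NA_real_
  term_recall <- if (any(pairs$truth_term)) {
    mean(pairs$called_term[pairs$truth_term])
  } else NA_real_
  term_precision <- if (any(pairs$called_term)) {
    mean(pairs$truth_term[pairs$called_term])
  } else NA_real_

  report <- tibble(
    stage = c("tss", "three_prime", "class", "terminator"),
    precision = c(tss_precision, NA_real_, NA_real_, term_precision),
    recall = c(tss_recall, frac3, frac_class, term_recall),
    n = c(nrow(truth), nrow(pairs), nrow(pairs), sum(pairs$truth_term))
  )
  attr(report, "pairs") <- pairs
  class(report) <- c("recovery_report", class(report))
  report
}
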