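# End-to-end orchestration: profiles -> TSS -> promoters -> collapse ->
# 3' ends -> merge -> terminators -> classification -> locus tags -> small
# ORFs -> optional conservation overlap and enrichment.

#' Drop TSS candidates explained by existing annotation
#'
#' Stacks inside rRNA/tRNA genes (either strand) or sense within a CDS are
#' mRNA/stable-RNA signals, not sRNA candidates, and are removed before
#' promoter analysis.
#'
#' @param candidates [detect_tss()] output.
#' @param annotation Annotation tibble.
#' @return Filtered candidate tibble.
#' @export
filter_tss_by_annotation <- function(candidates, annotation) {
  if (nrow(candidates) == 0) return(candidates)
  keep <- rep(TRUE, nrow(candidates))
  stable <- annotation[annotation$type %in% c("rRNA", "tRNA"), , drop = FALSE]
  if (nrow(stable) > 0) {
    keep <- keep & !IRanges::overlapsAny(
      IRanges::IRanges(candidates$position, candidates$position),
      IRanges::IRanges(stable$start, stable$end)
    )
  }
  cds <- annotation[annotation$type == "CDS", , drop = FALSE]
  for (str in c("+", "-")) {
    cs <- cds[cds$strand == str, , drop = FALSE]
    if (nrow(cs) == 0) next
    idx <- candidates$strand == str
    keep[idx] <- keep[idx] & !IRanges::overlapsAny(
      IRanges::IRanges(candidates$position[idx], candidates$position[idx]),
      IRanges::IRanges(cs$start, cs$end)
    )
  }
  candidates[keep, , drop = FALSE]
}

#' Pipeline configuration
#'
#' Collects all tunable thresholds with the canonical defaults: read-start
#' background threshold T = 19 with ratio R = 5, 3'-end coverage cutoff 10,
#' TSS collapse window 3 nt, multi-promoter merge window 100 bp, leader
#' distance 100 nt, antisense 5'/3'-UTR distances 100/60 nt, terminator
#' association window 60 nt, promoter spacer 16-20 bp.
#'
#' @param tss_threshold,tss_ratio TSS calling thresholds (T and R).
#' @param three_prime_cutoff Coverage cutoff for the 3'-end walk.
#' @param min_region_length Minimum transcript length in nt.
#' @param use_starts Walk 3' ends on read starts instead of coverage.
#' @param collapse_window,merge_window,leader_dist,as5_dist,as3_dist,terminator_window,promoter_window
#'   Stage windows in nt.
#' @param edge_margin No-call margin at the chromosome ends in nt.
#' @param p_thresholds Conservation probability thresholds (lenient,
#'   stringent).
#' @param enrichment_bounds Under/over-representation percentage bounds.
#' @param seed Integer seed recorded in the manifest and used by any stage
#'   that needs randomness.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tss_threshold = 19, tss_ratio = 5,
                            three_prime_cutoff = 10L,
                            min_region_length = 35L,
                            use_starts = FALSE,
                            collapse_window = 3L, merge_window = 100L,
                            leader_dist = 100L, as5_dist = 100L,
                            as3_dist = 60L, terminator_window = 60L,
                            promoter_window = 60L, edge_margin = 300L,
                            p_thresholds = c(0.5, 0.9),
                            enrichment_bounds = c(10, 20), seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(all(vapply(cfg[c("tss_threshold", "tss_ratio",
                             "three_prime_cutoff", "min_region_length",
                             "collapse_window", "merge_window", "leader_dist",
                             "as5_dist", "as3_dist", "terminator_window",
                             "promoter_window")], `>`, logical(1), 0)))
  structure(cfg, class = "pipeline_config")
}

#' Run the full sRNA discovery pipeline
#'
#' Executes every stage on a genome, its annotation and the two dRNA-Seq
#' libraries, optionally intersects with a conservation-window table and a
#' functional class map, and (if `out_dir` is given) writes deterministic
#' TSV/GFF3 outputs plus a JSON run manifest. Reruns with identical inputs
#' and configuration produce byte-identical files.
#'
#' @param genome Path to a FASTA file, or a DNAString(Set).
#' @param annotation Path to a GFF3 file, or an annotation tibble.
#' @param library1,library2 Alignment tibbles (see [read_alignments()]) or
#'   paths to BED6 files.
#' @param promoter_models List of calibrated `promoter_model`s (default: one
#'   consensus SigA model).
#' @param conservation Optional window tibble or TSV path.
#' @param class_map Optional gene-to-functional-class tibble or TSV path.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List with `tss`, `regions`, `orfs`, `conservation`, `enrichment`,
#'   `category_summary`, `stage_counts`, `config`.
#' @export
run_pipeline <- function(genome, annotation, library1, library2,
                         promoter_models = NULL, conservation = NULL,
                         class_map = NULL, config = pipeline_config(),
                         out_dir = NULL) {
  if (missing(library2) || is.null(library2)) {
    stop("library 2 (whole small transcriptome) is required: ",
         "3'-end calling walks its coverage profile", call. = FALSE)
  }
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  genome <- as_dnastring(genome)
  if (is.character(annotation)) annotation <- read_annotation_gff3(annotation)
  if (is.character(library1)) library1 <- read_alignments(library1, "bed", 1L)
  if (is.character(library2)) library2 <- read_alignments(library2, "bed", 2L)
  if (is.null(promoter_models)) {
    promoter_models <- list(consensus_promoter_model("SigA",
                                                     seed = config$seed))
  }
  if (is.character(conservation)) {
    conservation <- read_conservation_windows(conservation)
  }
  if (is.character(class_map)) {
    class_map <- readr::read_tsv(class_map, show_col_types = FALSE)
  }
  L <- length(genome)
  log_counts <- list()
  note <- function(stage, n) {
    log_counts[[length(log_counts) + 1L]] <<- tibble(stage = stage, n = n)
    message("[srnascan] ", stage, ": ", n)
  }

  prof1 <- build_profiles(library1, L, 1L)
  prof2 <- build_profiles(library2, L, 2L)
  note("library1_reads", nrow(library1))
  note("library2_reads", nrow(library2))

  cand <- detect_tss(prof1, T = config$tss_threshold, R = config$tss_ratio,
                     edge_margin = config$edge_margin)
  note("stacks_raw", nrow(cand))
  cand <- filter_tss_by_annotation(cand, annotation)
  in_anti_cds <- tss_in_antisense_cds(cand, annotation)
  note("stacks_filtered", nrow(cand))
  note("stacks_cis_antisense", sum(in_anti_cds))
  note("stacks_unannotated", sum(!in_anti_cds))

  tss_hits <- scan_promoters(cand, genome, promoter_models,
                             window = config$promoter_window)
  note("promoter_validated_tss",
       length(unique(paste(tss_hits$position, tss_hits$strand))))
  for (sg in unique(tss_hits$sigma)) {
    sub <- tss_hits[tss_hits$sigma == sg, ]
    anti <- tss_in_antisense_cds(sub, annotation)
    note(paste0("tss_", sg, "_cis_antisense"),
         length(unique(sub$position[anti])))
    note(paste0("tss_", sg, "_unannotated"),
         length(unique(sub$position[!anti])))
  }

  tss_hits <- collapse_nearby_tss(tss_hits, window = config$collapse_window)
  note("tss_after_collapse",
       length(unique(paste(tss_hits$position, tss_hits$strand))))

  regions <- build_regions(tss_hits, prof2,
                           cutoff = config$three_prime_cutoff,
                           min_len = config$min_region_length,
                           use_starts = config$use_starts)
  regions <- merge_multi_tss(regions, window = config$merge_window)
  note("regions_after_merge", nrow(regions))
  note("regions_multi_tss", sum(regions$n_tss > 1))

  term_hits <- scan_terminators(genome, regions,
                                window = config$terminator_window)
  regions <- associate_terminator(regions, term_hits,
                                  window = config$terminator_window)
  note("regions_with_terminator", sum(regions$terminator))

  regions <- classify_regions(regions, annotation,
                              leader_dist = config$leader_dist,
                              as5_dist = config$as5_dist,
                              as3_dist = config$as3_dist)
  for (cl in CLASS_LEVELS) note(paste0("class_", cl),
                                sum(regions$class == cl))
  antisense_raw <- sum(regions$class %in% c("asRNA", "as5UTR", "as3UTR"))
  note("class_antisense_total", antisense_raw)
  regions <- assign_locus_tags(regions, annotation)

  orfs <- call_small_mrnas(regions, genome,
                           min_nt = 48L, max_nt = 249L)
  note("small_mrnas", nrow(orfs))

  cons_res <- NULL
  if (!is.null(conservation)) {
    loci <- merge_windows(conservation, p_min = config$p_thresholds[1],
                          mpi_min = 60, annotation = annotation)
    trans <- regions[regions$class == "trans_encoded", , drop = FALSE]
    cons_res <- list(
      loci = loci,
      lenient = overlap_with_trans(loci, trans, config$p_thresholds[1]),
      stringent = overlap_with_trans(loci, trans, config$p_thresholds[2])
    )
    note("conserved_loci", nrow(loci))
    note("trans_matched_lenient", cons_res$lenient$n_matched)
    note("trans_matched_stringent", cons_res$stringent$n_matched)
  }

  enr <- NULL
  if (!is.null(class_map)) {
    targets <- asrna_target_genes(regions, annotation)
    enr <- compute_enrichment(targets, class_map,
                              under_pct = config$enrichment_bounds[1],
                              over_pct = config$enrichment_bounds[2])
    note("asrna_target_genes", length(unique(targets)))
  }

  cat1 <- summarize_categories(library1, annotation)
  cat2 <- summarize_categories(library2, annotation)
  stage_counts <- bind_rows(log_counts)

  result <- list(tss = tss_hits, regions = regions, orfs = orfs,
                 conservation = cons_res, enrichment = enr,
                 category_summary = list(library1 = cat1, library2 = cat2),
                 stage_counts = stage_counts, config = config)
  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir)
  }
  result
}

# Is a TSS candidate antisense within a CDS?
tss_in_antisense_cds <- function(candidates, annotation) {
  if (nrow(candidates) == 0) return(logical(0))
  cds <- annotation[annotation$type == "CDS", , drop = FALSE]
  out <- rep(FALSE, nrow(candidates))
  for (str in c("+", "-")) {
    opp <- cds[cds$strand != str, , drop = FALSE]
    idx <- which(candidates$strand == str)
    if (length(idx) == 0 || nrow(opp) == 0) next
    out[idx] <- IRanges::overlapsAny(
      IRanges::IRanges(candidates$position[idx], candidates$position[idx]),
      IRanges::IRanges(opp$start, opp$end)
    )
  }
  out
}

# Host genes of asRNA-class regions (CDS containing the TSS, opposite strand).
asrna_target_genes <- function(regions, annotation) {
  cds <- annotation[annotation$type == "CDS", , drop = FALSE]
  as_regions <- regions[regions$class == "asRNA", , drop = FALSE]
  targets <- character(0)
  for (i in seq_len(nrow(as_regions))) {
    opp <- cds[cds$strand != as_regions$strand[i] &
               cds$start <= as_regions$tss[i] &
               cds$end >= as_regions$tss[i], , drop = FALSE]
    targets <- c(targets, opp$locus_tag)
  }
  targets
}

#' Write pipeline outputs to a directory
#'
#' Writes the TSS table, the region table (start column = TSS, stop column =
#' 3' end, so start > stop on the minus strand), a GFF3 of classified
#' regions, the small-mRNA table, conservation and enrichment tables when
#' present, per-stage counts and a JSON manifest (configuration, seed,
#' package version). All writers are deterministic.
#'
#' @param result [run_pipeline()] return value.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(result$tss, p("tss.tsv"))
  regions_out <- result$regions |>
    mutate(start = .data$tss, stop = .data$three_prime,
           tss_all = vapply(.data$tss_all, paste, "", collapse = ",")) |>
    select("id", "locus_tag", "class", "secondary", "strand", "start",
           "stop", "length", "n_tss", "tss_all", "low_support", "sigma",
           "via_extended10", "terminator", "terminator_confidence")
  readr::write_tsv(regions_out, p("regions.tsv"))
  write_gff3(regions_to_gff(result$regions), p("regions.gff3"))
  orfs_out <- result$orfs |>
    mutate(runs = vapply(.data$runs, function(r) {
      paste(paste0(r$residue, r$run), collapse = ",")
    }, ""))
  readr::write_tsv(orfs_out, p("small_mrnas.tsv"))
  if (!is.null(result$conservation)) {
    readr::write_tsv(result$conservation$loci, p("conserved_loci.tsv"))
  }
  if (!is.null(result$enrichment)) {
    readr::write_tsv(result$enrichment, p("enrichment.tsv"))
  }
  readr::write_tsv(result$category_summary$library1,
                   p("categories_library1.tsv"))
  readr::write_tsv(result$category_summary$library2,
                   p("categories_library2.tsv"))
  readr::write_tsv(result$stage_counts, p("stage_counts.tsv"))
  manifest <- list(
    package = "srnascan",
    version = as.character(utils::packageVersion("srnascan")),
    config = unclass(result$config)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}

# Classified regions as GFF3 rows (ncRNA / antisense_RNA / five_prime_UTR).
regions_to_gff <- function(regions) {
  type <- dplyr::case_match(regions$class,
    "trans_encoded" ~ "ncRNA",
    c("asRNA", "as5UTR", "as3UTR") ~ "antisense_RNA",
    "mRNA_leader" ~ "five_prime_UTR"
  )
  tibble(
    seqname = "chr",
    type = type,
    start = pmin(regions$tss, regions$three_prime),
    end = pmax(regions$tss, regions$three_prime),
    strand = regions$strand,
    attributes = paste0(
      "ID=", ifelse(is.na(regions$locus_tag), regions$id,
                    regions$locus_tag),
      ";class=", regions$class
    )
  )
}

#' Read classified regions back from a pipeline GFF3
#'
#' @param path Path to a `regions.gff3` written by the pipeline.
#' @return Tibble `seqname`, `type`, `start`, `end`, `strand`, `id`.
#' @export
read_regions_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tibble(
    seqname = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id = as.character(gr$ID)
  )
}
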