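# Synthetic-world generation, library simulation, and truth-based scoring.

test_that("worlds are bit-identical for a fixed seed", {
  cfg <- synthetic_config(genome_length = 30000L,
                          counts = c(leader = 1L, asRNA = 2L, as5UTR = 1L,
                                     as3UTR = 1L, trans = 2L))
  w1 <- generate_world(cfg, seed = 9L)
  w2 <- generate_world(cfg, seed = 9L)
  expect_equal(as.character(w1$genome), as.character(w2$genome))
  expect_equal(w1$truth_regions, w2$truth_regions)
  expect_equal(w1$annotation, w2$annotation)
  a1 <- simulate_libraries(w1, seed = 9L)
  a2 <- simulate_libraries(w2, seed = 9L)
  expect_equal(a1, a2)
})

test_that("class counts in truth match the configuration", {
  w <- small_world()
  cfg <- w$config
  tab <- table(w$truth_regions$class)
  expect_equal(unname(tab[["mRNA_leader"]]), unname(cfg$counts[["leader"]]))
  expect_equal(unname(tab[["asRNA"]]), unname(cfg$counts[["asRNA"]]))
  expect_equal(unname(tab[["trans_encoded"]]), unname(cfg$counts[["trans"]]))
})

test_that("zero trans regions means no trans truth", {
  cfg <- synthetic_config(genome_length = 30000L,
                          counts = c(leader = 1L, asRNA = 1L, as5UTR = 1L,
                                     as3UTR = 1L, trans = 0L),
                          terminator_fraction = 0, conserved_fraction = 0)
  w <- generate_world(cfg, seed = 3L)
  expect_false(any(w$truth_regions$class == "trans_encoded"))
})

test_that("infeasible packing raises an error", {
  cfg <- synthetic_config(genome_length = 10000L, n_cds = 40L,
                          counts = c(leader = 5L, asRNA = 5L, as5UTR = 5L,
                                     as3UTR = 5L, trans = 20L))
  expect_error(generate_world(cfg, seed = 1L), "packing")
})

test_that("planted promoters rescored by the scanner always pass", {
  w <- small_world()
  truth <- w$truth_regions
  for (i in seq_len(nrow(truth))) {
    hit <- suppressWarnings(
      scan_promoter(w$promoter_model, w$genome, truth$tss[i],
                    truth$strand[i])
    )
    expect_equal(nrow(hit), 1L)
  }
})

test_that("library-1 stack heights match the configured mean", {
  w <- small_world()
  aln <- small_alignments()
  lib1 <- aln[aln$library == 1, ]
  truth <- w$truth_regions
  starts_at_tss <- vapply(seq_len(nrow(truth)), function(i) {
    fp <- ifelse(lib1$strand == "+", lib1$start, lib1$end)
    sum(fp == truth$tss[i] & lib1$strand == truth$strand[i])
  }, numeric(1))
  m <- mean(starts_at_tss)
  expect_lt(abs(m - w$config$tss_height),
            3 * sqrt(w$config$tss_height / nrow(truth)) + 1)
})

test_that("zero background leaves no reads outside transcripts", {
  cfg <- synthetic_config(genome_length = 30000L,
                          counts = c(leader = 1L, asRNA = 1L, as5UTR = 1L,
                                     as3UTR = 1L, trans = 2L),
                          background_rate = 0)
  w <- generate_world(cfg, seed = 13L)
  aln <- simulate_libraries(w, seed = 13L)
  truth <- w$truth_regions
  lo <- pmin(truth$tss, truth$three_prime)
  hi <- pmax(truth$tss, truth$three_prime)
  fp <- ifelse(aln$strand == "+", aln$start, aln$end)
  inside <- vapply(seq_len(nrow(aln)), function(i) {
    any(fp[i] >= lo & fp[i] <= hi & aln$strand[i] == truth$strand)
  }, logical(1))
  expect_true(all(inside))
})

test_that("library-2 coverage keeps short transcripts above the walk cutoff", {
  w <- small_world()
  aln <- small_alignments()
  prof2 <- build_profiles(aln[aln$library == 2, ], length(w$genome), 2L)
  truth <- w$truth_regions
  ok <- vapply(seq_len(nrow(truth)), function(i) {
    lo <- min(truth$tss[i], truth$three_prime[i])
    hi <- max(truth$tss[i], truth$three_prime[i])
    all(prof2$coverage[[truth$strand[i]]][lo:hi] >= 10)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("recovery scoring counts matches, misses, and spurious calls", {
  w <- small_world()
  truth <- w$truth_regions
  perfect <- truth |>
    dplyr::mutate(id = paste0("c", dplyr::row_number()),
                  tss_all = as.list(tss), terminator = truth$terminator)
  rep <- evaluate_against_truth(perfect, w)
  expect_equal(rep$recall[rep$stage == "tss"], 1)
  expect_equal(rep$precision[rep$stage == "tss"], 1)
  expect_equal(rep$recall[rep$stage == "class"], 1)

  none <- perfect[0, ]
  rep0 <- evaluate_against_truth(none, w)
  expect_equal(rep0$recall[rep0$stage == "tss"], 0)
  expect_true(is.na(rep0$precision[rep0$stage == "tss"]))

  # one spurious TSS among the true ones
  spurious <- perfect[1, ]
  spurious$id <- "fake"
  spurious$tss <- spurious$tss + 1000L
  spurious$tss_all <- list(spurious$tss)
  repx <- evaluate_against_truth(dplyr::bind_rows(perfect, spurious), w)
  n <- nrow(truth)
  expect_equal(repx$precision[repx$stage == "tss"], n / (n + 1))
  expect_equal(repx$recall[repx$stage == "tss"], 1)
})
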