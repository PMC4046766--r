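# EM promoter-model training, threshold calibration, and upstream-window
# scanning.

test_that("training rejects too few or unequal-length sites", {
  expect_error(train_promoter_model(rep("ACGTACGTACGTACGTACGTACGTACGTACGT", 5)),
               "at least 20")
  sites <- c(replicate(25, make_training_site()$seq), "ACGT")
  expect_error(train_promoter_model(sites), "uniform length")
})

test_that("EM recovers the planted box consensus (site-count oracle)", {
  fx <- trained_sites()
  m <- trained_model()
  # oracle: consensus from the count matrices computed directly at the
  # planted positions, independent of the EM path
  oracle35 <- paste(rownames(fx$counts35)[apply(fx$counts35, 2, which.max)],
                    collapse = "")
  oracle10 <- paste(rownames(fx$counts10)[apply(fx$counts10, 2, which.max)],
                    collapse = "")
  expect_equal(model_consensus(m, "minus35"), oracle35)
  expect_equal(model_consensus(m, "minus10"), oracle10)
  expect_true(m$converged)
})

test_that("control runs score stochastically below planted sites", {
  m <- trained_model()
  fx <- trained_sites()
  set.seed(88)
  planted <- vapply(fx$seqs[1:50], function(z) {
    bp <- srnascan:::best_placement(
      srnascan:::encode_dna(z),
      srnascan:::pwm_logodds(m$pwm35, m$background),
      srnascan:::pwm_logodds(m$pwm10, m$background),
      6L, 6L, m$spacer_range)
    bp$best_total
  }, numeric(1), USE.NAMES = FALSE)
  shuffled <- vapply(fx$seqs[1:50], function(z) {
    zs <- paste(sample(strsplit(z, "")[[1]]), collapse = "")
    bp <- srnascan:::best_placement(
      srnascan:::encode_dna(zs),
      srnascan:::pwm_logodds(m$pwm35, m$background),
      srnascan:::pwm_logodds(m$pwm10, m$background),
      6L, 6L, m$spacer_range)
    bp$best_total
  }, numeric(1), USE.NAMES = FALSE)
  expect_gt(mean(planted), mean(shuffled) + 5)
  expect_gt(mean(planted > shuffled), 0.9)
})

test_that("scanning finds planted consensus boxes at their spacer", {
  m <- consensus_promoter_model("SigA", seed = 3L)
  set.seed(5)
  g <- sample(BASES4, 200, replace = TRUE)
  # plant perfect consensus with spacer 18 ending 6 nt before the TSS at 150
  a <- 150 - (12 + 18 + 6)
  g <- plant_motif(g, "TTGACA", a, p = 1)
  g <- plant_motif(g, "TATAAT", a + 6 + 18, p = 1)
  hit <- scan_promoter(m, Biostrings::DNAString(paste(g, collapse = "")),
                       150L, "+")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$spacer, 18L)
  expect_false(hit$via_extended10)
})

test_that("spacers outside 16-20 are rejected even for consensus boxes", {
  m <- consensus_promoter_model("SigA", seed = 3L)
  set.seed(6)
  calls <- 0L
  for (i in 1:20) {
    g <- sample(BASES4, 200, replace = TRUE)
    a <- 150 - (12 + 22 + 6)
    g <- plant_motif(g, "TTGACA", a, p = 1)
    g <- plant_motif(g, "TATAAT", a + 6 + 22, p = 1)
    hit <- scan_promoter(m, Biostrings::DNAString(paste(g, collapse = "")),
                         150L, "+")
    calls <- calls + nrow(hit)
  }
  expect_equal(calls, 0L)
})

test_that("a strong extended -10 rescues a scrambled -35 (SigA only)", {
  m <- consensus_promoter_model("SigA", seed = 3L)
  ext_cons <- srnascan:::pwm_consensus(m$pwm_ext10)
  set.seed(7)
  g <- sample(BASES4, 200, replace = TRUE)
  p10 <- 150 - 6 - 6   # -10 box ending 6 nt before the TSS
  g <- plant_motif(g, "TATAAT", p10, p = 1)
  g <- plant_motif(g, ext_cons, p10 - 8, p = 1)
  hit <- scan_promoter(m, Biostrings::DNAString(paste(g, collapse = "")),
                       150L, "+")
  expect_equal(nrow(hit), 1L)
  expect_true(hit$via_extended10)
  expect_true(is.na(hit$spacer))
})

test_that("every reported hit satisfies its own thresholds", {
  res <- small_pipeline()
  tss <- res$tss
  m <- small_world()$promoter_model
  two_box <- tss[!tss$via_extended10, ]
  expect_true(all(two_box$minus35_score >= m$thresholds$minus35))
  expect_true(all(two_box$minus10_score >= m$thresholds$minus10))
  expect_true(all(two_box$spacer >= 16 & two_box$spacer <= 20))
  ext <- tss[tss$via_extended10, ]
  if (nrow(ext) > 0) {
    expect_true(all(ext$ext10_score >= m$thresholds$ext10))
    expect_true(all(ext$minus10_score >= m$thresholds$minus10))
  }
})

test_that("a TSS too close to the sequence end gives a no-call with warning", {
  m <- consensus_promoter_model("SigA", seed = 3L)
  g <- Biostrings::DNAString(paste(rep("ACGT", 30), collapse = ""))
  expect_warning(hit <- scan_promoter(m, g, 10L, "+"), "window")
  expect_equal(nrow(hit), 0L)
})

test_that("model serialization round-trips matrices and thresholds", {
  m <- trained_model()
  f <- withr::local_tempfile(fileext = ".txt")
  write_promoter_model(m, f)
  back <- read_promoter_model(f)
  expect_equal(back$sigma, m$sigma)
  expect_equal(back$pwm35, m$pwm35, tolerance = 1e-8)
  expect_equal(back$pwm10, m$pwm10, tolerance = 1e-8)
  expect_equal(back$pwm_ext10, m$pwm_ext10, tolerance = 1e-8)
  expect_equal(back$thresholds$combined, m$thresholds$combined,
               tolerance = 1e-8)
  expect_equal(back$spacer_range, m$spacer_range)
})

test_that("tidy and glance expose the fit in broom shape", {
  m <- trained_model()
  td <- tidy(m)
  expect_true(all(c("matrix", "position", "base", "prob") %in% names(td)))
  probs <- td |>
    dplyr::group_by(matrix, position) |>
    dplyr::summarise(s = sum(prob), .groups = "drop")
  expect_true(all(abs(probs$s - 1) < 1e-8))
  gl <- glance(m)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$consensus10, model_consensus(m, "minus10"))
})
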