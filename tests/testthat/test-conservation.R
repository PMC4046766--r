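# Structure-conservation window filtering, merging, and trans-sRNA overlap.

test_that("overlapping windows merge with the maximum probability recorded", {
  w <- tibble::tibble(
    start = c(100L, 140L), end = c(200L, 240L), strand = "+",
    p = c(0.7, 0.95), mpi = c(80, 85)
  )
  loci <- merge_windows(w)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start, 100L)
  expect_equal(loci$end, 240L)
  expect_equal(loci$p_max, 0.95)
})

test_that("disjoint or filtered windows stay apart", {
  w <- tibble::tibble(
    start = c(100L, 500L, 900L), end = c(200L, 600L, 1000L), strand = "+",
    p = c(0.7, 0.8, 0.9), mpi = c(80, 55, 85)
  )
  loci <- merge_windows(w)
  # mpi 55 dropped (> 60 is strict); the rest are disjoint
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$start, c(100L, 900L))

  # below p_min dropped
  w2 <- tibble::tibble(start = 1L, end = 100L, strand = "+", p = 0.4,
                       mpi = 80)
  expect_equal(nrow(merge_windows(w2)), 0L)
})

test_that("windows overlapping rRNA/tRNA genes are excluded", {
  ann <- tiny_annotation(list(tag = "rrn1", type = "rRNA", strand = "+",
                              start = 150L, end = 1500L))
  w <- tibble::tibble(start = c(100L, 2000L), end = c(200L, 2100L),
                      strand = "+", p = 0.9, mpi = 80)
  loci <- merge_windows(w, annotation = ann)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start, 2000L)
})

test_that("merging is order independent and idempotent", {
  set.seed(73)
  w <- tibble::tibble(
    start = sample(1:5000, 40), strand = sample(c("+", "-"), 40, TRUE),
    p = runif(40, 0.5, 1), mpi = runif(40, 61, 95)
  )
  w$end <- w$start + sample(50:200, 40, replace = TRUE)
  a <- merge_windows(w)
  b <- merge_windows(w[sample(nrow(w)), ])
  expect_equal(a, b)
  # re-merging the loci (as windows with p = p_max) changes nothing
  again <- merge_windows(
    tibble::tibble(start = a$start, end = a$end, strand = a$strand,
                   p = a$p_max, mpi = 80)
  )
  expect_equal(again$start, a$start)
  expect_equal(again$end, a$end)
  expect_equal(again$p_max, a$p_max)
})

test_that("trans regions match loci by >= 1 nt same-strand overlap", {
  trans <- tibble::tibble(id = c("t1", "t2"), strand = c("+", "+"),
                          tss = c(100L, 1000L),
                          three_prime = c(190L, 1090L))
  loci <- tibble::tibble(start = c(190L, 2000L), end = c(260L, 2100L),
                         strand = "+", p_max = c(0.95, 0.99),
                         n_windows = 1L)
  res <- overlap_with_trans(loci, trans, p_threshold = 0.9)
  expect_equal(res$n_matched, 1L)
  expect_equal(res$matched$id, "t1")
  expect_equal(res$matched$p_max, 0.95)
  expect_equal(res$fraction, 0.5)

  # strand-aware by default, with an escape hatch
  loci$strand <- "-"
  expect_equal(overlap_with_trans(loci, trans, 0.9)$n_matched, 0L)
  expect_equal(overlap_with_trans(loci, trans, 0.9,
                                  ignore_strand = TRUE)$n_matched, 1L)
})

test_that("raising the probability threshold never grows the matched set", {
  set.seed(79)
  trans <- tibble::tibble(
    id = paste0("t", 1:20), strand = sample(c("+", "-"), 20, TRUE),
    tss = seq(100L, by = 500L, length.out = 20)
  )
  trans$three_prime <- trans$tss + 90L
  loci <- tibble::tibble(
    start = seq(80L, by = 500L, length.out = 20) + sample(0:200, 20, TRUE),
    strand = sample(c("+", "-"), 20, TRUE),
    p_max = runif(20, 0.5, 1), n_windows = 1L
  )
  loci$end <- loci$start + 150L
  prev <- NULL
  for (thr in c(0.5, 0.7, 0.9, 0.95)) {
    cur <- overlap_with_trans(loci, trans, thr)$matched$id
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("zero trans regions report an undefined fraction", {
  loci <- tibble::tibble(start = 1L, end = 100L, strand = "+", p_max = 0.95,
                         n_windows = 1L)
  trans0 <- tibble::tibble(id = character(), strand = character(),
                           tss = integer(), three_prime = integer())
  res <- overlap_with_trans(loci, trans0, 0.5)
  expect_true(is.na(res$fraction))
  expect_equal(res$n_matched, 0L)
})
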