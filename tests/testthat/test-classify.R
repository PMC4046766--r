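# Positional classification relative to CDS, locus tags, length statistics.

region_row <- function(tss, tp, strand = "+", id = "r1") {
  tibble::tibble(id = id, strand = strand, tss = tss, three_prime = tp,
                 length = abs(tp - tss) + 1L)
}

test_that("leader distance is strictly below 100 nt", {
  ann <- tiny_annotation(list(tag = "cg0001", strand = "+", start = 1000L,
                              end = 1900L))
  # 3' end 50 nt before the CDS start
  expect_equal(classify_regions(region_row(850L, 950L), ann)$class,
               "mRNA_leader")
  # exactly 100 nt: not a leader
  expect_equal(classify_regions(region_row(800L, 900L), ann)$class,
               "trans_encoded")
  # 99 nt: leader
  expect_equal(classify_regions(region_row(801L, 901L), ann)$class,
               "mRNA_leader")
  # region overlapping the CDS 5' end: leader
  expect_equal(classify_regions(region_row(950L, 1050L), ann)$class,
               "mRNA_leader")
})

test_that("antisense classes follow the TSS position, with inclusive bounds", {
  ann <- tiny_annotation(list(tag = "cg0001", strand = "-", start = 1000L,
                              end = 1900L))
  # TSS at the midpoint of an opposite-strand CDS
  expect_equal(classify_regions(region_row(1450L, 1500L), ann)$class,
               "asRNA")
  # as5'-UTR: TSS within 100 nt upstream of the CDS 5' end (its end coord)
  expect_equal(classify_regions(region_row(2000L, 2060L), ann)$class,
               "as5UTR")
  expect_equal(classify_regions(region_row(1901L, 1960L), ann)$class,
               "as5UTR")
  # 101 nt out: trans
  expect_equal(classify_regions(region_row(2001L, 2060L), ann)$class,
               "trans_encoded")
  # as3'-UTR: TSS within 60 nt beyond the CDS 3' end (its start coord)
  expect_equal(classify_regions(region_row(940L, 990L), ann)$class,
               "as3UTR")
  expect_equal(classify_regions(region_row(939L, 990L), ann)$class,
               "trans_encoded")
})

test_that("positional precedence and documented dual labels", {
  # TSS inside an opposite CDS near its 5' end: asRNA wins over as5UTR
  ann <- tiny_annotation(list(tag = "cg0001", strand = "-", start = 1000L,
                              end = 1900L))
  got <- classify_regions(region_row(1880L, 1930L), ann)
  expect_equal(got$class, "asRNA")

  # as5UTR of one CDS that is also as3UTR of another: secondary recorded
  ann2 <- tiny_annotation(
    list(tag = "cg0001", strand = "-", start = 2000L, end = 2900L),
    list(tag = "cg0002", strand = "-", start = 1000L, end = 1920L)
  )
  got2 <- classify_regions(region_row(1950L, 1990L), ann2)
  expect_equal(got2$class, "as5UTR")
  expect_equal(got2$secondary, "as3UTR")

  # leader that is also as5UTR of a divergent opposite gene
  ann3 <- tiny_annotation(
    list(tag = "cg0001", strand = "+", start = 1000L, end = 1900L),
    list(tag = "cg0002", strand = "-", start = 300L, end = 880L)
  )
  got3 <- classify_regions(region_row(900L, 950L), ann3)
  expect_equal(got3$class, "mRNA_leader")
  expect_equal(got3$secondary, "as5UTR")
})

test_that("every region receives exactly one primary class (random worlds)", {
  set.seed(29)
  ann <- tiny_annotation(
    list(tag = "cg0001", strand = "+", start = 500L, end = 1400L),
    list(tag = "cg0002", strand = "-", start = 2000L, end = 2600L),
    list(tag = "cg0003", strand = "+", start = 3100L, end = 4000L)
  )
  for (i in 1:50) {
    tss <- sample(1:4500, 1)
    len <- sample(40:150, 1)
    strand <- sample(c("+", "-"), 1)
    tp <- if (strand == "+") tss + len - 1L else max(1L, tss - len + 1L)
    got <- classify_regions(region_row(tss, tp, strand), ann)
    expect_true(got$class %in% c("mRNA_leader", "asRNA", "as5UTR", "as3UTR",
                                 "trans_encoded"))
    expect_equal(length(got$class), 1L)
  }
})

test_that("class labels are invariant under strand mirroring", {
  set.seed(37)
  G <- 5000L
  ann <- tiny_annotation(
    list(tag = "cg0001", strand = "+", start = 500L, end = 1400L),
    list(tag = "cg0002", strand = "-", start = 2000L, end = 2600L)
  )
  mirror_ann <- ann
  mirror_ann$strand <- ifelse(ann$strand == "+", "-", "+")
  mirror_ann$start <- G + 1L - ann$end
  mirror_ann$end <- G + 1L - ann$start
  for (i in 1:30) {
    tss <- sample(1:4800, 1)
    len <- sample(40:120, 1)
    strand <- sample(c("+", "-"), 1)
    tp <- if (strand == "+") min(G, tss + len - 1L) else max(1L, tss - len + 1L)
    a <- classify_regions(region_row(tss, tp, strand), ann)
    b <- classify_regions(
      region_row(G + 1L - tss, G + 1L - tp,
                 ifelse(strand == "+", "-", "+")),
      mirror_ann
    )
    expect_equal(a$class, b$class)
  }
})

test_that("enlarging leader_dist can only grow the leader class", {
  set.seed(41)
  ann <- tiny_annotation(list(tag = "cg0001", strand = "+", start = 2000L,
                              end = 2900L))
  regions <- dplyr::bind_rows(lapply(1:40, function(i) {
    tss <- sample(1500:1990, 1)
    region_row(tss, tss + sample(40:120, 1), id = paste0("r", i))
  }))
  narrow <- classify_regions(regions, ann, leader_dist = 60L)
  wide <- classify_regions(regions, ann, leader_dist = 150L)
  narrow_leaders <- narrow$id[narrow$class == "mRNA_leader"]
  wide_leaders <- wide$id[wide$class == "mRNA_leader"]
  expect_true(all(narrow_leaders %in% wide_leaders))
})

test_that("locus tags follow the trailing-zero nomenclature", {
  expect_equal(renumber_cds_tag("cg0001"), "cgb_00010")
  ann <- tiny_annotation(
    list(tag = "cg0010", strand = "-", start = 9000L, end = 9900L),
    list(tag = "cg0012", strand = "-", start = 11000L, end = 11900L)
  )
  r <- region_row(10200L, 10100L, strand = "-")
  r$class <- "trans_encoded"
  r$secondary <- ""
  tagged <- assign_locus_tags(r, ann)
  expect_equal(tagged$locus_tag, "cgb_00105")

  # two features between the same CDS pair: distinct digits, position order
  r2 <- dplyr::bind_rows(
    region_row(10600L, 10500L, strand = "-", id = "x2"),
    region_row(10200L, 10100L, strand = "-", id = "x1")
  )
  r2$class <- "trans_encoded"
  r2$secondary <- ""
  tagged2 <- assign_locus_tags(r2, ann)
  d <- as.integer(substr(tagged2$locus_tag, 9, 9))
  expect_equal(length(unique(d)), 2L)
  # position order: x1 (lower coordinate) gets the smaller digit
  expect_lt(d[tagged2$id == "x1"], d[tagged2$id == "x2"])

  # leaders stay untagged
  r3 <- region_row(8000L, 8100L)
  r3$class <- "mRNA_leader"
  r3$secondary <- ""
  expect_true(is.na(assign_locus_tags(r3, ann)$locus_tag))
})

test_that("more than nine features between a CDS pair is an error", {
  ann <- tiny_annotation(
    list(tag = "cg0010", strand = "-", start = 1000L, end = 1900L),
    list(tag = "cg0012", strand = "-", start = 9000L, end = 9900L)
  )
  r <- dplyr::bind_rows(lapply(1:10, function(i) {
    region_row(2000L + i * 300L, 2040L + i * 300L, id = paste0("r", i))
  }))
  r$class <- "trans_encoded"
  r$secondary <- ""
  expect_error(assign_locus_tags(r, ann), "manual")
})

test_that("length statistics report mean/median/quartiles per class", {
  regions <- tibble::tibble(
    class = c("asRNA", "asRNA", "trans_encoded"),
    length = c(50L, 60L, 90L)
  )
  st <- length_stats(regions)
  expect_equal(st$mean[st$class == "asRNA"], 55)
  expect_equal(st$median[st$class == "trans_encoded"], 90)
  expect_equal(st$n[st$class == "mRNA_leader"], 0L)
  expect_true(is.na(st$mean[st$class == "mRNA_leader"]))
})
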