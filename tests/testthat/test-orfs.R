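# Small-ORF detection, RBS/leaderless calls and leader-peptide runs.

# reverse-translation helper with fixed codon choices
codons_for <- function(peptide) {
  table <- c(A = "GCT", E = "GAA", K = "AAA", S = "TCT", Q = "CAA",
             R = "CGT", D = "GAT", Y = "TAT", L = "CTT", M = "ATG",
             W = "TGG", F = "TTT", V = "GTT", T = "ACT", G = "GGT")
  paste(table[strsplit(peptide, "")[[1]]], collapse = "")
}

test_that("the 48 nt boundary separates accepted and rejected ORFs", {
  # ATG + 14 codons + TAA = 48 nt -> 15 aa peptide
  orf48 <- paste0("ATG", strrep("GCT", 14), "TAA")
  hits <- find_small_orfs(paste0("GGG", orf48, "GGG"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$nt_len, 48L)
  expect_equal(nchar(hits$peptide), 15L)
  expect_equal(hits$peptide, paste0("M", strrep("A", 14)))

  # 45 nt: rejected
  orf45 <- paste0("ATG", strrep("GCT", 13), "TAA")
  expect_equal(nrow(find_small_orfs(paste0("GGG", orf45, "GGG"))), 0L)
})

test_that("GTG/TTG starts are accepted and translated as methionine", {
  orf <- paste0("GTG", strrep("GCT", 14), "TAA")
  hits <- find_small_orfs(orf)
  expect_equal(substr(hits$peptide, 1, 1), "M")
})

test_that("ORF finding matches a brute-force 3-frame codon scan", {
  oracle <- function(s, min_nt = 48L, max_nt = 249L) {
    n <- nchar(s)
    found <- list()
    for (p in seq_len(max(0, n - 2))) {
      if (!substr(s, p, p + 2) %in% c("ATG", "GTG", "TTG")) next
      q <- p + 3
      while (q + 2 <= n && !substr(s, q, q + 2) %in% c("TAA", "TAG", "TGA")) {
        q <- q + 3
      }
      if (q + 2 > n) next
      len <- q + 2 - p + 1
      if (len >= min_nt && len <= max_nt) {
        found[[length(found) + 1]] <- c(p, q + 2)
      }
    }
    found
  }
  set.seed(61)
  for (i in 1:20) {
    s <- paste(sample(BASES4, 400, replace = TRUE), collapse = "")
    got <- find_small_orfs(s)
    exp <- oracle(s)
    expect_equal(nrow(got), length(exp))
    if (length(exp) > 0) {
      expect_equal(got$start, vapply(exp, `[`, 0, 1))
      expect_equal(got$end, vapply(exp, `[`, 0, 2))
    }
  }
})

test_that("a constructed frame encoding the tmRNA tag translates exactly", {
  tag <- "AEKSQRDYALAA"
  dna <- codons_for(tag)
  expect_equal(translate_orf(dna, init = FALSE), tag)
})

test_that("RBS matches and leaderless starts gate small-mRNA calls", {
  set.seed(67)
  bg <- sample(BASES4, 400, replace = TRUE)
  orf <- paste0("ATG", strrep("GCT", 14), "TAA")
  # plant an ORF at region position 30 with AGGAG ending 9 nt before it
  g <- bg
  orf_at <- 130L
  g[orf_at:(orf_at + 47L)] <- strsplit(orf, "")[[1]]
  g[(orf_at - 9L):(orf_at - 5L)] <- c("A", "G", "G", "A", "G")
  g[(orf_at - 4L):(orf_at - 1L)] <- c("C", "C", "C", "C")  # no stray starts
  genome <- Biostrings::DNAString(paste(g, collapse = ""))
  regions <- tibble::tibble(id = "r1", strand = "+", tss = 101L,
                            three_prime = 220L)
  calls <- call_small_mrnas(regions, genome)
  hit <- calls[calls$orf_start == orf_at, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$rbs, "AGGAG")
  expect_false(hit$leaderless)

  # leaderless: TSS exactly at the A of the start codon, no RBS needed
  g2 <- sample(c("C", "G"), 400, replace = TRUE)
  g2[101:148] <- strsplit(orf, "")[[1]]
  calls2 <- call_small_mrnas(
    tibble::tibble(id = "r1", strand = "+", tss = 101L, three_prime = 200L),
    Biostrings::DNAString(paste(g2, collapse = ""))
  )
  expect_equal(nrow(calls2), 1L)
  expect_true(calls2$leaderless)
})

test_that("leader-peptide homopolymer runs are reported", {
  pep_trp <- paste0("M", strrep("A", 5), strrep("W", 3), strrep("A", 6))
  pep_leu <- paste0("M", strrep("A", 4), strrep("L", 4), strrep("A", 6))
  runs_w <- srnascan:::residue_runs(pep_trp)
  expect_true(any(runs_w$residue == "W" & runs_w$run == 3L))
  runs_l <- srnascan:::residue_runs(pep_leu)
  expect_true(any(runs_l$residue == "L" & runs_l$run == 4L))
})

test_that("minus-strand regions are searched on their sense strand", {
  orf <- paste0("ATG", strrep("GCT", 14), "TAA")
  # build a minus-strand region: genome carries the reverse complement
  insert <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(orf)))
  g <- rep("C", 300)
  g[101:148] <- strsplit(insert, "")[[1]]
  genome <- Biostrings::DNAString(paste(g, collapse = ""))
  regions <- tibble::tibble(id = "r1", strand = "-", tss = 148L,
                            three_prime = 90L)
  calls <- call_small_mrnas(regions, genome)
  expect_equal(nrow(calls), 1L)
  expect_true(calls$leaderless)
  expect_equal(calls$peptide, paste0("M", strrep("A", 14)))
})
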