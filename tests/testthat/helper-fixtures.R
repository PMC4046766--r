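# Shared fixtures: planted promoter sites, windows, tiny annotations and a
# memoized trained model / synthetic world so expensive objects are built
# once per test run.

BASES4 <- c("A", "C", "G", "T")

plant_motif <- function(x, consensus, at, p = 0.95) {
  cons <- strsplit(consensus, "")[[1]]
  for (j in seq_along(cons)) {
    x[at + j - 1] <- if (runif(1) < p) cons[j] else sample(BASES4, 1)
  }
  x
}

# Equal-length training site with -35/-10 boxes at a random offset and
# spacer drawn from `spacer_range`; returns the sequence and the planted
# coordinates.
make_training_site <- function(len = 50L, p = 0.95, spacer_range = 16:20) {
  s <- spacer_range[[sample(length(spacer_range), 1)]]
  a <- sample(seq_len(len - (12 + s) + 1), 1)
  x <- sample(BASES4, len, replace = TRUE)
  x <- plant_motif(x, "TTGACA", a, p)
  x <- plant_motif(x, "TATAAT", a + 6 + s, p)
  list(seq = paste(x, collapse = ""), a35 = a, a10 = a + 6 + s, spacer = s)
}

# 60 nt TSS-upstream window with a promoter planted at gap 5-8 nt from the
# window end (i.e. from the TSS).
make_promoter_window <- function(spacer_range = 16:20, p = 0.95,
                                 len = 60L) {
  s <- spacer_range[[sample(length(spacer_range), 1)]]
  g <- sample(5:8, 1)
  a <- len - (12 + s + g) + 1
  x <- sample(BASES4, len, replace = TRUE)
  x <- plant_motif(x, "TTGACA", a, p)
  x <- plant_motif(x, "TATAAT", a + 6 + s, p)
  paste(x, collapse = "")
}

# Memoized expensive fixtures --------------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# 158 planted SigA training sites plus the planted-position count matrices
# (the independent oracle for EM recovery).
trained_sites <- function() {
  memo("sites", {
    set.seed(4242)
    raw <- lapply(seq_len(158), function(i) make_training_site())
    counts35 <- matrix(0, 4, 6, dimnames = list(BASES4, NULL))
    counts10 <- matrix(0, 4, 6, dimnames = list(BASES4, NULL))
    for (site in raw) {
      ch <- strsplit(site$seq, "")[[1]]
      for (j in 1:6) {
        counts35[ch[site$a35 + j - 1], j] <-
          counts35[ch[site$a35 + j - 1], j] + 1
        counts10[ch[site$a10 + j - 1], j] <-
          counts10[ch[site$a10 + j - 1], j] + 1
      }
    }
    list(seqs = vapply(raw, `[[`, "", "seq"),
         counts35 = counts35, counts10 = counts10)
  })
}

trained_model <- function() {
  memo("model", train_promoter_model(trained_sites()$seqs, "SigA",
                                     seed = 7L))
}

# Small synthetic world + pipeline run shared across module tests.
small_world <- function() {
  memo("world", {
    cfg <- synthetic_config(
      genome_length = 60000L,
      counts = c(leader = 3L, asRNA = 4L, as5UTR = 2L, as3UTR = 2L,
                 trans = 5L)
    )
    generate_world(cfg, seed = 5L)
  })
}

small_alignments <- function() {
  memo("aln", simulate_libraries(small_world(), seed = 5L))
}

small_pipeline <- function() {
  memo("pipeline", {
    w <- small_world()
    aln <- small_alignments()
    suppressMessages(run_pipeline(
      w$genome, w$annotation,
      aln[aln$library == 1, ], aln[aln$library == 2, ],
      promoter_models = list(w$promoter_model),
      conservation = w$truth_windows
    ))
  })
}

# Study-condition world (the acceptance conditions) -----------------------

study_world <- function() {
  memo("study_world", generate_world(synthetic_config(), seed = 101L))
}

study_pipeline <- function() {
  memo("study_pipeline", {
    w <- study_world()
    aln <- simulate_libraries(w, seed = 101L)
    suppressMessages(run_pipeline(
      w$genome, w$annotation,
      aln[aln$library == 1, ], aln[aln$library == 2, ],
      promoter_models = list(w$promoter_model),
      conservation = w$truth_windows
    ))
  })
}

# Tiny annotation helper: CDS (and optional rRNA/tRNA) rows.
tiny_annotation <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(seqname = "chr", type = r$type %||% "CDS",
                   locus_tag = r$tag, strand = r$strand,
                   start = r$start, end = r$end, product = NA_character_)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
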