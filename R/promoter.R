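# Sigma-factor promoter models: two-box (-35/-10) position weight matrices
# trained by expectation maximization, score thresholds from shuffled-sequence
# control runs, and the upstream-window scanner that gates TSS candidates.

BASES <- c("A", "C", "G", "T")

# DNA string -> integer vector (A=1, C=2, G=3, T=4)
encode_dna <- function(x) {
  v <- match(strsplit(toupper(x), "")[[1]], BASES)
  if (anyNA(v)) stop("sequence contains non-ACGT character", call. = FALSE)
  v
}

decode_dna <- function(v) paste(BASES[v], collapse = "")

# Score a motif (log-odds matrix, 4 x w) at every valid start of an encoded
# sequence. Returns numeric vector of length n - w + 1.
score_motif <- function(s, lo) {
  w <- ncol(lo)
  n <- length(s)
  if (n < w) return(numeric(0))
  p <- seq_len(n - w + 1)
  sc <- numeric(length(p))
  for (j in seq_len(w)) sc <- sc + lo[s[p + j - 1L], j]
  sc
}

pwm_logodds <- function(pwm, bg) log2(pwm / bg)

pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm, 2, which.max)], collapse = "")
}

new_promoter_model <- function(sigma, pwm35, pwm10, pwm_ext10, background,
                               spacer_range, thresholds = NULL,
                               loglik = NA_real_, iterations = NA_integer_,
                               converged = NA) {
  structure(
    list(sigma = sigma, pwm35 = pwm35, pwm10 = pwm10, pwm_ext10 = pwm_ext10,
         background = background, spacer_range = as.integer(spacer_range),
         thresholds = thresholds, loglik = loglik, iterations = iterations,
         converged = converged),
    class = "promoter_model"
  )
}

#' @export
print.promoter_model <- function(x, ...) {
  cat("<promoter_model>", x$sigma,
      "| -35:", pwm_consensus(x$pwm35),
      "| -10:", pwm_consensus(x$pwm10),
      if (!is.null(x$pwm_ext10)) paste("| ext-10:", pwm_consensus(x$pwm_ext10))
      else "",
      "| spacer", paste(x$spacer_range, collapse = "-"), "\n")
  if (!is.null(x$thresholds)) {
    cat("  thresholds: -10 >=", signif(x$thresholds$minus10, 4),
        ", -35 >=", signif(x$thresholds$minus35, 4),
        if (!is.na(x$thresholds$ext10)) paste(", ext-10 >=",
                                              signif(x$thresholds$ext10, 4)),
        "\n")
  }
  invisible(x)
}

#' Consensus string of a promoter box
#'
#' @param model A `promoter_model`.
#' @param box One of `"minus35"`, `"minus10"`, `"ext10"`.
#' @return Consensus string (most probable base per column).
#' @export
model_consensus <- function(model, box = c("minus10", "minus35", "ext10")) {
  box <- match.arg(box)
  pwm <- switch(box, minus35 = model$pwm35, minus10 = model$pwm10,
                ext10 = model$pwm_ext10)
  if (is.null(pwm)) stop("model has no ", box, " matrix", call. = FALSE)
  pwm_consensus(pwm)
}

# Enumerate valid (-35 start a, spacer s) placements for sequence length L.
placements <- function(L, w35, w10, spacer_range) {
  out <- list()
  for (s in seq(spacer_range[1], spacer_range[2])) {
    a_max <- L - (w35 + s + w10) + 1L
    if (a_max >= 1L) out[[length(out) + 1L]] <-
        cbind(a = seq_len(a_max), s = s)
  }
  do.call(rbind, out)
}

#' Train a two-box sigma-factor promoter model by expectation maximization
#'
#' Fits -35 and -10 position weight matrices to a set of equal-length
#' promoter-containing sequences. Each sequence is assumed to contain exactly
#' one occurrence of each box, with the spacer between them marginalized over
#' `spacer_range` (16-20 bp by default). The extended -10 matrix (the 8 nt
#' immediately upstream of the -10 box, SigA only) is estimated from the
#' posterior alignment after convergence. Score thresholds are calibrated on
#' `n_control` runs over per-run shuffles of the training sequences: every
#' threshold is derived from the best score a control run produces — the
#' per-box and combined (joint two-box) thresholds are the means of the
#' per-run best scores, and the extended -10 threshold is the maximum best
#' extended -10 score seen in any control run.
#'
#' @param training_sites Character vector of at least 20 equal-length DNA
#'   sequences containing the promoter.
#' @param sigma `"SigA"` (housekeeping; extended -10 trained) or `"SigH"`
#'   (ECF stress sigma factor; no extended -10).
#' @param w35,w10,w_ext Box widths in nt.
#' @param spacer_range Allowed -35/-10 spacer lengths in bp.
#' @param pseudocount Per-base pseudocount added to expected counts.
#' @param max_iter,tol EM iteration cap and absolute log-likelihood
#'   convergence tolerance.
#' @param n_restarts Random restarts; the fit with the best log-likelihood is
#'   kept.
#' @param n_control Number of shuffled-sequence control runs for threshold
#'   calibration.
#' @param seed Integer seed controlling initialization, restarts and control
#'   shuffles.
#' @return A `promoter_model` with probability matrices (`pwm35`, `pwm10`,
#'   `pwm_ext10`), background frequencies, spacer range, thresholds, and fit
#'   diagnostics. If the EM does not converge within `max_iter`, an error of
#'   class `srnascan_em_nonconvergence` is thrown carrying the best-so-far
#'   model in its `model` field.
#' @export
train_promoter_model <- function(training_sites, sigma = c("SigA", "SigH"),
                                 w35 = 6L, w10 = 6L, w_ext = 8L,
                                 spacer_range = c(16L, 20L),
                                 pseudocount = 0.25, max_iter = 200L,
                                 tol = 1e-6, n_restarts = 4L,
                                 n_control = 30L, seed = 1L) {
  sigma <- match.arg(sigma)
  if (length(training_sites) < 20) {
    stop("need at least 20 training sequences, got ", length(training_sites),
         call. = FALSE)
  }
  lens <- nchar(training_sites)
  if (length(unique(lens)) != 1) {
    stop("training sequences must have uniform length", call. = FALSE)
  }
  L <- lens[1]
  min_len <- w35 + spacer_range[1] + w10
  if (L < min_len) {
    stop("training sequences shorter than one full promoter (", min_len,
         " nt)", call. = FALSE)
  }
  S <- lapply(training_sites, encode_dna)
  bg <- tabulate(unlist(S), nbins = 4)
  bg <- (bg + 1) / sum(bg + 4)
  pl <- placements(L, w35, w10, spacer_range)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, r))
    fit <- em_two_box(S, L, w35, w10, spacer_range, pl, bg, pseudocount,
                      max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  pwm_ext10 <- if (sigma == "SigA") {
    ext10_from_posterior(S, best$post, w_ext, pseudocount)
  } else NULL

  model <- new_promoter_model(sigma, best$pwm35, best$pwm10, pwm_ext10, bg,
                              spacer_range, thresholds = NULL,
                              loglik = best$loglik,
                              iterations = best$iterations,
                              converged = best$converged)
  model$thresholds <- control_thresholds(
    model,
    make_control = function(run) {
      set.seed(derive_seed(seed, 1000L + run))
      lapply(S, sample)
    },
    n_control = n_control
  )
  if (!best$converged) {
    rlang::abort(
      paste0("EM did not converge within ", max_iter, " iterations"),
      class = "srnascan_em_nonconvergence", model = model
    )
  }
  model
}

# Core EM loop over encoded sequences. Returns pwms, loglik trace end state
# and the final per-sequence posterior over (-10 start) and (-35 start).
em_two_box <- function(S, L, w35, w10, spacer_range, pl, bg, pseudocount,
                       max_iter, tol) {
  n <- length(S)
  # init: one random placement per sequence
  init_counts <- function(width, starts) {
    cnt <- matrix(pseudocount, 4, width)
    for (i in seq_len(n)) {
      for (j in seq_len(width)) {
        b <- S[[i]][starts[i] + j - 1L]
        cnt[b, j] <- cnt[b, j] + 1
      }
    }
    sweep(cnt, 2, colSums(cnt), "/")
  }
  pick <- pl[sample(nrow(pl), n, replace = TRUE), , drop = FALSE]
  pwm35 <- init_counts(w35, pick[, "a"])
  pwm10 <- init_counts(w10, pick[, "a"] + w35 + pick[, "s"])

  a_vals <- pl[, "a"]
  p10_vals <- pl[, "a"] + w35 + pl[, "s"]
  ll_prev <- -Inf
  converged <- FALSE
  post <- NULL
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    lo35 <- pwm_logodds(pwm35, bg)
    lo10 <- pwm_logodds(pwm10, bg)
    c35 <- matrix(pseudocount, 4, w35)
    c10 <- matrix(pseudocount, 4, w10)
    ll <- 0
    post <- vector("list", n)
    for (i in seq_len(n)) {
      sc <- score_motif(S[[i]], lo35)[a_vals] +
            score_motif(S[[i]], lo10)[p10_vals]
      m <- max(sc)
      w <- exp((sc - m) * log(2))
      tot <- sum(w)
      ll <- ll + (m * log(2) + log(tot))
      w <- w / tot
      wa <- rowsum(w, a_vals)
      wp <- rowsum(w, p10_vals)
      ua <- as.integer(rownames(wa)); up <- as.integer(rownames(wp))
      for (j in seq_len(w35)) {
        t <- rowsum(wa[, 1], S[[i]][ua + j - 1L])
        c35[as.integer(rownames(t)), j] <-
          c35[as.integer(rownames(t)), j] + t[, 1]
      }
      for (j in seq_len(w10)) {
        t <- rowsum(wp[, 1], S[[i]][up + j - 1L])
        c10[as.integer(rownames(t)), j] <-
          c10[as.integer(rownames(t)), j] + t[, 1]
      }
      post[[i]] <- list(p10 = up, w10 = wp[, 1])
    }
    pwm35 <- sweep(c35, 2, colSums(c35), "/")
    pwm10 <- sweep(c10, 2, colSums(c10), "/")
    if (ll - ll_prev < tol && iter > 1L) {
      converged <- TRUE
      ll_prev <- ll
      break
    }
    ll_prev <- ll
  }
  list(pwm35 = pwm35, pwm10 = pwm10, loglik = ll_prev, iterations = iter,
       converged = converged, post = post, S = S)
}

# Expected-count extended -10 matrix: the w_ext nt immediately upstream of
# the -10 box, weighted by the posterior over -10 placements.
ext10_from_posterior <- function(S, post, w_ext, pseudocount) {
  cnt <- matrix(pseudocount, 4, w_ext)
  for (i in seq_along(S)) {
    p10 <- post[[i]]$p10
    w <- post[[i]]$w10
    ok <- p10 > w_ext
    for (k in which(ok)) {
      for (j in seq_len(w_ext)) {
        b <- S[[i]][p10[k] - w_ext + j - 1L]
        cnt[b, j] <- cnt[b, j] + w[k]
      }
    }
  }
  sweep(cnt, 2, colSums(cnt), "/")
}

# Best joint two-box placement of a model in one encoded sequence. The
# placement maximizes the weaker box score (both boxes must be recognized by
# the sigma factor), with the joint score as tie-break; the best joint score
# over all placements is reported alongside.
best_placement <- function(s, lo35, lo10, w35, w10, spacer_range) {
  L <- length(s)
  pl <- placements(L, w35, w10, spacer_range)
  if (is.null(pl)) return(NULL)
  sc35 <- score_motif(s, lo35)
  sc10 <- score_motif(s, lo10)
  a35 <- sc35[pl[, "a"]]
  a10 <- sc10[pl[, "a"] + w35 + pl[, "s"]]
  tot <- a35 + a10
  k <- which.max(pmin(a35, a10) + 1e-9 * tot)
  list(a = pl[k, "a"], s = pl[k, "s"], p10 = pl[k, "a"] + w35 + pl[k, "s"],
       s35 = a35[k], s10 = a10[k], total = tot[k], best_total = max(tot))
}

# Best extended-(-10) placement: maximizes ext10 + -10 score over all -10
# starts with room for the w_ext upstream extension.
best_ext10_placement <- function(s, lo10, lo_ext, w10) {
  L <- length(s)
  w_ext <- ncol(lo_ext)
  if (L - w10 + 1L < w_ext + 1L) return(NULL)
  p10 <- seq.int(w_ext + 1L, L - w10 + 1L)
  sc10 <- score_motif(s, lo10)
  sce <- score_motif(s, lo_ext)
  e <- sce[p10 - w_ext]
  tot <- e + sc10[p10]
  k <- which.max(tot)
  list(p10 = p10[k], s10 = sc10[p10[k]], ext = e[k], emax = max(e))
}

# Threshold calibration shared by trained and hand-specified models.
# make_control(run) must return a list of encoded control sequences.
control_thresholds <- function(model, make_control, n_control = 30L) {
  lo35 <- pwm_logodds(model$pwm35, model$background)
  lo10 <- pwm_logodds(model$pwm10, model$background)
  lo_ext <- if (!is.null(model$pwm_ext10)) {
    pwm_logodds(model$pwm_ext10, model$background)
  } else NULL
  w35 <- ncol(model$pwm35); w10 <- ncol(model$pwm10)
  m35 <- m10 <- mtot <- numeric(n_control)
  emax <- -Inf
  for (r in seq_len(n_control)) {
    ctrl <- make_control(r)
    b35 <- b10 <- btot <- numeric(length(ctrl))
    for (i in seq_along(ctrl)) {
      b35[i] <- max(score_motif(ctrl[[i]], lo35))
      b10[i] <- max(score_motif(ctrl[[i]], lo10))
      bp <- best_placement(ctrl[[i]], lo35, lo10, w35, w10,
                           model$spacer_range)
      btot[i] <- bp$best_total
      if (!is.null(lo_ext)) {
        be <- best_ext10_placement(ctrl[[i]], lo10, lo_ext, w10)
        if (!is.null(be)) emax <- max(emax, be$emax)
      }
    }
    m35[r] <- max(b35); m10[r] <- max(b10); mtot[r] <- max(btot)
  }
  list(minus35 = mean(m35), minus10 = mean(m10), combined = mean(mtot),
       ext10 = if (is.null(lo_ext)) NA_real_ else emax)
}

#' Scan the upstream window of a TSS for a promoter
#'
#' Extracts the strand-aware window ending one nt before the TSS and looks for
#' the best-scoring -35/-10 box pair with a spacer inside the model's range.
#' A hit requires both box scores to reach their control-run thresholds and
#' the joint score to beat the mean best score of the control runs. For
#' SigA, where the -35 box is often poorly conserved, a second chance is
#' given: if the extended -10 (the 8 nt immediately upstream of a -10 box
#' that itself passes its threshold) scores at or above the maximum control
#' score, a hit is reported regardless of the -35 score (`via_extended10`).
#'
#' @param model A `promoter_model` with calibrated thresholds.
#' @param genome A [Biostrings::DNAString] (or single-entry DNAStringSet).
#' @param tss TSS position (1-based, first transcribed base).
#' @param strand `"+"` or `"-"`.
#' @param window Upstream window length in nt (default 60).
#' @return One-row tibble (`sigma`, `minus35_pos`, `minus35_score`,
#'   `minus10_pos`, `minus10_score`, `spacer`, `ext10_score`,
#'   `via_extended10`) or a zero-row tibble when there is no hit. Positions
#'   are the genomic coordinate of the box's 5'-most base in promoter
#'   orientation.
#' @export
scan_promoter <- function(model, genome, tss, strand, window = 60L) {
  genome <- as_dnastring(genome)
  L <- length(genome)
  w35 <- ncol(model$pwm35); w10 <- ncol(model$pwm10)
  min_len <- w35 + model$spacer_range[1] + w10
  if (strand == "+") {
    from <- tss - window; to <- tss - 1L
  } else {
    from <- tss + 1L; to <- tss + window
  }
  if (from < 1L || to > L || to - from + 1L < min_len) {
    warning("TSS ", tss, strand, ": upstream window truncated, no promoter call")
    return(empty_promoter_hit())
  }
  wseq <- extract_oriented(genome, from, to, strand)
  s <- encode_dna(wseq)
  n <- length(s)
  to_genomic <- function(wpos) {
    if (strand == "+") from + wpos - 1L else to - wpos + 1L
  }
  lo35 <- pwm_logodds(model$pwm35, model$background)
  lo10 <- pwm_logodds(model$pwm10, model$background)
  thr <- model$thresholds
  bp <- best_placement(s, lo35, lo10, w35, w10, model$spacer_range)
  if (!is.null(bp) && bp$s35 >= thr$minus35 && bp$s10 >= thr$minus10 &&
      bp$total >= thr$combined) {
    return(tibble(
      sigma = model$sigma,
      minus35_pos = to_genomic(bp$a), minus35_score = bp$s35,
      minus10_pos = to_genomic(bp$p10), minus10_score = bp$s10,
      spacer = as.integer(bp$s), ext10_score = NA_real_,
      via_extended10 = FALSE
    ))
  }
  if (!is.null(model$pwm_ext10) && !is.na(thr$ext10)) {
    lo_ext <- pwm_logodds(model$pwm_ext10, model$background)
    be <- best_ext10_placement(s, lo10, lo_ext, w10)
    if (!is.null(be) && be$ext >= thr$ext10 && be$s10 >= thr$minus10) {
      return(tibble(
        sigma = model$sigma,
        minus35_pos = NA_integer_, minus35_score = NA_real_,
        minus10_pos = to_genomic(be$p10), minus10_score = be$s10,
        spacer = NA_integer_, ext10_score = be$ext,
        via_extended10 = TRUE
      ))
    }
  }
  empty_promoter_hit()
}

#' Best two-box score of a TSS upstream window
#'
#' Returns the best joint -35/-10 score (spacer constrained to the model's
#' range) of the window upstream of a TSS, without applying any threshold —
#' the raw quantity the calibrated thresholds are compared against.
#'
#' @inheritParams scan_promoter
#' @return Best joint score (numeric scalar), or `NA` if no window.
#' @export
score_promoter_window <- function(model, genome, tss, strand, window = 60L) {
  genome <- as_dnastring(genome)
  L <- length(genome)
  if (strand == "+") {
    from <- tss - window; to <- tss - 1L
  } else {
    from <- tss + 1L; to <- tss + window
  }
  min_len <- ncol(model$pwm35) + model$spacer_range[1] + ncol(model$pwm10)
  if (from < 1L || to > L || to - from + 1L < min_len) return(NA_real_)
  s <- encode_dna(extract_oriented(genome, from, to, strand))
  bp <- best_placement(s, pwm_logodds(model$pwm35, model$background),
                       pwm_logodds(model$pwm10, model$background),
                       ncol(model$pwm35), ncol(model$pwm10),
                       model$spacer_range)
  if (is.null(bp)) NA_real_ else bp$best_total
}

empty_promoter_hit <- function() {
  tibble(sigma = character(), minus35_pos = integer(),
         minus35_score = numeric(), minus10_pos = integer(),
         minus10_score = numeric(), spacer = integer(),
         ext10_score = numeric(), via_extended10 = logical())
}

#' Annotate TSS candidates with promoter hits
#'
#' Runs [scan_promoter()] for every candidate against every supplied model.
#' A TSS may carry hits from more than one sigma factor.
#'
#' @param candidates [detect_tss()] output.
#' @param genome DNAString(Set) of the chromosome.
#' @param models List of `promoter_model` objects.
#' @param window Upstream window length in nt.
#' @return Tibble of promoter hits joined to the candidate columns (one row
#'   per candidate x matching model).
#' @export
scan_promoters <- function(candidates, genome, models, window = 60L) {
  genome <- as_dnastring(genome)
  if (!is.list(models) || inherits(models, "promoter_model")) {
    models <- list(models)
  }
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    for (m in models) {
      hit <- scan_promoter(m, genome, candidates$position[i],
                           candidates$strand[i], window)
      if (nrow(hit) == 1) {
        rows[[length(rows) + 1L]] <-
          dplyr::bind_cols(candidates[i, ], hit)
      }
    }
  }
  if (length(rows) == 0) {
    return(dplyr::bind_cols(candidates[0, ], empty_promoter_hit()))
  }
  bind_rows(rows)
}

as_dnastring <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    if (length(genome) != 1) {
      stop("expected a single-chromosome genome", call. = FALSE)
    }
    genome <- genome[[1]]
  }
  if (!inherits(genome, "DNAString")) genome <- Biostrings::DNAString(genome)
  genome
}

#' Build a promoter model from consensus frequencies
#'
#' Constructs a `promoter_model` directly from consensus strings with a fixed
#' per-position probability for the consensus base (rest spread uniformly),
#' and calibrates its thresholds on random background sequence. Used by the
#' synthetic-data generator to plant promoters and as a reference model in
#' tests.
#'
#' @param sigma `"SigA"` or `"SigH"`.
#' @param consensus35,consensus10 Box consensus strings.
#' @param ext10_probs Optional 4 x w matrix for the extended -10; the default
#'   SigA extension is uninformative except for a TG dinucleotide just
#'   upstream of the -10 box.
#' @param strength Probability of the consensus base at each position.
#' @param gc Background GC fraction used for threshold calibration.
#' @param n_control,control_n,control_len Control-run geometry for threshold
#'   calibration.
#' @param seed Integer seed.
#' @return A calibrated `promoter_model`.
#' @export
consensus_promoter_model <- function(sigma = c("SigA", "SigH"),
                                     consensus35 = NULL, consensus10 = NULL,
                                     ext10_probs = NULL, strength = 0.85,
                                     gc = 0.54, n_control = 30L,
                                     control_n = 60L, control_len = 60L,
                                     seed = 1L) {
  sigma <- match.arg(sigma)
  if (is.null(consensus35)) {
    consensus35 <- if (sigma == "SigA") "TTGACA" else "GGAACA"
  }
  if (is.null(consensus10)) {
    consensus10 <- if (sigma == "SigA") "TATAAT" else "GTTGAA"
  }
  pwm_from_consensus <- function(cons) {
    v <- encode_dna(cons)
    pwm <- matrix((1 - strength) / 3, 4, length(v))
    pwm[cbind(v, seq_along(v))] <- strength
    pwm
  }
  pwm35 <- pwm_from_consensus(consensus35)
  pwm10 <- pwm_from_consensus(consensus10)
  pwm_ext10 <- NULL
  if (sigma == "SigA") {
    if (is.null(ext10_probs)) {
      pwm_ext10 <- matrix(0.25, 4, 8)
      pwm_ext10[, 6] <- c(0.05, 0.05, 0.1, 0.8)   # T
      pwm_ext10[, 7] <- c(0.05, 0.05, 0.8, 0.1)   # G
    } else {
      pwm_ext10 <- ext10_probs
    }
  }
  bg <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  model <- new_promoter_model(sigma, pwm35, pwm10, pwm_ext10, bg,
                              c(16L, 20L))
  model$thresholds <- control_thresholds(
    model,
    make_control = function(run) {
      set.seed(derive_seed(seed, 2000L + run))
      lapply(seq_len(control_n),
             function(i) sample(1:4, control_len, replace = TRUE, prob = bg))
    },
    n_control = n_control
  )
  model$converged <- TRUE
  model
}

#' @describeIn train_promoter_model Tidy the model matrices into a long
#'   tibble (`matrix`, `position`, `base`, `prob`).
#' @param x A `promoter_model`.
#' @param ... Unused.
#' @method tidy promoter_model
#' @export
tidy.promoter_model <- function(x, ...) {
  one <- function(pwm, nm) {
    tibble(matrix = nm,
           position = rep(seq_len(ncol(pwm)), each = 4),
           base = rep(BASES, ncol(pwm)),
           prob = as.vector(pwm))
  }
  out <- bind_rows(one(x$pwm35, "minus35"), one(x$pwm10, "minus10"))
  if (!is.null(x$pwm_ext10)) out <- bind_rows(out, one(x$pwm_ext10, "ext10"))
  out
}

#' @describeIn train_promoter_model One-row fit summary (consensus strings,
#'   log-likelihood, iterations, thresholds).
#' @method glance promoter_model
#' @export
glance.promoter_model <- function(x, ...) {
  tibble(
    sigma = x$sigma,
    consensus35 = pwm_consensus(x$pwm35),
    consensus10 = pwm_consensus(x$pwm10),
    loglik = x$loglik,
    iterations = x$iterations,
    converged = x$converged,
    thr_minus35 = x$thresholds$minus35 %||% NA_real_,
    thr_minus10 = x$thresholds$minus10 %||% NA_real_,
    thr_ext10 = x$thresholds$ext10 %||% NA_real_
  )
}

#' Write / read a promoter model as plain text
#'
#' Serializes the probability matrices, background, spacer range and
#' thresholds to a single human-readable text file.
#'
#' @param model A `promoter_model`.
#' @param path File path.
#' @return `path` invisibly (writer); a `promoter_model` (reader).
#' @export
write_promoter_model <- function(model, path) {
  fmt <- function(m) apply(m, 1, function(r) paste(format(r, digits = 10),
                                                   collapse = "\t"))
  lines <- c(
    paste0("#sigma\t", model$sigma),
    paste0("#spacer\t", model$spacer_range[1], "\t", model$spacer_range[2]),
    paste0("#background\t", paste(format(model$background, digits = 10),
                                  collapse = "\t")),
    paste0("#thresholds\t",
           paste(format(c(model$thresholds$minus35, model$thresholds$minus10,
                          model$thresholds$combined, model$thresholds$ext10),
                        digits = 10),
                 collapse = "\t")),
    "#pwm35", fmt(model$pwm35), "#pwm10", fmt(model$pwm10)
  )
  if (!is.null(model$pwm_ext10)) lines <- c(lines, "#pwm_ext10",
                                            fmt(model$pwm_ext10))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_promoter_model
#' @export
read_promoter_model <- function(path) {
  lines <- readLines(path)
  val <- function(key) {
    strsplit(sub(paste0("^#", key, "\t"), "",
                 grep(paste0("^#", key, "\t"), lines, value = TRUE)),
             "\t")[[1]]
  }
  grab_matrix <- function(key) {
    i <- which(lines == paste0("#", key))
    if (length(i) == 0) return(NULL)
    rows <- lines[(i + 1):(i + 4)]
    m <- do.call(rbind, lapply(strsplit(rows, "\t"), as.numeric))
    rownames(m) <- NULL
    m
  }
  thr <- as.numeric(val("thresholds"))
  new_promoter_model(
    sigma = val("sigma"),
    pwm35 = grab_matrix("pwm35"), pwm10 = grab_matrix("pwm10"),
    pwm_ext10 = grab_matrix("pwm_ext10"),
    background = as.numeric(val("background")),
    spacer_range = as.integer(val("spacer")),
    thresholds = list(minus35 = thr[1], minus10 = thr[2], combined = thr[3],
                      ext10 = thr[4])
  )
}
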