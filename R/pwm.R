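# Position-weight-matrix baseline: log-odds scoring of library sequences and
# an ordinary-least-squares fit of log2 activity against PWM score. This is
# the linear point of comparison for the nonlinear network.

PWM_FLOOR <- -30  # bits; stands in for log2(0) when pseudocount = 0

#' Build a position weight matrix from equal-length sequences
#'
#' Per position and base, the weight is `log2(f / background)` where `f` is
#' the (optionally pseudocounted, optionally strength-weighted) base
#' frequency: `f = (count + pseudocount * background) / (n + pseudocount)`.
#' Zero frequencies (possible only with `pseudocount = 0`) are floored at
#' -30 bits instead of -Inf.
#'
#' @param seqs character vector (>= 2) of equal-length sequences.
#' @param pseudocount non-negative pseudocount mass (default 0.5,
#'   Jeffreys-like), spread over bases proportionally to the background.
#' @param background base frequencies in (A, G, C, T) order; default uniform.
#' @param weights optional non-negative per-sequence weights (e.g. measured
#'   strengths) for a strength-weighted matrix.
#' @return object of class `pwm_model` with `weights` (L x 4 log-odds matrix,
#'   columns A G C T), `background` and `pseudocount`.
#' @export
build_pwm <- function(seqs, pseudocount = 0.5,
                      background = c(A = 0.25, G = 0.25, C = 0.25, T = 0.25),
                      weights = NULL) {
  if (length(seqs) < 2L) fail("a PWM needs at least 2 sequences")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) fail("sequences must have equal lengths")
  if (!is_scalar_num(pseudocount) || pseudocount < 0)
    fail("pseudocount must be >= 0")
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0))
    fail("background must be 4 positive frequencies (A, G, C, T)")
  background <- background / sum(background)
  if (is.null(weights)) weights <- rep(1, length(seqs))
  if (length(weights) != length(seqs) || any(weights < 0) || sum(weights) == 0)
    fail("weights must be non-negative with positive sum")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  if (any(!m %in% BASES)) fail("sequences must contain only A/C/G/T")
  L <- ncol(m)
  W <- matrix(NA_real_, L, 4L, dimnames = list(NULL, BASES))
  n <- sum(weights)
  for (j in seq_len(4L)) {
    cnt <- colSums((m == BASES[j]) * weights)
    f <- (cnt + pseudocount * background[j]) / (n + pseudocount)
    W[, j] <- log2(f / background[j])
  }
  W[!is.finite(W)] <- PWM_FLOOR
  structure(list(weights = W, background = setNames(background, BASES),
                 pseudocount = pseudocount),
            class = "pwm_model")
}

#' Score a sequence with a PWM
#'
#' Sum over positions of the log-odds entry for the sequence's base, in bits.
#'
#' @param pwm a `pwm_model`.
#' @param seq sequence of the matrix length.
#' @return scalar score (bits); vectorized over a character vector of
#'   sequences.
#' @export
score_sequence <- function(pwm, seq) {
  stopifnot(inherits(pwm, "pwm_model"))
  L <- nrow(pwm$weights)
  if (any(nchar(seq) != L))
    fail("sequence length %d does not match PWM length %d",
         nchar(seq[nchar(seq) != L][1L]), L)
  vapply(strsplit(toupper(seq), ""), function(ch) {
    j <- match(ch, BASES)
    if (anyNA(j)) fail("sequence contains non-ACGT characters")
    sum(pwm$weights[cbind(seq_len(L), j)])
  }, numeric(1L))
}

#' Fit log activity against PWM score
#'
#' Ordinary least squares of `log2(strength + epsilon)` on the PWM score;
#' `epsilon` shifts exact zeros (present in real libraries) off -Inf.
#'
#' @param scores PWM scores.
#' @param strengths matching non-negative relative strengths.
#' @param epsilon small positive shift before the log (default 1e-3).
#' @return list with `slope`, `intercept`, `r` (Pearson correlation between
#'   score and log activity) and `n`.
#' @export
fit_log_activity <- function(scores, strengths, epsilon = 1e-3) {
  if (length(scores) != length(strengths) || length(scores) < 3L)
    fail("scores and strengths must match and have length >= 3")
  if (any(strengths < 0)) fail("strengths must be >= 0")
  if (sd(scores) == 0) fail("constant scores: fit undefined")
  la <- log2(strengths + epsilon)
  fit <- lm(la ~ scores)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r = cor(scores, la), n = length(scores))
}

#' Best PWM fit of a strength library
#'
#' Builds PWMs from several training subsets of the library — all measured
#' records, the high-activity records (strength > 1), and a strength-weighted
#' matrix over all records — scores every measured record with each, fits
#' log2 activity against score, and reports the subset with the highest
#' correlation (the "best fitting result" of the baseline).
#'
#' @param lib a [strength_library] with measured strengths.
#' @param pseudocount passed to [build_pwm()].
#' @param epsilon passed to [fit_log_activity()].
#' @return list with `best` (subset name), `fits` (per-subset fit summaries)
#'   and `pwms` (the fitted `pwm_model`s).
#' @export
fit_pwm_baseline <- function(lib, pseudocount = 0.5, epsilon = 1e-3) {
  stopifnot(inherits(lib, "strength_library"))
  keep <- !is.na(lib$relative_strength)
  seqs <- lib$sequence[keep]
  y <- lib$relative_strength[keep]
  if (length(seqs) < 3L) fail("need >= 3 measured records")
  subsets <- list(all = rep(TRUE, length(seqs)), high_activity = y > 1)
  pwms <- list()
  fits <- list()
  for (nm in names(subsets)) {
    sel <- subsets[[nm]]
    if (sum(sel) < 2L) next
    pwms[[nm]] <- build_pwm(seqs[sel], pseudocount)
    fits[[nm]] <- fit_log_activity(score_sequence(pwms[[nm]], seqs), y, epsilon)
  }
  pwms$strength_weighted <- build_pwm(seqs, pseudocount, weights = y)
  fits$strength_weighted <-
    fit_log_activity(score_sequence(pwms$strength_weighted, seqs), y, epsilon)
  rs <- vapply(fits, `[[`, numeric(1L), "r")
  best <- names(which.max(rs))
  list(best = best, fits = fits, pwms = pwms)
}

#' Write / read a PWM as a TSV matrix
#'
#' L rows by 4 columns with header `A G C T` (tab-separated).
#'
#' @param pwm a `pwm_model`.
#' @param path file path.
#' @return `write_pwm` returns `path` invisibly; `read_pwm` a `pwm_model`
#'   (background and pseudocount are not stored in the TSV and default to
#'   uniform / 0.5).
#' @export
write_pwm <- function(pwm, path) {
  stopifnot(inherits(pwm, "pwm_model"))
  df <- as.data.frame(pwm$weights)
  write.table(format(df, digits = 15), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (!identical(colnames(df), BASES)) fail("PWM TSV must have header A G C T")
  structure(list(weights = as.matrix(df),
                 background = setNames(rep(0.25, 4L), BASES),
                 pseudocount = 0.5),
            class = "pwm_model")
}
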