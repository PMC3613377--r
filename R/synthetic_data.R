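# Synthetic mutant libraries with a planted sequence-to-strength ground
# truth, emulating a 100-member error-prone-PCR promoter/RBS library curated
# for even strength coverage: strengths in [0, 3.559], wild type == 1, about
# 20% of mutants above 1.
#
# The planted map is multiplicative with a saturating (Hill-type)
# nonlinearity: each (position, alternative base) pair carries an effect e,
# a sequence's raw score is the product of (1 + e) over its mutated sites,
# and strength = s_max * r^h / (r^h + (s_max - 1)), which fixes the wild
# type (r = 1) at exactly 1 and saturates at s_max. The nonlinearity is what
# lets the network genuinely outperform the additive PWM baseline here.

hill_strength <- function(r, s_max, hill) {
  s_max * r^hill / (r^hill + (s_max - 1))
}

#' Create a planted sequence-to-strength ground truth
#'
#' Plants `n_positive_sites` strong enhancing effects (e in \[0.3, 0.8\]) and
#' `n_negative_sites` strong reducing effects (e in \[-0.8, -0.3\]) at random
#' (position, alternative base) pairs of a wild-type sequence; all remaining
#' pairs receive mild effects (normal, sd 0.02, truncated at +/-0.08). The
#' defaults (15 positive, 120 negative, sd 0.05 measurement noise, maximum
#' strength 3.559) mirror the scale of a characterized 100-member library.
#'
#' @param seed RNG seed; the whole object is deterministic given it.
#' @param L element length in nt (default 224).
#' @param n_positive_sites,n_negative_sites numbers of strong planted
#'   effects; together at most `3 * L`.
#' @param noise_sd Gaussian measurement-noise standard deviation applied by
#'   [generate_library()].
#' @param s_max maximum strength (saturation ceiling), default 3.559.
#' @param wt_seq optional wild-type sequence; defaults to the packaged
#'   synthetic 224-nt fixture when `L` is 224, otherwise a random sequence.
#' @param hill Hill exponent of the saturating nonlinearity (default 3).
#' @return object of class `ground_truth`: `wt_seq`, `effects` (L x 4 matrix,
#'   `NA` at the wild-type base), `key_sites` (the planted strong effects),
#'   `noise_sd`, `s_max`, `hill`, `seed`.
#' @export
make_ground_truth <- function(seed = 1L, L = 224L, n_positive_sites = 15L,
                              n_negative_sites = 120L, noise_sd = 0.05,
                              s_max = 3.559, wt_seq = NULL, hill = 3) {
  stopifnot(is_count(seed), is_count(L), L >= 2,
            is_count(n_positive_sites), n_positive_sites >= 0,
            is_count(n_negative_sites), n_negative_sites >= 0,
            is_scalar_num(noise_sd), noise_sd >= 0,
            is_scalar_num(s_max), s_max > 1,
            is_scalar_num(hill), hill > 0)
  if (n_positive_sites + n_negative_sites > 3L * L)
    fail("requested %d strong sites exceed capacity 3L = %d",
         n_positive_sites + n_negative_sites, 3L * L)
  if (is.null(wt_seq)) {
    if (L == 224L) {
      fa <- system.file("extdata", "trc_wt_synthetic.fa", package = "promnet")
      wt_seq <- as.character(Biostrings::readDNAStringSet(fa))[[1L]]
    } else {
      wt_seq <- with_seed(derive_seed(seed, 0L),
                          paste(sample(BASES, L, TRUE), collapse = ""))
    }
  }
  wt_seq <- toupper(wt_seq)
  if (nchar(wt_seq) != L)
    fail("wt_seq has %d nt but L = %d", nchar(wt_seq), L)
  wt_chars <- strsplit(wt_seq, "")[[1L]]
  wt_idx <- match(wt_chars, BASES)
  if (anyNA(wt_idx)) fail("wt_seq must contain only A/C/G/T")

  gt <- with_seed(seed, {
    effects <- matrix(pmin(pmax(rnorm(L * 4L, 0, 0.02), -0.08), 0.08),
                      L, 4L, dimnames = list(NULL, BASES))
    # index of every mutable (position, base) pair: 3L of them
    mutable <- which(matrix(seq_len(4L), L, 4L, byrow = TRUE) !=
                       matrix(wt_idx, L, 4L))
    strong <- sample(mutable, n_positive_sites + n_negative_sites)
    pos_ix <- strong[seq_len(n_positive_sites)]
    neg_ix <- strong[seq_len(n_negative_sites) + n_positive_sites]
    effects[pos_ix] <- runif(n_positive_sites, 0.3, 0.8)
    effects[neg_ix] <- runif(n_negative_sites, -0.8, -0.3)
    effects[cbind(seq_len(L), wt_idx)] <- NA_real_
    strong_pos <- ((strong - 1L) %% L) + 1L
    strong_base <- BASES[((strong - 1L) %/% L) + 1L]
    key_sites <- data.frame(
      position = strong_pos, to_base = strong_base,
      effect = effects[strong],
      class = rep(c("positive", "negative"),
                  c(n_positive_sites, n_negative_sites)))
    key_sites <- key_sites[order(key_sites$position, key_sites$to_base), ]
    rownames(key_sites) <- NULL
    list(effects = effects, key_sites = key_sites)
  })

  structure(list(wt_seq = wt_seq, effects = gt$effects,
                 key_sites = gt$key_sites, noise_sd = noise_sd,
                 s_max = s_max, hill = hill, seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d nt, %d strong positive + %d strong negative sites\n",
              nchar(x$wt_seq), sum(x$key_sites$class == "positive"),
              sum(x$key_sites$class == "negative")))
  cat(sprintf("  s_max %.3f, hill %.1f, noise sd %.3f\n",
              x$s_max, x$hill, x$noise_sd))
  invisible(x)
}

#' Noise-free planted strength of sequences
#'
#' Evaluates the ground-truth map: product of (1 + effect) over every
#' position where the sequence differs from the wild type, passed through the
#' saturating nonlinearity. The wild type maps to exactly 1.
#'
#' @param gt a `ground_truth`.
#' @param seqs character vector of sequences of the wild-type length.
#' @return numeric vector of true strengths in \[0, `s_max`).
#' @export
true_strength <- function(gt, seqs) {
  stopifnot(inherits(gt, "ground_truth"))
  L <- nchar(gt$wt_seq)
  if (any(nchar(seqs) != L)) fail("sequences must have the wild-type length %d", L)
  wt_chars <- strsplit(gt$wt_seq, "")[[1L]]
  vapply(strsplit(toupper(seqs), ""), function(ch) {
    d <- which(ch != wt_chars)
    if (length(d) == 0L) return(1)
    e <- gt$effects[cbind(d, match(ch[d], BASES))]
    hill_strength(prod(1 + e), gt$s_max, gt$hill)
  }, numeric(1L))
}

#' True single-mutation effects of the planted map
#'
#' Enumerates all 3L single-point mutants of the wild type and returns their
#' noise-free strengths and relative changes versus the wild type (whose true
#' strength is exactly 1), for recovery tests of the scanning pipeline.
#'
#' @param gt a `ground_truth`.
#' @return data.frame with `position`, `from_base`, `to_base`, `site_effect`
#'   (the planted multiplicative e), `true_strength` and `delta_relative`.
#' @export
true_mutation_effects <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  L <- nchar(gt$wt_seq)
  wt_chars <- strsplit(gt$wt_seq, "")[[1L]]
  pos <- rep(seq_len(L), each = 3L)
  to <- unlist(lapply(wt_chars, function(b) setdiff(BASES, b)), use.names = FALSE)
  e <- gt$effects[cbind(pos, match(to, BASES))]
  s <- hill_strength(1 + e, gt$s_max, gt$hill)
  data.frame(position = pos, from_base = wt_chars[pos], to_base = to,
             site_effect = e, true_strength = s, delta_relative = s - 1)
}

#' Generate a synthetic strength library from a planted ground truth
#'
#' Emulates building and curating a mutant library: mutants derive from the
#' wild type by per-base substitution at a per-mutant rate drawn uniformly in
#' (0, `mutation_rate`] (error-prone PCR libraries are heterogeneous, "up
#' to" the nominal rate), measured strengths are the planted truth plus
#' Gaussian noise clamped to \[0, `s_max`\], and draws are accepted into
#' strength bins so the library covers the whole range with roughly
#' `positive_fraction_target` of mutants above 1 — mirroring how real
#' libraries are picked from thousands of mostly near-dead clones. The wild
#' type is included with strength exactly 1. Reproducible from `seed`.
#'
#' Binning: each side of 1 is split into 4 equal-width bins; half of the
#' negative quota sits in the lowest bin (most random mutants of a strong
#' element are near-dead), the rest is spread evenly. If the quotas cannot be
#' filled within the attempt budget the library is returned best-effort with
#' attribute `best_effort = TRUE` and a warning.
#'
#' @param gt a `ground_truth` from [make_ground_truth()].
#' @param n library size including the wild type (default 100).
#' @param mutation_rate nominal per-base mutation rate ceiling (default 0.20).
#' @param seed RNG seed.
#' @param positive_fraction_target fraction of mutants with strength > 1
#'   (default 0.20, achieved within +/- 0.05 when attainable).
#' @return a [strength_library] with records `WT`, `m001`, `m002`, ...
#' @export
generate_library <- function(gt, n = 100L, mutation_rate = 0.20, seed = 1L,
                             positive_fraction_target = 0.20) {
  stopifnot(inherits(gt, "ground_truth"))
  if (!is_count(n) || n < 2L) fail("n must be an integer >= 2")
  if (!is_scalar_num(mutation_rate) || mutation_rate <= 0 || mutation_rate >= 1)
    fail("mutation_rate must lie strictly in (0, 1)")
  if (!is_scalar_num(positive_fraction_target) ||
      positive_fraction_target < 0 || positive_fraction_target > 1)
    fail("positive_fraction_target must lie in [0, 1]")
  L <- nchar(gt$wt_seq)
  wt_chars <- strsplit(gt$wt_seq, "")[[1L]]
  alt <- lapply(wt_chars, function(b) setdiff(BASES, b))
  n_mut <- n - 1L
  quota_pos <- round(positive_fraction_target * n_mut)
  quota_neg <- n_mut - quota_pos

  # per-side strength bins and their target counts
  neg_caps <- if (quota_neg > 0) {
    first <- ceiling(quota_neg / 2)
    rest <- quota_neg - first
    c(first, rest %/% 3 + (seq_len(3) <= rest %% 3))
  } else rep(0L, 4L)
  pos_caps <- if (quota_pos > 0)
    quota_pos %/% 4 + (seq_len(4) <= quota_pos %% 4) else rep(0L, 4L)
  neg_breaks <- seq(0, 1, length.out = 5L)
  pos_breaks <- seq(1, gt$s_max, length.out = 5L)

  max_attempts <- 400L * n
  out <- with_seed(seed, {
    seqs <- character(n_mut)
    strengths <- numeric(n_mut)
    neg_fill <- integer(4L); pos_fill <- integer(4L)
    taken <- 0L
    attempts <- 0L
    best_effort <- FALSE
    draw <- function() {
      rate <- runif(1L, 0, mutation_rate)
      hit <- which(runif(L) < rate)
      s <- if (length(hit) == 0L) gt$wt_seq else
        mutate_at(wt_chars, hit,
                  vapply(hit, function(p) alt[[p]][sample.int(3L, 1L)],
                         character(1L)))
      y <- true_strength(gt, s)
      if (gt$noise_sd > 0) y <- y + rnorm(1L, 0, gt$noise_sd)
      list(seq = s, y = min(max(y, 0), gt$s_max))
    }
    accept <- function(d, strict_bins) {
      if (d$y > 1) {
        b <- findInterval(d$y, pos_breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
        if (strict_bins && pos_fill[b] >= pos_caps[b]) return(FALSE)
        if (sum(pos_fill) >= quota_pos) return(FALSE)
        pos_fill[b] <<- pos_fill[b] + 1L
      } else {
        b <- findInterval(d$y, neg_breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
        if (strict_bins && neg_fill[b] >= neg_caps[b]) return(FALSE)
        if (sum(neg_fill) >= quota_neg) return(FALSE)
        neg_fill[b] <<- neg_fill[b] + 1L
      }
      TRUE
    }
    strict_until <- floor(0.6 * max_attempts)
    while (taken < n_mut && attempts < max_attempts) {
      attempts <- attempts + 1L
      d <- draw()
      if (accept(d, strict_bins = attempts <= strict_until)) {
        taken <- taken + 1L
        seqs[taken] <- d$seq
        strengths[taken] <- d$y
      }
    }
    while (taken < n_mut) {  # budget exhausted: fill unconditionally
      best_effort <- TRUE
      d <- draw()
      taken <- taken + 1L
      seqs[taken] <- d$seq
      strengths[taken] <- d$y
    }
    list(seqs = seqs, strengths = strengths, best_effort = best_effort)
  })
  if (out$best_effort)
    warning(sprintf(
      "positive fraction target %.2f unattainable within %d attempts; returning best-effort library",
      positive_fraction_target, max_attempts))
  ids <- c("WT", sprintf("m%03d", seq_len(n_mut)))
  lib <- strength_library(ids, c(gt$wt_seq, out$seqs), c(1, out$strengths), "WT")
  attr(lib, "best_effort") <- out$best_effort
  lib
}

#' Serialize / load a ground truth as JSON
#'
#' @param gt a `ground_truth`.
#' @param path file path.
#' @return `write_ground_truth` returns `path` invisibly; `read_ground_truth`
#'   the reconstructed `ground_truth`.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  obj <- list(format = "promnet_ground_truth", version = 1L,
              wt_seq = gt$wt_seq, effects = gt$effects,
              key_sites = gt$key_sites, noise_sd = gt$noise_sd,
              s_max = gt$s_max, hill = gt$hill, seed = gt$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "promnet_ground_truth"))
    fail("'%s' is not a serialized ground truth", path)
  eff <- obj$effects
  if (!is.matrix(eff)) eff <- do.call(rbind, eff)
  colnames(eff) <- BASES
  structure(list(wt_seq = obj$wt_seq, effects = eff,
                 key_sites = as.data.frame(obj$key_sites),
                 noise_sd = obj$noise_sd, s_max = obj$s_max,
                 hill = obj$hill, seed = as.integer(obj$seed)),
            class = "ground_truth")
}
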