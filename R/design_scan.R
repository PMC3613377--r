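# In-silico mutagenesis scanning, key-point classification, conservation
# profiles, and the two de-novo design procedures (library screening and
# key-point combination search).

mutate_at <- function(seq_chars, positions, bases) {
  seq_chars[positions] <- bases
  paste(seq_chars, collapse = "")
}

#' Scan every single-point mutation of a wild-type sequence
#'
#' Substitutes each position by each of the three alternative bases (3L
#' mutants for an L-nt element), predicts every mutant's strength with the
#' model, and reports the relative change versus the model's own wild-type
#' prediction. Deterministic.
#'
#' @param model a trained `ann_model`.
#' @param wt_seq wild-type sequence of the trained length.
#' @return data.frame of class `mutation_scan` with columns `position`
#'   (1-based), `from_base`, `to_base`, `predicted_strength` and
#'   `delta_relative` = (predicted - wt) / wt; attribute `wt_predicted`
#'   carries the wild-type prediction.
#' @export
point_scan <- function(model, wt_seq) {
  stopifnot(inherits(model, "ann_model"))
  L <- model$input_length / 4L
  if (nchar(wt_seq) != L)
    fail("wild-type length %d does not match trained length %d", nchar(wt_seq), L)
  wt_seq <- toupper(wt_seq)
  ch <- strsplit(wt_seq, "")[[1L]]
  pos <- rep(seq_len(L), each = 3L)
  to <- unlist(lapply(ch, function(b) setdiff(BASES, b)), use.names = FALSE)
  seqs <- vapply(seq_along(pos),
                 function(i) mutate_at(ch, pos[i], to[i]), character(1L))
  pred <- predict_strength(model, seqs)
  wt_pred <- predict_strength(model, wt_seq)
  out <- data.frame(position = pos, from_base = ch[pos], to_base = to,
                    predicted_strength = pred,
                    delta_relative = (pred - wt_pred) / wt_pred)
  attr(out, "wt_predicted") <- wt_pred
  class(out) <- c("mutation_scan", "data.frame")
  out
}

#' Classify scanned mutations into positive and negative key points
#'
#' A key point is a single-base substitution predicted to change strength by
#' at least `threshold` (default 20%) relative to the wild-type prediction:
#' positive if it enhances, negative if it reduces. The threshold is
#' inclusive on both sides; effects strictly inside the band are discarded.
#'
#' @param effects a `mutation_scan` (or compatible data.frame with
#'   `delta_relative`).
#' @param wt_predicted the model's wild-type prediction (> 0); defaults to
#'   the scan's stored value.
#' @param threshold relative-change cutoff, default 0.20.
#' @return object of class `key_point_set`: `positive_points` and
#'   `negative_points` data.frames plus `threshold` and `wt_predicted`.
#' @export
classify_key_points <- function(effects,
                                wt_predicted = attr(effects, "wt_predicted"),
                                threshold = 0.20) {
  if (is.null(wt_predicted)) fail("wt_predicted is required")
  if (!is_scalar_num(wt_predicted) || wt_predicted <= 0)
    fail("relative change undefined: wt_predicted must be > 0")
  if (!is_scalar_num(threshold) || threshold <= 0)
    fail("threshold must be a positive scalar")
  eff <- as.data.frame(effects)
  pos <- eff[eff$delta_relative >= threshold, , drop = FALSE]
  neg <- eff[eff$delta_relative <= -threshold, , drop = FALSE]
  rownames(pos) <- rownames(neg) <- NULL
  structure(list(positive_points = pos, negative_points = neg,
                 threshold = threshold, wt_predicted = wt_predicted),
            class = "key_point_set")
}

#' @export
print.key_point_set <- function(x, ...) {
  cat(sprintf("key_point_set: %d positive, %d negative (|delta| >= %.0f%% of wt)\n",
              nrow(x$positive_points), nrow(x$negative_points),
              100 * x$threshold))
  invisible(x)
}

#' Generate a random in-silico mutant library
#'
#' Each sequence derives from the wild type by independent per-base
#' substitution at `mutation_rate`, uniform over the three alternative
#' bases. Duplicates (including unmutated copies) are permitted. Reproducible
#' from `seed`.
#'
#' @param wt_seq wild-type sequence.
#' @param n number of sequences.
#' @param mutation_rate per-base substitution probability in (0, 1).
#' @param seed RNG seed.
#' @return character vector of `n` sequences.
#' @export
generate_insilico_library <- function(wt_seq, n, mutation_rate, seed) {
  if (!is_count(n) || n < 1L) fail("n must be a positive integer")
  if (!is_scalar_num(mutation_rate) || mutation_rate <= 0 || mutation_rate >= 1)
    fail("mutation_rate must lie strictly in (0, 1)")
  wt_seq <- toupper(wt_seq)
  ch <- strsplit(wt_seq, "")[[1L]]
  L <- length(ch)
  alt <- lapply(ch, function(b) setdiff(BASES, b))
  with_seed(seed, vapply(seq_len(n), function(i) {
    hit <- which(runif(L) < mutation_rate)
    if (length(hit) == 0L) return(wt_seq)
    subs <- vapply(hit, function(p) alt[[p]][sample.int(3L, 1L)], character(1L))
    mutate_at(ch, hit, subs)
  }, character(1L)))
}

design_result <- function(candidates, desired, tolerance, approach) {
  satisfied <- abs(candidates$predicted_strength - desired) <= tolerance
  candidates$satisfied <- satisfied
  structure(list(candidates = candidates, desired_strength = desired,
                 tolerance = tolerance, approach = approach,
                 satisfied = any(satisfied),
                 nearest = candidates$predicted_strength[
                   which.min(abs(candidates$predicted_strength - desired))]),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("design_result (%s): target %.3f +/- %.3f, %d candidate(s)\n",
              x$approach, x$desired_strength, x$tolerance, nrow(x$candidates)))
  if (x$satisfied)
    cat(sprintf("  %d candidate(s) within tolerance\n", sum(x$candidates$satisfied)))
  else
    cat(sprintf("  UNSATISFIED: nearest achieved prediction %.3f\n", x$nearest))
  invisible(x)
}

count_mutations <- function(wt_chars, seq) {
  sum(strsplit(seq, "")[[1L]] != wt_chars)
}

mutation_string <- function(wt_chars, seq) {
  sc <- strsplit(seq, "")[[1L]]
  d <- which(sc != wt_chars)
  if (length(d) == 0L) return("")
  paste(sprintf("%d%s>%s", d, wt_chars[d], sc[d]), collapse = ",")
}

#' Design sequences by screening a random in-silico library
#'
#' Generates an in-silico mutant library (the wild type is always included in
#' the pool), predicts every member's strength, and returns the `k` sequences
#' whose predictions are nearest the desired strength, each flagged
#' satisfied/unsatisfied against the tolerance. A desired strength above the
#' model's training maximum is rejected: the network cannot design beyond the
#' strongest element it has seen.
#'
#' @param model a trained `ann_model`.
#' @param wt_seq wild-type sequence.
#' @param desired target relative strength (>= 0, <= `model$normalization_max`).
#' @param tolerance acceptable |prediction - desired|.
#' @param n in-silico library size (default 10,000).
#' @param mutation_rate per-base substitution rate (default 0.20).
#' @param seed RNG seed.
#' @param k number of candidates to return.
#' @return a `design_result`; candidates carry sequence, predicted strength,
#'   mutation count and mutation list versus the wild type.
#' @export
design_by_library <- function(model, wt_seq, desired, tolerance = 0.05,
                              n = 10000L, mutation_rate = 0.20, seed = 1L,
                              k = 10L) {
  stopifnot(inherits(model, "ann_model"))
  if (!is_scalar_num(desired) || desired < 0) fail("desired must be >= 0")
  if (desired > model$normalization_max)
    fail(paste0("desired strength %.3f exceeds the training maximum %.3f; ",
                "the model cannot design beyond the strongest training element"),
         desired, model$normalization_max)
  wt_seq <- toupper(wt_seq)
  pool <- c(wt_seq, generate_insilico_library(wt_seq, n, mutation_rate, seed))
  pred <- predict_strength(model, pool)
  ord <- order(abs(pred - desired), pool)
  take <- ord[seq_len(min(k, length(ord)))]
  wt_chars <- strsplit(wt_seq, "")[[1L]]
  cand <- data.frame(
    sequence = pool[take], predicted_strength = pred[take],
    n_mutations = vapply(pool[take], count_mutations, integer(1L),
                         wt_chars = wt_chars, USE.NAMES = FALSE),
    mutations = vapply(pool[take], mutation_string, character(1L),
                       wt_chars = wt_chars, USE.NAMES = FALSE))
  design_result(cand, desired, tolerance, "library")
}

# enumerate all combinations of key-point mutations (<= 1 per position,
# <= max_mutations total); returns list of integer index vectors
enumerate_combos <- function(positions, max_mutations) {
  combos <- list(integer(0L))
  out <- list()
  expand <- function(base, start) {
    if (length(base) >= max_mutations || start > length(positions)) return()
    for (i in start:length(positions)) {
      if (positions[i] %in% positions[base]) next
      nxt <- c(base, i)
      out[[length(out) + 1L]] <<- nxt
      expand(nxt, i + 1L)
    }
  }
  if (length(positions) > 0L) expand(integer(0L), 1L)
  out
}

#' Design sequences by combining key-point mutations
#'
#' Searches combinations of the key-point substitutions (at most one mutation
#' per position, at most `max_mutations` in total), scoring every combined
#' sequence with the model and returning the `k` combinations whose
#' predictions are nearest the desired strength. Instances with at most 10
#' key points are enumerated exhaustively; larger sets use deterministic beam
#' search of width `beam_width`. When nothing lands within the tolerance the
#' result is returned unsatisfied with the nearest achieved value rather than
#' erroring.
#'
#' @param model a trained `ann_model`.
#' @param wt_seq wild-type sequence.
#' @param keypoints a `key_point_set` from [classify_key_points()].
#' @param desired target relative strength.
#' @param tolerance acceptable |prediction - desired|.
#' @param max_mutations maximum number of combined mutations (>= 1).
#' @param beam_width beam width for the combination search (default 50).
#' @param k number of candidates to return.
#' @return a `design_result` with approach `"keypoint"`.
#' @export
design_by_keypoints <- function(model, wt_seq, keypoints, desired,
                                tolerance = 0.05, max_mutations = 5L,
                                beam_width = 50L, k = 10L) {
  stopifnot(inherits(model, "ann_model"), inherits(keypoints, "key_point_set"))
  if (!is_count(max_mutations) || max_mutations < 1L)
    fail("max_mutations must be >= 1")
  muts <- rbind(keypoints$positive_points, keypoints$negative_points)
  if (nrow(muts) == 0L) fail("key-point set is empty")
  if (!is_scalar_num(desired) || desired < 0) fail("desired must be >= 0")
  if (desired > model$normalization_max)
    fail("desired strength %.3f exceeds the training maximum %.3f",
         desired, model$normalization_max)
  wt_seq <- toupper(wt_seq)
  wt_chars <- strsplit(wt_seq, "")[[1L]]

  build_seq <- function(ix) mutate_at(wt_chars, muts$position[ix], muts$to_base[ix])
  score_sets <- function(sets) {
    seqs <- vapply(sets, build_seq, character(1L))
    predict_strength(model, seqs)
  }

  if (nrow(muts) <= 10L) {
    sets <- enumerate_combos(muts$position, max_mutations)
    if (length(sets) == 0L) fail("no combinations to enumerate")
    preds <- score_sets(sets)
  } else {
    # beam search: grow combinations one mutation at a time, keeping the
    # beam_width sets whose predictions are nearest the target
    seen_sets <- list()
    seen_pred <- numeric(0L)
    beam <- list(integer(0L))
    for (depth in seq_len(max_mutations)) {
      expanded <- list()
      for (st in beam) {
        start <- if (length(st)) max(st) + 1L else 1L
        if (start > nrow(muts)) next
        free <- seq(start, nrow(muts))
        free <- free[!(muts$position[free] %in% muts$position[st])]
        for (i in free) expanded[[length(expanded) + 1L]] <- c(st, i)
      }
      if (length(expanded) == 0L) break
      # deduplicate by key
      keys <- vapply(expanded, function(s) paste(sort(s), collapse = ","),
                     character(1L))
      keep <- !duplicated(keys)
      expanded <- expanded[keep]
      preds_e <- score_sets(expanded)
      seen_sets <- c(seen_sets, expanded)
      seen_pred <- c(seen_pred, preds_e)
      ord <- order(abs(preds_e - desired))
      beam <- expanded[ord[seq_len(min(beam_width, length(ord)))]]
    }
    sets <- seen_sets
    preds <- seen_pred
  }

  ord <- order(abs(preds - desired),
               vapply(sets, length, integer(1L)),
               vapply(sets, function(s) paste(sort(s), collapse = ","),
                      character(1L)))
  take <- ord[seq_len(min(k, length(ord)))]
  cand <- data.frame(
    sequence = vapply(sets[take], build_seq, character(1L)),
    predicted_strength = preds[take],
    n_mutations = vapply(sets[take], length, integer(1L)),
    mutations = vapply(sets[take], function(ix)
      paste(sprintf("%d%s>%s", muts$position[ix], muts$from_base[ix],
                    muts$to_base[ix])[order(muts$position[ix])],
            collapse = ","), character(1L)))
  design_result(cand, desired, tolerance, "keypoint")
}

#' Per-position information content of an alignment of equal-length sequences
#'
#' For each position, `2 - H` bits where `H` is the Shannon entropy of the
#' observed base frequencies (no pseudocounts or small-sample correction):
#' 2 bits for a perfectly conserved column, 0 for a uniform one. This is the
#' sequence-logo statistic used to compare conservation of high- versus
#' low-activity library members.
#'
#' @param seqs character vector (>= 2) of equal-length A/C/G/T sequences.
#' @return numeric vector of length L, information content in bits.
#' @export
conservation_profile <- function(seqs) {
  if (length(seqs) < 2L) fail("conservation needs at least 2 sequences")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) fail("sequences must have equal lengths")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  if (any(!m %in% BASES)) fail("sequences must contain only A/C/G/T")
  apply(m, 2L, function(col) {
    p <- tabulate(match(col, BASES), 4L) / length(col)
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Tally key-point mutations by substitution type
#'
#' Counts each (from, to) substitution pair separately for positive and
#' negative key points, plus the AT->GC / GC->AT aggregates (a mutation from
#' a weak (A/T) to a strong (G/C) base pair and vice versa).
#'
#' @param keypoints a `key_point_set`.
#' @return list with `pairs` (class, from_base, to_base, count over all 12
#'   substitution types) and `aggregate` (class x {AT_to_GC, GC_to_AT, other}
#'   counts).
#' @export
mutation_type_counts <- function(keypoints) {
  stopifnot(inherits(keypoints, "key_point_set"))
  types <- expand.grid(from_base = BASES, to_base = BASES,
                       stringsAsFactors = FALSE)
  types <- types[types$from_base != types$to_base, ]
  tally <- function(df, cls) {
    cnt <- integer(nrow(types))
    if (nrow(df) > 0L) {
      key <- paste(df$from_base, df$to_base)
      cnt <- vapply(paste(types$from_base, types$to_base),
                    function(k) sum(key == k), integer(1L), USE.NAMES = FALSE)
    }
    data.frame(class = cls, types, count = cnt, row.names = NULL)
  }
  pairs <- rbind(tally(keypoints$positive_points, "positive"),
                 tally(keypoints$negative_points, "negative"))
  agg_of <- function(df) {
    at <- c("A", "T"); gc <- c("G", "C")
    c(AT_to_GC = sum(df$from_base %in% at & df$to_base %in% gc),
      GC_to_AT = sum(df$from_base %in% gc & df$to_base %in% at),
      other = sum((df$from_base %in% at) == (df$to_base %in% at)))
  }
  aggregate <- rbind(positive = agg_of(keypoints$positive_points),
                     negative = agg_of(keypoints$negative_points))
  list(pairs = pairs, aggregate = aggregate)
}

#' Write a mutation scan to CSV
#'
#' Columns: position, from, to, predicted strength, relative delta, and the
#' key-point class at the given threshold.
#'
#' @param scan a `mutation_scan` from [point_scan()].
#' @param path output CSV path.
#' @param threshold key-point threshold used for the class column.
#' @return invisibly, `path`.
#' @export
write_scan <- function(scan, path, threshold = 0.20) {
  df <- as.data.frame(scan)
  df$class <- ifelse(df$delta_relative >= threshold, "positive",
                     ifelse(df$delta_relative <= -threshold, "negative",
                            "neutral"))
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
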