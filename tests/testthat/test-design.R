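scan_fixture <- function() fixture("scan_fixture", {
  sw <- small_world()
  point_scan(sw$model, sw$gt$wt_seq)
})

test_that("point_scan enumerates exactly three substitutions per position", {
  sw <- small_world()
  scan <- scan_fixture()
  L <- nchar(sw$gt$wt_seq)
  expect_identical(nrow(scan), 3L * L)
  expect_identical(as.integer(table(scan$position)), rep(3L, L))
  wt_chars <- strsplit(sw$gt$wt_seq, "")[[1]]
  expect_identical(scan$from_base, wt_chars[scan$position])
  expect_true(all(scan$from_base != scan$to_base))
  # every effect is reproducible by re-scoring the mutant sequence
  i <- c(1L, 17L, nrow(scan))
  seqs <- vapply(i, function(j) {
    ch <- wt_chars; ch[scan$position[j]] <- scan$to_base[j]
    paste(ch, collapse = "")
  }, character(1))
  expect_equal(predict_strength(sw$model, seqs), scan$predicted_strength[i],
               tolerance = 1e-12)
  expect_error(point_scan(sw$model, "ACGT"), "length")
})

test_that("a two-base element scans to the six expected mutants", {
  m <- structure(list(input_length = 8L,
                      hidden_weights = matrix(0, 2, 8), hidden_bias = c(0, 0),
                      output_weights = matrix(0, 1, 2), output_bias = 0,
                      normalization_max = 2, activation = "logsig",
                      config = training_config(hidden_neurons = 2L)),
                 class = "ann_model")
  scan <- point_scan(m, "AT")
  expect_identical(scan$position, rep(1:2, each = 3L))
  expect_setequal(scan$to_base[scan$position == 1], c("C", "G", "T"))
  expect_setequal(scan$to_base[scan$position == 2], c("A", "C", "G"))
  # constant-output model: all relative changes are exactly 0
  expect_identical(scan$delta_relative, rep(0, 6))
})

test_that("classify_key_points applies the inclusive 20% threshold", {
  eff <- data.frame(position = 1:3, from_base = "A", to_base = "G",
                    predicted_strength = c(1.25, 0.70, 1.05),
                    delta_relative = c(0.25, -0.30, 0.05))
  kp <- classify_key_points(eff, wt_predicted = 1)
  expect_identical(nrow(kp$positive_points), 1L)
  expect_identical(nrow(kp$negative_points), 1L)
  # exactly +/- threshold is included
  eff2 <- data.frame(position = 1:2, from_base = "A", to_base = "G",
                     predicted_strength = c(1.2, 0.8),
                     delta_relative = c(0.20, -0.20))
  kp2 <- classify_key_points(eff2, wt_predicted = 1)
  expect_identical(nrow(kp2$positive_points), 1L)
  expect_identical(nrow(kp2$negative_points), 1L)
  kp3 <- classify_key_points(eff[0, ], wt_predicted = 1)
  expect_identical(nrow(kp3$positive_points), 0L)
  expect_error(classify_key_points(eff, wt_predicted = 0), "wt_predicted")
  expect_error(classify_key_points(eff, wt_predicted = 1, threshold = -1),
               "threshold")
})

test_that("the trained scan recovers the planted sites of a learnable world", {
  sw <- small_world()
  scan <- scan_fixture()
  kp <- classify_key_points(scan)
  tme <- true_mutation_effects(sw$gt)
  strong <- tme[abs(tme$delta_relative) >= 1.5 * 0.20, ]
  cls <- ifelse(scan$delta_relative >= 0.20, "positive",
                ifelse(scan$delta_relative <= -0.20, "negative", "neutral"))
  got <- cls[match(paste(strong$position, strong$to_base),
                   paste(scan$position, scan$to_base))]
  want <- ifelse(strong$delta_relative > 0, "positive", "negative")
  expect_gte(mean(got == want), 0.90)
  # key-point sets are disjoint and respect the threshold
  expect_length(intersect(
    paste(kp$positive_points$position, kp$positive_points$to_base),
    paste(kp$negative_points$position, kp$negative_points$to_base)), 0L)
  expect_true(all(abs(c(kp$positive_points$delta_relative,
                        kp$negative_points$delta_relative)) >= 0.20))
})

test_that("generate_insilico_library hits the requested mutation rate", {
  wt <- random_seq(50, 3)
  seqs <- generate_insilico_library(wt, n = 2000, mutation_rate = 0.20,
                                    seed = 4)
  expect_length(seqs, 2000L)
  wt_chars <- strsplit(wt, "")[[1]]
  dists <- vapply(strsplit(seqs, ""), function(ch) sum(ch != wt_chars),
                  numeric(1))
  se <- sqrt(50 * 0.2 * 0.8 / 2000)
  expect_lt(abs(mean(dists) - 0.2 * 50), 3 * se)
  # seeded determinism
  expect_identical(generate_insilico_library(wt, 50, 0.2, seed = 4)[1:50],
                   seqs[1:50])
  # near-zero rate: essentially all wild-type copies
  low <- generate_insilico_library(wt, 5, 1e-9, seed = 5)
  expect_identical(low, rep(wt, 5))
  expect_error(generate_insilico_library(wt, 5, 0, seed = 1), "mutation_rate")
  expect_error(generate_insilico_library(wt, 5, 1, seed = 1), "mutation_rate")
})

test_that("design_by_library screens an in-silico pool toward the target", {
  sw <- small_world()
  wt_pred <- predict_strength(sw$model, sw$gt$wt_seq)
  res <- design_by_library(sw$model, sw$gt$wt_seq, desired = wt_pred,
                           tolerance = 0.05, n = 500, seed = 6, k = 5)
  # the wild type itself sits in the pool, so the target is matched exactly
  expect_true(res$satisfied)
  expect_true(sw$gt$wt_seq %in% res$candidates$sequence)
  # recorded predictions re-score exactly
  expect_equal(predict_strength(sw$model, res$candidates$sequence),
               res$candidates$predicted_strength, tolerance = 1e-12)
  # candidates are the k nearest to the target
  expect_true(all(diff(abs(res$candidates$predicted_strength - wt_pred)) >= 0))
  # a target above the training maximum is rejected outright
  expect_error(design_by_library(sw$model, sw$gt$wt_seq,
                                 desired = sw$model$normalization_max + 0.5),
               "training maximum")
  # unsatisfiable tolerance flags the result rather than erroring
  res2 <- design_by_library(sw$model, sw$gt$wt_seq, desired = wt_pred,
                            tolerance = 1e-12, n = 10, mutation_rate = 0.5,
                            seed = 7, k = 3)
  expect_s3_class(res2, "design_result")
})

test_that("key-point design matches brute-force enumeration on small sets", {
  sw <- small_world()
  scan <- scan_fixture()
  kp <- classify_key_points(scan)
  muts <- rbind(kp$positive_points, kp$negative_points)
  # restrict to <= 6 key points so 'exhaustive fallback' engages and the
  # oracle stays tiny
  muts6 <- head(muts[order(-abs(muts$delta_relative)), ], 6)
  kp6 <- structure(list(positive_points = muts6[muts6$delta_relative > 0, ],
                        negative_points = muts6[muts6$delta_relative < 0, ],
                        threshold = 0.2, wt_predicted = kp$wt_predicted),
                   class = "key_point_set")
  desired <- 1.8
  res <- design_by_keypoints(sw$model, sw$gt$wt_seq, kp6, desired,
                             tolerance = 0.1, max_mutations = 3, k = 1)
  oracle <- brute_force_design(sw$model, sw$gt$wt_seq, muts6, desired, 3)
  expect_equal(abs(res$candidates$predicted_strength[1] - desired),
               oracle$best, tolerance = 1e-12)
  # beam path (force > 10 key points) finds the same optimum as brute force
  muts12 <- head(muts[order(-abs(muts$delta_relative)), ], 12)
  kp12 <- structure(list(positive_points = muts12[muts12$delta_relative > 0, ],
                         negative_points = muts12[muts12$delta_relative < 0, ],
                         threshold = 0.2, wt_predicted = kp$wt_predicted),
                    class = "key_point_set")
  res12 <- design_by_keypoints(sw$model, sw$gt$wt_seq, kp12, desired,
                               tolerance = 0.1, max_mutations = 2,
                               beam_width = 80, k = 1)
  oracle12 <- brute_force_design(sw$model, sw$gt$wt_seq, muts12, desired, 2)
  expect_equal(abs(res12$candidates$predicted_strength[1] - desired),
               oracle12$best, tolerance = 1e-12)
})

test_that("key-point design degenerate and directional cases behave", {
  sw <- small_world()
  kp <- classify_key_points(scan_fixture())
  wt_pred <- kp$wt_predicted
  # max_mutations = 1 picks the single best key-point mutation
  desired <- wt_pred * 1.4
  res1 <- design_by_keypoints(sw$model, sw$gt$wt_seq, kp, desired,
                              tolerance = 0.5, max_mutations = 1, k = 1)
  muts <- rbind(kp$positive_points, kp$negative_points)
  expect_equal(min(abs(muts$predicted_strength - desired)),
               abs(res1$candidates$predicted_strength[1] - desired),
               tolerance = 1e-12)
  expect_identical(res1$candidates$n_mutations, 1L)
  # positive-only key points pushed upward stay at or above the wild type
  kp_pos <- structure(list(positive_points = kp$positive_points,
                           negative_points = kp$negative_points[0, ],
                           threshold = 0.2, wt_predicted = wt_pred),
                      class = "key_point_set")
  res_up <- design_by_keypoints(sw$model, sw$gt$wt_seq, kp_pos,
                                desired = min(2.5, sw$model$normalization_max),
                                tolerance = 0.3, max_mutations = 2, k = 5)
  expect_true(all(res_up$candidates$predicted_strength >= wt_pred - 1e-9))
  # an unreachable target yields an unsatisfied result, not an error
  res_un <- design_by_keypoints(sw$model, sw$gt$wt_seq, kp_pos,
                                desired = 1e-6, tolerance = 1e-6,
                                max_mutations = 1, k = 1)
  expect_false(res_un$satisfied)
  expect_true(is.finite(res_un$nearest))
  expect_error(design_by_keypoints(sw$model, sw$gt$wt_seq,
                                   classify_key_points(
                                     data.frame(position = integer(0),
                                                from_base = character(0),
                                                to_base = character(0),
                                                predicted_strength = numeric(0),
                                                delta_relative = numeric(0)),
                                     wt_predicted = 1),
                                   desired = 1), "empty")
})

test_that("conservation_profile computes per-position information content", {
  expect_equal(conservation_profile(c("AAA", "AAA", "AAA")), rep(2, 3))
  expect_equal(conservation_profile(c("AT", "CT", "GA", "TC"))[1], 0)
  expect_equal(conservation_profile(c("AG", "AG", "TC", "TC"))[1], 1)
  expect_error(conservation_profile(c("AA", "AAA")), "equal")
  expect_error(conservation_profile("AA"), "at least 2")
  # high- vs low-activity conservation on the planted world: strong negative
  # positions are more conserved among high-activity members
  sw <- small_world()
  y <- sw$lib$relative_strength
  high <- sw$lib$sequence[y > 1]
  prof <- conservation_profile(high)
  expect_length(prof, nchar(sw$gt$wt_seq))
  expect_true(all(prof >= 0 & prof <= 2))
})

test_that("mutation_type_counts tallies substitution classes exactly", {
  empty <- classify_key_points(
    data.frame(position = integer(0), from_base = character(0),
               to_base = character(0), predicted_strength = numeric(0),
               delta_relative = numeric(0)), wt_predicted = 1)
  cnt0 <- mutation_type_counts(empty)
  expect_true(all(cnt0$pairs$count == 0))
  expect_true(all(cnt0$aggregate == 0))

  eff <- data.frame(position = 1:4,
                    from_base = c("A", "T", "A", "G"),
                    to_base = c("G", "C", "C", "A"),
                    predicted_strength = c(0.5, 0.5, 0.5, 1.5),
                    delta_relative = c(-0.5, -0.5, -0.5, 0.5))
  kp <- classify_key_points(eff, wt_predicted = 1)
  cnt <- mutation_type_counts(kp)
  # all three negatives move a weak (A/T) base to a strong (G/C) base,
  # including the A->C transversion
  expect_identical(unname(cnt$aggregate["negative", "AT_to_GC"]), 3L)
  expect_identical(unname(cnt$aggregate["positive", "GC_to_AT"]), 1L)
  expect_identical(sum(cnt$pairs$count),
                   nrow(kp$positive_points) + nrow(kp$negative_points))
  neg_ag <- cnt$pairs[cnt$pairs$class == "negative" &
                        cnt$pairs$from_base == "A" & cnt$pairs$to_base == "G", ]
  expect_identical(neg_ag$count, 1L)
})
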