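# Shared fixtures, memoized so expensive ones (trained models) are built once
# per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

random_seq <- function(L, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
}

# four 8-nt sequences with strengths spanning [0, 1]; small enough that the
# network must genuinely separate them
tiny_library <- function() {
  strength_library(
    ids = c("s0", "s1", "s2", "wt"),
    sequences = c("AAAAAAAA", "AAAATTTT", "TTTTAAAA", "TTTTTTTT"),
    strengths = c(0, 0.2, 0.8, 1.0),
    wild_type_id = "wt")
}

tiny_model <- function() fixture("tiny_model", {
  lib <- tiny_library()
  train_network(encode_library(lib$sequence), lib$relative_strength,
                training_config(hidden_neurons = 4L, seed = 11L))
})

# a small, learnable planted world: many more training sequences than strong
# sites, so the network can localize every planted effect
small_world <- function() fixture("small_world", {
  gt <- make_ground_truth(seed = 7L, L = 30L, n_positive_sites = 4L,
                          n_negative_sites = 8L, noise_sd = 0.01)
  lib <- generate_library(gt, n = 150L, mutation_rate = 0.1, seed = 8L,
                          positive_fraction_target = 0.3)
  X <- encode_library(lib$sequence)
  best <- NULL
  for (r in 1:10) {
    m <- train_network(X, lib$relative_strength,
                       training_config(hidden_neurons = 10L, seed = r))
    if (is.null(best) || m$final_sse < best$final_sse) best <- m
  }
  list(gt = gt, lib = lib, model = best)
})

# Brute-force oracle for the key-point combination search: enumerate every
# subset with <= 1 mutation per position and <= max_mutations members.
brute_force_design <- function(model, wt_seq, muts, desired, max_mutations) {
  wt_chars <- strsplit(wt_seq, "")[[1]]
  n <- nrow(muts)
  sets <- list()
  for (size in seq_len(max_mutations)) {
    combos <- utils::combn(n, size, simplify = FALSE)
    combos <- Filter(function(ix) !anyDuplicated(muts$position[ix]), combos)
    sets <- c(sets, combos)
  }
  seqs <- vapply(sets, function(ix) {
    ch <- wt_chars; ch[muts$position[ix]] <- muts$to_base[ix]
    paste(ch, collapse = "")
  }, character(1))
  preds <- predict_strength(model, seqs)
  list(sets = sets, preds = preds, best = min(abs(preds - desired)))
}

# a mid-size planted world (L = 40) for model-selection properties
grid_world <- function() fixture("grid_world", {
  gt <- make_ground_truth(seed = 11L, L = 40L, n_positive_sites = 5L,
                          n_negative_sites = 10L, noise_sd = 0.05)
  lib <- generate_library(gt, n = 100L, mutation_rate = 0.15, seed = 12L)
  list(gt = gt, lib = lib)
})
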