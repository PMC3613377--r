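# Model selection: random train/test splits and the
# (training size x hidden width x restarts) grid search, with per-cell model
# names "NET{size}_{hidden}_{restart}" and per-size SSE/error summaries.

#' Randomly split a library into training and test sets
#'
#' Uniform sampling without replacement; the two sets are disjoint and
#' exhaustive, and the split is reproducible from `seed`.
#'
#' @param lib a [strength_library] whose records all carry strengths.
#' @param train_size number of training records, between 2 and `n - 1`.
#' @param seed RNG seed.
#' @return list with `train` and `test` strength libraries.
#' @export
split_library <- function(lib, train_size, seed) {
  stopifnot(inherits(lib, "strength_library"))
  n <- length(lib$id)
  if (!is_count(train_size) || train_size < 2L || train_size > n - 1L)
    fail("train_size must be in [2, %d], got %s", n - 1L, format(train_size))
  idx <- with_seed(seed, sample.int(n, train_size))
  list(train = lib[sort(idx)], test = lib[sort(setdiff(seq_len(n), idx))])
}

#' Sample Pearson correlation coefficient
#'
#' @param x,y equal-length numeric vectors (length >= 3), neither constant.
#' @return correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    fail("pearson_r needs two equal-length vectors of length >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    fail("correlation with a constant vector is undefined")
  cor(x, y)
}

grid_cell_name <- function(size, hidden, restart)
  sprintf("NET%d_%d_%d", size, hidden, restart)

#' Grid search over training size, hidden width and random restarts
#'
#' For every (size, hidden, restart) triple, draws a fresh seeded split,
#' trains a network, and evaluates test SSE, test prediction error and
#' train/test Pearson correlations on the measurement (denormalized) scale.
#' Cells are named `NET{size}_{hidden}_{restart}` with 1-based restart
#' indices. Child seeds derive deterministically from `master_seed`, so any
#' cell can be reproduced in isolation. With `count_only = TRUE` the planned
#' grid is enumerated without any training (the full published-scale grid,
#' sizes 40-90 x hidden 5-30 x 1,000 restarts, has 1,326,000 cells).
#'
#' @param lib a [strength_library] with measured strengths.
#' @param sizes integer vector of training-set sizes.
#' @param hidden_range integer vector of hidden-layer widths.
#' @param restarts number of random restarts per (size, hidden) pair.
#' @param base_config [training_config()] supplying optimizer settings; its
#'   `hidden_neurons` and `seed` are overridden per cell.
#' @param master_seed integer seed for the whole search.
#' @param count_only if `TRUE`, return the cell count and grid dimensions
#'   without training.
#' @return object of class `grid_search_report`: `cells` (one row per cell),
#'   `per_size` summaries (max/min test SSE and error per size), and `best`
#'   (model name chosen by [select_best()]). For `count_only`, a list with
#'   `n_cells`, `sizes`, `hidden_range`, `restarts`.
#' @export
grid_search <- function(lib, sizes, hidden_range, restarts,
                        base_config = training_config(), master_seed = 1L,
                        count_only = FALSE) {
  sizes <- sort(unique(as.integer(sizes)))
  hidden_range <- sort(unique(as.integer(hidden_range)))
  if (length(sizes) == 0L || length(hidden_range) == 0L)
    fail("size and hidden ranges must be non-empty")
  if (!is_count(restarts) || restarts < 1L) fail("restarts must be >= 1")
  n_cells <- length(sizes) * length(hidden_range) * restarts
  if (count_only)
    return(list(n_cells = n_cells, sizes = sizes,
                hidden_range = hidden_range, restarts = as.integer(restarts)))

  stopifnot(inherits(lib, "strength_library"))
  if (anyNA(lib$relative_strength))
    fail("grid search needs strengths for every record")
  n <- length(lib$id)
  if (max(sizes) > n - 1L)
    fail("largest training size %d exceeds n - 1 = %d", max(sizes), n - 1L)

  X_all <- encode_library(lib$sequence)
  cells <- vector("list", n_cells)
  k <- 0L
  for (size in sizes) for (hidden in hidden_range) for (r in seq_len(restarts)) {
    k <- k + 1L
    cell_seed <- derive_seed(master_seed, size, hidden, r)
    sp_idx <- with_seed(derive_seed(cell_seed, 1L), sample.int(n, size))
    test_idx <- setdiff(seq_len(n), sp_idx)
    cfg <- base_config
    cfg$hidden_neurons <- hidden
    cfg$seed <- derive_seed(cell_seed, 2L)
    model <- train_network(X_all[sp_idx, , drop = FALSE],
                           lib$relative_strength[sp_idx], cfg)
    pred_tr <- predict_strength(model, X_all[sp_idx, , drop = FALSE])
    pred_te <- predict_strength(model, X_all[test_idx, , drop = FALSE])
    y_tr <- lib$relative_strength[sp_idx]
    y_te <- lib$relative_strength[test_idx]
    cells[[k]] <- data.frame(
      train_size = size, hidden_neurons = hidden, restart_index = r,
      model_name = grid_cell_name(size, hidden, r), seed = cell_seed,
      sse_train = model$final_sse,
      sse_test = sse(pred_te, y_te),
      error_test = prediction_error(pred_te, y_te),
      r_train = if (sd(y_tr) > 0 && sd(pred_tr) > 0) cor(pred_tr, y_tr) else NA_real_,
      r_test = if (length(y_te) >= 3 && sd(y_te) > 0 && sd(pred_te) > 0)
        cor(pred_te, y_te) else NA_real_,
      converged = model$converged)
  }
  cells <- do.call(rbind, cells)
  per_size <- do.call(rbind, lapply(split(cells, cells$train_size), function(d)
    data.frame(train_size = d$train_size[1L],
               sse_test_max = max(d$sse_test), sse_test_min = min(d$sse_test),
               error_test_max = max(d$error_test),
               error_test_min = min(d$error_test))))
  rownames(per_size) <- NULL
  rep <- structure(list(cells = cells, per_size = per_size, best = NULL),
                   class = "grid_search_report")
  rep$best <- select_best(rep)
  rep
}

#' @export
print.grid_search_report <- function(x, ...) {
  cat(sprintf("grid_search_report: %d cells (%d sizes x %d hidden x %d restarts)\n",
              nrow(x$cells), length(unique(x$cells$train_size)),
              length(unique(x$cells$hidden_neurons)),
              max(x$cells$restart_index)))
  best <- x$cells[x$cells$model_name == x$best, ]
  cat(sprintf("  best: %s (test SSE %.4g, test R %.3f)\n", x$best,
              best$sse_test, best$r_test))
  invisible(x)
}

#' Select the best grid cell
#'
#' Minimum test-set SSE; ties broken by maximum test correlation, then by
#' lexicographic model name.
#'
#' @param report a `grid_search_report` from [grid_search()].
#' @return the winning model name, e.g. `"NET90_19_576"`.
#' @export
select_best <- function(report) {
  cells <- if (inherits(report, "grid_search_report")) report$cells else report
  if (is.null(cells) || nrow(cells) == 0L) fail("empty grid search report")
  r_key <- ifelse(is.na(cells$r_test), -Inf, cells$r_test)
  ord <- order(cells$sse_test, -r_key, cells$model_name)
  cells$model_name[ord[1L]]
}

#' Retrain the model behind a grid cell
#'
#' Reconstructs a cell's split and configuration from its stored seed and
#' retrains, returning the identical model (training is deterministic given
#' the seed).
#'
#' @param lib the library used for the search.
#' @param report a `grid_search_report`.
#' @param model_name cell name; defaults to the report's best.
#' @param base_config the `base_config` passed to [grid_search()].
#' @return list with `model` (an `ann_model`), `train` and `test` libraries.
#' @export
refit_cell <- function(lib, report, model_name = report$best,
                       base_config = training_config()) {
  cell <- report$cells[report$cells$model_name == model_name, ]
  if (nrow(cell) != 1L) fail("model '%s' not found in report", model_name)
  n <- length(lib$id)
  sp_idx <- with_seed(derive_seed(cell$seed, 1L), sample.int(n, cell$train_size))
  cfg <- base_config
  cfg$hidden_neurons <- cell$hidden_neurons
  cfg$seed <- derive_seed(cell$seed, 2L)
  train <- lib[sort(sp_idx)]
  test <- lib[sort(setdiff(seq_len(n), sp_idx))]
  model <- train_network(encode_library(train$sequence),
                         train$relative_strength, cfg)
  list(model = model, train = train, test = test)
}

#' Write a grid search report to CSV + JSON
#'
#' One CSV row per cell plus a JSON summary with the best model and the
#' per-size max/min curves.
#'
#' @param report a `grid_search_report`.
#' @param csv_path,json_path output paths.
#' @return invisibly, the report.
#' @export
write_grid_report <- function(report, csv_path, json_path) {
  stopifnot(inherits(report, "grid_search_report"))
  write.table(report$cells, csv_path, sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(best = report$best, per_size = report$per_size),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
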