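# First-pass screen: gradient-boosted-tree relative-energy regression,
# initial ranking r, the acceptance-capacity heuristic, and the
# mean-increase-RMSE feature importance.

#' Default GBT hyperparameters
#'
#' Exposed in full so alternative settings can be supplied to every
#' training entry point.
#'
#' @param nrounds number of boosting rounds.
#' @param max_depth maximum tree depth.
#' @param eta learning rate.
#' @param subsample row subsampling fraction per round.
#' @param holdout_fraction fraction of systems held out for the stored RMSE.
#' @return named list of hyperparameters.
#' @export
gbt_hyperparams <- function(nrounds = 300L, max_depth = 6L, eta = 0.1,
                            subsample = 1.0, holdout_fraction = 0.2) {
  list(nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
       eta = eta, subsample = subsample,
       holdout_fraction = holdout_fraction)
}

.xgb_fit <- function(x, y, hp, seed) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1L)
  xgboost::xgb.train(
    params = list(max_depth = hp$max_depth, eta = hp$eta,
                  subsample = hp$subsample, objective = "reg:squarederror",
                  nthread = 1L, seed = seed),
    data = dtrain, nrounds = hp$nrounds, verbose = 0)
}

# Split system ids into train/holdout deterministically for a seed.
.split_systems <- function(system_ids, holdout_fraction, seed) {
  ids <- sort(unique(system_ids))
  n_hold <- max(1L, floor(length(ids) * holdout_fraction))
  if (n_hold >= length(ids)) n_hold <- length(ids) - 1L
  set.seed(seed)
  hold <- sample(ids, n_hold)
  list(train = setdiff(ids, hold), hold = hold)
}

#' Train the relative-energy ranker
#'
#' Fits a gradient-boosted-tree regressor to the `re_label` column of a
#' training table. The stored RMSE is computed on a held-out split made by
#' system (so no system straddles the split); it is this RMSE that later
#' feeds the acceptance-capacity heuristic.
#'
#' @param table training table (see [validate_training_table()]).
#' @param hyperparams list from [gbt_hyperparams()].
#' @param seed integer seed controlling the split and the fit.
#' @param mode ion mode the model is trained for.
#' @return a `ranker_model`: regressor handle, held-out `training_rmse`,
#'   `feature_schema`, `mode`, `seed`.
#' @export
train_ranker <- function(table, hyperparams = gbt_hyperparams(), seed = 1L,
                         mode = "[M+H]+") {
  validate_training_table(table)
  if (nrow(table) < 20L || length(unique(table$system_id)) < 2L) {
    stop("training requires >= 20 rows spanning >= 2 systems", call. = FALSE)
  }
  x <- as.matrix(table[, feature_schema()])
  if (any(apply(x, 2L, stats::sd) == 0) && stats::sd(table$re_label) > 0) {
    # constant columns are tolerated; a fully constant feature matrix is not
    if (all(apply(x, 2L, stats::sd) == 0)) {
      stop("degenerate training table: all features constant", call. = FALSE)
    }
  }
  split <- .split_systems(table$system_id, hyperparams$holdout_fraction, seed)
  tr <- table$system_id %in% split$train
  fit_tr <- .xgb_fit(x[tr, , drop = FALSE], table$re_label[tr], hyperparams,
                     seed)
  pred_hold <- stats::predict(fit_tr, x[!tr, , drop = FALSE])
  rmse <- sqrt(mean((pred_hold - table$re_label[!tr])^2))
  # final model uses all rows so deployment sees every system
  fit <- .xgb_fit(x, table$re_label, hyperparams, seed)
  structure(
    list(regressor = fit, training_rmse = rmse,
         feature_schema = feature_schema(), mode = mode,
         seed = as.integer(seed), hyperparams = hyperparams,
         holdout_systems = split$hold, format_version = 1L),
    class = "ranker_model")
}

#' @export
print.ranker_model <- function(x, ...) {
  cat(sprintf("<ranker_model> %s, held-out RMSE %.3f kcal/mol, seed %d\n",
              x$mode, x$training_rmse, x$seed))
  invisible(x)
}

#' Predict relative energies and assign initial ranks
#'
#' Featurizes every charge-state model, predicts its relative energy with
#' the trained regressor, and assigns the initial rank r by ascending
#' predicted RE (rank 1 = most stable). Exact ties are broken by ascending
#' CBA index so output is deterministic.
#'
#' @param ranker a `ranker_model`.
#' @param models list of charge-state models from [enumerate_models()].
#' @return the models, ordered by `initial_rank_r`, with `predicted_re`
#'   and `initial_rank_r` set.
#' @export
predict_and_rank <- function(ranker, models) {
  stopifnot(inherits(ranker, "ranker_model"), length(models) > 0L)
  feats <- t(vapply(models, featurize, numeric(10L)))
  if (!identical(colnames(feats), ranker$feature_schema)) {
    stop("feature schema mismatch between models and ranker", call. = FALSE)
  }
  pred <- stats::predict(ranker$regressor, feats)
  cba <- vapply(models, function(m) m$cba_index, integer(1L))
  ord <- order(pred, cba)
  ranks <- integer(length(models))
  ranks[ord] <- seq_along(models)
  models <- lapply(seq_along(models), function(k) {
    m <- models[[k]]
    m$predicted_re <- pred[k]
    m$initial_rank_r <- ranks[k]
    m
  })
  models[ord]
}

#' Acceptance capacity
#'
#' The heuristic `capacity = (1/3) * (rmse + re_min) / (sigma + s)` where
#' `re_min` is the minimum predicted relative energy, and `sigma` and `s`
#' are the population standard deviation and variance of the predicted REs
#' of one system's model ensemble. It balances model confidence (the
#' regressor's held-out RMSE) against how well separated the ensemble is:
#' tightly clustered predictions (small sigma + s) inflate the capacity so
#' more candidates survive to refinement. With a single model, or an
#' all-equal ensemble, the denominator degenerates and the capacity is set
#' to 1 so exactly the top model advances.
#'
#' @param rmse held-out RMSE of the ranker, kcal/mol.
#' @param predicted_res numeric vector of predicted REs, kcal/mol.
#' @return list with `rmse`, `re_min`, `sigma`, `variance_s`, `capacity`.
#' @export
acceptance_capacity <- function(rmse, predicted_res) {
  if (length(predicted_res) == 0L) {
    stop("predicted_res must be non-empty", call. = FALSE)
  }
  stopifnot(rmse >= 0)
  re_min <- min(predicted_res)
  mu <- mean(predicted_res)
  s <- mean((predicted_res - mu)^2)   # population variance
  sigma <- sqrt(s)
  capacity <- if (sigma + s < 1e-9) {
    1
  } else {
    (1 / 3) * (rmse + re_min) / (sigma + s)
  }
  list(rmse = rmse, re_min = re_min, sigma = sigma, variance_s = s,
       capacity = capacity)
}

#' Select models to forward to refinement
#'
#' Forwards the top `k = clamp(ceiling(capacity), 1, n)` models by initial
#' rank. The rank-1 model is always forwarded, safeguarding against the
#' loss of true positives.
#'
#' @param ranked models ordered by `initial_rank_r`.
#' @param stats list from [acceptance_capacity()].
#' @return the forwarded models (never empty, always including rank 1).
#' @export
select_models <- function(ranked, stats) {
  n <- length(ranked)
  k <- max(1L, min(n, as.integer(ceiling(stats$capacity))))
  r <- vapply(ranked, function(m) m$initial_rank_r, integer(1L))
  ranked[order(r)][seq_len(k)]
}

#' Mean-increase-RMSE feature importance
#'
#' For each feature, retrains the regressor without it and reports the
#' mean, over repeated seeded system-level splits, of the increase in
#' held-out RMSE relative to the full-schema model. Features the model
#' relies on show a large positive MIR; pure-noise features sit near zero.
#'
#' @param table training table.
#' @param hyperparams list from [gbt_hyperparams()].
#' @param seed base seed; repeat `t` uses `seed + t`.
#' @param n_repeats number of repeated splits averaged.
#' @return named numeric vector, one MIR (kcal/mol) per schema feature.
#' @export
mir_feature_importance <- function(table, hyperparams = gbt_hyperparams(),
                                   seed = 1L, n_repeats = 3L) {
  validate_training_table(table)
  schema <- feature_schema()
  x_full <- as.matrix(table[, schema])
  y <- table$re_label
  deltas <- matrix(NA_real_, n_repeats, length(schema),
                   dimnames = list(NULL, schema))
  for (t in seq_len(n_repeats)) {
    s <- seed + t - 1L
    split <- .split_systems(table$system_id, hyperparams$holdout_fraction, s)
    tr <- table$system_id %in% split$train
    fit_full <- .xgb_fit(x_full[tr, , drop = FALSE], y[tr], hyperparams, s)
    rmse_full <- sqrt(mean((stats::predict(fit_full, x_full[!tr, , drop = FALSE]) -
                              y[!tr])^2))
    for (f in schema) {
      x_red <- x_full[, setdiff(schema, f), drop = FALSE]
      fit_red <- .xgb_fit(x_red[tr, , drop = FALSE], y[tr], hyperparams, s)
      rmse_red <- sqrt(mean((stats::predict(fit_red, x_red[!tr, , drop = FALSE]) -
                               y[!tr])^2))
      deltas[t, f] <- rmse_red - rmse_full
    }
  }
  colMeans(deltas)
}

# --- persistence ---------------------------------------------------------

#' Save a ranker to a single-file bundle
#'
#' @param ranker a `ranker_model`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
save_ranker <- function(ranker, path) {
  stopifnot(inherits(ranker, "ranker_model"))
  bundle <- ranker
  bundle$regressor <- xgboost::xgb.save.raw(ranker$regressor)
  saveRDS(bundle, path)
  invisible(path)
}

#' Load a ranker bundle
#'
#' @param path file written by [save_ranker()].
#' @return a `ranker_model`.
#' @export
load_ranker <- function(path) {
  bundle <- readRDS(path)
  if (is.null(bundle$format_version) || bundle$format_version != 1L) {
    stop("unrecognized ranker bundle format", call. = FALSE)
  }
  bundle$regressor <- xgboost::xgb.load.raw(bundle$regressor)
  class(bundle) <- "ranker_model"
  bundle
}
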