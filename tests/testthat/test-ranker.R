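test_that("training learns a planted signal and is seed-reproducible", {
  tab <- synthetic_training_table(synthetic_spec(n_systems = 40L, seed = 11L))
  rk <- train_ranker(tab, gbt_hyperparams(nrounds = 120L), seed = 11L)
  hold <- tab$system_id %in% rk$holdout_systems
  x <- as.matrix(tab[, feature_schema()])
  pred <- predict(rk$regressor, x[hold, , drop = FALSE])
  expect_gte(cor(pred, tab$re_label[hold], method = "spearman"), 0.8)
  expect_gte(rk$training_rmse, 0)

  rk2 <- train_ranker(tab, gbt_hyperparams(nrounds = 120L), seed = 11L)
  expect_identical(predict(rk2$regressor, x), predict(rk$regressor, x))
})

test_that("constant labels train to near-zero RMSE", {
  tab <- synthetic_training_table(synthetic_spec(n_systems = 10L, seed = 4L,
                                                 noise_sd = 0))
  tab$re_label <- rep(0, nrow(tab))  # constant: every model already minimal
  rk <- train_ranker(tab, gbt_hyperparams(nrounds = 50L), seed = 4L)
  expect_lte(rk$training_rmse, 1e-6)
})

test_that("training rejects degenerate tables", {
  tab <- synthetic_training_table(synthetic_spec(n_systems = 10L, seed = 4L))
  expect_error(train_ranker(tab[1:10, ], seed = 1L), ">= 20 rows")
  flat <- tab
  flat[, feature_schema()] <- 1
  expect_error(train_ranker(flat, seed = 1L), "degenerate")
})

test_that("initial ranking sorts by predicted RE with CBA tie-break", {
  models <- enumerate_models(toy_library()$glycine, "[M+H]+")
  ranked <- predict_and_rank(fake_ranker(c(2.0, 0.5, 1.1)), models)
  # models enumerated at CBA 1, 4, 5 receive REs 2.0, 0.5, 1.1 -> r = 3, 1, 2
  r_by_cba <- sapply(ranked, function(m) m$initial_rank_r)[
    order(sapply(ranked, function(m) m$cba_index))]
  expect_identical(r_by_cba, c(3L, 1L, 2L))
  expect_identical(sapply(ranked, function(m) m$initial_rank_r), 1:3)

  single <- predict_and_rank(fake_ranker(1.7), models[2L])
  expect_identical(single[[1L]]$initial_rank_r, 1L)

  tied <- predict_and_rank(fake_ranker(c(1, 1, 1)), models)
  expect_identical(sapply(tied, function(m) m$cba_index),
                   sort(sapply(models, function(m) m$cba_index)))
})

test_that("acceptance capacity reproduces the closed form", {
  st <- acceptance_capacity(3, c(0, 2))
  expect_identical(st$re_min, 0)
  expect_equal(st$sigma, 1)
  expect_equal(st$variance_s, 1)
  expect_equal(st$capacity, 0.5, tolerance = 1e-15)
  expect_equal(st$sigma^2, st$variance_s, tolerance = 1e-12)

  expect_equal(acceptance_capacity(1, 4.2)$capacity, 1)  # degeneracy guard
  expect_equal(acceptance_capacity(1, c(2, 2, 2))$capacity, 1)
  expect_error(acceptance_capacity(1, numeric(0)), "non-empty")

  # strictly increasing in the RMSE at fixed REs
  res <- c(0, 1.2, 3.4)
  caps <- sapply(seq(0, 10, by = 0.5),
                 function(r) acceptance_capacity(r, res)$capacity)
  expect_true(all(diff(caps) > 0))
})

test_that("model selection forwards ceil(capacity) clamped to [1, n]", {
  models <- enumerate_models(toy_library()$glycine, "[M+H]+")
  ranked <- predict_and_rank(fake_ranker(c(2.0, 0.5, 1.1)), models)
  pick <- function(cap) select_models(ranked, list(capacity = cap))
  expect_identical(length(pick(0.5)), 1L)
  expect_identical(pick(0.5)[[1L]]$initial_rank_r, 1L)
  expect_identical(length(pick(2.2)), 3L)   # ceil -> 3 of 3
  expect_identical(length(pick(10)), 3L)    # clamped to n
  expect_identical(length(pick(0)), 1L)     # never empty
  for (cap in c(0, 0.3, 1.4, 7)) {
    expect_identical(pick(cap)[[1L]]$initial_rank_r, 1L)  # rank 1 kept
  }
})

test_that("MIR covers the schema and flags an uninformative feature", {
  tab <- synthetic_training_table(synthetic_spec(n_systems = 30L, seed = 9L))
  mir <- mir_feature_importance(tab, gbt_hyperparams(nrounds = 60L),
                                seed = 9L, n_repeats = 2L)
  expect_identical(names(mir), feature_schema())
  expect_identical(names(which.max(mir)), "dist_cba_coe")
  # a feature with zero planted weight carries ~no importance
  expect_lt(abs(mir[["interaction_angle"]]), 0.1 * mir[["dist_cba_coe"]])
})

test_that("ranker bundles round trip through disk", {
  tab <- synthetic_training_table(synthetic_spec(n_systems = 25L, seed = 6L))
  rk <- train_ranker(tab, gbt_hyperparams(nrounds = 60L), seed = 6L,
                     mode = "[M-H]-")
  path <- tempfile(fileext = ".rds")
  save_ranker(rk, path)
  back <- load_ranker(path)
  expect_identical(back$mode, "[M-H]-")
  expect_identical(back$training_rmse, rk$training_rmse)
  expect_identical(back$feature_schema, feature_schema())
  x <- as.matrix(tab[, feature_schema()])
  expect_equal(predict(back$regressor, x), predict(rk$regressor, x),
               tolerance = 1e-12)
  saveRDS(list(a = 1), path)
  expect_error(load_ranker(path), "unrecognized")
  unlink(path)
})
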