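# Shared helpers: independent oracles and cached expensive objects.

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# Independent weighted-mean evaluation (oracle for COE and COM).
weighted_mean_position <- function(coords, weights) {
  colSums(coords * weights) / sum(weights)
}

# Independent brute-force SASA: random (seeded) dot directions instead of
# the implementation's golden-spiral template.
sasa_bruteforce <- function(mol, probe = 1.4, n_dots = 4000L, seed = 99L) {
  set.seed(seed)
  radii <- protomeR::vdw_radius(mol$elements) + probe
  n <- length(mol$elements)
  total <- 0
  for (i in seq_len(n)) {
    dirs <- matrix(rnorm(3L * n_dots), n_dots, 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    pts <- dirs * radii[i] +
      matrix(mol$coords[i, ], n_dots, 3L, byrow = TRUE)
    exposed <- rep(TRUE, n_dots)
    for (j in seq_len(n)[-i]) {
      dj <- pts - matrix(mol$coords[j, ], n_dots, 3L, byrow = TRUE)
      exposed <- exposed & (rowSums(dj^2) > radii[j]^2)
    }
    total <- total + 4 * pi * radii[i]^2 * sum(exposed) / n_dots
  }
  total
}

# A fixed-output regressor so ranking logic can be tested with chosen
# predicted REs (values recycled over the rows of newdata).
constant_predictor <- function(values) {
  structure(list(values = values), class = "constant_predictor")
}
predict.constant_predictor <- function(object, newdata, ...) {
  rep_len(object$values, nrow(newdata))
}
registerS3method("predict", "constant_predictor", predict.constant_predictor,
                 envir = asNamespace("stats"))

fake_ranker <- function(values, rmse = 1) {
  structure(list(regressor = constant_predictor(values), training_rmse = rmse,
                 feature_schema = protomeR::feature_schema(),
                 mode = "[M+H]+", seed = 0L,
                 hyperparams = protomeR::gbt_hyperparams(),
                 holdout_systems = character(0), format_version = 1L),
            class = "ranker_model")
}

# One modest trained ranker shared across pipeline tests.
test_ranker <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tab <- protomeR::synthetic_training_table(
        protomeR::synthetic_spec(n_systems = 50L, seed = 42L))
      cache <<- protomeR::train_ranker(
        tab, protomeR::gbt_hyperparams(nrounds = 120L), seed = 42L)
    }
    cache
  }
})
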