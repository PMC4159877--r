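# Shared in-code fixtures for the test suite.

# Reference activities in registry order: experimental, PM6- and
# PM7-predicted columns matched by compound name.
fixture_pairs <- function() {
  fx <- qsar_fixtures()
  act <- fx$activities[match(fx$registry$name, fx$activities$name), ]
  stopifnot(!anyNA(act$name))
  act
}

# Random-but-valid energy table covering every registry compound for the
# FC and QB7 forms under one method, energies in a plausible
# heat-of-formation range (kcal/mol).
make_energy_table <- function(registry, method = "PM6", seed = 101) {
  set.seed(seed)
  grid <- expand.grid(compound = registry$name, form = c("FC", "QB7"),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  e_neutral <- rnorm(n, 50, 40)
  data.frame(grid, method = method,
             e_neutral = e_neutral,
             e_cation = e_neutral + runif(n, 120, 220),   # I > 0
             e_anion = e_neutral - runif(n, 20, 80),      # A > 0
             stringsAsFactors = FALSE)
}

# A known ("planted") 2-input Takagi-Sugeno model on the unit square plus
# Gaussian noise of the given SD; returns data and the generating model.
make_planted_ts <- function(n, sigma = 0, seed = 11) {
  set.seed(seed)
  X <- cbind(x1 = runif(n), x2 = runif(n))
  truth <- anfis_init(X, mfs_per_input = 2, standardize = FALSE)
  truth$consequents <- matrix(
    c( 2,  1.5, -0.5,
      -1,  0.8,  2.0,
       3, -1.2,  0.4,
       0,  0.6, -1.5),
    nrow = 4, byrow = TRUE,
    dimnames = dimnames(truth$consequents))
  y <- predict(truth, X) + rnorm(n, sd = sigma)
  list(X = X, y = y, truth = truth, sigma = sigma)
}
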