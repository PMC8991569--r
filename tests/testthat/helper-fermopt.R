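# Shared fixtures and independent oracles for the test suite.

# Published case-study statistics (screening rows, polynomial, yields).
published <- list(
  main_effects = c(Glucose = 0.11, KNO3 = 0.004, K2HPO4 = -0.044,
                   CaCl2 = 0.31, MgSO4 = -0.07, Tyrosine = -0.005,
                   TraceElement = -0.15, pH = -0.035, CultureAge = -0.06,
                   InoculumSize = 0.11, Volume = 0.31),
  abs_t = c(Glucose = 0.69, KNO3 = 0.02, K2HPO4 = 0.28, CaCl2 = 2.53,
            MgSO4 = 0.46, Tyrosine = 0.02, TraceElement = 1.0, pH = 0.22,
            CultureAge = 0.37, InoculumSize = 0.73, Volume = 2.47),
  # intercept, 3 linear, 3 interactions (12, 13, 23), 3 squared
  coefs = c(0.64, 0.13625, 0.015, 0.22875, -0.045, -0.0825, 0.015,
            0.09125, 0.02375, -0.05875),
  r_squared = 0.853,
  predicted_opt = 0.994, observed_opt = 0.938, basal = 0.646
)

# Evaluate a length-10 quadratic coefficient vector (3 factors, model-matrix
# order) at rows of a 3-column matrix. Independent of the package's
# predict() path.
eval_quad3 <- function(cf, pts) {
  pts <- matrix(pts, ncol = 3L)
  drop(cbind(1, pts, pts[, 1] * pts[, 2], pts[, 1] * pts[, 3],
             pts[, 2] * pts[, 3], pts^2) %*% cf)
}

# Dense-grid maximization oracle over [-1,1]^3 (step 0.01 by default).
grid_max3 <- function(cf, step = 0.01) {
  s <- seq(-1, 1, by = step)
  g <- as.matrix(expand.grid(s, s, s))
  v <- eval_quad3(cf, g)
  i <- which.max(v)
  list(value = v[i], point = g[i, ])
}

# Multi-start bounded quasi-Newton oracle for the box maximum.
optim_max <- function(model, n_starts = 25L, seed = 42L) {
  set.seed(seed)
  k <- model$k
  f <- function(x) -predict(model, x)
  best <- -Inf
  starts <- rbind(matrix(stats::runif(n_starts * k, -1, 1), ncol = k),
                  rep(0, k), rep(1, k), rep(-1, k))
  for (i in seq_len(nrow(starts))) {
    r <- stats::optim(starts[i, ], f, method = "L-BFGS-B",
                      lower = -1, upper = 1)
    if (-r$value > best) best <- -r$value
  }
  best
}

# Random full quadratic in k factors with coefficients on the case-study
# scale.
random_quadratic <- function(k = 3L) {
  nint <- k * (k - 1) / 2
  quadraticModel(beta0 = stats::runif(1, -1, 1),
                 linear = stats::runif(k, -1, 1),
                 interaction = stats::runif(nint, -1, 1),
                 squared = stats::runif(k, -1, 1))
}

case_study_factors_bb <- function()
  list(designFactor("CaCl2", 0.375, 1.125, unit = "g/L"),
       designFactor("TraceElement", 0.25, 0.75, unit = "mL/L"),
       designFactor("Volume", 75, 225, unit = "mL/500 mL"))
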