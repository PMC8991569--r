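test_that("fit to the case-study table reproduces the published polynomial", {
  bb <- caseStudyBB()
  m <- fitQuadratic(bb$design, bb$response)
  cf <- unname(coef(m))
  # intercept and X1X2 interaction are exactly determined by the shipped
  # two-decimal responses (intercept = mean of the three center runs)
  expect_equal(cf[1], 0.64, tolerance = 1e-12)
  expect_equal(cf[1], mean(c(0.58, 0.69, 0.65)), tolerance = 1e-12)
  expect_equal(cf[5], -0.045, tolerance = 1e-12)
  expect_equal(cf[5], (-0.59 - 1.01 + 0.44 + 0.98) / 4, tolerance = 1e-12)
  # remaining coefficients deviate only through the rounding of the
  # published responses
  expect_true(all(abs(cf - published$coefs) <= 0.03))
  expect_equal(m$r_squared, published$r_squared, tolerance = 0.03 / 0.853)
})

test_that("residuals are orthogonal to every model column and R^2 is in range", {
  bb <- caseStudyBB()
  m <- fitQuadratic(bb$design, bb$response)
  M <- cbind(1, bb$design$coded,
             bb$design$coded[, 1] * bb$design$coded[, 2],
             bb$design$coded[, 1] * bb$design$coded[, 3],
             bb$design$coded[, 2] * bb$design$coded[, 3],
             bb$design$coded^2)
  expect_true(all(abs(crossprod(M, m$residuals)) < 1e-10))
  expect_gte(m$r_squared, 0)
  expect_lte(m$r_squared, 1)
})

test_that("noiseless synthetic responses are recovered exactly and refits are idempotent", {
  set.seed(21)
  for (k in 3:5) {
    truth <- random_quadratic(k)
    sim <- simulateBB(syntheticSpec("bb", coefficients = truth, noise_sd = 0))
    m <- fitQuadratic(sim$design, sim$response)
    expect_equal(coef(m), coef(truth), tolerance = 1e-10)
    # refit on the model's own predictions reproduces the coefficients
    m2 <- fitQuadratic(sim$design, predict(m, sim$design$coded))
    expect_equal(coef(m2), coef(m), tolerance = 1e-10)
  }
})

test_that("linear and interaction coefficients equal their contrast estimates on BB designs", {
  set.seed(31)
  for (rep in 1:10) {
    d <- bbDesign(3, 3)
    y <- stats::runif(15, 0, 1)
    m <- fitQuadratic(d, y)
    x <- d$coded
    for (i in 1:3)
      expect_equal(unname(m$linear[i]), sum(x[, i] * y) / sum(x[, i]^2),
                   tolerance = 1e-10)
    pr <- list(c(1, 2), c(1, 3), c(2, 3))
    for (p in seq_along(pr)) {
      xij <- x[, pr[[p]][1]] * x[, pr[[p]][2]]
      expect_equal(unname(m$interaction[p]), sum(xij * y) / sum(xij^2),
                   tolerance = 1e-10)
    }
  }
})

test_that("rank-deficient and underdetermined fits fail loudly", {
  d <- bbDesign(3, 3)
  d$coded <- d$coded[1:8, ]
  d$is_center <- d$is_center[1:8]
  expect_error(fitQuadratic(d, stats::runif(8)), "at least")
  d2 <- bbDesign(3, 3)
  d2$coded[, 3] <- d2$coded[, 2]  # duplicated factor column
  expect_error(fitQuadratic(d2, stats::runif(15)), "rank deficient")
})

test_that("prediction evaluates the polynomial term by term", {
  m <- caseStudyModel()
  expect_equal(predict(m, c(1, -1, 1)), 0.99375, tolerance = 1e-12)
  expect_equal(round(predict(m, c(1, -1, 1)), 3), 0.994)
  expect_equal(predict(m, c(0, 0, 0)), m$beta0)
  pts <- matrix(stats::runif(30, -1, 1), ncol = 3)
  expect_equal(predict(m, pts), eval_quad3(unname(coef(m)), pts),
               tolerance = 1e-12)
  expect_error(predict(m, c(1, 2)), "coordinates")
})

test_that("the published polynomial is maximized at the reported optimum", {
  m <- caseStudyModel()
  opt <- maximizeOverBox(m)
  expect_equal(unname(opt$coded), c(1, -1, 1))
  expect_equal(unname(opt$natural), c(1.125, 0.25, 225))
  expect_equal(round(opt$predicted, 3), 0.994)
  expect_true(all(opt$boundary))
  # agreement with the dense grid oracle (the optimum is a grid point)
  g <- grid_max3(published$coefs, step = 0.01)
  expect_lt(abs(opt$predicted - g$value), 1e-6)
  expect_equal(unname(g$point), c(1, -1, 1))
})

test_that("face enumeration handles interior, linear and degenerate quadratics", {
  # concave bowl: interior stationary maximum at the origin
  bowl <- quadraticModel(0, rep(0, 3), rep(0, 3), rep(-1, 3))
  ob <- maximizeOverBox(bowl)
  expect_equal(unname(ob$coded), rep(0, 3))
  expect_equal(ob$predicted, 0)
  expect_false(any(ob$boundary))
  # pure linear: maximum at the +1 corner of the active coordinate
  lin <- quadraticModel(0, c(1, 0, 0), rep(0, 3), rep(0, 3))
  ol <- maximizeOverBox(lin)
  expect_equal(unname(ol$coded[1]), 1)
  expect_equal(ol$predicted, 1)
  expect_true(ol$boundary[1])
  # singular Hessian with a linear tilt: flat directions end on a face
  dg <- quadraticModel(0, c(0.5, 0.25, 0), rep(0, 3), c(-1, 0, 0))
  od <- maximizeOverBox(dg)
  expect_equal(od$predicted, 0.0625 + 0.25, tolerance = 1e-9)
})

test_that("box maximization matches a multi-start bounded optimizer on random quadratics", {
  set.seed(101)
  for (rep in 1:100) {
    m <- random_quadratic(3)
    opt <- maximizeOverBox(m)
    expect_lt(abs(opt$predicted - optim_max(m, n_starts = 20, seed = rep)),
              1e-6)
    expect_true(all(abs(opt$coded) <= 1 + 1e-9))
    expect_equal(predict(m, unname(opt$coded)), opt$predicted,
                 tolerance = 1e-9)
  }
})

test_that("the box maximum dominates random interior points", {
  set.seed(55)
  m <- random_quadratic(3)
  opt <- maximizeOverBox(m)
  pts <- matrix(stats::runif(3000, -1, 1), ncol = 3)
  expect_true(all(predict(m, pts) <= opt$predicted + 1e-9))
})

test_that("surface grids slice the model as plotted", {
  m <- caseStudyModel()
  g <- surfaceGrid(m, c("CaCl2", "Volume"))
  expect_equal(nrow(g), 41L * 41L)
  expect_true(all(c("CaCl2", "Volume", "predicted",
                    "CaCl2_natural", "Volume_natural") %in% names(g)))
  # the high-CaCl2, high-volume corner region carries the grid maximum
  best <- g[which.max(g$predicted), ]
  expect_equal(c(best$CaCl2, best$Volume), c(1, 1))
  # grid max cannot exceed the exact maximum of the restricted slice
  slice <- quadraticModel(m$beta0, m$linear[c(1, 3)], m$interaction[2],
                          m$squared[c(1, 3)])
  expect_lte(max(g$predicted), maximizeOverBox(slice)$predicted + 1e-9)
  # constant model gives a flat grid
  flat <- quadraticModel(0.4, rep(0, 3), rep(0, 3), rep(0, 3))
  expect_equal(unique(surfaceGrid(flat, c(1, 2))$predicted), 0.4)
  expect_error(surfaceGrid(m, c(1, 1)), "distinct")
})

test_that("verification report quantifies prediction accuracy and gain", {
  m <- caseStudyModel()
  opt <- maximizeOverBox(m)
  v <- verificationReport(m, opt, observed = 0.938, basal = 0.646)
  expect_equal(v$deviation, 0.99375 - 0.938, tolerance = 1e-9)
  expect_equal(v$relative_deviation, (0.99375 - 0.938) / 0.99375,
               tolerance = 1e-9)
  expect_equal(v$fold_change, 1.45)
  v2 <- verificationReport(m, opt, observed = opt$predicted, basal = 0.646)
  expect_equal(v2$deviation, 0)
})
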