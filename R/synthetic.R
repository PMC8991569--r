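#' Specify a synthetic screening or response-surface dataset
#'
#' Describes a dataset with known ground truth: a design, true effect sizes
#' (PB) or true polynomial coefficients (BB), and i.i.d. run-to-run noise.
#' PB responses follow `y = mu + sum(E_j/2 * x_j) + eps` so that factor j's
#' expected main effect is exactly `E_j`; BB responses are the true
#' quadratic evaluated at the coded runs plus noise.
#'
#' @param kind `"pb"` or `"bb"`.
#' @param effects (PB) numeric vector of true main effects, one per factor,
#'   in response units (g/L).
#' @param coefficients (BB) true coefficient vector in model-matrix order
#'   (intercept, k linear, k(k-1)/2 interactions, k squared) or a
#'   `quadratic_model`.
#' @param noise_sd Standard deviation of the run-to-run noise (g/L, >= 0).
#' @param mu (PB) baseline response level; defaults to 0.338 g/L, the grand
#'   mean of the case-study screening responses, so simulated yields live on
#'   a realistic scale.
#' @param n_runs (PB) factorial run count, default 12.
#' @param n_center Number of center runs (default 0 for PB, 3 for BB).
#' @param noise `"gaussian"` (default) or `"t"` for a heavy-tailed
#'   alternative (Student t with `t_df` degrees of freedom, scaled to sd
#'   `noise_sd`) used in robustness checks.
#' @param t_df Degrees of freedom for the `"t"` noise option (> 2).
#' @param nonnegative If `TRUE`, responses are clamped at 0 (yields cannot
#'   be negative); off by default so estimator checks stay unbiased.
#' @param factors Optional list of [designFactor()] objects.
#' @return A `synthetic_spec` list.
#' @export
syntheticSpec <- function(kind = c("pb", "bb"), effects = NULL,
                          coefficients = NULL, noise_sd = 0.05,
                          mu = 0.338, n_runs = 12L,
                          n_center = if (kind == "bb") 3L else 0L,
                          noise = c("gaussian", "t"), t_df = 3,
                          nonnegative = FALSE, factors = NULL) {
  kind <- match.arg(kind)
  noise <- match.arg(noise)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (kind == "pb") {
    if (is.null(effects)) stop("a PB spec needs 'effects'")
    effects <- as.numeric(unlist(effects))
    k <- length(effects)
  } else {
    if (is.null(coefficients)) stop("a BB spec needs 'coefficients'")
    if (inherits(coefficients, "quadratic_model")) {
      k <- coefficients$k
      coefficients <- unname(coef(coefficients))
    } else {
      coefficients <- as.numeric(unlist(coefficients))
      # invert p = 1 + 2k + k(k-1)/2 for k
      p <- length(coefficients)
      k <- which(1 + 2 * (1:5) + (1:5) * (0:4) / 2 == p)
      if (!length(k))
        stop("coefficient count ", p,
             " does not match a full quadratic in 3-5 factors")
    }
  }
  structure(
    list(kind = kind, k = k, effects = effects, coefficients = coefficients,
         noise_sd = noise_sd, mu = mu, n_runs = as.integer(n_runs),
         n_center = as.integer(n_center), noise = noise, t_df = t_df,
         nonnegative = nonnegative, factors = factors),
    class = "synthetic_spec"
  )
}

.draw_noise <- function(spec, n) {
  if (spec$noise_sd == 0) return(numeric(n))
  if (spec$noise == "gaussian") {
    stats::rnorm(n, 0, spec$noise_sd)
  } else {
    scale <- spec$noise_sd / sqrt(spec$t_df / (spec$t_df - 2))
    scale * stats::rt(n, spec$t_df)
  }
}

.finish_response <- function(spec, y) {
  if (spec$nonnegative) pmax(y, 0) else y
}

#' Simulate a Plackett-Burman screening dataset
#'
#' @param spec A `synthetic_spec` with `kind = "pb"`.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `design` (a `doe_design`) and `response`.
#' @examples
#' sim <- simulatePB(syntheticSpec("pb", effects = c(0.3, rep(0, 10)),
#'                                 noise_sd = 0), seed = 1)
#' mainEffects(sim$design, sim$response)  # exactly (0.3, 0, ..., 0)
#' @export
simulatePB <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "pb")
  if (!is.null(seed)) set.seed(seed)
  design <- pbDesign(spec$k, spec$n_runs, spec$n_center, spec$factors)
  mean_y <- spec$mu + drop(design$coded %*% (spec$effects / 2))
  y <- .finish_response(spec, mean_y + .draw_noise(spec, length(mean_y)))
  list(design = design, response = y)
}

#' Simulate a Box-Behnken response-surface dataset
#'
#' @param spec A `synthetic_spec` with `kind = "bb"`.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `design`, `response`, and `truth` (the generating
#'   `quadratic_model`).
#' @examples
#' truth <- caseStudyModel()
#' sim <- simulateBB(syntheticSpec("bb", coefficients = truth,
#'                                 noise_sd = 0), seed = 1)
#' coef(fitQuadratic(sim$design, sim$response))  # recovers coef(truth)
#' @export
simulateBB <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "bb")
  if (!is.null(seed)) set.seed(seed)
  design <- bbDesign(spec$k, spec$n_center, spec$factors)
  mean_y <- drop(quadraticModelMatrix(design$coded) %*% spec$coefficients)
  y <- .finish_response(spec, mean_y + .draw_noise(spec, length(mean_y)))
  k <- spec$k
  nint <- k * (k - 1) / 2
  truth <- quadraticModel(
    beta0 = spec$coefficients[1L],
    linear = spec$coefficients[1L + seq_len(k)],
    interaction = spec$coefficients[1L + k + seq_len(nint)],
    squared = spec$coefficients[1L + k + nint + seq_len(k)],
    factors = spec$factors
  )
  list(design = design, response = y, truth = truth)
}
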