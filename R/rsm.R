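# Expanded second-order model matrix [1 | Xi | XiXj (i<j) | Xi^2] for a
# coded run matrix. Column order is fixed: intercept, k linear terms,
# k(k-1)/2 interactions in combn order, k squared terms.
quadraticModelMatrix <- function(coded) {
  coded <- as.matrix(coded)
  k <- ncol(coded)
  nms <- colnames(coded)
  if (is.null(nms)) nms <- paste0("X", seq_len(k))
  cols <- list(`(Intercept)` = rep(1, nrow(coded)))
  for (i in seq_len(k)) cols[[nms[i]]] <- coded[, i]
  if (k >= 2L) {
    pr <- utils::combn(k, 2L)
    for (p in seq_len(ncol(pr))) {
      i <- pr[1L, p]; j <- pr[2L, p]
      cols[[paste0(nms[i], ":", nms[j])]] <- coded[, i] * coded[, j]
    }
  }
  for (i in seq_len(k)) cols[[paste0(nms[i], "^2")]] <- coded[, i]^2
  do.call(cbind, cols)
}

.new_quadratic <- function(beta0, linear, interaction, squared, factors,
                           r_squared = NA_real_, residuals = NULL,
                           fitted = NULL) {
  k <- length(linear)
  structure(
    list(k = k, beta0 = beta0, linear = linear, interaction = interaction,
         squared = squared, factors = factors, r_squared = r_squared,
         residuals = residuals, fitted = fitted),
    class = "quadratic_model"
  )
}

#' Build a second-order polynomial model from known coefficients
#'
#' Constructs the same object [fitQuadratic()] returns, from externally
#' supplied coefficients over coded variables — e.g. a published polynomial
#' or the ground truth of a simulation.
#'
#' @param beta0 Intercept (g/L).
#' @param linear Numeric vector of k linear coefficients.
#' @param interaction Numeric vector of k(k-1)/2 pairwise interaction
#'   coefficients, ordered (1,2), (1,3), ..., (k-1,k).
#' @param squared Numeric vector of k squared-term coefficients.
#' @param factors Optional list of [designFactor()] objects for
#'   natural-unit reporting.
#' @return A `quadratic_model` object.
#' @export
quadraticModel <- function(beta0, linear, interaction, squared,
                           factors = NULL) {
  k <- length(linear)
  if (length(squared) != k)
    stop("'squared' must have length ", k)
  if (length(interaction) != k * (k - 1) / 2)
    stop("'interaction' must have length k(k-1)/2 = ", k * (k - 1) / 2)
  nms <- if (!is.null(factors)) vapply(factors, `[[`, "", "name")
         else paste0("X", seq_len(k))
  linear <- stats::setNames(as.numeric(linear), nms)
  squared <- stats::setNames(as.numeric(squared), paste0(nms, "^2"))
  inms <- if (k >= 2L)
    apply(utils::combn(k, 2L), 2L, function(p) paste(nms[p], collapse = ":"))
  else character(0)
  interaction <- stats::setNames(as.numeric(interaction), inms)
  .new_quadratic(as.numeric(beta0), linear, interaction, squared, factors)
}

#' Fit the full second-order response model by least squares
#'
#' Fits `Y = b0 + sum(bi Xi) + sum(bij Xi Xj) + sum(bii Xi^2)` over coded
#' variables to a response-surface design via QR least squares
#' ([stats::lm.fit()] on the expanded model matrix). For Box-Behnken
#' designs the linear and interaction coefficients are cross-checked
#' against their closed-form contrast estimates `sum(Xi y) / sum(Xi^2)` and
#' `sum(XiXj y) / sum((XiXj)^2)`, which orthogonality makes exact.
#'
#' @param design A `doe_design` (typically from [bbDesign()] or
#'   [caseStudyBB()]).
#' @param response Per-run responses (g/L).
#' @return A `quadratic_model` with coefficients, `r_squared`
#'   (`1 - SSE/SST`), residuals and fitted values.
#' @examples
#' cs <- caseStudyBB()
#' fit <- fitQuadratic(cs$design, cs$response)
#' coef(fit)
#' @export
fitQuadratic <- function(design, response) {
  validateResponse(design, response)
  M <- quadraticModelMatrix(design$coded)
  if (nrow(M) < ncol(M))
    stop("need at least ", ncol(M), " runs to fit ", ncol(M), " coefficients")
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- colnames(M)[qrM$pivot[-seq_len(qrM$rank)]]
    stop("model matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(M, response)
  beta <- fit$coefficients
  k <- ncol(design$coded)
  nint <- k * (k - 1) / 2
  sse <- sum(fit$residuals^2)
  sst <- sum((response - mean(response))^2)
  model <- .new_quadratic(
    beta0 = unname(beta[1L]),
    linear = beta[1L + seq_len(k)],
    interaction = beta[1L + k + seq_len(nint)],
    squared = beta[1L + k + nint + seq_len(k)],
    factors = design$factors,
    r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
    residuals = unname(fit$residuals),
    fitted = unname(fit$fitted.values)
  )
  if (design$type == "bb") .check_bb_contrasts(design, response, model)
  model
}

# Internal consistency check: on a BB design, orthogonality forces the LS
# linear/interaction coefficients to equal their contrast estimates.
.check_bb_contrasts <- function(design, response, model, tol = 1e-8) {
  x <- design$coded
  for (i in seq_len(ncol(x))) {
    est <- sum(x[, i] * response) / sum(x[, i]^2)
    if (abs(est - model$linear[i]) > tol)
      stop("internal error: linear coefficient ", i,
           " disagrees with its contrast estimate")
  }
  pr <- utils::combn(ncol(x), 2L)
  for (p in seq_len(ncol(pr))) {
    xij <- x[, pr[1L, p]] * x[, pr[2L, p]]
    est <- sum(xij * response) / sum(xij^2)
    if (abs(est - model$interaction[p]) > tol)
      stop("internal error: interaction coefficient ", p,
           " disagrees with its contrast estimate")
  }
  invisible(TRUE)
}

#' @export
coef.quadratic_model <- function(object, ...) {
  c("(Intercept)" = object$beta0, object$linear, object$interaction,
    object$squared)
}

#' Evaluate a fitted quadratic at coded points
#'
#' @param object A `quadratic_model`.
#' @param newdata Coded point: a length-k vector or an n x k matrix.
#' @param ... Unused.
#' @return Predicted response(s), g/L.
#' @export
predict.quadratic_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$k)
    stop("points must have ", object$k, " coordinates")
  drop(quadraticModelMatrix(newdata) %*% coef(object))
}

#' @export
print.quadratic_model <- function(x, digits = 5, ...) {
  cat(sprintf("Second-order model in %d coded variables", x$k))
  if (!is.na(x$r_squared)) cat(sprintf("  (R^2 = %.3f)", x$r_squared))
  cat("\n")
  print(round(coef(x), digits))
  invisible(x)
}

# Quadratic in the form f(x) = c + b'x + x'Hx with H symmetric
# (H[i,i] = beta_ii, H[i,j] = beta_ij / 2).
.quad_parts <- function(model) {
  k <- model$k
  H <- diag(as.numeric(model$squared), k)
  if (k >= 2L) {
    pr <- utils::combn(k, 2L)
    for (p in seq_len(ncol(pr))) {
      H[pr[1L, p], pr[2L, p]] <- H[pr[2L, p], pr[1L, p]] <-
        model$interaction[p] / 2
    }
  }
  list(c = model$beta0, b = as.numeric(model$linear), H = H)
}

#' Exact global maximum of a quadratic over the coded cube
#'
#' Maximizes the second-order model over the box `[lower, upper]^k` by
#' exhaustive face enumeration: every subset of coordinates is fixed at a
#' bound, the stationary point of the restricted quadratic in the free
#' coordinates is solved from its normal equations and kept when it lies
#' inside the face, and all corners are included. The best candidate is the
#' exact global maximum (a quadratic restricted to a face is again a
#' quadratic, so every local maximum is either a face-interior stationary
#' point or lies on that face's boundary, which a lower-dimensional face
#' covers; singular restricted Hessians simply contribute no interior
#' candidate).
#'
#' @param model A `quadratic_model`.
#' @param lower,upper Box bounds per coded coordinate (scalars; default -1
#'   and +1, the design region).
#' @return An `optimum` object: `coded` (argmax), `natural` (same point in
#'   natural units when the model carries factor bindings), `predicted`
#'   (model value, g/L), and `boundary` (logical, which coordinates are
#'   clamped at a bound).
#' @examples
#' m <- caseStudyModel()
#' maximizeOverBox(m)   # coded (+1, -1, +1), predicted 0.99375 g/L
#' @export
maximizeOverBox <- function(model, lower = -1, upper = 1) {
  stopifnot(inherits(model, "quadratic_model"), lower < upper)
  if (model$k > 5L) stop("face enumeration implemented for k <= 5")
  qp <- .quad_parts(model)
  k <- model$k
  best_x <- NULL
  best_v <- -Inf
  # status per coordinate: 0 = free, 1 = at lower, 2 = at upper
  for (code in seq_len(3L^k) - 1L) {
    status <- (code %/% 3L^(seq_len(k) - 1L)) %% 3L
    x <- numeric(k)
    x[status == 1L] <- lower
    x[status == 2L] <- upper
    free <- which(status == 0L)
    if (length(free)) {
      Hff <- qp$H[free, free, drop = FALSE]
      rhs <- if (length(free) == k) -qp$b
             else -(qp$b[free] +
                      2 * drop(qp$H[free, -free, drop = FALSE] %*% x[-free]))
      sol <- tryCatch(solve(2 * Hff, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      if (any(sol < lower - 1e-12) || any(sol > upper + 1e-12)) next
      x[free] <- pmin(pmax(as.numeric(sol), lower), upper)
    }
    v <- drop(qp$c + sum(qp$b * x) + t(x) %*% qp$H %*% x)
    if (v > best_v) { best_v <- v; best_x <- x }
  }
  coded <- stats::setNames(best_x, names(model$linear))
  natural <- if (!is.null(model$factors))
    stats::setNames(
      vapply(seq_len(k), function(i) decodeLevels(model$factors[[i]], best_x[i]),
             numeric(1)),
      names(model$linear))
  else NULL
  structure(
    list(coded = coded, natural = natural, predicted = best_v,
         boundary = abs(abs(best_x) - max(abs(lower), abs(upper))) < 1e-9),
    class = "optimum"
  )
}

#' @export
print.optimum <- function(x, ...) {
  cat("Box-constrained optimum of the fitted quadratic\n")
  cat("  coded:    ", paste(sprintf("%s = %+g", names(x$coded), x$coded),
                            collapse = ", "), "\n")
  if (!is.null(x$natural))
    cat("  natural:  ", paste(sprintf("%s = %g", names(x$natural), x$natural),
                              collapse = ", "), "\n")
  cat(sprintf("  predicted response: %.5f g/L\n", x$predicted))
  invisible(x)
}

#' Response-surface grid for two factors
#'
#' Evaluates the model on a rectangular grid over `[-1, 1]^2` in two chosen
#' factors, the remaining factors held at fixed coded levels (default 0,
#' the centre), for 3-D surface or contour plotting.
#'
#' @param model A `quadratic_model`.
#' @param pair Indices (or names) of the two factors to vary.
#' @param fixed Coded levels for the other factors; scalar or named vector
#'   (default 0).
#' @param n Grid points per axis (default 41).
#' @return A data frame with coded coordinates (`<a>`, `<b>`), natural
#'   coordinates (`<a>_natural`, `<b>_natural`, when factor bindings are
#'   present) and `predicted` (g/L).
#' @export
surfaceGrid <- function(model, pair, fixed = 0, n = 41L) {
  nms <- names(model$linear)
  if (is.character(pair)) pair <- match(pair, nms)
  if (length(pair) != 2L || anyNA(pair) || pair[1L] == pair[2L])
    stop("'pair' must name two distinct factors")
  others <- setdiff(seq_len(model$k), pair)
  fx <- rep(0, model$k)
  if (length(fixed) == 1L) fx[others] <- fixed
  else fx[others] <- fixed[nms[others]]
  s <- seq(-1, 1, length.out = n)
  g <- expand.grid(a = s, b = s)
  pts <- matrix(rep(fx, each = nrow(g)), nrow(g), model$k)
  pts[, pair[1L]] <- g$a
  pts[, pair[2L]] <- g$b
  out <- data.frame(g$a, g$b, predicted = predict(model, pts))
  names(out)[1:2] <- nms[pair]
  if (!is.null(model$factors)) {
    out[[paste0(nms[pair[1L]], "_natural")]] <-
      decodeLevels(model$factors[[pair[1L]]], g$a)
    out[[paste0(nms[pair[2L]], "_natural")]] <-
      decodeLevels(model$factors[[pair[2L]]], g$b)
  }
  out
}

#' Compare the model prediction at the optimum with observed yields
#'
#' Tabulates the predicted response at the optimum against the yield
#' measured in a verification run, with absolute and relative deviation,
#' and the fold change of the observed yield over a basal-medium yield.
#'
#' @param model A `quadratic_model`.
#' @param optimum An `optimum` from [maximizeOverBox()].
#' @param observed Measured yield at the optimum (g/L, > 0).
#' @param basal Yield under the unoptimized basal medium (g/L, > 0).
#' @return A `verification_report` list: `predicted`, `observed`,
#'   `deviation`, `relative_deviation`, `fold_change`.
#' @export
verificationReport <- function(model, optimum, observed, basal) {
  stopifnot(observed > 0, basal > 0)
  pred <- optimum$predicted
  structure(
    list(predicted = pred, observed = observed,
         deviation = abs(pred - observed),
         relative_deviation = abs(pred - observed) / pred,
         fold_change = foldChange(observed, basal)),
    class = "verification_report"
  )
}

#' @export
print.verification_report <- function(x, ...) {
  cat("Verification of the model optimum\n")
  cat(sprintf("  predicted yield:  %.3f g/L\n", x$predicted))
  cat(sprintf("  observed yield:   %.3f g/L\n", x$observed))
  cat(sprintf("  deviation:        %.3f g/L (%.1f%% of predicted)\n",
              x$deviation, 100 * x$relative_deviation))
  cat(sprintf("  fold over basal:  %.2f\n", x$fold_change))
  invisible(x)
}
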