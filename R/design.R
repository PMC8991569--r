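# Standard cyclic first-row generators for Plackett-Burman designs.
# Row i is a cyclic right shift of row i-1; the final row is all -1.
.pb_generators <- list(
  `8`  = c(1, 1, 1, -1, 1, -1, -1),
  `12` = c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1),
  `16` = c(1, 1, 1, 1, -1, 1, -1, 1, 1, -1, -1, 1, -1, -1, -1),
  `20` = c(1, 1, -1, -1, 1, 1, 1, 1, -1, 1, -1, 1, -1, -1, -1, -1, 1, 1, -1),
  `24` = c(1, 1, 1, 1, 1, -1, 1, -1, 1, 1, -1, -1, 1, 1, -1, -1, 1, -1,
           1, -1, -1, -1, -1)
)

.new_design <- function(coded, factors, type) {
  is_center <- apply(coded, 1L, function(r) all(r == 0))
  if (!is.null(factors)) colnames(coded) <- vapply(factors, `[[`, "", "name")
  else colnames(coded) <- paste0("X", seq_len(ncol(coded)))
  rownames(coded) <- as.character(seq_len(nrow(coded)))
  structure(
    list(coded = coded, factors = factors, is_center = is_center, type = type),
    class = "doe_design"
  )
}

#' Generate a Plackett-Burman screening design
#'
#' Two-level fractional factorial screening design in `n_runs` runs (a
#' multiple of 4) for up to `n_runs - 1` factors, built from the standard
#' cyclic first-row generator: the generator row is cyclically shifted
#' `n_runs - 1` times and an all-minus row is appended, then the matrix is
#' truncated to the first `n_factors` columns. Columns are balanced (equal
#' numbers of +1 and -1) and mutually orthogonal. Optional all-zero center
#' runs are appended last.
#'
#' @param n_factors Number of factors to screen (2 to `n_runs - 1`).
#' @param n_runs Number of factorial runs; one of 8, 12, 16, 20, 24.
#' @param n_center Number of appended center (all-zero) runs.
#' @param factors Optional list of [designFactor()] objects (length
#'   `n_factors`) binding natural units to the coded columns.
#' @return A `doe_design` object; see [validateDesign()] for the structural
#'   guarantees.
#' @examples
#' d <- pbDesign(11, n_runs = 12, n_center = 1)
#' crossprod(d$coded[!d$is_center, ])  # 12 * I on the diagonal, 0 elsewhere
#' @export
pbDesign <- function(n_factors, n_runs = 12L, n_center = 0L, factors = NULL) {
  n_runs <- as.integer(n_runs)
  gen <- .pb_generators[[as.character(n_runs)]]
  if (is.null(gen))
    stop("no Plackett-Burman generator for n_runs = ", n_runs,
         "; supported sizes: ", paste(names(.pb_generators), collapse = ", "))
  if (n_factors < 2L || n_factors > n_runs - 1L)
    stop("n_factors must be between 2 and n_runs - 1 = ", n_runs - 1L)
  if (!is.null(factors) && length(factors) != n_factors)
    stop("'factors' must have length n_factors = ", n_factors)
  m <- n_runs - 1L
  rows <- t(vapply(seq_len(m) - 1L,
                   function(s) gen[((seq_len(m) - 1L - s) %% m) + 1L],
                   numeric(m)))
  coded <- rbind(rows, rep(-1, m))[, seq_len(n_factors), drop = FALSE]
  if (n_center > 0L)
    coded <- rbind(coded, matrix(0, n_center, n_factors))
  d <- .new_design(coded, factors, "pb")
  validateDesign(d)
  d
}

#' Generate a Box-Behnken response-surface design
#'
#' Three-level design whose non-center runs sit at the midpoints of the
#' edges of the factor cube: for every pair of factors (in factor-index
#' order) all four combinations of coded -1/+1 are run with every other
#' factor at 0, followed by `n_center` center runs. For 3 factors and 3
#' center runs this is the classical 15-run design supporting a full
#' second-order polynomial fit.
#'
#' @param n_factors Number of factors, 3 to 5.
#' @param n_center Number of center runs (>= 1).
#' @param factors Optional list of [designFactor()] objects.
#' @return A `doe_design` object.
#' @examples
#' d <- bbDesign(3, n_center = 3)
#' nrow(d$coded)          # 15
#' rowSums(d$coded != 0)  # each non-center run varies exactly two factors
#' @export
bbDesign <- function(n_factors = 3L, n_center = 3L, factors = NULL) {
  n_factors <- as.integer(n_factors)
  if (n_factors < 3L || n_factors > 5L)
    stop("Box-Behnken construction supports 3 to 5 factors, got ", n_factors)
  if (n_center < 1L) stop("n_center must be >= 1")
  if (!is.null(factors) && length(factors) != n_factors)
    stop("'factors' must have length n_factors = ", n_factors)
  pairs <- utils::combn(n_factors, 2L)
  signs <- as.matrix(expand.grid(a = c(-1, 1), b = c(-1, 1)))
  coded <- matrix(0, ncol(pairs) * 4L + n_center, n_factors)
  r <- 0L
  for (p in seq_len(ncol(pairs))) {
    for (s in seq_len(4L)) {
      r <- r + 1L
      coded[r, pairs[1L, p]] <- signs[s, 1L]
      coded[r, pairs[2L, p]] <- signs[s, 2L]
    }
  }
  d <- .new_design(coded, factors, "bb")
  validateDesign(d)
  d
}

#' Validate the structural invariants of a design
#'
#' Checks that every coded entry is -1, 0 or +1 and that `is_center` flags
#' exactly the all-zero rows. For PB designs, additionally checks (after
#' excluding center runs) column balance and pairwise column orthogonality;
#' for BB designs, that each non-center run has exactly two nonzero entries
#' and that linear columns are orthogonal to each other and to all
#' pairwise-product columns. Errors describe the first violated invariant.
#'
#' @param design A `doe_design` object.
#' @return Invisibly `TRUE` if all checks pass.
#' @export
validateDesign <- function(design) {
  stopifnot(inherits(design, "doe_design"))
  x <- design$coded
  if (!all(x %in% c(-1, 0, 1)))
    stop("coded entries must all be -1, 0 or +1")
  if (!identical(unname(design$is_center),
                 unname(apply(x, 1L, function(r) all(r == 0)))))
    stop("is_center flags disagree with all-zero rows")
  f <- x[!design$is_center, , drop = FALSE]
  if (design$type == "pb") {
    if (any(f == 0)) stop("PB factorial runs must use only +1/-1 levels")
    if (any(colSums(f) != 0))
      stop("PB columns unbalanced: ",
           paste(colnames(f)[colSums(f) != 0], collapse = ", "))
    g <- crossprod(f)
    if (any(g[upper.tri(g)] != 0))
      stop("PB columns are not mutually orthogonal")
  } else if (design$type == "bb") {
    if (any(rowSums(f != 0) != 2L))
      stop("BB non-center runs must vary exactly two factors")
    k <- ncol(f)
    if (any(colSums(f) != 0)) stop("BB linear columns must sum to zero")
    g <- crossprod(f)
    if (any(g[upper.tri(g)] != 0))
      stop("BB linear columns are not mutually orthogonal")
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      prod_col <- f[, i] * f[, j]
      if (any(abs(crossprod(f, prod_col)) > 0))
        stop("BB linear columns not orthogonal to product column ",
             colnames(f)[i], ":", colnames(f)[j])
    }
  }
  invisible(TRUE)
}

#' @export
print.doe_design <- function(x, ...) {
  cat(sprintf("%s design: %d runs (%d center) x %d factors\n",
              toupper(x$type), nrow(x$coded), sum(x$is_center), ncol(x$coded)))
  print(x$coded)
  invisible(x)
}

# Factorial (non-center) rows of a design, with the aligned response.
.factorial_part <- function(design, response = NULL) {
  keep <- !design$is_center
  out <- list(coded = design$coded[keep, , drop = FALSE])
  if (!is.null(response)) out$response <- response[keep]
  out
}

#' Check a response vector against a design
#'
#' Responses must align one-to-one with design runs and be finite. With
#' `nonnegative = TRUE` (the rule applied when measured yields are read
#' from disk) negative values are rejected too; the analysis functions
#' leave it off so that unclamped synthetic responses remain usable.
#'
#' @param design A `doe_design` object.
#' @param response Numeric vector of per-run responses (g/L).
#' @param nonnegative Reject negative values (yields are masses per litre).
#' @return Invisibly `TRUE`.
#' @export
validateResponse <- function(design, response, nonnegative = FALSE) {
  stopifnot(inherits(design, "doe_design"))
  if (length(response) != nrow(design$coded))
    stop("response length ", length(response),
         " does not match ", nrow(design$coded), " design runs")
  if (!all(is.finite(response))) stop("responses must be finite")
  if (nonnegative && any(response < 0))
    stop("negative responses are not allowed for yields")
  invisible(TRUE)
}
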