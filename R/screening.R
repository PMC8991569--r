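#' Default significance thresholds for screening t-statistics
#'
#' Tabulated two-sided critical t values used to classify per-factor
#' statistics from a 12-run screening design (10 degrees of freedom):
#' 3.70 (1\%), 2.446 (5\%), 1.94 (10\%), 1.372 (20\%).
#'
#' @return A data frame with columns `level` (character) and `critical`
#'   (numeric, strictly decreasing).
#' @export
tThresholds <- function() {
  data.frame(level = c("1%", "5%", "10%", "20%"),
             critical = c(3.70, 2.446, 1.94, 1.372),
             stringsAsFactors = FALSE)
}

# Split a response into high/low groups for one coded column; center runs
# must already be excluded. Errors if the +/- groups are unbalanced.
.groups <- function(x, y, name) {
  hi <- y[x == 1]; lo <- y[x == -1]
  if (length(hi) != length(lo))
    stop("column '", name, "' is unbalanced after excluding center runs (",
         length(hi), " high vs ", length(lo), " low)")
  list(hi = hi, lo = lo)
}

#' Per-factor main effects from a screening design
#'
#' The main effect of factor i is `(sum of responses at +1 - sum at -1) / N`
#' with `N` = half the number of factorial runs — equivalently the
#' difference between the high-group and low-group mean responses. Center
#' runs carry no +/- level and are excluded.
#'
#' @param design A PB `doe_design`.
#' @param response Per-run responses (g/L), aligned with the design rows.
#' @return Named numeric vector of main effects, in response units.
#' @export
mainEffects <- function(design, response) {
  validateResponse(design, response)
  fp <- .factorial_part(design, response)
  vapply(colnames(fp$coded), function(nm) {
    g <- .groups(fp$coded[, nm], fp$response, nm)
    mean(g$hi) - mean(g$lo)
  }, numeric(1))
}

#' Per-factor pooled t-statistics from a screening design
#'
#' Equal-variance unpaired two-sample t between the responses at a factor's
#' high and low levels:
#' `t = (mean+ - mean-) / sqrt(s2p * (1/n+ + 1/n-))` with the pooled
#' variance `s2p = ((n+ - 1) s2+ + (n- - 1) s2-) / (n+ + n- - 2)`. Center
#' runs are excluded. A zero pooled variance yields signed `Inf` (with a
#' warning) when the effect is nonzero, and `t = 0` when it is zero.
#'
#' @inheritParams mainEffects
#' @return Named numeric vector of t statistics, with attribute `df` giving
#'   the per-factor degrees of freedom `n+ + n- - 2`.
#' @export
tValues <- function(design, response) {
  validateResponse(design, response)
  fp <- .factorial_part(design, response)
  df <- numeric(ncol(fp$coded))
  tv <- vapply(seq_len(ncol(fp$coded)), function(j) {
    nm <- colnames(fp$coded)[j]
    g <- .groups(fp$coded[, j], fp$response, nm)
    n1 <- length(g$hi); n2 <- length(g$lo)
    if (n1 < 2L) stop("column '", nm, "': each group needs >= 2 runs")
    df[j] <<- n1 + n2 - 2L
    s2p <- ((n1 - 1) * stats::var(g$hi) + (n2 - 1) * stats::var(g$lo)) /
      (n1 + n2 - 2)
    eff <- mean(g$hi) - mean(g$lo)
    if (s2p == 0) {
      if (eff == 0) return(0)
      warning("column '", nm, "': zero pooled variance with nonzero effect")
      return(sign(eff) * Inf)
    }
    eff / sqrt(s2p * (1 / n1 + 1 / n2))
  }, numeric(1))
  names(tv) <- colnames(fp$coded)
  attr(tv, "df") <- stats::setNames(df, colnames(fp$coded))
  tv
}

#' Classify t-statistics against a threshold table
#'
#' Each `|t|` is labelled with the most stringent tabulated level whose
#' critical value it reaches (boundary inclusive: `|t|` equal to a critical
#' value earns that level), else `"n.s."`.
#'
#' @param t Numeric vector of t statistics.
#' @param thresholds Threshold table as from [tThresholds()].
#' @return Character vector of significance labels.
#' @export
classifySignificance <- function(t, thresholds = tThresholds()) {
  stopifnot(is.data.frame(thresholds),
            all(c("level", "critical") %in% names(thresholds)))
  if (any(diff(thresholds$critical) >= 0))
    stop("threshold critical values must be strictly decreasing")
  vapply(abs(t), function(at) {
    hit <- which(thresholds$critical <= at)
    if (length(hit)) thresholds$level[hit[1L]] else "n.s."
  }, character(1))
}

#' Screen factors with a Plackett-Burman design
#'
#' Runs the full screening analysis: main effects, pooled t statistics,
#' significance classification, and a ranking by `|t|`.
#'
#' @inheritParams mainEffects
#' @param thresholds Significance threshold table; see [tThresholds()].
#' @return A data frame of class `pb_screening` with one row per factor:
#'   `factor`, `main_effect`, `t_value`, `abs_t`, `df`, `significance`,
#'   `sign` (`"+"`/`"-"`/`"0"`), `rank`.
#' @examples
#' cs <- caseStudyPB()
#' pbScreen(cs$design, cs$response)
#' @export
pbScreen <- function(design, response, thresholds = tThresholds()) {
  me <- mainEffects(design, response)
  tv <- tValues(design, response)
  res <- data.frame(
    factor = names(me),
    main_effect = unname(me),
    t_value = unname(tv),
    abs_t = abs(unname(tv)),
    df = unname(attr(tv, "df")),
    significance = classifySignificance(tv, thresholds),
    sign = ifelse(me > 0, "+", ifelse(me < 0, "-", "0")),
    stringsAsFactors = FALSE
  )
  ord <- order(-res$abs_t, -abs(res$main_effect), seq_len(nrow(res)))
  res$rank <- match(seq_len(nrow(res)), ord)
  class(res) <- c("pb_screening", class(res))
  res
}

#' @export
print.pb_screening <- function(x, digits = 3, ...) {
  cat("Plackett-Burman screening:", nrow(x), "factors\n")
  y <- x[order(x$rank), ]
  y$main_effect <- signif(y$main_effect, digits)
  y$t_value <- signif(y$t_value, digits)
  y$abs_t <- signif(y$abs_t, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Select the top-ranked factors from a screening
#'
#' Orders factors by `|t|` descending (ties broken by `|main effect|`, then
#' input order) and returns the first `k`, each tagged with the direction in
#' which the follow-up design should explore: a positive main effect points
#' upward (centre the next design above the current high level), a negative
#' one downward.
#'
#' @param screening A `pb_screening` result from [pbScreen()].
#' @param k Number of factors to keep (`k <=` number screened).
#' @return A data frame with columns `factor`, `main_effect`, `t_value`,
#'   `sign`, in rank order.
#' @export
selectSignificant <- function(screening, k) {
  stopifnot(inherits(screening, "pb_screening"))
  if (k > nrow(screening)) stop("k exceeds the number of screened factors")
  out <- screening[order(screening$rank), , drop = FALSE][seq_len(k), ]
  out <- out[, c("factor", "main_effect", "t_value", "sign")]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Fold change of a yield over a reference yield
#'
#' @param new_yield Yield under the new condition (g/L).
#' @param reference_yield Yield under the reference condition (g/L, > 0).
#' @param digits Decimal places to round to (default 2, the conventional
#'   reporting precision).
#' @return `new_yield / reference_yield`, rounded.
#' @examples
#' foldChange(0.938, 0.646)  # 1.45
#' @export
foldChange <- function(new_yield, reference_yield, digits = 2) {
  if (any(reference_yield <= 0)) stop("reference yield must be positive")
  round(new_yield / reference_yield, digits)
}
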