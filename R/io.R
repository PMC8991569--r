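#' Load a factor configuration file
#'
#' Reads a YAML file with a top-level `levels: coded|natural` key and a
#' `factors` list of blocks with `name`, `unit`, `low`, `high` and optional
#' `center`.
#'
#' @param path Path to the YAML config.
#' @return A list with `factors` (list of [designFactor()]) and `levels`.
#' @export
readFactorConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$factors)) stop("config has no 'factors' block: ", path)
  levels <- cfg$levels %||% "coded"
  if (!levels %in% c("coded", "natural"))
    stop("config 'levels' must be 'coded' or 'natural', got '", levels, "'")
  factors <- lapply(cfg$factors, function(f) {
    if (is.null(f$name) || is.null(f$low) || is.null(f$high))
      stop("each factor block needs 'name', 'low' and 'high'")
    if (is.null(f$center))
      designFactor(f$name, f$low, f$high, unit = f$unit %||% "")
    else
      designFactor(f$name, f$low, f$high, center = f$center,
                   unit = f$unit %||% "")
  })
  list(factors = factors, levels = levels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a design (and optional response) from CSV
#'
#' Expects a header `run,<factor1>,...,<factorK>[,response]` and one row
#' per run. Levels may be coded (-1/0/+1) or natural; natural levels are
#' converted to coded on load and must equal a factor's low, center or high
#' level exactly. Malformed rows are reported with their line numbers.
#'
#' @param path Path to the CSV file.
#' @param config A config list from [readFactorConfig()], or a bare list of
#'   [designFactor()] objects (then `levels` applies).
#' @param levels `"coded"` or `"natural"`; overrides the config when given.
#' @param type Design type for validation: `"pb"`, `"bb"`, or `"none"`
#'   (structure checks skipped).
#' @return A list with `design` (a `doe_design`) and `response` (numeric,
#'   or `NULL` when the file has no response column).
#' @examples
#' cfg <- system.file("extdata", "hw_as1_bb_factors.yml", package = "fermopt")
#' csv <- system.file("extdata", "hw_as1_bb_design.csv", package = "fermopt")
#' dat <- readDesign(csv, readFactorConfig(cfg), type = "bb")
#' @export
readDesign <- function(path, config, levels = NULL, type = "none") {
  if (!file.exists(path)) stop("design file not found: ", path)
  factors <- if (!is.null(config$factors)) config$factors else config
  if (is.null(levels)) levels <- config$levels %||% "coded"
  tab <- tryCatch(
    utils::read.csv(path, check.names = FALSE, strip.white = TRUE),
    error = function(e) stop("cannot parse '", path, "': ", conditionMessage(e))
  )
  if (nrow(tab) == 0L) stop("design file '", path, "' contains no runs")
  fnames <- vapply(factors, `[[`, "", "name")
  missing <- setdiff(fnames, names(tab))
  if (length(missing))
    stop("design file is missing factor column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(tab), c("run", fnames, "response"))
  if (length(extra))
    stop("unknown column(s) in design file: ", paste(extra, collapse = ", "))
  coded <- matrix(NA_real_, nrow(tab), length(fnames),
                  dimnames = list(NULL, fnames))
  for (j in seq_along(fnames)) {
    v <- tab[[fnames[j]]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop("non-numeric level for '", fnames[j], "' at data line ",
           paste(bad + 1L, collapse = ", "))
    }
    if (levels == "natural") {
      f <- factors[[j]]
      lv <- c(f$low, f$center, f$high)
      idx <- match(v, lv)
      if (anyNA(idx))
        stop("factor '", fnames[j], "': natural level(s) ",
             paste(unique(v[is.na(idx)]), collapse = ", "),
             " not among {low=", f$low, ", center=", f$center,
             ", high=", f$high, "} (data line ",
             paste(which(is.na(idx)) + 1L, collapse = ", "), ")")
      coded[, j] <- c(-1, 0, 1)[idx]
    } else {
      if (!all(v %in% c(-1, 0, 1)))
        stop("factor '", fnames[j], "': coded levels must be -1/0/+1 ",
             "(data line ",
             paste(which(!v %in% c(-1, 0, 1)) + 1L, collapse = ", "), ")")
      coded[, j] <- v
    }
  }
  response <- NULL
  if ("response" %in% names(tab)) {
    response <- tab$response
    if (!is.numeric(response) || anyNA(response)) {
      bad <- which(is.na(suppressWarnings(as.numeric(response))) |
                     is.na(response))
      stop("non-numeric or missing response at data line ",
           paste(bad + 1L, collapse = ", "),
           if (!is.null(tab$run)) paste0(" (run ",
                                         paste(tab$run[bad], collapse = ", "),
                                         ")") else "")
    }
  }
  design <- .new_design(coded, factors, type)
  if (type %in% c("pb", "bb")) validateDesign(design)
  if (!is.null(response)) validateResponse(design, response, nonnegative = TRUE)
  list(design = design, response = response)
}

#' Write a design (and optional response) to CSV
#'
#' Inverse of [readDesign()]: writes `run,<factors>[,response]` with coded
#' or natural levels.
#'
#' @param design A `doe_design`.
#' @param path Output CSV path.
#' @param response Optional response vector, aligned with the design rows.
#' @param levels `"coded"` (default) or `"natural"` (requires factor
#'   bindings).
#' @return Invisibly, `path`.
#' @export
writeDesign <- function(design, path, response = NULL, levels = "coded") {
  stopifnot(inherits(design, "doe_design"))
  x <- design$coded
  if (levels == "natural") {
    if (is.null(design$factors))
      stop("natural-level output needs factor bindings")
    for (j in seq_len(ncol(x)))
      x[, j] <- decodeLevels(design$factors[[j]], x[, j])
  }
  out <- data.frame(run = seq_len(nrow(x)), x, check.names = FALSE)
  if (!is.null(response)) {
    validateResponse(design, response)
    out$response <- response
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "fermopt")
  if (!nzchar(path)) stop("fixture '", file, "' not found")
  path
}

#' Case-study screening dataset (H. werneckii AS1 melanin)
#'
#' The 11-factor, 12-run Plackett-Burman screening table of the Hortaea
#' werneckii AS1 melanin optimization case study, plus its appended center
#' run (trial 13), with measured melanin yields (g/L). The matrix is
#' shipped exactly as run, preserving the original trial order.
#'
#' @return A list with `design` (13-run `doe_design` with factor bindings)
#'   and `response`.
#' @export
caseStudyPB <- function() {
  cfg <- readFactorConfig(.extdata("hw_as1_pb_factors.yml"))
  readDesign(.extdata("hw_as1_pb_design.csv"), cfg, type = "pb")
}

#' Case-study response-surface dataset (H. werneckii AS1 melanin)
#'
#' The 3-factor, 15-run Box-Behnken table of the case study (CaCl2, trace
#' element solution, culture volume; three center runs) with measured
#' melanin yields (g/L), in the original run order.
#'
#' @return A list with `design` and `response`.
#' @export
caseStudyBB <- function() {
  cfg <- readFactorConfig(.extdata("hw_as1_bb_factors.yml"))
  readDesign(.extdata("hw_as1_bb_design.csv"), cfg, type = "bb")
}

#' Case-study published second-order polynomial
#'
#' The second-order polynomial reported for the case study's Box-Behnken
#' experiment, over coded CaCl2 (X1), trace element (X2) and culture
#' volume (X3):
#' `Y = 0.64 + 0.13625 X1 + 0.015 X2 + 0.22875 X3 - 0.045 X1X2
#'  - 0.0825 X1X3 + 0.015 X2X3 + 0.09125 X1^2 + 0.02375 X2^2 - 0.05875 X3^2`.
#' Refitting the shipped (2-decimal) responses reproduces the intercept and
#' X1X2 coefficient exactly and the rest to within about 0.02; the original
#' fit evidently used unrounded yields, so this constructor carries the
#' published coefficients verbatim.
#'
#' @return A `quadratic_model` with the case-study factor bindings.
#' @export
caseStudyModel <- function() {
  cfg <- readFactorConfig(.extdata("hw_as1_bb_factors.yml"))
  quadraticModel(
    beta0 = 0.64,
    linear = c(0.13625, 0.015, 0.22875),
    interaction = c(-0.045, -0.0825, 0.015),
    squared = c(0.09125, 0.02375, -0.05875),
    factors = cfg$factors
  )
}
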