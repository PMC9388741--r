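#' Univariate linear association model
#'
#' Ordinary least squares of an outcome on a single predictor, as in a
#' general-linear-model univariate screen. Continuous (or dichotomous 0/1)
#' predictors are reported as slope beta +/- SE with a two-sided p;
#' categorical predictors as per-level outcome means +/- SE with the overall
#' F-test p. Complete-case analysis: rows with `NA` in the outcome or
#' predictor are dropped.
#'
#' @param data data.frame.
#' @param outcome,predictor column names.
#' @return list of class `assoc_model`: `terms` (data.frame term/beta/se/p),
#'   `model_p` (overall F), `r_squared`, `n`, `fit` (the underlying `lm`),
#'   and `kind` ("continuous" or "categorical").
#' @export
fit_univariate <- function(data, outcome, predictor) {
  d <- data[stats::complete.cases(data[, c(outcome, predictor)]),
            c(outcome, predictor)]
  if (nrow(d) < 3L) stop("need >= 3 complete cases", call. = FALSE)
  x <- d[[predictor]]
  categorical <- is.character(x) || is.factor(x)
  if (!categorical && length(unique(x)) < 2L) {
    stop(sprintf("constant predictor '%s'", predictor), call. = FALSE)
  }
  if (categorical) d[[predictor]] <- factor(x)
  fit <- stats::lm(stats::reformulate(predictor, outcome), data = d)
  sm <- suppressWarnings(summary(fit))   # exact fits are legitimate here
  fstat <- sm$fstatistic
  model_p <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  if (categorical) {
    lv <- levels(d[[predictor]])
    means <- tapply(d[[outcome]], d[[predictor]], mean)
    ses <- tapply(d[[outcome]], d[[predictor]], function(v) stats::sd(v) / sqrt(length(v)))
    terms <- data.frame(term = lv, beta = as.numeric(means), se = as.numeric(ses),
                        p = NA_real_, stringsAsFactors = FALSE)
  } else {
    co <- sm$coefficients
    terms <- data.frame(term = predictor, beta = co[2, 1], se = co[2, 2],
                        p = co[2, 4], stringsAsFactors = FALSE)
  }
  structure(list(outcome = outcome, predictor = predictor, terms = terms,
                 model_p = model_p, r_squared = sm$r.squared, n = nrow(d),
                 kind = if (categorical) "categorical" else "continuous",
                 fit = fit),
            class = "assoc_model")
}

#' @export
print.assoc_model <- function(x, ...) {
  cat(sprintf("Linear model: %s ~ %s  (n = %d)\n", x$outcome,
              paste(x$predictor, collapse = " + "), x$n))
  print(x$terms, row.names = FALSE)
  cat(sprintf("model p = %.4g, R^2 = %.3f\n", x$model_p, x$r_squared))
  invisible(x)
}

#' Apply the univariate inclusion rule
#'
#' Candidates whose univariate p-value is below the inclusion threshold
#' enter the multivariable model. With `printed = TRUE` the p-values are
#' taken to be rounded table entries, so a value printed exactly at the
#' threshold is treated as potentially below it and included (a table
#' printing p = 0.10 at two decimals covers unrounded values down to
#' 0.095).
#'
#' @param p named numeric of univariate p-values.
#' @param threshold inclusion threshold (default 0.10).
#' @param printed are the p-values rounded table entries?
#' @return character vector of selected candidate names.
#' @export
select_candidates <- function(p, threshold = 0.10, printed = FALSE) {
  keep <- if (printed) p <= threshold else p < threshold
  names(p)[which(keep)]
}

#' Build the multivariable association model
#'
#' Runs the univariate screen for every candidate (unless pre-computed
#' p-values are supplied), applies the inclusion rule, and fits a single
#' OLS model containing all passing candidates. An explicit `override`
#' candidate list bypasses the rule, for reproducing a published model whose
#' term selection departed from the stated rule. If nothing passes, an
#' empty-model result is returned rather than an error.
#'
#' @param data data.frame.
#' @param outcome outcome column name.
#' @param candidates character vector of candidate predictor columns.
#' @param threshold univariate inclusion threshold (default 0.10).
#' @param univariate_p optional named numeric of pre-computed univariate
#'   p-values (e.g. printed table entries; implies `printed = TRUE` routing
#'   unless overridden).
#' @param printed treat `univariate_p` as rounded table entries (see
#'   [select_candidates()]); default `TRUE` when `univariate_p` is given.
#' @param override optional character vector of terms to fit regardless of
#'   the rule.
#' @return `assoc_model` with an extra `selected` element; `fit` is `NULL`
#'   for the empty model.
#' @export
build_multivariable <- function(data, outcome, candidates, threshold = 0.10,
                                univariate_p = NULL,
                                printed = !is.null(univariate_p),
                                override = NULL) {
  if (is.null(univariate_p)) {
    univariate_p <- vapply(candidates, function(v) {
      m <- fit_univariate(data, outcome, v)
      if (m$kind == "categorical") m$model_p else m$terms$p[1]
    }, numeric(1))
  }
  selected <- override %||% select_candidates(univariate_p, threshold, printed)
  if (length(selected) == 0L) {
    return(structure(list(outcome = outcome, predictor = character(0),
                          terms = data.frame(term = character(0), beta = numeric(0),
                                             se = numeric(0), p = numeric(0)),
                          model_p = NA_real_, r_squared = NA_real_, n = 0L,
                          kind = "empty", fit = NULL, selected = character(0),
                          univariate_p = univariate_p),
                     class = "assoc_model"))
  }
  d <- data[stats::complete.cases(data[, c(outcome, selected)]),
            c(outcome, selected)]
  fit <- stats::lm(stats::reformulate(selected, outcome), data = d)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  co <- sm$coefficients
  terms <- data.frame(term = rownames(co)[-1], beta = co[-1, 1], se = co[-1, 2],
                      p = co[-1, 4], row.names = NULL, stringsAsFactors = FALSE)
  structure(list(outcome = outcome, predictor = selected, terms = terms,
                 model_p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                            lower.tail = FALSE)),
                 r_squared = sm$r.squared, n = nrow(d), kind = "multivariable",
                 fit = fit, selected = selected, univariate_p = univariate_p),
            class = "assoc_model")
}

#' Association of trabecular bone mineral content with predictors
#'
#' Univariate OLS of total trabecular BMC (or any BMC column) on each
#' predictor in turn; a convenience wrapper over [fit_univariate()] for the
#' biomarker-bone analyses.
#'
#' @param data data.frame.
#' @param predictors character vector of predictor columns.
#' @param outcome outcome column (default `"bmc_total_g"`).
#' @return named list of `assoc_model` objects.
#' @export
bmc_association <- function(data, predictors, outcome = "bmc_total_g") {
  stats::setNames(lapply(predictors, function(v) fit_univariate(data, outcome, v)),
                  predictors)
}
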