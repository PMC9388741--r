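#' Run the cohort characteristic tests from summary tables
#'
#' Reproduces a cohort characteristics table's testing column from printed
#' summary statistics alone. Continuous variables (rows of `summaries`)
#' with two groups get the summary t-test with automatic variance rule;
#' with three or more groups, one-way ANOVA plus Tukey-Kramer pairwise
#' comparisons. Categorical variables (rows of `counts`) are routed by
#' expected cell counts to Fisher's exact or Pearson chi-squared tests via
#' [select_test()].
#'
#' @param summaries data.frame with columns `variable`, `group`, `mean`,
#'   `sd`, `n` (one row per variable x group; omit groups where the
#'   variable does not apply).
#' @param counts optional data.frame with columns `variable`, `level`,
#'   `group`, `count` for categorical variables.
#' @param groups optional character vector restricting (and ordering) the
#'   groups compared, e.g. `c("acute", "chronic")` for the SCI-only table.
#' @return data.frame: `variable`, `comparison` (`"overall"` or a pairwise
#'   label), `method`, `statistic`, `df`, `p`, `rule`.
#' @export
cohort_tests <- function(summaries, counts = NULL, groups = NULL) {
  out <- list()
  add <- function(variable, comparison, method, res) {
    out[[length(out) + 1L]] <<- data.frame(
      variable = variable, comparison = comparison, method = method,
      statistic = res$statistic, df = paste(signif(res$df, 6), collapse = ","),
      p = res$p.value,
      rule = if (is.null(res$variance_rule)) NA_character_ else res$variance_rule,
      stringsAsFactors = FALSE)
  }
  for (v in unique(summaries$variable)) {
    sv <- summaries[summaries$variable == v & !is.na(summaries$mean), ]
    if (!is.null(groups)) sv <- sv[sv$group %in% groups, ]
    if (!is.null(groups)) sv <- sv[order(match(sv$group, groups)), ]
    if (nrow(sv) < 2L) next
    gs <- group_summary(sv$group, sv$mean, sv$sd, sv$n)
    plan <- select_test("continuous", gs)
    add(v, "overall", plan$method, plan$result)
    if (plan$method == "anova") {
      for (nm in names(plan$pairwise)) add(v, nm, "tukey", plan$pairwise[[nm]])
    }
  }
  if (!is.null(counts)) {
    for (v in unique(counts$variable)) {
      cv <- counts[counts$variable == v, ]
      if (!is.null(groups)) cv <- cv[cv$group %in% groups, ]
      tab <- stats::xtabs(count ~ level + group, data = cv)
      if (!is.null(groups)) tab <- tab[, intersect(groups, colnames(tab)), drop = FALSE]
      if (any(dim(tab) < 2L)) next
      plan <- select_test("categorical", tab)
      add(v, "overall", plan$method, plan$result)
    }
  }
  do.call(rbind, out)
}

#' Read a cohort summary-statistics CSV
#' @param path CSV with columns variable, group, mean, sd, n.
#' @return data.frame.
#' @export
read_summaries_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
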