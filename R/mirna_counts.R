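#' Median-of-ratios library size factors
#'
#' Per-sample library size parameter s_j for a miRNA count matrix: each
#' miRNA's pseudo-reference count is its geometric mean across all samples,
#' and s_j is the median over miRNAs of the ratio c_ij / reference_i.
#' Only miRNAs with strictly positive counts in every sample enter the
#' reference (a zero anywhere makes the geometric mean zero). Dividing a
#' column by its factor puts all samples on a common scale regardless of
#' sequencing depth.
#'
#' @param counts numeric matrix of non-negative integer counts,
#'   miRNAs x samples.
#' @return named numeric vector of size factors, one per sample (column);
#'   attribute `"pseudo_reference"` holds the per-miRNA geometric means
#'   (NA for miRNAs excluded by the positivity rule).
#' @examples
#' m <- cbind(A = c(1, 4, 16), B = c(4, 4, 4))
#' size_factors(m)  # both 1: the median ratio is 1 in each sample
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) {
    stop("no miRNA has positive counts in every sample; cannot form the pseudo-reference",
         call. = FALSE)
  }
  logc <- log(counts[ok, , drop = FALSE])
  ref <- exp(rowMeans(logc))                       # geometric means
  sf <- apply(counts[ok, , drop = FALSE], 2, function(col) stats::median(col / ref))
  names(sf) <- colnames(counts)
  full_ref <- rep(NA_real_, nrow(counts))
  full_ref[ok] <- ref
  names(full_ref) <- rownames(counts)
  attr(sf, "pseudo_reference") <- full_ref
  sf
}

#' Normalize a count matrix by size factors
#'
#' Divides each sample column by its library size factor; zeros are
#' preserved. The normalized matrix is invariant to rescaling any column
#' together with its factor.
#'
#' @param counts miRNAs x samples count matrix.
#' @param factors named (or positionally matched) positive size factors, one
#'   per sample; defaults to [size_factors()] of `counts`.
#' @return numeric matrix of normalized counts, same dimnames as `counts`.
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  counts <- as.matrix(counts)
  if (!is.null(names(factors)) && !is.null(colnames(counts))) {
    if (!all(colnames(counts) %in% names(factors))) {
      stop("missing size factor for some samples", call. = FALSE)
    }
    factors <- factors[colnames(counts)]
  }
  if (length(factors) != ncol(counts)) {
    stop("one size factor per sample required", call. = FALSE)
  }
  if (any(factors <= 0)) stop("size factors must be positive", call. = FALSE)
  sweep(counts, 2, factors, "/")
}

#' Differential expression screen on normalized counts
#'
#' Per-miRNA group comparison of normalized counts. The default policy
#' mirrors the cohort testing engine: two groups are compared with a
#' two-sample t-test whose variance rule is chosen by a folded-F pretest,
#' three or more groups with one-way ANOVA. The log2 fold change is computed
#' from normalized group means (second group over first for two groups),
#' with a pseudo-count guarding zero means, and each miRNA is tiered at the
#' `alpha` thresholds, yielding a volcano-ready table.
#'
#' @param normalized miRNAs x samples matrix of normalized counts.
#' @param groups factor/character of group labels, one per sample.
#' @param test `"auto"` (t-test / ANOVA as above), `"pooled"` or
#'   `"satterthwaite"` to force a two-group variance rule.
#' @param alpha two significance tiers (default 0.05 and 0.01).
#' @param pseudo pseudo-count added to group means that are zero when
#'   forming the fold change (default 0.5).
#' @param p_adjust multiplicity correction passed to [stats::p.adjust()]
#'   (default `"none"`: raw p-values are tiered).
#' @return data.frame with one row per miRNA: per-group means, `log2fc`,
#'   `p`, `p_adj`, `tier` (`"ns"`, `"p<0.05"`, `"p<0.01"`), `direction`
#'   (`"up"`, `"down"`, `"none"`) and `neg_log10_p`.
#' @export
differential_screen <- function(normalized, groups,
                                test = c("auto", "pooled", "satterthwaite"),
                                alpha = c(0.05, 0.01), pseudo = 0.5,
                                p_adjust = "none") {
  test <- match.arg(test)
  normalized <- as.matrix(normalized)
  groups <- as.factor(groups)
  if (length(groups) != ncol(normalized)) {
    stop("one group label per sample required", call. = FALSE)
  }
  lv <- levels(groups)
  if (length(lv) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples", call. = FALSE)
  alpha <- sort(as.numeric(alpha), decreasing = TRUE)

  idx <- split(seq_along(groups), groups)
  res <- t(apply(normalized, 1, function(x) {
    ms <- vapply(idx, function(i) mean(x[i]), numeric(1))
    ss <- vapply(idx, function(i) stats::sd(x[i]), numeric(1))
    ns <- lengths(idx)
    if (all(ss == 0) && length(unique(ms)) == 1L) {
      return(c(ms, p = 1))
    }
    if (length(lv) == 2L) {
      rule <- if (test == "auto") "auto" else test
      p <- ttest_summary(list(mean = ms[1], sd = ss[1], n = ns[1]),
                         list(mean = ms[2], sd = ss[2], n = ns[2]),
                         rule = rule)$p.value
    } else {
      p <- anova_summary(group_summary(lv, ms, ss, ns))$p.value
    }
    c(ms, p = p)
  }))
  means <- res[, seq_along(lv), drop = FALSE]
  colnames(means) <- paste0("mean_", lv)
  p <- res[, length(lv) + 1L]
  p_adj <- stats::p.adjust(p, method = p_adjust)

  m1 <- means[, 1]; m2 <- means[, min(2L, ncol(means))]
  num <- ifelse(m2 == 0, m2 + pseudo, m2)
  den <- ifelse(m1 == 0, m1 + pseudo, m1)
  log2fc <- log2(num / den)

  tier <- rep("ns", length(p))
  tier[p_adj < alpha[1]] <- sprintf("p<%g", alpha[1])
  tier[p_adj < alpha[2]] <- sprintf("p<%g", alpha[2])
  direction <- ifelse(tier == "ns", "none", ifelse(log2fc > 0, "up", "down"))

  out <- data.frame(mirna = rownames(normalized) %||% seq_len(nrow(normalized)),
                    means, log2fc = log2fc, p = p, p_adj = p_adj,
                    tier = tier, direction = direction,
                    neg_log10_p = -log10(pmax(p, .Machine$double.xmin)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a miRNA count matrix from TSV
#'
#' First column miRNA ids, remaining columns one sample each.
#' @param path file path.
#' @return integer matrix with dimnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a count or normalized matrix to TSV
#' @param mat matrix with row and column names.
#' @param path output path.
#' @export
write_counts_tsv <- function(mat, path) {
  df <- data.frame(mirna = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
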