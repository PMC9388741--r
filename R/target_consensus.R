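#' Consensus predicted targets across three databases
#'
#' Intersects predicted target gene lists from TargetScan, MicroCosm and
#' miRTarBase after filtering TargetScan records at the context-score
#' cutoff (more negative scores mean stronger predicted repression, so the
#' default keeps scores <= -0.4). Gene symbols are matched
#' case-insensitively.
#'
#' @param targetscan data.frame with columns `gene` and `score`, or a
#'   character vector of genes (then no score filtering applies).
#' @param microcosm,mirtarbase data.frames with a `gene` column, or
#'   character vectors.
#' @param cutoff context-score cutoff (default -0.4).
#' @param direction `"le"` keeps scores <= cutoff (default), `"ge"` the
#'   opposite reading.
#' @param mode `"intersection"` (strict three-way, default) or
#'   `"two_of_three"`.
#' @return sorted character vector of consensus gene symbols (upper case).
#' @examples
#' ts <- data.frame(gene = c("WNT1", "IGF1"), score = c(-0.5, -0.3))
#' consensus_targets(ts, c("WNT1", "IGF1"), c("wnt1", "igf1"))
#' @export
consensus_targets <- function(targetscan, microcosm, mirtarbase,
                              cutoff = -0.4, direction = c("le", "ge"),
                              mode = c("intersection", "two_of_three")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  genes_of <- function(x) {
    if (is.data.frame(x)) toupper(as.character(x$gene)) else toupper(as.character(x))
  }
  ts <- if (is.data.frame(targetscan) && "score" %in% names(targetscan)) {
    keep <- if (direction == "le") targetscan$score <= cutoff else
      targetscan$score >= cutoff
    toupper(as.character(targetscan$gene[keep]))
  } else {
    genes_of(targetscan)
  }
  sets <- list(unique(ts), unique(genes_of(microcosm)),
               unique(genes_of(mirtarbase)))
  all_genes <- unique(unlist(sets))
  hits <- vapply(all_genes, function(g) sum(vapply(sets, function(s) g %in% s,
                                                   logical(1))), numeric(1))
  need <- if (mode == "intersection") 3 else 2
  sort(all_genes[hits >= need])
}

#' Read a target list CSV
#' @param path CSV with a `gene` column and optionally `score`.
#' @return data.frame.
#' @export
read_target_list <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
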