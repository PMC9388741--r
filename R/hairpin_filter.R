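#' Hairpin candidate
#'
#' A novel pre-miRNA hairpin candidate: RNA sequence, its dot-bracket
#' secondary structure (computed upstream by a folding engine and consumed
#' here as input), the predicted minimum free energy, and the coordinates of
#' the mature miRNA arm within the precursor.
#'
#' @param id candidate identifier.
#' @param sequence RNA string (A/C/G/U, case-insensitive).
#' @param structure dot-bracket string, same length as `sequence`.
#' @param free_energy predicted folding free energy in kcal/mol.
#' @param mature_start,mature_end 1-based inclusive position of the mature
#'   sequence within the precursor.
#' @return list of class `hairpin_candidate`.
#' @export
hairpin_candidate <- function(id, sequence, structure, free_energy,
                              mature_start, mature_end) {
  sequence <- toupper(sequence)
  if (nchar(sequence) != nchar(structure)) {
    stop("sequence and structure lengths differ", call. = FALSE)
  }
  if (grepl("[^.()]", structure)) stop("structure may contain only '.', '(' and ')'",
                                       call. = FALSE)
  if (mature_start < 1 || mature_end > nchar(sequence) || mature_start > mature_end) {
    stop("mature interval outside sequence", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, structure = structure,
                 free_energy = free_energy, mature_start = as.integer(mature_start),
                 mature_end = as.integer(mature_end)),
            class = "hairpin_candidate")
}

#' Parse a single-hairpin dot-bracket structure
#'
#' Stack-based bracket matching plus structural feature extraction for a
#' fold-back hairpin: the pairing map, the terminal loop (the unpaired run
#' enclosed by the innermost pair), the stem arms, and every internal
#' loop/bulge in the stem with the unpaired run lengths on each strand.
#' Structures with zero or more than one terminal loop (multibranch folds,
#' or several disjoint hairpins) are rejected: they are not hairpins.
#'
#' @param candidate a [hairpin_candidate()] (or bare dot-bracket string).
#' @return list with elements
#'   `pair` (integer partner per position, 0 = unpaired),
#'   `n_pairs`, `loop_start`, `loop_end`, `loop_len`,
#'   `outer_start`, `outer_end` (outermost pair), `hairpin_length`
#'   (outer span including both paired ends),
#'   `arm_positions` (stem region: both arms, internal loops included,
#'   terminal loop and dangling ends excluded), and
#'   `bulges`: data.frame with one row per unpaired run inside the stem
#'   (`strand` "5p"/"3p", `start`, `end`, `length`, `loop_id`,
#'   `opposite_length` = run length on the facing strand of the same
#'   internal loop).
#' @export
parse_hairpin <- function(candidate) {
  db <- if (inherits(candidate, "hairpin_candidate")) candidate$structure else candidate
  n <- nchar(db)
  ch <- strsplit(db, "")[[1]]
  pair <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced structure: unmatched ')'", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pair[i] <- j; pair[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced structure: unmatched '('", call. = FALSE)
  n_pairs <- sum(ch == "(")
  if (n_pairs == 0L) stop("no base pairs: not a hairpin", call. = FALSE)
  # one terminal loop <=> exactly one "(...)" innermost motif
  n_loops <- length(gregexpr("\\(\\.*\\)", db)[[1]])
  if (n_loops != 1L) {
    stop(sprintf("structure has %d terminal loops: not a single hairpin", n_loops),
         call. = FALSE)
  }
  opens <- which(ch == "(")
  outer_start <- opens[1]; outer_end <- pair[opens[1]]
  inner5 <- opens[length(opens)]; inner3 <- pair[inner5]
  loop_start <- inner5 + 1L; loop_end <- inner3 - 1L
  loop_len <- inner3 - inner5 - 1L

  # internal loops: gaps between consecutive stem pairs (outside -> in)
  i5 <- opens                      # ascending
  j3 <- pair[opens]                # descending
  bulges <- list(); loop_id <- 0L
  if (length(opens) > 1L) {
    for (k in seq_len(length(opens) - 1L)) {
      g5 <- i5[k + 1L] - i5[k] - 1L
      g3 <- j3[k] - j3[k + 1L] - 1L
      if (g5 > 0L || g3 > 0L) {
        loop_id <- loop_id + 1L
        if (g5 > 0L) {
          bulges[[length(bulges) + 1L]] <-
            data.frame(strand = "5p", start = i5[k] + 1L, end = i5[k + 1L] - 1L,
                       length = g5, loop_id = loop_id, opposite_length = g3)
        }
        if (g3 > 0L) {
          bulges[[length(bulges) + 1L]] <-
            data.frame(strand = "3p", start = j3[k + 1L] + 1L, end = j3[k] - 1L,
                       length = g3, loop_id = loop_id, opposite_length = g5)
        }
      }
    }
  }
  bulges <- if (length(bulges)) do.call(rbind, bulges) else
    data.frame(strand = character(0), start = integer(0), end = integer(0),
               length = integer(0), loop_id = integer(0),
               opposite_length = integer(0))
  arm_positions <- c(seq.int(outer_start, inner5), seq.int(inner3, outer_end))
  list(pair = pair, n_pairs = n_pairs,
       loop_start = loop_start, loop_end = loop_end, loop_len = loop_len,
       outer_start = outer_start, outer_end = outer_end,
       hairpin_length = outer_end - outer_start + 1L,
       arm_positions = arm_positions, bulges = bulges)
}

#' Secondary-structure criteria thresholds
#'
#' The eleven structural criteria a novel pre-miRNA hairpin must satisfy,
#' with their default thresholds and inequality directions:
#' nucleotides in any one stem bulge <= 12; stem base pairs >= 16; free
#' energy <= -15 kcal/mol; hairpin length (both stems plus terminal loop)
#' >= 50; terminal loop length <= 20; nucleotides in any one bulge in the
#' mature region <= 8; biased errors in one bulge in the mature region <= 4;
#' biased bulges in the mature region <= 2; errors (unpaired positions) in
#' the mature region <= 7; base pairs in the mature region >= 12; percent of
#' the mature sequence lying in the stem >= 80.
#'
#' "Biased" quantities measure strand asymmetry of an internal loop: for a
#' loop with unpaired runs of a and b nucleotides on the two strands, the
#' biased error count is |a - b|, and a biased bulge is a loop with a != b.
#'
#' @param max_stem_bulge_nt,min_stem_base_pairs,max_free_energy,min_hairpin_length,max_loop_length,max_mature_bulge_nt,max_mature_biased_errors,max_mature_biased_bulges,max_mature_errors,min_mature_base_pairs,min_percent_mature_in_stem
#'   numeric thresholds; defaults as listed above.
#' @return named list of class `hairpin_criteria`.
#' @export
hairpin_criteria <- function(max_stem_bulge_nt = 12, min_stem_base_pairs = 16,
                             max_free_energy = -15, min_hairpin_length = 50,
                             max_loop_length = 20, max_mature_bulge_nt = 8,
                             max_mature_biased_errors = 4,
                             max_mature_biased_bulges = 2,
                             max_mature_errors = 7, min_mature_base_pairs = 12,
                             min_percent_mature_in_stem = 80) {
  structure(list(max_stem_bulge_nt = max_stem_bulge_nt,
                 min_stem_base_pairs = min_stem_base_pairs,
                 max_free_energy = max_free_energy,
                 min_hairpin_length = min_hairpin_length,
                 max_loop_length = max_loop_length,
                 max_mature_bulge_nt = max_mature_bulge_nt,
                 max_mature_biased_errors = max_mature_biased_errors,
                 max_mature_biased_bulges = max_mature_biased_bulges,
                 max_mature_errors = max_mature_errors,
                 min_mature_base_pairs = min_mature_base_pairs,
                 min_percent_mature_in_stem = min_percent_mature_in_stem),
            class = "hairpin_criteria")
}

criterion_names <- c("stem_bulge_nt", "stem_base_pairs", "free_energy",
                     "hairpin_length", "loop_length", "mature_bulge_nt",
                     "mature_biased_errors", "mature_biased_bulges",
                     "mature_errors", "mature_base_pairs",
                     "percent_mature_in_stem")

#' Evaluate a hairpin candidate against the structural criteria
#'
#' Parses the candidate and measures each of the eleven criteria (see
#' [hairpin_criteria()]); the overall verdict is the conjunction of the
#' per-criterion flags. The mature interval must be 18-26 nt, matching the
#' read-length window of the small-RNA discovery pipeline; shorter or longer
#' intervals are rejected.
#'
#' @param candidate a [hairpin_candidate()].
#' @param config a [hairpin_criteria()] threshold set.
#' @return data.frame of class `criteria_report`: one row per criterion with
#'   `criterion`, `value`, `threshold`, `direction` ("<=" or ">="), `pass`;
#'   attribute `verdict` (logical) and `id`.
#' @export
evaluate_hairpin <- function(candidate, config = hairpin_criteria()) {
  stopifnot(inherits(candidate, "hairpin_candidate"))
  mlen <- candidate$mature_end - candidate$mature_start + 1L
  if (mlen < 18L || mlen > 26L) {
    stop(sprintf("mature length %d outside 18-26 nt", mlen), call. = FALSE)
  }
  f <- parse_hairpin(candidate)
  mat <- seq.int(candidate$mature_start, candidate$mature_end)

  overlaps <- function(s, e) s <= max(mat) & e >= min(mat)
  b <- f$bulges
  in_mat <- if (nrow(b)) overlaps(b$start, b$end) else logical(0)
  mature_bulge_nt <- if (any(in_mat)) max(b$length[in_mat]) else 0
  # per internal loop overlapping the mature region: strand asymmetry
  loops_in_mat <- unique(b$loop_id[in_mat])
  asym <- vapply(loops_in_mat, function(l) {
    rows <- b[b$loop_id == l, , drop = FALSE]
    g5 <- if (any(rows$strand == "5p")) rows$length[rows$strand == "5p"][1] else 0L
    g3 <- if (any(rows$strand == "3p")) rows$length[rows$strand == "3p"][1] else 0L
    abs(g5 - g3)
  }, numeric(1))
  mature_biased_errors <- if (length(asym)) max(asym) else 0
  mature_biased_bulges <- sum(asym > 0)

  unpaired <- which(f$pair == 0L)
  mature_errors <- sum(mat %in% unpaired)
  mature_pairs <- sum(!(mat %in% unpaired))
  pct_in_stem <- 100 * sum(mat %in% f$arm_positions) / mlen

  values <- c(if (nrow(b)) max(b$length) else 0, f$n_pairs,
              candidate$free_energy, f$hairpin_length, f$loop_len,
              mature_bulge_nt, mature_biased_errors, mature_biased_bulges,
              mature_errors, mature_pairs, pct_in_stem)
  thresholds <- unlist(config, use.names = FALSE)
  direction <- c("<=", ">=", "<=", ">=", "<=", "<=", "<=", "<=", "<=", ">=", ">=")
  pass <- ifelse(direction == "<=", values <= thresholds, values >= thresholds)
  rep <- data.frame(criterion = criterion_names, value = values,
                    threshold = thresholds, direction = direction, pass = pass,
                    stringsAsFactors = FALSE)
  attr(rep, "verdict") <- all(pass)
  attr(rep, "id") <- candidate$id
  class(rep) <- c("criteria_report", "data.frame")
  rep
}

#' Filter a batch of hairpin candidates
#'
#' Evaluates every candidate, collecting per-candidate reports; candidates
#' that fail to parse (unbalanced or multibranch structures, malformed
#' mature intervals) are recorded with the error message rather than
#' aborting the batch.
#'
#' @param candidates list of [hairpin_candidate()] objects.
#' @param config a [hairpin_criteria()] threshold set.
#' @return list with `passing` (character ids), `report` (one row per
#'   candidate: id, the 11 measured values, the 11 flags, `verdict`), and
#'   `errors` (named character of parse failures).
#' @export
filter_hairpins <- function(candidates, config = hairpin_criteria()) {
  reports <- list(); errors <- character(0)
  for (cand in candidates) {
    res <- tryCatch(evaluate_hairpin(cand, config), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[as.character(cand$id)]] <- conditionMessage(res)
    } else {
      reports[[as.character(cand$id)]] <- res
    }
  }
  if (length(reports)) {
    rows <- lapply(names(reports), function(id) {
      r <- reports[[id]]
      vals <- as.list(r$value); names(vals) <- r$criterion
      flags <- as.list(r$pass); names(flags) <- paste0("pass_", r$criterion)
      cbind(data.frame(id = id, stringsAsFactors = FALSE),
            as.data.frame(vals), as.data.frame(flags),
            data.frame(verdict = attr(r, "verdict")))
    })
    report <- do.call(rbind, rows)
  } else {
    report <- data.frame(id = character(0), verdict = logical(0))
  }
  list(passing = report$id[report$verdict], report = report, errors = errors)
}

#' Read hairpin candidates from a Vienna-style file
#'
#' Records of three lines: a header `>id mature=start-end energy=x` (mature
#' coordinates 1-based inclusive; energy optional if given on the structure
#' line), the sequence, and the dot-bracket structure optionally followed by
#' the free energy in parentheses, e.g. `((((....)))) (-21.30)`.
#'
#' @param path file path.
#' @return list of [hairpin_candidate()] objects.
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  lapply(starts, function(s) {
    header <- sub("^>", "", lines[s])
    id <- strsplit(header, "\\s+")[[1]][1]
    mat <- regmatches(header, regexpr("mature=\\d+-\\d+", header))
    if (!length(mat)) stop("header missing mature=start-end: ", header, call. = FALSE)
    mm <- as.integer(strsplit(sub("mature=", "", mat), "-")[[1]])
    seq <- lines[s + 1L]
    struct_line <- lines[s + 2L]
    en <- regmatches(struct_line, regexpr("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", struct_line))
    energy <- if (length(en)) as.numeric(gsub("[()[:space:]]", "", en)) else NA_real_
    db <- sub("\\s*\\(\\s*-?[0-9.]+\\s*\\)\\s*$", "", struct_line)
    hairpin_candidate(id, seq, db, energy, mm[1], mm[2])
  })
}

#' Write hairpin candidates to a Vienna-style file
#' @param candidates list of [hairpin_candidate()] objects.
#' @param path output path.
#' @export
write_vienna <- function(candidates, path) {
  lines <- unlist(lapply(candidates, function(cand) {
    c(sprintf(">%s mature=%d-%d", cand$id, cand$mature_start, cand$mature_end),
      cand$sequence,
      sprintf("%s (%.2f)", cand$structure, cand$free_energy))
  }))
  writeLines(lines, path)
  invisible(path)
}
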