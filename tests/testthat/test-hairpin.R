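test_that("structure parsing extracts pairs, loop and bulges", {
  f <- parse_hairpin("((((....))))")
  expect_equal(f$n_pairs, 4L)
  expect_equal(f$loop_len, 4L)
  expect_equal(nrow(f$bulges), 0L)
  expect_equal(f$hairpin_length, 12L)

  g <- parse_hairpin("(((..(((....)))..)))")
  expect_equal(g$n_pairs, 6L)
  expect_equal(sort(g$bulges$length), c(2L, 2L))
  expect_setequal(g$bulges$strand, c("5p", "3p"))
  expect_equal(unique(g$bulges$loop_id), 1L)
  expect_equal(g$bulges$opposite_length, c(2L, 2L))

  expect_error(parse_hairpin("(..)(..)"), "terminal loops")
  expect_error(parse_hairpin("((..)"), "unbalanced")
  expect_error(parse_hairpin("....."), "no base pairs")
})

test_that("pairing map agrees with a depth-profile matcher on random hairpins", {
  set.seed(11)
  for (i in 1:200) {
    k <- sample(1:4, 1)
    runs <- sample(3:8, k, replace = TRUE)
    g5 <- if (k > 1) sample(0:4, k - 1, replace = TRUE) else integer(0)
    g3 <- if (k > 1) sample(0:4, k - 1, replace = TRUE) else integer(0)
    db <- marrowmir:::make_hairpin_structure(runs, g5, g3,
                                             loop_len = sample(3:12, 1),
                                             dangle5 = sample(0:3, 1),
                                             dangle3 = sample(0:3, 1))
    expect_equal(parse_hairpin(db)$pair, match_pairs_depth(db))
  }
})

test_that("each violation construction fails exactly its one criterion", {
  for (v in names(marrowmir:::hairpin_violation_builders)) {
    b <- marrowmir:::hairpin_violation_builders[[v]]()
    cand <- hairpin_candidate(v, marrowmir:::sequence_for_structure(b$structure),
                              b$structure, b$energy, b$mature[1], b$mature[2])
    rep <- evaluate_hairpin(cand)
    expect_false(attr(rep, "verdict"))
    expect_equal(rep$criterion[!rep$pass], v)
  }
})

test_that("verdict is the conjunction of flags and thresholds act monotonically", {
  gen <- generate_hairpins(hairpin_sim_spec(n_candidates = 40,
                                            valid_fraction = 0.4, seed = 3))
  base <- filter_hairpins(gen$candidates)
  expect_equal(base$report$verdict,
               apply(base$report[, grep("^pass_", names(base$report))], 1, all))

  # relaxing any single threshold never shrinks the passing set
  relax <- list(max_stem_bulge_nt = 100, min_stem_base_pairs = 1,
                max_free_energy = 100, min_hairpin_length = 1,
                max_loop_length = 100, max_mature_bulge_nt = 100,
                max_mature_biased_errors = 100, max_mature_biased_bulges = 100,
                max_mature_errors = 100, min_mature_base_pairs = 0,
                min_percent_mature_in_stem = 0)
  for (nm in names(relax)) {
    cfg <- hairpin_criteria()
    cfg[[nm]] <- relax[[nm]]
    loosened <- filter_hairpins(gen$candidates, cfg)
    expect_true(all(base$passing %in% loosened$passing))
  }

  all_loose <- do.call(hairpin_criteria, relax)
  expect_equal(sort(filter_hairpins(gen$candidates, all_loose)$passing),
               sort(gen$truth$id))
})

test_that("filter verdicts agree 100% with generator truth labels", {
  gen <- generate_hairpins(hairpin_sim_spec(n_candidates = 200,
                                            valid_fraction = 0.5, seed = 9))
  res <- filter_hairpins(gen$candidates)
  expect_length(res$errors, 0L)
  expect_equal(res$report$verdict[match(gen$truth$id, res$report$id)],
               gen$truth$valid)
  expect_equal(sort(res$passing), sort(gen$truth$id[gen$truth$valid]))
})

test_that("mature length bounds and empty batches are handled", {
  db <- marrowmir:::make_hairpin_structure(30L)
  sq <- marrowmir:::sequence_for_structure(db)
  short <- hairpin_candidate("s", sq, db, -30, 1, 17)
  expect_error(evaluate_hairpin(short), "18-26")
  res <- filter_hairpins(list(short))
  expect_length(res$passing, 0L)
  expect_match(res$errors[["s"]], "18-26")
  empty <- filter_hairpins(list())
  expect_equal(nrow(empty$report), 0L)
})

test_that("vienna files round-trip candidates", {
  gen <- generate_hairpins(hairpin_sim_spec(n_candidates = 6, seed = 2))
  tf <- tempfile(fileext = ".vienna")
  write_vienna(gen$candidates, tf)
  back <- read_vienna(tf)
  expect_length(back, 6L)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$sequence, gen$candidates[[i]]$sequence)
    expect_equal(back[[i]]$structure, gen$candidates[[i]]$structure)
    expect_equal(back[[i]]$free_energy, gen$candidates[[i]]$free_energy,
                 tolerance = 0.01)
    expect_equal(back[[i]]$mature_start, gen$candidates[[i]]$mature_start)
  }
})
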