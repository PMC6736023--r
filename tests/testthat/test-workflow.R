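# The decision cascade, batch execution and self-screen.

# a small shared bundle: 10 allergens, helix structures for the first 3
make_test_bundle <- function(seed = 201L, n = 10L, n_struct = 3L,
                             lengths = c(60L, 120L)) {
  db <- make_synthetic_db(fixture_spec(seed = seed, n = n,
                                       length_range = lengths,
                                       prefix = "alg"))
  structs <- lapply(seq_len(n_struct), function(i) {
    make_helix_structure(db$sequence[i], id = paste0("st_", db$id[i]))
  })
  names(structs) <- vapply(structs, `[[`, character(1L), "id")
  model <- train_fingerprint(make_qrich_peptides(n = 40L, seed = seed + 1L))
  reference_bundle(db, structs, model)
}

test_that("workflow_config validates its fields", {
  cfg <- workflow_config()
  expect_equal(cfg$entropy_min, 0.34)
  expect_equal(cfg$epitope_strong_identity, 0.93)
  expect_equal(cfg$window_len, 80L)
  expect_equal(cfg$max_batch, 50L)
  expect_error(workflow_config(window_min_identity = 1.2), "window_min_identity")
  expect_error(workflow_config(e_max = -1), "e_max")

  path <- tempfile(fileext = ".cfg")
  writeLines(c("# comment", "e_max = 0.01", "window_len: 60"), path)
  over <- read_workflow_config(path)
  expect_equal(over$e_max, 0.01)
  expect_equal(over$window_len, 60L)
  expect_equal(over$entropy_min, 0.34)
  writeLines("no_such_key = 1", path)
  expect_error(read_workflow_config(path), "no_such_key")
})

test_that("verbatim allergen with structure gives strong epitope3d at 1.0", {
  refs <- make_test_bundle()
  call <- assess(list(id = "self", sequence = refs$allergens$sequence[1L]),
                 refs)
  expect_equal(call$evidence, "strong")
  expect_equal(call$basis, "epitope3d")
  expect_equal(call$epitope_identity, 1)
  expect_gte(call$epitope_identity, 0.93)
  expect_equal(call$best_allergen, "alg001")
  expect_equal(call$best_structure, "st_alg001")
})

test_that("a Q-repeat carrier is strong regardless of other evidence", {
  refs <- make_test_bundle()
  carrier <- withr_seed(202L, {
    paste0(random_seq(25L), paste(rep("QQP", 5L), collapse = ""),
           random_seq(25L))
  })
  call <- assess(list(id = "qq", sequence = carrier), refs)
  expect_equal(call$evidence, "strong")
  expect_equal(call$basis, "qrepeat")
  # shadowing: even a verbatim allergen is reported as qrepeat when the
  # Q-repeat stage fires first
  embedded <- paste0(refs$allergens$sequence[1L],
                     paste(rep("Q", 15L), collapse = ""))
  call2 <- assess(list(id = "qq2", sequence = embedded), refs)
  expect_equal(call2$basis, "qrepeat")
})

test_that("an unrelated random query yields none, each stage missing", {
  refs <- make_test_bundle()
  q <- random_seq(60L, seed = 203L)
  call <- assess(list(id = "rand", sequence = q), refs)
  expect_equal(call$evidence, "none")
  expect_equal(call$basis, "none")
  # confirm stage by stage with the component functions
  expect_false(qrepeat_hit(refs$qrepeat_model, q)$hit)
  expect_equal(nrow(search_db(q, refs$rep_db)), 0L)
  wid <- vapply(refs$allergens$sequence, function(a) {
    linear_window_hit(q, a)$identity
  }, numeric(1L))
  expect_true(all(wid < 0.35))
  expect_length(triple_hit(valid_hexamers(q), kmer_index(refs$allergens)), 0L)
})

test_that("short queries are reported as too short, not assessed", {
  refs <- make_test_bundle()
  call <- assess(list(id = "tiny", sequence = "MKVLA"), refs)
  expect_equal(call$evidence, "none")
  expect_match(call$notes, "too short")
  expect_error(assess(list(id = "none", sequence = ""), refs), "length")
})

test_that("structure removal degrades epitope3d calls down the cascade", {
  refs <- make_test_bundle()
  level_rank <- c(none = 0L, weak = 1L, strong = 2L)
  bare <- reference_bundle(refs$allergens, list(), refs$qrepeat_model)
  for (i in c(1L, 2L)) {
    q <- mutate_homolog(refs$allergens$sequence[i], 0.9, seed = 210L + i)
    with_st <- assess(list(id = "q", sequence = q), refs)
    without <- assess(list(id = "q", sequence = q), bare)
    expect_false(without$basis == "epitope3d")
    expect_lte(level_rank[[without$evidence]] -
                 level_rank[[with_st$evidence]], 1L)
    # never stronger without structures than with them for the same query
    # unless promoted by the linear-window rule (which reports strong);
    # the epitope basis itself must vanish
    if (with_st$basis == "epitope3d" && with_st$evidence == "strong") {
      expect_true(without$evidence %in% c("strong", "weak", "none"))
    }
  }
})

test_that("reference-set growth is monotone: calls never drop to none", {
  small <- make_test_bundle(seed = 221L, n = 5L, n_struct = 0L)
  extra <- make_synthetic_db(fixture_spec(seed = 222L, n = 5L,
                                          length_range = c(60L, 120L),
                                          prefix = "new"))
  grown <- reference_bundle(merge_databases(list(small$allergens, extra)),
                            list(), small$qrepeat_model)
  queries <- withr_seed(223L, {
    c(vapply(1:3, function(i) {
      mutate_homolog(small$allergens$sequence[i], 0.9,
                     seed = sample.int(1e6, 1L))
    }, character(1L)), replicate(3L, random_seq(80L)))
  })
  level_rank <- c(none = 0L, weak = 1L, strong = 2L)
  for (q in queries) {
    before <- assess(list(id = "q", sequence = q), small)
    after <- assess(list(id = "q", sequence = q), grown)
    if (before$evidence != "none") {
      expect_true(after$evidence != "none")
    }
  }
})

test_that("run_batch preserves order, enforces the limit, is deterministic", {
  refs <- make_test_bundle()
  queries <- sequence_database(
    c("qa", "qb", "qc"),
    c(refs$allergens$sequence[2L], random_seq(70L, seed = 231L),
      mutate_homolog(refs$allergens$sequence[5L], 0.9, seed = 232L)),
    name = "queries")
  out1 <- tempfile(fileext = ".csv")
  res <- run_batch(queries, refs, out = out1)
  expect_equal(res$query_id, c("qa", "qb", "qc"))
  tab <- read.csv(out1, colClasses = "character")
  expect_equal(names(tab),
               c("query_id", "evidence", "basis", "best_allergen",
                 "best_structure", "epitope_identity", "window_identity",
                 "hexamer_hits", "notes"))
  expect_equal(nrow(tab), 3L)

  # byte-identical on re-run
  out2 <- tempfile(fileext = ".csv")
  run_batch(queries, refs, out = out2)
  expect_identical(readLines(out1), readLines(out2))

  # exceeding the limit errors before writing any output
  cfg2 <- workflow_config(max_batch = 2L)
  out3 <- tempfile(fileext = ".csv")
  expect_error(run_batch(queries, refs, cfg2, out = out3), "limit of 2")
  expect_false(file.exists(out3))
  expect_error(run_batch(queries[0L, ], refs), "at least one")
})

test_that("self-screen is fully sensitive and jack-knife never raises it", {
  refs <- make_test_bundle(seed = 241L, n = 12L, n_struct = 4L,
                           lengths = c(40L, 90L))
  res <- self_screen(refs)
  expect_equal(nrow(res$calls), 12L)
  expect_equal(res$counts[["none"]], 0L)
  # with a structure: strong at identity 1; without: linear window self-hit
  expect_true(all(res$calls$evidence == "strong"))
  expect_equal(nrow(res$missed), 0L)

  jk <- self_screen(refs, jackknife = TRUE)
  expect_lte(jk$counts[["strong"]], res$counts[["strong"]])

  # an injected length-5 sequence is reported missed with a reason
  db5 <- merge_databases(list(refs$allergens,
                              sequence_database("tiny5", "MKVLA")))
  refs5 <- reference_bundle(db5, refs$structures, refs$qrepeat_model,
                            epitope_tables = refs$epitope_tables)
  res5 <- self_screen(refs5)
  expect_equal(res5$missed$query_id, "tiny5")
  expect_match(res5$missed$notes, "too short")
})
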