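# Pairwise alignment, E-value search, linear-window rule, triple mapping.

test_that("global_align agrees with the independent DP oracle", {
  # identical sequences: identity 1, no gaps
  s <- random_seq(40L, seed = 91L)
  al <- global_align(s, s)
  expect_equal(al$identity, 1)
  expect_false(grepl("-", al$aligned_a))
  # self-alignment optimality: reversal scores strictly lower
  rev_s <- paste(rev(strsplit(s, NULL)[[1L]]), collapse = "")
  expect_lt(global_align(s, rev_s)$score, al$score)

  # seeded pairs vs the Gotoh oracle
  pairs <- withr_seed(92L, {
    lapply(1:8, function(i) {
      a <- random_seq(30L)
      list(a = a,
           b = if (i %% 2 == 0) random_seq(25L) else {
             mutate_homolog(a, 0.8, seed = i)
           })
    })
  })
  for (p in pairs) {
    expect_equal(global_align(p$a, p$b)$score,
                 oracle_align_score(p$a, p$b, "global"))
  }
})

test_that("search_db finds self-matches and rejects insignificant ones", {
  db <- make_synthetic_db(fixture_spec(seed = 93L, n = 10L,
                                       length_range = c(60L, 120L)))
  q <- db$sequence[4L]
  hits <- search_db(q, db, query_id = "q4")
  expect_s3_class(hits, "AlignmentHits")
  expect_equal(hits$target_id[1L], db$id[4L])
  expect_lt(hits$evalue[1L], 1e-10)
  expect_equal(hits$qstart[1L], 1L)
  expect_equal(hits$qend[1L], nchar(q))

  # length-6 random query vs an unrelated db: best attainable score cannot
  # reach E < 0.001 (direct E-value computation as oracle)
  q6 <- "MKVLAT"
  scores <- vapply(db$sequence, function(t) {
    oracle_align_score(q6, t, "local")
  }, numeric(1L))
  E <- 0.041 * 6 * nchar(db$sequence) * exp(-0.267 * scores)
  expect_true(all(E >= 0.001))
  expect_equal(nrow(search_db(q6, db)), 0L)

  # raw top-hit scores equal the brute-force Smith-Waterman oracle
  queries <- withr_seed(94L, replicate(4L, random_seq(40L)))
  small <- db[1:4, ]
  for (q in queries) {
    got <- search_db(q, small, e_max = 1e6)
    want <- vapply(small$sequence, function(t) {
      oracle_align_score(q, t, "local")
    }, numeric(1L))
    names(want) <- small$id
    expect_equal(got$score[match(small$id, got$target_id)], unname(want))
  }
})

test_that("E-values decrease monotonically in score at fixed lengths", {
  S <- seq(20, 200, by = 5)
  E <- 0.041 * 100 * 100 * exp(-0.267 * S)
  expect_true(all(diff(E) < 0))
  # bitscore transform is increasing in raw score
  bits <- (0.267 * S - log(0.041)) / log(2)
  expect_true(all(diff(bits) > 0))
})

test_that("linear-window rule: inclusive 35% boundary at 28/80 vs 27/80", {
  # base drawn from residues with a positively-scoring non-identical
  # BLOSUM62 partner, so the substituted pair still aligns gaplessly on the
  # diagonal (every mismatch column scores >= +1; a gap costs 12)
  partner <- c(K = "R", L = "I", D = "E", F = "Y", S = "T")
  base <- withr_seed(95L, {
    paste(sample(names(partner), 100L, replace = TRUE), collapse = "")
  })
  make_pair <- function(k) {
    ch <- strsplit(base, NULL)[[1L]]
    other <- unname(partner[ch])
    paste(c(ch[seq_len(k)], other[(k + 1L):100L]), collapse = "")
  }
  hit28 <- linear_window_hit(base, make_pair(28L))
  expect_equal(hit28$identity, 28 / 80)
  expect_true(hit28$hit)                        # >= is inclusive
  hit27 <- linear_window_hit(base, make_pair(27L))
  expect_equal(hit27$identity, 27 / 80)
  expect_equal(hit27$identity, 0.3375)
  expect_false(hit27$hit)

  # identical sequences: identity 1 and a hit
  full <- linear_window_hit(base, base)
  expect_equal(full$identity, 1)
  expect_true(full$hit)

  # brute-force window scan of the fixed alignment as oracle
  al <- global_align(base, make_pair(28L))
  ca <- strsplit(al$aligned_a, NULL)[[1L]]
  cb <- strsplit(al$aligned_b, NULL)[[1L]]
  idc <- ca == cb & ca != "-"
  w <- min(80L, length(idc))
  best <- max(vapply(seq_len(length(idc) - w + 1L), function(i) {
    sum(idc[i:(i + w - 1L)])
  }, numeric(1L)))
  expect_equal(hit28$matches, best)

  # short alignments use the whole alignment as one window
  short <- linear_window_hit("MKVLATPWED", "MKVLATPWED")
  expect_equal(short$window_cols, 10L)
  expect_equal(short$identity, 1)
})

test_that("max window identity obeys the covering pigeonhole bound", {
  # the alignment's L columns are covered by ceiling(L/w) complete windows,
  # so the best window holds at least matches/ceiling(L/w) of the matches
  # (the literal "window identity >= overall identity" only holds up to
  # edge effects; this is the exact form of the bound)
  pairs <- withr_seed(97L, {
    lapply(1:6, function(i) {
      a <- random_seq(120L)
      list(a = a, b = mutate_homolog(a, runif(1, 0.4, 0.9),
                                     seed = 1000L + i))
    })
  })
  for (p in pairs) {
    al <- global_align(p$a, p$b)
    wh <- linear_window_hit(p$a, p$b)
    w <- wh$window_cols
    bound <- al$matches / (w * ceiling(al$length / w))
    expect_gte(wh$identity + 1e-12, bound)
    expect_gte(wh$identity + 1e-12, al$identity * al$length /
                 (w * ceiling(al$length / w)))
  }
})

test_that("the indexed window scan equals the aligned-string column scan", {
  # linear_window_scan reconstructs match columns from the compact
  # alignment representation; it must agree exactly with the padded-string
  # scan used by linear_window_hit, at every window size and orientation
  withr_seed(191L, {
    for (trial in 1:40) {
      q <- random_seq(sample(10:100, 1L))
      ts <- vapply(1:3, function(i) {
        if (i == 1L) random_seq(sample(10:100, 1L)) else {
          mutate_homolog(substr(q, sample(1:5, 1L), nchar(q)),
                         runif(1, 0.5, 1), seed = sample.int(1e6, 1L))
        }
      }, character(1L))
      db <- sequence_database(paste0("t", 1:3), ts, name = "x")
      w <- sample(c(5L, 20L, 80L), 1L)
      fast <- allerscreen:::linear_window_scan(q, db, window = w)
      slow <- vapply(ts, function(t) {
        al <- global_align(t, q)
        allerscreen:::window_scan_alignment(al$aligned_a, al$aligned_b,
                                            w)$identity
      }, numeric(1L))
      expect_equal(fast, unname(slow), tolerance = 1e-12)
    }
  })
})

test_that("anchored_triple_map anchors on the representative", {
  rep <- random_seq(60L, seed = 98L)
  m <- anchored_triple_map(rep, rep, rep)
  expect_equal(nrow(m), 60L)
  expect_identical(m$query_res, m$rep_res)
  expect_identical(m$allergen_res, m$rep_res)

  # query missing the rep's first 10 residues -> gaps on the query side
  m2 <- anchored_triple_map(substr(rep, 11L, 60L), rep, rep)
  expect_true(all(is.na(m2$query_res[1:10])))
  expect_identical(m2$query_res[11:60], m2$rep_res[11:60])

  # three-way consistency: every mapped pair appears in its pairwise
  # alignment (checked by re-aligning seeded mutants)
  q <- mutate_homolog(rep, 0.85, seed = 99L)
  a <- mutate_homolog(rep, 0.9, seed = 100L)
  m3 <- anchored_triple_map(q, rep, a)
  alq <- global_align(q, rep)
  cq <- strsplit(alq$aligned_a, NULL)[[1L]]
  cr <- strsplit(alq$aligned_b, NULL)[[1L]]
  pairs_q <- cq[cr != "-"]
  pairs_q[pairs_q == "-"] <- NA_character_
  expect_identical(m3$query_res, pairs_q)
})

test_that("best_epitope_identity counts, ranks and tie-breaks correctly", {
  rep <- random_seq(40L, seed = 101L)
  st <- make_helix_structure(rep, id = "tie")
  tab <- build_epitope_table(st, surface_residues(st))
  # identical query and allergen: every epitope identity 1; tie broken by
  # the larger epitope, then smaller center
  m <- anchored_triple_map(rep, rep, rep)
  res <- best_epitope_identity(m, tab)
  expect_equal(res$identity, 1)
  sizes <- lengths(tab$epitopes)
  expect_equal(res$size, max(sizes))
  cands <- as.integer(names(sizes))[sizes == max(sizes)]
  expect_equal(res$center, min(cands))

  # constructed count: mutate allergen at 2 members of a known epitope
  center <- names(tab$epitopes)[8L]
  members <- tab$epitopes[[center]]
  ch <- strsplit(rep, NULL)[[1L]]
  touch <- members[c(2L, 5L)]
  for (p in touch) {
    ch[p] <- setdiff(c("A", "G", "V"), ch[p])[1L]
  }
  allergen <- paste(ch, collapse = "")
  m2 <- anchored_triple_map(rep, rep, allergen)
  same <- !is.na(m2$allergen_res) & m2$allergen_res == m2$rep_res
  manual <- sum(members %in% m2$rep_pos[same]) / length(members)
  res2 <- best_epitope_identity(m2, tab)
  # the manual count for this epitope can never exceed the best
  expect_gte(res2$identity, manual)
  expect_equal(manual, (length(members) - 2L) / length(members))

  # all query positions gapped -> identity 0 everywhere
  m3 <- m2
  m3$query_res <- NA_character_
  res3 <- best_epitope_identity(m3, tab)
  expect_equal(res3$identity, 0)
  # empty table -> NULL marker
  empty <- structure(list(structure_id = "e", epitopes = list(),
                          radius = 12, min_size = 13L),
                     class = "EpitopeTable")
  expect_null(best_epitope_identity(m2, empty))

  # permutation invariance in epitope enumeration order
  tab_perm <- tab
  perm <- withr_seed(102L, sample(seq_along(tab$epitopes)))
  tab_perm$epitopes <- tab$epitopes[perm]
  expect_equal(best_epitope_identity(m2, tab_perm)$identity, res2$identity)
  expect_equal(best_epitope_identity(m2, tab_perm)$center, res2$center)
})
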