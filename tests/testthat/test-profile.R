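test_that("profile scores follow the pseudocount log-odds formula", {
  # ten identical rows, a column of all C, alpha = 1, uniform background
  rows <- setNames(rep("C", 10), paste0("r", 1:10))
  prof <- buildProfile(rows, alpha = 1)
  expected <- log2(((10 + 1 / 20) / 11) / (1 / 20))
  expect_equal(unname(profileScores(prof)["C", 1]), expected, tolerance = 1e-12)
  expect_equal(expected, 4.191623, tolerance = 1e-6)

  # a column whose frequencies equal the background scores zero everywhere
  balanced <- setNames(AA, paste0("s", 1:20))
  prof0 <- buildProfile(balanced, alpha = 0.7)
  expect_equal(unname(profileScores(prof0)[, 1]), rep(0, 20), tolerance = 1e-12)

  # all-gap columns also score zero (frequency vector collapses to background)
  gappy <- c(a = "C-", b = "C-")
  profG <- buildProfile(gappy)
  expect_equal(unname(profileScores(profG)[, 2]), rep(0, 20))

  expect_error(buildProfile(rows, alpha = 0), class = "rgkscan_usage")
  expect_error(buildProfile(character(0)), class = "rgkscan_usage")
})

test_that("window scoring matches a per-residue column-sum oracle", {
  withr::with_seed(41, {
    for (i in 1:50) {
      nrows <- sample(2:6, 1)
      L <- sample(3:10, 1)
      aln <- setNames(vapply(1:nrows, function(j) randomSeq(L), character(1)),
                      paste0("r", 1:nrows))
      prof <- buildProfile(aln, alpha = 0.5)
      seq <- randomSeq(L + sample(0:20, 1), c(AA, "X"))
      off <- sample(seq_len(nchar(seq) - L + 1), 1)
      chars <- strsplit(seq, "")[[1]]
      expected <- 0
      for (j in 1:L) {
        res <- chars[off + j - 1]
        if (res %in% AA) expected <- expected + unname(profileScores(prof)[res, j])
      }
      expect_equal(scoreWindow(seq, prof, off), expected, tolerance = 1e-12)
    }
  })
})

test_that("self-similar windows score maximally and X contributes zero", {
  prof <- buildProfile(c(r = "ACD"), alpha = 1)
  withr::with_seed(43, {
    for (i in 1:20) {
      super <- paste0(randomSeq(sample(0:10, 1)), "ACD",
                      randomSeq(sample(0:10, 1)))
      own <- scoreWindow("ACD", prof, 1)
      expect_equal(bestWindowScore(super, prof), own, tolerance = 1e-12)
    }
  })
  expect_equal(scoreWindow("XXX", prof, 1), 0)
  expect_error(scoreWindow("AC", prof, 1), class = "rgkscan_usage")
  expect_error(scoreWindow("ACDE", prof, 3), class = "rgkscan_usage")
})

test_that("the empirical null is seeded, finite and guarded", {
  prof <- buildProfile(c(a = "CCC", b = "CCC", c = "CCD"))
  n1 <- empiricalNull(prof, nShuffles = 200, seed = 9, seqLength = 50)
  n2 <- empiricalNull(prof, nShuffles = 200, seed = 9, seqLength = 50)
  expect_identical(n1, n2)
  expect_true(is.finite(n1$mean) && is.finite(n1$sd) && n1$sd > 0)
  n3 <- empiricalNull(prof, nShuffles = 200, seed = 10, seqLength = 50)
  expect_false(identical(n1$mean, n3$mean))
  expect_error(empiricalNull(prof, nShuffles = 10, seed = 1),
               class = "rgkscan_usage")
})

test_that("adding a sequence to the profile never lowers its own score", {
  withr::with_seed(47, {
    for (i in 1:30) {
      L <- sample(4:12, 1)
      nrows <- sample(2:5, 1)
      aln <- vapply(1:nrows, function(j) randomSeq(L), character(1))
      names(aln) <- paste0("r", 1:nrows)
      target <- randomSeq(L)
      before <- scoreWindow(target, buildProfile(aln), 1)
      after <- scoreWindow(target, buildProfile(c(aln, new = target)), 1)
      expect_gte(after, before - 1e-12)
    }
  })
})

test_that("pattern-initiated search finds a planted record at iteration 1", {
  withr::with_seed(53, {
    seed8 <- generateRgkLike(8, benchmarkSpec(tailNoise = 0))$records
    tails <- vapply(as.character(seed8),
                    function(s) substr(s, nchar(s) - 39, nchar(s)), character(1))
    positive <- generateRgkLike(1, benchmarkSpec(tailNoise = 0),
                                idPrefix = "pos")$records
    bg <- generateBackground(2, c(200, 300), idPrefix = "neg")
  })
  db <- c(positive, bg)
  res <- patternInitiatedSearch(db, seedAlignment = tails, seed = 3)
  expect_equal(res$record_id[res$included], "pos_0001")
  expect_equal(res$iteration_found[res$included], 1L)

  empty <- patternInitiatedSearch(Biostrings::AAStringSet(character(0)),
                                  seedAlignment = tails, seed = 3)
  expect_equal(nrow(empty), 0L)
})

test_that("near-miss homologs are recovered only at iteration 2", {
  spec <- benchmarkSpec(nRgk = 20, nDecoy = 10, nBackground = 30,
                        nearMissFraction = 0.2)
  b <- generateBenchmark(spec, seed = 42)
  withr::with_seed(61, {
    seed8 <- generateRgkLike(8, benchmarkSpec(tailNoise = 0))$records
  })
  tails <- vapply(as.character(seed8),
                  function(s) substr(s, nchar(s) - 39, nchar(s)), character(1))
  res <- patternInitiatedSearch(b$records, seedAlignment = tails, seed = 5)
  nearMiss <- b$truth$record_id[which(b$truth$near_miss)]
  found <- res[res$record_id %in% nearMiss, ]
  # near-miss tails carry no anchored pattern hit, so iteration 1 cannot see them
  expect_true(all(is.na(found$iteration_found) | found$iteration_found == 2L))
  expect_true(any(found$included))

  # iteration-2 inclusions are a superset of iteration-1 inclusions
  res1 <- patternInitiatedSearch(b$records, seedAlignment = tails, seed = 5,
                                 maxIter = 1)
  expect_true(all(res$included[res1$included]))

  # full determinism given (db order, seed)
  res2 <- patternInitiatedSearch(b$records, seedAlignment = tails, seed = 5)
  expect_identical(res, res2)
})
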