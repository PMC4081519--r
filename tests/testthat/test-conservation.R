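test_that("conservation scores hit their analytic endpoints", {
  # fully conserved column -> log2 20; uniform column -> 0
  aln <- setNames(paste0("L", AA), paste0("s", 1:20))
  cp <- conservationProfile(aln, w = 1)
  expect_equal(conservationScores(cp)[1], log2(20), tolerance = 1e-12)
  expect_equal(conservationScores(cp)[2], 0, tolerance = 1e-12)

  # constant profiles are invariant under smoothing
  flat <- setNames(rep(strrep("C", 9), 4), paste0("s", 1:4))
  cpf <- conservationProfile(flat, w = 5)
  expect_equal(smoothedScores(cpf), rep(log2(20), 9), tolerance = 1e-12)

  expect_error(conservationProfile(character(0)), class = "rgkscan_usage")
})

test_that("scores are bounded, smoothing contracts, rows are exchangeable", {
  withr::with_seed(71, {
    for (i in 1:20) {
      nr <- sample(3:12, 1)
      nc <- sample(6:30, 1)
      rows <- vapply(1:nr, function(j) {
        s <- strsplit(randomSeq(nc), "")[[1]]
        s[runif(nc) < 0.15] <- "-"
        paste(s, collapse = "")
      }, character(1))
      names(rows) <- paste0("s", 1:nr)
      cp <- conservationProfile(rows)
      expect_true(all(conservationScores(cp) >= -1e-9))
      expect_true(all(conservationScores(cp) <= log2(20) + 1e-9))
      sm <- smoothedScores(cp)
      expect_lte(max(abs(sm), na.rm = TRUE),
                 max(abs(conservationScores(cp))) + 1e-9)

      # column statistics do not depend on row order
      perm <- sample(nr)
      cp2 <- conservationProfile(rows[perm])
      expect_equal(conservationScores(cp2), conservationScores(cp))
      expect_equal(smoothedScores(cp2), smoothedScores(cp))
    }
  })
})

test_that("gap-heavy columns are masked but still scored", {
  rows <- c(a = "C-A", b = "C-A", c = "CC-", d = "CC-")
  cp <- conservationProfile(rows, w = 1, gapCutoff = 0.4)
  expect_identical(maskedColumns(cp), c(FALSE, TRUE, TRUE))
  expect_equal(conservationScores(cp)[2], log2(20))  # reported despite mask
  expect_true(is.na(smoothedScores(cp)[2]))
})

test_that("reference residue numbers map to alignment columns bijectively", {
  cmap <- mapColumns(c(ref = "A-CD", other = "AACD"), "ref")
  expect_identical(cmap, setNames(c(1L, 3L, 4L), c("1", "2", "3")))

  expect_warning(empty <- mapColumns(c(ref = "---", o = "ACD"), "ref"),
                 "all gaps")
  expect_equal(length(empty), 0L)
  expect_error(mapColumns(c(a = "ACD"), "nope"), class = "rgkscan_usage")

  withr::with_seed(73, {
    for (i in 1:20) {
      nc <- sample(5:30, 1)
      ref <- strsplit(randomSeq(nc), "")[[1]]
      ref[runif(nc) < 0.3] <- "-"
      rows <- c(ref = paste(ref, collapse = ""), o = randomSeq(nc))
      if (all(ref == "-")) next
      cmap <- mapColumns(rows, "ref")
      expect_equal(anyDuplicated(cmap), 0L)          # injective
      expect_true(all(ref[cmap] != "-"))             # lands on residues
      expect_equal(length(cmap), sum(ref != "-"))    # onto all residues
    }
  })
})

test_that("differential conservation behaves at its fixed points", {
  withr::with_seed(79, {
    rows <- setNames(vapply(1:5, function(i) randomSeq(12), character(1)),
                     c("ref", paste0("s", 2:5)))
  })
  d0 <- differentialConservation(alignmentA = rows, alignmentB = rows,
                                 referenceId = "ref")
  expect_equal(d0$difference, rep(0, nrow(d0)))

  # A fully conserved, B uniform at every column
  alnA <- setNames(rep(strrep("W", 20), 20), c("ref", paste0("a", 2:20)))
  alnB <- setNames(c(strrep("W", 20),
                     vapply(setdiff(AA, "W"), function(r) strrep(r, 20),
                            character(1))),
                   c("ref", paste0("b", 2:20)))
  d1 <- differentialConservation(alignmentA = alnA, alignmentB = alnB,
                                 referenceId = "ref")
  expect_equal(d1$difference, rep(log2(20), 20), tolerance = 1e-12)

  # hand-built: one column divergent in B only
  a <- c(ref = "WAC", x = "WAC", y = "WAC")
  b <- c(ref = "WAC", x = "WDC", y = "WEC")
  d2 <- differentialConservation(alignmentA = a, alignmentB = b,
                                 referenceId = "ref")
  expect_equal(d2$difference[c(1, 3)], c(0, 0))
  expect_gt(d2$difference[2], 0)

  # reference residues absent from one alignment are omitted and listed
  a2 <- c(ref = "WAC", x = "WAC")
  b2 <- c(ref = "WA-", x = "WDC")
  d3 <- differentialConservation(alignmentA = a2, alignmentB = b2,
                                 referenceId = "ref")
  expect_equal(d3$residue, c(1L, 2L))
  expect_equal(attr(d3, "omitted"), 3L)

  expect_error(differentialConservation(alignmentA = a, alignmentB = b,
                                        referenceId = "zz"),
               class = "rgkscan_usage")
})

test_that("logo heights partition the column information content", {
  aln <- setNames(rep("C", 10), paste0("s", 1:10))
  lm <- logoMatrix(aln, span = 1)
  expect_equal(logoInformation(lm), log2(20), tolerance = 1e-12)
  expect_equal(unname(logoHeights(lm)["C", 1]), log2(20), tolerance = 1e-12)

  # 50/50 split between two residues: R = log2 20 - 1, heights R/2 each
  half <- setNames(c(rep("C", 5), rep("W", 5)), paste0("s", 1:10))
  lm2 <- logoMatrix(half, span = 1)
  expect_equal(logoInformation(lm2), log2(20) - 1, tolerance = 1e-12)
  expect_equal(unname(logoHeights(lm2)["C", 1]), (log2(20) - 1) / 2, tolerance = 1e-12)
  expect_equal(unname(logoHeights(lm2)["W", 1]), (log2(20) - 1) / 2, tolerance = 1e-12)

  # all-gap column: zero information, no letters
  gappy <- c(a = "C-", b = "C-")
  lm3 <- logoMatrix(gappy, span = 1:2)
  expect_equal(logoInformation(lm3)[2], 0)
  expect_equal(sum(logoHeights(lm3)[, 2]), 0)

  # heights always sum to the information content
  withr::with_seed(83, {
    rows <- setNames(vapply(1:8, function(i) randomSeq(25), character(1)),
                     paste0("s", 1:8))
  })
  lm4 <- logoMatrix(rows)  # default span: terminal 20 columns
  expect_equal(length(logoInformation(lm4)), 20L)
  expect_equal(unname(colSums(logoHeights(lm4))), logoInformation(lm4),
               tolerance = 1e-12)
  expect_true(all(logoHeights(lm4) >= 0))

  # the small-sample correction can only lower the information content
  lm5 <- logoMatrix(rows, smallSample = TRUE)
  expect_true(all(logoInformation(lm5) <= logoInformation(lm4) + 1e-12))

  expect_error(logoMatrix(rows, span = integer(0)), class = "rgkscan_usage")
  expect_error(logoMatrix(rows, span = 100), class = "rgkscan_usage")
})

test_that("percent identity counts only co-aligned columns", {
  expect_equal(percentIdentity("ACDE", "ACDE"), 100)
  expect_equal(percentIdentity("AC-D", "AG-D"), 100 * 2 / 3, tolerance = 1e-12)
  expect_error(percentIdentity("A---", "-A--"), class = "rgkscan_undefined")
  expect_error(percentIdentity("AC", "ACD"), class = "rgkscan_usage")
})
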