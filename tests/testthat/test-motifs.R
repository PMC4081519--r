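test_that("the RGK signature compiles to its documented structure", {
  sig <- rgkSignature()
  expect_s4_class(sig, "MotifPattern")
  expect_equal(motifLength(sig), 11L)
  cls <- patternClasses(sig)
  expect_identical(cls[[1]], c("K", "R"))
  expect_identical(cls[[5]], "C")
  expect_equal(length(cls[[9]]), 20L)  # wildcard position
  # exactly one singleton-cysteine position
  expect_equal(sum(vapply(cls, identical, logical(1), y = "C")), 1L)
})

test_that("the pattern grammar compiles, renders and rejects bad input", {
  p <- compilePattern("x")
  expect_equal(motifLength(p), 1L)
  expect_equal(length(patternClasses(p)[[1]]), 20L)

  # compile(render(p)) is equivalent to p
  withr::with_seed(5, {
    for (i in 1:50) {
      spec <- randomPatternSpec(sample(1:12, 1))
      p <- compilePattern(spec$text)
      p2 <- compilePattern(renderPattern(p))
      expect_identical(patternClasses(p2), patternClasses(p))
    }
  })

  expect_error(compilePattern("[KR"), "unbalanced", class = "rgkscan_pattern")
  expect_error(compilePattern("KR]"), "unbalanced", class = "rgkscan_pattern")
  expect_error(compilePattern("[]KR"), "empty", class = "rgkscan_pattern")
  expect_error(compilePattern("K1R"), "offset 2", class = "rgkscan_pattern")
  expect_error(compilePattern(""), class = "rgkscan_usage")
})

test_that("matchAt applies per-position classes and mismatch tolerance", {
  sig <- rgkSignature()
  hit <- matchAt("KSKHCHDLSVL", sig, 1)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$n_mismatches, 0L)
  expect_equal(hit$end, 11L)

  # violating the singleton cysteine class kills the match at tolerance 0
  expect_equal(nrow(matchAt("KSKHSHDLSVL", sig, 1)), 0L)
  relaxed <- matchAt("KSKHSHDLSVL", sig, 1, maxMismatches = 1)
  expect_equal(relaxed$n_mismatches, 1L)

  expect_error(matchAt("KSKHCHDLSVL", sig, 2), class = "rgkscan_usage")
  expect_error(matchAt("KSKHCHDLSVL", sig, 0), class = "rgkscan_usage")
})

test_that("C-terminal scanning is anchored by default", {
  sig <- rgkSignature()
  rec <- paste0(strrep("M", 20), "RSKHCHDMAVL")
  hit <- scanCTerminus(rec, sig)
  expect_equal(hit$start, 21L)
  expect_equal(hit$end, 31L)

  expect_equal(nrow(scanCTerminus("MKTLV", sig)), 0L)

  # a signature 20 residues before the end is invisible to the anchored scan
  internal <- paste0("M", "KSKHCHDLSVL", strrep("G", 20))
  expect_equal(nrow(scanCTerminus(internal, sig)), 0L)
  anywhere <- scanCTerminus(internal, sig, anchored = FALSE)
  expect_equal(nrow(anywhere), 1L)
  expect_equal(anywhere$start, 2L)
})

test_that("pattern scanning agrees with the brute-force oracle", {
  withr::with_seed(23, {
    for (i in 1:1000) {
      spec <- randomPatternSpec(sample(2:8, 1))
      len <- sample(5:60, 1)
      alphabet <- if (i %% 10 == 0) c(AA, "X") else AA
      seq <- randomSeq(len, alphabet)
      tol <- sample(0:2, 1)
      got <- scanPattern(seq, compilePattern(spec$text), maxMismatches = tol)
      expect_identical(got$start, oracleScan(seq, spec$classes, tol))
    }
  })
})

test_that("G-motifs are found in ascending order with flagged tolerant hits", {
  hits <- findGMotifs("MGDSGVGKSTTDKWETTETSAMM")
  expect_true(all(diff(hits$start) >= 0))
  expect_true(all(c("G1", "G3", "G5") %in% hits$motif))
  g1 <- hits[hits$motif == "G1", ]
  expect_equal(g1$start, 2L)
  expect_equal(g1$matched, "GDSGVGKS")

  expect_equal(nrow(findGMotifs("AAAAAAAAAA")), 0L)

  # one fixed-position deviation is recovered only in tolerant mode
  seq <- "MGDSGVGKATT"  # G1 with S->A in the last position
  expect_false("G1" %in% findGMotifs(seq)$motif)
  tol <- findGMotifs(seq, tolerant = TRUE)
  expect_true("G1" %in% tol$motif)
  expect_equal(tol$n_mismatches[tol$motif == "G1"], 1L)
})

test_that("G-domain extraction applies the -6/+30 rules and conventions", {
  # G1 at 77, G5 at 220 (so the 0-based anchors are 76 and 219)
  seq <- paste0(strrep("A", 76), "GDSGVGKS", strrep("L", 135), "ETSA",
                strrep("G", 40))
  dom <- extractGDomain(seq, "x")
  expect_equal(dom@g1Start, 77L)
  expect_equal(dom@g5Start, 220L)
  expect_equal(dom@start, 71L)
  expect_equal(dom@end, 249L)
  expect_equal(gdomainLength(dom), 179L)
  expect_false(dom@truncated)

  dom2 <- extractGDomain(seq, "x", convention = "g5-end+30")
  expect_equal(dom2@end, 253L)
  expect_equal(gdomainLength(dom2) - gdomainLength(dom), 4L)

  # start clamped at the first residue
  clamped <- paste0("AAA", "GDSGVGKS", strrep("L", 131), "ETSA", strrep("G", 30))
  domC <- extractGDomain(clamped, "x")
  expect_equal(domC@start, 1L)
  expect_true(domC@truncated)

  expect_error(extractGDomain(strrep("A", 50), "x"),
               "G1, G5", class = "rgkscan_no_domain")
  expect_error(extractGDomain(paste0("GDSGVGKS", strrep("A", 50)), "x"),
               "G5", class = "rgkscan_no_domain")
})

test_that("ambiguous G1/G5 pairings resolve to the length closest to 175", {
  # two G5 candidates: separations 100 and 139 -> lengths 136 and 175
  seq <- paste0(strrep("A", 70), "GDSGVGKS",
                strrep("L", 92), "ETSA",
                strrep("M", 35), "ETSA",
                strrep("G", 40))
  dom <- extractGDomain(seq, "x")
  expect_equal(dom@g5Start - dom@g1Start, 139L)
  expect_equal(gdomainLength(dom), 175L)
})

test_that("convention length difference equals the G5 motif length", {
  withr::with_seed(31, {
    recs <- generateRgkLike(10, benchmarkSpec(tailNoise = 0))$records
  })
  for (id in names(recs)) {
    s <- as.character(recs[[id]])
    a <- extractGDomain(s, id, convention = "g5-start+30")
    b <- extractGDomain(s, id, convention = "g5-end+30")
    expect_equal(gdomainLength(b) - gdomainLength(a), 4L)
  }
})

test_that("C-terminal features are annotated by offset from the end", {
  # signature position 4 drawn as S, so the -8 serine is present
  tail <- paste0(strrep("M", 30), "KRKKRSKTKRKKRRSNKRRSRSSRS", "KSKSCHDLSVL")
  ann <- annotateCTerminus(tail, "t1")
  expect_true(ann$signature_present)
  expect_true(ann$c7_cysteine)
  expect_true(ann$ser_minus8)
  expect_true(ann$pdz_class1)
  expect_gt(ann$polybasic_fraction, 0.5)

  noC <- paste0(strrep("M", 30), "AHDLSVL")
  expect_false(annotateCTerminus(noC)$c7_cysteine)

  short <- annotateCTerminus(strrep("A", 20))
  expect_true(is.na(short$polybasic_fraction))
  tiny <- annotateCTerminus("MKTLV")
  expect_true(is.na(tiny$signature_present))
})

test_that("annotation output is deterministic", {
  withr::with_seed(7, seqs <- vapply(1:20, function(i) randomSeq(80), character(1)))
  t1 <- do.call(rbind, lapply(seqs, annotateCTerminus))
  t2 <- do.call(rbind, lapply(seqs, annotateCTerminus))
  expect_identical(t1, t2)
})
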