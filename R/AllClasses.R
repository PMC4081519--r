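#' MotifPattern: a compiled position-class pattern
#'
#' A compiled PROSITE-like pattern: one residue class per position, where a
#' class is a non-empty subset of the 20 amino acids and the wildcard class
#' is the full alphabet. Build with \code{\link{compilePattern}}.
#'
#' @slot source The pattern text the object was compiled from.
#' @slot classes List of character vectors, one residue class per position.
#' @slot fixed Integer indices of the non-wildcard positions.
#' @export
setClass("MotifPattern", representation(
  source = "character",
  classes = "list",
  fixed = "integer"
))

setValidity("MotifPattern", function(object) {
  cls <- object@classes
  if (length(cls) < 1L) return("pattern must have at least one position")
  for (i in seq_along(cls)) {
    k <- cls[[i]]
    if (length(k) == 0L) return(sprintf("empty residue class at position %d", i))
    if (!all(k %in% AA20)) return(sprintf("illegal residue letter at position %d", i))
    if (anyDuplicated(k)) return(sprintf("duplicated residue at position %d", i))
  }
  wide <- vapply(cls, function(k) length(k) == 20L, logical(1))
  if (!identical(object@fixed, which(!wide))) {
    return("fixed-position index out of step with classes")
  }
  TRUE
})

#' @describeIn MotifPattern Number of positions in the pattern.
#' @param x,object A \code{MotifPattern}.
#' @export
motifLength <- function(x) length(x@classes)

#' @describeIn MotifPattern The per-position residue classes (list of
#'   character vectors).
#' @export
patternClasses <- function(x) x@classes

setMethod("show", "MotifPattern", function(object) {
  cat("MotifPattern of length", motifLength(object), "\n")
  cat("  pattern:", renderPattern(object), "\n")
  cat("  fixed positions:", paste(object@fixed, collapse = " "), "\n")
})

#' GMotifDefinition: a named G-motif with mismatch tolerance
#'
#' Couples a canonical G-box pattern (G1--G5 of the Ras GTPase fold) with
#' the number of fixed-position mismatches tolerated when scanning. The
#' stock catalog is returned by \code{\link{gMotifCatalog}}.
#'
#' @slot name Motif name (e.g. "G1").
#' @slot pattern The compiled \code{MotifPattern}.
#' @slot maxMismatches Fixed-position mismatches tolerated in tolerant mode.
#' @slot annotationOnly If \code{TRUE} the motif is reported but never used
#'   as a G-domain boundary anchor (G4's short N-K core).
#' @export
setClass("GMotifDefinition", representation(
  name = "character",
  pattern = "MotifPattern",
  maxMismatches = "integer",
  annotationOnly = "logical"
))

setValidity("GMotifDefinition", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name)) return("name required")
  if (object@maxMismatches < 0L) return("maxMismatches must be >= 0")
  TRUE
})

setMethod("show", "GMotifDefinition", function(object) {
  cat(sprintf("GMotifDefinition %s: %s (tolerant mismatches: %d%s)\n",
              object@name, renderPattern(object@pattern), object@maxMismatches,
              if (object@annotationOnly) ", annotation-only" else ""))
})

#' GDomainAnnotation: a motif-anchored G-domain interval
#'
#' The parsed Ras-homology G-domain of one record: the G1/G5 anchor hits and
#' the interval they imply under the -6 (from G1 start) and +30 (from the G5
#' anchor) boundary rules. Coordinates are 1-based inclusive. Produced by
#' \code{\link{extractGDomain}}.
#'
#' @slot recordId Identifier of the annotated record.
#' @slot g1Start,g1End,g5Start,g5End Anchor motif coordinates.
#' @slot start,end The G-domain interval.
#' @slot convention "g5-start+30" or "g5-end+30".
#' @slot truncated \code{TRUE} when the start was clamped at residue 1 or the
#'   end clipped at the sequence length.
#' @export
setClass("GDomainAnnotation", representation(
  recordId = "character",
  g1Start = "integer", g1End = "integer",
  g5Start = "integer", g5End = "integer",
  start = "integer", end = "integer",
  convention = "character",
  truncated = "logical"
))

setValidity("GDomainAnnotation", function(object) {
  if (object@end <= object@start) return("end must exceed start")
  if (!object@convention %in% c("g5-start+30", "g5-end+30")) {
    return("unknown G5 end convention")
  }
  TRUE
})

#' @describeIn GDomainAnnotation G-domain length in residues.
#' @param x,object A \code{GDomainAnnotation}.
#' @export
gdomainLength <- function(x) x@end - x@start + 1L

#' @describeIn GDomainAnnotation Start/end as a length-2 integer vector.
#' @export
gdomainRange <- function(x) c(start = x@start, end = x@end)

setMethod("show", "GDomainAnnotation", function(object) {
  cat(sprintf("GDomainAnnotation for %s: [%d, %d] (%d aa, %s%s)\n",
              object@recordId, object@start, object@end, gdomainLength(object),
              object@convention,
              if (object@truncated) ", truncated" else ""))
  cat(sprintf("  G1 at %d-%d, G5 at %d-%d\n",
              object@g1Start, object@g1End, object@g5Start, object@g5End))
})

#' ProfileModel: a position-specific scoring matrix
#'
#' Per-position log-odds scores (bits) over the 20 amino acids, built from an
#' alignment with pseudocounts against a background distribution:
#' p_a = (c_a + alpha * q_a) / (N + alpha), score(a) = log2(p_a / q_a),
#' where c_a is the observed count of residue a in the column and N the
#' number of non-gap observations. Build with \code{\link{buildProfile}}.
#'
#' @slot scores 20 x L numeric matrix of log-odds scores, rows named by
#'   amino acid.
#' @slot alpha Pseudocount weight (> 0).
#' @slot background Named numeric background frequencies (sum 1).
#' @slot sources Identifiers of the sequences the profile was built from.
#' @export
setClass("ProfileModel", representation(
  scores = "matrix",
  alpha = "numeric",
  background = "numeric",
  sources = "character"
))

setValidity("ProfileModel", function(object) {
  if (!identical(rownames(object@scores), AA20)) {
    return("score matrix rows must be the 20 amino acids")
  }
  if (object@alpha <= 0) return("alpha must be > 0")
  q <- object@background
  if (length(q) != 20L || any(q <= 0) || abs(sum(q) - 1) > 1e-8) {
    return("background must be 20 strictly positive frequencies summing to 1")
  }
  TRUE
})

#' @describeIn ProfileModel Number of profile columns.
#' @param x,object A \code{ProfileModel}.
#' @export
profileLength <- function(x) ncol(x@scores)

#' @describeIn ProfileModel The 20 x L log-odds score matrix (bits).
#' @export
profileScores <- function(x) x@scores

setMethod("show", "ProfileModel", function(object) {
  cat(sprintf("ProfileModel: %d columns, alpha = %g, %d source sequence(s)\n",
              profileLength(object), object@alpha, length(object@sources)))
  cat(sprintf("  score range: [%.3f, %.3f] bits\n",
              min(object@scores), max(object@scores)))
})

#' ConservationProfile: per-column conservation of an alignment
#'
#' Information-content conservation (log2 20 minus the Shannon entropy of the
#' column's non-gap residue frequencies, in bits) with a centred moving
#' average and a gap-fraction mask. Build with
#' \code{\link{conservationProfile}}.
#'
#' @slot scores Raw per-column scores in [0, log2 20].
#' @slot smoothed Moving-average scores (NA at masked columns).
#' @slot mask Logical; columns whose gap fraction exceeds the cutoff.
#' @slot w Smoothing window width (odd).
#' @slot gapCutoff Gap-fraction cutoff used for the mask.
#' @export
setClass("ConservationProfile", representation(
  scores = "numeric",
  smoothed = "numeric",
  mask = "logical",
  w = "integer",
  gapCutoff = "numeric"
))

setValidity("ConservationProfile", function(object) {
  n <- length(object@scores)
  if (length(object@smoothed) != n || length(object@mask) != n) {
    return("scores, smoothed and mask must have one entry per column")
  }
  if (any(object@scores < -1e-9 | object@scores > log2(20) + 1e-9)) {
    return("scores must lie in [0, log2 20]")
  }
  if (object@w %% 2L == 0L) return("smoothing window must be odd")
  TRUE
})

#' @describeIn ConservationProfile Raw per-column scores (bits).
#' @param x,object A \code{ConservationProfile}.
#' @export
conservationScores <- function(x) x@scores

#' @describeIn ConservationProfile Smoothed scores (NA at masked columns).
#' @export
smoothedScores <- function(x) x@smoothed

#' @describeIn ConservationProfile Logical mask of gap-heavy columns.
#' @export
maskedColumns <- function(x) x@mask

setMethod("show", "ConservationProfile", function(object) {
  cat(sprintf("ConservationProfile: %d columns (window %d, gap cutoff %.2f)\n",
              length(object@scores), object@w, object@gapCutoff))
  cat(sprintf("  score range [%.3f, %.3f] bits; %d masked column(s)\n",
              min(object@scores), max(object@scores), sum(object@mask)))
})

#' LogoMatrix: sequence-logo letter heights
#'
#' Per-column information content R = log2 20 - H (bits, gaps excluded) and
#' letter heights h_a = f_a * R, as drawn by sequence-logo software. Build
#' with \code{\link{logoMatrix}}.
#'
#' @slot heights 20 x k matrix of letter heights, rows named by amino acid.
#' @slot info Information content per column (bits).
#' @slot span Integer alignment-column indices the logo covers.
#' @export
setClass("LogoMatrix", representation(
  heights = "matrix",
  info = "numeric",
  span = "integer"
))

setValidity("LogoMatrix", function(object) {
  if (!identical(rownames(object@heights), AA20)) {
    return("height matrix rows must be the 20 amino acids")
  }
  if (ncol(object@heights) != length(object@info) ||
      length(object@span) != length(object@info)) {
    return("heights, info and span must agree in length")
  }
  if (any(object@heights < -1e-9)) return("letter heights must be non-negative")
  TRUE
})

#' @describeIn LogoMatrix Letter-height matrix.
#' @param x,object A \code{LogoMatrix}.
#' @export
logoHeights <- function(x) x@heights

#' @describeIn LogoMatrix Per-column information content (bits).
#' @export
logoInformation <- function(x) x@info

setMethod("show", "LogoMatrix", function(object) {
  cat(sprintf("LogoMatrix over %d column(s) (alignment columns %d-%d)\n",
              length(object@span), min(object@span), max(object@span)))
  cat(sprintf("  information content range [%.3f, %.3f] bits\n",
              min(object@info), max(object@info)))
})

#' BenchmarkSpec: parameters of the synthetic-proteome generator
#'
#' Describes one synthetic benchmark: how many RGK-like records, Ras-like
#' decoys and i.i.d. background sequences to emit and the sequence geometry
#' the generator plants. See \code{\link{benchmarkSpec}} for the constructor
#' and defaults, and \code{\link{generateBenchmark}} to realise it.
#'
#' @slot nRgk,nDecoy,nBackground Record counts per class.
#' @slot tailNoise Per-position substitution probability applied to the
#'   C-terminal tail outside anchor positions.
#' @slot anchorMode "fixed" (all class-constrained signature positions are
#'   protected from noise) or "cysteine" (only the invariant cysteine is).
#' @slot nTermRange Min/max N-terminus length (uniform draw).
#' @slot separation Distance from G1 start to G5 start in planted domains.
#' @slot tailLength C-terminal tail length (the aligned-tail span).
#' @slot backgroundLengthRange Min/max background sequence length.
#' @slot backgroundFreqs Background residue distribution.
#' @slot nearMissFraction Fraction of decoys given a signature-conforming
#'   tail mutated exactly at the invariant-cysteine position.
#' @slot polybasicRate Probability that a tail residue in the polybasic
#'   window (-35..-15) is drawn as K or R.
#' @export
setClass("BenchmarkSpec", representation(
  nRgk = "integer", nDecoy = "integer", nBackground = "integer",
  tailNoise = "numeric",
  anchorMode = "character",
  nTermRange = "integer",
  separation = "integer",
  tailLength = "integer",
  backgroundLengthRange = "integer",
  backgroundFreqs = "numeric",
  nearMissFraction = "numeric",
  polybasicRate = "numeric"
))

setValidity("BenchmarkSpec", function(object) {
  if (min(object@nRgk, object@nDecoy, object@nBackground) < 0L) {
    return("record counts must be >= 0")
  }
  p <- c(object@tailNoise, object@nearMissFraction, object@polybasicRate)
  if (any(p < 0 | p > 1)) return("probabilities must lie in [0, 1]")
  if (!object@anchorMode %in% c("fixed", "cysteine")) {
    return("anchorMode must be 'fixed' or 'cysteine'")
  }
  if (object@separation < 8L) return("separation must leave room for the G1 motif")
  if (object@tailLength < 11L) return("tail must be at least as long as the signature")
  if (diff(object@nTermRange) < 0L || object@nTermRange[1] < 7L) {
    return("nTermRange must be increasing and leave room for the -6 rule")
  }
  if (diff(object@backgroundLengthRange) < 0L) {
    return("backgroundLengthRange must be increasing")
  }
  TRUE
})

setMethod("show", "BenchmarkSpec", function(object) {
  cat("BenchmarkSpec:\n")
  cat(sprintf("  records: %d RGK-like, %d decoy, %d background\n",
              object@nRgk, object@nDecoy, object@nBackground))
  cat(sprintf("  tail noise %.3f (anchors: %s), near-miss fraction %.2f\n",
              object@tailNoise, object@anchorMode, object@nearMissFraction))
  cat(sprintf("  N-terminus %d-%d aa, G1->G5 separation %d, tail %d aa\n",
              object@nTermRange[1], object@nTermRange[2],
              object@separation, object@tailLength))
})
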