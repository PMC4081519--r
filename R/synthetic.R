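#' Construct a synthetic-benchmark specification
#'
#' Defaults describe the benchmark used throughout the package's tests: 200
#' RGK-like records, 200 Ras-like decoys and 600 background sequences.
#' RGK-like records carry a variable-length N-terminus (60--150 residues,
#' spanning the vertebrate and the longer invertebrate ranges), a G-domain
#' scaffold with exact planted G1 (\code{GDSGVGKS}), G3 (\code{DKWE}), G4
#' (\code{NK}) and G5 (\code{ETSA}) motifs with the G5 start 139 residues
#' after the G1 start (so the default extraction rules give a 175-residue
#' domain, the midpoint of the family's typical 170--180), and a 40-residue
#' tail whose last eleven residues are drawn from the signature classes.
#' Decoys share the G-domain scaffold but their tails are rejection-sampled
#' to miss the signature; a \code{nearMissFraction} of them instead get a
#' signature-conforming tail mutated exactly at the invariant-cysteine
#' position. Background records are i.i.d. residues.
#'
#' \code{tailNoise} substitutes tail residues (uniformly over the 20 amino
#' acids) with the given per-position probability, outside anchor positions.
#' With \code{anchorMode = "fixed"} (default) every class-constrained
#' signature position is an anchor, so noise never destroys a planted
#' signature and class labels remain detection-consistent. With
#' \code{anchorMode = "cysteine"} only the invariant cysteine is protected
#' and noise can knock a record out of the signature class; the per-sequence
#' retention probability then has the closed form
#' \code{prod(1 - p (1 - k/20))} over the unprotected constrained positions
#' with class sizes k.
#'
#' @param nRgk,nDecoy,nBackground Record counts.
#' @param tailNoise Per-position tail substitution probability.
#' @param anchorMode "fixed" or "cysteine" (see above).
#' @param nTermRange Length-2 range of N-terminus lengths.
#' @param separation G1-start to G5-start distance (139 gives a 175-residue
#'   domain under the default extraction convention).
#' @param tailLength Tail length (default 40).
#' @param backgroundLengthRange Length-2 range of background sequence lengths.
#' @param backgroundFreqs Background residue distribution (default uniform).
#' @param nearMissFraction Fraction of decoys given near-miss tails.
#' @param polybasicRate K/R enrichment rate in the tail's -35..-15 window.
#' @return A \code{\linkS4class{BenchmarkSpec}}.
#' @examples
#' benchmarkSpec(nRgk = 5, nDecoy = 5, nBackground = 10)
#' @export
benchmarkSpec <- function(nRgk = 200L, nDecoy = 200L, nBackground = 600L,
                          tailNoise = 0.05, anchorMode = c("fixed", "cysteine"),
                          nTermRange = c(60L, 150L), separation = 139L,
                          tailLength = 40L,
                          backgroundLengthRange = c(100L, 500L),
                          backgroundFreqs = uniformBackground(),
                          nearMissFraction = 0.1, polybasicRate = 0.6) {
  anchorMode <- match.arg(anchorMode)
  methods::new("BenchmarkSpec",
               nRgk = as.integer(nRgk), nDecoy = as.integer(nDecoy),
               nBackground = as.integer(nBackground),
               tailNoise = tailNoise, anchorMode = anchorMode,
               nTermRange = as.integer(nTermRange),
               separation = as.integer(separation),
               tailLength = as.integer(tailLength),
               backgroundLengthRange = as.integer(backgroundLengthRange),
               backgroundFreqs = .checkBackground(backgroundFreqs),
               nearMissFraction = nearMissFraction,
               polybasicRate = polybasicRate)
}

# Planted motif sequences (exact instances of the G-motif patterns).
.PLANT_G1 <- "GDSGVGKS"
.PLANT_G3 <- "DKWE"
.PLANT_G4 <- "NK"
.PLANT_G5 <- "ETSA"

# Relative offsets (from the G1 start) at which G3/G4 are planted, shaped
# after the spacing in the vertebrate Gem G-domain.
.G3_REL <- 62L
.G4_REL <- 114L

# Sample one tail of length spec@tailLength whose last 11 residues are drawn
# uniformly from the signature classes; K/R-enriched in the polybasic window.
.sampleTailBody <- function(spec) {
  tl <- spec@tailLength
  body <- .randResidues(tl - 11L, spec@backgroundFreqs)
  # polybasic/calmodulin window: offsets -35..-15 from the record end
  polyIdx <- seq.int(max(1L, tl - 34L), tl - 14L)
  polyIdx <- polyIdx[polyIdx <= length(body)]
  kr <- runif(length(polyIdx)) < spec@polybasicRate
  body[polyIdx[kr]] <- sample(c("K", "R"), sum(kr), replace = TRUE)
  body
}

.sampleSignature <- function(signature) {
  vapply(patternClasses(signature), function(k) {
    k[sample.int(length(k), 1L)]
  }, character(1))
}

# Tail positions protected from noise (indices within the tail).
.noiseAnchors <- function(spec, signature) {
  tl <- spec@tailLength
  sigStart <- tl - motifLength(signature) + 1L
  if (spec@anchorMode == "fixed") {
    sigStart - 1L + signature@fixed
  } else {
    cysPos <- which(vapply(patternClasses(signature),
                           function(k) identical(k, "C"), logical(1)))
    sigStart - 1L + cysPos
  }
}

.applyTailNoise <- function(tail, spec, signature) {
  anchors <- .noiseAnchors(spec, signature)
  eligible <- setdiff(seq_along(tail), anchors)
  hit <- eligible[runif(length(eligible)) < spec@tailNoise]
  if (length(hit) > 0L) {
    tail[hit] <- sample(AA20, length(hit), replace = TRUE)
  }
  tail
}

# One G-domain scaffold: 6 pre-G1 residues, G1, spacer with planted G3/G4,
# G5, then 26 residues completing the +30 span. Returns list(chars, g1, g5)
# with g1/g5 relative to the scaffold start.
.sampleScaffold <- function(spec) {
  sep <- spec@separation
  mid <- .randResidues(sep - nchar(.PLANT_G1), spec@backgroundFreqs)
  plant <- function(mid, rel, motif) {
    # rel is the motif offset from the G1 start; mid starts at rel 8
    at <- rel - nchar(.PLANT_G1) + 1L
    if (at >= 1L && at + nchar(motif) - 1L <= length(mid)) {
      mid[at:(at + nchar(motif) - 1L)] <- .chars(motif)
    }
    mid
  }
  mid <- plant(mid, .G3_REL, .PLANT_G3)
  mid <- plant(mid, .G4_REL, .PLANT_G4)
  chars <- c(.randResidues(6L, spec@backgroundFreqs),
             .chars(.PLANT_G1), mid, .chars(.PLANT_G5),
             .randResidues(26L, spec@backgroundFreqs))
  list(chars = chars, g1 = 7L, g5 = 7L + sep)
}

.truthRow <- function(id, class, g1 = NA_integer_, g5 = NA_integer_,
                      sig = NA_integer_, nearMiss = FALSE) {
  data.frame(record_id = id, class = class, g1_start = g1, g5_start = g5,
             signature_start = sig, near_miss = nearMiss,
             stringsAsFactors = FALSE)
}

#' Generate RGK-like synthetic records
#'
#' See \code{\link{benchmarkSpec}} for the sequence layout. Returns both the
#' sequences and a truth table recording where each motif was planted.
#'
#' @param n Number of records.
#' @param spec A \code{BenchmarkSpec}.
#' @param seed Optional integer seed (when NULL the current RNG stream is
#'   used, as \code{\link{generateBenchmark}} does).
#' @param idPrefix Record id prefix.
#' @return list(records = AAStringSet, truth = data.frame).
#' @export
generateRgkLike <- function(n, spec = benchmarkSpec(), seed = NULL,
                            idPrefix = "rgk") {
  if (!is.null(seed)) set.seed(as.integer(seed))
  signature <- rgkSignature()
  seqs <- character(n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    ntermLen <- sample(spec@nTermRange[1]:spec@nTermRange[2], 1L)
    nterm <- .randResidues(ntermLen, spec@backgroundFreqs)
    sc <- .sampleScaffold(spec)
    tail <- c(.sampleTailBody(spec), .sampleSignature(signature))
    tail <- .applyTailNoise(tail, spec, signature)
    chars <- c(nterm, sc$chars, tail)
    id <- sprintf("%s_%04d", idPrefix, i)
    seqs[i] <- paste(chars, collapse = "")
    truth[[i]] <- .truthRow(id, "RGK",
                            g1 = ntermLen + sc$g1,
                            g5 = ntermLen + sc$g5,
                            sig = length(chars) - motifLength(signature) + 1L)
    names(seqs)[i] <- id
  }
  list(records = Biostrings::AAStringSet(seqs),
       truth = do.call(rbind, truth))
}

#' Generate Ras-like decoy records
#'
#' Decoys carry the same planted G-domain scaffold as RGK-like records but a
#' background-sampled tail rejection-sampled to miss the anchored signature.
#' A \code{nearMissFraction} of decoys instead receive a signature-conforming
#' tail mutated at exactly the invariant-cysteine position: these fail a
#' zero-tolerance scan but hit with one mismatch, and retain high profile
#' similarity.
#'
#' @inheritParams generateRgkLike
#' @return list(records = AAStringSet, truth = data.frame).
#' @export
generateDecoys <- function(n, spec = benchmarkSpec(), seed = NULL,
                           idPrefix = "decoy") {
  if (!is.null(seed)) set.seed(as.integer(seed))
  signature <- rgkSignature()
  L <- motifLength(signature)
  nNear <- round(n * spec@nearMissFraction)
  seqs <- character(n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    ntermLen <- sample(spec@nTermRange[1]:spec@nTermRange[2], 1L)
    nterm <- .randResidues(ntermLen, spec@backgroundFreqs)
    sc <- .sampleScaffold(spec)
    nearMiss <- i <= nNear
    if (nearMiss) {
      sig <- .sampleSignature(signature)
      cysPos <- which(vapply(patternClasses(signature),
                             function(k) identical(k, "C"), logical(1)))
      sig[cysPos] <- sample(setdiff(AA20, "C"), 1L)
      tail <- c(.sampleTailBody(spec), sig)
    } else {
      repeat {
        tail11 <- .randResidues(L, spec@backgroundFreqs)
        if (nrow(matchAt(paste(tail11, collapse = ""), signature, 1L)) == 0L) break
      }
      tail <- c(.sampleTailBody(spec), tail11)
    }
    chars <- c(nterm, sc$chars, tail)
    id <- sprintf("%s_%04d", idPrefix, i)
    seqs[i] <- paste(chars, collapse = "")
    names(seqs)[i] <- id
    truth[[i]] <- .truthRow(id, "decoy",
                            g1 = ntermLen + sc$g1,
                            g5 = ntermLen + sc$g5,
                            nearMiss = nearMiss)
  }
  list(records = Biostrings::AAStringSet(seqs),
       truth = do.call(rbind, truth))
}

#' Generate i.i.d. background records
#'
#' @param n Number of records.
#' @param lengthRange Length-2 range; lengths are uniform over it.
#' @param frequencies Residue distribution (default uniform).
#' @param seed Optional integer seed.
#' @param idPrefix Record id prefix.
#' @return An \code{AAStringSet}.
#' @export
generateBackground <- function(n, lengthRange = c(100L, 500L),
                               frequencies = uniformBackground(),
                               seed = NULL, idPrefix = "bg") {
  if (!is.null(seed)) set.seed(as.integer(seed))
  q <- .checkBackground(frequencies)
  if (n == 0L) return(Biostrings::AAStringSet(character(0)))
  lens <- sample(lengthRange[1]:lengthRange[2], n, replace = TRUE)
  seqs <- vapply(lens, function(l) paste(.randResidues(l, q), collapse = ""),
                 character(1))
  names(seqs) <- sprintf("%s_%04d", idPrefix, seq_len(n))
  Biostrings::AAStringSet(seqs)
}

#' Realise a full synthetic benchmark
#'
#' Draws the RGK-like, decoy and background records of a
#' \code{\linkS4class{BenchmarkSpec}} from a single seeded random stream and
#' assembles the combined record set and truth table. Identical (spec, seed)
#' pairs give byte-identical output.
#'
#' @param spec A \code{BenchmarkSpec}.
#' @param seed Integer seed.
#' @return list(records = AAStringSet, truth = data.frame with columns
#'   record_id, class, g1_start, g5_start, signature_start, near_miss).
#' @examples
#' b <- generateBenchmark(benchmarkSpec(nRgk = 2, nDecoy = 2, nBackground = 2),
#'                        seed = 1)
#' b$truth
#' @export
generateBenchmark <- function(spec = benchmarkSpec(), seed = 42L) {
  set.seed(as.integer(seed))
  rgk <- generateRgkLike(spec@nRgk, spec)
  dec <- generateDecoys(spec@nDecoy, spec)
  bg <- generateBackground(spec@nBackground, spec@backgroundLengthRange,
                           spec@backgroundFreqs)
  bgTruth <- if (length(bg) > 0L) {
    do.call(rbind, lapply(names(bg), .truthRow, class = "background"))
  } else NULL
  records <- c(rgk$records, dec$records, bg)
  truth <- rbind(rgk$truth, dec$truth, bgTruth)
  rownames(truth) <- NULL
  list(records = records, truth = truth)
}

#' Generate an alignment with a prescribed conservation layout
#'
#' Each column is assigned a regime with an analytically known conservation
#' score: \code{"fixed"} (one residue, score log2 20), \code{"pair"} (an
#' exact 50/50 split of two residues, score log2 20 - 1 for even row counts)
#' or \code{"uniform"} (i.i.d. uniform residues, score near 0 for large row
#' counts).
#'
#' @param nRows Number of alignment rows.
#' @param layout Character vector of regimes, one per column.
#' @param seed Optional integer seed.
#' @return An \code{AAMultipleAlignment} with rows named seq_0001, ...
#' @export
generateAlignment <- function(nRows, layout, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (!all(layout %in% c("fixed", "pair", "uniform"))) {
    .rgkStop("layout regimes must be 'fixed', 'pair' or 'uniform'",
             "rgkscan_usage")
  }
  m <- matrix("", nrow = nRows, ncol = length(layout))
  for (j in seq_along(layout)) {
    m[, j] <- switch(layout[j],
      fixed = rep(sample(AA20, 1L), nRows),
      pair = {
        res <- sample(AA20, 2L)
        half <- nRows %/% 2L
        c(rep(res[1], half), rep(res[2], nRows - half))
      },
      uniform = sample(AA20, nRows, replace = TRUE)
    )
  }
  rows <- apply(m, 1L, paste, collapse = "")
  names(rows) <- sprintf("seq_%04d", seq_len(nRows))
  Biostrings::AAMultipleAlignment(Biostrings::AAStringSet(rows))
}
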