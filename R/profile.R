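#' Build a position-specific scoring matrix from an alignment
#'
#' One profile column per alignment column. Gaps (and unknown 'X' residues)
#' are excluded from the counts; a column with no observations scores zero
#' everywhere (its frequency vector collapses to the background). Scores are
#' log2(p_a / q_a) bits with pseudocounted frequencies
#' p_a = (c_a + alpha * q_a) / (N + alpha).
#'
#' @param alignment An \code{AAMultipleAlignment}, \code{AAStringSet}, named
#'   character vector of equal-length (gapped) rows, or character matrix.
#' @param alpha Pseudocount weight (> 0, default 0.5).
#' @param background Background residue frequencies (default uniform).
#' @return A \code{\linkS4class{ProfileModel}}.
#' @examples
#' prof <- buildProfile(c(a = "ACD", b = "ACD"))
#' profileScores(prof)["A", 1]
#' @export
buildProfile <- function(alignment, alpha = 0.5, background = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    .rgkStop("pseudocount weight alpha must be > 0", "rgkscan_usage")
  }
  q <- .checkBackground(if (is.null(background)) uniformBackground() else background)
  m <- .alnMatrix(alignment)
  if (nrow(m) == 0L || ncol(m) == 0L) {
    .rgkStop("empty alignment", "rgkscan_usage")
  }
  scores <- matrix(0, nrow = 20L, ncol = ncol(m),
                   dimnames = list(AA20, NULL))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col %in% AA20]
    N <- length(col)
    counts <- tabulate(factor(col, levels = AA20), nbins = 20L)
    p <- (counts + alpha * q) / (N + alpha)
    scores[, j] <- log2(p / q)
  }
  src <- rownames(m)
  methods::new("ProfileModel", scores = scores, alpha = alpha,
               background = q,
               sources = if (is.null(src)) character(0) else src)
}

#' Score a sequence window against a profile
#'
#' Sum of the column scores for the residues in the window starting at
#' \code{offset}; unknown residues ('X') contribute zero.
#'
#' @param seq Protein sequence.
#' @param profile A \code{ProfileModel}.
#' @param offset 1-based window start.
#' @return Window score in bits.
#' @export
scoreWindow <- function(seq, profile, offset) {
  chars <- .chars(seq)
  L <- profileLength(profile)
  if (length(chars) < L) {
    .rgkStop(sprintf("sequence (%d aa) shorter than profile (%d columns)",
                     length(chars), L), "rgkscan_usage")
  }
  if (offset < 1L || offset > length(chars) - L + 1L) {
    .rgkStop(sprintf("offset %d out of range for a %d-column profile on a %d aa sequence",
                     offset, L, length(chars)), "rgkscan_usage")
  }
  win <- chars[offset:(offset + L - 1L)]
  idx <- match(win, AA20)
  known <- !is.na(idx)
  sum(profile@scores[cbind(idx[known], which(known))])
}

#' Best window score of a sequence against a profile
#'
#' @inheritParams scoreWindow
#' @return The maximum \code{\link{scoreWindow}} over all offsets.
#' @export
bestWindowScore <- function(seq, profile) {
  chars <- .chars(seq)
  L <- profileLength(profile)
  if (length(chars) < L) {
    .rgkStop(sprintf("sequence (%d aa) shorter than profile (%d columns)",
                     length(chars), L), "rgkscan_usage")
  }
  idx <- match(chars, AA20)
  best <- -Inf
  for (off in seq_len(length(chars) - L + 1L)) {
    win <- idx[off:(off + L - 1L)]
    known <- !is.na(win)
    s <- sum(profile@scores[cbind(win[known], which(known))])
    if (s > best) best <- s
  }
  best
}

#' Empirical null distribution of profile scores
#'
#' Replaces database-search E-values with a transparent simulation null:
#' random sequences are drawn from the background distribution and the best
#' window score of each against the profile is recorded. A query's z-score is
#' (score - mean) / sd against this null.
#'
#' @param profile A \code{ProfileModel}.
#' @param nShuffles Number of null sequences (>= 100; default 500).
#' @param seed Integer seed; the null is reproducible for a fixed seed.
#' @param seqLength Length of each null sequence (default: the profile
#'   length, i.e. a single-window null, which matches C-terminal-anchored
#'   scoring).
#' @param background Residue distribution for the null sequences (default:
#'   the profile's own background).
#' @return List with elements \code{mean}, \code{sd} and \code{n}.
#' @export
empiricalNull <- function(profile, nShuffles = 500L, seed = 1L,
                          seqLength = profileLength(profile),
                          background = profile@background) {
  if (nShuffles < 100L) {
    .rgkStop("at least 100 null sequences are required", "rgkscan_usage")
  }
  if (seqLength < profileLength(profile)) {
    .rgkStop("null sequence length must be >= profile length", "rgkscan_usage")
  }
  q <- .checkBackground(background)
  scores <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(nShuffles), function(i) {
      s <- paste(.randResidues(seqLength, q), collapse = "")
      bestWindowScore(s, profile)
    }, numeric(1))
  })
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0) {
    .rgkStop("degenerate null: zero score variance", "rgkscan_null")
  }
  list(mean = mean(scores), sd = s, n = nShuffles)
}

#' Pattern-hit-initiated iterative profile search
#'
#' A transparent re-expression of the pattern-seeded, iteratively refined
#' homolog search: iteration 1 admits only records carrying the anchored
#' C-terminal signature, scores their terminal window against a profile built
#' from the seed alignment, and includes those at or above the z threshold.
#' Iteration 2 rebuilds the profile from the seed rows plus the iteration-1
#' inclusions and rescores \emph{every} record -- the pattern requirement is
#' dropped, mirroring the relaxation from pattern-seeded to profile-only
#' iterations. Records included at iteration 1 stay included. The z-scores
#' are taken against a seeded simulation null (\code{\link{empiricalNull}})
#' recomputed for each iteration's profile.
#'
#' @param db Records to search: \code{AAStringSet} or named character vector.
#' @param signature Signature pattern (default \code{\link{rgkSignature}()}).
#' @param seedAlignment Seed alignment covering the C-terminal region; the
#'   terminal \code{window} columns are used.
#' @param zThreshold Inclusion threshold in null standard deviations
#'   (default 5).
#' @param seed Integer seed driving the null simulations.
#' @param alpha Pseudocount weight for profiles.
#' @param background Background distribution (default uniform).
#' @param window Number of terminal alignment columns profiled (default 40,
#'   the span over which this family's C-termini align).
#' @param nShuffles Null sample size per iteration.
#' @param maxIter Number of iterations (default 2).
#' @return data.frame with one row per db record: record_id, score_bits, z,
#'   iteration_found (NA when never included), included.
#' @export
patternInitiatedSearch <- function(db, signature = rgkSignature(),
                                   seedAlignment, zThreshold = 5,
                                   seed = 1L, alpha = 0.5,
                                   background = NULL, window = 40L,
                                   nShuffles = 500L, maxIter = 2L) {
  seqs <- if (is.character(db)) db else as.character(db)
  ids <- names(seqs)
  if (length(seqs) == 0L) {
    return(data.frame(record_id = character(0), score_bits = numeric(0),
                      z = numeric(0), iteration_found = integer(0),
                      included = logical(0), stringsAsFactors = FALSE))
  }
  if (is.null(ids) || any(!nzchar(ids))) {
    .rgkStop("db records must be named", "rgkscan_usage")
  }
  m <- .alnMatrix(seedAlignment)
  if (ncol(m) > window) {
    m <- m[, (ncol(m) - window + 1L):ncol(m), drop = FALSE]
  }
  q <- .checkBackground(if (is.null(background)) uniformBackground() else background)
  L <- ncol(m)
  lens <- nchar(seqs)
  terminalWindow <- function(s) substr(s, nchar(s) - L + 1L, nchar(s))

  score_bits <- rep(NA_real_, length(seqs))
  z <- rep(NA_real_, length(seqs))
  iteration_found <- rep(NA_integer_, length(seqs))
  included <- rep(FALSE, length(seqs))

  profileRows <- m
  for (iter in seq_len(maxIter)) {
    prof <- buildProfile(profileRows, alpha = alpha, background = q)
    null <- empiricalNull(prof, nShuffles = nShuffles,
                          seed = as.integer(seed) + iter,
                          background = q)
    if (iter == 1L) {
      candidate <- vapply(seqs, function(s) {
        nchar(s) >= motifLength(signature) &&
          nrow(scanCTerminus(s, signature)) > 0L
      }, logical(1))
      candidate <- candidate & lens >= L
    } else {
      candidate <- lens >= L
    }
    for (k in which(candidate)) {
      sc <- scoreWindow(terminalWindow(seqs[k]), prof, 1L)
      score_bits[k] <- sc
      z[k] <- (sc - null$mean) / null$sd
      if (!included[k] && z[k] >= zThreshold) {
        included[k] <- TRUE
        iteration_found[k] <- iter
      }
    }
    if (iter < maxIter && any(included)) {
      newRows <- vapply(seqs[included], terminalWindow, character(1))
      profileRows <- rbind(m, do.call(rbind, strsplit(newRows, "", fixed = TRUE)))
    }
  }
  data.frame(record_id = ids, score_bits = score_bits, z = z,
             iteration_found = iteration_found, included = included,
             stringsAsFactors = FALSE, row.names = NULL)
}
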