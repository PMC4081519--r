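#' Per-column conservation profile of an alignment
#'
#' Conservation is scored as information content: log2(20) minus the Shannon
#' entropy of the column's residue frequencies, computed over non-gap
#' residues (unknown 'X' residues are also excluded). Columns whose gap
#' fraction exceeds \code{gapCutoff} are flagged in the mask; their raw score
#' is still reported but they are excluded from smoothing. Smoothing is a
#' centred moving average of width \code{w} over the unmasked scores,
#' truncated at the profile edges.
#'
#' This is a transparent, alignment-only conservation score; it is not a
#' phylogenetic rate estimate and makes no use of a tree.
#'
#' @param alignment An alignment (see \code{\link{buildProfile}} for accepted
#'   forms).
#' @param w Odd moving-average window (default 5).
#' @param gapCutoff Gap-fraction cutoff for the mask (default 0.5).
#' @return A \code{\linkS4class{ConservationProfile}}.
#' @examples
#' cp <- conservationProfile(c(a = "LLLL", b = "LLLV"))
#' conservationScores(cp)
#' @export
conservationProfile <- function(alignment, w = 5L, gapCutoff = 0.5) {
  w <- as.integer(w)
  if (w < 1L || w %% 2L == 0L) {
    .rgkStop("smoothing window w must be a positive odd integer", "rgkscan_usage")
  }
  m <- .alnMatrix(alignment)
  if (nrow(m) == 0L || ncol(m) == 0L) {
    .rgkStop("empty alignment", "rgkscan_usage")
  }
  nc <- ncol(m)
  scores <- numeric(nc)
  mask <- logical(nc)
  for (j in seq_len(nc)) {
    col <- m[, j]
    gapFrac <- mean(col %in% GAP_CHARS)
    res <- col[col %in% AA20]
    if (length(res) == 0L) {
      scores[j] <- 0
      mask[j] <- TRUE
      next
    }
    scores[j] <- log2(20) - .entropy(res)
    mask[j] <- gapFrac > gapCutoff
  }
  half <- (w - 1L) %/% 2L
  smoothed <- rep(NA_real_, nc)
  unmasked <- which(!mask)
  for (j in unmasked) {
    win <- unmasked[unmasked >= j - half & unmasked <= j + half]
    smoothed[j] <- mean(scores[win])
  }
  methods::new("ConservationProfile", scores = scores, smoothed = smoothed,
               mask = mask, w = w, gapCutoff = gapCutoff)
}

# Shannon entropy (bits) of a residue sample.
.entropy <- function(res) {
  f <- table(res) / length(res)
  -sum(f * log2(f))
}

#' Map reference residue numbers to alignment columns
#'
#' For each non-gap residue of the reference row, gives the alignment column
#' it occupies. Residue numbers are 1-based counting only reference residues
#' (the numbering used when a family alignment is annotated "residue numbers
#' are for the reference sequence").
#'
#' @param alignment The alignment.
#' @param referenceId Row id of the reference sequence.
#' @return Named integer vector: names are residue numbers, values are
#'   column indices. Empty (with a warning) for an all-gap reference row.
#' @examples
#' mapColumns(c(ref = "A-CD", other = "AACD"), "ref")
#' @export
mapColumns <- function(alignment, referenceId) {
  m <- .alnMatrix(alignment)
  if (is.null(rownames(m)) || !referenceId %in% rownames(m)) {
    .rgkStop(sprintf("reference id '%s' is not a row of the alignment", referenceId),
             "rgkscan_usage")
  }
  row <- m[referenceId, ]
  cols <- which(!row %in% GAP_CHARS)
  if (length(cols) == 0L) {
    warning(sprintf("reference row '%s' is all gaps; empty column map", referenceId))
    return(setNames(integer(0), character(0)))
  }
  setNames(cols, as.character(seq_along(cols)))
}

#' Differential conservation between two subfamily alignments
#'
#' Compares per-column conservation of two alignments (e.g. the RGK family
#' versus classical Ras orthologs) through a shared reference sequence: at
#' each reference residue present (non-gap) in both alignments the difference
#' \code{score A - score B} is reported. No smoothing is applied. Reference
#' residues absent from either alignment are omitted and listed in the
#' \code{"omitted"} attribute.
#'
#' @param profileA,profileB \code{ConservationProfile}s of the two
#'   alignments (computed with \code{\link{conservationProfile}} if NULL).
#' @param alignmentA,alignmentB The two alignments; both must contain the
#'   reference row.
#' @param referenceId Shared reference row id.
#' @return data.frame with columns residue, column_a, column_b, score_a,
#'   score_b, difference; attribute \code{"omitted"} lists skipped residue
#'   numbers. Positive differences mean family A is more conserved.
#' @export
differentialConservation <- function(profileA = NULL, alignmentA,
                                     profileB = NULL, alignmentB,
                                     referenceId) {
  if (is.null(profileA)) profileA <- conservationProfile(alignmentA)
  if (is.null(profileB)) profileB <- conservationProfile(alignmentB)
  mapA <- mapColumns(alignmentA, referenceId)
  mapB <- mapColumns(alignmentB, referenceId)
  shared <- intersect(names(mapA), names(mapB))
  allRes <- union(names(mapA), names(mapB))
  omitted <- setdiff(allRes, shared)
  shared <- shared[order(as.integer(shared))]
  out <- data.frame(
    residue = as.integer(shared),
    column_a = unname(mapA[shared]),
    column_b = unname(mapB[shared]),
    score_a = conservationScores(profileA)[mapA[shared]],
    score_b = conservationScores(profileB)[mapB[shared]],
    stringsAsFactors = FALSE
  )
  out$difference <- out$score_a - out$score_b
  attr(out, "omitted") <- as.integer(omitted)
  out
}

#' Sequence-logo matrix of an alignment span
#'
#' Per-column information content R = log2 20 - H (bits; gaps and unknowns
#' excluded from the frequencies) and letter heights f_a * R, the quantities
#' sequence-logo renderers draw. By default the terminal 20 columns are used,
#' the span over which this family's C-terminal signature is displayed. An
#' all-gap column has R = 0 and no letters. The standard small-sample
#' correction e_n = 19 / (2 ln2 n) can be subtracted from R with
#' \code{smallSample = TRUE} (off by default).
#'
#' @param alignment The alignment.
#' @param span Integer vector of column indices (default: terminal 20).
#' @param smallSample Apply the small-sample correction.
#' @return A \code{\linkS4class{LogoMatrix}}.
#' @export
logoMatrix <- function(alignment, span = NULL, smallSample = FALSE) {
  m <- .alnMatrix(alignment)
  nc <- ncol(m)
  if (is.null(span)) span <- seq.int(max(1L, nc - 19L), nc)
  span <- as.integer(span)
  if (length(span) == 0L) .rgkStop("empty logo span", "rgkscan_usage")
  if (any(span < 1L | span > nc)) {
    .rgkStop("logo span outside alignment columns", "rgkscan_usage")
  }
  heights <- matrix(0, nrow = 20L, ncol = length(span),
                    dimnames = list(AA20, NULL))
  info <- numeric(length(span))
  for (k in seq_along(span)) {
    col <- m[, span[k]]
    res <- col[col %in% AA20]
    if (length(res) == 0L) next
    f <- tabulate(factor(res, levels = AA20), nbins = 20L) / length(res)
    H <- -sum(f[f > 0] * log2(f[f > 0]))
    R <- log2(20) - H
    if (smallSample) R <- R - 19 / (2 * log(2) * length(res))
    R <- max(0, R)
    info[k] <- R
    heights[, k] <- f * R
  }
  methods::new("LogoMatrix", heights = heights, info = info, span = span)
}

#' Percent identity between two aligned rows
#'
#' 100 times the fraction of identical residues over columns where both rows
#' are non-gap. Rows must come from the same alignment (equal gapped length).
#'
#' @param rowA,rowB Gapped sequences of equal length.
#' @return Percentage in [0, 100].
#' @examples
#' percentIdentity("AC-D", "AG-D")
#' @export
percentIdentity <- function(rowA, rowB) {
  a <- .chars(rowA)
  b <- .chars(rowB)
  if (length(a) != length(b)) {
    .rgkStop("rows must have equal (gapped) length", "rgkscan_usage")
  }
  both <- !(a %in% GAP_CHARS) & !(b %in% GAP_CHARS)
  if (!any(both)) {
    .rgkStop("no co-aligned columns: percent identity undefined",
             "rgkscan_undefined")
  }
  100 * sum(a[both] == b[both]) / sum(both)
}
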