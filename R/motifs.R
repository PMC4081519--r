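#' Compile a PROSITE-like pattern
#'
#' The grammar is the minimal subset needed for position-class protein
#' motifs: single residue letters, bracketed alternatives \code{[...]}, and
#' the wildcard \code{x} (any residue). No repetition counts or exclusion
#' classes.
#'
#' @param text Pattern text, e.g.
#'   \code{"[KR][SAF][KR][SH][C][HNED][DNEV][LM]x[VSA][L]"}.
#' @return A \code{\linkS4class{MotifPattern}}.
#' @examples
#' p <- compilePattern("GxxGxGKS")
#' motifLength(p)
#' @export
compilePattern <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    .rgkStop("pattern text must be a non-empty string", "rgkscan_usage")
  }
  chars <- .chars(text)
  classes <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      members <- character(0)
      while (j <= n && chars[j] != "]") {
        if (!toupper(chars[j]) %in% AA20) {
          .rgkStop(sprintf("illegal residue '%s' at offset %d of pattern '%s'",
                           chars[j], j, text), "rgkscan_pattern")
        }
        members <- c(members, toupper(chars[j]))
        j <- j + 1L
      }
      if (j > n) {
        .rgkStop(sprintf("unbalanced '[' at offset %d of pattern '%s'", i, text),
                 "rgkscan_pattern")
      }
      if (length(members) == 0L) {
        .rgkStop(sprintf("empty residue class at offset %d of pattern '%s'", i, text),
                 "rgkscan_pattern")
      }
      classes <- c(classes, list(unique(members)))
      i <- j + 1L
    } else if (ch %in% c("x", "X")) {
      classes <- c(classes, list(AA20))
      i <- i + 1L
    } else if (toupper(ch) %in% AA20) {
      classes <- c(classes, list(toupper(ch)))
      i <- i + 1L
    } else if (ch == "]") {
      .rgkStop(sprintf("unbalanced ']' at offset %d of pattern '%s'", i, text),
               "rgkscan_pattern")
    } else {
      .rgkStop(sprintf("illegal character '%s' at offset %d of pattern '%s'",
                       ch, i, text), "rgkscan_pattern")
    }
  }
  wide <- vapply(classes, function(k) length(k) == 20L, logical(1))
  methods::new("MotifPattern", source = text, classes = classes,
               fixed = which(!wide))
}

#' Render a compiled pattern back to text
#'
#' Compiling the rendered text yields an equivalent pattern (same classes).
#'
#' @param pattern A \code{MotifPattern}.
#' @return Pattern text.
#' @export
renderPattern <- function(pattern) {
  stopifnot(methods::is(pattern, "MotifPattern"))
  paste(vapply(pattern@classes, function(k) {
    if (length(k) == 20L) "x"
    else if (length(k) == 1L) k
    else paste0("[", paste(k, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' The RGK C-terminal signature pattern
#'
#' The eleven-residue C-terminal signature of RGK proteins,
#' \code{[KR][SAF][KR][SH][C][HNED][DNEV][LM]x[VSA][L]}: eleven position
#' classes whose only singleton-cysteine position is the invariant C-7
#' cysteine (seven residues from the protein end when the pattern is
#' anchored at the C-terminus).
#'
#' @return A \code{\linkS4class{MotifPattern}} of length 11.
#' @examples
#' rgkSignature()
#' @export
rgkSignature <- function() {
  compilePattern("[KR][SAF][KR][SH][C][HNED][DNEV][LM]x[VSA][L]")
}

# Mismatch counts of `pattern` against `chars` at every offset in `offsets`.
# A residue matches a non-wildcard class only if it is a member; 'X'
# (unknown) never matches a non-wildcard class.
.mismatchCounts <- function(chars, pattern, offsets) {
  mm <- integer(length(offsets))
  for (j in pattern@fixed) {
    mm <- mm + !(chars[offsets + j - 1L] %in% pattern@classes[[j]])
  }
  mm
}

.hitFrame <- function(motif = character(0), start = integer(0),
                      end = integer(0), n_mismatches = integer(0),
                      matched = character(0)) {
  data.frame(motif = motif, start = start, end = end,
             n_mismatches = n_mismatches, matched = matched,
             stringsAsFactors = FALSE)
}

#' Test a pattern at one offset
#'
#' @param seq Protein sequence (character scalar or AAString).
#' @param pattern A \code{MotifPattern}.
#' @param offset 1-based start position to test.
#' @param maxMismatches Fixed-position mismatches tolerated (default 0).
#' @param name Motif name recorded in the hit.
#' @return A one-row hit data.frame (columns motif, start, end,
#'   n_mismatches, matched) or a zero-row frame when the pattern does not
#'   match within tolerance.
#' @examples
#' matchAt("KSKHCHDLSVL", rgkSignature(), 1)
#' @export
matchAt <- function(seq, pattern, offset, maxMismatches = 0L,
                    name = renderPattern(pattern)) {
  chars <- .chars(seq)
  L <- motifLength(pattern)
  if (offset < 1L || offset > length(chars) - L + 1L) {
    .rgkStop(sprintf("offset %d out of range for a length-%d pattern on a length-%d sequence",
                     offset, L, length(chars)), "rgkscan_usage")
  }
  mm <- .mismatchCounts(chars, pattern, offset)
  if (mm > maxMismatches) return(.hitFrame())
  .hitFrame(name, as.integer(offset), as.integer(offset + L - 1L), mm,
            paste(chars[offset:(offset + L - 1L)], collapse = ""))
}

#' Scan a sequence for all pattern matches
#'
#' Tests every offset; hits are returned in ascending start order.
#'
#' @inheritParams matchAt
#' @return Hit data.frame (possibly zero rows).
#' @export
scanPattern <- function(seq, pattern, maxMismatches = 0L,
                        name = renderPattern(pattern)) {
  chars <- .chars(seq)
  L <- motifLength(pattern)
  n <- length(chars)
  if (n < L) return(.hitFrame())
  offsets <- seq_len(n - L + 1L)
  mm <- .mismatchCounts(chars, pattern, offsets)
  keep <- which(mm <= maxMismatches)
  if (length(keep) == 0L) return(.hitFrame())
  .hitFrame(name, keep, keep + L - 1L, mm[keep],
            vapply(keep, function(s) paste(chars[s:(s + L - 1L)], collapse = ""),
                   character(1)))
}

#' Scan the C-terminus of a record for a signature pattern
#'
#' In anchored mode (the default) only the final \code{motifLength(pattern)}
#' residues are tested, which is how the C-terminal RGK signature is defined;
#' "anywhere" mode scans all offsets.
#'
#' @inheritParams matchAt
#' @param anchored Test only the terminal window (default TRUE).
#' @return Hit data.frame; zero rows when there is no hit or the sequence is
#'   shorter than the pattern.
#' @examples
#' scanCTerminus("MAAAAAAAAARSKHCHDMAVL", rgkSignature())
#' @export
scanCTerminus <- function(seq, pattern = rgkSignature(), maxMismatches = 0L,
                          anchored = TRUE, name = "signature") {
  chars <- .chars(seq)
  L <- motifLength(pattern)
  if (length(chars) < L) return(.hitFrame())
  if (anchored) {
    matchAt(seq, pattern, length(chars) - L + 1L, maxMismatches, name = name)
  } else {
    scanPattern(seq, pattern, maxMismatches, name = name)
  }
}

#' The stock G-motif catalog
#'
#' Canonical G-box motifs of the RGK branch of the Ras superfamily:
#' G1 (P-loop) \code{GxxGxGKS}, G3 \code{DxWE} (the RGK variant of the usual
#' DxxG), G4 core \code{NK} (annotation-only: too short to anchor a domain
#' boundary), and G5 \code{ExSA}. In tolerant scans one fixed-position
#' mismatch is allowed for G1, G3 and G5, reflecting the weaker conservation
#' of these motifs outside vertebrates.
#'
#' @return Named list of \code{\linkS4class{GMotifDefinition}} objects.
#' @examples
#' gMotifCatalog()[["G1"]]
#' @export
gMotifCatalog <- function() {
  def <- function(name, text, tol, annot = FALSE) {
    methods::new("GMotifDefinition", name = name, pattern = compilePattern(text),
                 maxMismatches = as.integer(tol), annotationOnly = annot)
  }
  list(
    G1 = def("G1", "GxxGxGKS", 1L),
    G3 = def("G3", "DxWE", 1L),
    G4 = def("G4", "NK", 0L, annot = TRUE),
    G5 = def("G5", "ExSA", 1L)
  )
}

#' Find G-motifs in a protein sequence
#'
#' Scans for every motif in the catalog and returns all hits in ascending
#' start order. In tolerant mode each motif's own mismatch allowance is
#' applied (one fixed-position mismatch for G1/G3/G5); tolerant hits carry
#' \code{n_mismatches > 0}.
#'
#' @param seq Protein sequence.
#' @param catalog Named list of \code{GMotifDefinition}s
#'   (default \code{\link{gMotifCatalog}()}).
#' @param tolerant Allow each motif's mismatch tolerance (default FALSE:
#'   exact fixed positions only).
#' @return Hit data.frame with columns motif, start, end, n_mismatches,
#'   matched.
#' @examples
#' findGMotifs("MGDSGVGKSTTTETSAMM")
#' @export
findGMotifs <- function(seq, catalog = gMotifCatalog(), tolerant = FALSE) {
  if (length(catalog) == 0L) {
    .rgkStop("empty G-motif catalog", "rgkscan_usage")
  }
  hits <- lapply(catalog, function(def) {
    tol <- if (tolerant) def@maxMismatches else 0L
    scanPattern(seq, def@pattern, maxMismatches = tol, name = def@name)
  })
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(out$start, out$motif), , drop = FALSE]
}

#' Extract the G-domain using the -6 / +30 boundary rules
#'
#' The G-domain starts 6 residues before the G1 motif (clamped at the first
#' residue, with \code{truncated} flagged) and ends 30 residues from the G5
#' anchor. Two G5 anchor conventions are in circulation for this family and
#' both are implemented: \code{"g5-start+30"} counts the 30 residues from the
#' first G5 residue (the default), \code{"g5-end+30"} counts them from the
#' residue after the motif, so its domain is exactly one G5-length longer.
#' When several G1/G5 pairings exist, the pairing whose domain length is
#' closest to 175 residues wins; ties go to the leftmost G1, then leftmost
#' G5.
#'
#' @param seq Protein sequence.
#' @param recordId Identifier recorded in the annotation.
#' @param convention G5 anchor convention (see above).
#' @param catalog G-motif catalog (\code{G1} and \code{G5} entries are used).
#' @param tolerant Allow tolerant motif hits when anchoring.
#' @param targetLength Pairing-selection target (default 175, the midpoint of
#'   the 170--180 residue range typical of this family).
#' @return A \code{\linkS4class{GDomainAnnotation}}.
#' @examples
#' seq <- paste0(strrep("A", 70), "GDSGVGKS", strrep("L", 131), "ETSA",
#'               strrep("A", 40))
#' extractGDomain(seq, "toy")
#' @export
extractGDomain <- function(seq, recordId = "record",
                           convention = c("g5-start+30", "g5-end+30"),
                           catalog = gMotifCatalog(), tolerant = FALSE,
                           targetLength = 175L) {
  convention <- match.arg(convention)
  chars <- .chars(seq)
  n <- length(chars)
  g1 <- scanPattern(seq, catalog[["G1"]]@pattern,
                    maxMismatches = if (tolerant) catalog[["G1"]]@maxMismatches else 0L,
                    name = "G1")
  g5 <- scanPattern(seq, catalog[["G5"]]@pattern,
                    maxMismatches = if (tolerant) catalog[["G5"]]@maxMismatches else 0L,
                    name = "G5")
  missing <- c(if (nrow(g1) == 0L) "G1", if (nrow(g5) == 0L) "G5")
  if (length(missing) > 0L) {
    .rgkStop(sprintf("no G-domain in '%s': missing motif(s) %s",
                     recordId, paste(missing, collapse = ", ")),
             "rgkscan_no_domain")
  }
  pairs <- expand.grid(i = seq_len(nrow(g1)), j = seq_len(nrow(g5)))
  pairs <- pairs[g5$start[pairs$j] > g1$end[pairs$i], , drop = FALSE]
  if (nrow(pairs) == 0L) {
    .rgkStop(sprintf("no G-domain in '%s': no G5 downstream of a G1", recordId),
             "rgkscan_no_domain")
  }
  anchor <- if (convention == "g5-start+30") g5$start else g5$end + 1L
  starts <- pmax(1L, g1$start[pairs$i] - 6L)
  ends <- anchor[pairs$j] + 29L
  lens <- pmin(ends, n) - starts + 1L
  ord <- order(abs(lens - targetLength), g1$start[pairs$i], g5$start[pairs$j])
  k <- ord[1L]
  i <- pairs$i[k]; j <- pairs$j[k]
  truncated <- g1$start[i] - 6L < 1L || ends[k] > n
  methods::new("GDomainAnnotation",
               recordId = recordId,
               g1Start = g1$start[i], g1End = g1$end[i],
               g5Start = g5$start[j], g5End = g5$end[j],
               start = starts[k], end = min(ends[k], n),
               convention = convention,
               truncated = truncated)
}

#' Annotate C-terminal features of a record
#'
#' Offsets count from the C-terminus with the final residue at -1. Reported
#' features: the anchored eleven-residue signature; the invariant cysteine at
#' -7; the candidate 14-3-3 serine at -8 (positional check only); the class I
#' PDZ ligand X-[ST]-X-[VL] over the last four residues; and the K/R fraction
#' in the polybasic/calmodulin window -35..-15. Fields whose window does not
#' fit the sequence are NA.
#'
#' @param seq Protein sequence.
#' @param recordId Identifier for the output row.
#' @param signature Signature pattern (default \code{\link{rgkSignature}()}).
#' @param maxMismatches Tolerance for the anchored signature test.
#' @return One-row data.frame with columns record_id, signature_present,
#'   signature_mismatches, c7_cysteine, ser_minus8, pdz_class1,
#'   polybasic_fraction.
#' @examples
#' annotateCTerminus(paste0(strrep("A", 30), "KRKKRSKTKRKKRRSNKRRSRSSRSKSKHCHDLSVL"))
#' @export
annotateCTerminus <- function(seq, recordId = "record",
                              signature = rgkSignature(),
                              maxMismatches = 0L) {
  chars <- .chars(seq)
  n <- length(chars)
  at <- function(off) chars[n + off + 1L]  # off is negative, -1 = last residue
  L <- motifLength(signature)
  if (n >= L) {
    hit <- scanCTerminus(seq, signature, maxMismatches)
    sig_present <- nrow(hit) > 0L
    sig_mm <- if (sig_present) hit$n_mismatches else NA_integer_
  } else {
    sig_present <- NA
    sig_mm <- NA_integer_
  }
  c7 <- if (n >= 7L) identical(at(-7L), "C") else NA
  s8 <- if (n >= 8L) identical(at(-8L), "S") else NA
  pdz <- if (n >= 4L) (at(-3L) %in% c("S", "T")) && (at(-1L) %in% c("V", "L")) else NA
  poly <- if (n >= 35L) {
    win <- chars[(n - 34L):(n - 14L)]  # offsets -35..-15 inclusive
    mean(win %in% c("K", "R"))
  } else NA_real_
  data.frame(record_id = recordId,
             signature_present = sig_present,
             signature_mismatches = sig_mm,
             c7_cysteine = c7,
             ser_minus8 = s8,
             pdz_class1 = pdz,
             polybasic_fraction = poly,
             stringsAsFactors = FALSE)
}
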