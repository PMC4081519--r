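#' Reference key-residue map for RGK classification
#'
#' Key residues carried by the classifier and the alignment checker:
#' \itemize{
#'   \item \code{interaction}: the three G4--G5-region residues whose
#'     mutation disrupts the Gem--Cavbeta interaction, in mouse Gem
#'     numbering -- R196 (arginine only), V223 (valine, leucine or
#'     isoleucine, the hydrophobic substitutions that keep the interaction
#'     intact), H225 (histidine only).
#'   \item \code{annotation}: residues reported for orientation only, in
#'     human Gem numbering -- W141, C146 (alpha-2 helix), N191, K192 (G4),
#'     E219, S221 (G5).
#'   \item \code{partner}: the rat Cavbeta3 residues on the other side of
#'     the interface (D194, D270, D272); recorded for documentation, never
#'     evaluated against RGK sequences.
#' }
#'
#' @return Nested list with elements interaction, annotation, partner; each
#'   named entry maps "X<number>" to its allowed residue set.
#' @examples
#' referenceResidueMap()$interaction
#' @export
referenceResidueMap <- function() {
  list(
    interaction = list(R196 = "R", V223 = c("V", "L", "I"), H225 = "H"),
    annotation = list(W141 = "W", C146 = "C", N191 = "N", K192 = "K",
                      E219 = "E", S221 = "S"),
    partner = c("D194", "D270", "D272")
  )
}

.residueNumber <- function(label) as.integer(sub("^[A-Z]", "", label))

#' Check key interaction residues across an alignment
#'
#' For every row of the alignment, the residue in the column occupied by each
#' reference key residue is tested against its allowed set. A gap at that
#' column fails with reason "gap". The reference row itself is included (and
#' passes when the map matches it).
#'
#' @param alignment Alignment containing the reference row.
#' @param referenceId Row id of the reference (e.g. a Gem sequence whose
#'   numbering the map uses).
#' @param refmap Key-residue map (default
#'   \code{\link{referenceResidueMap}()}); the \code{interaction} entries are
#'   evaluated.
#' @return data.frame with columns record_id, residue, ref_number, observed,
#'   pass, reason.
#' @export
checkInteractionResidues <- function(alignment, referenceId,
                                     refmap = referenceResidueMap()) {
  m <- .alnMatrix(alignment)
  cmap <- mapColumns(alignment, referenceId)
  keyset <- refmap$interaction
  rows <- rownames(m)
  out <- list()
  for (label in names(keyset)) {
    num <- .residueNumber(label)
    if (!as.character(num) %in% names(cmap)) {
      .rgkStop(sprintf("reference residue %s beyond the reference row (%d residues)",
                       label, length(cmap)), "rgkscan_internal")
    }
    col <- cmap[[as.character(num)]]
    obs <- m[, col]
    isGap <- obs %in% GAP_CHARS
    pass <- obs %in% keyset[[label]]
    out[[label]] <- data.frame(
      record_id = rows, residue = label, ref_number = num, observed = obs,
      pass = pass,
      reason = ifelse(pass, "", ifelse(isGap, "gap", "disallowed")),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classifier configuration
#'
#' Bundles the patterns, conventions and thresholds the classifier uses.
#' The G-domain length window [170, 180] is advisory: it is reported but
#' never gates the verdict, because genuine family members with G-domain
#' insertions fall outside it.
#'
#' @param signature Signature pattern.
#' @param catalog G-motif catalog.
#' @param convention G5 anchor convention for domain extraction.
#' @param tolerant Tolerant G-motif anchoring.
#' @param signatureMismatches Mismatches tolerated in the anchored signature
#'   scan (default 0: the signature is the family gate).
#' @param lengthWindow Advisory G-domain length window.
#' @param refAlignment,referenceId Optional alignment with a reference Gem
#'   row for interaction-residue checks; when absent those fields are
#'   reported as not evaluated (NA).
#' @return A list of class \code{rgkscan_config}.
#' @export
classifyConfig <- function(signature = rgkSignature(),
                           catalog = gMotifCatalog(),
                           convention = "g5-start+30",
                           tolerant = FALSE,
                           signatureMismatches = 0L,
                           lengthWindow = c(170L, 180L),
                           refAlignment = NULL, referenceId = NULL) {
  structure(list(signature = signature, catalog = catalog,
                 convention = convention, tolerant = tolerant,
                 signatureMismatches = as.integer(signatureMismatches),
                 lengthWindow = as.integer(lengthWindow),
                 refAlignment = refAlignment, referenceId = referenceId),
            class = "rgkscan_config")
}

# Classify one sequence; returns a one-row data.frame.
.classifyOne <- function(seq, id, config, interactionPass = NA) {
  evidence <- character(0)
  sigHit <- if (nchar(seq) >= motifLength(config$signature)) {
    scanCTerminus(seq, config$signature, config$signatureMismatches)
  } else .hitFrame()
  sigPresent <- nrow(sigHit) > 0L
  evidence <- c(evidence,
                if (sigPresent) sprintf("anchored signature hit (%d mismatch(es))",
                                        sigHit$n_mismatches)
                else "no anchored signature hit")
  dom <- tryCatch(
    extractGDomain(seq, recordId = id, convention = config$convention,
                   catalog = config$catalog, tolerant = config$tolerant),
    rgkscan_no_domain = function(e) {
      evidence <<- c(evidence, conditionMessage(e))
      NULL
    })
  if (is.null(dom)) {
    verdict <- "no-G-domain"
  } else {
    evidence <- c(evidence,
                  sprintf("G-domain [%d, %d] (%d aa) via G1@%d/G5@%d",
                          dom@start, dom@end, gdomainLength(dom),
                          dom@g1Start, dom@g5Start))
    verdict <- if (sigPresent) "RGK-like" else "Ras-like-non-RGK"
  }
  lenOk <- if (is.null(dom)) NA else {
    gdomainLength(dom) >= config$lengthWindow[1] &&
      gdomainLength(dom) <= config$lengthWindow[2]
  }
  cterm <- annotateCTerminus(seq, recordId = id, signature = config$signature,
                             maxMismatches = config$signatureMismatches)
  data.frame(
    record_id = id,
    verdict = verdict,
    signature_present = sigPresent,
    g_domain_found = !is.null(dom),
    g_domain_start = if (is.null(dom)) NA_integer_ else dom@start,
    g_domain_end = if (is.null(dom)) NA_integer_ else dom@end,
    g_domain_length = if (is.null(dom)) NA_integer_ else gdomainLength(dom),
    g_domain_length_ok = lenOk,
    g_domain_truncated = if (is.null(dom)) NA else dom@truncated,
    c7_cysteine = cterm$c7_cysteine,
    ser_minus8 = cterm$ser_minus8,
    pdz_class1 = cterm$pdz_class1,
    polybasic_fraction = cterm$polybasic_fraction,
    interaction_pass = interactionPass,
    evidence = paste(evidence, collapse = "; "),
    stringsAsFactors = FALSE
  )
}

#' Classify one protein record
#'
#' Applies the RGK decision ladder to a single sequence: no usable G1/G5
#' anchor pair gives \code{"no-G-domain"}; a G-domain without the anchored
#' C-terminal signature gives \code{"Ras-like-non-RGK"}; a G-domain plus the
#' signature gives \code{"RGK-like"}. The ladder is an explicit rendering of
#' practice (pattern hit plus G-domain inspection); every rule firing is
#' recorded in the \code{evidence} column.
#'
#' @param seq Protein sequence.
#' @param id Record id.
#' @param config A \code{\link{classifyConfig}}.
#' @return One-row data.frame (see \code{\link{classifySet}} for columns).
#' @examples
#' toy <- paste0(strrep("A", 70), "GDSGVGKS", strrep("L", 131), "ETSA",
#'               strrep("G", 29), "KSKHCHDLSVL")
#' classifyRecord(toy, "toy")$verdict
#' @export
classifyRecord <- function(seq, id = "record", config = classifyConfig()) {
  .classifyOne(as.character(seq), id, config)
}

#' Classify a set of protein records
#'
#' Vectorised \code{\link{classifyRecord}}. When the configuration carries a
#' reference alignment, records that appear as alignment rows also get an
#' interaction-residue summary (\code{interaction_pass}: TRUE when all key
#' residues pass); records absent from the alignment report NA (not
#' evaluated).
#'
#' @param records \code{AAStringSet} or named character vector.
#' @param config A \code{\link{classifyConfig}}.
#' @return data.frame with one row per record: record_id, verdict,
#'   signature_present, g_domain_found, g_domain_start/end/length,
#'   g_domain_length_ok, g_domain_truncated, c7_cysteine, ser_minus8,
#'   pdz_class1, polybasic_fraction, interaction_pass, evidence.
#' @export
classifySet <- function(records, config = classifyConfig()) {
  seqs <- if (is.character(records)) records else as.character(records)
  ids <- names(seqs)
  if (length(seqs) > 0L && (is.null(ids) || any(!nzchar(ids)))) {
    .rgkStop("records must be named", "rgkscan_usage")
  }
  interaction <- rep(NA, length(seqs))
  if (!is.null(config$refAlignment)) {
    if (is.null(config$referenceId)) {
      .rgkStop("referenceId required with refAlignment", "rgkscan_usage")
    }
    tab <- checkInteractionResidues(config$refAlignment, config$referenceId)
    byRec <- tapply(tab$pass, tab$record_id, all)
    hitIdx <- match(ids, names(byRec))
    interaction <- as.logical(byRec[hitIdx])
  }
  rows <- lapply(seq_along(seqs), function(i) {
    .classifyOne(seqs[i], ids[i], config, interactionPass = interaction[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full discovery pipeline
#'
#' Reads a FASTA database, classifies every record, annotates C-termini,
#' writes the extracted G-domains, and optionally runs the iterative profile
#' search (given a seed alignment) and conservation profiling (given a family
#' alignment). All outputs are plain text and byte-stable: rerunning with the
#' same inputs and seed reproduces them exactly. A JSON manifest records the
#' parameters, seed and input digests needed to reproduce the run.
#'
#' @param dbPath FASTA file of protein records.
#' @param outDir Output directory (created if needed).
#' @param config A \code{\link{classifyConfig}}.
#' @param seed Integer seed (used by the profile-search null).
#' @param seedAlignmentPath Optional seed alignment for
#'   \code{\link{patternInitiatedSearch}}.
#' @param alignmentPath Optional alignment for
#'   \code{\link{conservationProfile}} and \code{\link{logoMatrix}}.
#' @param alignmentFormat Format of the optional alignment files.
#' @param zThreshold Profile-search inclusion threshold.
#' @return Invisibly, a named list of output file paths.
#' @export
runPipeline <- function(dbPath, outDir, config = classifyConfig(), seed = 1L,
                        seedAlignmentPath = NULL, alignmentPath = NULL,
                        alignmentFormat = "fasta", zThreshold = 5) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  failMarker <- file.path(outDir, "FAILED")
  if (file.exists(failMarker)) file.remove(failMarker)
  stage <- "read"
  paths <- list()
  tryCatch({
    records <- readProteinFasta(dbPath)

    stage <- "classify"
    report <- classifySet(records, config)
    paths$classification <- file.path(outDir, "classification.tsv")
    .writeTsv(report, paths$classification)

    stage <- "gdomain"
    withDom <- report$record_id[report$g_domain_found]
    if (length(withDom) > 0L) {
      doms <- vapply(withDom, function(id) {
        row <- report[report$record_id == id, ]
        substr(as.character(records[[id]]), row$g_domain_start, row$g_domain_end)
      }, character(1))
      paths$gdomains <- file.path(outDir, "gdomains.fasta")
      writeProteinFasta(Biostrings::AAStringSet(doms), paths$gdomains)
    }

    if (!is.null(seedAlignmentPath)) {
      stage <- "profile-search"
      seedAln <- readAlignmentBlock(seedAlignmentPath, alignmentFormat)
      hits <- patternInitiatedSearch(records, config$signature, seedAln,
                                     zThreshold = zThreshold, seed = seed)
      paths$profile_search <- file.path(outDir, "profile_search.tsv")
      .writeTsv(hits, paths$profile_search)
    }

    if (!is.null(alignmentPath)) {
      stage <- "conservation"
      aln <- readAlignmentBlock(alignmentPath, alignmentFormat)
      cp <- conservationProfile(aln)
      consTab <- data.frame(column = seq_along(conservationScores(cp)),
                            score = conservationScores(cp),
                            smoothed = smoothedScores(cp),
                            masked = maskedColumns(cp))
      paths$conservation <- file.path(outDir, "conservation.tsv")
      .writeTsv(consTab, paths$conservation)
      lm <- logoMatrix(aln)
      logoTab <- data.frame(column = lm@span, information = lm@info,
                            t(lm@heights))
      paths$logo <- file.path(outDir, "logo.tsv")
      .writeTsv(logoTab, paths$logo)
    }

    stage <- "manifest"
    manifest <- list(
      tool = "rgkscan",
      version = as.character(utils::packageVersion("rgkscan")),
      seed = as.integer(seed),
      z_threshold = zThreshold,
      signature = renderPattern(config$signature),
      convention = config$convention,
      tolerant = config$tolerant,
      signature_mismatches = config$signatureMismatches,
      length_window = config$lengthWindow,
      n_records = length(records),
      verdicts = as.list(table(report$verdict)),
      inputs = .inputDigests(c(db = dbPath, seed_alignment = seedAlignmentPath,
                               alignment = alignmentPath))
    )
    paths$manifest <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }, error = function(e) {
    writeLines(sprintf("stage: %s\n%s", stage, conditionMessage(e)), failMarker)
    .rgkStop(sprintf("pipeline failed at stage '%s': %s", stage,
                     conditionMessage(e)), "rgkscan_pipeline")
  })
  invisible(paths)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.inputDigests <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  lapply(paths, function(p) list(path = p, md5 = unname(tools::md5sum(p))))
}
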