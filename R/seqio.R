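#' Read a protein FASTA file
#'
#' Reads protein sequences and normalises them for downstream pattern
#' scanning: sequences are uppercased, a single trailing stop character
#' (\code{*}) is stripped, and the rare/ambiguous letters B, Z, U, O, J are
#' mapped to \code{X} with a warning. The record id is the first whitespace
#' token of the header; the remainder is kept as the description.
#'
#' @param path Path to a FASTA file.
#' @return An \code{AAStringSet} whose names are the record ids, with the
#'   header descriptions in \code{metadata(x)$description} (a character
#'   vector parallel to the records).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a first record", "MKTL", ">b", "mavr*"), fa)
#' readProteinFasta(fa)
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) {
    .rgkStop(sprintf("FASTA file not found: %s", path), "rgkscan_io")
  }
  set <- withCallingHandlers(
    tryCatch(
      Biostrings::readAAStringSet(path),
      error = function(e) .rgkStop(
        sprintf("malformed FASTA in %s: %s", path, conditionMessage(e)),
        "rgkscan_parse")
    ),
    warning = function(w) {
      # readAAStringSet silently drops invalid letters; treat that as malformed
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        .rgkStop(sprintf("malformed FASTA in %s: invalid sequence characters",
                         path), "rgkscan_parse")
      }
    }
  )
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) {
    .rgkStop(sprintf("record %d has an empty header",
                     which(!nzchar(ids))[1]), "rgkscan_parse")
  }
  if (anyDuplicated(ids)) {
    .rgkStop(sprintf("duplicate record id '%s'", ids[anyDuplicated(ids)]),
             "rgkscan_parse")
  }
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  if (any(!nzchar(seqs))) {
    .rgkStop(sprintf("record '%s' has an empty sequence",
                     ids[which(!nzchar(seqs))[1]]), "rgkscan_parse")
  }
  if (any(grepl("[-.]", seqs))) {
    .rgkStop(sprintf("record '%s' contains gap characters",
                     ids[grep("[-.]", seqs)[1]]), "rgkscan_parse")
  }
  odd <- grepl(sprintf("[%s]", paste(names(AA_REMAP), collapse = "")), seqs)
  if (any(odd)) {
    warning(sprintf(
      "mapping non-standard residue letters (%s) to X in %d record(s)",
      paste(names(AA_REMAP), collapse = ","), sum(odd)))
    seqs <- chartr(paste(names(AA_REMAP), collapse = ""),
                   strrep("X", length(AA_REMAP)), seqs)
  }
  bad <- grepl(sprintf("[^%sX]", paste(AA20, collapse = "")), seqs)
  if (any(bad)) {
    .rgkStop(sprintf("record '%s' contains characters outside the amino-acid alphabet",
                     ids[which(bad)[1]]), "rgkscan_parse")
  }
  out <- Biostrings::AAStringSet(setNames(seqs, ids))
  S4Vectors::metadata(out)$description <- desc
  out
}

#' Write protein sequences as FASTA
#'
#' Output is fixed at 60 residues per line so repeated runs are
#' byte-identical. Descriptions stored by \code{\link{readProteinFasta}} are
#' re-attached to the headers.
#'
#' @param x An \code{AAStringSet} or named character vector.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeProteinFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  desc <- S4Vectors::metadata(x)$description
  out <- x
  if (!is.null(desc) && any(nzchar(desc))) {
    names(out) <- ifelse(nzchar(desc), paste(names(x), desc), names(x))
  }
  Biostrings::writeXStringSet(out, path, width = 60L)
  invisible(path)
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA and (interleaved) Clustal format; Clustal blocks
#' are concatenated. Rows are uppercased and '.' gaps normalised to '-'.
#'
#' @param path Path to the alignment file.
#' @param format "fasta" or "clustal".
#' @return An \code{AAMultipleAlignment}.
#' @export
readAlignmentBlock <- function(path, format = c("fasta", "clustal")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) .rgkStop(
                       sprintf("unknown alignment format '%s'", format[1]),
                       "rgkscan_usage"))
  if (!file.exists(path)) {
    .rgkStop(sprintf("alignment file not found: %s", path), "rgkscan_io")
  }
  aln <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = format),
    error = function(e) .rgkStop(
      sprintf("cannot parse %s as %s alignment: %s",
              path, format, conditionMessage(e)),
      "rgkscan_alignment")
  )
  rows <- toupper(as.character(Biostrings::unmasked(aln)))
  rows <- chartr(".", "-", rows)
  if (length(unique(nchar(rows))) > 1L) {
    .rgkStop("alignment rows differ in length", "rgkscan_alignment")
  }
  Biostrings::AAMultipleAlignment(Biostrings::AAStringSet(rows))
}

# Character matrix (rows x columns) view of an alignment; accepts an
# AAMultipleAlignment, AAStringSet, named character vector or matrix.
.alnMatrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  if (methods::is(aln, "AAMultipleAlignment")) {
    aln <- Biostrings::unmasked(aln)
  }
  rows <- as.character(aln)
  names(rows) <- names(aln)  # as.character() drops names on character input
  rows <- chartr(".", "-", toupper(rows))
  if (length(rows) == 0L) {
    .rgkStop("empty alignment", "rgkscan_usage")
  }
  if (length(unique(nchar(rows))) > 1L) {
    .rgkStop("alignment rows differ in length", "rgkscan_alignment")
  }
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(m) <- names(rows)
  m
}

#' Find exact occurrences of a DNA site in an oligonucleotide
#'
#' Returns every (possibly overlapping) exact-match start position of a
#' recognition site, e.g. MluI (\code{ACGCGT}) or NotI (\code{GCGGCCGC}), in
#' a primer sequence. Positions are 1-based.
#'
#' @param oligo Oligonucleotide sequence (A/C/G/T string).
#' @param site Recognition site (non-empty A/C/G/T string).
#' @return Integer vector of start positions, ascending (possibly empty).
#' @examples
#' findDnaSites("GATCACGCGTACC", "ACGCGT")
#' @export
findDnaSites <- function(oligo, site) {
  oligo <- toupper(as.character(oligo))
  site <- toupper(as.character(site))
  if (!nzchar(site)) .rgkStop("empty recognition site", "rgkscan_usage")
  if (grepl("[^ACGT]", site) || grepl("[^ACGT]", oligo)) {
    .rgkStop("oligo and site must use the A/C/G/T alphabet", "rgkscan_usage")
  }
  if (nchar(site) > nchar(oligo)) return(integer(0))
  hits <- Biostrings::matchPattern(site, Biostrings::DNAString(oligo))
  sort(BiocGenerics::start(hits))
}

#' Read an oligonucleotide table
#'
#' Tab-separated file with columns \code{name}, \code{direction}
#' (forward/reverse) and \code{sequence}; '#' lines are comments. The
#' cloning-primer table shipped in \code{inst/extdata/rgk_primers.tsv}
#' follows this layout.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns name, direction, sequence.
#' @export
readOligoTable <- function(path) {
  if (!file.exists(path)) {
    .rgkStop(sprintf("oligo table not found: %s", path), "rgkscan_io")
  }
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "direction", "sequence")
  if (!all(need %in% names(tab))) {
    .rgkStop("oligo table must have columns name, direction, sequence",
             "rgkscan_parse")
  }
  tab$sequence <- toupper(tab$sequence)
  bad <- grepl("[^ACGT]", tab$sequence)
  if (any(bad)) {
    .rgkStop(sprintf("oligo '%s' contains non-ACGT characters",
                     tab$name[which(bad)[1]]), "rgkscan_parse")
  }
  tab
}

#' Read a pattern file
#'
#' One pattern per line; '#' starts a comment; an optional leading name token
#' (separated by whitespace) names the pattern.
#'
#' @param path Path to the pattern file.
#' @return Named character vector of pattern texts.
#' @export
readPatternFile <- function(path) {
  if (!file.exists(path)) {
    .rgkStop(sprintf("pattern file not found: %s", path), "rgkscan_io")
  }
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  named <- grepl("\\s", lines)
  out <- ifelse(named, sub("^\\S+\\s+", "", lines), lines)
  names(out) <- ifelse(named, sub("\\s.*$", "", lines),
                       sprintf("pattern%d", seq_along(lines)))
  out
}
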