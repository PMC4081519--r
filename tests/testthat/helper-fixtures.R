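# Shared fixtures and independent oracles for the test suite.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randomSeq <- function(len, alphabet = AA) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Random position-class pattern as a plain list of residue subsets plus its
# textual rendering; the class list feeds the oracle, the text feeds the
# package compiler, so the two routes stay independent.
randomPatternSpec <- function(len) {
  classes <- lapply(seq_len(len), function(i) {
    type <- sample(c("single", "class", "wild"), 1, prob = c(0.4, 0.4, 0.2))
    switch(type,
      single = sample(AA, 1),
      class = sort(sample(AA, sample(2:5, 1))),
      wild = AA
    )
  })
  text <- paste(vapply(classes, function(k) {
    if (length(k) == 20) "x"
    else if (length(k) == 1) k
    else paste0("[", paste(k, collapse = ""), "]")
  }, character(1)), collapse = "")
  list(classes = classes, text = text)
}

# Brute-force scan oracle: explicit per-offset, per-position membership test.
oracleScan <- function(seq, classes, maxMismatches = 0) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(classes)
  n <- length(chars)
  if (n < L) return(integer(0))
  hits <- integer(0)
  for (off in 1:(n - L + 1)) {
    mm <- 0
    for (j in 1:L) {
      if (length(classes[[j]]) < 20 && !(chars[off + j - 1] %in% classes[[j]])) {
        mm <- mm + 1
      }
    }
    if (mm <= maxMismatches) hits <- c(hits, off)
  }
  hits
}

# Naive all-offsets substring oracle for DNA site search.
oracleSubstring <- function(oligo, site) {
  n <- nchar(oligo); m <- nchar(site)
  if (m > n) return(integer(0))
  which(vapply(1:(n - m + 1), function(i) {
    substr(oligo, i, i + m - 1) == site
  }, logical(1)))
}

writeTempFasta <- function(seqs, lineWidth = 60) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = lineWidth)
    writeLines(substring(s, starts, pmin(starts + lineWidth - 1, nchar(s))), con)
  }
  path
}

writeTempClustal <- function(rows, blockWidth = 60) {
  path <- tempfile(fileext = ".aln")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", ""), con)
  width <- nchar(rows[[1]])
  namePad <- formatC(names(rows), width = max(nchar(names(rows))) + 3,
                     flag = "-")
  for (start in seq(1, width, by = blockWidth)) {
    stop_ <- min(start + blockWidth - 1, width)
    for (i in seq_along(rows)) {
      writeLines(paste0(namePad[i], substr(rows[[i]], start, stop_)), con)
    }
    writeLines("", con)
  }
  path
}

# A noise-free canonical RGK-like sequence built by hand (not through the
# generator): 70-residue N-terminus, G1 at 77, G5 at 216, conforming tail.
handBuiltRgk <- function() {
  paste0(strrep("A", 70), "GDSGVGKS", strrep("L", 131), "ETSA",
         strrep("G", 26), strrep("A", 14), "KRKKRSKTKRKKRRS",
         "KSKHCHDLSVL")
}
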