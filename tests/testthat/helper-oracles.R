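# Independent oracles and small fixture builders used across the suite.

AA20_ <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

blosum62_ <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[c(AA20_, "X"), c(AA20_, "X")]
  m["X", ] <- 0
  m[, "X"] <- 0
  m
})

# Top-down memoised affine-gap global alignment, written independently of the
# package's bottom-up matrices. State: score of aligning a[1..i] with b[1..j]
# with the last alignment column of type M (substitution), X (gap in b) or
# Y (gap in a). Gap convention: first gap residue costs `open`, later ones
# `extend`.
oracle_nw <- function(a, b, submat = blosum62_, open = -10, extend = -0.5) {
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  n <- length(ra)
  m <- length(rb)
  if (n == 0 && m == 0) stop("empty")
  if (n == 0) return(open + (m - 1) * extend)
  if (m == 0) return(open + (n - 1) * extend)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (state == "M") {
      if (i == 0 && j == 0) 0
      else if (i == 0 || j == 0) -Inf
      else max(rec(i - 1, j - 1, "M"), rec(i - 1, j - 1, "X"),
               rec(i - 1, j - 1, "Y")) + submat[ra[i], rb[j]]
    } else if (state == "X") {
      if (i == 0) -Inf
      else max(rec(i - 1, j, "M") + open, rec(i - 1, j, "X") + extend,
               rec(i - 1, j, "Y") + open)
    } else {
      if (j == 0) -Inf
      else max(rec(i, j - 1, "M") + open, rec(i, j - 1, "Y") + extend,
               rec(i, j - 1, "X") + open)
    }
    memo[[key]] <- val
    val
  }
  max(rec(n, m, "M"), rec(n, m, "X"), rec(n, m, "Y"))
}

# Rank-sum (Mann-Whitney) AUC: probability a random positive outscores a
# random negative, ties counted half.
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  nP <- sum(labels)
  nN <- sum(!labels)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - nP * (nP + 1) / 2) / (nP * nN)
}

random_peptide <- function(n) paste(sample(AA20_, n, replace = TRUE),
                                    collapse = "")

# Write a small domain annotation table and return its path.
write_domain_fixture <- function(rows, path = tempfile(fileext = ".tsv"),
                                 header = TRUE) {
  lines <- if (header) {
    "# domain_id\taccession\tshort_name\tdescription\tlength\tconsensus\tgo_terms"
  } else {
    character(0)
  }
  writeLines(c(lines, rows), path)
  path
}

# Three-entry table used by several parser tests.
domain_fixture_rows <- c(
  "d1\tACC1\tRRM\tRNA-binding ribosomal protein S4 domain\t69\t\tGO:0003723 RNA binding",
  "d2\tACC2\tCSD\tshock protein, cold-inducible\t75\t\t",
  "d3\tACC3\tPK\tprotein kinase domain\t60\t\tGO:0016301 kinase activity")
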