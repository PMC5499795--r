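# Internal helpers shared across modules.

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Run `expr` with a temporarily seeded RNG, restoring the caller's RNG state
# afterwards so library code never perturbs user-level randomness.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (the convention used for reported metrics;
# base round() rounds half to even).
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.stop_input <- function(...) stop(..., call. = FALSE)

.check_file <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    .stop_input("input file not found: ", path)
  }
  invisible(path)
}

.split_residues <- function(seq) strsplit(as.character(seq), "", fixed = TRUE)[[1]]

# Alphabet check: the 20 standard residues, X tolerated as a neutral unknown.
.check_alphabet <- function(seq, what = "sequence") {
  res <- .split_residues(toupper(seq))
  bad <- setdiff(unique(res), c(AA20, "X"))
  if (length(bad) > 0L) {
    .stop_input(what, " contains illegal residue characters: ",
                paste(bad, collapse = ", "))
  }
  res
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "DomainSifter")
  if (!nzchar(path)) .stop_input("packaged data file missing: ", file)
  path
}

.load_scale <- function(file, key) {
  if (is.null(.ds_cache[[key]])) {
    .ds_cache[[key]] <- read.table(.extdata(file), header = FALSE, sep = "\t",
                                   comment.char = "#", stringsAsFactors = FALSE)
  }
  .ds_cache[[key]]
}

.residue_masses <- function() {
  if (is.null(.ds_cache$masses)) {
    tab <- .load_scale("residue_masses.tsv", "masses_raw")
    m <- setNames(tab[[2]], tab[[1]])
    m["X"] <- mean(m[AA20])  # unknown residue: mean residue mass
    .ds_cache$masses <- m
  }
  .ds_cache$masses
}

.pka_table <- function() {
  if (is.null(.ds_cache$pka)) {
    tab <- .load_scale("pka_scale.tsv", "pka_raw")
    .ds_cache$pka <- data.frame(group = tab[[1]], pka = tab[[2]], sign = tab[[3]],
                                stringsAsFactors = FALSE)
  }
  .ds_cache$pka
}

.ss_propensity <- function() {
  if (is.null(.ds_cache$ssprop)) {
    tab <- .load_scale("ss_propensity.tsv", "ss_raw")
    .ds_cache$ssprop <- data.frame(residue = tab[[1]], helix = tab[[2]],
                                   strand = tab[[3]], stringsAsFactors = FALSE)
  }
  .ds_cache$ssprop
}

# BLOSUM62 with X made neutral (score 0 against everything, including itself).
.blosum62 <- function() {
  if (is.null(.ds_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    keep <- c(AA20, "X")
    m <- m[keep, keep]
    m["X", ] <- 0
    m[, "X"] <- 0
    .ds_cache$blosum62 <- m
  }
  .ds_cache$blosum62
}

## ---- keyword matching (shared by domain selection and result classification)

.match_term_in_field <- function(field, term, regex = FALSE) {
  if (is.na(field) || !nzchar(field)) return(FALSE)
  if (regex) {
    return(grepl(term, field, perl = TRUE, ignore.case = TRUE))
  }
  words <- strsplit(trimws(term), "\\s+")[[1]]
  lf <- tolower(field)
  all(vapply(words, function(w) grepl(tolower(w), lf, fixed = TRUE), logical(1)))
}

.validate_regex <- function(term) {
  ok <- tryCatch({
    suppressWarnings(grepl(term, "", perl = TRUE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) .stop_input("invalid regular expression in keyword term: '", term, "'")
  invisible(TRUE)
}

# Searchable fields of one domain entry. A multi-word term must have all its
# words inside a single field (short name, description, or one GO annotation),
# never spread across fields. Plain terms see GO term *names* (the text after
# a leading GO:nnnnnnn token); regex terms see the full GO strings.
.entry_fields <- function(short_name, description, go_terms, regex = FALSE) {
  gos <- if (is.na(go_terms) || !nzchar(go_terms)) {
    character(0)
  } else {
    trimws(strsplit(go_terms, ";", fixed = TRUE)[[1]])
  }
  if (!regex && length(gos) > 0L) {
    gos <- trimws(sub("^GO:[0-9]+\\s*", "", gos))
    gos <- gos[nzchar(gos)]
  }
  c(short_name, description, gos)
}

.entry_matches_term <- function(short_name, description, go_terms, term,
                                regex = FALSE) {
  fields <- .entry_fields(short_name, description, go_terms, regex = regex)
  any(vapply(fields, .match_term_in_field, logical(1),
             term = term, regex = regex))
}
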