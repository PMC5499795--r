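# Reference domain set construction: domain annotation tables and
# keyword-driven selection.

#' Construct a DomainSet from a data.frame
#'
#' @param entries data.frame with at least \code{domain_id}, \code{accession},
#'   \code{short_name}, \code{description} and \code{length}; optional
#'   \code{consensus} and \code{go_terms} columns are filled with NA / ""
#'   when absent.
#' @param sourceDb label of the originating resource dialect.
#' @return a \code{\link{DomainSet-class}} object.
#' @examples
#' ds <- DomainSet(data.frame(
#'   domain_id = "d1", accession = "ACC1", short_name = "CSD",
#'   description = "cold shock domain", length = 5L, consensus = "GFGFI"))
#' domainIds(ds)
#' @export
DomainSet <- function(entries, sourceDb = "CDD-style") {
  stopifnot(is.data.frame(entries))
  if (!"consensus" %in% names(entries)) {
    entries$consensus <- rep(NA_character_, nrow(entries))
  }
  if (!"go_terms" %in% names(entries)) {
    entries$go_terms <- rep("", nrow(entries))
  }
  entries$go_terms[is.na(entries$go_terms)] <- ""
  entries$consensus[!is.na(entries$consensus) &
                      !nzchar(entries$consensus)] <- NA_character_
  entries$length <- as.integer(entries$length)
  entries <- entries[, .DOMAIN_COLS, drop = FALSE]
  rownames(entries) <- NULL
  new("DomainSet", entries = entries, sourceDb = sourceDb)
}

#' Load a domain annotation table
#'
#' Reads a tab-separated domain annotation table with columns
#' \code{domain_id accession short_name description length [consensus]
#' [go_terms]} (GO annotations semicolon-joined). Leading lines starting with
#' \code{#} are treated as header/comment lines and skipped. Row order is
#' preserved.
#'
#' @param path path to the TSV file.
#' @param sourceDb label recorded for the resulting set (e.g. "CDD-style" or
#'   "InterPro-style").
#' @return a \code{\link{DomainSet-class}}.
#' @seealso \code{\link{selectDomains}} for keyword selection.
#' @export
readDomainTable <- function(path, sourceDb = "CDD-style") {
  .check_file(path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(DomainSet(data.frame(domain_id = character(0),
                                accession = character(0),
                                short_name = character(0),
                                description = character(0),
                                length = integer(0)), sourceDb))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 5L) {
      .stop_input("malformed domain record at line ", lineno[i],
                  ": expected >= 5 tab-separated columns, found ", length(f))
    }
    len <- suppressWarnings(as.integer(f[5]))
    if (is.na(len) || len < 1L) {
      .stop_input("malformed domain record at line ", lineno[i],
                  ": length '", f[5], "' is not a positive integer")
    }
    cons <- if (length(f) >= 6L && nzchar(f[6])) toupper(f[6]) else NA_character_
    if (!is.na(cons) && nchar(cons) != len) {
      .stop_input("malformed domain record at line ", lineno[i],
                  ": consensus has ", nchar(cons),
                  " residues but length column says ", len)
    }
    go <- if (length(f) >= 7L) f[7] else ""
    data.frame(domain_id = f[1], accession = f[2], short_name = f[3],
               description = f[4], length = len, consensus = cons,
               go_terms = go, stringsAsFactors = FALSE)
  })
  DomainSet(do.call(rbind, rows), sourceDb)
}

#' Construct a KeywordSpec
#'
#' @param terms character vector of search terms; duplicates collapse,
#'   empty strings are dropped.
#' @param regex logical, recycled along \code{terms}: \code{TRUE} marks terms
#'   interpreted as Perl-compatible regular expressions (validated here).
#' @return a \code{\link{KeywordSpec-class}}.
#' @examples
#' KeywordSpec(c("RNA-bind", "cold shock"))
#' @export
KeywordSpec <- function(terms, regex = FALSE) {
  terms <- as.character(terms)
  regex <- rep_len(as.logical(regex), length(terms))
  keep <- nzchar(trimws(terms)) & !duplicated(terms)
  terms <- terms[keep]
  regex <- regex[keep]
  for (t in terms[regex]) .validate_regex(t)
  new("KeywordSpec", terms = terms, isRegex = regex)
}

#' Read a keyword file
#'
#' One term per line; blank lines and \code{#} comments are skipped. When
#' \code{regexMode} is enabled, lines starting with \code{re:} are stripped of
#' the prefix and interpreted as regular expressions; without it the prefix is
#' left verbatim and all terms are plain.
#'
#' @param path path to the keyword file.
#' @param regexMode enable interpretation of \code{re:}-prefixed patterns.
#' @return a \code{\link{KeywordSpec-class}}.
#' @export
readKeywords <- function(path, regexMode = FALSE) {
  .check_file(path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  is_re <- regexMode & startsWith(lines, "re:")
  lines[is_re] <- sub("^re:", "", lines[is_re])
  KeywordSpec(lines, regex = is_re)
}

#' Select reference domains by keyword
#'
#' An entry is selected when at least one term matches one of its searchable
#' annotation fields (short name, description, or one GO annotation). A
#' multi-word plain term matches only when all of its words occur within the
#' same field; matching is case-insensitive substring, so the term
#' \code{"RNA-bind"} selects entries annotated "RNA-binding". Regex terms are
#' Perl-compatible patterns applied per field (and see the full GO strings,
#' so GO identifiers can be selected verbatim that way).
#'
#' @param x a \code{\link{DomainSet-class}}.
#' @param keywords a \code{\link{KeywordSpec-class}} or character vector of
#'   plain terms.
#' @return the selected \code{DomainSet} (order preserved, deduplicated by
#'   \code{domain_id}).
#' @examples
#' ds <- DomainSet(data.frame(
#'   domain_id = c("d1", "d2"), accession = c("A1", "A2"),
#'   short_name = c("RRM", "PK"),
#'   description = c("RNA-binding ribosomal protein S4 domain",
#'                   "protein kinase domain"),
#'   length = c(70L, 60L)))
#' domainIds(selectDomains(ds, "RNA-bind"))
#' @export
selectDomains <- function(x, keywords) {
  stopifnot(is(x, "DomainSet"))
  if (!is(keywords, "KeywordSpec")) keywords <- KeywordSpec(keywords)
  e <- entryData(x)
  if (nrow(e) == 0L) return(x)
  terms <- keywordTerms(keywords)
  regex <- isRegexTerm(keywords)
  hit <- vapply(seq_len(nrow(e)), function(i) {
    any(vapply(seq_along(terms), function(j) {
      .entry_matches_term(e$short_name[i], e$description[i], e$go_terms[i],
                          terms[j], regex = regex[j])
    }, logical(1)))
  }, logical(1))
  sel <- e[hit, , drop = FALSE]
  sel <- sel[!duplicated(sel$domain_id), , drop = FALSE]
  DomainSet(sel, sourceDb = sourceDb(x))
}

#' Terms matching each domain entry
#'
#' Helper used by result classification: for every entry of \code{x}, the
#' subset of keyword terms that match it under the same rules as
#' \code{\link{selectDomains}}.
#'
#' @inheritParams selectDomains
#' @return named list (by \code{domain_id}) of character vectors of matching
#'   terms (possibly empty).
#' @export
matchingTerms <- function(x, keywords) {
  stopifnot(is(x, "DomainSet"))
  if (!is(keywords, "KeywordSpec")) keywords <- KeywordSpec(keywords)
  e <- entryData(x)
  terms <- keywordTerms(keywords)
  regex <- isRegexTerm(keywords)
  out <- lapply(seq_len(nrow(e)), function(i) {
    terms[vapply(seq_along(terms), function(j) {
      .entry_matches_term(e$short_name[i], e$description[i], e$go_terms[i],
                          terms[j], regex = regex[j])
    }, logical(1))]
  })
  names(out) <- e$domain_id
  out
}

#' Write a domain table
#'
#' Inverse of \code{\link{readDomainTable}}; writes the 7-column TSV with a
#' \code{#}-prefixed header line.
#'
#' @param x a \code{\link{DomainSet-class}}.
#' @param path output path.
#' @param provenance optional extra \code{#} header lines.
#' @return \code{path}, invisibly.
#' @export
writeDomainTable <- function(x, path, provenance = NULL) {
  stopifnot(is(x, "DomainSet"))
  e <- entryData(x)
  e$consensus[is.na(e$consensus)] <- ""
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  writeLines(paste0("# ", paste(.DOMAIN_COLS, collapse = "\t")), con)
  write.table(e, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
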