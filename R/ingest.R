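# Ingestion of domain-search outputs (BLAST-tabular and InterProScan-style
# dialects) into the unified hit representation, and per-hit statistics.

.new_hit_row <- function(query_id, method, domain_id, q_start, q_end,
                         s_start, s_end, aligned_length,
                         identical = NA_integer_, positive = NA_integer_,
                         gaps = NA_integer_, evalue = NA_real_,
                         bitscore = NA_real_, span_based = FALSE) {
  data.frame(query_id = query_id, method = method, domain_id = domain_id,
             q_start = as.integer(q_start), q_end = as.integer(q_end),
             s_start = as.integer(s_start), s_end = as.integer(s_end),
             aligned_length = as.integer(aligned_length),
             identical = as.integer(identical), positive = as.integer(positive),
             gaps = as.integer(gaps), evalue = as.numeric(evalue),
             bitscore = as.numeric(bitscore),
             coverage_pct = NA_real_, similarity_pct = NA_real_,
             identity_pct = NA_real_, gap_pct = NA_real_,
             span_based = span_based, partial_stats = FALSE,
             stringsAsFactors = FALSE)
}

.as_hittable <- function(rows) {
  if (length(rows) == 0L) return(new("HitTable", hits = .empty_hits()))
  new("HitTable", hits = do.call(rbind, rows))
}

.num_field <- function(x, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) {
    .stop_input("malformed hit record at line ", lineno, ": ", what,
                " '", x, "' is not numeric")
  }
  v
}

.int_field <- function(x, lineno, what) {
  v <- .num_field(x, lineno, what)
  as.integer(round(v))
}

.read_tsv_lines <- function(path) {
  .check_file(path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Parse a BLAST-tabular domain-search output
#'
#' Reads the extended tabular format with columns \code{qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore positives
#' gaps}. The identical-residue count is recovered as
#' \code{round(pident * length / 100)}; the positive (similar) count is taken
#' from the \code{positives} column. When the \code{positives}/\code{gaps}
#' columns are absent (plain 12-column outfmt 6) those counts are left NA and
#' downstream similarity is marked unavailable rather than guessed.
#'
#' @param path path to the TSV file.
#' @return a \code{\link{HitTable-class}} with \code{method =
#'   "rpsblast-like"}; statistics columns are NA until
#'   \code{\link{computeHitStats}}.
#' @export
readRpsblastHits <- function(path) {
  tl <- .read_tsv_lines(path)
  if (length(tl$lines) == 0L) return(.as_hittable(list()))
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    ln <- tl$lineno[i]
    if (length(f) != 12L && length(f) != 14L) {
      .stop_input("malformed hit record at line ", ln,
                  ": expected 12 or 14 columns, found ", length(f))
    }
    pident <- .num_field(f[3], ln, "pident")
    alen <- .int_field(f[4], ln, "length")
    ident <- as.integer(round(pident * alen / 100))
    pos <- if (length(f) >= 13L) .int_field(f[13], ln, "positives") else NA_integer_
    gaps <- if (length(f) >= 14L) .int_field(f[14], ln, "gaps") else NA_integer_
    .new_hit_row(query_id = f[1], method = "rpsblast-like", domain_id = f[2],
                 q_start = .int_field(f[7], ln, "qstart"),
                 q_end = .int_field(f[8], ln, "qend"),
                 s_start = .int_field(f[9], ln, "sstart"),
                 s_end = .int_field(f[10], ln, "send"),
                 aligned_length = alen, identical = ident, positive = pos,
                 gaps = gaps, evalue = .num_field(f[11], ln, "evalue"),
                 bitscore = .num_field(f[12], ln, "bitscore"))
  })
  .as_hittable(rows)
}

#' Parse an InterProScan-style TSV
#'
#' Reads the standard 11+ column layout (protein accession, MD5, sequence
#' length, analysis, signature accession, signature description, start, stop,
#' score, status, date, ...). This dialect reports only the matched query
#' span: subject coordinates are set to \code{1..span} and the hit is flagged
#' \code{span_based}, so that \code{\link{computeHitStats}} derives coverage
#' from the matched span over the reference length (capped at 100). Identical
#' and positive residue counts are not reported, so residue similarity and
#' identity stay unavailable (\code{partial_stats}); the score column is used
#' as the E-value when parseable.
#'
#' @param path path to the TSV file.
#' @return a \code{\link{HitTable-class}} with \code{method =
#'   "interproscan-like"}.
#' @export
readInterproscanHits <- function(path) {
  tl <- .read_tsv_lines(path)
  if (length(tl$lines) == 0L) return(.as_hittable(list()))
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    ln <- tl$lineno[i]
    if (length(f) < 11L) {
      .stop_input("malformed hit record at line ", ln,
                  ": expected >= 11 columns, found ", length(f))
    }
    qs <- .int_field(f[7], ln, "start")
    qe <- .int_field(f[8], ln, "stop")
    span <- qe - qs + 1L
    ev <- suppressWarnings(as.numeric(f[9]))  # "-" for status-only analyses
    .new_hit_row(query_id = f[1], method = "interproscan-like",
                 domain_id = f[5], q_start = qs, q_end = qe,
                 s_start = 1L, s_end = span, aligned_length = span,
                 evalue = ev, span_based = TRUE)
  })
  .as_hittable(rows)
}

#' Compute per-hit statistics against the reference domain set
#'
#' Fills the four derived statistics of every hit from its counts and the
#' length of its reference domain: \describe{
#'   \item{coverage_pct}{\code{100 * (s_end - s_start + 1) / ref_length} —
#'     the percentage of the reference domain length spanned by the
#'     prediction (capped at 100 for span-based dialects that report query
#'     spans longer than the reference).}
#'   \item{similarity_pct}{\code{100 * positive / ref_length}.}
#'   \item{identity_pct}{\code{100 * identical / ref_length}.}
#'   \item{gap_pct}{\code{100 * gaps / aligned_length} (a property of the
#'     alignment, not the reference).}
#' }
#' The denominator for coverage, similarity and identity is the reference
#' domain length. Hits whose \code{domain_id} is absent from \code{domains}
#' keep NA statistics and trigger one warning; hits lacking residue counts
#' are flagged \code{partial_stats}.
#'
#' @param hits a \code{\link{HitTable-class}}.
#' @param domains a \code{\link{DomainSet-class}} supplying reference lengths.
#' @return the \code{HitTable} with statistics populated.
#' @export
computeHitStats <- function(hits, domains) {
  stopifnot(is(hits, "HitTable"), is(domains, "DomainSet"))
  h <- hitData(hits)
  if (nrow(h) == 0L) return(hits)
  e <- entryData(domains)
  idx <- match(h$domain_id, e$domain_id)
  if (anyNA(idx)) {
    warning("reference length unknown for ",
            length(unique(h$domain_id[is.na(idx)])),
            " domain id(s); their statistics stay unavailable",
            call. = FALSE)
  }
  L <- e$length[idx]
  span <- h$s_end - h$s_start + 1L
  bad <- !is.na(L) & !h$span_based & h$s_end > L
  if (any(bad)) {
    .stop_input("hit/reference mismatch: s_end exceeds reference length for ",
                sum(bad), " hit(s), first on domain '",
                h$domain_id[which(bad)[1]], "'")
  }
  h$coverage_pct <- ifelse(is.na(L), NA_real_,
                           pmin(100, 100 * span / L))
  h$similarity_pct <- ifelse(is.na(L) | is.na(h$positive), NA_real_,
                             100 * h$positive / L)
  h$identity_pct <- ifelse(is.na(L) | is.na(h$identical), NA_real_,
                           100 * h$identical / L)
  h$gap_pct <- ifelse(is.na(h$gaps), NA_real_,
                      100 * h$gaps / h$aligned_length)
  h$partial_stats <- is.na(h$similarity_pct) | is.na(h$identity_pct)
  new("HitTable", hits = h)
}

#' Write / read the unified hit table
#'
#' The unified TSV carries all hit columns so that parsed hits round-trip
#' exactly; coordinates are 1-based inclusive (stated in the header).
#' Percentage statistics are written at full precision here; rounded 2-decimal
#' presentation is applied only in report tables.
#'
#' @param hits a \code{\link{HitTable-class}}.
#' @param path file path.
#' @param provenance optional extra \code{#} header lines.
#' @return \code{writeHitTable}: \code{path} invisibly; \code{readHitTable}:
#'   a \code{HitTable}.
#' @export
writeHitTable <- function(hits, path, provenance = NULL) {
  stopifnot(is(hits, "HitTable"))
  h <- hitData(hits)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  writeLines("# coordinates: 1-based inclusive", con)
  writeLines(paste(.HIT_COLS, collapse = "\t"), con)
  write.table(format(h, digits = 17, scientific = NA, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeHitTable
#' @export
readHitTable <- function(path) {
  .check_file(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) <= 1L) return(.as_hittable(list()))
  h <- read.table(text = lines, sep = "\t", header = TRUE,
                  stringsAsFactors = FALSE, na.strings = "NA")
  for (col in c("q_start", "q_end", "s_start", "s_end", "aligned_length",
                "identical", "positive", "gaps")) {
    h[[col]] <- as.integer(h[[col]])
  }
  for (col in c("evalue", "bitscore", "coverage_pct", "similarity_pct",
                "identity_pct", "gap_pct")) {
    h[[col]] <- as.numeric(h[[col]])
  }
  for (col in c("query_id", "method", "domain_id")) {
    h[[col]] <- as.character(h[[col]])
  }
  new("HitTable", hits = h[, .HIT_COLS])
}
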