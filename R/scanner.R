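# Lightweight internal profile scanner: ungapped position-specific scoring
# so the pipeline runs end-to-end on fixtures without external search
# engines. Not a substitute for a gapped profile search at scale.

#' Build a position-specific scoring profile
#'
#' Column residue frequencies with an additive pseudocount, as natural-log
#' odds against a background distribution:
#' \code{log(((count + pseudocount) / (n + 20 * pseudocount)) / background)}.
#'
#' @param alignment character vector of equal-length residue strings (an
#'   ungapped alignment; a single sequence is allowed).
#' @param domainId identifier recorded on the profile.
#' @param pseudocount additive pseudocount per residue (> 0, default 1).
#' @param background residue background frequencies over the 20 standard
#'   residues (default uniform 1/20).
#' @return a \code{\link{DomainProfile-class}}.
#' @export
buildProfile <- function(alignment, domainId = "profile", pseudocount = 1,
                         background = rep(1 / 20, 20)) {
  stopifnot(length(alignment) >= 1L, pseudocount > 0)
  if (length(background) != 20L) .stop_input("background must have 20 entries")
  background <- background / sum(background)
  names(background) <- AA20
  rows <- lapply(alignment, .check_alphabet, what = "alignment row")
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    .stop_input("ragged alignment: rows of lengths ",
                paste(sort(unique(lens)), collapse = ", "))
  }
  L <- lens[1]
  n <- length(rows)
  mat <- matrix(NA_real_, L, 20L, dimnames = list(NULL, AA20))
  aligned <- do.call(rbind, rows)
  for (p in seq_len(L)) {
    counts <- table(factor(aligned[, p], levels = AA20))  # X contributes nothing
    freq <- (as.numeric(counts) + pseudocount) / (n + 20 * pseudocount)
    mat[p, ] <- log(freq / background)
  }
  new("DomainProfile", domainId = domainId, matrix = mat,
      background = background)
}

# Scores of every window start of `res` (residue vector) under profile
# matrix `mat`. Unknown residues (X) score 0 at their position.
.window_scores <- function(mat, res) {
  L <- nrow(mat)
  n <- length(res)
  if (n < L) return(numeric(0))
  col <- match(res, colnames(mat))
  starts <- seq_len(n - L + 1L)
  offsets <- rep(starts, each = L) + seq_len(L) - 1L
  vals <- mat[cbind(rep(seq_len(L), times = length(starts)), col[offsets])]
  vals[is.na(vals)] <- 0
  colSums(matrix(vals, nrow = L))
}

#' Scan a protein sequence with a profile
#'
#' Slides an ungapped window of the profile length over the sequence, scores
#' every start, and reports non-overlapping local maxima whose empirical
#' E-value is at or below \code{maxEvalue}. The E-value of a window score is
#' the expected number of windows at or above that score in a
#' composition-preserving shuffle of the query (averaged over
#' \code{nShuffles} shuffles) — an empirical alternative to analytic
#' score statistics, adequate at desk scale. Hits carry identical/positive
#' residue counts against the profile consensus (positive = residue pairs
#' with a positive BLOSUM62 score), so downstream coverage/similarity/identity
#' statistics are available.
#'
#' @param profile a \code{\link{DomainProfile-class}}.
#' @param seq the query protein sequence.
#' @param queryId identifier recorded on the hits.
#' @param nShuffles shuffles building the empirical null (default 200).
#' @param seed integer seed (the scan is deterministic given it).
#' @param maxEvalue report hits with empirical E-value at or below this
#'   (default 0.01).
#' @return a \code{\link{HitTable-class}} (possibly empty; a sequence shorter
#'   than the profile yields an empty table with a warning).
#' @export
scanProfile <- function(profile, seq, queryId = "query", nShuffles = 200L,
                        seed = 1L, maxEvalue = 0.01) {
  stopifnot(is(profile, "DomainProfile"))
  mat <- profileMatrix(profile)
  L <- nrow(mat)
  res <- .check_alphabet(seq, "query sequence")
  if (length(res) < L) {
    warning("query '", queryId, "' is shorter than the profile; no hits",
            call. = FALSE)
    return(.as_hittable(list()))
  }
  obs <- .window_scores(mat, res)

  null <- withSeed(seed, {
    unlist(lapply(seq_len(nShuffles), function(i) {
      .window_scores(mat, sample(res))
    }))
  })
  null <- sort(null)
  # E-value: expected count per shuffled query of windows scoring >= s
  evalue_of <- function(s) {
    (length(null) - findInterval(s - 1e-12, null)) / nShuffles
  }
  ev <- vapply(obs, evalue_of, numeric(1))

  keep <- which(ev <= maxEvalue)
  if (length(keep) == 0L) return(.as_hittable(list()))
  # greedy non-overlapping local maxima, best score first
  keep <- keep[order(-obs[keep], keep)]
  chosen <- integer(0)
  for (s in keep) {
    if (!any(abs(chosen - s) < L)) chosen <- c(chosen, s)
  }
  chosen <- sort(chosen)

  cons <- .split_residues(profileConsensus(profile))
  b62 <- .blosum62()
  rows <- lapply(chosen, function(s) {
    win <- res[s:(s + L - 1L)]
    ident <- sum(win == cons)
    pos <- sum(b62[cbind(win, cons)] > 0)
    .new_hit_row(query_id = queryId, method = "internal-scanner",
                 domain_id = profile@domainId, q_start = s, q_end = s + L - 1L,
                 s_start = 1L, s_end = L, aligned_length = L,
                 identical = ident, positive = pos, gaps = 0L,
                 evalue = ev[s], bitscore = obs[s] / log(2))
  })
  .as_hittable(rows)
}

#' Scan many proteins with many profiles
#'
#' Convenience wrapper used by the pipeline runner: scans every query with
#' every profile and binds the hits. Per-scan seeds are derived
#' deterministically from \code{seed}.
#'
#' @param profiles list of \code{\link{DomainProfile-class}} objects.
#' @param queries named character vector or \code{Biostrings::AAStringSet}.
#' @param ... passed to \code{\link{scanProfile}} (\code{nShuffles},
#'   \code{maxEvalue}).
#' @param seed integer base seed.
#' @return a combined \code{\link{HitTable-class}}.
#' @export
scanProteins <- function(profiles, queries, seed = 1L, ...) {
  if (is(queries, "AAStringSet")) {
    queries <- setNames(as.character(queries), names(queries))
  }
  tabs <- list()
  k <- 0L
  for (p in seq_along(profiles)) {
    for (q in seq_along(queries)) {
      k <- k + 1L
      ht <- suppressWarnings(
        scanProfile(profiles[[p]], queries[[q]], queryId = names(queries)[q],
                    seed = seed + k, ...))
      if (nHits(ht) > 0L) tabs[[length(tabs) + 1L]] <- hitData(ht)
    }
  }
  if (length(tabs) == 0L) return(.as_hittable(list()))
  new("HitTable", hits = do.call(rbind, tabs))
}

#' Write / read a profile as TSV
#'
#' One row per position, columns the 20 residues (natural-log odds); header
#' lines carry the domain id and background frequencies.
#'
#' @param profile a \code{\link{DomainProfile-class}}.
#' @param path file path.
#' @return \code{writeProfile}: \code{path} invisibly; \code{readProfile}:
#'   a \code{DomainProfile}.
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "DomainProfile"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# domain_id=", profile@domainId), con)
  writeLines(paste0("# background=",
                    paste(format(profile@background, digits = 17),
                          collapse = ",")), con)
  writeLines(paste(c("position", AA20), collapse = "\t"), con)
  m <- profileMatrix(profile)
  write.table(cbind(position = seq_len(nrow(m)),
                    format(m, digits = 17, trim = TRUE)),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeProfile
#' @export
readProfile <- function(path) {
  .check_file(path)
  lines <- readLines(path, warn = FALSE)
  id <- sub("^# domain_id=", "", lines[startsWith(lines, "# domain_id=")][1])
  bg <- as.numeric(strsplit(sub("^# background=", "",
                                lines[startsWith(lines, "# background=")][1]),
                            ",", fixed = TRUE)[[1]])
  names(bg) <- AA20
  body <- lines[!startsWith(lines, "#")]
  tab <- read.table(text = body, sep = "\t", header = TRUE,
                    check.names = FALSE)
  m <- as.matrix(tab[, AA20])
  dimnames(m) <- list(NULL, AA20)
  new("DomainProfile", domainId = id, matrix = m, background = bg)
}
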