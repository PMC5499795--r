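# Candidate selection: cut-off filtering of hits, per-protein grouping, and
# merging of candidate sets across prediction methods.

#' Construct filter parameters
#'
#' Defaults are the optimized combined rule: minimum domain coverage 39\%
#' AND minimum residue similarity 24\%. Minimum residue identity (optimized
#' value 15\%), maximum E-value (optimized value 0.01) and maximum gap
#' percentage are opt-in: pass a value to enable, NA to disable.
#'
#' @param minCoverage minimum domain coverage percentage (default 39).
#' @param minSimilarity minimum residue similarity percentage (default 24).
#' @param minIdentity minimum residue identity percentage (default disabled).
#' @param maxEvalue maximum E-value (default disabled).
#' @param maxGap maximum gap percentage (default disabled).
#' @return a \code{\link{FilterParams-class}}.
#' @examples
#' FilterParams()                      # optimized default pair
#' FilterParams(minIdentity = 15, maxEvalue = 0.01)
#' @export
FilterParams <- function(minCoverage = 39, minSimilarity = 24,
                         minIdentity = NA_real_, maxEvalue = NA_real_,
                         maxGap = NA_real_) {
  new("FilterParams", minCoverage = as.numeric(minCoverage),
      minSimilarity = as.numeric(minSimilarity),
      minIdentity = as.numeric(minIdentity),
      maxEvalue = as.numeric(maxEvalue), maxGap = as.numeric(maxGap))
}

# One threshold check. A hit with an unavailable (NA) statistic passes the
# similarity/identity/gap checks (it is gated on the remaining parameters and
# flagged partial_stats) but fails the coverage check: coverage is the core
# parameter and is only NA when the reference itself is unknown.
.pass_min <- function(value, threshold, na_passes) {
  if (is.na(threshold)) return(rep(TRUE, length(value)))
  ifelse(is.na(value), na_passes, value >= threshold)
}

.pass_max <- function(value, threshold, na_passes) {
  if (is.na(threshold)) return(rep(TRUE, length(value)))
  ifelse(is.na(value), na_passes, value <= threshold)
}

#' Filter hits by statistical cut-offs and the reference domain set
#'
#' A hit passes when its \code{domain_id} belongs to the reference set and
#' every enabled threshold is satisfied; boundary values pass. Hits whose
#' residue similarity/identity is unavailable (e.g. the InterProScan-style
#' dialect) are gated on the remaining parameters only and are flagged
#' \code{partial_stats}; hits whose coverage is unavailable fail an enabled
#' coverage threshold. Input order is preserved.
#'
#' @param hits a \code{\link{HitTable-class}} with statistics populated
#'   (see \code{\link{computeHitStats}}).
#' @param params a \code{\link{FilterParams-class}}.
#' @param referenceSet character vector of reference \code{domain_id}s, or a
#'   \code{\link{DomainSet-class}}; NULL admits every domain.
#' @return the filtered \code{HitTable}.
#' @export
filterHits <- function(hits, params = FilterParams(), referenceSet = NULL) {
  stopifnot(is(hits, "HitTable"), is(params, "FilterParams"))
  h <- hitData(hits)
  if (nrow(h) == 0L) return(hits)
  if (is(referenceSet, "DomainSet")) referenceSet <- domainIds(referenceSet)
  in_ref <- if (is.null(referenceSet)) rep(TRUE, nrow(h)) else
    h$domain_id %in% referenceSet
  pass <- in_ref &
    .pass_min(h$coverage_pct, params@minCoverage, na_passes = FALSE) &
    .pass_min(h$similarity_pct, params@minSimilarity, na_passes = TRUE) &
    .pass_min(h$identity_pct, params@minIdentity, na_passes = TRUE) &
    .pass_max(h$evalue, params@maxEvalue, na_passes = TRUE) &
    .pass_max(h$gap_pct, params@maxGap, na_passes = TRUE)
  out <- h[pass, , drop = FALSE]
  rownames(out) <- NULL
  new("HitTable", hits = out)
}

#' Group passing hits per candidate protein
#'
#' A protein is a candidate when it carries at least one passing hit. Hits
#' are grouped by query and ordered by ascending E-value (NA last) then
#' descending coverage.
#'
#' @param hits a \code{\link{HitTable-class}} of passing hits.
#' @return named list (by \code{query_id}) of per-protein hit data.frames.
#' @export
selectProteins <- function(hits) {
  stopifnot(is(hits, "HitTable"))
  h <- hitData(hits)
  if (nrow(h) == 0L) return(setNames(list(), character(0)))
  ord <- order(h$query_id, xtfrm(h$evalue), -xtfrm(h$coverage_pct),
               na.last = TRUE)
  h <- h[ord, , drop = FALSE]
  out <- split(h, factor(h$query_id, levels = unique(h$query_id)))
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

#' Merge candidate sets identified by two methods
#'
#' @param setA,setB character vectors of candidate protein identifiers from
#'   two prediction methods (duplicates ignored).
#' @param labels length-2 labels for the two methods, used in the provenance
#'   table.
#' @return list with the union and intersection id vectors, the per-method
#'   and merged counts, and a \code{members} data.frame flagging each union
#'   member's provenance.
#' @examples
#' m <- mergeMethodCandidates(c("P1", "P2", "P3"), c("P3", "P4"))
#' m$nUnion         # 4
#' @export
mergeMethodCandidates <- function(setA, setB,
                                  labels = c("method_a", "method_b")) {
  a <- unique(as.character(setA))
  b <- unique(as.character(setB))
  u <- union(a, b)
  i <- intersect(a, b)
  members <- data.frame(query_id = u, stringsAsFactors = FALSE)
  members[[labels[1]]] <- u %in% a
  members[[labels[2]]] <- u %in% b
  list(union = u, intersection = i,
       nA = length(a), nB = length(b),
       nUnion = length(u), nIntersection = length(i),
       members = members)
}
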