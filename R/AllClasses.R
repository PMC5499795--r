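# S4 classes for the central data objects. Slot access goes through the
# accessor functions defined next to each class; user code should not reach
# into slots directly.

## ---- KeywordSpec -----------------------------------------------------------

#' Keyword specification for domain selection and result classification
#'
#' An ordered set of search terms. A plain term matches an annotation field
#' when every whitespace-separated word of the term occurs (case-insensitive
#' substring) within that single field; a regex term is a Perl-compatible
#' pattern applied to each field. Duplicate terms collapse to one.
#'
#' @slot terms character vector of non-empty terms.
#' @slot isRegex logical vector parallel to \code{terms}; \code{TRUE} marks a
#'   term interpreted as a regular expression.
#' @exportClass KeywordSpec
setClass("KeywordSpec",
         representation(terms = "character", isRegex = "logical"))

setValidity("KeywordSpec", function(object) {
  if (length(object@terms) == 0L) return("terms must be non-empty")
  if (any(!nzchar(trimws(object@terms)))) return("terms must be non-empty strings")
  if (length(object@isRegex) != length(object@terms)) {
    return("isRegex must parallel terms")
  }
  if (anyDuplicated(object@terms)) return("duplicate terms must be collapsed")
  TRUE
})

## ---- DomainSet -------------------------------------------------------------

#' Reference domain set
#'
#' A table of domain/motif records: identifier, accession, short name, free
#' text description, reference length, optional consensus sequence and
#' semicolon-joined GO annotations. The keyword-selected subset of a loaded
#' table is the \emph{reference domain set} that defines the functional class
#' of interest.
#'
#' @slot entries data.frame with columns \code{domain_id}, \code{accession},
#'   \code{short_name}, \code{description}, \code{length}, \code{consensus}
#'   (NA when absent), \code{go_terms} (empty string when absent).
#' @slot sourceDb label of the originating resource dialect, e.g.
#'   \code{"CDD-style"}.
#' @exportClass DomainSet
setClass("DomainSet",
         representation(entries = "data.frame", sourceDb = "character"))

.DOMAIN_COLS <- c("domain_id", "accession", "short_name", "description",
                  "length", "consensus", "go_terms")

setValidity("DomainSet", function(object) {
  e <- object@entries
  if (!all(.DOMAIN_COLS %in% names(e))) {
    return(paste("entries must have columns:", paste(.DOMAIN_COLS, collapse = ", ")))
  }
  if (nrow(e) == 0L) return(TRUE)
  if (anyDuplicated(e$domain_id)) return("domain_id must be unique within a set")
  if (any(is.na(e$length)) || any(e$length < 1L)) return("length must be >= 1")
  has_cons <- !is.na(e$consensus) & nzchar(e$consensus)
  if (any(nchar(e$consensus[has_cons]) != e$length[has_cons])) {
    return("consensus residue count must equal the stated length")
  }
  TRUE
})

## ---- HitTable --------------------------------------------------------------

#' Predicted domain occurrences on query proteins
#'
#' One row per predicted domain hit, in the unified representation shared by
#' all ingestion dialects and the internal scanner. Coordinates are 1-based
#' inclusive; \code{q_*} on the query protein, \code{s_*} on the reference
#' domain. Derived percentage statistics (see \code{\link{computeHitStats}})
#' are NA until computed, and stay NA where a dialect does not supply the
#' underlying counts (\code{partial_stats} flags such hits).
#'
#' @slot hits data.frame with the unified hit columns.
#' @exportClass HitTable
setClass("HitTable", representation(hits = "data.frame"))

.HIT_COLS <- c("query_id", "method", "domain_id", "q_start", "q_end",
               "s_start", "s_end", "aligned_length", "identical", "positive",
               "gaps", "evalue", "bitscore", "coverage_pct", "similarity_pct",
               "identity_pct", "gap_pct", "span_based", "partial_stats")

.empty_hits <- function() {
  data.frame(query_id = character(0), method = character(0),
             domain_id = character(0), q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             aligned_length = integer(0), identical = integer(0),
             positive = integer(0), gaps = integer(0), evalue = numeric(0),
             bitscore = numeric(0), coverage_pct = numeric(0),
             similarity_pct = numeric(0), identity_pct = numeric(0),
             gap_pct = numeric(0), span_based = logical(0),
             partial_stats = logical(0), stringsAsFactors = FALSE)
}

setValidity("HitTable", function(object) {
  h <- object@hits
  if (!all(.HIT_COLS %in% names(h))) {
    return(paste("hits must have columns:", paste(.HIT_COLS, collapse = ", ")))
  }
  if (nrow(h) == 0L) return(TRUE)
  if (any(h$q_start < 1L) || any(h$q_end < h$q_start)) {
    return("query coordinates must satisfy 1 <= q_start <= q_end")
  }
  if (any(h$s_start < 1L) || any(h$s_end < h$s_start)) {
    return("subject coordinates must satisfy 1 <= s_start <= s_end")
  }
  ok <- !is.na(h$identical) & !is.na(h$positive)
  if (any(h$identical[ok] > h$positive[ok])) {
    return("identical count cannot exceed positive count")
  }
  ok <- !is.na(h$positive)
  if (any(h$positive[ok] > h$aligned_length[ok])) {
    return("positive count cannot exceed aligned length")
  }
  ok <- !is.na(h$gaps)
  if (any(h$gaps[ok] > h$aligned_length[ok])) {
    return("gap count cannot exceed aligned length")
  }
  TRUE
})

## ---- FilterParams ----------------------------------------------------------

#' Statistical cut-offs gating predicted domains
#'
#' The cut-off bundle applied by \code{\link{filterHits}}. The defaults are
#' the optimized pair of minimum domain coverage 39\% and minimum residue
#' similarity 24\%; minimum residue identity (optimized value 15\%), maximum
#' E-value (optimized value 0.01) and maximum gap percentage are available
#' but disabled (NA) unless set. Boundary values pass (\code{>=} / \code{<=}).
#'
#' @slot minCoverage,minSimilarity,minIdentity minimum percentages in
#'   [0, 100], NA = disabled.
#' @slot maxEvalue maximum E-value, NA = disabled.
#' @slot maxGap maximum gap percentage in [0, 100], NA = disabled.
#' @exportClass FilterParams
setClass("FilterParams",
         representation(minCoverage = "numeric", minSimilarity = "numeric",
                        minIdentity = "numeric", maxEvalue = "numeric",
                        maxGap = "numeric"))

setValidity("FilterParams", function(object) {
  pct <- c(object@minCoverage, object@minSimilarity, object@minIdentity,
           object@maxGap)
  pct <- pct[!is.na(pct)]
  if (length(pct) && (any(pct < 0) || any(pct > 100) || any(!is.finite(pct)))) {
    return("percentage thresholds must be finite and within [0, 100]")
  }
  if (!is.na(object@maxEvalue) &&
      (!is.finite(object@maxEvalue) || object@maxEvalue < 0)) {
    return("maxEvalue must be finite and non-negative")
  }
  TRUE
})

## ---- FeatureScores ---------------------------------------------------------

.FEATURE_NAMES <- c("chem_mass", "chem_pka", "chem_pi",
                    "aln_primary", "aln_secondary",
                    "dist_dipeptide", "dist_tripeptide", "dist_physchem",
                    "site_similarity")

#' Feature-based scores of one predicted site against its reference consensus
#'
#' Per-feature scores in [0, 1] across the four feature categories (chemical
#' properties; primary/secondary alignment; composition distances; site
#' similarity), the combined Bayesian score, and empirical P-values for the
#' sequence-based features. Chemical-property features carry no P-values.
#' Unavailable features are NA and are skipped in the combination.
#'
#' @slot queryId,domainId identifiers of the scored hit.
#' @slot scores named numeric of the nine feature scores (NA = unavailable).
#' @slot combined combined Bayesian score in [0, 1].
#' @slot pvalues named numeric of empirical P-values in (0, 1].
#' @exportClass FeatureScores
setClass("FeatureScores",
         representation(queryId = "character", domainId = "character",
                        scores = "numeric", combined = "numeric",
                        pvalues = "numeric"))

setValidity("FeatureScores", function(object) {
  s <- object@scores
  if (!identical(sort(names(s)), sort(.FEATURE_NAMES))) {
    return("scores must be named with the nine feature names")
  }
  ok <- s[!is.na(s)]
  if (length(ok) && (any(ok < 0) || any(ok > 1))) {
    return("feature scores must lie within [0, 1]")
  }
  if (!is.na(object@combined) &&
      (object@combined < 0 || object@combined > 1)) {
    return("combined score must lie within [0, 1]")
  }
  if (length(object@pvalues)) {
    if (any(startsWith(names(object@pvalues), "chem_"))) {
      return("chemical-property features carry no P-values")
    }
    if (any(object@pvalues <= 0) || any(object@pvalues > 1)) {
      return("P-values must lie within (0, 1]")
    }
  }
  TRUE
})

## ---- ConfusionCounts / Metrics / ROCCurve ----------------------------------

#' Binary-classification confusion counts
#'
#' @slot tp,fp,tn,fn non-negative counts of true positives, false positives,
#'   true negatives and false negatives.
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
         representation(tp = "numeric", fp = "numeric",
                        tn = "numeric", fn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(is.na(v)) || any(v < 0)) return("counts must be non-negative")
  TRUE
})

#' Derived classification metrics
#'
#' Sensitivity, specificity, accuracy, Matthews correlation coefficient and
#' the F-measure in its sensitivity/specificity form
#' \eqn{2 \cdot SN \cdot SP / (SN + SP)} (not the precision/recall form).
#' Any metric whose denominator is zero is defined as 0.
#'
#' @slot sn,sp,acc,mcc,fmeasure numeric metric values at full precision.
#' @exportClass Metrics
setClass("Metrics",
         representation(sn = "numeric", sp = "numeric", acc = "numeric",
                        mcc = "numeric", fmeasure = "numeric"))

setValidity("Metrics", function(object) {
  rng <- c(object@sn, object@sp, object@acc)
  if (any(rng < 0 - 1e-12) || any(rng > 1 + 1e-12)) {
    return("sn, sp and acc must lie within [0, 1]")
  }
  if (object@mcc < -1 - 1e-12 || object@mcc > 1 + 1e-12) {
    return("mcc must lie within [-1, 1]")
  }
  TRUE
})

#' Receiver operating characteristic curve
#'
#' Threshold sweep over distinct score values (ties cross together), points
#' ordered by increasing false positive rate with the (0,0) and (1,1)
#' endpoints present, and the trapezoidal area under the curve.
#'
#' @slot points data.frame with columns \code{threshold}, \code{fpr},
#'   \code{tpr}.
#' @slot auc trapezoidal area under the curve, in [0, 1].
#' @exportClass ROCCurve
setClass("ROCCurve", representation(points = "data.frame", auc = "numeric"))

setValidity("ROCCurve", function(object) {
  p <- object@points
  if (!all(c("threshold", "fpr", "tpr") %in% names(p))) {
    return("points must have columns threshold, fpr, tpr")
  }
  if (is.unsorted(p$fpr)) return("points must be sorted by fpr")
  if (object@auc < 0 - 1e-12 || object@auc > 1 + 1e-12) {
    return("auc must lie within [0, 1]")
  }
  TRUE
})

## ---- DomainProfile ---------------------------------------------------------

#' Position-specific scoring profile for the internal scanner
#'
#' Per-position log-odds over the 20 standard residues, derived from an
#' ungapped alignment with additive pseudocounts against a background
#' distribution. Used by \code{\link{scanProfile}} as a desk-scale stand-in
#' for an external profile search engine.
#'
#' @slot domainId identifier of the domain the profile models.
#' @slot matrix numeric matrix, one row per position, columns named by the 20
#'   residues, entries natural-log odds.
#' @slot background residue background frequencies (sums to 1).
#' @exportClass DomainProfile
setClass("DomainProfile",
         representation(domainId = "character", matrix = "matrix",
                        background = "numeric"))

setValidity("DomainProfile", function(object) {
  m <- object@matrix
  if (!identical(colnames(m), AA20)) {
    return("matrix columns must be the 20 standard residues")
  }
  if (nrow(m) < 1L) return("profile must have at least one position")
  if (any(!is.finite(m))) return("all log-odds must be finite")
  if (length(object@background) != 20L ||
      abs(sum(object@background) - 1) > 1e-8) {
    return("background must be 20 frequencies summing to 1")
  }
  TRUE
})
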