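# Accessors and show methods. Slot access from user code should go through
# these.

#' @rdname DomainSet-class
#' @param object,x a \code{DomainSet}.
#' @return \code{entryData} returns the underlying data.frame of domain
#'   records; \code{domainIds} the identifiers; \code{sourceDb} the dialect
#'   label; \code{refLength} and \code{consensusOf} the length / consensus of
#'   one entry.
#' @export
entryData <- function(x) {
  stopifnot(is(x, "DomainSet"))
  x@entries
}

#' @rdname DomainSet-class
#' @export
domainIds <- function(x) entryData(x)$domain_id

#' @rdname DomainSet-class
#' @export
sourceDb <- function(x) {
  stopifnot(is(x, "DomainSet"))
  x@sourceDb
}

#' @rdname DomainSet-class
#' @param id a single domain identifier.
#' @export
refLength <- function(x, id) {
  e <- entryData(x)
  i <- match(id, e$domain_id)
  if (is.na(i)) .stop_input("unknown domain_id: ", id)
  e$length[i]
}

#' @rdname DomainSet-class
#' @export
consensusOf <- function(x, id) {
  e <- entryData(x)
  i <- match(id, e$domain_id)
  if (is.na(i)) .stop_input("unknown domain_id: ", id)
  cons <- e$consensus[i]
  if (is.na(cons) || !nzchar(cons)) NA_character_ else cons
}

setMethod("show", "DomainSet", function(object) {
  e <- object@entries
  n_cons <- sum(!is.na(e$consensus) & nzchar(e$consensus))
  cat("DomainSet (", object@sourceDb, ") with ", nrow(e), " entries, ",
      n_cons, " with consensus\n", sep = "")
  if (nrow(e) > 0L) {
    shown <- utils::head(e[, c("domain_id", "short_name", "length")], 5L)
    print(shown, row.names = FALSE)
    if (nrow(e) > 5L) cat("... and", nrow(e) - 5L, "more\n")
  }
})

#' @rdname KeywordSpec-class
#' @param x a \code{KeywordSpec}.
#' @return \code{keywordTerms} returns the terms; \code{isRegexTerm} the
#'   parallel logical regex flags.
#' @export
keywordTerms <- function(x) {
  stopifnot(is(x, "KeywordSpec"))
  x@terms
}

#' @rdname KeywordSpec-class
#' @export
isRegexTerm <- function(x) {
  stopifnot(is(x, "KeywordSpec"))
  x@isRegex
}

setMethod("show", "KeywordSpec", function(object) {
  cat("KeywordSpec with", length(object@terms), "terms\n")
  flag <- ifelse(object@isRegex, " [regex]", "")
  cat(paste0("  '", object@terms, "'", flag, collapse = "\n"), "\n")
})

#' @rdname HitTable-class
#' @param object,x a \code{HitTable}.
#' @return \code{hitData} returns the underlying data.frame (one row per
#'   hit); \code{nHits} the number of hits.
#' @export
hitData <- function(x) {
  stopifnot(is(x, "HitTable"))
  x@hits
}

#' @rdname HitTable-class
#' @export
nHits <- function(x) nrow(hitData(x))

setMethod("show", "HitTable", function(object) {
  h <- object@hits
  cat("HitTable with ", nrow(h), " hits on ",
      length(unique(h$query_id)), " queries\n", sep = "")
  if (nrow(h) > 0L) {
    cols <- c("query_id", "method", "domain_id", "q_start", "q_end",
              "coverage_pct", "similarity_pct", "identity_pct", "evalue")
    print(utils::head(h[, cols], 5L), row.names = FALSE, digits = 4)
    if (nrow(h) > 5L) cat("... and", nrow(h) - 5L, "more\n")
  }
})

#' @rdname FilterParams-class
#' @param x a \code{FilterParams}.
#' @return named numeric vector of the five thresholds (NA = disabled).
#' @export
filterThresholds <- function(x) {
  stopifnot(is(x, "FilterParams"))
  c(min_coverage_pct = x@minCoverage, min_similarity_pct = x@minSimilarity,
    min_identity_pct = x@minIdentity, max_evalue = x@maxEvalue,
    max_gap_pct = x@maxGap)
}

setMethod("show", "FilterParams", function(object) {
  th <- filterThresholds(object)
  cat("FilterParams:\n")
  for (nm in names(th)) {
    cat("  ", nm, ": ", if (is.na(th[[nm]])) "disabled" else th[[nm]], "\n",
        sep = "")
  }
})

#' @rdname FeatureScores-class
#' @param object,x a \code{FeatureScores}.
#' @return \code{featureValues} returns the named vector of the nine feature
#'   scores; \code{combinedScore} the combined Bayesian score;
#'   \code{featurePvalues} the named empirical P-values.
#' @export
featureValues <- function(x) {
  stopifnot(is(x, "FeatureScores"))
  x@scores
}

#' @rdname FeatureScores-class
#' @export
combinedScore <- function(x) {
  stopifnot(is(x, "FeatureScores"))
  x@combined
}

#' @rdname FeatureScores-class
#' @export
featurePvalues <- function(x) {
  stopifnot(is(x, "FeatureScores"))
  x@pvalues
}

setMethod("show", "FeatureScores", function(object) {
  cat("FeatureScores for query '", object@queryId, "' vs domain '",
      object@domainId, "'\n", sep = "")
  print(round(object@scores, 4))
  cat("combined:", round(object@combined, 4), "\n")
  if (length(object@pvalues)) {
    cat("P-values:\n")
    print(round(object@pvalues, 4))
  }
})

#' @rdname ConfusionCounts-class
#' @param object,x a \code{ConfusionCounts}.
#' @return named numeric vector \code{c(tp, fp, tn, fn)}.
#' @export
confusionVector <- function(x) {
  stopifnot(is(x, "ConfusionCounts"))
  c(tp = x@tp, fp = x@fp, tn = x@tn, fn = x@fn)
}

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts: TP=", object@tp, " FP=", object@fp,
      " TN=", object@tn, " FN=", object@fn, "\n", sep = "")
})

#' @rdname Metrics-class
#' @param object,x a \code{Metrics}.
#' @param digits decimals for the rounded report (half-up); use \code{NULL}
#'   for full precision.
#' @return named numeric vector of sn, sp, acc, mcc and fmeasure.
#' @export
metricsVector <- function(x, digits = NULL) {
  stopifnot(is(x, "Metrics"))
  v <- c(sn = x@sn, sp = x@sp, acc = x@acc, mcc = x@mcc,
         fmeasure = x@fmeasure)
  if (!is.null(digits)) v <- roundHalfUp(v, digits)
  v
}

setMethod("show", "Metrics", function(object) {
  print(metricsVector(object, digits = 2))
})

#' @rdname ROCCurve-class
#' @param object,x a \code{ROCCurve}.
#' @return \code{rocPoints} returns the data.frame of (threshold, fpr, tpr)
#'   points; \code{aucOf} the trapezoidal area under the curve.
#' @export
rocPoints <- function(x) {
  stopifnot(is(x, "ROCCurve"))
  x@points
}

#' @rdname ROCCurve-class
#' @export
aucOf <- function(x) {
  stopifnot(is(x, "ROCCurve"))
  x@auc
}

setMethod("show", "ROCCurve", function(object) {
  cat("ROCCurve with ", nrow(object@points), " points, AUC = ",
      round(object@auc, 4), "\n", sep = "")
})

#' @rdname DomainProfile-class
#' @param object,x a \code{DomainProfile}.
#' @return \code{profileMatrix} returns the position x residue log-odds
#'   matrix; \code{profileLength} the number of positions;
#'   \code{profileConsensus} the per-position argmax residue string.
#' @export
profileMatrix <- function(x) {
  stopifnot(is(x, "DomainProfile"))
  x@matrix
}

#' @rdname DomainProfile-class
#' @export
profileLength <- function(x) nrow(profileMatrix(x))

#' @rdname DomainProfile-class
#' @export
profileConsensus <- function(x) {
  m <- profileMatrix(x)
  paste(colnames(m)[apply(m, 1L, which.max)], collapse = "")
}

setMethod("show", "DomainProfile", function(object) {
  cat("DomainProfile '", object@domainId, "' with ",
      nrow(object@matrix), " positions\n", sep = "")
  cat("consensus:", profileConsensus(object), "\n")
})
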