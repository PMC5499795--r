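# Feature-based scoring of predicted sites against their reference consensus:
# chemical properties, global alignment (primary and secondary structure),
# composition-distance features, Bayesian combination, empirical P-values.

## ---- global alignment ------------------------------------------------------

# Gotoh affine-gap global alignment. Gap cost convention: the first residue
# of a gap costs `gapOpen`, every further residue `gapExtend` (so a length-L
# terminal gap costs gapOpen + (L-1)*gapExtend).
.nw_raw <- function(ra, rb, submat, gapOpen, gapExtend) {
  n <- length(ra)
  m <- length(rb)
  if (n == 0L && m == 0L) .stop_input("both sequences are empty")
  if (n == 0L) return(gapOpen + (m - 1L) * gapExtend)
  if (m == 0L) return(gapOpen + (n - 1L) * gapExtend)
  NEG <- -1e18
  # rows: states M (match), X (gap in b, consumes a), Y (gap in a, consumes b)
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  X[2L:(n + 1L), 1L] <- gapOpen + (seq_len(n) - 1L) * gapExtend
  Y[1L, 2L:(m + 1L)] <- gapOpen + (seq_len(m) - 1L) * gapExtend
  sa <- submat[ra, rb, drop = FALSE]
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + sa[i, j]
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] + gapOpen,
                               X[i, j + 1L] + gapExtend,
                               Y[i, j + 1L] + gapOpen)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + gapOpen,
                               Y[i + 1L, j] + gapExtend,
                               X[i + 1L, j] + gapOpen)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

.self_score <- function(rb, submat) {
  if (length(rb) == 0L) return(0)
  sum(submat[cbind(rb, rb)])
}

#' Global (Needleman-Wunsch) alignment score
#'
#' Optimal global alignment under a substitution matrix with affine gap
#' penalties (a gap of length L costs \code{gapOpen + (L-1) * gapExtend}).
#' The normalized similarity divides the raw score by the self-alignment
#' score of \code{b} and clamps to [0, 1], so identical sequences score 1.
#'
#' @param a,b amino-acid strings over the 20-letter alphabet; X is tolerated
#'   and scores 0 against everything. At least one must be non-empty.
#' @param submat substitution matrix (default BLOSUM62 with neutral X).
#' @param gapOpen,gapExtend gap penalties (negative; defaults -10 / -0.5).
#' @return list with \code{raw} (optimal score) and \code{normalized}
#'   (similarity in [0, 1]).
#' @examples
#' nwAlign("HEAGAWGHEE", "HEAGAWGHEE")$normalized  # 1
#' @export
nwAlign <- function(a, b, submat = NULL, gapOpen = -10, gapExtend = -0.5) {
  if (is.null(submat)) submat <- .blosum62()
  ra <- if (nchar(a) > 0L) .check_alphabet(a, "sequence a") else character(0)
  rb <- if (nchar(b) > 0L) .check_alphabet(b, "sequence b") else character(0)
  raw <- .nw_raw(ra, rb, submat, gapOpen, gapExtend)
  self <- .self_score(rb, submat)
  normalized <- if (self > 0) max(0, min(1, raw / self)) else 0
  list(raw = raw, normalized = normalized)
}

#' Predict 3-state secondary structure (built-in stand-in)
#'
#' A deliberately simple per-residue propensity classifier over the states
#' \{H, E, C\} using Chou-Fasman helix/strand propensities: H when the helix
#' propensity is the larger and exceeds 1, E when the strand propensity is
#' at least as large and exceeds 1, C otherwise. It exists so the
#' secondary-structure alignment feature can run without an external
#' predictor; supply real 3-state strings when available.
#'
#' @param seq amino-acid string.
#' @return string over \{H, E, C\} of the same length.
#' @export
predictSecondary <- function(seq) {
  res <- .check_alphabet(seq, "sequence")
  prop <- .ss_propensity()
  idx <- match(res, prop$residue)
  h <- prop$helix[idx]
  e <- prop$strand[idx]
  state <- ifelse(is.na(idx), "C",
                  ifelse(h > e & h > 1, "H",
                         ifelse(e >= h & e > 1, "E", "C")))
  paste(state, collapse = "")
}

#' Align two 3-state secondary-structure strings
#'
#' Global alignment over \{H, E, C\} scoring +1 match, 0 mismatch, -1 gap
#' position; normalized by the self score of \code{b} (its length).
#'
#' @param a,b strings over \{H, E, C\}.
#' @return list with \code{raw} and \code{normalized} (in [0, 1]).
#' @export
ssAlign <- function(a, b) {
  states <- c("H", "E", "C")
  m <- matrix(0, 3, 3, dimnames = list(states, states))
  diag(m) <- 1
  ra <- .split_residues(toupper(a))
  rb <- .split_residues(toupper(b))
  bad <- setdiff(unique(c(ra, rb)), states)
  if (length(bad)) {
    .stop_input("secondary-structure strings must use H/E/C, found: ",
                paste(bad, collapse = ", "))
  }
  raw <- .nw_raw(ra, rb, m, gapOpen = -1, gapExtend = -1)
  self <- length(rb)
  list(raw = raw, normalized = if (self > 0) max(0, min(1, raw / self)) else 0)
}

## ---- composition features --------------------------------------------------

.kmer_levels <- function(k) {
  key <- paste0("kmers", k)
  if (is.null(.ds_cache[[key]])) {
    grids <- rep(list(AA20), k)
    g <- do.call(expand.grid, c(rev(grids), stringsAsFactors = FALSE))
    .ds_cache[[key]] <- apply(g[, rev(seq_len(k)), drop = FALSE], 1L, paste0,
                              collapse = "")
  }
  .ds_cache[[key]]
}

#' k-peptide composition vector
#'
#' Frequency vector over all 20^k k-peptides: each entry is the count of that
#' k-mer divided by the number of (valid) windows, so the vector sums to 1.
#' Windows containing a non-standard residue (X) are excluded from both
#' numerator and denominator.
#'
#' @param seq amino-acid string with at least k residues.
#' @param k 2 (dipeptides) or 3 (tripeptides).
#' @return named numeric vector of length \code{20^k}.
#' @examples
#' v <- compositionVector("ACDC", k = 2)
#' v[c("AC", "CD", "DC")]   # each 1/3
#' @export
compositionVector <- function(seq, k = 2) {
  k <- as.integer(k)
  stopifnot(k %in% c(2L, 3L))
  res <- .check_alphabet(seq, "sequence")
  n <- length(res)
  if (n < k) {
    .stop_input("sequence of length ", n, " is shorter than k = ", k)
  }
  starts <- seq_len(n - k + 1L)
  wins <- vapply(starts, function(i) paste(res[i:(i + k - 1L)], collapse = ""),
                 character(1))
  valid <- !grepl("X", wins, fixed = TRUE)
  if (!any(valid)) .stop_input("no window free of unknown residues")
  lv <- .kmer_levels(k)
  counts <- table(factor(wins[valid], levels = lv))
  v <- as.numeric(counts) / sum(valid)
  names(v) <- lv
  v
}

.PHYSCHEM_GROUPS <- list(hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "P"),
                         polar = c("G", "S", "T", "C", "Y", "N", "Q"),
                         acidic = c("D", "E"),
                         basic = c("K", "R", "H"))

#' Physico-chemical property composition vector
#'
#' Residues are mapped to four property groups (hydrophobic AVLIMFWP, polar
#' GSTCYNQ, acidic DE, basic KRH). The vector concatenates the group
#' frequencies (summing to 1) and the 16 group-pair transition frequencies of
#' consecutive residues (summing to 1 when at least one transition exists).
#' Unknown residues (X) are skipped.
#'
#' @param seq non-empty amino-acid string.
#' @return named numeric vector of length 20 (4 group + 16 transition
#'   entries).
#' @export
physchemComposition <- function(seq) {
  res <- .check_alphabet(seq, "sequence")
  gnames <- names(.PHYSCHEM_GROUPS)
  gmap <- setNames(rep(gnames, lengths(.PHYSCHEM_GROUPS)),
                   unlist(.PHYSCHEM_GROUPS))
  groups <- unname(gmap[res])
  groups <- groups[!is.na(groups)]
  if (length(groups) == 0L) .stop_input("no standard residues in sequence")
  gfreq <- as.numeric(table(factor(groups, levels = gnames))) / length(groups)
  names(gfreq) <- paste0("grp_", gnames)
  pairs <- expand.grid(from = gnames, to = gnames, stringsAsFactors = FALSE)
  plev <- paste0("trans_", pairs$from, "_", pairs$to)
  if (length(groups) >= 2L) {
    tr <- paste0("trans_", groups[-length(groups)], "_", groups[-1L])
    tfreq <- as.numeric(table(factor(tr, levels = plev))) / (length(groups) - 1L)
  } else {
    tfreq <- rep(0, length(plev))
  }
  names(tfreq) <- plev
  c(gfreq, tfreq)
}

#' Euclidean distance between composition vectors, as a 0-1 score
#'
#' @param va,vb equal-length numeric vectors.
#' @return list with \code{distance} (Euclidean) and \code{score}
#'   \code{= 1 / (1 + distance)}, a strictly decreasing map into (0, 1] that
#'   is 1 exactly for identical vectors.
#' @export
distanceScore <- function(va, vb) {
  if (length(va) != length(vb)) {
    .stop_input("composition vectors differ in length: ", length(va), " vs ",
                length(vb))
  }
  d <- sqrt(sum((va - vb)^2))
  list(distance = d, score = 1 / (1 + d))
}

## ---- chemical properties ---------------------------------------------------

.net_charge <- function(counts, pH, pka) {
  q <- 0
  for (i in seq_len(nrow(pka))) {
    g <- pka$group[i]
    n <- if (g == "Nterm" || g == "Cterm") 1 else counts[[g]] %||% 0
    if (n == 0) next
    if (pka$sign[i] > 0) {
      q <- q + n / (1 + 10^(pH - pka$pka[i]))
    } else {
      q <- q - n / (1 + 10^(pka$pka[i] - pH))
    }
  }
  q
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Chemical properties of a peptide
#'
#' Average molecular mass (sum of residue average masses plus one water),
#' isoelectric point (pH of zero net charge under the Henderson-Hasselbalch
#' model with the packaged EMBOSS-style pKa scale, solved by bisection to
#' |charge| < 1e-4), and the count-weighted mean pKa of the ionizable side
#' chains present (NA when none).
#'
#' @param seq non-empty amino-acid string (X contributes the mean residue
#'   mass and no charge).
#' @return list with \code{mass} (Da), \code{pI}, \code{meanPka}.
#' @examples
#' chemicalProps("G")$mass   # glycine residue mass + water
#' @export
chemicalProps <- function(seq) {
  res <- .check_alphabet(seq, "sequence")
  if (length(res) == 0L) .stop_input("sequence is empty")
  masses <- .residue_masses()
  mass <- sum(masses[res]) + 18.01524
  pka <- .pka_table()
  counts <- as.list(table(res))
  lo <- 0; hi <- 14
  for (iter in seq_len(200L)) {
    mid <- (lo + hi) / 2
    q <- .net_charge(counts, mid, pka)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  side <- pka[!(pka$group %in% c("Nterm", "Cterm")), ]
  n_side <- vapply(side$group, function(g) counts[[g]] %||% 0, numeric(1))
  meanPka <- if (sum(n_side) > 0) sum(side$pka * n_side) / sum(n_side) else NA_real_
  list(mass = unname(mass), pI = mid, meanPka = meanPka)
}

# Relative agreement of one chemical property between query region and
# reference fragment: 1 - min(1, |q - r| / r).
.chem_score <- function(q, r) {
  if (is.na(q) || is.na(r) || r == 0) return(NA_real_)
  1 - min(1, abs(q - r) / abs(r))
}

## ---- combination and significance ------------------------------------------

#' Combine feature scores into a Bayesian 0-1 score
#'
#' Naive-Bayes posterior with a uniform prior:
#' \eqn{\prod s_i / (\prod s_i + \prod (1 - s_i))}. Scores of exactly 0 or 1
#' are clamped to [1e-6, 1 - 1e-6] first; NA features are skipped. The result
#' is 1 only when every feature agrees completely, 0.5 when all features are
#' uninformative, symmetric in its arguments and strictly increasing in each.
#'
#' @param scores numeric vector of feature scores in [0, 1] (NAs dropped); at
#'   least one non-NA value required.
#' @return combined score in [0, 1].
#' @examples
#' combineBayesian(c(0.9, 0.8, 0.7))  # ~0.988
#' @export
combineBayesian <- function(scores) {
  s <- scores[!is.na(scores)]
  if (length(s) == 0L) .stop_input("no feature scores to combine")
  if (any(s < 0) || any(s > 1)) .stop_input("feature scores must lie in [0, 1]")
  eps <- 1e-6
  s <- pmin(pmax(s, eps), 1 - eps)
  # products via log-space for stability
  lp <- sum(log(s))
  lq <- sum(log1p(-s))
  1 / (1 + exp(lq - lp))
}

#' Empirical P-value of a feature score
#'
#' The null distribution is the feature recomputed on composition-preserving
#' shuffles of the hit region against the fixed reference fragment;
#' \eqn{p = (1 + \#\{null \ge observed\}) / (1 + n)}, always in (0, 1] and
#' deterministic for a fixed seed.
#'
#' @param observed the observed feature score.
#' @param statFun function(region, refFragment) returning the feature score.
#' @param hitRegion,refFragment the two residue strings.
#' @param nShuffles number of shuffles (>= 1, default 100).
#' @param seed integer seed.
#' @return P-value in (0, 1].
#' @export
empiricalPvalue <- function(observed, statFun, hitRegion, refFragment,
                            nShuffles = 100L, seed = 1L) {
  stopifnot(nShuffles >= 1L)
  null <- withSeed(seed, {
    res <- .split_residues(hitRegion)
    vapply(seq_len(nShuffles), function(i) {
      statFun(paste(sample(res), collapse = ""), refFragment)
    }, numeric(1))
  })
  (1 + sum(null >= observed)) / (1 + nShuffles)
}

## ---- per-hit scoring -------------------------------------------------------

#' Control options for feature scoring
#'
#' @param gapOpen,gapExtend affine gap penalties of the primary-sequence
#'   alignment (defaults -10 / -0.5 under BLOSUM62).
#' @param useSsPredictor use the built-in 3-state propensity predictor when
#'   secondary-structure strings are not supplied.
#' @param computePvalues attach empirical P-values to the sequence-based
#'   features.
#' @param nShuffles shuffles for the empirical null (default 100).
#' @param seed integer seed for the shuffles.
#' @return list of scoring options for \code{\link{scoreHit}}.
#' @export
featureControl <- function(gapOpen = -10, gapExtend = -0.5,
                           useSsPredictor = TRUE, computePvalues = TRUE,
                           nShuffles = 100L, seed = 1L) {
  list(gapOpen = gapOpen, gapExtend = gapExtend,
       useSsPredictor = useSsPredictor, computePvalues = computePvalues,
       nShuffles = as.integer(nShuffles), seed = as.integer(seed))
}

#' Score one predicted site against its reference consensus
#'
#' Extracts the predicted query region \code{[q_start..q_end]} and the
#' reference consensus fragment \code{[s_start..s_end]} and compares them
#' across the four feature categories: chemical properties (average mass,
#' mean side-chain pKa, pI, each scored as relative agreement), global
#' alignment scores (primary sequence under BLOSUM62; secondary structure
#' over \{H,E,C\} from supplied strings or the built-in stand-in predictor),
#' Euclidean composition distances (dipeptide, tripeptide, physico-chemical),
#' and the site-similarity measure (the hit's residue identity as a fraction,
#' when available). Scores are combined with \code{\link{combineBayesian}};
#' empirical P-values are attached to the sequence-based features (never to
#' the chemical properties; site similarity is taken from the hit statistics
#' and carries none either).
#'
#' @param hit one hit: a single-row \code{\link{HitTable-class}} or a list
#'   with \code{q_start}, \code{q_end}, \code{s_start}, \code{s_end} and
#'   optionally \code{identity_pct}, \code{query_id}, \code{domain_id}.
#' @param querySeq the full query protein sequence.
#' @param ref the reference entry: a \code{\link{DomainSet-class}} containing
#'   the hit's domain (with consensus).
#' @param secondaryQuery,secondaryRef optional 3-state strings for the full
#'   query and the full consensus; when absent and
#'   \code{control$useSsPredictor} is TRUE the stand-in predictor is used.
#' @param control see \code{\link{featureControl}}.
#' @return a \code{\link{FeatureScores-class}}.
#' @export
scoreHit <- function(hit, querySeq, ref, secondaryQuery = NULL,
                     secondaryRef = NULL, control = featureControl()) {
  if (is(hit, "HitTable")) {
    stopifnot(nHits(hit) == 1L)
    hit <- as.list(hitData(hit)[1L, ])
  }
  stopifnot(is(ref, "DomainSet"))
  domain_id <- hit$domain_id %||% domainIds(ref)[1]
  cons <- consensusOf(ref, domain_id)
  if (is.na(cons)) {
    stop(structure(class = c("scoringUnavailable", "error", "condition"),
                   list(message = paste0("no consensus available for domain '",
                                         domain_id, "'; hit left unscored"),
                        call = NULL)))
  }
  querySeq <- toupper(as.character(querySeq))
  if (hit$q_end > nchar(querySeq)) {
    .stop_input("hit coordinates exceed the query sequence length")
  }
  region <- substr(querySeq, hit$q_start, hit$q_end)
  frag <- substr(cons, hit$s_start, min(hit$s_end, nchar(cons)))

  scores <- setNames(rep(NA_real_, length(.FEATURE_NAMES)), .FEATURE_NAMES)

  cq <- chemicalProps(region)
  cr <- chemicalProps(frag)
  scores["chem_mass"] <- .chem_score(cq$mass, cr$mass)
  scores["chem_pka"] <- .chem_score(cq$meanPka, cr$meanPka)
  scores["chem_pi"] <- .chem_score(cq$pI, cr$pI)

  aln_fun <- function(s, r) {
    nwAlign(s, r, gapOpen = control$gapOpen,
            gapExtend = control$gapExtend)$normalized
  }
  scores["aln_primary"] <- aln_fun(region, frag)

  ss_fun <- NULL
  if (!is.null(secondaryQuery) && !is.null(secondaryRef)) {
    ssq <- substr(secondaryQuery, hit$q_start, hit$q_end)
    ssr <- substr(secondaryRef, hit$s_start, min(hit$s_end, nchar(secondaryRef)))
    scores["aln_secondary"] <- ssAlign(ssq, ssr)$normalized
    # null model: shuffle the observed 3-state string alongside the region
    ss_fun <- function(s, r) ssAlign(s, ssr)$normalized
    ss_region <- ssq
  } else if (isTRUE(control$useSsPredictor)) {
    ssr <- predictSecondary(frag)
    scores["aln_secondary"] <- ssAlign(predictSecondary(region), ssr)$normalized
    ss_fun <- function(s, r) ssAlign(predictSecondary(s), ssr)$normalized
    ss_region <- region
  }

  di_fun <- function(s, r) distanceScore(compositionVector(s, 2),
                                         compositionVector(r, 2))$score
  tri_fun <- function(s, r) distanceScore(compositionVector(s, 3),
                                          compositionVector(r, 3))$score
  pc_fun <- function(s, r) distanceScore(physchemComposition(s),
                                         physchemComposition(r))$score
  if (nchar(region) >= 2L && nchar(frag) >= 2L) {
    scores["dist_dipeptide"] <- di_fun(region, frag)
  }
  if (nchar(region) >= 3L && nchar(frag) >= 3L) {
    scores["dist_tripeptide"] <- tri_fun(region, frag)
  }
  scores["dist_physchem"] <- pc_fun(region, frag)

  idp <- hit$identity_pct %||% NA_real_
  if (!is.na(idp)) scores["site_similarity"] <- idp / 100

  combined <- combineBayesian(scores)

  pvalues <- numeric(0)
  if (isTRUE(control$computePvalues)) {
    pfuns <- list(aln_primary = aln_fun, dist_dipeptide = di_fun,
                  dist_tripeptide = tri_fun, dist_physchem = pc_fun)
    pv <- c()
    k <- 0L
    for (nm in names(pfuns)) {
      if (is.na(scores[[nm]])) next
      k <- k + 1L
      pv[nm] <- empiricalPvalue(scores[[nm]], pfuns[[nm]], region, frag,
                                nShuffles = control$nShuffles,
                                seed = control$seed + k)
    }
    if (!is.na(scores[["aln_secondary"]]) && !is.null(ss_fun)) {
      pv["aln_secondary"] <- empiricalPvalue(scores[["aln_secondary"]], ss_fun,
                                             ss_region, frag,
                                             nShuffles = control$nShuffles,
                                             seed = control$seed + k + 1L)
    }
    pvalues <- pv
  }

  new("FeatureScores",
      queryId = as.character(hit$query_id %||% NA_character_),
      domainId = as.character(domain_id),
      scores = scores, combined = combined, pvalues = pvalues)
}

#' Score all candidate hits
#'
#' Applies \code{\link{scoreHit}} to every hit of a filtered table. Hits on
#' consensus-free reference entries are reported unscored (one warning);
#' the pipeline continues.
#'
#' @param hits a \code{\link{HitTable-class}} (typically the filter output).
#' @param queries named character vector or \code{Biostrings::AAStringSet} of
#'   query protein sequences.
#' @param domains a \code{\link{DomainSet-class}} with consensus sequences.
#' @param control see \code{\link{featureControl}}.
#' @return data.frame with one row per hit: identifiers, \code{scored} flag,
#'   the nine feature scores, \code{combined}, and \code{p_}-prefixed
#'   P-value columns.
#' @export
scoreCandidates <- function(hits, queries, domains,
                            control = featureControl()) {
  stopifnot(is(hits, "HitTable"), is(domains, "DomainSet"))
  if (is(queries, "AAStringSet")) {
    queries <- setNames(as.character(queries), names(queries))
  }
  h <- hitData(hits)
  pcols <- paste0("p_", c("aln_primary", "aln_secondary", "dist_dipeptide",
                          "dist_tripeptide", "dist_physchem"))
  out <- data.frame(query_id = h$query_id, domain_id = h$domain_id,
                    scored = FALSE, stringsAsFactors = FALSE)
  for (nm in .FEATURE_NAMES) out[[nm]] <- NA_real_
  out$combined <- NA_real_
  for (nm in pcols) out[[nm]] <- NA_real_
  n_unscored <- 0L
  for (i in seq_len(nrow(h))) {
    qid <- h$query_id[i]
    if (!qid %in% names(queries)) {
      n_unscored <- n_unscored + 1L
      next
    }
    fs <- tryCatch(
      scoreHit(as.list(h[i, ]), queries[[qid]], domains, control = control),
      scoringUnavailable = function(e) NULL)
    if (is.null(fs)) {
      n_unscored <- n_unscored + 1L
      next
    }
    out$scored[i] <- TRUE
    out[i, .FEATURE_NAMES] <- as.list(featureValues(fs))
    out$combined[i] <- combinedScore(fs)
    pv <- featurePvalues(fs)
    for (nm in names(pv)) out[[paste0("p_", nm)]][i] <- pv[[nm]]
  }
  if (n_unscored > 0L) {
    warning(n_unscored, " hit(s) left unscored (missing consensus or query ",
            "sequence)", call. = FALSE)
  }
  out
}
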