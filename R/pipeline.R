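# End-to-end runner and result classification. Every stage writes its table
# so any stage can be re-entered from disk.

#' Classify candidate proteins by result-classification keywords
#'
#' A protein is listed under every keyword that matches the annotations of
#' any of its passing hits' domains (same matching rules as
#' \code{\link{selectDomains}}); proteins matching no keyword are listed
#' under \code{"unclassified"}. Subsets may overlap.
#'
#' @param hits a \code{\link{HitTable-class}} of passing hits.
#' @param domains the \code{\link{DomainSet-class}} the hits refer to.
#' @param keywords a \code{\link{KeywordSpec-class}} or character vector.
#' @return named list of protein-id vectors, one per keyword plus
#'   \code{"unclassified"}.
#' @export
classifyResults <- function(hits, domains, keywords) {
  stopifnot(is(hits, "HitTable"), is(domains, "DomainSet"))
  if (!is(keywords, "KeywordSpec")) keywords <- KeywordSpec(keywords)
  h <- hitData(hits)
  terms <- keywordTerms(keywords)
  dom_terms <- matchingTerms(domains, keywords)
  out <- setNames(vector("list", length(terms) + 1L),
                  c(terms, "unclassified"))
  for (t in seq_along(out)) out[[t]] <- character(0)
  for (qid in unique(h$query_id)) {
    doms <- unique(h$domain_id[h$query_id == qid])
    matched <- unique(unlist(dom_terms[doms]))
    if (length(matched) == 0L) {
      out$unclassified <- c(out$unclassified, qid)
    } else {
      for (t in matched) out[[t]] <- c(out[[t]], qid)
    }
  }
  out
}

#' Read a flat key=value run configuration file
#'
#' Lines of the form \code{key = value}; \code{#} comments and blank lines
#' skipped. Values are returned as strings; \code{\link{runPipeline}} coerces
#' the ones it knows.
#'
#' @param path path to the configuration file.
#' @return named list of strings.
#' @export
readRunConfig <- function(path) {
  .check_file(path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) .stop_input("malformed config line: '", lines[bad][1], "'")
  setNames(lapply(kv, function(m) trimws(m[3])),
           vapply(kv, function(m) trimws(m[2]), character(1)))
}

.provenance <- function(seed, params) {
  paste0("DomainSifter ", as.character(utils::packageVersion("DomainSifter")),
         "; seed=", seed, "; min_coverage=", params@minCoverage,
         "; min_similarity=", params@minSimilarity)
}

.write_kv_table <- function(df, path, provenance) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", provenance), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    write.table(format(df, digits = 17, scientific = NA, trim = TRUE), con,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes reference-domain selection, hit acquisition (external-dialect
#' tables and/or the internal scanner), statistics, cut-off filtering,
#' per-protein candidate selection, feature scoring, result classification
#' and — when truth labels are supplied — performance assessment. Every
#' stage's table is written under \code{outDir} so any stage can be
#' re-entered from its file; rerunning with an identical configuration and
#' seed reproduces the outputs byte for byte.
#'
#' @param queries path to the query FASTA, or a named character vector /
#'   \code{AAStringSet}.
#' @param domains path to a domain table TSV, or a
#'   \code{\link{DomainSet-class}}.
#' @param keywords domain-selection keywords (\code{\link{KeywordSpec-class}},
#'   character vector, or path to a keyword file); NULL keeps all domains.
#' @param outDir output directory (created).
#' @param rpsblastTable,interproscanTable optional paths to hit tables in the
#'   two external dialects.
#' @param useScanner run the internal profile scanner over the reference
#'   domains' consensus sequences (default TRUE when no hit table is given).
#' @param params a \code{\link{FilterParams-class}}.
#' @param classifyKeywords optional result-classification keywords.
#' @param labels optional named logical vector of true labels (or a
#'   2-column TSV path: protein_id, label) for assessment.
#' @param seed integer seed governing all randomness (scanner nulls,
#'   P-value shuffles).
#' @param control feature-scoring options, see \code{\link{featureControl}}.
#' @param scanEvalue scanner empirical E-value threshold.
#' @param scanShuffles shuffles for the scanner's empirical null.
#' @param verbose print stage progress to standard error.
#' @return list with the stage outputs (\code{referenceSet}, \code{hits},
#'   \code{candidates}, \code{proteins}, \code{scores},
#'   \code{classification}, \code{metrics} or NULL, and \code{files}).
#' @export
runPipeline <- function(queries, domains, keywords = NULL, outDir,
                        rpsblastTable = NULL, interproscanTable = NULL,
                        useScanner = is.null(rpsblastTable) &&
                          is.null(interproscanTable),
                        params = FilterParams(), classifyKeywords = NULL,
                        labels = NULL, seed = 1L,
                        control = featureControl(seed = seed),
                        scanEvalue = 0.01, scanShuffles = 200L,
                        verbose = FALSE) {
  say <- function(...) if (verbose) message("[DomainSifter] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  if (is.character(queries) && length(queries) == 1L && file.exists(queries)) {
    queries <- Biostrings::readAAStringSet(queries)
  }
  if (is(queries, "AAStringSet")) {
    queries <- setNames(as.character(queries),
                        sub("\\s.*$", "", names(queries)))
  }
  if (is.character(domains) && length(domains) == 1L) {
    domains <- stage("refdomains", readDomainTable(domains))
  }
  prov <- .provenance(seed, params)

  say("selecting reference domains")
  refSet <- stage("refdomains", {
    if (is.null(keywords)) {
      domains
    } else {
      if (is.character(keywords) && length(keywords) == 1L &&
          file.exists(keywords)) {
        keywords <- readKeywords(keywords)
      }
      selectDomains(domains, keywords)
    }
  })
  files <- c(reference = file.path(outDir, "reference_domains.tsv"))
  writeDomainTable(refSet, files[["reference"]], provenance = prov)

  say("acquiring hits")
  hits <- stage("ingest", {
    parts <- list()
    if (!is.null(rpsblastTable)) {
      parts <- c(parts, list(hitData(readRpsblastHits(rpsblastTable))))
    }
    if (!is.null(interproscanTable)) {
      parts <- c(parts, list(hitData(readInterproscanHits(interproscanTable))))
    }
    if (isTRUE(useScanner)) {
      e <- entryData(refSet)
      e <- e[!is.na(e$consensus), , drop = FALSE]
      profiles <- lapply(seq_len(nrow(e)), function(i) {
        buildProfile(e$consensus[i], domainId = e$domain_id[i])
      })
      parts <- c(parts, list(hitData(
        scanProteins(profiles, queries, seed = seed, maxEvalue = scanEvalue,
                     nShuffles = scanShuffles))))
    }
    parts <- parts[vapply(parts, nrow, integer(1)) > 0L]
    if (length(parts) == 0L) .as_hittable(list()) else
      new("HitTable", hits = do.call(rbind, parts))
  })
  hits <- stage("ingest", computeHitStats(hits, domains))
  files[["hits"]] <- file.path(outDir, "hits.tsv")
  writeHitTable(hits, files[["hits"]], provenance = prov)

  say("filtering ", nHits(hits), " hits")
  candidates <- stage("filtering", filterHits(hits, params, refSet))
  files[["candidates"]] <- file.path(outDir, "candidates.tsv")
  writeHitTable(candidates, files[["candidates"]], provenance = prov)
  proteins <- selectProteins(candidates)
  prot_tab <- data.frame(
    query_id = names(proteins),
    n_hits = vapply(proteins, nrow, integer(1)),
    best_evalue = vapply(proteins, function(d) d$evalue[1], numeric(1)),
    best_coverage_pct = vapply(proteins, function(d) max(d$coverage_pct),
                               numeric(1)),
    stringsAsFactors = FALSE)
  files[["proteins"]] <- file.path(outDir, "candidate_proteins.tsv")
  .write_kv_table(prot_tab, files[["proteins"]], prov)

  say("feature scoring ", nHits(candidates), " candidate hits")
  scores <- stage("features", suppressWarnings(
    scoreCandidates(candidates, queries, domains, control = control)))
  files[["scores"]] <- file.path(outDir, "scored.tsv")
  .write_kv_table(scores, files[["scores"]], prov)

  classification <- NULL
  if (!is.null(classifyKeywords)) {
    say("classifying results")
    classification <- stage("classify",
                            classifyResults(candidates, domains,
                                            classifyKeywords))
    cls_tab <- data.frame(
      keyword = rep(names(classification), lengths(classification)),
      query_id = unlist(classification, use.names = FALSE),
      stringsAsFactors = FALSE)
    files[["classification"]] <- file.path(outDir, "classification.tsv")
    .write_kv_table(cls_tab, files[["classification"]], prov)
  }

  metrics <- NULL
  if (!is.null(labels)) {
    say("assessing against labels")
    metrics <- stage("assess", {
      if (is.character(labels) && length(labels) == 1L) {
        lt <- read.table(labels, sep = "\t", header = FALSE,
                         comment.char = "#", stringsAsFactors = FALSE)
        labels <- setNames(as.logical(lt[[2]]), lt[[1]])
      }
      predicted <- names(queries) %in% names(proteins)
      truth <- labels[names(queries)]
      counts <- ConfusionCounts(tp = sum(predicted & truth),
                                fp = sum(predicted & !truth),
                                tn = sum(!predicted & !truth),
                                fn = sum(!predicted & truth))
      list(counts = counts, metrics = classMetrics(counts))
    })
    mv <- metricsVector(metrics$metrics, digits = 2)
    met_tab <- data.frame(metric = c(names(confusionVector(metrics$counts)),
                                     names(mv)),
                          value = c(unname(confusionVector(metrics$counts)),
                                    unname(mv)))
    files[["metrics"]] <- file.path(outDir, "metrics.tsv")
    .write_kv_table(met_tab, files[["metrics"]], prov)
  }

  files[["log"]] <- file.path(outDir, "run.log")
  writeLines(c(paste0("# ", prov),
               paste0("queries: ", length(queries)),
               paste0("reference_domains: ", nrow(entryData(refSet))),
               paste0("hits: ", nHits(hits)),
               paste0("candidate_hits: ", nHits(candidates)),
               paste0("candidate_proteins: ", length(proteins))),
             files[["log"]])
  say("done")
  list(referenceSet = refSet, hits = hits, candidates = candidates,
       proteins = proteins, scores = scores, classification = classification,
       metrics = metrics, files = files)
}
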