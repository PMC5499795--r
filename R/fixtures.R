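# Synthetic-data generator: labeled protein sets with planted domain copies
# at controlled divergence, plus hit tables in both external dialects. This
# is the desk-scale test bed for the whole pipeline.

#' Fixture generator configuration
#'
#' Study conditions for the synthetic labeled set: 50 positives and 50
#' negatives, protein lengths uniform in 150-250 residues, 10\% residue
#' substitution in the planted copy, no indels, uniform residue background.
#'
#' @param nPositive,nNegative class sizes (defaults 50 / 50).
#' @param lengthRange integer length-2 range of protein lengths.
#' @param substitutionRate per-residue substitution probability in the
#'   planted copy, in [0, 1] (default 0.1).
#' @param indelRate per-residue probability of a single-residue indel event
#'   in the planted copy, in [0, 1] (default 0).
#' @param seed integer seed; all generator randomness flows from it.
#' @param background residue background frequencies (default uniform 1/20).
#' @return a list of class \code{fixtureConfig}.
#' @export
fixtureConfig <- function(nPositive = 50L, nNegative = 50L,
                          lengthRange = c(150L, 250L),
                          substitutionRate = 0.1, indelRate = 0,
                          seed = 1L, background = rep(1 / 20, 20)) {
  stopifnot(nPositive >= 0L, nNegative >= 0L,
            substitutionRate >= 0, substitutionRate <= 1,
            indelRate >= 0, indelRate <= 1,
            length(lengthRange) == 2L, lengthRange[1] <= lengthRange[2],
            length(background) == 20L)
  structure(list(nPositive = as.integer(nPositive),
                 nNegative = as.integer(nNegative),
                 lengthRange = as.integer(lengthRange),
                 substitutionRate = substitutionRate, indelRate = indelRate,
                 seed = as.integer(seed),
                 background = background / sum(background)),
            class = "fixtureConfig")
}

#' Built-in example domain set
#'
#' Three synthetic domain entries (an RRM-like, a cold-shock-like and a
#' KH-like motif) with fixed consensus sequences and annotations exercising
#' the keyword rules. Purely synthetic: the consensus strings are generated,
#' not database-derived.
#'
#' @return a \code{\link{DomainSet-class}} with consensus present on every
#'   entry.
#' @export
exampleDomainSet <- function() {
  cons <- withSeed(20260921L, vapply(c(70L, 65L, 60L), function(L) {
    paste(sample(AA20, L, replace = TRUE), collapse = "")
  }, character(1)))
  DomainSet(data.frame(
    domain_id = c("synRRM", "synCSD", "synKH"),
    accession = c("SYN001", "SYN002", "SYN003"),
    short_name = c("RRM_syn", "CSD_syn", "KH_syn"),
    description = c("RNA-binding RNA recognition motif, synthetic",
                    "cold shock DNA/RNA-binding domain, synthetic",
                    "KH RNA-binding domain, synthetic"),
    length = c(70L, 65L, 60L),
    consensus = cons,
    go_terms = c("GO:0003723 RNA binding", "GO:0003676 nucleic acid binding",
                 "GO:0003723 RNA binding"),
    stringsAsFactors = FALSE), sourceDb = "synthetic")
}

.sample_background <- function(n, background) {
  paste(sample(AA20, n, replace = TRUE, prob = background), collapse = "")
}

# Mutate a residue string: substitutions to a different residue at
# `subRate`, then single-residue indel events at `indelRate` (insertion or
# deletion with equal probability).
.mutate <- function(seq, subRate, indelRate, background) {
  res <- .split_residues(seq)
  if (subRate > 0) {
    hit <- runif(length(res)) < subRate
    for (i in which(hit)) {
      alt <- setdiff(AA20, res[i])
      res[i] <- sample(alt, 1L, prob = background[match(alt, AA20)])
    }
  }
  if (indelRate > 0) {
    out <- character(0)
    for (i in seq_along(res)) {
      ev <- runif(1)
      if (ev < indelRate / 2) {
        next  # deletion
      } else if (ev < indelRate) {
        out <- c(out, res[i],
                 sample(AA20, 1L, prob = background))  # insertion after i
      } else {
        out <- c(out, res[i])
      }
    }
    res <- out
  }
  paste(res, collapse = "")
}

#' Generate a labeled synthetic protein set
#'
#' Positives are background-sampled proteins carrying exactly one mutated
#' copy of a randomly chosen domain consensus, overwritten at a recorded
#' position; negatives are pure background. Fully reproducible for a fixed
#' seed: the same configuration yields byte-identical sequences and truth
#' table.
#'
#' @param cfg a \code{\link{fixtureConfig}}.
#' @param domains a \code{\link{DomainSet-class}}; every entry must carry a
#'   consensus no longer than the maximum protein length.
#' @return list with \code{sequences} (a \code{Biostrings::AAStringSet}) and
#'   \code{truth} (data.frame: protein_id, label, domain_id, plant_start,
#'   plant_end).
#' @export
generateLabeledSet <- function(cfg, domains = exampleDomainSet()) {
  stopifnot(inherits(cfg, "fixtureConfig"), is(domains, "DomainSet"))
  e <- entryData(domains)
  if (any(is.na(e$consensus))) {
    .stop_input("every domain must carry a consensus sequence")
  }
  if (max(e$length) > cfg$lengthRange[2]) {
    .stop_input("domain of length ", max(e$length),
                " exceeds the maximum protein length ", cfg$lengthRange[2])
  }
  withSeed(cfg$seed, {
    rows <- list()
    seqs <- character(0)
    for (i in seq_len(cfg$nPositive)) {
      d <- e[sample(nrow(e), 1L), ]
      plant <- .mutate(d$consensus, cfg$substitutionRate, cfg$indelRate,
                       cfg$background)
      pl <- nchar(plant)
      L <- max(sample(cfg$lengthRange[1]:cfg$lengthRange[2], 1L), pl)
      base <- .sample_background(L, cfg$background)
      start <- sample(L - pl + 1L, 1L)
      seq <- paste0(substr(base, 1L, start - 1L), plant,
                    substr(base, start + pl, L))
      id <- sprintf("POS%03d", i)
      seqs[id] <- seq
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, label = TRUE, domain_id = d$domain_id,
        plant_start = start, plant_end = start + pl - 1L,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(cfg$nNegative)) {
      L <- sample(cfg$lengthRange[1]:cfg$lengthRange[2], 1L)
      id <- sprintf("NEG%03d", i)
      seqs[id] <- .sample_background(L, cfg$background)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, label = FALSE, domain_id = NA_character_,
        plant_start = NA_integer_, plant_end = NA_integer_,
        stringsAsFactors = FALSE)
    }
    list(sequences = Biostrings::AAStringSet(seqs),
         truth = do.call(rbind, rows))
  })
}

#' Write a fixture set to disk
#'
#' @param fix result of \code{\link{generateLabeledSet}}.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths (fasta, truth),
#'   invisibly.
#' @export
writeFixtureSet <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "proteins.fasta")
  tt <- file.path(dir, "truth.tsv")
  Biostrings::writeXStringSet(fix$sequences, fa)
  con <- file(tt, open = "wt")
  writeLines(paste0("# ", paste(names(fix$truth), collapse = "\t")), con)
  write.table(fix$truth, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(con)
  invisible(c(fasta = fa, truth = tt))
}

# Ungapped position-wise comparison of a planted region with its consensus
# (end-gapping the shorter): identical / positive counts, gap count = length
# difference. Exact for the default indel-free generator.
.plant_stats <- function(region, consensus) {
  rr <- .split_residues(region)
  rc <- .split_residues(consensus)
  n <- min(length(rr), length(rc))
  b62 <- .blosum62()
  idx <- cbind(rr[seq_len(n)], rc[seq_len(n)])
  list(aligned_length = max(length(rr), length(rc)),
       identical = sum(rr[seq_len(n)] == rc[seq_len(n)]),
       positive = sum(b62[idx] > 0),
       gaps = abs(length(rr) - length(rc)),
       s_end = n)
}

#' Emit a synthetic hit table in an external dialect
#'
#' Writes one true hit per positive protein, with statistics computed from
#' the actual mutated region (position-wise comparison against the
#' consensus), plus seeded spurious low-coverage hits on randomly chosen
#' proteins, in either the BLAST-tabular or the InterProScan-style dialect —
#' parseable by the corresponding reader.
#'
#' @param fix result of \code{\link{generateLabeledSet}}.
#' @param domains the \code{\link{DomainSet-class}} used to generate it.
#' @param path output TSV path.
#' @param dialect \code{"rpsblast-like"} or \code{"interproscan-like"}.
#' @param noise expected number of spurious hits per protein (default 0).
#' @param seed integer seed for the spurious hits and synthetic E-values.
#' @return \code{path}, invisibly.
#' @export
emitHitTables <- function(fix, domains = exampleDomainSet(), path,
                          dialect = c("rpsblast-like", "interproscan-like"),
                          noise = 0, seed = 1L) {
  dialect <- match.arg(dialect)
  stopifnot(is(domains, "DomainSet"))
  e <- entryData(domains)
  truth <- fix$truth
  seqs <- setNames(as.character(fix$sequences), names(fix$sequences))

  withSeed(seed, {
    lines <- character(0)
    emit <- function(qid, did, qs, qe, st, ev, bits) {
      if (dialect == "rpsblast-like") {
        pident <- 100 * st$identical / st$aligned_length
        mism <- st$aligned_length - st$identical - st$gaps
        sprintf("%s\t%s\t%.4f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.1f\t%d\t%d",
                qid, did, pident, st$aligned_length, mism,
                as.integer(st$gaps > 0), qs, qe, 1L, st$s_end, ev, bits,
                st$positive, st$gaps)
      } else {
        desc <- e$description[match(did, e$domain_id)]
        sprintf("%s\t-\t%d\tSyntheticScan\t%s\t%s\t%d\t%d\t%.3g\tT\t2026-01-01",
                qid, nchar(seqs[[qid]]), did, desc, qs, qe, ev)
      }
    }
    for (i in which(truth$label)) {
      qid <- truth$protein_id[i]
      did <- truth$domain_id[i]
      cons <- e$consensus[match(did, e$domain_id)]
      region <- substr(seqs[[qid]], truth$plant_start[i], truth$plant_end[i])
      st <- .plant_stats(region, cons)
      ev <- 10^(-runif(1, 10, 30))
      lines <- c(lines, emit(qid, did, truth$plant_start[i],
                             truth$plant_end[i], st, ev, 2 * st$identical))
    }
    if (noise > 0) {
      n_spur <- stats::rpois(1, noise * nrow(truth))
      for (k in seq_len(n_spur)) {
        i <- sample(nrow(truth), 1L)
        qid <- truth$protein_id[i]
        d <- e[sample(nrow(e), 1L), ]
        # short random window: low coverage relative to the reference length
        span <- max(5L, as.integer(round(d$length * runif(1, 0.08, 0.30))))
        Lq <- nchar(seqs[[qid]])
        if (span >= Lq) next
        qs <- sample(Lq - span + 1L, 1L)
        region <- substr(seqs[[qid]], qs, qs + span - 1L)
        st <- .plant_stats(region, substr(d$consensus, 1L, span))
        ev <- runif(1, 0.2, 8)
        lines <- c(lines, emit(qid, d$domain_id, qs, qs + span - 1L, st,
                               ev, st$identical))
      }
    }
    writeLines(lines, path)
  })
  invisible(path)
}
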