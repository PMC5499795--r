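test_that("global alignment matches the memoised recursion oracle", {
  # textbook pair
  got <- nwAlign("HEAGAWGHEE", "PAWHEAE")
  expect_equal(got$raw, oracle_nw("HEAGAWGHEE", "PAWHEAE"))

  set.seed(41)
  for (i in 1:30) {
    a <- random_peptide(sample(1:10, 1))
    b <- random_peptide(sample(1:10, 1))
    expect_equal(nwAlign(a, b)$raw, oracle_nw(a, b), info = paste(a, b))
  }
})

test_that("alignment normalization and degenerate inputs behave as specified", {
  set.seed(42)
  for (i in 1:5) {
    s <- random_peptide(sample(5:20, 1))
    expect_equal(nwAlign(s, s)$normalized, 1)
  }
  # one terminal gap: open + (n-1) * extend
  expect_equal(nwAlign("", "AAAA")$raw, -10 + 3 * -0.5)
  expect_equal(nwAlign("", "AAAA")$normalized, 0)
  expect_error(nwAlign("", ""), "empty")
  expect_error(nwAlign("AB!", "AAA"), "illegal")
  # X is neutral
  expect_equal(nwAlign("AXA", "AXA")$raw,
               2 * DomainSifter:::.blosum62()["A", "A"])
})

test_that("k-peptide composition vectors are normalized frequencies", {
  v <- compositionVector("AA", k = 2)
  expect_equal(unname(v["AA"]), 1)
  expect_equal(sum(v), 1)

  v <- compositionVector("ACDC", k = 2)
  expect_equal(unname(v[c("AC", "CD", "DC")]), rep(1 / 3, 3))

  set.seed(13)
  for (k in 2:3) {
    for (i in 1:10) {
      v <- compositionVector(random_peptide(sample((k + 1):40, 1)), k = k)
      expect_equal(sum(v), 1, tolerance = 1e-12)
      expect_equal(length(v), 20^k)
    }
  }
  expect_error(compositionVector("AC", k = 3), "shorter than k")
})

test_that("physico-chemical composition blocks each sum to one", {
  v <- physchemComposition("DDDD")
  expect_equal(unname(v["grp_acidic"]), 1)
  expect_equal(sum(v[startsWith(names(v), "grp_")]), 1)

  v <- physchemComposition("DK")
  expect_equal(unname(v[c("grp_acidic", "grp_basic")]), c(0.5, 0.5))
  expect_equal(unname(v["trans_acidic_basic"]), 1)

  set.seed(14)
  s <- random_peptide(30)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  grp <- function(x) physchemComposition(x)[startsWith(names(physchemComposition(x)), "grp_")]
  expect_equal(grp(s), grp(perm))
})

test_that("composition distance maps to a (0,1] score", {
  expect_equal(distanceScore(c(0.2, 0.8), c(0.2, 0.8))$score, 1)
  d <- distanceScore(c(1, 0), c(0, 1))
  expect_equal(d$distance, sqrt(2))
  expect_equal(d$score, 1 / (1 + sqrt(2)))
  expect_error(distanceScore(1:3, 1:2), "length")
  set.seed(15)
  for (i in 1:10) {
    s <- distanceScore(runif(8), runif(8))$score
    expect_gt(s, 0); expect_lte(s, 1)
  }
})

test_that("chemical properties match table sums and a grid-scan pI oracle", {
  masses <- local({
    tab <- read.table(system.file("extdata", "residue_masses.tsv",
                                  package = "DomainSifter"),
                      sep = "\t", comment.char = "#")
    setNames(tab[[2]], tab[[1]])
  })
  expect_equal(chemicalProps("G")$mass, masses[["G"]] + 18.01524)
  expect_equal(chemicalProps("GAV")$mass,
               sum(masses[c("G", "A", "V")]) + 18.01524)
  expect_lt(chemicalProps("D")$pI, chemicalProps("K")$pI)
  expect_equal(chemicalProps("DE")$meanPka, (3.9 + 4.1) / 2)

  # independent fine-grid scan for the zero-charge pH
  pka <- read.table(system.file("extdata", "pka_scale.tsv",
                                package = "DomainSifter"),
                    sep = "\t", comment.char = "#",
                    col.names = c("group", "pka", "sign"))
  grid_pi <- function(seq) {
    res <- strsplit(seq, "")[[1]]
    charge <- function(pH) {
      q <- 0
      for (r in seq_len(nrow(pka))) {
        g <- pka$group[r]
        n <- if (g %in% c("Nterm", "Cterm")) 1 else sum(res == g)
        if (n == 0) next
        q <- q + if (pka$sign[r] > 0) n / (1 + 10^(pH - pka$pka[r])) else
          -n / (1 + 10^(pka$pka[r] - pH))
      }
      q
    }
    grid <- seq(0, 14, by = 0.001)
    grid[which.min(abs(vapply(grid, charge, numeric(1))))]
  }
  set.seed(16)
  for (i in 1:6) {
    s <- random_peptide(sample(5:30, 1))
    expect_equal(chemicalProps(s)$pI, grid_pi(s), tolerance = 0.01)
  }
})

test_that("Bayesian combination is symmetric, monotone and clamped", {
  expect_equal(combineBayesian(c(0.5, 0.5, 0.5)), 0.5)
  expect_equal(combineBayesian(c(0.9, 0.8, 0.7)),
               (0.9 * 0.8 * 0.7) / (0.9 * 0.8 * 0.7 + 0.1 * 0.2 * 0.3))
  expect_gte(combineBayesian(rep(1, 3)), 1 - 1e-5)
  expect_lte(combineBayesian(rep(0, 3)), 1e-5)
  expect_equal(combineBayesian(c(0.2, 0.9, 0.6)),
               combineBayesian(c(0.9, 0.6, 0.2)))
  set.seed(18)
  for (i in 1:10) {
    s <- runif(4)
    j <- sample(4, 1)
    s2 <- s; s2[j] <- min(1, s[j] + 0.1)
    expect_gt(combineBayesian(s2), combineBayesian(s))
  }
  expect_equal(combineBayesian(c(NA, 0.5, NA)), 0.5)
  expect_error(combineBayesian(NA_real_), "no feature scores")
})

test_that("empirical P-values are exact counts, bounded and reproducible", {
  # stat that no shuffle can beat
  p <- empiricalPvalue(2, function(s, r) 0.5, "ACDEFG", "ACDEFG",
                       nShuffles = 19, seed = 1)
  expect_equal(p, 1 / 20)
  # stat that every shuffle ties or beats
  p <- empiricalPvalue(0.5, function(s, r) 0.5, "ACDEFG", "ACDEFG",
                       nShuffles = 19, seed = 1)
  expect_equal(p, 1)

  # recount oracle: capture the null sample and recount it
  seen <- new.env(); seen$null <- numeric(0)
  stat <- function(s, r) nwAlign(s, r)$normalized
  rec <- function(s, r) { v <- stat(s, r); seen$null <- c(seen$null, v); v }
  obs <- stat("GAVLIMF", "GAVLIMW")
  p <- empiricalPvalue(obs, rec, "GAVLIMF", "GAVLIMW",
                       nShuffles = 50, seed = 7)
  expect_equal(p, (1 + sum(seen$null >= obs)) / 51)
  expect_equal(p, empiricalPvalue(obs, stat, "GAVLIMF", "GAVLIMW",
                                  nShuffles = 50, seed = 7))
  expect_gt(p, 0); expect_lte(p, 1)
})

test_that("scoring an identical region yields a near-perfect profile", {
  ds <- exampleDomainSet()
  cons <- consensusOf(ds, "synCSD")
  L <- nchar(cons)
  query <- paste0("MKT", cons, "GGS")
  hit <- list(query_id = "Q1", domain_id = "synCSD", q_start = 4L,
              q_end = 3L + L, s_start = 1L, s_end = L, identity_pct = 100)
  fs <- scoreHit(hit, query, ds, control = featureControl(nShuffles = 20))
  sc <- featureValues(fs)
  expect_equal(unname(sc[c("aln_primary", "aln_secondary", "dist_dipeptide",
                           "dist_tripeptide", "dist_physchem",
                           "site_similarity")]),
               rep(1, 6))
  expect_gt(combinedScore(fs), 0.99)
  pv <- featurePvalues(fs)
  expect_true(all(pv > 0 & pv <= 1))
  expect_false(any(startsWith(names(pv), "chem_")))
})

test_that("substituted regions score strictly below the identical region", {
  ds <- exampleDomainSet()
  cons <- consensusOf(ds, "synRRM")
  L <- nchar(cons)
  set.seed(19)
  res <- strsplit(cons, "")[[1]]
  idx <- sample(L, L %/% 2)
  for (i in idx) res[i] <- sample(setdiff(AA20_, res[i]), 1)
  mutated <- paste(res, collapse = "")

  mkhit <- function(region) {
    query <- paste0("MA", region, "GS")
    hit <- list(query_id = "Q", domain_id = "synRRM", q_start = 3L,
                q_end = 2L + L, s_start = 1L, s_end = L,
                identity_pct = 100 * mean(strsplit(region, "")[[1]] ==
                                            strsplit(cons, "")[[1]]))
    scoreHit(hit, query, ds,
             control = featureControl(computePvalues = FALSE))
  }
  perfect <- mkhit(cons)
  worse <- mkhit(mutated)
  nm <- c("aln_primary", "dist_dipeptide", "dist_tripeptide",
          "dist_physchem", "site_similarity")
  expect_true(all(featureValues(worse)[nm] < featureValues(perfect)[nm]))
  expect_lt(combinedScore(worse), combinedScore(perfect))
})

test_that("consensus-free entries degrade gracefully", {
  ds <- DomainSet(data.frame(domain_id = "bare", accession = "a",
                             short_name = "s", description = "d",
                             length = 10L))
  hit <- list(query_id = "Q", domain_id = "bare", q_start = 1L, q_end = 10L,
              s_start = 1L, s_end = 10L, identity_pct = NA_real_)
  expect_error(scoreHit(hit, "ACDEFGHIKL", ds), class = "scoringUnavailable")

  row <- DomainSifter:::.new_hit_row("Q", "rpsblast-like", "bare",
                                     1, 10, 1, 10, 10, 5, 7, 0, 1e-5, 10)
  ht <- new("HitTable", hits = row)
  expect_warning(out <- scoreCandidates(ht, c(Q = "ACDEFGHIKL"), ds),
                 "unscored")
  expect_false(out$scored)
  expect_true(is.na(out$combined))
})

test_that("median combined score degrades monotonically with substitution", {
  ds <- exampleDomainSet()
  cons <- consensusOf(ds, "synKH")
  L <- nchar(cons)
  med <- sapply(c(0, 0.25, 0.5), function(rate) {
    set.seed(100 + round(rate * 100))
    median(replicate(6, {
      res <- strsplit(cons, "")[[1]]
      hitpos <- which(runif(L) < rate)
      for (i in hitpos) res[i] <- sample(setdiff(AA20_, res[i]), 1)
      region <- paste(res, collapse = "")
      hit <- list(query_id = "Q", domain_id = "synKH", q_start = 1L,
                  q_end = L, s_start = 1L, s_end = L,
                  identity_pct = 100 * mean(res == strsplit(cons, "")[[1]]))
      combinedScore(scoreHit(hit, region, ds,
                             control = featureControl(computePvalues = FALSE)))
    }))
  })
  expect_true(all(diff(med) <= 0))
})
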