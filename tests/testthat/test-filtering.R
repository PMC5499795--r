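make_hit <- function(query = "Q", domain = "d", coverage = 50, similarity = 30,
                     identity = 20, evalue = 1e-6, gap = 0) {
  row <- DomainSifter:::.new_hit_row(query, "rpsblast-like", domain,
                                     1, 10, 1, 10, 10, 5, 7, 0, evalue, 10)
  row$coverage_pct <- coverage
  row$similarity_pct <- similarity
  row$identity_pct <- identity
  row$gap_pct <- gap
  row
}

as_ht <- function(...) new("HitTable", hits = do.call(rbind, list(...)))

test_that("default cut-offs pass the Hfq-like hit and enforce boundaries", {
  hfq <- make_hit(coverage = 41.33, similarity = 25.33, identity = 17.33,
                  evalue = 1e-5)
  expect_equal(nHits(filterHits(as_ht(hfq), FilterParams(), "d")), 1L)

  # below-boundary coverage rejected, exact boundary passes
  low <- make_hit(coverage = 38.99, similarity = 100, identity = 100,
                  evalue = 0)
  expect_equal(nHits(filterHits(as_ht(low), FilterParams(), "d")), 0L)
  edge <- make_hit(coverage = 39, similarity = 24)
  expect_equal(nHits(filterHits(as_ht(edge), FilterParams(), "d")), 1L)

  # reference-set membership is required
  expect_equal(nHits(filterHits(as_ht(hfq), FilterParams(), "other")), 0L)

  # unavailable similarity is gated on the remaining parameters
  part <- make_hit(coverage = 80, similarity = NA_real_, identity = NA_real_)
  expect_equal(nHits(filterHits(as_ht(part), FilterParams(), "d")), 1L)
  expect_equal(nHits(filterHits(as_ht(part),
                                FilterParams(maxEvalue = 1e-9), "d")), 0L)
})

test_that("filtering equals a brute-force threshold recheck", {
  set.seed(17)
  rows <- lapply(1:10, function(i) {
    make_hit(query = sprintf("P%d", sample(3, 1)),
             domain = sample(c("d1", "d2", "d3"), 1),
             coverage = runif(1, 0, 100), similarity = runif(1, 0, 100),
             identity = runif(1, 0, 100), evalue = 10^runif(1, -20, 1),
             gap = runif(1, 0, 30))
  })
  ht <- new("HitTable", hits = do.call(rbind, rows))
  params <- FilterParams(minCoverage = 39, minSimilarity = 24,
                         minIdentity = 15, maxEvalue = 0.01, maxGap = 10)
  ref <- c("d1", "d2")
  got <- hitData(filterHits(ht, params, ref))

  h <- hitData(ht)
  keep <- h$domain_id %in% ref & h$coverage_pct >= 39 &
    h$similarity_pct >= 24 & h$identity_pct >= 15 &
    h$evalue <= 0.01 & h$gap_pct <= 10
  expect_equal(got, local({ x <- h[keep, ]; rownames(x) <- NULL; x }))
})

test_that("filtering is anti-monotone and identity when disabled", {
  set.seed(23)
  rows <- lapply(1:20, function(i) {
    make_hit(query = sprintf("P%d", i), domain = "d",
             coverage = runif(1, 0, 100), similarity = runif(1, 0, 100),
             identity = runif(1, 0, 100), evalue = 10^runif(1, -10, 1))
  })
  ht <- new("HitTable", hits = do.call(rbind, rows))
  loose <- filterHits(ht, FilterParams(minCoverage = 30, minSimilarity = 20), "d")
  for (dc in c(10, 25, 40)) {
    tight <- filterHits(ht, FilterParams(minCoverage = 30 + dc,
                                         minSimilarity = 20 + dc / 2), "d")
    expect_true(all(hitData(tight)$query_id %in% hitData(loose)$query_id))
    expect_lte(nHits(tight), nHits(loose))
  }
  # all thresholds disabled + full reference set = identity
  all_off <- FilterParams(minCoverage = NA, minSimilarity = NA)
  expect_equal(hitData(filterHits(ht, all_off, NULL)), hitData(ht))
})

test_that("candidate proteins group passing hits, sorted by significance", {
  rows <- rbind(make_hit("P1", evalue = 1e-3, coverage = 50),
                make_hit("P1", evalue = 1e-8, coverage = 60),
                make_hit("P2", evalue = 1e-4))
  prot <- selectProteins(new("HitTable", hits = rows))
  expect_equal(length(prot), 2L)
  expect_equal(prot$P1$evalue, c(1e-8, 1e-3))

  expect_equal(length(selectProteins(as_ht(make_hit()[0, ]))), 0L)

  # 25 hits over 8 proteins equals a brute-force group-by
  set.seed(5)
  rows <- do.call(rbind, lapply(1:25, function(i) {
    make_hit(sprintf("P%d", sample(8, 1)), evalue = 10^runif(1, -12, 0),
             coverage = runif(1, 0, 100))
  }))
  prot <- selectProteins(new("HitTable", hits = rows))
  expect_setequal(names(prot), unique(rows$query_id))
  expect_equal(sum(vapply(prot, nrow, integer(1))), 25L)
  for (q in names(prot)) {
    expect_equal(nrow(prot[[q]]), sum(rows$query_id == q))
    expect_false(is.unsorted(prot[[q]]$evalue))
  }
})

test_that("merging method candidates reports union/intersection counts", {
  # sizes printed for the E. coli proteome analysis: 673 and 502 with 369 shared
  a <- sprintf("P%04d", 1:673)
  b <- sprintf("P%04d", c(1:369, 674:806))
  m <- mergeMethodCandidates(a, b)
  expect_equal(m$nA, 673L)
  expect_equal(m$nB, 502L)
  expect_equal(m$nIntersection, 369L)
  expect_equal(m$nUnion, 806L)
  expect_equal(m$nUnion, m$nA + m$nB - m$nIntersection)

  d <- mergeMethodCandidates(c("a", "b"), c("x", "y", "z"))
  expect_equal(d$nUnion, 5L)
  expect_equal(d$nIntersection, 0L)

  set.seed(9)
  for (i in 1:10) {
    a <- sample(sprintf("q%03d", 1:120), sample(5:60, 1))
    b <- sample(sprintf("q%03d", 1:120), sample(5:60, 1))
    m <- mergeMethodCandidates(a, b)
    expect_setequal(m$union, union(a, b))
    expect_setequal(m$intersection, intersect(a, b))
    expect_equal(sum(m$members[[2]] & m$members[[3]]), length(intersect(a, b)))
  }
})
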