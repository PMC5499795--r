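test_that("BLAST-tabular hits parse to hand-checked fields", {
  path <- tempfile()
  writeLines("P1\tdom7\t50.00\t100\t48\t2\t10\t109\t1\t100\t1e-20\t80.5\t70\t4",
             path)
  h <- hitData(readRpsblastHits(path))
  expect_equal(nrow(h), 1L)
  expect_equal(h$query_id, "P1")
  expect_equal(h$domain_id, "dom7")
  expect_equal(h$identical, 50L)   # round(50.00 * 100 / 100)
  expect_equal(h$positive, 70L)
  expect_equal(h$gaps, 4L)
  expect_equal(h$q_start, 10L)
  expect_equal(h$s_end, 100L)
  expect_equal(h$evalue, 1e-20)
  expect_equal(h$method, "rpsblast-like")

  # 12-column outfmt: positives/gaps unavailable, not guessed
  writeLines("P1\tdom7\t50.00\t100\t48\t2\t10\t109\t1\t100\t1e-20\t80.5", path)
  h12 <- hitData(readRpsblastHits(path))
  expect_true(is.na(h12$positive) && is.na(h12$gaps))

  writeLines(character(0), path)
  expect_equal(nHits(readRpsblastHits(path)), 0L)

  writeLines("P1\tdom7\t50.00\t100\t48\t2\t10\t109\t1\t100\tn/a\t80.5\t70\t4",
             path)
  expect_error(readRpsblastHits(path), "line 1")
})

test_that("InterProScan-style hits parse as span-based with partial stats", {
  path <- tempfile()
  writeLines(paste("P1", "md5", "200", "CDDlike", "sig1", "a domain", "5",
                   "64", "3.2e-12", "T", "2026-01-01", sep = "\t"), path)
  hits <- readInterproscanHits(path)
  h <- hitData(hits)
  expect_true(h$span_based)
  expect_equal(c(h$q_start, h$q_end), c(5L, 64L))
  expect_equal(c(h$s_start, h$s_end), c(1L, 60L))
  expect_equal(h$evalue, 3.2e-12)

  ds <- DomainSet(data.frame(domain_id = "sig1", accession = "x",
                             short_name = "s", description = "d",
                             length = 60L))
  st <- hitData(computeHitStats(hits, ds))
  expect_equal(st$coverage_pct, 100)           # span 60 over reference 60
  expect_true(st$partial_stats)                # no residue counts
  expect_true(is.na(st$similarity_pct))

  # unknown signature: retained, coverage unavailable, warning raised
  ds2 <- DomainSet(data.frame(domain_id = "other", accession = "x",
                              short_name = "s", description = "d",
                              length = 60L))
  expect_warning(st2 <- computeHitStats(hits, ds2), "unknown")
  expect_equal(nHits(st2), 1L)
  expect_true(is.na(hitData(st2)$coverage_pct))

  writeLines(character(0), path)
  expect_equal(nHits(readInterproscanHits(path)), 0L)
})

test_that("hit statistics use the reference domain length as denominator", {
  ds <- DomainSet(data.frame(
    domain_id = c("csra", "hfq"), accession = c("a", "b"),
    short_name = c("CsrA", "RRM"), description = c("x", "y"),
    length = c(69L, 75L)))
  rows <- rbind(
    DomainSifter:::.new_hit_row("CsrA", "rpsblast-like", "csra",
                                1, 58, 1, 58, 58, 34, 50, 0, 1e-20, 80),
    DomainSifter:::.new_hit_row("Hfq", "rpsblast-like", "hfq",
                                1, 31, 1, 31, 31, 13, 19, 0, 1e-5, 40))
  st <- hitData(computeHitStats(new("HitTable", hits = rows), ds))
  expect_equal(round(st$coverage_pct, 2), c(84.06, 41.33))   # 58/69, 31/75
  expect_equal(round(st$similarity_pct, 2), c(72.46, 25.33)) # 50/69, 19/75
  expect_equal(round(st$identity_pct, 2), c(49.28, 17.33))   # 34/69, 13/75

  # full-length exact match
  full <- DomainSifter:::.new_hit_row("Q", "rpsblast-like", "csra",
                                      1, 69, 1, 69, 69, 69, 69, 0, 0, 120)
  stf <- hitData(computeHitStats(new("HitTable", hits = full), ds))
  expect_equal(c(stf$coverage_pct, stf$similarity_pct, stf$identity_pct,
                 stf$gap_pct), c(100, 100, 100, 0))

  # subject end beyond the reference is a coordinate error
  bad <- DomainSifter:::.new_hit_row("Q", "rpsblast-like", "csra",
                                     1, 70, 1, 70, 70, 10, 10, 0, 0, 1)
  expect_error(computeHitStats(new("HitTable", hits = bad), ds),
               "exceeds reference length")
})

test_that("consistent random hits satisfy the percentage bounds", {
  set.seed(31)
  for (i in 1:25) {
    L <- sample(40:90, 1)
    span <- sample(10:L, 1)
    s_start <- sample(L - span + 1L, 1)
    alen <- span
    pos <- sample(0:alen, 1)
    ident <- sample(0:pos, 1)
    ds <- DomainSet(data.frame(domain_id = "d", accession = "a",
                               short_name = "s", description = "x",
                               length = L))
    row <- DomainSifter:::.new_hit_row("q", "rpsblast-like", "d",
                                       1, span, s_start, s_start + span - 1L,
                                       alen, ident, pos, 0, 1e-3, 10)
    st <- hitData(computeHitStats(new("HitTable", hits = row), ds))
    expect_lte(st$identity_pct, st$similarity_pct)
    expect_lte(st$similarity_pct, 100)
    expect_lte(st$coverage_pct, 100)
  }
})

test_that("the unified hit TSV round-trips parsed hits exactly", {
  path <- tempfile()
  writeLines(c("P1\tdom7\t50.00\t100\t48\t2\t10\t109\t1\t100\t1e-20\t80.5\t70\t4",
               "P2\tdom8\t80.00\t60\t12\t0\t3\t62\t1\t60\t5e-8\t55.1\t55\t0"),
             path)
  ds <- DomainSet(data.frame(domain_id = c("dom7", "dom8"),
                             accession = c("a", "b"),
                             short_name = c("s1", "s2"),
                             description = c("x", "y"),
                             length = c(100L, 60L)))
  hits <- computeHitStats(readRpsblastHits(path), ds)
  out <- tempfile()
  writeHitTable(hits, out)
  back <- readHitTable(out)
  expect_equal(hitData(back), hitData(hits), tolerance = 1e-12)
})
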