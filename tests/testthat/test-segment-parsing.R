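test_that("perfect stripes are classified with the full support strength", {
  ## antiparallel: all pairs on i + j = 40
  i <- 10:15
  cs <- contactSetFromPairs(i, 40L - i, rep(0.9, 6), 60)
  e_sum <- sum(contactPairs(cs)$e)
  f <- orientationFit(cs, c(8, 17), c(22, 32))
  expect_equal(f$orientation, "antiparallel")
  expect_equal(f$strength_anti, e_sum, tolerance = 1e-12)
  expect_lt(f$strength_par, f$strength_anti)
  ## parallel: all pairs on j - i = 25
  cs2 <- contactSetFromPairs(i, i + 25L, rep(0.9, 6), 60)
  f2 <- orientationFit(cs2, c(8, 17), c(33, 42))
  expect_equal(f2$orientation, "parallel")
  expect_equal(f2$strength_par, sum(contactPairs(cs2)$e))
})

test_that("orientation fit ignores segment argument order and thin blocks", {
  cs <- randomContactSet(L = 60, n = 30, seed = 2)
  f_ab <- orientationFit(cs, c(5, 15), c(30, 45))
  f_ba <- orientationFit(cs, c(30, 45), c(5, 15))
  expect_equal(f_ab, f_ba)
  ## fewer than min_support contacts -> none
  one <- contactSetFromPairs(c(10, 11), c(30, 29), c(0.9, 0.8), 60)
  f1 <- orientationFit(one, c(8, 14), c(26, 33))
  expect_equal(f1$orientation, "none")
  expect_equal(f1$n_support, 2L)
})

test_that("noisy hairpin strengths match a brute-force stripe evaluation", {
  b <- makeBundle(bundleSpec(n_helices = 2, bundle_radius = 5))
  oc <- oracleContacts(b$trace, cutoff = 9, rank_noise = 0.2, seed = 5)
  s <- segmentTable(b$segments)
  f <- orientationFit(oc, c(s$start[1], s$end[1]), c(s$start[2], s$end[2]))
  expect_equal(f$orientation, "antiparallel")
  ## independent evaluation: scan every kink candidate of both models
  p <- contactPairs(oc)
  inb <- p$i >= s$start[1] & p$i <= s$end[1] &
         p$j >= s$start[2] & p$j <= s$end[2]
  strength <- function(d, e, w = 4) {
    best <- 0
    for (c0 in c(d, d - w, d + w)) {
      v <- sum(e * pmax(0, 1 - abs(d - c0) / w))
      if (v > best) best <- v
    }
    best
  }
  expect_equal(f$strength_par,
               strength(p$j[inb] - p$i[inb], p$e[inb]))
  expect_equal(f$strength_anti,
               strength(p$i[inb] + p$j[inb], p$e[inb]))
})

test_that("zero shift reproduces the plain per-pair fits", {
  b <- defaultBundle()
  oc <- oracleContacts(b$trace, cutoff = 8, rank_noise = 0.1, seed = 3)
  pr <- parseContactMap(oc, b$segments)
  expect_equal(segmentTable(adjustedSegments(pr))[, c("start", "end")],
               segmentTable(b$segments)[, c("start", "end")])
  s <- segmentTable(b$segments)
  tot <- 0
  for (a in 1:3) for (bb in (a + 1):4) {
    f <- orientationFit(oc, c(s$start[a], s$end[a]),
                        c(s$start[bb], s$end[bb]))
    if (f$orientation != "none")
      tot <- tot + max(f$strength_par, f$strength_anti)
  }
  expect_equal(totalFit(pr), tot)
})

test_that("boundary shifts recover truncated helices and increase the fit", {
  b <- defaultBundle()
  oc <- oracleContacts(b$trace, cutoff = 8, rank_noise = 0, seed = 1)
  s <- segmentTable(b$segments)
  shrunk <- tmbundle:::newSegmentSet(s$start + 3L, s$end - 3L,
                                     s$n_term_side)
  pr0 <- parseContactMap(oc, shrunk)
  pr <- optimizeBoundaries(oc, shrunk, max_shift = 3L)
  expect_gt(totalFit(pr), totalFit(pr0))
  adj <- segmentTable(adjustedSegments(pr))
  ## every boundary moves back toward the true segment
  expect_true(all(adj$start <= s$start + 3L))
  expect_true(all(adj$end >= s$end - 3L))
})

test_that("the DP equals exhaustive enumeration on random 3-helix instances", {
  for (seed in 1:10) {
    inst <- randomParsingInstance(seed)
    shift <- 1L + seed %% 2L
    dp <- optimizeBoundaries(inst$contacts, inst$segments,
                             max_shift = shift)
    br <- bruteBoundaryOracle(inst$contacts, inst$segments, shift)
    adj <- segmentTable(adjustedSegments(dp))
    expect_equal(totalFit(dp), br$tot, tolerance = 1e-9,
                 label = paste("fit, seed", seed))
    expect_equal(adj$start, br$ns, label = paste("starts, seed", seed))
    expect_equal(adj$end, br$ne, label = paste("ends, seed", seed))
  }
})

test_that("total fit never decreases with a larger shift allowance", {
  for (seed in c(3, 8)) {
    inst <- randomParsingInstance(seed)
    fits <- vapply(0:2, function(ms)
      totalFit(optimizeBoundaries(inst$contacts, inst$segments,
                                  max_shift = ms)), numeric(1))
    expect_true(all(diff(fits) >= -1e-12))
  }
})

test_that("packing graph reports hairpin topology without spurious edges", {
  ## two hairpins (1+2, 3+4) plus a 1-4 closure, encoded as stripes
  blocks <- list(c(1, 2), c(3, 4), c(1, 4))
  segs <- tmbundle:::newSegmentSet(c(5L, 25L, 45L, 65L),
                                  c(15L, 35L, 55L, 75L), "unknown")
  s <- segmentTable(segs)
  i <- c(); j <- c()
  for (bl in blocks) {
    a <- bl[1]; bb <- bl[2]
    ii <- s$start[a]:(s$start[a] + 5L)
    i <- c(i, ii); j <- c(j, s$end[bb] - (ii - s$start[a]))
  }
  cs <- contactSetFromPairs(i, j, seq(0.9, 0.5, length.out = length(i)),
                            80)
  pr <- parseContactMap(cs, segs)
  g <- packingGraph(pr)
  el <- igraph::as_edgelist(g)
  got <- sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  expect_equal(got, sort(c("1 2", "3 4", "1 4")))
  expect_true(all(igraph::E(g)$orientation == "antiparallel"))
  expect_match(packingSummary(pr), "1-2 anti")
  ## empty parse -> empty graph
  empty <- parseContactMap(contactSetFromPairs(1, 10, 0.5, 80), segs)
  expect_equal(igraph::ecount(packingGraph(empty)), 0)
})
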