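test_that("CASP-RR parsing assigns ranks by descending score and swaps i > j", {
  tf <- withr::local_tempfile(fileext = ".rr")
  writeLines(c("PFRMAT RR", "1 10 0 8 0.9", "2 12 0 8 0.5",
               "3 14 0 8 0.7", "12 4 0 8 0.3", "END"), tf)
  cs <- readContactList(tf, "casp_rr", length = 20)
  p <- contactPairs(cs)
  expect_equal(p$rank[match(paste(p$i, p$j), c("1 10", "2 12", "3 14"))][1:3],
               c(1L, 3L, 2L))
  expect_true(all(p$i < p$j))
  expect_true(any(p$i == 4L & p$j == 12L))  # (12, 4) stored swapped
})

test_that("all dialect readers agree on the same pairs", {
  d <- data.frame(i = c(2L, 5L, 9L), j = c(20L, 30L, 40L),
                  p = c(0.8, 0.6, 0.9))
  f_rr <- withr::local_tempfile(); f_ps <- withr::local_tempfile()
  f_gr <- withr::local_tempfile(); f_ev <- withr::local_tempfile()
  writeLines(sprintf("%d %d 0 8 %.3f", d$i, d$j, d$p), f_rr)
  writeLines(sprintf("%d %d 0 8 %.3f", d$i, d$j, d$p), f_ps)
  writeLines(c("i\tj\tscore",
               sprintf("%d\t%d\t%.3f", d$i, d$j, d$p)), f_gr)
  writeLines(c("i,A_i,j,A_j,fn,cn",
               sprintf("%d,A,%d,V,0,%.3f", d$i, d$j, d$p)), f_ev)
  sets <- list(readContactList(f_rr, "casp_rr", length = 50),
               readContactList(f_ps, "psicov", length = 50),
               readContactList(f_gr, "gremlin", length = 50),
               readContactList(f_ev, "evfold", length = 50))
  for (cs in sets[-1L])
    expect_equal(contactPairs(cs)[, c("i", "j", "rank")],
                 contactPairs(sets[[1L]])[, c("i", "j", "rank")])
})

test_that("reader errors name the offence", {
  bad <- withr::local_tempfile()
  writeLines(c("1 10 0 8 0.9", "oops not a line 5"), bad)
  expect_error(readContactList(bad, "casp_rr", length = 20), "line 2")
  dup <- withr::local_tempfile()
  writeLines(c("1 10 0 8 0.9", "10 1 0 8 0.5"), dup)
  expect_error(readContactList(dup, "casp_rr", length = 20), "duplicate")
  oob <- withr::local_tempfile()
  writeLines("1 30 0 8 0.9", oob)
  expect_error(readContactList(oob, "casp_rr", length = 20), "exceeds")
})

test_that("write-then-read round-trips a 300-pair oracle set exactly", {
  b <- defaultBundle(bundle_radius = 9)
  oc <- oracleContacts(b$trace, cutoff = 12)
  oc300 <- filterPairs(oc, top_k = 300)
  tf <- withr::local_tempfile(fileext = ".rr")
  writeContactList(oc300, tf)
  back <- rankTransform(readContactList(tf, "casp_rr"))
  expect_equal(proteinLength(back), proteinLength(oc300))
  expect_equal(contactPairs(back)[, c("i", "j", "rank", "e")],
               contactPairs(oc300)[, c("i", "j", "rank", "e")],
               tolerance = 1e-9)
})

test_that("rank transform follows e = exp(-r^2/100L) and preserves order", {
  cs <- contactSetFromPairs(c(1, 2, 3), c(10, 12, 14), c(0.9, 0.5, 0.7),
                            L = 100, transform = FALSE)
  ct <- rankTransform(cs)
  p <- contactPairs(ct)
  expect_equal(p$e, exp(-(p$rank^2) * 0.01 / 100))
  expect_equal(p$e[p$rank == 1L], exp(-1e-4))
  ## order by e must equal order by rank on a larger random set
  big <- randomContactSet(L = 80, n = 40, seed = 3)
  pb <- contactPairs(big)
  expect_equal(order(-pb$e), order(pb$rank))
  expect_error(rankTransform(tmbundle:::newContactSet(0L, "x",
    data.frame(i = integer(), j = integer(), p_raw = numeric(),
               rank = integer(), e = numeric()))))
})

test_that("pairs at or above e = exp(-1) number 10*sqrt(L)", {
  ## ranks r with r^2 * 0.01 / L <= 1, i.e. r <= 10*sqrt(L); the
  ## boundary rank sits exactly at exp(-1) and is counted
  for (L in c(49, 100, 400)) {
    n <- as.integer(11 * sqrt(L))  # more pairs than the threshold count
    ut <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
    ut <- ut[seq_len(n), , drop = FALSE]
    set.seed(L)
    cs <- contactSetFromPairs(ut[, 1L], ut[, 2L], runif(n, 0.1, 1), L)
    expect_equal(sum(contactPairs(cs)$e >= exp(-1)), 10 * sqrt(L))
  }
})

test_that("combining sets sums e, re-ranks, and is permutation invariant", {
  s1 <- contactSetFromPairs(c(1, 2, 3), c(10, 20, 30), c(0.9, 0.8, 0.7), 50)
  s2 <- contactSetFromPairs(c(1, 4, 3), c(10, 25, 30), c(0.9, 0.8, 0.7), 50)
  s3 <- contactSetFromPairs(c(1, 2, 4), c(10, 20, 25), c(0.9, 0.5, 0.4), 50)
  cons <- combineContactSets(list(s1, s2, s3))
  ## brute-force oracle: accumulate e by hand over all pairs
  acc <- new.env()
  for (s in list(s1, s2, s3)) {
    p <- contactPairs(s)
    for (k in seq_len(nrow(p))) {
      key <- paste(p$i[k], p$j[k])
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p$e[k]
    }
  }
  keys <- ls(acc)
  sums <- vapply(keys, function(k) acc[[k]], numeric(1))
  pc <- contactPairs(cons)
  expect_equal(paste(pc$i, pc$j), keys[order(-sums, keys)])
  ## pair ranked 1 everywhere stays rank 1
  expect_equal(pc[pc$rank == 1L, c("i", "j")],
               data.frame(i = 1L, j = 10L), ignore_attr = TRUE)
  ## permutation invariance
  cons2 <- combineContactSets(list(s3, s1, s2))
  expect_equal(contactPairs(cons2), contactPairs(cons))
  ## single input keeps its ordering
  one <- combineContactSets(list(s1))
  expect_equal(contactPairs(one)[, c("i", "j", "rank")],
               contactPairs(s1)[, c("i", "j", "rank")])
  expect_error(combineContactSets(list()), "no contact sets")
  s_bad <- contactSetFromPairs(1, 10, 0.5, 40)
  expect_error(combineContactSets(list(s1, s_bad)), "length")
})

test_that("filtering drops short separations, clamps, and is idempotent", {
  cs <- contactSetFromPairs(c(3, 3), c(6, 20), c(0.9, 0.8), 30)
  f <- filterPairs(cs, min_sep = 8)
  expect_equal(contactPairs(f)[, c("i", "j")],
               data.frame(i = 3L, j = 20L), ignore_attr = TRUE)
  big <- randomContactSet(L = 100, n = 500, seed = 9)
  f300 <- filterPairs(big, min_sep = 5, top_k = 300)
  p <- contactPairs(f300)
  expect_lte(nrow(p), 300)
  expect_true(all(p$j - p$i >= 5))
  expect_equal(contactPairs(filterPairs(f300, min_sep = 5, top_k = 300)),
               contactPairs(f300))
  ## top_k beyond availability returns everything surviving
  few <- filterPairs(cs, min_sep = 0, top_k = 1000)
  expect_equal(nrow(contactPairs(few)), 2L)
})
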