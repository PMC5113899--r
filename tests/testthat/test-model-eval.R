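test_that("pseudo-centroids sit 2 A beyond the outward bisector", {
  ## right-angle toy chain: middle centroid is hand-computable
  tr <- tmbundle:::newCaTrace("toy", 1:3,
                              rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  cen <- centroidCoords(pseudoCentroids(tr))
  expect_equal(cen[2L, ], c(1 + sqrt(2), -sqrt(2), 0), tolerance = 1e-12)
  ## terminals copy their neighbour's offset
  expect_equal(cen[1L, ] - caCoords(tr)[1L, ],
               cen[2L, ] - caCoords(tr)[2L, ])
  ## straight chain: degenerate rule puts centroids on the Ca
  line <- tmbundle:::newCaTrace("line", 1:5,
                                cbind(seq(0, 15.2, 3.8), 0, 0))
  expect_equal(centroidCoords(pseudoCentroids(line)), caCoords(line))
  expect_error(pseudoCentroids(tmbundle:::newCaTrace("tiny", 1:2,
    rbind(c(0, 0, 0), c(3.8, 0, 0)))), "3 residues")
})

test_that("helix centroids point outward from the helix axis", {
  one <- makeBundle(bundleSpec(n_helices = 1))
  tr <- pseudoCentroids(one$trace)
  ## the single helix is centred on (bundle_radius, 0) in xy
  ctr <- one$truth$helix_centers[1L, 1:2]
  r_ca <- sqrt(rowSums(sweep(caCoords(tr)[, 1:2], 2L, ctr)^2))
  r_cen <- sqrt(rowSums(sweep(centroidCoords(tr)[, 1:2], 2L, ctr)^2))
  interior <- 2:(length(r_ca) - 1L)
  expect_true(all(r_cen[interior] > r_ca[interior]))
})

test_that("soft score matches its closed form at the landmark distances", {
  expect_equal(softQ(5, 5), 1)
  expect_equal(softQ(10, 5), exp(-1))
  expect_lt(softQ(10, 5), 0.37)
  expect_equal(softQ(0, 5), exp(-1))
  expect_equal(softQ(15, 5), exp(-4))
  expect_lt(softQ(15, 5), 0.02)
  ## symmetric about the optimum
  expect_equal(softQ(3, 5), softQ(7, 5))
  expect_error(softQ(5, 0), "positive")
  expect_error(softQ(-1, 5))
})

test_that("doubling the spread never lowers q and widens the tolerance", {
  d <- seq(0, 20, 0.25)
  q1 <- softQ(d, 5); q2 <- softQ(d, 10)
  expect_true(all(q2 >= q1))
  expect_true(all(q2[d != 5] > q1[d != 5]))
})

test_that("model scoring honours min_sep, coverage and rigid motions", {
  b <- defaultBundle()
  oc <- oracleContacts(b$trace, cutoff = 8)
  sc <- scoreModel(b$trace, oc)
  expect_gt(as.numeric(sc), 0)
  expect_equal(attr(sc, "coverage"), 1)
  ## a short-separation pair contributes nothing
  near <- contactSetFromPairs(10, 13, 0.9, 95)
  expect_equal(as.numeric(scoreModel(b$trace, near)), 0)
  ## rigid motion invariance
  moved <- transformTrace(b$trace)
  expect_equal(as.numeric(scoreModel(moved, oc)), as.numeric(sc),
               tolerance = 1e-9)
  ## absent residues contribute zero and lower coverage
  keep <- residueIds(b$trace) <= 70L
  part <- tmbundle:::newCaTrace("part", residueIds(b$trace)[keep],
                                caCoords(b$trace)[keep, ])
  scp <- scoreModel(part, oc)
  expect_lt(as.numeric(scp), as.numeric(sc))
  expect_lt(attr(scp, "coverage"), 1)
})

test_that("score decays monotonically with coordinate noise", {
  b <- defaultBundle()
  oc <- oracleContacts(b$trace, cutoff = 8)
  sig <- c(0, 2, 5, 10)
  avg <- vapply(sig, function(s) {
    if (s == 0) return(as.numeric(scoreModel(b$trace, oc)))
    mean(vapply(1:20, function(k)
      as.numeric(scoreModel(makeDecoys(b$trace, b$segments, "noise",
                                       magnitude = s, seed = k), oc)),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(avg) < 0))
})

test_that("the true structure outranks decoys and s/n_top barely matter", {
  b <- defaultBundle()
  sets <- list(oracleContacts(b$trace, 8, 0.1, 21),
               oracleContacts(b$trace, 10, 0.1, 22))
  decoys <- c(lapply(1:6, function(k)
                makeDecoys(b$trace, b$segments, "noise", 5, seed = k)),
              list(makeDecoys(b$trace, b$segments, "stray_helix", 25,
                              helices = 2),
                   makeDecoys(b$trace, b$segments, "swap_helices",
                              helices = c(1, 3))))
  traces <- c(list(b$trace), decoys)
  for (params in list(scoreParams(), scoreParams(s = 2.5),
                      scoreParams(s = 10), scoreParams(n_top = 50),
                      scoreParams(n_top = 200))) {
    tab <- rankModels(traces, sets, params)
    expect_equal(tab$model[1L], modelId(b$trace),
                 label = sprintf("s=%g n_top=%d", params$s, params$n_top))
  }
})

test_that("rank table is deterministic and consistent with scoreModel", {
  b <- defaultBundle()
  oc <- oracleContacts(b$trace, cutoff = 8)
  tab1 <- rankModels(list(b$trace), list(one = oc))
  expect_equal(nrow(tab1), 1L)
  expect_equal(tab1$one, as.numeric(scoreModel(b$trace, oc)))
  expect_equal(tab1$one, tab1$combined)
  dup <- b$trace; dup@modelId <- "copy"
  tab2 <- rankModels(list(b$trace, dup), list(one = oc))
  expect_equal(tab2$one[1L], tab2$one[2L])
})

test_that("PDB write/read round-trips the trace at format precision", {
  b <- makeBundle(bundleSpec(n_helices = 2))
  tr <- pseudoCentroids(b$trace)
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeCaTrace(tr, tf)
  back <- readCaTrace(tf, model_id = "back")
  expect_equal(residueIds(back), residueIds(tr))
  expect_equal(caCoords(back), caCoords(tr), tolerance = 1e-3)
})
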