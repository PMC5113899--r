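test_that("cap zones take the two terminal residues plus two beyond", {
  segs <- tmbundle:::newSegmentSet(10L, 30L, "inside")
  cz <- assignCaps(segs, 100L)[[1L]]
  expect_equal(cz$n_cap, c(8L, 9L, 10L, 11L))
  expect_equal(cz$c_cap, c(29L, 30L, 31L, 32L))
  ## clipping at the chain terminus keeps at least the 2 inside residues
  edge <- tmbundle:::newSegmentSet(1L, 20L, "inside")
  cze <- assignCaps(edge, 20L)[[1L]]
  expect_equal(cze$n_cap, c(1L, 2L))
  expect_equal(cze$c_cap, c(19L, 20L))
  ## extension slides the outer two residues outward, max 10 positions
  cx <- assignCaps(segs, 100L, extend = 10L)[[1L]]
  expect_equal(cx$n_cap, c(0L, 1L, 10L, 11L)[-1L])  # 0 clipped
  expect_equal(cx$c_cap, c(29L, 30L, 39L, 40L))
  cx3 <- assignCaps(segs, 100L, extend = 3L)[[1L]]
  expect_equal(cx3$n_cap, c(5L, 6L, 10L, 11L))
  expect_error(assignCaps(tmbundle:::newSegmentSet(5L, 5L, "inside"),
                          20L), "2 residues")
})

test_that("bundle axis recovers generator truth within 5 degrees", {
  angleTo <- function(v, w) {
    acos(min(1, abs(sum(v * w)) /
               sqrt(sum(v^2) * sum(w^2)))) * 180 / pi
  }
  one <- makeBundle(bundleSpec(n_helices = 1))
  ax1 <- bundleAxis(one$trace, assignCaps(one$segments, 95L))
  expect_lt(angleTo(ax1$direction, c(0, 0, 1)), 5)
  b <- defaultBundle()
  caps <- assignCaps(b$segments, max(residueIds(b$trace)))
  ax <- bundleAxis(b$trace, caps)
  expect_lt(angleTo(ax$direction, b$truth$axis), 5)
  ## antiparallel helices reinforce instead of cancelling
  expect_gt(sqrt(sum(ax$direction^2)), 0.999)
  ## axis ignores cap enumeration order
  ax_rev <- bundleAxis(b$trace, rev(caps))
  expect_lt(angleTo(ax_rev$direction, ax$direction), 1e-6)
  expect_equal(ax_rev$points[nrow(ax_rev$points), ],
               ax$points[nrow(ax$points), ], tolerance = 1e-9)
})

test_that("two identical parallel helices give their common direction", {
  z <- seq(0, 28.5, 1.5)
  th <- seq_along(z) * 100 * pi / 180
  h <- function(x0) cbind(x0 + 2.3 * cos(th), 2.3 * sin(th), z)
  ## separate residue ranges so caps never bleed into the other helix
  tr <- tmbundle:::newCaTrace("pair", c(1:20, 31:50), rbind(h(0), h(10)))
  segs <- tmbundle:::newSegmentSet(c(1L, 31L), c(20L, 50L), "unknown")
  caps <- assignCaps(segs, 50L)
  ax <- bundleAxis(tr, caps)
  ## identical samples average to the sample itself: the bundle axis
  ## equals the axis derived from either helix alone
  ax1 <- bundleAxis(tr, caps[1L])
  expect_equal(ax$direction, ax1$direction, tolerance = 1e-9)
  expect_gt(abs(ax$direction[3L]), 0.99)
})

test_that("axial RoG matches closed forms and flags stray helices", {
  ## an ideal helix whose TM segment sits clear of the chain ends, so
  ## both caps carry their full 4 residues: RoG about the recovered
  ## axis is the Ca radius
  t <- 0:29
  helix <- tmbundle:::newCaTrace("helix", 1:30,
    cbind(2.3 * cos(t * 100 * pi / 180),
          2.3 * sin(t * 100 * pi / 180), 1.5 * t))
  hsegs <- tmbundle:::newSegmentSet(3L, 28L, "inside")
  hcaps <- assignCaps(hsegs, 30L)
  hax <- bundleAxis(helix, hcaps)
  expect_equal(axialRog(helix, hax, hsegs, hcaps, "tm_only"),
               2.3, tolerance = 0.1)
  ## a chain-terminal helix clips its caps to 2 residues; the estimate
  ## degrades gracefully but stays near the Ca radius
  one <- makeBundle(bundleSpec(n_helices = 1))
  caps1 <- assignCaps(one$segments, max(residueIds(one$trace)))
  ax1 <- bundleAxis(one$trace, caps1)
  expect_equal(axialRog(one$trace, ax1, one$segments, caps1, "tm_only"),
               2.3, tolerance = 0.4)
  ## residues exactly on the axis
  line <- tmbundle:::newCaTrace("line", 1:10, cbind(0, 0, 3.8 * (1:10)))
  axl <- structure(list(points = matrix(0, 1, 3),
                        direction = c(0, 0, 1)), class = "BundleAxis")
  lsegs <- tmbundle:::newSegmentSet(1L, 10L, "unknown")
  expect_equal(axialRog(line, axl, lsegs, assignCaps(lsegs, 10L),
                        "tm_only"), 0)
  ## compact vs stray
  b <- defaultBundle()
  caps <- assignCaps(b$segments, max(residueIds(b$trace)))
  ax <- bundleAxis(b$trace, caps)
  rog_ok <- axialRog(b$trace, ax, b$segments, caps, "tm_only")
  expect_lt(rog_ok, 12)
  stray <- makeDecoys(b$trace, b$segments, "stray_helix", 25,
                      helices = 2)
  axs <- bundleAxis(stray, caps)
  rog_bad <- axialRog(stray, axs, b$segments, caps, "tm_only")
  expect_gt(rog_bad, 15)
  expect_gt(rog_bad, rog_ok)
})

test_that("RoG grows monotonically as one helix is displaced", {
  b <- defaultBundle()
  caps <- assignCaps(b$segments, max(residueIds(b$trace)))
  rogs <- vapply(c(0, 10, 20, 30), function(mag) {
    tr <- if (mag == 0) b$trace else
      makeDecoys(b$trace, b$segments, "stray_helix", mag, helices = 3)
    axialRog(tr, bundleAxis(tr, caps), b$segments, caps, "tm_only")
  }, numeric(1))
  expect_true(all(diff(rogs) > 0))
})

test_that("axial RoG is invariant under joint rigid motion", {
  b <- defaultBundle()
  caps <- assignCaps(b$segments, max(residueIds(b$trace)))
  ax <- bundleAxis(b$trace, caps)
  v0 <- axialRog(b$trace, ax, b$segments, caps, "whole")
  moved <- transformTrace(b$trace, angle = 1.1, axis = c(1, 2, 0.5))
  axm <- bundleAxis(moved, caps)  # axis recomputed from moved caps
  expect_equal(axialRog(moved, axm, b$segments, caps, "whole"), v0,
               tolerance = 1e-9)
})

test_that("compactness thresholds are 12 and 15 Angstrom", {
  expect_equal(flagCompactness(16), "stray")
  expect_equal(flagCompactness(13), "check")
  expect_equal(flagCompactness(8), "ok")
  expect_equal(flagCompactness(c(11.9, 12.1, 15.1)),
               c("ok", "check", "stray"))
})

test_that("handedness tracks the generator label and flips under mirror", {
  for (h in c("clockwise", "anticlockwise")) {
    b <- makeBundle(bundleSpec(handedness = h))
    want <- if (h == "clockwise") 1 else -1
    expect_equal(bundleHandedness(b$trace, b$segments), want)
    mir <- makeDecoys(b$trace, b$segments, "mirror")
    expect_equal(bundleHandedness(mir, b$segments), -want)
  }
})

test_that("collinear helix arrangements give handedness zero", {
  z <- seq(0, 28.5, 1.5)
  th <- seq_along(z) * 100 * pi / 180
  h <- function(x0, up) {
    zz <- if (up) z else rev(z)
    cbind(x0 + 1.5 * cos(th), 1.5 * sin(th), zz)
  }
  tr <- tmbundle:::newCaTrace("row", 1:60,
                              rbind(h(0, TRUE), h(12, FALSE), h(24, TRUE)))
  segs <- tmbundle:::newSegmentSet(c(1L, 21L, 41L), c(20L, 40L, 60L),
                                   "unknown")
  expect_equal(bundleHandedness(tr, segs), 0)
  expect_error(bundleHandedness(tr,
    tmbundle:::newSegmentSet(1L, 20L, "unknown")), "3 segments")
})
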