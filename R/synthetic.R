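## Synthetic ground truth: ideal helix bundles with known segments,
## oracle contact lists derived from the true coordinates, jittered
## topology tracks and decoy structures.  Everything is a pure function
## of (spec, seed), so the whole test surface needs no external data.

#' Specification of an ideal transmembrane helix bundle
#'
#' Geometry defaults are textbook ideal alpha-helix values: 1.5 A rise
#' per residue, 100 degrees twist, 2.3 A Ca radius.  Helices are placed
#' at equal angles on a circle of `bundle_radius` and alternate up/down
#' across the (implicit) membrane according to `topology`.
#'
#' @param n_helices number of helices (default 4).
#' @param helix_length residues per helix (default 20).
#' @param loop_length residues per connecting loop (default 5).
#' @param bundle_radius circle radius in Angstrom (default 10).
#' @param rise_per_residue,twist_per_residue,ca_radius ideal helix
#'   parameters.
#' @param handedness `"clockwise"` or `"anticlockwise"`: the direction
#'   of the helix order as viewed along the bundle axis (first helix
#'   pointing away from the viewer).
#' @param topology character vector of `"up"`/`"down"` per helix;
#'   default alternates starting "up".
#' @param seed integer seed (generation is deterministic; kept in the
#'   spec so derived randomised artefacts inherit it).
#' @return a list of class `"BundleSpec"`.
#' @export
bundleSpec <- function(n_helices = 4L, helix_length = 20L,
                       loop_length = 5L, bundle_radius = 10,
                       rise_per_residue = 1.5, twist_per_residue = 100,
                       ca_radius = 2.3,
                       handedness = c("clockwise", "anticlockwise"),
                       topology = NULL, seed = 1L) {
  handedness <- match.arg(handedness)
  stopifnot(n_helices >= 1L, helix_length >= 4L, loop_length >= 1L,
            bundle_radius > 0, rise_per_residue > 0, ca_radius > 0)
  if (is.null(topology))
    topology <- rep_len(c("up", "down"), n_helices)
  stopifnot(length(topology) == n_helices,
            all(topology %in% c("up", "down")))
  structure(list(n_helices = as.integer(n_helices),
                 helix_length = as.integer(helix_length),
                 loop_length = as.integer(loop_length),
                 bundle_radius = bundle_radius,
                 rise_per_residue = rise_per_residue,
                 twist_per_residue = twist_per_residue,
                 ca_radius = ca_radius, handedness = handedness,
                 topology = topology, seed = as.integer(seed)),
            class = "BundleSpec")
}

#' Build an ideal helix bundle from a spec
#'
#' Helices are ideal alpha-helices on a circle, alternating up/down per
#' the spec topology, joined by straight interpolated loops.  The
#' bundle axis is the z axis; a `"clockwise"` spec orders the helix
#' positions clockwise as viewed along +z.
#'
#' @param spec a [bundleSpec()].
#' @return list: `trace` ([CaTrace-class]), `segments`
#'   ([SegmentSet-class]), `truth` (list with `handedness`, `axis`,
#'   `helix_centers`, `track`).
#' @export
makeBundle <- function(spec) {
  stopifnot(inherits(spec, "BundleSpec"))
  n <- spec$n_helices; hl <- spec$helix_length; ll <- spec$loop_length
  ## clockwise is judged looking down the bundle with helix 1
  ## approaching; with helix 1 "up" that view is from +z downward,
  ## where decreasing standard angle appears clockwise
  step <- -2 * pi / max(n, 2L)
  if (spec$handedness == "anticlockwise") step <- -step
  if (spec$topology[1L] == "down") step <- -step
  twist <- spec$twist_per_residue * pi / 180
  zspan <- (hl - 1L) * spec$rise_per_residue
  coords <- NULL
  seg_start <- integer(n); seg_end <- integer(n)
  centers <- matrix(0, n, 3L)
  res <- 0L
  prev_end <- NULL
  for (k in seq_len(n)) {
    ang <- (k - 1L) * step
    cx <- spec$bundle_radius * cos(ang)
    cy <- spec$bundle_radius * sin(ang)
    centers[k, ] <- c(cx, cy, 0)
    up <- spec$topology[k] == "up"
    t <- 0:(hl - 1L)
    z <- if (up) -zspan / 2 + t * spec$rise_per_residue
         else zspan / 2 - t * spec$rise_per_residue
    th <- ang + (if (up) t else -t) * twist
    h <- cbind(cx + spec$ca_radius * cos(th),
               cy + spec$ca_radius * sin(th), z)
    if (!is.null(prev_end)) {
      gap <- h[1L, ] - prev_end
      glen <- sqrt(sum(gap^2))
      spacing <- glen / (ll + 1L)
      if (spacing > 4.3)
        stop("loop of ", ll, " residues cannot span ",
             format(glen, digits = 4), " A between helices ", k - 1L,
             " and ", k)
      lt <- seq_len(ll) / (ll + 1L)
      loop <- sweep(outer(lt, gap), 2L, prev_end, `+`)
      coords <- rbind(coords, loop)
      res <- res + ll
    }
    seg_start[k] <- res + 1L
    coords <- rbind(coords, h)
    res <- res + hl
    seg_end[k] <- res
    prev_end <- h[hl, ]
  }
  side0 <- if (spec$topology[1L] == "up") "inside" else "outside"
  sides <- rep(c(side0, if (side0 == "inside") "outside" else "inside"),
               length.out = n)
  segments <- newSegmentSet(seg_start, seg_end, sides)
  trace <- newCaTrace(sprintf("bundle_n%d_%s", n, spec$handedness),
                      seq_len(res), coords)
  track <- segmentsToTrack(segments, res)
  list(trace = trace, segments = segments,
       truth = list(handedness = spec$handedness,
                    axis = c(0, 0, 1), helix_centers = centers,
                    track = track))
}

#' Oracle contact list from a true structure
#'
#' Lists every residue pair at sequence separation >= 5 whose
#' pseudo-centroid separation is within `cutoff`, scored
#' `p_raw = 1 / (1 + (d / cutoff)^2)` so rank order follows distance.
#' Centroid (not Ca) distances are used so that the true structure can
#' attain the scoring maximum.  A fraction `rank_noise` of adjacent
#' rank pairs is then swapped (seeded) to emulate imperfect prediction
#' rankings, and the set is rank-transformed.
#'
#' @param trace a [CaTrace-class] (centroids computed on the fly).
#' @param cutoff centroid distance cutoff in Angstrom (default 8).
#' @param rank_noise fraction in [0, 1] of adjacent rank pairs swapped.
#' @param seed integer seed for the swaps.
#' @return a rank-transformed [ContactSet-class], method `"oracle"`.
#' @export
oracleContacts <- function(trace, cutoff = 8, rank_noise = 0,
                           seed = 1L) {
  stopifnot(is(trace, "CaTrace"), rank_noise >= 0, rank_noise <= 1)
  if (!nrow(trace@centroids)) trace <- pseudoCentroids(trace)
  cen <- centroidCoords(trace)
  rn <- residueIds(trace)
  D <- as.matrix(dist(cen))
  sep <- abs(outer(rn, rn, `-`))
  hit <- which(upper.tri(D) & D <= cutoff & sep >= 5L, arr.ind = TRUE)
  if (!nrow(hit)) stop("no contacts under the cutoff")
  d <- D[hit]
  pairs <- data.frame(i = rn[hit[, 1L]], j = rn[hit[, 2L]],
                      p_raw = 1 / (1 + (d / cutoff)^2))
  swap <- pairs$i > pairs$j
  if (any(swap)) {
    tmp <- pairs$i[swap]; pairs$i[swap] <- pairs$j[swap]
    pairs$j[swap] <- tmp
  }
  pairs <- assignRanks(pairs)
  if (rank_noise > 0 && nrow(pairs) > 1L) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    n <- nrow(pairs)
    n_sw <- round(rank_noise * (n - 1L))
    pos <- sample(n - 1L, min(n_sw, n - 1L))
    ord <- order(pairs$rank)
    pairs <- pairs[ord, , drop = FALSE]
    for (p_ in pos) {
      tmp <- pairs[p_, ]; pairs[p_, ] <- pairs[p_ + 1L, ]
      pairs[p_ + 1L, ] <- tmp
    }
    pairs$rank <- seq_len(nrow(pairs))
  }
  rankTransform(newContactSet(max(rn), "oracle", pairs))
}

#' Decoy structures from a true trace
#'
#' Four decoy families mirroring the failure modes seen in real model
#' sets: `mirror` (reflect x; the enantiomer), `stray_helix` (one helix
#' rigidly translated radially outward by `magnitude` Angstrom, as
#' fragment assembly often leaves), `swap_helices` (two helices
#' exchange positions, the fold change RMSD struggles to see) and
#' `noise` (per-atom Gaussian jitter of sd `magnitude`).
#'
#' @param trace a [CaTrace-class].
#' @param segments a [SegmentSet-class] locating the helices.
#' @param kind one of `"mirror"`, `"stray_helix"`, `"swap_helices"`,
#'   `"noise"`.
#' @param magnitude Angstrom (translation or jitter sd); ignored for
#'   mirror/swap.
#' @param helices helix index (stray) or index pair (swap).
#' @param seed integer seed (noise only).
#' @return a new [CaTrace-class] (centroids cleared).
#' @export
makeDecoys <- function(trace, segments,
                       kind = c("mirror", "stray_helix", "swap_helices",
                                "noise"),
                       magnitude = 25, helices = 1L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is(trace, "CaTrace"), is(segments, "SegmentSet"))
  s <- segmentTable(segments)
  rn <- residueIds(trace)
  xyz <- caCoords(trace)
  segIdx <- function(k) {
    if (k < 1L || k > nrow(s)) stop("invalid helix index ", k)
    which(rn >= s$start[k] & rn <= s$end[k])
  }
  if (kind == "mirror") {
    xyz[, 1L] <- -xyz[, 1L]
  } else if (kind == "stray_helix") {
    idx <- segIdx(helices[1L])
    ctr <- colMeans(xyz)
    hc <- colMeans(xyz[idx, , drop = FALSE])
    dirv <- hc - ctr; dirv[3L] <- 0
    nv <- sqrt(sum(dirv^2))
    dirv <- if (nv > 1e-8) dirv / nv else c(1, 0, 0)
    xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2L,
                        magnitude * dirv, `+`)
  } else if (kind == "swap_helices") {
    if (length(helices) != 2L) stop("swap_helices needs an index pair")
    ia <- segIdx(helices[1L]); ib <- segIdx(helices[2L])
    if (length(ia) != length(ib))
      stop("swapped helices must have equal lengths")
    tmp <- xyz[ia, , drop = FALSE]
    xyz[ia, ] <- xyz[ib, , drop = FALSE]
    xyz[ib, ] <- tmp
  } else {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    xyz <- xyz + matrix(rnorm(length(xyz), sd = magnitude),
                        nrow(xyz), 3L)
  }
  suffix <- switch(kind,
    mirror = "mirror",
    stray_helix = paste0("stray", helices[1L]),
    swap_helices = paste0("swap", helices[1L], helices[2L]),
    noise = paste0("noise", seed))
  newCaTrace(paste0(modelId(trace), "_", suffix), rn, xyz)
}

#' Jittered per-method topology tracks from a true segment list
#'
#' Emulates disagreeing topology predictors: each method's copy of the
#' truth has every segment boundary independently shifted by up to
#' `jitter` residues (clamped so segments stay valid and ordered).
#'
#' @param segments the true [SegmentSet-class].
#' @param chain_length protein length.
#' @param n_methods number of methods (default 3).
#' @param jitter maximum boundary shift in residues (default 0).
#' @param seed integer seed.
#' @return named list of [SegmentSet-class] (`method1`, `method2`,
#'   ...); each also carries its i/M/o track as attribute `"track"`.
#' @export
makeTopologyTracks <- function(segments, chain_length, n_methods = 3L,
                               jitter = 0L, seed = 1L) {
  stopifnot(is(segments, "SegmentSet"), jitter >= 0L, n_methods >= 1L)
  s <- segmentTable(segments)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  out <- list()
  for (m in seq_len(n_methods)) {
    st <- s$start; en <- s$end
    if (jitter > 0L) {
      st <- st + sample(seq.int(-jitter, jitter), length(st),
                        replace = TRUE)
      en <- en + sample(seq.int(-jitter, jitter), length(en),
                        replace = TRUE)
      st <- pmax(st, 1L); en <- pmin(en, chain_length)
      en <- pmax(en, st)
      if (length(st) > 1L) for (k in 2L:length(st)) {
        if (st[k] <= en[k - 1L]) st[k] <- en[k - 1L] + 1L
        if (en[k] < st[k]) en[k] <- st[k]
      }
    }
    ss <- newSegmentSet(st, en, s$n_term_side)
    attr(ss, "track") <- segmentsToTrack(ss, chain_length)
    out[[paste0("method", m)]] <- ss
  }
  out
}
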