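## Bundle axis and axial radius of gyration.
##
## The membrane is not represented explicitly, so compactness is judged
## about an average bundle axis derived from the helix terminal regions
## (caps): each TM segment gets two 4-residue capping zones, the cap
## midpoints of each segment define an axis sample, and samples are
## accumulated from the most widely separated pair down, flipping
## antiparallel pairs so directions reinforce rather than cancel.

#' Assign capping zones to transmembrane segments
#'
#' Each segment receives an N-side and a C-side cap of 4 residues: the
#' two terminal residues of the segment plus the two beyond, extending
#' outward.  With `extend > 0` the two outward residues slide further
#' out (never beyond 10 positions from the segment end), for use when
#' the topology prediction around the segment end is variable.  Caps
#' are clipped to the chain (minimum the 2 in-segment residues).
#'
#' @param segments a [SegmentSet-class].
#' @param chain_length protein length.
#' @param extend outward slide of the two outer cap residues, 0..10.
#' @return list of cap zones, one per segment:
#'   `list(segment = k, n_cap = <indices>, c_cap = <indices>)`.
#' @export
assignCaps <- function(segments, chain_length, extend = 0L) {
  stopifnot(is(segments, "SegmentSet"), extend >= 0L, extend <= 10L)
  s <- segmentTable(segments)
  if (any(s$end - s$start + 1L < 2L))
    stop("segments must be at least 2 residues long to cap")
  out_far <- min(2L + extend, 10L)
  out_near <- min(1L + extend, 9L)
  lapply(seq_len(nrow(s)), function(k) {
    n_cap <- c(s$start[k] - out_far, s$start[k] - out_near,
               s$start[k], s$start[k] + 1L)
    c_cap <- c(s$end[k] - 1L, s$end[k],
               s$end[k] + out_near, s$end[k] + out_far)
    list(segment = k,
         n_cap = sort(unique(n_cap[n_cap >= 1L & n_cap <= chain_length])),
         c_cap = sort(unique(c_cap[c_cap >= 1L & c_cap <= chain_length])))
  })
}

.capMid <- function(trace, residues) {
  idx <- match(residues, residueIds(trace))
  idx <- idx[!is.na(idx)]
  if (!length(idx)) return(NULL)
  colMeans(caCoords(trace)[idx, , drop = FALSE])
}

#' Average bundle axis from cap midpoints
#'
#' For every segment the N- and C-cap midpoints define one axis sample
#' (point = their midpoint, direction = N-to-C).  Samples are sorted by
#' cap separation and accumulated from the longest down as a running
#' mean, flipping any sample whose direction opposes the running mean
#' so that antiparallel helices reinforce instead of cancel.
#'
#' @param trace a [CaTrace-class].
#' @param caps cap zones from [assignCaps()] (>= 2 segments for a
#'   meaningful bundle, 1 is allowed for a single helix).
#' @return object of class `"BundleAxis"`: `points` (running mean after
#'   each accumulation, last row = final axis anchor), `direction`
#'   (unit vector).
#' @export
bundleAxis <- function(trace, caps) {
  stopifnot(is(trace, "CaTrace"), length(caps) >= 1L)
  samples <- list()
  for (cz in caps) {
    mn <- .capMid(trace, cz$n_cap); mc <- .capMid(trace, cz$c_cap)
    if (is.null(mn) || is.null(mc)) next
    v <- mc - mn
    len <- sqrt(sum(v^2))
    if (len < 1e-8) next
    samples[[length(samples) + 1L]] <-
      list(mid = (mn + mc) / 2, dir = v / len, len = len)
  }
  if (!length(samples))
    stop("all cap pairs degenerate; cannot define a bundle axis")
  ord <- order(-vapply(samples, `[[`, numeric(1), "len"))
  samples <- samples[ord]
  mid_sum <- samples[[1L]]$mid
  dir_sum <- samples[[1L]]$dir
  pts <- matrix(mid_sum, 1L, 3L)
  if (length(samples) > 1L) for (k in 2L:length(samples)) {
    d <- samples[[k]]$dir
    if (sum(d * dir_sum) < 0) d <- -d   # orientation flip
    mid_sum <- mid_sum + samples[[k]]$mid
    dir_sum <- dir_sum + d
    pts <- rbind(pts, mid_sum / k)
  }
  dir <- dir_sum / sqrt(sum(dir_sum^2))
  structure(list(points = pts, direction = dir), class = "BundleAxis")
}

#' @export
print.BundleAxis <- function(x, ...) {
  cat("BundleAxis:", nrow(x$points), "accumulated point(s); direction",
      paste(sprintf("%.3f", x$direction), collapse = " "), "\n")
  invisible(x)
}

.axisDistances <- function(xyz, axis) {
  anchor <- axis$points[nrow(axis$points), ]
  d <- axis$direction
  rel <- sweep(xyz, 2L, anchor)
  along <- as.numeric(rel %*% d)
  perp <- rel - outer(along, d)
  sqrt(rowSums(perp^2))
}

#' Axial radius of gyration
#'
#' Weighted RoG of the Ca positions about the (infinite) bundle-axis
#' line: `sqrt(sum(w * r^2) / sum(w))` with r the perpendicular
#' distance to the axis.  Three weighting schemes:
#' \describe{
#'   \item{`tm_only`}{TM residues 1, everything else 0.}
#'   \item{`tm_caps`}{TM 1, cap residues 0.5, rest 0.}
#'   \item{`whole`}{TM 2, caps 1, rest 0.5.}
#' }
#'
#' @param trace a [CaTrace-class].
#' @param axis a `"BundleAxis"` from [bundleAxis()].
#' @param segments a [SegmentSet-class].
#' @param caps cap zones from [assignCaps()].
#' @param scheme one of `"tm_only"`, `"tm_caps"`, `"whole"`.
#' @return RoG in Angstrom.
#' @export
axialRog <- function(trace, axis, segments, caps,
                     scheme = c("whole", "tm_caps", "tm_only")) {
  scheme <- match.arg(scheme)
  stopifnot(is(trace, "CaTrace"), inherits(axis, "BundleAxis"))
  rn <- residueIds(trace)
  s <- segmentTable(segments)
  tm <- rep(FALSE, length(rn))
  for (k in seq_len(nrow(s)))
    tm <- tm | (rn >= s$start[k] & rn <= s$end[k])
  capres <- sort(unique(unlist(lapply(caps, function(cz)
    c(cz$n_cap, cz$c_cap)))))
  cap <- rn %in% capres & !tm
  w <- switch(scheme,
    tm_only = ifelse(tm, 1, 0),
    tm_caps = ifelse(tm, 1, ifelse(cap, 0.5, 0)),
    whole   = ifelse(tm, 2, ifelse(cap, 1, 0.5)))
  if (sum(w) <= 0) stop("no residue carries positive weight")
  r <- .axisDistances(caCoords(trace), axis)
  sqrt(sum(w * r^2) / sum(w))
}

#' Compactness flag from the axial RoG
#'
#' Operational guidance for typical TM bundles: an RoG above 15 A almost
#' always means one or more stray helices detached from the bundle; one
#' above 12 A deserves a look.
#'
#' @param rog RoG in Angstrom (vectorised).
#' @return character: `"stray"` (> 15), `"check"` (12 < rog <= 15) or
#'   `"ok"`.
#' @export
flagCompactness <- function(rog) {
  stopifnot(all(rog >= 0))
  ifelse(rog > 15, "stray", ifelse(rog > 12, "check", "ok"))
}

#' Bundle handedness
#'
#' Distance constraints cannot discriminate a bundle from its mirror
#' image, so chirality must be checked geometrically.  Helix midpoints
#' are projected onto the plane normal to the bundle axis and the sign
#' of the cyclic cross-product sum over consecutive helices (in
#' sequence order) is returned, using the viewing convention "down the
#' bundle with the first helix approaching" (the view direction is the
#' axis direction sign-aligned against the first segment's N-to-C
#' vector): `+1` = the helix order runs clockwise in that view, `-1` =
#' anticlockwise, `0` = degenerate (collinear midpoints).  Mirroring a
#' model flips the sign.
#'
#' @param trace a [CaTrace-class].
#' @param segments a [SegmentSet-class] with >= 3 segments.
#' @param axis a `"BundleAxis"`; computed from default caps if missing.
#' @return `+1`, `-1` or `0`.
#' @export
bundleHandedness <- function(trace, segments, axis = NULL) {
  stopifnot(is(trace, "CaTrace"), is(segments, "SegmentSet"))
  s <- segmentTable(segments)
  if (nrow(s) < 3L) stop("handedness needs at least 3 segments")
  if (is.null(axis))
    axis <- bundleAxis(trace, assignCaps(segments,
                                         max(residueIds(trace))))
  rn <- residueIds(trace); xyz <- caCoords(trace)
  mids <- t(vapply(seq_len(nrow(s)), function(k) {
    idx <- which(rn >= s$start[k] & rn <= s$end[k])
    colMeans(xyz[idx, , drop = FALSE])
  }, numeric(3)))
  ## first helix approaching the viewer: view along -N-to-C of segment 1
  i1 <- which(rn >= s$start[1L] & rn <= s$end[1L])
  half <- length(i1) %/% 2L
  h1 <- colMeans(xyz[tail(i1, half), , drop = FALSE]) -
        colMeans(xyz[head(i1, half), , drop = FALSE])
  d <- axis$direction
  if (sum(d * h1) < 0) d <- -d
  d <- -d
  anchor <- axis$points[nrow(axis$points), ]
  rel <- sweep(mids, 2L, anchor)
  proj <- rel - outer(as.numeric(rel %*% d), d)
  ctr <- colMeans(proj)
  v <- sweep(proj, 2L, ctr)
  n <- nrow(v)
  tot <- 0
  for (k in seq_len(n)) {
    a <- v[k, ]; b <- v[if (k == n) 1L else k + 1L, ]
    cr <- c(a[2L] * b[3L] - a[3L] * b[2L],
            a[3L] * b[1L] - a[1L] * b[3L],
            a[1L] * b[2L] - a[2L] * b[1L])
    tot <- tot + sum(cr * d)
  }
  scale <- mean(rowSums(v^2))
  if (abs(tot) < 1e-6 * max(scale, 1e-12)) return(0)
  if (tot > 0) 1 else -1
}
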