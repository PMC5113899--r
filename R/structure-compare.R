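## Environment-weighted superposition and RMSD suite.
##
## Whole-structure RMSD is easily skewed by a few badly modelled loops,
## so residue pairs are down-weighted where the two structures disagree
## about that residue's context.  The models being compared share one
## sequence (a one-to-one correspondence, no alignment step), so each
## residue's context is summarised by its internal distance profile and
## the weight decays with the mean profile discrepancy.

#' Context-derived residue weights for a structure pair
#'
#' For each residue i the discrepancy
#' `Delta_i = mean_j | ||Ca_i - Ca_j||_a - ||Ca_i - Ca_j||_b |`
#' (mean absolute difference of the internal distance profiles, in
#' Angstrom) is converted to a weight `exp(-Delta_i / sigma)`.
#' Residues whose local environment agrees get weight near 1; residues
#' displaced relative to the rest of the structure are suppressed
#' smoothly.
#'
#' @param a,b two [CaTrace-class] objects with equal residue counts.
#' @param sigma decay constant in Angstrom (default 4).
#' @return numeric vector of weights in (0, 1], one per residue.
#' @export
environmentWeights <- function(a, b, sigma = 4) {
  stopifnot(is(a, "CaTrace"), is(b, "CaTrace"))
  if (length(residueIds(a)) != length(residueIds(b)))
    stop("traces differ in length: ", length(residueIds(a)), " vs ",
         length(residueIds(b)))
  da <- as.matrix(dist(caCoords(a)))
  db <- as.matrix(dist(caCoords(b)))
  n <- nrow(da)
  delta <- rowSums(abs(da - db)) / (n - 1L)
  unname(exp(-delta / sigma))
}

#' Weighted rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation + translation of `b` minimising
#' `sum(w_i * ||a_i - T(b_i)||^2)` (reflections excluded, so a mirror
#' image never superposes to zero) and reports the weighted RMSD
#' `sqrt(sum(w ||.||^2) / sum(w))`.
#'
#' @param a,b [CaTrace-class] objects of equal length.
#' @param w per-residue weights (default uniform); must contain a
#'   positive entry.
#' @return list: `R` (3x3 rotation applied to b), `t` (translation),
#'   `wrmsd`, and `bxyz` (the transformed coordinates of b).
#' @export
weightedSuperpose <- function(a, b, w = NULL) {
  stopifnot(is(a, "CaTrace"), is(b, "CaTrace"))
  A <- caCoords(a); B <- caCoords(b)
  if (nrow(A) != nrow(B)) stop("traces differ in length")
  n <- nrow(A)
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n) stop("weight vector must match residue count")
  if (all(w <= 0)) stop("weights must contain a positive entry")
  w <- w / sum(w)
  ca <- colSums(A * w); cb <- colSums(B * w)
  Ac <- sweep(A, 2L, ca); Bc <- sweep(B, 2L, cb)
  H <- t(Bc * w) %*% Ac
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Bt <- Bc %*% t(R)
  wrmsd <- sqrt(sum(w * rowSums((Ac - Bt)^2)))
  list(R = R, t = ca - as.numeric(R %*% cb), wrmsd = wrmsd,
       bxyz = sweep(Bt, 2L, ca, `+`))
}

.schemeWeights <- function(trace, segments, caps, scheme) {
  rn <- residueIds(trace)
  s <- segmentTable(segments)
  tm <- rep(FALSE, length(rn))
  for (k in seq_len(nrow(s)))
    tm <- tm | (rn >= s$start[k] & rn <= s$end[k])
  capres <- sort(unique(unlist(lapply(caps, function(cz)
    c(cz$n_cap, cz$c_cap)))))
  cap <- rn %in% capres & !tm
  switch(scheme,
    tm_only = ifelse(tm, 1, 0),
    tm_caps = ifelse(tm, 1, ifelse(cap, 0.5, 0)),
    whole   = ifelse(tm, 2, ifelse(cap, 1, 0.5)))
}

#' Four weighted RMSD values for a model pair
#'
#' The environment-weighted RMSD plus three fixed-scheme values using
#' the same weights as the axial RoG (`tm_only`, `tm_caps`, `whole`),
#' each from its own weighted superposition.
#'
#' @param a,b [CaTrace-class] objects of equal length.
#' @param segments a [SegmentSet-class].
#' @param caps cap zones from [assignCaps()]; derived from `segments`
#'   when missing.
#' @param sigma passed to [environmentWeights()].
#' @return named numeric: `env_weighted`, `tm_only`, `tm_caps`, `whole`.
#' @export
rmsdSuite <- function(a, b, segments, caps = NULL, sigma = 4) {
  if (is.null(caps))
    caps <- assignCaps(segments, max(residueIds(a)))
  ew <- environmentWeights(a, b, sigma)
  out <- c(env_weighted = weightedSuperpose(a, b, ew)$wrmsd)
  for (scheme in c("tm_only", "tm_caps", "whole")) {
    w <- .schemeWeights(a, segments, caps, scheme)
    out[scheme] <- weightedSuperpose(a, b, w)$wrmsd
  }
  out
}

#' Pairwise weighted-RMSD distance matrix for an ensemble
#'
#' @param traces list of equal-length [CaTrace-class] objects.
#' @param segments,caps,sigma as [rmsdSuite()].
#' @param scheme which suite member fills the matrix (default
#'   `"env_weighted"`).
#' @return symmetric matrix (zero diagonal) with model ids as dimnames.
#' @export
distanceMatrix <- function(traces, segments, caps = NULL,
                           scheme = c("env_weighted", "tm_only",
                                      "tm_caps", "whole"),
                           sigma = 4) {
  scheme <- match.arg(scheme)
  n <- length(traces)
  if (n < 2L) stop("need at least two traces")
  lens <- vapply(traces, function(t) length(residueIds(t)), integer(1))
  if (length(unique(lens)) != 1L) {
    bad <- vapply(traces, modelId, character(1))
    stop("traces differ in length: ",
         paste(paste0(bad, "(", lens, ")"), collapse = ", "))
  }
  ids <- vapply(traces, modelId, character(1))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (x in seq_len(n - 1L)) for (y in (x + 1L):n) {
    v <- rmsdSuite(traces[[x]], traces[[y]], segments, caps, sigma)[scheme]
    D[x, y] <- D[y, x] <- as.numeric(v)
  }
  D
}

#' Sorted RMSD values of one reference against an ensemble
#'
#' The plot-ready cumulative-RMSD profile: weighted RMSDs of the
#' reference against every other model, sorted ascending.
#'
#' @param reference a [CaTrace-class].
#' @param others list of [CaTrace-class] objects.
#' @param segments,caps,sigma,scheme as [distanceMatrix()].
#' @return named numeric vector (model ids), sorted ascending.
#' @export
cumulativeRmsd <- function(reference, others, segments, caps = NULL,
                           scheme = c("env_weighted", "tm_only",
                                      "tm_caps", "whole"),
                           sigma = 4) {
  scheme <- match.arg(scheme)
  if (!length(others)) stop("need at least one other model")
  v <- vapply(others, function(o)
    as.numeric(rmsdSuite(reference, o, segments, caps, sigma)[scheme]),
    numeric(1))
  names(v) <- vapply(others, modelId, character(1))
  sort(v)
}
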