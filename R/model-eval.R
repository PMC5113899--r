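#' Read a Ca trace from a PDB file
#'
#' Extracts the alpha-carbon trace of the first chain of the first model
#' via [bio3d::read.pdb()].  Alternate locations other than "A" are
#' dropped; insertion codes are rejected (renumber the model first).
#' Chain-contiguous Ca-Ca distances outside 2.0-4.5 Angstrom trigger a
#' warning (broken or compressed chain).
#'
#' @param path PDB file path.
#' @param model_id identifier stored in the trace; defaults to the file
#'   base name.
#' @return a [CaTrace-class] (centroids not yet computed).
#' @export
readCaTrace <- function(path, model_id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  if (is.null(model_id))
    model_id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                         verbose = FALSE)
  at <- pdb$atom
  at <- at[at$elety == "CA" & at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no CA atoms in ", path)
  at <- at[at$chain == at$chain[1L] | is.na(at$chain), , drop = FALSE]
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes present in ", path,
         "; renumber the structure before use")
  at <- at[!duplicated(at$resno), , drop = FALSE]
  tr <- newCaTrace(model_id, at$resno, cbind(at$x, at$y, at$z))
  .warnChainGeometry(tr)
  tr
}

.warnChainGeometry <- function(trace) {
  rn <- residueIds(trace); xyz <- caCoords(trace)
  if (length(rn) < 2L) return(invisible(NULL))
  adj <- which(diff(rn) == 1L)
  if (!length(adj)) return(invisible(NULL))
  d <- sqrt(rowSums((xyz[adj + 1L, , drop = FALSE] -
                     xyz[adj, , drop = FALSE])^2))
  bad <- d < 2.0 | d > 4.5
  if (any(bad))
    warning(sum(bad), " consecutive Ca-Ca distance(s) outside 2.0-4.5 A",
            " in model ", modelId(trace), call. = FALSE)
  invisible(NULL)
}

#' Write a Ca trace (and its pseudo-centroids) as PDB
#'
#' Ca atoms go to chain A; when centroids have been computed they are
#' written as pseudo-atoms (CEN) in chain B for visual inspection.
#'
#' @param trace a [CaTrace-class].
#' @param path output path.
#' @param centroids also write pseudo-centroids if present (default TRUE).
#' @return `path`, invisibly.
#' @export
writeCaTrace <- function(trace, path, centroids = TRUE) {
  stopifnot(is(trace, "CaTrace"))
  rn <- residueIds(trace)
  xyz <- caCoords(trace)
  has_cen <- centroids && nrow(trace@centroids) > 0L
  n <- length(rn)
  resno <- rn; chain <- rep("A", n); elety <- rep("CA", n)
  co <- xyz
  if (has_cen) {
    resno <- c(resno, rn); chain <- c(chain, rep("B", n))
    elety <- c(elety, rep("CEN", n))
    co <- rbind(co, trace@centroids)
  }
  bio3d::write.pdb(file = path, xyz = as.numeric(t(co)), resno = resno,
                   chain = chain, elety = elety,
                   resid = rep("GLY", length(resno)),
                   eleno = seq_along(resno))
  invisible(path)
}

#' Place pseudo-centroids 2 A beyond the Ca bisector
#'
#' At Ca resolution the two faces of a helix differ by only a few
#' Angstrom, so contacts are evaluated at a pseudo-beta-carbon/centroid
#' instead: a dummy atom placed 2 A beyond each Ca along the *outward*
#' negative bisector of the two adjacent Ca-Ca virtual bonds (the
#' direction a Cb points, away from the helix axis).  With u, v the
#' unit vectors from Ca_i toward its chain neighbours,
#' `centroid_i = Ca_i - 2 * normalize(u + v)`.  Terminal residues copy
#' the adjacent interior residue's offset so coverage stays complete;
#' where u + v vanishes (locally straight chain) the centroid falls on
#' the Ca itself.
#'
#' @param trace a [CaTrace-class] with at least 3 residues.
#' @return the trace with the `centroids` slot filled.
#' @export
pseudoCentroids <- function(trace) {
  stopifnot(is(trace, "CaTrace"))
  xyz <- caCoords(trace)
  n <- nrow(xyz)
  if (n < 3L) stop("pseudo-centroids need at least 3 residues")
  offs <- matrix(0, n, 3L)
  for (k in 2L:(n - 1L)) {
    u <- xyz[k - 1L, ] - xyz[k, ]
    v <- xyz[k + 1L, ] - xyz[k, ]
    u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
    b <- u + v
    nb <- sqrt(sum(b^2))
    if (nb > 1e-8) offs[k, ] <- -2 * b / nb
  }
  offs[1L, ] <- offs[2L, ]
  offs[n, ] <- offs[n - 1L, ]
  initialize(trace, centroids = xyz + offs)
}

#' Soft Gaussian contact score
#'
#' A strict distance cutoff is too brittle for rough pseudo-centroid
#' models, so a contact at observed separation d scores
#' \deqn{q = \exp(-(d - 5)^2 / s^2)}
#' with its maximum of 1 at 5 A (around the minimum pseudo-centroid
#' separation seen in native structures) and spread s.  With the
#' default s = 5, separations beyond 10 A score under 0.37, beyond
#' 15 A almost zero, and d = 0 is slightly penalised (also 0.37).
#'
#' @param d separation(s) in Angstrom (vectorised), `d >= 0`.
#' @param s Gaussian spread in Angstrom, `s > 0`.
#' @param d0 ideal separation (default 5 A).
#' @return score(s) in (0, 1].
#' @export
#' @examples
#' softQ(5)    # 1
#' softQ(10)   # exp(-1), just under 0.37
#' softQ(0)    # also exp(-1)
#' softQ(15)   # ~0.018
softQ <- function(d, s = 5, d0 = 5) {
  if (s <= 0) stop("Gaussian spread s must be positive")
  stopifnot(all(d >= 0))
  exp(-((d - d0)^2) / s^2)
}

#' Scoring parameters
#'
#' @param s Gaussian spread in Angstrom (default 5).
#' @param d0 ideal pseudo-centroid separation in Angstrom (default 5).
#' @param n_top number of top-ranked pairs summed (default 100).
#' @param min_sep minimum sequence separation scored (default 8, two
#'   helical turns).
#' @return a list of class `"ScoreParams"`.
#' @export
scoreParams <- function(s = 5, d0 = 5, n_top = 100L, min_sep = 8L) {
  stopifnot(s > 0, n_top >= 1L, min_sep >= 0L)
  structure(list(s = s, d0 = d0, n_top = as.integer(n_top),
                 min_sep = as.integer(min_sep)), class = "ScoreParams")
}

#' Score a model against predicted contacts
#'
#' Sums `e * q(d)` over the `n_top` strongest predicted pairs at
#' sequence separation `>= min_sep`, where e is the rank-transformed
#' reliability and d the pseudo-centroid separation in the model.  The
#' score is highest when the strongest predictions sit near the ideal
#' 5 A separation.  Pairs touching residues absent from the trace
#' contribute 0 and are reported through the `"coverage"` attribute
#' (fraction of scored pairs fully present).
#'
#' @param trace a [CaTrace-class]; centroids are computed on the fly if
#'   absent.
#' @param contacts rank-transformed [ContactSet-class].
#' @param params a [scoreParams()] list.
#' @return numeric(1) score with attribute `coverage`.
#' @export
scoreModel <- function(trace, contacts, params = scoreParams()) {
  stopifnot(is(trace, "CaTrace"), is(contacts, "ContactSet"),
            inherits(params, "ScoreParams"))
  if (!isRankTransformed(contacts))
    stop("contacts must be rank-transformed")
  if (!nrow(trace@centroids)) trace <- pseudoCentroids(trace)
  top <- contactPairs(filterPairs(contacts, min_sep = params$min_sep,
                                  top_k = params$n_top))
  ## filterPairs re-ranks, which would re-stretch e; score with the e
  ## values the pairs carry in the full set
  full <- contactPairs(contacts)
  key_full <- paste(full$i, full$j)
  e <- full$e[match(paste(top$i, top$j), key_full)]
  idx <- match(top$i, residueIds(trace))
  jdx <- match(top$j, residueIds(trace))
  ok <- !is.na(idx) & !is.na(jdx)
  cen <- centroidCoords(trace)
  sc <- 0
  if (any(ok)) {
    d <- sqrt(rowSums((cen[idx[ok], , drop = FALSE] -
                       cen[jdx[ok], , drop = FALSE])^2))
    sc <- sum(e[ok] * softQ(d, params$s, params$d0))
  }
  structure(sc, coverage = if (nrow(top)) mean(ok) else NA_real_)
}

#' Score a model ensemble against several contact sets
#'
#' Scores every model against every contact set plus the combined
#' consensus ([combineContactSets()]) and returns the matrix sorted by
#' the combined column.
#'
#' @param traces list of [CaTrace-class] objects.
#' @param contact_sets list of rank-transformed [ContactSet-class]
#'   objects (named; unnamed sets get their method tag).
#' @param params a [scoreParams()] list.
#' @return data.frame: `model`, one score column per contact set, and
#'   `combined`; rows ordered by `combined` descending (ties by model
#'   id) — deterministic.
#' @export
rankModels <- function(traces, contact_sets, params = scoreParams()) {
  stopifnot(length(traces) >= 1L, length(contact_sets) >= 1L)
  nms <- names(contact_sets)
  if (is.null(nms)) nms <- rep("", length(contact_sets))
  blank <- !nzchar(nms)
  nms[blank] <- vapply(contact_sets[blank], contactMethod, character(1))
  nms <- make.unique(nms)
  traces <- lapply(traces, function(tr)
    if (nrow(tr@centroids)) tr else pseudoCentroids(tr))
  cols <- lapply(contact_sets, function(cs)
    vapply(traces, function(tr) as.numeric(scoreModel(tr, cs, params)),
           numeric(1)))
  names(cols) <- nms
  comb <- if (length(contact_sets) > 1L)
    combineContactSets(contact_sets) else contact_sets[[1L]]
  combined <- vapply(traces, function(tr)
    as.numeric(scoreModel(tr, comb, params)), numeric(1))
  out <- data.frame(model = vapply(traces, modelId, character(1)),
                    stringsAsFactors = FALSE)
  for (nm in nms) out[[nm]] <- cols[[nm]]
  out$combined <- combined
  out[order(-out$combined, out$model), , drop = FALSE]
}
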