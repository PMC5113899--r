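#' @import methods
#' @importFrom stats cmdscale dist rnorm runif setNames sd
#' @importFrom utils read.table write.table head tail
NULL

## Central data containers.  All residue numbering is 1-based throughout.

#' Ranked residue-pair contact predictions from one method
#'
#' A `ContactSet` holds the ranked residue-pair contact predictions of a
#' single coevolution method (or of a consensus built from several).  Each
#' pair carries the method-native reliability `p_raw`, its integer `rank` in
#' the descending-reliability ordering (1 = strongest) and, once
#' [rankTransform()] has been applied, the normalized reliability
#' `e = exp(-rank^2 * 0.01 / L)` on a common (0, 1] scale.
#'
#' @slot proteinLength integer(1); number of residues L in the protein.
#' @slot method character(1); free-text source tag (e.g. "psicov",
#'   "gremlin", "evfold" or "consensus").
#' @slot pairs data.frame with columns `i`, `j` (1 <= i < j <= L), `p_raw`,
#'   `rank` (a permutation of 1..n) and `e` (NA until rank-transformed).
#'
#' @seealso [readContactList()], [rankTransform()], [combineContactSets()],
#'   [filterPairs()]
#' @export
setClass("ContactSet",
  representation(proteinLength = "integer",
                 method = "character",
                 pairs = "data.frame"),
  prototype(proteinLength = 0L, method = "unknown",
            pairs = data.frame(i = integer(), j = integer(),
                               p_raw = numeric(), rank = integer(),
                               e = numeric())))

setValidity("ContactSet", function(object) {
  p <- object@pairs
  msg <- character()
  need <- c("i", "j", "p_raw", "rank", "e")
  if (!all(need %in% names(p)))
    return(paste("pairs must have columns", paste(need, collapse = ", ")))
  if (length(object@proteinLength) != 1L || is.na(object@proteinLength) ||
      object@proteinLength < 1L)
    msg <- c(msg, "proteinLength must be a single positive integer")
  if (nrow(p)) {
    if (any(p$i < 1L) || any(p$j > object@proteinLength))
      msg <- c(msg, "residue indices must lie in 1..proteinLength")
    if (any(p$i >= p$j))
      msg <- c(msg, "pairs must satisfy i < j")
    if (anyDuplicated(p[, c("i", "j")]))
      msg <- c(msg, "duplicate (i, j) pairs are not allowed")
    if (!setequal(p$rank, seq_len(nrow(p))))
      msg <- c(msg, "ranks must be a permutation of 1..n_pairs")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Transmembrane segment definitions
#'
#' A `SegmentSet` stores non-overlapping, sequence-sorted transmembrane
#' segments.  The optional `agreement` column ("all"/"majority") marks
#' consensus support when the object was produced by
#' [consensusSegments()] (thick/thin bar semantics).
#'
#' @slot segments data.frame with columns `start`, `end` (1-based,
#'   inclusive), `n_term_side` (one of "inside", "outside", "unknown")
#'   and optionally `agreement`.
#'
#' @seealso [readTopologyTable()], [consensusSegments()]
#' @export
setClass("SegmentSet",
  representation(segments = "data.frame"),
  prototype(segments = data.frame(start = integer(), end = integer(),
                                  n_term_side = character())))

setValidity("SegmentSet", function(object) {
  s <- object@segments
  if (!all(c("start", "end", "n_term_side") %in% names(s)))
    return("segments needs columns start, end, n_term_side")
  if (nrow(s)) {
    if (any(s$start > s$end))
      return("segment start must not exceed end")
    if (is.unsorted(s$start))
      return("segments must be sorted by start")
    if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)]))
      return("segments must not overlap")
    if (!all(s$n_term_side %in% c("inside", "outside", "unknown")))
      return("n_term_side must be inside/outside/unknown")
  }
  TRUE
})

#' Multi-method topology with thick/thin consensus
#'
#' Per-method transmembrane segment predictions together with the
#' per-residue vote consensus: residues called membrane by every method
#' form "all" (thick bar) runs, residues called by at least two form
#' "majority" (thin bar) runs.
#'
#' @slot perMethod named list of [SegmentSet-class] objects, one per method.
#' @slot consensus a [SegmentSet-class] whose `segments` carry an
#'   `agreement` column.
#'
#' @seealso [consensusSegments()]
#' @export
setClass("TopologyConsensus",
  representation(perMethod = "list", consensus = "SegmentSet"))

#' An alpha-carbon trace with optional pseudo-centroids
#'
#' Holds the Ca coordinates of one model (ordered by residue) plus, once
#' [pseudoCentroids()] has been run, the derived pseudo-centroid
#' positions: dummy atoms 2 A beyond each Ca along the outward (Cb-like)
#' bisector of the two adjacent virtual bonds.
#'
#' @slot modelId character(1) identifier.
#' @slot resno integer vector of 1-based residue indices.
#' @slot xyz numeric n x 3 matrix of Ca positions in Angstrom.
#' @slot centroids numeric n x 3 matrix of pseudo-centroid positions
#'   (0 rows until computed).
#'
#' @seealso [readCaTrace()], [pseudoCentroids()], [scoreModel()]
#' @export
setClass("CaTrace",
  representation(modelId = "character", resno = "integer",
                 xyz = "matrix", centroids = "matrix"),
  prototype(modelId = "model", resno = integer(),
            xyz = matrix(numeric(), 0L, 3L),
            centroids = matrix(numeric(), 0L, 3L)))

setValidity("CaTrace", function(object) {
  n <- length(object@resno)
  if (ncol(object@xyz) != 3L) return("xyz must have 3 columns")
  if (nrow(object@xyz) != n) return("xyz must have one row per residue")
  if (anyDuplicated(object@resno)) return("residue indices must be unique")
  if (is.unsorted(object@resno)) return("residue indices must be sorted")
  if (nrow(object@centroids) && nrow(object@centroids) != n)
    return("centroids, when present, must match residue count")
  TRUE
})

#' Helix-packing parse of a contact map
#'
#' The result of fitting parallel/antiparallel stripe models to every
#' segment pair and (optionally) shifting segment boundaries to maximise
#' the total fit.
#'
#' @slot blocks data.frame with one row per segment pair: `a`, `b`
#'   (segment indices), `orientation` ("parallel"/"antiparallel"/"none"),
#'   `strength_par`, `strength_anti`, `n_support`.
#' @slot adjustedSegments [SegmentSet-class] after boundary optimisation.
#' @slot totalFit numeric(1); sum of winning strengths over all blocks.
#'
#' @seealso [orientationFit()], [optimizeBoundaries()], [packingGraph()]
#' @export
setClass("ParseResult",
  representation(blocks = "data.frame", adjustedSegments = "SegmentSet",
                 totalFit = "numeric"))

#' Low-dimensional fold-space embedding of a model ensemble
#'
#' Coordinates produced by the gradual projection of a pairwise RMSD
#' matrix (triangle-inequality balancing, full-dimensional start,
#' stepwise dimension halving with weighted stress majorization).
#'
#' @slot coords numeric n x dim matrix of embedded model positions.
#' @slot stress numeric(1); weighted residual
#'   sum(w * (delta - d)^2) / sum(w) at the final dimension.
#' @slot dimSchedule integer vector of the intermediate dimensions used.
#'
#' @seealso [projectFoldspace()]
#' @export
setClass("FoldEmbedding",
  representation(coords = "matrix", stress = "numeric",
                 dimSchedule = "integer"))

## ---- show methods -------------------------------------------------------

setMethod("show", "ContactSet", function(object) {
  p <- object@pairs
  cat("ContactSet [", object@method, "]: ", nrow(p), " pairs, L = ",
      object@proteinLength, "\n", sep = "")
  if (nrow(p)) {
    transformed <- !all(is.na(p$e))
    cat("  rank-transformed:", if (transformed) "yes" else "no", "\n")
    top <- p[order(p$rank), , drop = FALSE][seq_len(min(3L, nrow(p))), ]
    for (k in seq_len(nrow(top)))
      cat(sprintf("  #%d  (%d, %d)  p_raw = %.4g%s\n", top$rank[k],
                  top$i[k], top$j[k], top$p_raw[k],
                  if (transformed) sprintf("  e = %.4f", top$e[k]) else ""))
  }
  invisible(NULL)
})

setMethod("show", "SegmentSet", function(object) {
  s <- object@segments
  cat("SegmentSet:", nrow(s), "segment(s)\n")
  for (k in seq_len(nrow(s)))
    cat(sprintf("  %d: %d-%d (N-term %s)%s\n", k, s$start[k], s$end[k],
                s$n_term_side[k],
                if ("agreement" %in% names(s))
                  paste0(" [", s$agreement[k], "]") else ""))
  invisible(NULL)
})

setMethod("show", "TopologyConsensus", function(object) {
  cat("TopologyConsensus over", length(object@perMethod), "methods:",
      paste(names(object@perMethod), collapse = ", "), "\n")
  cat("Consensus:\n")
  show(object@consensus)
  invisible(NULL)
})

setMethod("show", "CaTrace", function(object) {
  cat("CaTrace [", object@modelId, "]: ", length(object@resno),
      " residues", sep = "")
  if (length(object@resno))
    cat(" (", min(object@resno), "-", max(object@resno), ")", sep = "")
  cat("; centroids:", if (nrow(object@centroids)) "yes" else "no", "\n")
  invisible(NULL)
})

setMethod("show", "ParseResult", function(object) {
  cat("ParseResult:", nrow(object@blocks), "block(s), total fit",
      format(object@totalFit, digits = 5), "\n")
  b <- object@blocks
  b <- b[b$orientation != "none", , drop = FALSE]
  if (nrow(b)) cat(" ", packingSummary(object), "\n")
  invisible(NULL)
})

setMethod("show", "FoldEmbedding", function(object) {
  cat("FoldEmbedding:", nrow(object@coords), "models in",
      ncol(object@coords), "dimensions; stress =",
      format(object@stress, digits = 4), "\n")
  invisible(NULL)
})

## ---- accessors ----------------------------------------------------------

#' @describeIn ContactSet-class data.frame of contact pairs (i, j, p_raw,
#'   rank, e), ordered by rank.
#' @param x a `ContactSet`
#' @export
contactPairs <- function(x) {
  stopifnot(is(x, "ContactSet"))
  p <- x@pairs
  p[order(p$rank), , drop = FALSE]
}

#' @describeIn ContactSet-class protein length L.
#' @export
proteinLength <- function(x) {
  stopifnot(is(x, "ContactSet"))
  x@proteinLength
}

#' @describeIn ContactSet-class source method tag.
#' @export
contactMethod <- function(x) {
  stopifnot(is(x, "ContactSet"))
  x@method
}

#' @describeIn SegmentSet-class data.frame of segments.
#' @param x a `SegmentSet` (or `TopologyConsensus` for
#'   `consensusTrack`).
#' @export
segmentTable <- function(x) {
  if (is(x, "TopologyConsensus")) return(x@consensus@segments)
  stopifnot(is(x, "SegmentSet"))
  x@segments
}

#' @describeIn CaTrace-class n x 3 matrix of Ca coordinates.
#' @param x a `CaTrace`
#' @export
caCoords <- function(x) {
  stopifnot(is(x, "CaTrace"))
  x@xyz
}

#' @describeIn CaTrace-class n x 3 matrix of pseudo-centroids (error if
#'   not yet computed).
#' @export
centroidCoords <- function(x) {
  stopifnot(is(x, "CaTrace"))
  if (!nrow(x@centroids))
    stop("pseudo-centroids not computed; call pseudoCentroids() first")
  x@centroids
}

#' @describeIn CaTrace-class model identifier.
#' @export
modelId <- function(x) {
  stopifnot(is(x, "CaTrace"))
  x@modelId
}

#' @describeIn CaTrace-class residue indices present in the trace.
#' @export
residueIds <- function(x) {
  stopifnot(is(x, "CaTrace"))
  x@resno
}

#' @describeIn ParseResult-class data.frame of helix-pair blocks.
#' @param x a `ParseResult`
#' @export
parseBlocks <- function(x) {
  stopifnot(is(x, "ParseResult"))
  x@blocks
}

#' @describeIn ParseResult-class segments after boundary optimisation.
#' @export
adjustedSegments <- function(x) {
  stopifnot(is(x, "ParseResult"))
  x@adjustedSegments
}

#' @describeIn ParseResult-class total winning-orientation fit.
#' @export
totalFit <- function(x) {
  stopifnot(is(x, "ParseResult"))
  x@totalFit
}

#' @describeIn FoldEmbedding-class embedded coordinates.
#' @param x a `FoldEmbedding`
#' @export
foldCoords <- function(x) {
  stopifnot(is(x, "FoldEmbedding"))
  x@coords
}

#' @describeIn FoldEmbedding-class residual weighted stress.
#' @export
embeddingStress <- function(x) {
  stopifnot(is(x, "FoldEmbedding"))
  x@stress
}

## internal constructors ---------------------------------------------------

newContactSet <- function(L, method, pairs) {
  pairs$i <- as.integer(pairs$i)
  pairs$j <- as.integer(pairs$j)
  pairs$rank <- as.integer(pairs$rank)
  if (is.null(pairs$e)) pairs$e <- NA_real_
  rownames(pairs) <- NULL
  new("ContactSet", proteinLength = as.integer(L),
      method = as.character(method), pairs = pairs)
}

newSegmentSet <- function(start, end, n_term_side = "unknown",
                          agreement = NULL) {
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   n_term_side = rep_len(as.character(n_term_side),
                                         length(start)),
                   stringsAsFactors = FALSE)
  if (!is.null(agreement)) df$agreement <- as.character(agreement)
  new("SegmentSet", segments = df)
}

newCaTrace <- function(modelId, resno, xyz,
                       centroids = matrix(numeric(), 0L, 3L)) {
  ord <- order(resno)
  xyz <- as.matrix(xyz)[ord, , drop = FALSE]
  dimnames(xyz) <- NULL
  if (nrow(centroids)) {
    centroids <- as.matrix(centroids)[ord, , drop = FALSE]
    dimnames(centroids) <- NULL
  }
  new("CaTrace", modelId = as.character(modelId),
      resno = as.integer(resno)[ord], xyz = xyz, centroids = centroids)
}
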