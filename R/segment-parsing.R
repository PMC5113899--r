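## Helix-packing stripes in a contact map.
##
## Contacts between two aligned helices form stripes parallel to the map
## diagonal (parallel packing, j - i roughly constant) or orthogonal to
## it (antiparallel packing, i + j roughly constant).  Both stripe models
## are fitted with fixed slopes +/-1 and a free intercept; the strength
## of a fit is the e-weighted support
##   sum_k e_k * max(0, 1 - |d_k - c| / w)
## maximised over the intercept c, with half-width w residues.  The
## maximum over c of this piecewise-linear function is attained at a
## kink, so scanning c over {d_k, d_k - w, d_k + w} is exact.

.stripeStrength <- function(d, e, w) {
  if (!length(d)) return(0)
  cand <- unique(c(d, d - w, d + w))
  a <- abs(outer(d, cand, "-"))
  max(.colSums(e * pmax(0, 1 - a / w), length(d), length(cand)))
}

## winning-orientation fit for residues i in [ai, ae], j in [bi, be]
.blockFit <- function(pi_, pj, pe, ai, ae, bi, be, w, min_support) {
  sel <- pi_ >= ai & pi_ <= ae & pj >= bi & pj <= be
  n <- sum(sel)
  if (n < min_support)
    return(list(par = 0, anti = 0, n = n, orientation = "none",
                strength = 0))
  i <- pi_[sel]; j <- pj[sel]; e <- pe[sel]
  par <- .stripeStrength(j - i, e, w)
  anti <- .stripeStrength(i + j, e, w)
  list(par = par, anti = anti, n = n,
       orientation = if (par > anti) "parallel" else "antiparallel",
       strength = max(par, anti))
}

#' Fit parallel and antiparallel stripe models to one helix pair
#'
#' Collects the contacts between two segments and fits both stripe
#' directions (see the package vignette for the functional form).  The
#' orientation is the stronger direction, or `"none"` when fewer than
#' `min_support` contacts fall in the block (two points fit any line).
#' Ties between equal strengths are resolved to antiparallel, the
#' overwhelmingly common case in membrane bundles.
#'
#' @param contacts a rank-transformed [ContactSet-class].
#' @param seg_a,seg_b two segments, given either as [SegmentSet-class]
#'   rows (`list(start=, end=)`) or numeric `c(start, end)`; order in
#'   sequence does not matter.
#' @param w stripe half-width in residues (default 4).
#' @param min_support minimum contacts for a non-"none" call (default 3).
#' @return one-row data.frame: `a_start`, `a_end`, `b_start`, `b_end`,
#'   `orientation`, `strength_par`, `strength_anti`, `n_support`.
#' @export
orientationFit <- function(contacts, seg_a, seg_b, w = 4, min_support = 3L) {
  stopifnot(is(contacts, "ContactSet"))
  if (!isRankTransformed(contacts))
    stop("contacts must be rank-transformed")
  sa <- .asSegment(seg_a); sb <- .asSegment(seg_b)
  if (sa[1L] > sb[1L]) { tmp <- sa; sa <- sb; sb <- tmp }
  p <- contacts@pairs
  f <- .blockFit(p$i, p$j, p$e, sa[1L], sa[2L], sb[1L], sb[2L],
                 w, min_support)
  data.frame(a_start = sa[1L], a_end = sa[2L],
             b_start = sb[1L], b_end = sb[2L],
             orientation = f$orientation, strength_par = f$par,
             strength_anti = f$anti, n_support = f$n,
             stringsAsFactors = FALSE)
}

.asSegment <- function(s) {
  if (is(s, "SegmentSet")) {
    tb <- segmentTable(s)
    stopifnot(nrow(tb) == 1L)
    return(c(tb$start, tb$end))
  }
  if (is.list(s)) return(c(as.integer(s$start), as.integer(s$end)))
  as.integer(s[1:2])
}

## enumerate feasible (start-shift, end-shift) choices for one segment,
## sorted lexicographically by (ss, es) so that choice index order is
## shift-vector lexicographic order
.segChoices <- function(start, end, max_shift, L) {
  sh <- seq.int(-max_shift, max_shift)
  g <- expand.grid(es = sh, ss = sh)  # es varies fastest => (ss, es) lex
  ns <- start + g$ss; ne <- end + g$es
  ok <- ns >= 1L & ne <= L & ns <= ne
  g <- g[ok, , drop = FALSE]
  data.frame(ss = g$ss, es = g$es, ns = ns[ok], ne = ne[ok],
             absshift = abs(g$ss) + abs(g$es))
}

#' Optimise segment boundaries against the contact map
#'
#' Lets every segment start and end shift by up to `max_shift` residues
#' and maximises the total winning-orientation strength over all segment
#' pairs, re-fitting each block under the candidate boundaries.  Shifted
#' segments must stay within the chain and must not overlap.  The search
#' is an exact dynamic programme over segments in sequence order whose
#' state carries the boundary choices of the last R segments, where R is
#' the longest-range segment pair that can ever attract enough contacts
#' to score; when that state space would be too large the window is
#' capped and the result polished by coordinate ascent (and never
#' returned worse than the unshifted segmentation).  Ties are broken by
#' the smallest total absolute shift, then lexicographically on the
#' shift vector.
#'
#' @param contacts rank-transformed [ContactSet-class].
#' @param segments a [SegmentSet-class] (sorted, non-overlapping).
#' @param max_shift maximum shift per boundary in residues (default 5).
#' @param w,min_support stripe parameters, as [orientationFit()].
#' @param state_limit cap on the DP state count before the window is
#'   truncated (default 2e5).
#' @return a [ParseResult-class] with the re-fitted blocks, the adjusted
#'   segments and the total fit.
#' @export
optimizeBoundaries <- function(contacts, segments, max_shift = 5L,
                               w = 4, min_support = 3L,
                               state_limit = 2e5) {
  stopifnot(is(contacts, "ContactSet"), is(segments, "SegmentSet"),
            max_shift >= 0L)
  if (!isRankTransformed(contacts))
    stop("contacts must be rank-transformed")
  segs <- segmentTable(segments)
  n <- nrow(segs)
  L <- proteinLength(contacts)
  p <- contacts@pairs
  if (n == 0L)
    return(new("ParseResult", blocks = .emptyBlocks(),
               adjustedSegments = segments, totalFit = 0))

  choices <- lapply(seq_len(n), function(k)
    .segChoices(segs$start[k], segs$end[k], max_shift, L))
  m <- vapply(choices, nrow, integer(1))
  if (any(m == 0L)) stop("segment cannot be placed inside the chain")

  ## which pairs can ever score? (widest windows, support threshold)
  coupled <- matrix(FALSE, n, n)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    lo_a <- max(1L, segs$start[a] - max_shift)
    hi_a <- min(L, segs$end[a] + max_shift)
    lo_b <- max(1L, segs$start[b] - max_shift)
    hi_b <- min(L, segs$end[b] + max_shift)
    cnt <- sum(p$i >= lo_a & p$i <= hi_a & p$j >= lo_b & p$j <= hi_b)
    coupled[a, b] <- cnt >= min_support
  }
  ranges <- which(coupled, arr.ind = TRUE)
  R_need <- if (nrow(ranges)) max(ranges[, 2L] - ranges[, 1L]) else 1L
  R <- max(1L, R_need)
  while (R > 1L && prod(sort(m, decreasing = TRUE)[seq_len(min(R, n))]) >
         state_limit)
    R <- R - 1L
  capped <- R < R_need

  ## memoised pair tables S[[key]][ca, cb] for coupled pairs in window
  tables <- new.env(parent = emptyenv())
  pairTab <- function(a, b) {
    key <- paste(a, b)
    if (!is.null(tables[[key]])) return(tables[[key]])
    ca <- choices[[a]]; cb <- choices[[b]]
    S <- matrix(0, nrow(ca), nrow(cb))
    if (coupled[a, b]) {
      for (x in seq_len(nrow(ca))) {
        sel_i <- p$i >= ca$ns[x] & p$i <= ca$ne[x]
        for (y in seq_len(nrow(cb))) {
          f <- .blockFit(p$i[sel_i], p$j[sel_i], p$e[sel_i],
                         ca$ns[x], ca$ne[x], cb$ns[y], cb$ne[y],
                         w, min_support)
          S[x, y] <- f$strength
        }
      }
    }
    tables[[key]] <- S
    S
  }

  ## per-choice lexicographic digit: (ss + s)*b + (es + s), b = 2s+1;
  ## a whole shift vector packs into one double when it fits 52 bits
  b <- 2L * max_shift + 1L
  segval <- lapply(choices, function(ck)
    (ck$ss + max_shift) * b + (ck$es + max_shift))
  lex_ok <- n * 2 * log2(max(b, 2L)) < 52
  lexw <- if (lex_ok) as.numeric(b)^(2 * (n - seq_len(n))) else
    rep(0, n)

  ## vectorised sliding-window DP.  State after step k = the choice
  ## indices of the last W = min(k, R) segments; per state we keep the
  ## best (score desc, total |shift| asc, lex asc) partial solution and
  ## a backpointer for path reconstruction.
  win_cols <- list(matrix(seq_len(m[1L]), ncol = 1L))
  bp <- list(rep(0L, m[1L]))
  pick <- list(seq_len(m[1L]))
  score <- 0 * seq_len(m[1L])
  absshift <- choices[[1L]]$absshift
  lex <- segval[[1L]] * lexw[1L]
  if (n >= 2L) for (k in 2L:n) {
    S <- win_cols[[k - 1L]]
    ns_ <- nrow(S); nc <- m[k]
    st_rep <- rep(seq_len(ns_), each = nc)
    ch_rep <- rep(seq_len(nc), times = ns_)
    prev_idx <- S[st_rep, ncol(S)]
    feas <- choices[[k]]$ns[ch_rep] > choices[[k - 1L]]$ne[prev_idx]
    if (!any(feas)) stop("shifted segments would overlap at every choice")
    st_rep <- st_rep[feas]; ch_rep <- ch_rep[feas]
    add <- 0
    Wlen <- ncol(S)
    for (wi in seq_len(Wlen)) {
      a <- k - 1L - Wlen + wi
      if (coupled[a, k])
        add <- add + pairTab(a, k)[cbind(S[st_rep, wi], ch_rep)]
    }
    new_score <- score[st_rep] + add
    new_abs <- absshift[st_rep] + choices[[k]]$absshift[ch_rep]
    new_lex <- lex[st_rep] + segval[[k]][ch_rep] * lexw[k]
    new_win <- cbind(S[st_rep, , drop = FALSE], ch_rep)
    if (ncol(new_win) > R) new_win <- new_win[, -1L, drop = FALSE]
    ## mixed-radix key over the window; capacity bounded by state_limit
    key <- new_win[, 1L] - 1
    if (ncol(new_win) > 1L) for (cc in 2L:ncol(new_win))
      key <- key * m[k - ncol(new_win) + cc] + (new_win[, cc] - 1)
    ord <- order(key, -new_score, new_abs, new_lex)
    first <- !duplicated(key[ord])
    keep <- ord[first]
    win_cols[[k]] <- new_win[keep, , drop = FALSE]
    bp[[k]] <- st_rep[keep]
    pick[[k]] <- ch_rep[keep]
    score <- new_score[keep]
    absshift <- new_abs[keep]
    lex <- new_lex[keep]
  }

  best <- order(-score, absshift, lex)[1L]
  sel <- integer(n)
  cur <- best
  for (k in rev(seq_len(n))) {
    sel[k] <- pick[[k]][cur]
    cur <- bp[[k]][cur]
  }
  ns <- vapply(seq_len(n), function(k) choices[[k]]$ns[sel[k]], integer(1))
  ne <- vapply(seq_len(n), function(k) choices[[k]]$ne[sel[k]], integer(1))

  fullObjective <- function(ns, ne) {
    tot <- 0
    for (a in seq_len(max(0L, n - 1L))) for (b in (a + 1L):n) {
      f <- .blockFit(p$i, p$j, p$e, ns[a], ne[a], ns[b], ne[b],
                     w, min_support)
      tot <- tot + f$strength
    }
    tot
  }

  if (capped) {
    ## polish: coordinate ascent on the full objective
    repeat {
      improved <- FALSE
      for (k in seq_len(n)) {
        ck <- choices[[k]]
        lo <- if (k > 1L) ne[k - 1L] else 0L
        hi <- if (k < n) ns[k + 1L] else L + 1L
        feas <- which(ck$ns > lo & ck$ne < hi)
        cur <- fullObjective(ns, ne)
        for (ci in feas) {
          ns2 <- ns; ne2 <- ne
          ns2[k] <- ck$ns[ci]; ne2[k] <- ck$ne[ci]
          v <- fullObjective(ns2, ne2)
          if (v > cur + 1e-12) {
            ns <- ns2; ne <- ne2; cur <- v; improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    if (fullObjective(ns, ne) < fullObjective(segs$start, segs$end)) {
      ns <- segs$start; ne <- segs$end
    }
  }

  adj <- newSegmentSet(ns, ne, segs$n_term_side)
  blocks <- .refitBlocks(p, ns, ne, w, min_support)
  tot <- sum(blocks$strength_win)
  new("ParseResult", blocks = blocks[, setdiff(names(blocks),
                                               "strength_win")],
      adjustedSegments = adj, totalFit = tot)
}

.emptyBlocks <- function() {
  data.frame(a = integer(), b = integer(), orientation = character(),
             strength_par = numeric(), strength_anti = numeric(),
             n_support = integer(), stringsAsFactors = FALSE)
}

.refitBlocks <- function(p, ns, ne, w, min_support) {
  n <- length(ns)
  rows <- list(); r <- 0L
  for (a in seq_len(max(0L, n - 1L))) for (b in (a + 1L):n) {
    f <- .blockFit(p$i, p$j, p$e, ns[a], ne[a], ns[b], ne[b],
                   w, min_support)
    r <- r + 1L
    rows[[r]] <- data.frame(a = a, b = b, orientation = f$orientation,
                            strength_par = f$par, strength_anti = f$anti,
                            n_support = f$n, strength_win = f$strength,
                            stringsAsFactors = FALSE)
  }
  if (!r) return(cbind(.emptyBlocks(), strength_win = numeric()))
  do.call(rbind, rows)
}

#' Parse a contact map against fixed segments
#'
#' Convenience wrapper: [optimizeBoundaries()] with `max_shift = 0`,
#' i.e. stripe fits for every segment pair at the declared boundaries.
#'
#' @inheritParams optimizeBoundaries
#' @return a [ParseResult-class].
#' @export
parseContactMap <- function(contacts, segments, w = 4, min_support = 3L)
  optimizeBoundaries(contacts, segments, max_shift = 0L, w = w,
                     min_support = min_support)

#' Helix-packing graph of a parse
#'
#' Builds an undirected [igraph][igraph::graph_from_data_frame] graph
#' over segment indices with one edge per non-"none" block, labelled
#' with the packing orientation and weighted by the winning strength —
#' the machine-readable form of the packing cartoons (solid circle =
#' antiparallel, open circle = parallel).
#'
#' @param parse a [ParseResult-class].
#' @param min_strength drop edges weaker than this (default 0).
#' @return an igraph object (possibly with zero edges).
#' @export
packingGraph <- function(parse, min_strength = 0) {
  stopifnot(is(parse, "ParseResult"))
  b <- parseBlocks(parse)
  nseg <- nrow(segmentTable(adjustedSegments(parse)))
  b <- b[b$orientation != "none", , drop = FALSE]
  wgt <- pmax(b$strength_par, b$strength_anti)
  keep <- wgt >= min_strength
  b <- b[keep, , drop = FALSE]; wgt <- wgt[keep]
  g <- igraph::make_empty_graph(n = nseg, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(nseg))
  if (nrow(b)) {
    g <- igraph::add_edges(g, rbind(b$a, b$b))
    igraph::E(g)$orientation <- b$orientation
    igraph::E(g)$weight <- wgt
  }
  g
}

#' One-line text summary of the packing interactions
#'
#' @param parse a [ParseResult-class].
#' @param min_strength as [packingGraph()].
#' @return character(1) like `"1-2 anti; 3-4 anti; 1-4 anti"` (empty
#'   string when nothing packs).
#' @export
packingSummary <- function(parse, min_strength = 0) {
  b <- parseBlocks(parse)
  b <- b[b$orientation != "none", , drop = FALSE]
  wgt <- pmax(b$strength_par, b$strength_anti)
  b <- b[wgt >= min_strength, , drop = FALSE]
  if (!nrow(b)) return("")
  paste(sprintf("%d-%d %s", b$a, b$b,
                ifelse(b$orientation == "antiparallel", "anti", "par")),
        collapse = "; ")
}
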