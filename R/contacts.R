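#' Rank-transform contact reliabilities onto a common scale
#'
#' Coevolution methods report "probabilities" with very different
#' distributions (EVfold scores, for instance, decay almost
#' exponentially), which unbalances any score summed across methods.
#' The transform therefore replaces the raw reliability of the pair at
#' rank r by
#' \deqn{e = \exp(-r^2 \cdot 0.01 / L)}
#' where L is the protein length.  The number of pairs above any fixed
#' value of e then grows with the square root of the protein length
#' (e.g. exactly `10*sqrt(L)` pairs exceed `exp(-1)`), so proteins of
#' different size are treated comparably.
#'
#' @param set a [ContactSet-class] with ranks assigned.
#' @return the same `ContactSet` with the `e` column filled; ordering by
#'   `e` equals ordering by rank.
#' @export
#' @examples
#' tf <- tempfile(); writeLines("1 10 0 8 0.9", tf)
#' cs <- rankTransform(readContactList(tf, "casp_rr", length = 100))
#' contactPairs(cs)$e  # exp(-0.0001)
rankTransform <- function(set) {
  stopifnot(is(set, "ContactSet"))
  L <- proteinLength(set)
  if (L <= 0L) stop("protein length must be positive")
  p <- set@pairs
  p$e <- exp(-(p$rank^2) * 0.01 / L)
  newContactSet(L, contactMethod(set), p)
}

isRankTransformed <- function(set) {
  nrow(set@pairs) == 0L || !anyNA(set@pairs$e)
}

#' Combine contact sets into a consensus prediction
#'
#' Sums the normalized reliabilities `e` of each pair over all
#' contributing sets (a pair missing from a set contributes 0), re-ranks
#' the union by the summed value and re-applies [rankTransform()] so the
#' consensus lives on the same (0, 1] scale as its inputs.  Summation on
#' the `e` scale is the natural choice because the rank transform exists
#' precisely to equalize the methods' score distributions.
#'
#' @param sets list of rank-transformed [ContactSet-class] objects
#'   sharing one protein length.
#' @param method tag for the result (default `"consensus"`).
#' @return a rank-transformed consensus [ContactSet-class]; its `p_raw`
#'   column holds the summed e values.
#' @export
combineContactSets <- function(sets, method = "consensus") {
  if (!length(sets)) stop("no contact sets supplied")
  stopifnot(all(vapply(sets, is, logical(1), "ContactSet")))
  Ls <- vapply(sets, proteinLength, integer(1))
  if (length(unique(Ls)) != 1L)
    stop("contact sets disagree on protein length: ",
         paste(unique(Ls), collapse = ", "))
  if (!all(vapply(sets, isRankTransformed, logical(1))))
    stop("all sets must be rank-transformed before combining")
  L <- Ls[1L]
  all_pairs <- do.call(rbind, lapply(sets, function(s)
    s@pairs[, c("i", "j", "e")]))
  key <- paste(all_pairs$i, all_pairs$j)
  summed <- tapply(all_pairs$e, key, sum)
  first <- !duplicated(key)
  pairs <- data.frame(i = all_pairs$i[first], j = all_pairs$j[first],
                      p_raw = as.numeric(summed[key[first]]))
  pairs <- assignRanks(pairs)
  rankTransform(newContactSet(L, method, pairs))
}

#' Filter contact pairs by sequence separation and rank
#'
#' Removes pairs with `j - i < min_sep`, keeps the `top_k` survivors by
#' rank, and re-assigns ranks 1..k.  Used both for plotting conventions
#' (top 300, separation >= 5) and for scoring (separation >= 8, i.e.
#' two helical turns, so local pairs cannot dominate).
#'
#' @param set a [ContactSet-class].
#' @param min_sep minimum sequence separation `j - i` retained.
#' @param top_k maximum number of pairs retained (clamped to what is
#'   available; an empty result is legal).
#' @return filtered [ContactSet-class]; `e` is re-computed from the new
#'   ranks when the input was rank-transformed.
#' @export
filterPairs <- function(set, min_sep = 0L, top_k = .Machine$integer.max) {
  stopifnot(is(set, "ContactSet"), min_sep >= 0L, top_k >= 1L)
  p <- contactPairs(set)
  p <- p[p$j - p$i >= min_sep, , drop = FALSE]
  p <- p[seq_len(min(top_k, nrow(p))), , drop = FALSE]
  had_e <- nrow(p) > 0L && !anyNA(p$e)
  p$rank <- seq_len(nrow(p))
  out <- newContactSet(proteinLength(set), contactMethod(set), p)
  if (had_e || isRankTransformed(set)) out <- rankTransform(out)
  out
}
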