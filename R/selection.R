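## Top-slice model selection.
##
## Models are plotted as score (y) against axial RoG (x); the best
## models sit in the upper-left (high score, compact).  A diagonal
## slice y = gradient*x + c with the intercept c pushed as high as
## possible while still admitting up to max_n models selects exactly
## the models with the largest margin y - gradient*x.

#' Select models above a diagonal slice of the score-vs-RoG plot
#'
#' Chooses the largest intercept c such that at most `max_n` models
#' satisfy `score >= gradient * rog + c` and returns that set.  This is
#' equivalent to ranking by the margin `score - gradient * rog`; ties
#' at the boundary are broken by higher score, then lower RoG, then
#' model id.
#'
#' @param scores named numeric vector of model scores (names = model
#'   ids; an unnamed vector gets ids "1", "2", ...).
#' @param rogs numeric vector of axial RoG values, same length/order.
#' @param gradient slice gradient (default 10, score units per
#'   Angstrom).
#' @param max_n maximum number of selected models (default 20).
#' @param tag free-text label for the contact set that produced the
#'   scores.
#' @return list of class `"SliceSelection"`: `tag`, `intercept` (the
#'   realised c), `selected` (model ids), `margin` (named margins of
#'   the selected models).
#' @export
topSlice <- function(scores, rogs, gradient = 10, max_n = 20L,
                     tag = "scores") {
  if (!length(scores)) stop("no models to select from")
  if (length(scores) != length(rogs))
    stop("scores and rogs must have equal length")
  stopifnot(gradient > 0, max_n >= 1L)
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  margin <- as.numeric(scores) - gradient * as.numeric(rogs)
  ord <- order(-margin, -as.numeric(scores), as.numeric(rogs), ids)
  keep <- ord[seq_len(min(max_n, length(ord)))]
  sel <- ids[keep]
  structure(list(tag = tag, intercept = min(margin[keep]),
                 selected = sel,
                 margin = setNames(margin[keep], sel)),
            class = "SliceSelection")
}

#' @export
print.SliceSelection <- function(x, ...) {
  cat("SliceSelection [", x$tag, "]: ", length(x$selected),
      " model(s), intercept c = ", format(x$intercept, digits = 5),
      "\n", sep = "")
  invisible(x)
}

#' Keep models recurring across several slices
#'
#' The cross-slice consensus cull: a model survives only if it appears
#' in at least `min_count` of the slice selections (one slice per
#' contact set).  Survivors are ordered by occurrence count, then mean
#' margin, descending.
#'
#' @param selections list of `"SliceSelection"` objects.
#' @param min_count minimum number of slices a model must appear in
#'   (default 3).
#' @return character vector of model ids.
#' @export
crossSliceCull <- function(selections, min_count = 3L) {
  if (!length(selections)) stop("no slice selections supplied")
  stopifnot(min_count >= 1L)
  all_ids <- unlist(lapply(selections, `[[`, "selected"))
  cnt <- table(all_ids)
  keep <- names(cnt)[cnt >= min_count]
  if (!length(keep)) return(character())
  mm <- vapply(keep, function(id)
    mean(unlist(lapply(selections, function(s)
      if (id %in% s$selected) s$margin[[id]] else NULL))), numeric(1))
  keep[order(-as.numeric(cnt[keep]), -mm, keep)]
}

#' Balance a selected pool across construction methods
#'
#' Per method, keeps the `per_method_target` most-recurrent models (all
#' of them when fewer are available), ties broken by model id, so no
#' single method dominates the consensus pool.
#'
#' @param ids character vector of model ids.
#' @param methods character vector tagging each id's construction
#'   method.
#' @param counts occurrence counts (e.g. how often each id recurred
#'   across scoring schemes); default 1 each.
#' @param per_method_target models retained per method (default 30).
#' @return character vector of retained ids.
#' @export
balancePool <- function(ids, methods, counts = NULL,
                        per_method_target = 30L) {
  stopifnot(length(ids) == length(methods), per_method_target >= 0L)
  if (per_method_target == 0L) return(character())
  if (is.null(counts)) counts <- rep(1L, length(ids))
  out <- character()
  for (m in unique(methods)) {
    sel <- which(methods == m)
    ord <- sel[order(-counts[sel], ids[sel])]
    out <- c(out, ids[ord[seq_len(min(per_method_target, length(ord)))]])
  }
  out
}
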