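## End-to-end workflow: normalize/combine contacts -> parse map ->
## score models -> axial RoG -> compare/embed -> top-slice selection.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full consensus-selection workflow
#'
#' Wires the package operations into one deterministic pass: contact
#' lists are read and rank-transformed, combined into a consensus, the
#' contact map parsed against the segments, every model scored against
#' every contact set (plus the consensus), bundle compactness measured
#' as the axial RoG, the ensemble compared pairwise and embedded into
#' fold space, and a consensus pool selected by per-contact-set top
#' slices with a cross-slice cull.  All outputs are plain TSV (plus a
#' `manifest.txt` recording parameters), written under `out_dir`;
#' re-running on identical inputs reproduces them byte for byte.
#'
#' @param contacts named list: [ContactSet-class] objects, or file
#'   paths (then `dialects` gives each file's dialect).
#' @param models list of [CaTrace-class] objects, or a character vector
#'   of PDB paths, or a directory containing `*.pdb`.
#' @param segments a [SegmentSet-class] or a segment/topology file path
#'   (first method row used).
#' @param out_dir output directory (created if needed); `NULL` skips
#'   all file output.
#' @param dialects per-file dialects when `contacts` are paths.
#' @param params a [scoreParams()] list.
#' @param length protein length (required when contacts are paths
#'   without headers and models do not cover the chain).
#' @param gradient,max_n,min_count top-slice parameters.
#' @param max_shift boundary-shift allowance for the contact parse.
#' @param extend cap extension, 0..10.
#' @param rog_scheme RoG scheme fed to selection (default `"whole"`).
#' @param dim,weight_scale,seed fold-space projection parameters.
#' @return list: `scores` (data.frame), `rogs` (data.frame with flag),
#'   `parse` ([ParseResult-class]), `dist` (matrix or NULL),
#'   `embedding` ([FoldEmbedding-class] or NULL), `slices`,
#'   `pool` (character ids).
#' @export
runPipeline <- function(contacts, models, segments, out_dir = NULL,
                        dialects = NULL, params = scoreParams(),
                        length = NULL, gradient = 10, max_n = 20L,
                        min_count = 3L, max_shift = 2L, extend = 0L,
                        rog_scheme = "whole", dim = 3L,
                        weight_scale = 10, seed = 1L) {
  sets <- .stage("contacts", {
    if (!length(contacts)) stop("no contact sets supplied")
    if (is.character(contacts[[1L]])) {
      if (is.null(dialects)) dialects <- rep("casp_rr", length(contacts))
      sets <- mapply(function(p, d) readContactList(p, d, length = length),
                     contacts, dialects, SIMPLIFY = FALSE)
    } else sets <- contacts
    lapply(sets, function(s)
      if (isRankTransformed(s)) s else rankTransform(s))
  })
  segs <- .stage("segments", {
    if (is.character(segments)) readTopologyTable(segments)[[1L]]
    else segments
  })
  traces <- .stage("models", {
    if (is.character(models) && length(models) == 1L &&
        dir.exists(models))
      models <- list.files(models, pattern = "\\.pdb$",
                           full.names = TRUE)
    if (is.character(models)) {
      if (!length(models)) stop("no models found")
      lapply(models, readCaTrace)
    } else {
      if (!length(models)) stop("no models supplied")
      models
    }
  })
  comb <- .stage("combine",
    if (length(sets) > 1L) combineContactSets(sets) else sets[[1L]])
  parse <- .stage("parse-map",
    optimizeBoundaries(comb, segs, max_shift = max_shift))
  score_tab <- .stage("score", rankModels(traces, sets, params))
  rog_tab <- .stage("rog", {
    caps <- assignCaps(segs, max(vapply(traces, function(t)
      max(residueIds(t)), numeric(1))), extend = extend)
    v <- vapply(traces, function(tr) {
      ax <- bundleAxis(tr, caps)
      axialRog(tr, ax, segs, caps, rog_scheme)
    }, numeric(1))
    data.frame(model = vapply(traces, modelId, character(1)),
               rog = v, flag = flagCompactness(v),
               stringsAsFactors = FALSE)
  })
  dmat <- NULL; emb <- NULL
  if (length(traces) >= 2L) {
    dmat <- .stage("compare", distanceMatrix(traces, segs))
    if (nrow(dmat) >= dim + 1L)
      emb <- .stage("embed",
        projectFoldspace(dmat, dim = dim, weight_scale = weight_scale,
                         seed = seed))
  }
  sel <- .stage("select", {
    rogv <- setNames(rog_tab$rog, rog_tab$model)
    cols <- setdiff(names(score_tab), "model")
    slices <- lapply(cols, function(cn)
      topSlice(setNames(score_tab[[cn]], score_tab$model),
               rogv[score_tab$model], gradient = gradient,
               max_n = max_n, tag = cn))
    pool <- crossSliceCull(slices, min_count = min(min_count,
                                                   length(slices)))
    list(slices = slices, pool = pool)
  })
  out <- list(scores = score_tab, rogs = rog_tab, parse = parse,
              dist = dmat, embedding = emb, slices = sel$slices,
              pool = sel$pool)
  if (!is.null(out_dir)) .stage("write", .writeOutputs(out, out_dir,
    list(s = params$s, d0 = params$d0, n_top = params$n_top,
         min_sep = params$min_sep, gradient = gradient, max_n = max_n,
         min_count = min_count, max_shift = max_shift, extend = extend,
         rog_scheme = rog_scheme, dim = dim,
         weight_scale = weight_scale, seed = seed)))
  out
}

.writeOutputs <- function(out, out_dir, cfg) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) write.table(df, file.path(out_dir, f),
                                    sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  wt(out$scores, "scores.tsv")
  wt(out$rogs, "rog.tsv")
  wt(parseBlocks(out$parse), "parse_blocks.tsv")
  writeSegmentTable(adjustedSegments(out$parse),
                    file.path(out_dir, "parse_segments.tsv"))
  if (!is.null(out$dist))
    write.table(out$dist, file.path(out_dir, "distance_matrix.tsv"),
                sep = "\t", quote = FALSE)
  if (!is.null(out$embedding))
    write.table(data.frame(model = rownames(foldCoords(out$embedding)),
                           foldCoords(out$embedding)),
                file.path(out_dir, "embedding.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  writeLines(out$pool, file.path(out_dir, "pool.txt"))
  manifest <- c(sprintf("tmbundle_version=%s",
                        as.character(utils::packageVersion("tmbundle"))),
                sprintf("%s=%s", names(cfg),
                        vapply(cfg, as.character, character(1))))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(NULL)
}
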