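## Topology tracks use the i/M/o alphabet: i = inside (cytoplasmic),
## M = membrane, o = outside (periplasmic).

trackToSegments <- function(track) {
  letters_ <- strsplit(track, "")[[1]]
  bad <- setdiff(unique(letters_), c("i", "M", "o"))
  if (length(bad))
    stop("unknown topology letter(s): ", paste(bad, collapse = ", "))
  r <- rle(letters_ == "M")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg_start <- starts[r$values]
  seg_end <- ends[r$values]
  if (!length(seg_start))
    return(newSegmentSet(integer(), integer(), character()))
  side <- vapply(seg_start, function(s) {
    if (s == 1L) return("unknown")
    switch(letters_[s - 1L], i = "inside", o = "outside", "unknown")
  }, character(1))
  newSegmentSet(seg_start, seg_end, side)
}

segmentsToTrack <- function(segset, chain_length) {
  s <- segmentTable(segset)
  out <- rep("o", chain_length)
  side <- "i"  # assume N-terminus inside unless told otherwise
  if (nrow(s) && s$n_term_side[1L] == "outside") side <- "o"
  pos <- 1L
  for (k in seq_len(nrow(s))) {
    if (s$start[k] > pos) out[pos:(s$start[k] - 1L)] <- side
    out[s$start[k]:s$end[k]] <- "M"
    side <- if (side == "i") "o" else "i"
    pos <- s$end[k] + 1L
  }
  if (pos <= chain_length) out[pos:chain_length] <- side
  paste(out, collapse = "")
}

#' Read per-method transmembrane topology predictions
#'
#' Ingests a TOPCONS-style text file with one row per method.  Two row
#' forms are accepted and may be mixed: a per-residue letter track
#' (`method  iiiMMMMooo`, alphabet i/M/o) or segment-table rows
#' (`method  start  end  n_term_side`, repeated per segment).  Blank
#' lines and `#` comments are skipped.
#'
#' @param path file path.
#' @return named list of [SegmentSet-class] objects, one per method.
#' @export
readTopologyTable <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  track_rows <- list()
  seg_rows <- list()
  track_len <- NA_integer_
  for (x in lines) {
    f <- strsplit(x, "\\s+")[[1]]
    if (length(f) == 2L && grepl("^[iMo]+$", f[2L])) {
      if (!is.na(track_len) && nchar(f[2L]) != track_len)
        stop("inconsistent track lengths in ", path)
      track_len <- nchar(f[2L])
      track_rows[[f[1L]]] <- trackToSegments(f[2L])
    } else if (length(f) >= 3L &&
               !is.na(suppressWarnings(as.integer(f[2L])))) {
      seg_rows[[length(seg_rows) + 1L]] <-
        data.frame(method = f[1L], start = as.integer(f[2L]),
                   end = as.integer(f[3L]),
                   n_term_side = if (length(f) >= 4L) f[4L] else "unknown",
                   stringsAsFactors = FALSE)
    } else stop("unparseable topology row: ", x)
  }
  out <- track_rows
  if (length(seg_rows)) {
    tb <- do.call(rbind, seg_rows)
    for (m in unique(tb$method)) {
      sub <- tb[tb$method == m, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      out[[m]] <- newSegmentSet(sub$start, sub$end, sub$n_term_side)
    }
  }
  if (!length(out)) stop("no topology rows found in ", path)
  out
}

#' Write segments as a 1-based TSV (the tool's native segment format)
#'
#' Columns: method, start, end, n_term_side (and agreement when
#' present).  Readable back with [readTopologyTable()].
#'
#' @param segsets named list of [SegmentSet-class] (or a single one,
#'   written under method name "segments").
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSegmentTable <- function(segsets, path) {
  if (is(segsets, "SegmentSet")) segsets <- list(segments = segsets)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# method\tstart\tend\tn_term_side", con)
  for (m in names(segsets)) {
    s <- segmentTable(segsets[[m]])
    for (k in seq_len(nrow(s)))
      writeLines(paste(m, s$start[k], s$end[k], s$n_term_side[k],
                       sep = "\t"), con)
  }
  invisible(path)
}

#' Thick/thin consensus of per-method topology predictions
#'
#' Votes per residue: residues every method calls membrane form
#' unanimous stretches ("all", the thick bar), residues at least two
#' methods call membrane form majority stretches ("majority", the thin
#' bar).  Maximal runs of (all or majority) residues become consensus
#' segments; a run is tagged `"all"` only when every residue in it is
#' unanimous.  The N-terminal side of each consensus segment is the
#' majority vote over methods, ties giving `"unknown"`.
#'
#' @param per_method named list of >= 2 [SegmentSet-class] objects.
#' @param chain_length protein length; defaults to the largest segment
#'   end seen.
#' @return a [TopologyConsensus-class].
#' @export
consensusSegments <- function(per_method, chain_length = NULL) {
  if (length(per_method) < 2L)
    stop("consensus requires at least two methods")
  stopifnot(all(vapply(per_method, is, logical(1), "SegmentSet")))
  if (is.null(chain_length))
    chain_length <- max(vapply(per_method, function(s) {
      tb <- segmentTable(s)
      if (nrow(tb)) max(tb$end) else 0L
    }, numeric(1)))
  n_meth <- length(per_method)
  votes <- matrix(FALSE, n_meth, chain_length)
  for (k in seq_len(n_meth)) {
    tb <- segmentTable(per_method[[k]])
    for (r in seq_len(nrow(tb)))
      votes[k, tb$start[r]:tb$end[r]] <- TRUE
  }
  nv <- colSums(votes)
  member <- nv >= 2L
  unanimous <- nv == n_meth
  r <- rle(member)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  seg_start <- starts[r$values]; seg_end <- ends[r$values]
  if (length(seg_start)) {
    agreement <- vapply(seq_along(seg_start), function(k)
      if (all(unanimous[seg_start[k]:seg_end[k]])) "all" else "majority",
      character(1))
    ## majority vote on the N-terminal side, matching each consensus
    ## segment to the overlapping segment of each method
    side <- vapply(seq_along(seg_start), function(k) {
      v <- vapply(per_method, function(s) {
        tb <- segmentTable(s)
        hit <- which(tb$start <= seg_end[k] & tb$end >= seg_start[k])
        if (length(hit)) tb$n_term_side[hit[1L]] else NA_character_
      }, character(1))
      v <- v[!is.na(v) & v != "unknown"]
      if (!length(v)) return("unknown")
      tt <- sort(table(v), decreasing = TRUE)
      if (length(tt) > 1L && tt[1L] == tt[2L]) "unknown" else names(tt)[1L]
    }, character(1))
    cons <- newSegmentSet(seg_start, seg_end, side, agreement)
  } else {
    cons <- newSegmentSet(integer(), integer(), character(), character())
  }
  new("TopologyConsensus", perMethod = per_method, consensus = cons)
}
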