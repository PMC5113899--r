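## Contact-list readers and writer.
##
## Dialect column maps (the tool's format reference):
##   casp_rr : optional header lines (PFRMAT/TARGET/AUTHOR/METHOD/MODEL/
##             REMARK/END and bare sequence lines are skipped); body lines
##             "i j d_lo d_hi p" or "i j p", whitespace-separated.
##   psicov  : "i j 0 8 score", whitespace-separated, no header.
##   gremlin : delimited table (tab/space) with a header row; columns named
##             i and j (or residue_i/residue_j) and the score in a column
##             named one of score/scaled_score/prob/probability; extra
##             columns are ignored.
##   evfold  : comma- or whitespace-separated "i A_i j A_j fn cn" with the
##             coupling score in the last column; a header row is detected
##             and skipped.

.dialects <- c("casp_rr", "psicov", "gremlin", "evfold")

#' Read a ranked contact list
#'
#' Parses a coevolution contact prediction file in one of four dialects
#' into a [ContactSet-class].  Pairs are stored with `i < j` (swapping
#' where needed) and ranks are assigned by descending raw reliability,
#' ties broken by (i, j) lexicographic order.
#'
#' @param path file path.
#' @param dialect one of `"casp_rr"`, `"psicov"`, `"gremlin"`, `"evfold"`.
#' @param length protein length L.  Required unless the file carries it
#'   (a CASP-RR `TARGET`/`REMARK L=` header is not assumed); for
#'   `casp_rr` a `REMARK L=<n>` line is honoured.
#' @param method source tag stored in the result; defaults to the dialect.
#' @param zero_based set `TRUE` for files that number residues from 0.
#' @return a [ContactSet-class] (not yet rank-transformed: `e` is `NA`).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".rr")
#' writeLines(c("1 10 0 8 0.9", "2 12 0 8 0.5", "3 14 0 8 0.7"), tf)
#' cs <- readContactList(tf, "casp_rr", length = 20)
#' contactPairs(cs)
readContactList <- function(path, dialect = c("casp_rr", "psicov",
                                              "gremlin", "evfold"),
                            length = NULL, method = NULL,
                            zero_based = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("contact file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (is.null(method)) method <- dialect

  parse_fail <- function(ln) stop("malformed ", dialect, " line ", ln,
                                  " in ", path, call. = FALSE)
  rows <- switch(dialect,
    casp_rr = {
      out <- list(); n <- 0L
      for (ln in seq_along(lines)) {
        x <- trimws(lines[ln])
        if (x == "" || grepl("^(PFRMAT|TARGET|AUTHOR|METHOD|MODEL|REMARK|END)",
                             x)) {
          m <- regmatches(x, regexec("^REMARK\\s+L=(\\d+)", x))[[1]]
          if (length(m) == 2L && is.null(length)) length <- as.integer(m[2])
          next
        }
        if (grepl("^[A-Za-z]+$", x)) next  # wrapped sequence line
        f <- strsplit(x, "\\s+")[[1]]
        if (!(length(f) %in% c(3L, 5L))) parse_fail(ln)
        v <- suppressWarnings(as.numeric(f))
        if (anyNA(v[c(1L, 2L, length(f))])) parse_fail(ln)
        n <- n + 1L
        out[[n]] <- c(v[1L], v[2L], v[length(f)])
      }
      out
    },
    psicov = {
      out <- list(); n <- 0L
      for (ln in seq_along(lines)) {
        x <- trimws(lines[ln])
        if (x == "") next
        f <- strsplit(x, "\\s+")[[1]]
        if (length(f) != 5L) parse_fail(ln)
        v <- suppressWarnings(as.numeric(f))
        if (anyNA(v)) parse_fail(ln)
        n <- n + 1L
        out[[n]] <- v[c(1L, 2L, 5L)]
      }
      out
    },
    gremlin = {
      tb <- tryCatch(read.table(path, header = TRUE,
                                stringsAsFactors = FALSE),
                     error = function(e) stop("malformed gremlin table in ",
                                              path, ": ",
                                              conditionMessage(e),
                                              call. = FALSE))
      nm <- tolower(names(tb))
      ic <- match(TRUE, nm %in% c("i", "residue_i", "res_i"))
      jc <- match(TRUE, nm %in% c("j", "residue_j", "res_j"))
      sc <- match(TRUE, nm %in% c("score", "scaled_score", "prob",
                                  "probability", "r_sco"))
      if (anyNA(c(ic, jc, sc)))
        stop("gremlin table in ", path,
             " lacks recognisable i/j/score columns", call. = FALSE)
      lapply(seq_len(nrow(tb)),
             function(k) as.numeric(c(tb[k, ic], tb[k, jc], tb[k, sc])))
    },
    evfold = {
      out <- list(); n <- 0L
      for (ln in seq_along(lines)) {
        x <- trimws(lines[ln])
        if (x == "") next
        f <- strsplit(x, "[,\\s]+")[[1]]
        if (length(f) < 5L) parse_fail(ln)
        v1 <- suppressWarnings(as.numeric(f[1L]))
        if (is.na(v1)) {
          if (ln == 1L) next else parse_fail(ln)  # header row
        }
        v3 <- suppressWarnings(as.numeric(f[3L]))
        vs <- suppressWarnings(as.numeric(f[length(f)]))
        if (anyNA(c(v3, vs))) parse_fail(ln)
        n <- n + 1L
        out[[n]] <- c(v1, v3, vs)
      }
      out
    })

  if (!length(rows)) stop("no contact pairs found in ", path)
  m <- do.call(rbind, rows)
  i <- as.integer(round(m[, 1L])); j <- as.integer(round(m[, 2L]))
  if (zero_based) { i <- i + 1L; j <- j + 1L }
  p <- m[, 3L]
  swap <- i > j
  if (any(swap)) { tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp }
  if (any(i == j)) stop("self-contact (i == j) in ", path)
  if (is.null(length)) length <- max(j)
  L <- as.integer(length)
  if (any(j > L)) stop("residue index ", max(j), " exceeds protein length ",
                       L, " in ", path)
  if (anyDuplicated(cbind(i, j)))
    stop("duplicate contact pair in ", path)
  pairs <- data.frame(i = i, j = j, p_raw = p)
  pairs <- assignRanks(pairs)
  newContactSet(L, method, pairs)
}

## descending p_raw, ties by (i, j) lexicographic
assignRanks <- function(pairs) {
  ord <- order(-pairs$p_raw, pairs$i, pairs$j)
  pairs <- pairs[ord, , drop = FALSE]
  pairs$rank <- seq_len(nrow(pairs))
  pairs$e <- if (is.null(pairs$e)) NA_real_ else pairs$e
  rownames(pairs) <- NULL
  pairs
}

#' Write a contact set in CASP-RR format
#'
#' The canonical interchange writer: a `REMARK L=` header carrying the
#' protein length followed by body lines `i j 0 8 p_raw` in rank order.
#' [readContactList()] round-trips the output exactly.
#'
#' @param set a [ContactSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeContactList <- function(set, path) {
  stopifnot(is(set, "ContactSet"))
  p <- contactPairs(set)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("PFRMAT RR",
               paste0("REMARK L=", proteinLength(set)),
               paste0("REMARK METHOD ", contactMethod(set))), con)
  if (nrow(p))  # full precision so write/read round-trips exactly
    writeLines(sprintf("%d %d 0 8 %.17g", p$i, p$j, p$p_raw), con)
  writeLines("END", con)
  invisible(path)
}
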