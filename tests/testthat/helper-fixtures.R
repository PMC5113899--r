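## Shared fixture builders.  Everything is generated in code; no data
## files are read.

## the canonical 4-helix up-down test bundle
defaultBundle <- function(...) makeBundle(bundleSpec(...))

## a ContactSet with explicit pairs (assigns ranks, optionally e)
contactSetFromPairs <- function(i, j, p, L, transform = TRUE,
                                method = "test") {
  df <- data.frame(i = i, j = j, p_raw = p)
  cs <- tmbundle:::newContactSet(L, method, tmbundle:::assignRanks(df))
  if (transform) rankTransform(cs) else cs
}

## random ContactSet for property tests
randomContactSet <- function(L = 60L, n = 25L, seed = 1L,
                             method = "rand") {
  set.seed(seed)
  i <- sample.int(L - 5L, 3L * n, replace = TRUE)
  j <- pmin(L, i + sample(5:(L %/% 2L), 3L * n, replace = TRUE))
  df <- unique(data.frame(i = i, j = j))
  df <- df[df$i < df$j, , drop = FALSE]
  df <- df[seq_len(min(n, nrow(df))), , drop = FALSE]
  df$p_raw <- runif(nrow(df))
  contactSetFromPairs(df$i, df$j, df$p_raw, L, method = method)
}

## random 3-helix boundary-optimisation instance
randomParsingInstance <- function(seed) {
  set.seed(seed)
  st <- c(5L, 22L, 40L) + sample(-2:2, 3L, replace = TRUE)
  en <- st + sample(6:9, 3L, replace = TRUE)
  segs <- tmbundle:::newSegmentSet(st, en, "unknown")
  cs <- randomContactSet(L = 60L, n = 25L, seed = seed + 1000L)
  list(contacts = cs, segments = segs)
}

## independent exhaustive-enumeration oracle for boundary optimisation:
## enumerates every feasible boundary combination, scores each via
## orientationFit, and applies the declared tie-break (max total fit,
## then min total |shift|, then lexicographic on the shift vector).
bruteBoundaryOracle <- function(cs, segs, shift) {
  s <- segmentTable(segs)
  n <- nrow(s)
  L <- proteinLength(cs)
  ch <- lapply(seq_len(n), function(k) {
    g <- expand.grid(es = -shift:shift, ss = -shift:shift)
    ns <- s$start[k] + g$ss
    ne <- s$end[k] + g$es
    ok <- ns >= 1L & ne <= L & ns <= ne
    data.frame(ss = g$ss[ok], es = g$es[ok], ns = ns[ok], ne = ne[ok])
  })
  m <- vapply(ch, nrow, integer(1))
  ## pair tables from the public single-block fit
  tab <- list()
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    S <- matrix(0, m[a], m[b])
    for (x in seq_len(m[a])) for (y in seq_len(m[b])) {
      f <- orientationFit(cs, c(ch[[a]]$ns[x], ch[[a]]$ne[x]),
                          c(ch[[b]]$ns[y], ch[[b]]$ne[y]))
      S[x, y] <- if (f$orientation == "none") 0 else
        max(f$strength_par, f$strength_anti)
    }
    tab[[paste(a, b)]] <- S
  }
  grid <- expand.grid(lapply(rev(m), seq_len))
  grid <- as.matrix(grid[, rev(seq_len(n)), drop = FALSE])
  feas <- rep(TRUE, nrow(grid))
  for (k in 2L:n)
    feas <- feas & ch[[k]]$ns[grid[, k]] > ch[[k - 1L]]$ne[grid[, k - 1L]]
  grid <- grid[feas, , drop = FALSE]
  tot <- rep(0, nrow(grid))
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
    tot <- tot + tab[[paste(a, b)]][cbind(grid[, a], grid[, b])]
  absshift <- rep(0, nrow(grid))
  lex <- rep(0, nrow(grid))
  bb <- 2 * shift + 1
  for (k in seq_len(n)) {
    absshift <- absshift + abs(ch[[k]]$ss[grid[, k]]) +
      abs(ch[[k]]$es[grid[, k]])
    lex <- lex * bb^2 + (ch[[k]]$ss[grid[, k]] + shift) * bb +
      (ch[[k]]$es[grid[, k]] + shift)
  }
  best <- order(-tot, absshift, lex)[1L]
  list(tot = tot[best],
       ns = vapply(seq_len(n), function(k) ch[[k]]$ns[grid[best, k]],
                   integer(1)),
       ne = vapply(seq_len(n), function(k) ch[[k]]$ne[grid[best, k]],
                   integer(1)))
}

## rigid rotation + translation of a trace
transformTrace <- function(trace, angle = 0.7,
                           axis = c(0, 0, 1), shift = c(5, -3, 2)) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3L, 3L, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  xyz <- caCoords(trace) %*% t(R)
  xyz <- sweep(xyz, 2L, shift, `+`)
  tmbundle:::newCaTrace(modelId(trace), residueIds(trace), xyz)
}
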