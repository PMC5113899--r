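## Gradual fold-space projection.
##
## Pairwise RMSD values form a consistent Euclidean metric only in n-1
## dimensions, so instead of a direct low-dimensional MDS the ensemble
## is embedded exactly (where possible) in n-1 dimensions and the
## dimensionality then reduced in gradual stages (a halving schedule),
## each stage re-refining coordinates against the target distances by
## weighted stress majorization.  Before projection the distance matrix
## is repaired to satisfy the triangle inequality, replacing any
## violating distance by its tightest path bound.

.triangleBalance <- function(D, tol = 1e-9) {
  n <- nrow(D)
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`) + tol * 0)
  D
}

.pinvLaplacian <- function(V) {
  n <- nrow(V)
  J <- matrix(1 / n, n, n)
  out <- tryCatch(solve(V + J) - J, error = function(e) NULL)
  if (!is.null(out)) return(out)
  sv <- svd(V)
  pos <- sv$d > max(sv$d) * 1e-12
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

.weightedStress <- function(X, delta, W) {
  d <- as.matrix(dist(X))
  ut <- upper.tri(delta)
  sum(W[ut] * (delta[ut] - d[ut])^2) / sum(W[ut])
}

## SMACOF majorization at fixed dimension
.refineStage <- function(X, delta, W, tol = 1e-6, max_iter = 500L) {
  n <- nrow(X)
  V <- -W; diag(V) <- 0; diag(V) <- -rowSums(V)
  Vp <- .pinvLaplacian(V)
  s_old <- .weightedStress(X, delta, W)
  for (it in seq_len(max_iter)) {
    d <- as.matrix(dist(X))
    ratio <- ifelse(d > 1e-12, delta / d, 0)
    B <- -W * ratio; diag(B) <- 0; diag(B) <- -rowSums(B)
    X <- Vp %*% (B %*% X)
    s_new <- .weightedStress(X, delta, W)
    if (abs(s_old - s_new) <= tol * max(s_old, 1e-12)) {
      s_old <- s_new; break
    }
    s_old <- s_new
  }
  list(X = X, stress = s_old)
}

#' Project a distance matrix into low-dimensional fold space
#'
#' Three stages: (1) repair triangle-inequality violations by the
#' tightest path bound; (2) initialise coordinates in n-1 dimensions by
#' classical scaling, which reproduces the repaired distances exactly
#' where they are Euclidean; (3) halve the dimension stepwise down to
#' `dim`, after each reduction (projection onto the principal axes)
#' running weighted stress majorization with distance weights
#' `w_ab = min(1, weight_scale / d_ab)` — close pairs count fully,
#' distant (less reliable) similarities are down-weighted.
#'
#' @param d symmetric non-negative distance matrix, zero diagonal.
#' @param dim target dimension, 2 or 3 (any `>= 1` accepted).
#' @param weight_scale distance (Angstrom) below which pairs get full
#'   weight 1 (default 10).
#' @param seed integer; controls only the tiny tie-breaking
#'   perturbation applied before each reduction stage.
#' @param tol relative stress-change convergence tolerance (default
#'   1e-6).
#' @param max_iter majorization iterations per stage (default 500).
#' @return a [FoldEmbedding-class].
#' @export
projectFoldspace <- function(d, dim = 3L, weight_scale = 10, seed = 1L,
                             tol = 1e-6, max_iter = 500L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be symmetric")
  if (any(d < 0) || any(abs(diag(d)) > 1e-12))
    stop("distances must be non-negative with a zero diagonal")
  if (n < dim + 1L) stop("need at least dim + 1 models")
  delta <- .triangleBalance((d + t(d)) / 2)
  W <- ifelse(delta > 1e-12, pmin(1, weight_scale / delta), 1)
  diag(W) <- 0

  k0 <- n - 1L
  X <- suppressWarnings(cmdscale(delta, k = k0))
  if (ncol(X) < k0)
    X <- cbind(X, matrix(0, n, k0 - ncol(X)))

  schedule <- integer()
  kcur <- k0
  while (kcur > dim) {
    kcur <- max(dim, ceiling(kcur / 2))
    schedule <- c(schedule, kcur)
  }
  if (!length(schedule)) schedule <- as.integer(dim)

  set.seed(as.integer(seed) %% .Machine$integer.max)
  scale0 <- max(delta)
  for (k in schedule) {
    Xc <- sweep(X, 2L, colMeans(X))
    X <- Xc %*% svd(Xc)$v[, seq_len(k), drop = FALSE]
    X <- X + matrix(rnorm(n * k, sd = 1e-7 * max(scale0, 1)), n, k)
    res <- .refineStage(X, delta, W, tol, max_iter)
    X <- res$X
  }
  stress <- .weightedStress(X, delta, W)
  rownames(X) <- rownames(d)
  new("FoldEmbedding", coords = X, stress = stress,
      dimSchedule = as.integer(schedule))
}
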