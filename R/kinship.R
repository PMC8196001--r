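#' Genetic relationship (kinship) matrix
#'
#' `K = Z Z' / m` with `Z` the column-standardized dosage matrix: each
#' variant centered at `2 * EAF` and scaled by `sqrt(2 * EAF * (1 - EAF))`.
#' Under Hardy-Weinberg equilibrium the diagonal averages ~1 and
#' off-diagonals for unrelated pairs have SD ~ `1/sqrt(m)`. Monomorphic
#' variants (and variants below `maf_min`) are excluded.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency for inclusion.
#' @return symmetric `n x n` matrix with sample IDs as dimnames.
#' @export
kinship <- function(g, maf_min = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"))
  eaf <- g$variants$eaf
  keep <- pmin(eaf, 1 - eaf) >= max(maf_min, 1e-12)
  if (sum(keep) < 2)
    stop("fewer than 2 polymorphic variants pass maf_min = ", maf_min)
  Z <- standardize_dosage(g$dosage[, keep, drop = FALSE], eaf[keep])
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(g$samples, g$samples)
  K
}

standardize_dosage <- function(D, eaf) {
  Z <- sweep(D, 2, 2 * eaf, "-")
  sweep(Z, 2, sqrt(2 * eaf * (1 - eaf)), "/")
}

#' LD-informed variant weights
#'
#' Down-weights variants in proportion to how well they are tagged by
#' their neighbours: `w_j = 1 / sum_{k in window(j)} r2_jk`, with the
#' self-term `r2_jj = 1` included, so weights lie in (0, 1]. A variant with
#' no LD partners gets weight 1; `d` perfect copies each get `1/d`. This is
#' an inverse local LD score, a simplification of tagging-based weight
#' solvers that preserves the down-weighting of redundant variants.
#'
#' @param g a [genotype_matrix()] with position-sorted variants.
#' @param window_bp half-width of the physical window for local LD
#'   (default 1 Mb).
#' @return numeric vector of per-variant weights.
#' @export
ld_weights <- function(g, window_bp = 1e6) {
  stopifnot(inherits(g, "genotype_matrix"))
  v <- g$variants
  m <- nrow(v)
  if (is.unsorted(order(v$chrom, v$pos) == seq_len(m)) &&
      any(order(v$chrom, v$pos) != seq_len(m)))
    stop("variants must be sorted by chrom, pos")
  X <- g$dosage
  mu <- colMeans(X)
  sds <- sqrt(pmax(colMeans(X^2) - mu^2, 0))
  poly <- sds > 1e-12
  Z <- sweep(X, 2, mu, "-")
  Z[, poly] <- sweep(Z[, poly, drop = FALSE], 2, sds[poly], "/")
  Z[, !poly] <- 0
  n <- nrow(X)
  ld_score <- numeric(m)
  chunk <- 256L
  for (start in seq(1L, m, by = chunk)) {
    idx <- start:min(start + chunk - 1L, m)
    lo <- findInterval(v$pos[idx] - window_bp - 1, v$pos) + 1L
    hi <- findInterval(v$pos[idx] + window_bp, v$pos)
    nb_lo <- min(lo); nb_hi <- max(hi)
    nb <- nb_lo:nb_hi
    R <- crossprod(Z[, idx, drop = FALSE], Z[, nb, drop = FALSE]) / n
    same_chrom <- outer(v$chrom[idx], v$chrom[nb], "==")
    in_window <- outer(v$pos[idx], v$pos, function(a, b) abs(a - b) <= window_bp)[, nb, drop = FALSE]
    R2 <- R^2 * same_chrom * in_window
    ld_score[idx] <- rowSums(R2)
  }
  ld_score[!poly] <- 1 # monomorphic: self-only
  ld_score[poly] <- pmax(ld_score[poly], 1) # self-term floor
  1 / ld_score
}

#' Weighted kinship matrix
#'
#' `K = Z W Z' / c` with `W = diag(weights)` and the trace normalization
#' `c` chosen so the mean diagonal equals 1. Invariant to rescaling all
#' weights by a constant; unit weights reduce to [kinship()].
#'
#' @param g a [genotype_matrix()].
#' @param weights nonnegative per-variant weights (length `m`).
#' @return symmetric `n x n` matrix, mean diagonal exactly 1.
#' @export
weighted_kinship <- function(g, weights) {
  stopifnot(inherits(g, "genotype_matrix"))
  m <- ncol(g$dosage)
  if (length(weights) != m) stop("weights must have length ", m)
  if (any(weights < 0) || any(!is.finite(weights)))
    stop("weights must be finite and nonnegative")
  if (all(weights == 0)) stop("all weights are zero")
  eaf <- g$variants$eaf
  poly <- pmin(eaf, 1 - eaf) > 1e-12 & weights > 0
  if (sum(poly) < 2) stop("fewer than 2 weighted polymorphic variants")
  Z <- standardize_dosage(g$dosage[, poly, drop = FALSE], eaf[poly])
  Zw <- sweep(Z, 2, sqrt(weights[poly]), "*")
  K <- tcrossprod(Zw)
  K <- K / mean(diag(K))
  dimnames(K) <- list(g$samples, g$samples)
  K
}

#' Greedy LD pruning
#'
#' Walks variants in position order and keeps a variant only if its
#' squared correlation with every previously kept variant inside the
#' trailing window is below `r2_max`. Principal-component/Tracy-Widom
#' analysis assumes approximately independent markers, so ancestry PCs
#' should be computed on a pruned set.
#'
#' @param g a [genotype_matrix()].
#' @param r2_max maximum allowed pairwise r2 (default 0.2).
#' @param window number of previously kept variants to test against.
#' @return the pruned `genotype_matrix`.
#' @export
ld_prune <- function(g, r2_max = 0.2, window = 50L) {
  stopifnot(inherits(g, "genotype_matrix"))
  X <- g$dosage
  n <- nrow(X)
  mu <- colMeans(X)
  sds <- sqrt(pmax(colMeans(X^2) - mu^2, 0))
  m <- ncol(X)
  Z <- sweep(X, 2, mu, "-")
  poly <- sds > 1e-12
  Z[, poly] <- sweep(Z[, poly, drop = FALSE], 2, sds[poly], "/")
  keep <- integer(0)
  for (j in seq_len(m)) {
    if (!poly[j]) next
    recent <- utils::tail(keep, window)
    if (length(recent)) {
      r <- crossprod(Z[, recent, drop = FALSE], Z[, j]) / n
      if (max(r^2) > r2_max) next
    }
    keep <- c(keep, j)
  }
  if (!length(keep)) stop("no variants left after pruning")
  subset_variants(g, keep)
}
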