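#' Jensen-Shannon distance between two compositions
#'
#' `D(a, b) = sqrt( (KL(a || m) + KL(b || m)) / 2 )` with
#' `m = (a + b) / 2`, Kullback-Leibler terms evaluated with base-2
#' logarithms and the `0 * log 0 = 0` convention. With base-2 logs the
#' distance is bounded by 1, with equality exactly when the supports are
#' disjoint.
#'
#' @param a,b non-negative numeric vectors of equal length, each summing
#'   to 1 (tolerance 1e-8).
#' @return the distance, a scalar in \[0, 1\].
#' @export
jsd_pair <- function(a, b) {
  if (length(a) != length(b)) stop("compositions must have equal length")
  if (any(a < 0) || any(b < 0)) stop("compositions must be non-negative")
  if (abs(sum(a) - 1) > 1e-8 || abs(sum(b) - 1) > 1e-8)
    stop("compositions must each sum to 1")
  m <- (a + b) / 2
  ia <- a > 0
  ib <- b > 0
  div <- 0.5 * (sum(a[ia] * log2(a[ia] / m[ia])) +
                  sum(b[ib] * log2(b[ib] / m[ib])))
  sqrt(max(0, min(1, div)))
}

#' Pairwise Jensen-Shannon distance matrix
#'
#' @param compositions numeric matrix, one composition per row (rows sum
#'   to 1), or an `otu_table` (converted via [to_relative()]).
#' @return symmetric matrix with zero diagonal and entries in \[0, 1\].
#' @export
jsd_matrix <- function(compositions) {
  if (inherits(compositions, "otu_table"))
    compositions <- to_relative(compositions)
  stopifnot(is.matrix(compositions))
  if (any(compositions < 0)) stop("compositions must be non-negative")
  rs <- rowSums(compositions)
  if (any(abs(rs - 1) > 1e-8)) stop("every row must sum to 1")
  n <- nrow(compositions)
  # vectorised over pairs: entropy form, H(m) - (H(a)+H(b))/2 per pair
  P <- compositions
  plogp <- P * log2(P)
  plogp[P == 0] <- 0
  h <- -rowSums(plogp)               # per-sample Shannon entropy (bits)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    Mi <- (P[(i + 1L):n, , drop = FALSE] +
             matrix(P[i, ], n - i, ncol(P), byrow = TRUE)) / 2
    mlogm <- Mi * log2(Mi)
    mlogm[Mi == 0] <- 0
    hm <- -rowSums(mlogm)
    div <- hm - (h[i] + h[(i + 1L):n]) / 2
    D[i, (i + 1L):n] <- D[(i + 1L):n, i] <- sqrt(pmax(0, pmin(1, div)))
  }
  dimnames(D) <- list(rownames(compositions), rownames(compositions))
  D
}

#' Similarity kernel M = 1 - JSD
#'
#' The Jensen-Shannon distance matrix is mapped to a similarity matrix used
#' as the covariance of the RKHS animal effect. `1 - JSD` is not guaranteed
#' positive semidefinite, so by default negative eigenvalues are floored at
#' zero and the matrix reconstituted (`repair = "clip"`); the diagonal is
#' restored to 1 afterwards. `repair = "none"` keeps the raw construction,
#' `repair = "jitter"` adds the smallest diagonal shift making the minimum
#' eigenvalue zero.
#'
#' @param JSD symmetric distance matrix (zero diagonal, entries in \[0,1\]).
#' @param repair one of `"clip"`, `"none"`, `"jitter"`.
#' @return list of class `kernel_matrix`: `M`, `JSD`, `repair`,
#'   `eigen_floor_applied` (largest magnitude of clipped eigenvalue, 0 if
#'   none).
#' @export
kernel_from_jsd <- function(JSD, repair = c("clip", "none", "jitter")) {
  repair <- match.arg(repair)
  stopifnot(is.matrix(JSD), nrow(JSD) == ncol(JSD))
  if (max(abs(JSD - t(JSD))) > 1e-8) stop("JSD must be symmetric")
  M <- 1 - JSD
  floor_applied <- 0
  if (repair != "none") {
    eig <- eigen(M, symmetric = TRUE)
    neg <- eig$values < 0
    if (any(neg)) {
      floor_applied <- abs(min(eig$values))
      if (repair == "clip") {
        vals <- pmax(eig$values, 0)
        M <- eig$vectors %*% (vals * t(eig$vectors))
      } else {
        M <- M + diag(floor_applied, nrow(M))
      }
      # restore unit diagonal lost in the reconstruction
      d <- diag(M)
      d[d <= 0] <- 1
      M <- M / sqrt(outer(d, d))
      M <- (M + t(M)) / 2
    }
  }
  diag(M) <- 1
  dimnames(M) <- dimnames(JSD)
  structure(list(M = M, JSD = JSD, repair = repair,
                 eigen_floor_applied = floor_applied),
            class = "kernel_matrix")
}
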