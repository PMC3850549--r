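#' Partition statistics for split evaluation
#'
#' The split heuristic needs, for each candidate partition of the examples
#' at a tree node, two quantities per side:
#' \itemize{
#'   \item the class-vector variance `Var(U) = (1/n) sum_i d(L_i, Lbar)^2`,
#'     with `d` the hierarchy-weighted Euclidean distance; and
#'   \item the network autocorrelation
#'     `A_Y(U) = 1 - ((n-1) * sum_ij w_ij d(L_i,L_j)^2) /
#'               (4 * sum_ij w_ij * sum_i d(L_i, Lbar)^2)`,
#'     a Geary's C adapted to hierarchy-weighted label vectors and mapped
#'     onto [0, 1] (1 strong positive autocorrelation, 0.5 none, 0 strong
#'     negative).
#' }
#' Both are maintained from sufficient statistics — per-class bit sums and
#' sums of squares, and the within-partition sums of edge weights and of
#' weight-scaled squared pair distances — so that moving one example
#' between the two sides of a candidate split costs O(degree + K) instead
#' of a from-scratch rescan.
#'
#' @param L 0/1 label matrix (examples x classes), ancestor closed.
#' @param omega positive class weights aligned with the columns of `L`.
#' @param W symmetric nonnegative adjacency matrix over the same examples
#'   (zero diagonal), or `NULL` for no network.
#' @return an object of class `partition_stats`: a list with `n`,
#'   `sum_bits`, `sum_sq`, `ssd` (weighted sum of squared distances to the
#'   mean vector), `w_sum` (sum of `w_ij` over ordered pairs) and `wd_sum`
#'   (sum of `w_ij * d(L_i, L_j)^2` over ordered pairs).
#' @export
partition_stats <- function(L, omega, W = NULL) {
  L <- as.matrix(L)
  n <- nrow(L)
  sum_bits <- colSums(L)
  sum_sq <- colSums(L^2)
  ssd <- ssd_from_sums(sum_bits, sum_sq, n, omega)
  if (is.null(W) || n == 0L) {
    w_sum <- 0
    wd_sum <- 0
  } else {
    D2 <- pair_dist2(L, omega)
    w_sum <- sum(W)
    wd_sum <- sum(W * D2)
  }
  structure(list(n = n, sum_bits = sum_bits, sum_sq = sum_sq, ssd = ssd,
                 w_sum = w_sum, wd_sum = wd_sum),
            class = "partition_stats")
}

# sum_i d(L_i, Lbar)^2 = sum_k omega_k * (sum_i L_ik^2 - (sum_i L_ik)^2 / n)
ssd_from_sums <- function(sum_bits, sum_sq, n, omega) {
  if (n == 0L) return(0)
  max(0, sum(omega * (sum_sq - sum_bits^2 / n)))
}

# dense matrix of squared hierarchy-weighted distances between all rows
pair_dist2 <- function(L, omega) {
  G <- L %*% (omega * t(L))
  h <- diag(G)
  D2 <- outer(h, h, "+") - 2 * G
  D2[D2 < 0] <- 0
  D2
}

#' Class-vector variance of a partition
#'
#' @param stats a `partition_stats` object with `n >= 1`.
#' @return `ssd / n`, a nonnegative scalar.
#' @export
variance <- function(stats) {
  if (stats$n < 1L) stop("variance undefined for an empty partition")
  stats$ssd / stats$n
}

#' Network autocorrelation of a partition
#'
#' Evaluates the HMC Geary-style statistic on the unit interval. The
#' degenerate cases — no within-partition edges, fewer than two examples,
#' or zero label variance — return the neutral value 0.5, so partitions
#' the network says nothing about are neither rewarded nor punished.
#' The raw formula can stray outside [0, 1] on adversarial weight
#' configurations; the result is clamped to the stated range.
#'
#' @param stats a `partition_stats` object.
#' @return a scalar in [0, 1].
#' @export
autocorrelation <- function(stats) {
  if (stats$n < 2L || stats$w_sum <= 0 || stats$ssd <= 0) return(0.5)
  a <- 1 - ((stats$n - 1) * stats$wd_sum) / (4 * stats$w_sum * stats$ssd)
  min(1, max(0, a))
}

#' Incremental sweep over the two sides of a candidate split
#'
#' Creates a mutable state holding two `partition_stats` over a fixed set
#' of examples, together with the example-to-side assignment. Initially
#' every example sits in side 1 (or as given by `side`). Candidate tests
#' at a tree node are then evaluated by sweeping examples from side 1 to
#' side 2 one at a time with [move_example()], each move updating both
#' sides' statistics incrementally.
#'
#' @param L 0/1 label matrix (examples x classes).
#' @param omega positive class weights.
#' @param W symmetric adjacency over the examples, or `NULL`.
#' @param side integer vector of 1/2 initial assignments (default all 1).
#' @return an environment of class `split_sweep` with fields `s1`, `s2`
#'   (partition_stats), `side`, and cached `W`, `WD2`, `L`, `omega`.
#' @export
split_sweep <- function(L, omega, W = NULL, side = NULL) {
  L <- as.matrix(L)
  n <- nrow(L)
  if (is.null(side)) side <- rep(1L, n)
  stopifnot(length(side) == n, all(side %in% c(1L, 2L)))
  e <- new.env(parent = emptyenv())
  e$L <- L
  e$omega <- omega
  e$W <- W
  e$WD2 <- if (!is.null(W)) W * pair_dist2(L, omega) else NULL
  e$side <- side
  i1 <- side == 1L
  e$s1 <- partition_stats(L[i1, , drop = FALSE], omega,
                          if (!is.null(W)) W[i1, i1, drop = FALSE])
  e$s2 <- partition_stats(L[!i1, , drop = FALSE], omega,
                          if (!is.null(W)) W[!i1, !i1, drop = FALSE])
  class(e) <- "split_sweep"
  e
}

#' Move one example between the two sides of a sweep
#'
#' Updates both partitions' sufficient statistics in O(degree + K): the
#' per-class sums lose/gain the example's bits (from which the weighted
#' sum of squared distances to the mean is re-derived in closed form —
#' the one-pass variance update), and the edge sums lose the example's
#' edge terms to members of the side it leaves and gain those to members
#' of the side it joins. Edges to examples on the opposite side contribute
#' to neither partition.
#'
#' @param sweep a `split_sweep`.
#' @param i example index to move.
#' @param to target side (1 or 2); defaults to the other side.
#' @return the sweep, invisibly (modified in place).
#' @export
move_example <- function(sweep, i, to = NULL) {
  from <- sweep$side[i]
  if (is.null(to)) to <- if (from == 1L) 2L else 1L
  if (from == to) stop("example ", i, " is already in side ", to)
  li <- sweep$L[i, ]
  om <- sweep$omega
  upd_counts <- function(s, sign) {
    s$n <- s$n + sign
    s$sum_bits <- s$sum_bits + sign * li
    s$sum_sq <- s$sum_sq + sign * li^2
    s$ssd <- ssd_from_sums(s$sum_bits, s$sum_sq, s$n, om)
    s
  }
  sf <- if (from == 1L) sweep$s1 else sweep$s2
  st <- if (to == 1L) sweep$s1 else sweep$s2
  sf <- upd_counts(sf, -1)
  st <- upd_counts(st, +1)
  if (!is.null(sweep$W)) {
    wrow <- sweep$W[i, ]
    wdrow <- sweep$WD2[i, ]
    in_from <- sweep$side == from
    in_from[i] <- FALSE
    in_to <- sweep$side == to
    sf$w_sum <- sf$w_sum - 2 * sum(wrow[in_from])
    sf$wd_sum <- sf$wd_sum - 2 * sum(wdrow[in_from])
    st$w_sum <- st$w_sum + 2 * sum(wrow[in_to])
    st$wd_sum <- st$wd_sum + 2 * sum(wdrow[in_to])
    # guard against negative drift from cancellation
    sf$w_sum <- max(0, sf$w_sum); sf$wd_sum <- max(0, sf$wd_sum)
  }
  if (from == 1L) { sweep$s1 <- sf; sweep$s2 <- st }
  else { sweep$s2 <- sf; sweep$s1 <- st }
  sweep$side[i] <- to
  invisible(sweep)
}

#' Min-max normalization
#'
#' Maps a vector affinely onto [0, 1]; a constant vector maps to all
#' zeros. Used to put the variance term of the split heuristic on the
#' same scale as the autocorrelation term.
#'
#' @param values non-empty numeric vector.
#' @return numeric vector in [0, 1].
#' @export
minmax_normalize <- function(values) {
  stopifnot(length(values) > 0L)
  lo <- min(values)
  hi <- max(values)
  if (hi == lo) return(rep(0, length(values)))
  (values - lo) / (hi - lo)
}
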