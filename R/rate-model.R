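#' Copy-number event rate parameters
#'
#' The continuous-time model of copy-number evolution in two adjacent genomic
#' bins on one lineage uses three rates: `alpha`, the extra rate of single-copy
#' (+/-1) events; `beta`, the rate of events of any magnitude; and `gamma`,
#' the relative rate of events spanning both adjacent bins. Single-copy
#' events occur at rate `alpha + beta` so that they can be more frequent
#' than larger jumps.
#'
#' @param alpha rate of +/-1 copy events (>= 0).
#' @param beta rate of any copy-number event (> 0).
#' @param gamma relative rate of events affecting both adjacent bins (>= 0).
#' @return An object of class `cna_rates`.
#' @export
cna_rates <- function(alpha, beta, gamma) {
  if (alpha < 0 || gamma < 0 || beta <= 0)
    stop("require alpha >= 0, beta > 0, gamma >= 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "cna_rates")
}

#' @export
print.cna_rates <- function(x, ...) {
  cat(sprintf("<cna_rates> alpha=%.4g beta=%.4g gamma=%.4g\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

# state indexing over pairs (U,V), U,V in 0..k: (U,V) -> U*(k+1)+V+1 (1-based)
pair_state_index <- function(U, V, k) U * (k + 1L) + V + 1L

pair_state_labels <- function(k) {
  g <- expand.grid(V = 0:k, U = 0:k)  # V fastest => row-major in U
  sprintf("(%d,%d)", g$U, g$V)
}

#' Instantaneous rate matrix for adjacent-bin copy numbers
#'
#' Builds the generator of the continuous-time Markov chain on states
#' (U, V), the copy numbers of two adjacent bins on one lineage, with
#' U, V in 0..k. Off-diagonal rates: `gamma*(alpha+beta)` for joint +/-1
#' moves of both bins, `gamma*beta` for joint moves of magnitude > 1,
#' `alpha+beta` for single-bin +/-1 moves, `beta` for single-bin moves of
#' magnitude > 1, and 0 otherwise (in particular for moves changing the two
#' bins by different amounts). Moves that would leave the state space
#' contribute nothing. Diagonals are the negative row sums.
#'
#' States are indexed row-major: (U,V) at position `U*(k+1)+V+1`.
#'
#' @param params a [cna_rates] object.
#' @param k maximum copy number (>= 1).
#' @return A `(k+1)^2` square matrix with zero row sums.
#' @export
build_rate_matrix <- function(params, k) {
  stopifnot(inherits(params, "cna_rates"))
  if (k < 1) stop("k must be >= 1")
  k <- as.integer(k)
  S <- (k + 1L)^2
  Q <- matrix(0, S, S)
  a <- params$alpha; b <- params$beta; g <- params$gamma
  for (U in 0:k) for (V in 0:k) {
    i <- pair_state_index(U, V, k)
    for (n in 1:k) {
      rate1 <- if (n == 1L) a + b else b
      rateJ <- if (n == 1L) g * (a + b) else g * b
      # single-bin moves
      if (U + n <= k) Q[i, pair_state_index(U + n, V, k)] <- rate1
      if (U - n >= 0) Q[i, pair_state_index(U - n, V, k)] <- rate1
      if (V + n <= k) Q[i, pair_state_index(U, V + n, k)] <- rate1
      if (V - n >= 0) Q[i, pair_state_index(U, V - n, k)] <- rate1
      # joint moves of both bins by the same amount
      if (U + n <= k && V + n <= k)
        Q[i, pair_state_index(U + n, V + n, k)] <- rateJ
      if (U - n >= 0 && V - n >= 0)
        Q[i, pair_state_index(U - n, V - n, k)] <- rateJ
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(pair_state_labels(k), pair_state_labels(k))
  Q
}

#' Transition probability matrix of the adjacent-bin process
#'
#' Computes `expm(Q t)` by Pade scaling-and-squaring. Tiny negative entries
#' produced by round-off (> -1e-12) are clipped to zero and rows are
#' renormalised; larger negative entries raise an error.
#'
#' @param Q rate matrix from [build_rate_matrix].
#' @param t evolutionary time (>= 0).
#' @return Row-stochastic matrix of the same dimension as `Q`.
#' @export
transition_matrix <- function(Q, t) {
  if (t < 0) stop("t must be >= 0")
  if (t == 0) {
    P <- diag(nrow(Q))
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
  if (min(P) < -1e-12)
    stop("matrix exponential produced negative entry ", min(P))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

#' Joint adjacent-bin transition probabilities for a pair of cells
#'
#' For cells A and B related by a three-branch tree (shared branch t1 from
#' the diploid ancestor to the unobserved divergence state, then private
#' branches t2 to A and t3 to B), computes the joint probability of cell A
#' moving from copy number `ciA` in window i to `cjA` in window i+1 while
#' cell B moves `ciB -> cjB`, marginalising the unobserved adjacent-bin
#' state (W, Y) at divergence:
#' `f = sum_{W,Y} P1[(2,2),(W,Y)] P2[(W,Y),(ciA,cjA)] P3[(W,Y),(ciB,cjB)]`.
#'
#' The result is indexed by paired-cell states (CN_A, CN_B), row-major in
#' CN_A, and has grand total 1.
#'
#' @param P1,P2,P3 transition matrices for branches t1, t2, t3, all built
#'   from the same rate matrix and `k`.
#' @param k maximum copy number (>= 2, so the diploid ancestral state
#'   exists).
#' @return A `(k+1)^2` square matrix `F` over paired-cell states.
#' @export
pair_joint_adjacent <- function(P1, P2, P3, k) {
  if (k < 2) stop("k must be >= 2: no diploid ancestral state otherwise")
  S1 <- (k + 1L)^2
  stopifnot(nrow(P1) == S1, nrow(P2) == S1, nrow(P3) == S1)
  anc <- pair_state_index(2L, 2L, k)
  w1 <- P1[anc, ]
  Fm <- matrix(0, S1, S1)
  kp1 <- k + 1L
  for (wy in seq_len(S1)) {
    if (w1[wy] == 0) next
    # reshape rows of P2/P3 as (current bin CN) x (next bin CN) matrices;
    # row state index is U*(k+1)+V+1 so byrow=TRUE puts U on rows
    A2 <- matrix(P2[wy, ], kp1, kp1, byrow = TRUE)
    B3 <- matrix(P3[wy, ], kp1, kp1, byrow = TRUE)
    # paired-cell state (cA,cB) -> cA*(k+1)+cB+1, so kron(A2, B3) lands
    # entry [(ciA,ciB),(cjA,cjB)] at exactly that indexing
    Fm <- Fm + w1[wy] * kronecker(A2, B3)
  }
  lab <- pair_state_labels(k)
  dimnames(Fm) <- list(lab, lab)
  Fm
}

#' Genome-wide transition matrix for a pair of cells
#'
#' Row-normalises the joint adjacent-bin matrix: the transition probability
#' from paired state (CN_iA, CN_iB) to (CN_(i+1)A, CN_(i+1)B) is the joint
#' probability divided by the marginal probability of the window-i state.
#'
#' @param F joint matrix from [pair_joint_adjacent].
#' @return Row-stochastic matrix of the same dimension.
#' @export
genome_transition <- function(F) {
  rs <- rowSums(F)
  zero <- which(rs == 0)
  if (length(zero))
    stop("zero row in joint matrix at state index ", zero[1L])
  F / rs
}

#' Genome-wide transition matrix for a single cell
#'
#' The one-lineage specialisation: the chain over single-window copy numbers
#' with `m[U,V] = P[(2,2),(U,V)] / sum_V' P[(2,2),(U,V')]`, where P is the
#' adjacent-bin transition matrix after evolving time t from the diploid
#' ancestor.
#'
#' @param P transition matrix from [transition_matrix].
#' @param k maximum copy number (>= 2).
#' @return A `(k+1)` square row-stochastic matrix.
#' @export
single_cell_genome_transition <- function(P, k) {
  if (k < 2) stop("k must be >= 2")
  anc <- pair_state_index(2L, 2L, k)
  kp1 <- k + 1L
  Fm <- matrix(P[anc, ], kp1, kp1, byrow = TRUE)  # rows U, cols V
  rs <- rowSums(Fm)
  zero <- which(rs == 0)
  if (length(zero))
    stop("zero row in single-cell chain at copy number ", zero[1L] - 1L)
  M <- Fm / rs
  dimnames(M) <- list(as.character(0:k), as.character(0:k))
  M
}

#' Stationary distribution of a genome-wide transition chain
#'
#' Dominant left eigenvector of the row-stochastic matrix, normalised to a
#' probability vector, with a power-iteration fallback (tolerance 1e-12,
#' at most 1e5 iterations).
#'
#' @param M row-stochastic matrix.
#' @return Probability vector `pi` with `pi %*% M = pi`.
#' @export
steady_state <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  pi <- tryCatch({
    e <- eigen(t(M))
    i <- which.min(abs(e$values - 1))
    v <- Re(e$vectors[, i])
    if (sum(v) < 0) v <- -v
    if (min(v) < -1e-8) NULL else {
      v[v < 0] <- 0
      v / sum(v)
    }
  }, error = function(e) NULL)
  if (is.null(pi)) {
    pi <- rep(1 / nrow(M), nrow(M))
    for (it in seq_len(1e5)) {
      pin <- as.vector(pi %*% M)
      pin <- pin / sum(pin)
      if (max(abs(pin - pi)) < 1e-12) {
        pi <- pin
        break
      }
      pi <- pin
    }
  }
  if (max(abs(as.vector(pi %*% M) - pi)) > 1e-8)
    stop("steady state did not converge; chain may be reducible")
  names(pi) <- rownames(M)
  pi
}
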