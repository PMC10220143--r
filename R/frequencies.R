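## Simplex states and the drift/diffusion building blocks.
##
## Haplotype frequencies are plain numeric vectors on the simplex
## Delta_{d-1}, stacked row-major in the locus indices (last locus fastest):
## two-locus (i,j) -> (i-1)*L + j.

#' Validate a haplotype-frequency vector
#'
#' Checks that \code{x} is a nonnegative vector summing to 1 within
#' \code{tol}.  Validation never renormalizes; renormalization is an explicit
#' simulator step only.
#'
#' @param x numeric vector of haplotype frequencies.
#' @param d expected length (optional).
#' @param tol simplex tolerance (default \code{1e-9}).
#' @param interior require all entries strictly positive.
#' @return \code{x}, invisibly, or an error.
#' @export
check_freq <- function(x, d = NULL, tol = 1e-9, interior = FALSE) {
  if (!is.null(d) && length(x) != d)
    stop("frequency vector has length ", length(x), ", expected ", d)
  if (any(x < -tol)) stop("negative haplotype frequencies")
  if (abs(sum(x) - 1) > tol)
    stop("haplotype frequencies must sum to 1 (off by ",
         format(sum(x) - 1), ")")
  if (interior && any(x <= 0))
    stop("frequencies must lie in the interior of the simplex")
  invisible(x)
}

#' Allele-frequency marginals of a two-locus state
#'
#' Row and column sums of the \eqn{K \times L} haplotype-frequency table:
#' \eqn{x_{i\cdot} = \sum_l x_{il}} and \eqn{x_{\cdot j} = \sum_k x_{kj}}.
#'
#' @param x stacked frequency vector of length \eqn{d = KL}.
#' @param K,L allele counts at the two loci.
#' @return list with components \code{A} (length K) and \code{B} (length L).
#' @examples
#' marginals(c(0.4, 0.2, 0.2, 0.2), 2, 2)
#' @export
marginals <- function(x, K, L) {
  if (length(x) != K * L)
    stop("length(x) = ", length(x), " but K*L = ", K * L)
  M <- matrix(x, nrow = K, ncol = L, byrow = TRUE)
  list(A = rowSums(M), B = colSums(M))
}

#' Linkage-disequilibrium coefficients
#'
#' For each haplotype \eqn{(i,j)} the deviation from linkage equilibrium,
#' \eqn{D_{ij} = x_{ij} - x_{i\cdot}x_{\cdot j}}.  The coefficients sum to 0;
#' in the diallelic case all four share the same magnitude.
#'
#' @inheritParams marginals
#' @return length-\eqn{d} numeric vector.
#' @examples
#' linkage_disequilibrium(c(0.4, 0.2, 0.2, 0.2))
#' @export
linkage_disequilibrium <- function(x, K = NULL, L = NULL) {
  kl <- infer_KL(x, K, L)
  m <- marginals(x, kl[1], kl[2])
  x - as.vector(outer(m$A, m$B))[stack_order(kl[1], kl[2])]
}

## outer(A,B) flattens column-major (i fastest); our stacking is j fastest.
## stack_order() gives the permutation taking column-major (i,j) pairs to
## row-major flat indices.
stack_order <- function(K, L) as.vector(t(matrix(seq_len(K * L), K, L)))

## product of marginals, stacked: x_{i.} * x_{.j} per haplotype
marginal_product <- function(x, K, L) {
  m <- marginals(x, K, L)
  as.vector(outer(m$A, m$B))[stack_order(K, L)]
}

infer_KL <- function(x, K, L) {
  if (!is.null(K) && !is.null(L)) return(c(K, L))
  d <- length(x)
  if (d == 4L) return(c(2L, 2L))
  stop("cannot infer allele counts from a length-", d,
       " state; supply K and L")
}

#' Recombination component of the drift
#'
#' \eqn{a_{ij}(x;\rho) = \rho(x_{i\cdot}x_{\cdot j} - x_{ij}) = -\rho D_{ij}}.
#' Vanishes identically at \eqn{\rho = 0} (the reference measure) and at any
#' state in linkage equilibrium; always sums to 0 over haplotypes.
#'
#' @inheritParams marginals
#' @param rho recombination rate.
#' @return length-\eqn{d} drift vector.
#' @export
drift_recombination <- function(x, rho, K = NULL, L = NULL) {
  -rho * linkage_disequilibrium(x, K, L)
}

#' Mutation component of the drift
#'
#' \eqn{c_{ij}(x) = \frac{\theta_A}{2}\sum_k x_{kj}(P^A_{ki} - \delta_{ik})
#'   + \frac{\theta_B}{2}\sum_l x_{il}(P^B_{lj} - \delta_{jl})}.
#' Sums to 0 over haplotypes (required for the process to stay on the
#' simplex).
#'
#' @param x stacked frequency vector.
#' @param model a \code{"wf_model"} supplying \eqn{\theta_A,\theta_B,P^A,P^B}.
#' @return length-\eqn{d} drift vector.
#' @export
drift_mutation <- function(x, model) {
  stopifnot(inherits(model, "wf_model"), model$num_loci == 2L)
  K <- model$K; L <- model$L
  X <- matrix(x, nrow = K, ncol = L, byrow = TRUE)
  cm <- model$theta_A / 2 * (t(model$P_A) %*% X - X) +
        model$theta_B / 2 * (X %*% model$P_B - X)
  as.vector(t(cm))
}

#' Selection component of the drift
#'
#' For the general diploid epistatic tensor \eqn{s_{ij,kl}} the drift is
#' \deqn{a_{ij}(x) = \frac{x_{ij}}{2}\Big(\sum_{kl} s_{ij,kl} x_{kl}
#'   - \sum_{kl,mn} s_{kl,mn} x_{kl} x_{mn}\Big),}
#' i.e. marginal fitness minus mean fitness.  Genic and additive schemes are
#' special cases; the genic form at locus A reduces to
#' \eqn{(x_{ij}/2)(s_i - \sum_k s_k x_{k\cdot})}.
#'
#' @param x stacked frequency vector.
#' @param selection a \code{"wf_selection"} scheme.
#' @param K,L allele counts.
#' @return length-\eqn{d} drift vector (sums to 0).
#' @export
drift_selection <- function(x, selection, K = NULL, L = NULL) {
  kl <- infer_KL(x, K, L)
  S <- selection_tensor(selection, kl[1], kl[2])
  marg_fit <- as.vector(S %*% x)
  mean_fit <- sum(x * marg_fit)
  x / 2 * (marg_fit - mean_fit)
}

#' Full drift of a model at a state
#'
#' Sum of the mutation, recombination and (optional) selection components.
#'
#' @inheritParams drift_mutation
#' @return length-\eqn{d} drift vector.
#' @export
drift_total <- function(x, model) {
  if (model$num_loci == 2L) {
    a <- drift_recombination(x, model$rho, model$K, model$L) +
      drift_mutation(x, model)
    if (!is.null(model$selection))
      a <- a + drift_selection(x, model$selection, model$K, model$L)
    a
  } else {
    drift_recombination_multilocus(x, model)
  }
}

#' Wright--Fisher diffusion matrix
#'
#' \eqn{V_{ij}(x) = x_i(\delta_{ij} - x_j)}: symmetric, positive
#' semidefinite, rows summing to 0 (rank at most \eqn{d-1}).
#'
#' @param x frequency vector.
#' @return \eqn{d \times d} matrix.
#' @export
diffusion_matrix <- function(x) {
  diag(x, nrow = length(x)) - tcrossprod(x)
}

#' Closed-form inverse of the reduced diffusion matrix
#'
#' The leading \eqn{(d-1)\times(d-1)} block \eqn{V^*(x)} of the diffusion
#' matrix is invertible on the interior of the simplex, with
#' \eqn{[V^*(x)^{-1}]_{ij} = x_d^{-1} + x_i^{-1}\delta_{ij}}.
#'
#' @param x frequency vector with all entries strictly positive.
#' @return \eqn{(d-1)\times(d-1)} matrix.
#' @export
vstar_inverse <- function(x) {
  if (any(x <= 0))
    stop("V* is singular: state has a zero coordinate")
  d <- length(x)
  matrix(1 / x[d], d - 1, d - 1) + diag(1 / x[-d], nrow = d - 1)
}

#' Boundary-safe square root of the diffusion matrix
#'
#' The symmetric decomposition
#' \eqn{\sigma_{ij}(x) = \sqrt{x_i}(\delta_{ij} - \sqrt{x_i x_j})}
#' satisfies \eqn{\sigma\sigma^\top = V(x)} and, unlike the analytic Cholesky
#' factor, stays bounded on all of the simplex, which makes it the natural
#' choice for simulating near the boundary.  It uses \eqn{d} driving Brownian
#' coordinates (one more than strictly necessary).
#'
#' @param x frequency vector (entries \eqn{\ge 0}).
#' @return \eqn{d \times d} matrix.
#' @export
sigma_pal <- function(x) {
  if (any(x < 0)) stop("negative frequencies")
  s <- sqrt(x)
  diag(s, nrow = length(x)) - outer(x, s)
}

## ---- multi-locus marginalization -----------------------------------------

## flatten an l-dimensional table (lexicographic, last locus fastest)
## prefix marginal x_{i<=j}: sum over loci j+1..l; suffix x_{i>j}: sum over 1..j.

#' Prefix/suffix marginals of a multi-locus state
#'
#' Marginalizes the stacked frequency vector over the loci after (prefix) or
#' up to (suffix) a cut position \code{j}, returning the per-haplotype values
#' \eqn{x_{i\le j}} and \eqn{x_{i>j}} used by the multi-locus recombination
#' drift and estimators.
#'
#' @param x stacked frequency vector of length \code{prod(allele_counts)}.
#' @param allele_counts integer vector of per-locus allele counts.
#' @param j cut position, \eqn{1 \le j \le \ell-1}.
#' @return list with per-haplotype vectors \code{prefix} (\eqn{x_{i\le j}})
#'   and \code{suffix} (\eqn{x_{i>j}}), each of length \eqn{d}.
#' @export
multilocus_marginals <- function(x, allele_counts, j) {
  ell <- length(allele_counts)
  if (j < 1 || j > ell - 1) stop("cut index must be in 1..", ell - 1)
  d <- prod(allele_counts)
  if (length(x) != d) stop("state length does not match allele counts")
  n_pre <- prod(allele_counts[seq_len(j)])
  n_suf <- d / n_pre
  ## lexicographic last-fastest: flat index = (prefix-1)*n_suf + suffix
  M <- matrix(x, nrow = n_pre, ncol = n_suf, byrow = TRUE)
  pre <- rowSums(M)   # x_{i<=j} per distinct prefix
  suf <- colSums(M)   # x_{i>j} per distinct suffix
  list(prefix = rep(pre, each = n_suf), suffix = rep(suf, times = n_pre))
}

#' Multi-locus recombination drift
#'
#' \eqn{a_i(x;\rho_1,\dots,\rho_{\ell-1}) =
#'   \sum_j \rho_j (x_{i\le j} x_{i>j} - x_i)}, one term per interval between
#' consecutive loci.  Reduces to [drift_recombination()] for two loci.
#'
#' @param x stacked frequency vector.
#' @param model a \code{"wf_model"} (supplies allele counts and the rate
#'   vector).
#' @return length-\eqn{d} drift vector.
#' @export
drift_recombination_multilocus <- function(x, model) {
  counts <- model$allele_counts
  ell <- model$num_loci
  rho <- model$rho
  if (ell == 2L) return(drift_recombination(x, rho, counts[1], counts[2]))
  a <- numeric(length(x))
  for (j in seq_len(ell - 1L)) {
    mm <- multilocus_marginals(x, counts, j)
    a <- a + rho[j] * (mm$prefix * mm$suffix - x)
  }
  a
}

#' Random interior simplex points
#'
#' Uniform (flat Dirichlet) draws on the simplex interior, used by the
#' numeric robustness checks and property tests.
#'
#' @param n number of points.
#' @param d dimension.
#' @return \eqn{n \times d} matrix of frequency vectors.
#' @export
rsimplex <- function(n, d) {
  g <- matrix(stats::rexp(n * d), n, d)
  g / rowSums(g)
}
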