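#' Specify a Wright--Fisher diffusion model of haplotype frequencies
#'
#' Constructs the full drift/diffusion specification for a neutral or selected
#' multi-locus Wright--Fisher diffusion: number of loci, allele counts,
#' recurrent-mutation rates and transition matrices (two loci), per-interval
#' recombination rates, and an optional selection scheme.
#'
#' The drift decomposes as \eqn{\mu(x) = c(x) + a(x;\rho)} where
#' \eqn{a_{ij}(x;\rho) = \rho(x_{i\cdot}x_{\cdot j} - x_{ij})} is the
#' recombination component carrying the parameter of interest and \eqn{c}
#' collects the "known" forces (mutation, and optionally selection treated as
#' a known confounder).  Mutation occurs at locus A (resp. B) at rate
#' \eqn{\theta_A/2} (resp. \eqn{\theta_B/2}) with transition matrices
#' \code{P_A}, \code{P_B}; selection carries its conventional factor 1/2.
#' Note the timescale convention: the recombination rate \code{rho} enters the
#' drift \emph{without} a factor of 1/2.
#'
#' Haplotypes are stacked row-major / lexicographically in the locus indices:
#' two-locus haplotype \eqn{(i,j)} maps to flat index \eqn{(i-1)L + j}; for
#' \eqn{\ell} loci the last locus index varies fastest.
#'
#' @param allele_counts integer vector of length \eqn{\ell \ge 2}; number of
#'   alleles at each locus (each \eqn{\ge 2}).  Default \code{c(2, 2)}.
#' @param rho recombination rate(s), all \eqn{\ge 0}: a scalar for two loci or
#'   a vector of length \eqn{\ell - 1} (rate between consecutive loci).
#' @param theta_A,theta_B mutation rates (\eqn{\ge 0}) at the first and second
#'   locus; only supported for two loci.
#' @param P_A,P_B row-stochastic mutation transition matrices
#'   (\eqn{K \times K} and \eqn{L \times L}).  Default: all entries equal
#'   (symmetric parent-independent mutation).
#' @param selection optional selection scheme; one of
#'   \code{selection_genic(s, locus)}, \code{selection_additive(s_A, s_B)} or
#'   \code{selection_epistatic(S)}.
#' @return an object of class \code{"wf_model"}.
#' @examples
#' m <- wf_model(rho = 5, theta_A = 1, theta_B = 1)
#' m
#' @seealso [simulate.wf_model()], [rho_mle()], [drift_recombination()]
#' @export
wf_model <- function(allele_counts = c(2, 2), rho = 0,
                     theta_A = 0, theta_B = 0,
                     P_A = NULL, P_B = NULL,
                     selection = NULL) {
  allele_counts <- as.integer(allele_counts)
  ell <- length(allele_counts)
  if (ell < 2L || any(allele_counts < 2L))
    stop("need at least two loci with at least two alleles each")
  d <- prod(allele_counts)
  if (any(rho < 0)) stop("recombination rates must be >= 0")
  if (ell == 2L) {
    if (length(rho) != 1L) stop("two-locus model takes a scalar 'rho'")
  } else {
    if (length(rho) == 1L) rho <- rep(rho, ell - 1L)
    if (length(rho) != ell - 1L)
      stop("'rho' must have length ", ell - 1L, " (one rate per locus interval)")
    if (theta_A > 0 || theta_B > 0)
      stop("mutation is only supported in the two-locus model")
    if (!is.null(selection))
      stop("selection is only supported in the two-locus model")
  }
  if (theta_A < 0 || theta_B < 0) stop("mutation rates must be >= 0")
  K <- allele_counts[1L]
  L <- allele_counts[2L]
  if (ell == 2L) {
    if (is.null(P_A)) P_A <- matrix(1 / K, K, K)
    if (is.null(P_B)) P_B <- matrix(1 / L, L, L)
    check_stochastic(P_A, K, "P_A")
    check_stochastic(P_B, L, "P_B")
    if (!is.null(selection)) selection <- validate_selection(selection, K, L)
  } else {
    P_A <- P_B <- NULL
  }
  structure(
    list(num_loci = ell, allele_counts = allele_counts, d = d,
         K = K, L = L, rho = rho,
         theta_A = theta_A, theta_B = theta_B,
         P_A = P_A, P_B = P_B, selection = selection),
    class = "wf_model")
}

check_stochastic <- function(P, n, name, tol = 1e-9) {
  if (!is.matrix(P) || nrow(P) != n || ncol(P) != n)
    stop("'", name, "' must be a ", n, "x", n, " matrix")
  if (any(P < -tol) || any(abs(rowSums(P) - 1) > tol))
    stop("'", name, "' must be row-stochastic (rows summing to 1)")
  invisible(P)
}

#' Selection parameterizations
#'
#' Three ways to specify diploid selection on two loci, all reducible to the
#' general epistatic tensor \eqn{s_{ij,kl}} giving the selective advantage of
#' an individual carrying haplotypes (i,j) and (k,l):
#' \describe{
#'   \item{genic}{per-allele (haploid) effects \eqn{s_1,\dots,s_K} at one
#'     locus, so \eqn{s_{ij,kl} = s_i + s_k} (locus A); drift
#'     \eqn{a_{ij} = (x_{ij}/2)(s_i - \sum_k s_k x_{k\cdot})}.}
#'   \item{additive}{per-locus genotype effects
#'     \eqn{s_{ij,kl} = s^A_{ik} + s^B_{jl}} (no epistasis).}
#'   \item{epistatic}{a dense \eqn{d \times d} tensor over stacked haplotype
#'     pairs.  Symmetry \eqn{s_{ij,kl} = s_{kl,ij}} is not required, but a
#'     warning is issued if it fails since fitness models are usually
#'     symmetric.}
#' }
#'
#' @param s numeric vector of allele effects (length = allele count at
#'   \code{locus}).
#' @param locus which locus ("A" or "B") the genic effects act on.
#' @param s_A,s_B symmetric genotype-effect matrices (\eqn{K\times K},
#'   \eqn{L\times L}); either may be zero.
#' @param S dense \eqn{d \times d} tensor over stacked haplotypes.
#' @return a classed list describing the selection scheme.
#' @export
selection_genic <- function(s, locus = c("A", "B")) {
  locus <- match.arg(locus)
  structure(list(type = "genic", s = as.numeric(s), locus = locus),
            class = "wf_selection")
}

#' @rdname selection_genic
#' @export
selection_additive <- function(s_A = NULL, s_B = NULL) {
  structure(list(type = "additive", s_A = s_A, s_B = s_B),
            class = "wf_selection")
}

#' @rdname selection_genic
#' @export
selection_epistatic <- function(S) {
  structure(list(type = "epistatic", S = S), class = "wf_selection")
}

validate_selection <- function(sel, K, L) {
  if (!inherits(sel, "wf_selection"))
    stop("'selection' must be built with selection_genic(), ",
         "selection_additive() or selection_epistatic()")
  d <- K * L
  if (sel$type == "genic") {
    nk <- if (sel$locus == "A") K else L
    if (length(sel$s) != nk)
      stop("genic selection needs one coefficient per allele at locus ", sel$locus)
  } else if (sel$type == "additive") {
    if (is.null(sel$s_A)) sel$s_A <- matrix(0, K, K)
    if (is.null(sel$s_B)) sel$s_B <- matrix(0, L, L)
    stopifnot(all(dim(sel$s_A) == K), all(dim(sel$s_B) == L))
  } else if (sel$type == "epistatic") {
    if (!is.matrix(sel$S) || nrow(sel$S) != d || ncol(sel$S) != d)
      stop("epistatic tensor must be ", d, "x", d, " over stacked haplotypes")
    if (max(abs(sel$S - t(sel$S))) > 1e-8 * max(1, max(abs(sel$S))))
      warning("epistatic selection tensor is not symmetric (s_{ij,kl} != s_{kl,ij})")
  }
  sel
}

#' Stacked selection tensor for a selection scheme
#'
#' Canonicalizes any of the three selection parameterizations to the dense
#' \eqn{d \times d} tensor \eqn{s_{ij,kl}} over stacked haplotypes.  Genic
#' effects become \eqn{s^A_{ik} = s_i + s_k} (haploid effects add), additive
#' effects become \eqn{s_{ij,kl} = s^A_{ik} + s^B_{jl}}.
#'
#' @param selection a \code{"wf_selection"} object.
#' @param K,L allele counts at the two loci.
#' @return a \eqn{d \times d} numeric matrix.
#' @export
selection_tensor <- function(selection, K, L) {
  sel <- validate_selection(selection, K, L)
  if (sel$type == "epistatic") return(sel$S)
  if (sel$type == "genic") {
    if (sel$locus == "A") {
      s_A <- outer(sel$s, sel$s, `+`)
      s_B <- matrix(0, L, L)
    } else {
      s_A <- matrix(0, K, K)
      s_B <- outer(sel$s, sel$s, `+`)
    }
  } else {
    s_A <- sel$s_A
    s_B <- sel$s_B
  }
  # S[(ij),(kl)] = s_A[i,k] + s_B[j,l] under row-major stacking
  iA <- rep(seq_len(K), each = L)
  iB <- rep(seq_len(L), times = K)
  s_A[iA, iA] + s_B[iB, iB]
}

#' @export
print.wf_model <- function(x, ...) {
  cat("Wright-Fisher diffusion model\n")
  cat("  loci:", x$num_loci, " alleles:", paste(x$allele_counts, collapse = " x "),
      " (d =", x$d, "haplotypes)\n")
  cat("  recombination rate(s):", paste(format(x$rho), collapse = ", "), "\n")
  if (x$num_loci == 2L)
    cat("  mutation: theta_A =", x$theta_A, ", theta_B =", x$theta_B, "\n")
  if (!is.null(x$selection))
    cat("  selection:", x$selection$type, "\n")
  invisible(x)
}

#' Mutation drift as a linear map
#'
#' The two-locus mutation drift is linear in the frequencies,
#' \eqn{c(x) = C x}.  This returns the \eqn{d \times d} matrix \eqn{C},
#' used by the simulator's inner loop.
#'
#' @param model a \code{"wf_model"}.
#' @return a \eqn{d \times d} matrix (zero when both mutation rates are 0).
#' @keywords internal
mutation_generator <- function(model) {
  d <- model$d
  C <- matrix(0, d, d)
  if (model$num_loci != 2L || (model$theta_A == 0 && model$theta_B == 0))
    return(C)
  for (m in seq_len(d)) {
    e <- numeric(d)
    e[m] <- 1
    C[, m] <- drift_mutation(e, model)
  }
  C
}

#' Serialize a model to a YAML configuration file
#'
#' Writes/reads the full parameter set as flat keys with matrices as nested
#' lists.  Keys: \code{num_loci}, \code{allele_counts}, \code{rho},
#' \code{theta_A}, \code{theta_B}, \code{P_A}, \code{P_B}, and (optionally)
#' \code{selection} with sub-keys \code{type} and the scheme's parameters.
#'
#' @param model a \code{"wf_model"}.
#' @param path file path.
#' @return \code{read_wf_model} returns a \code{"wf_model"};
#'   \code{write_wf_model} returns \code{path} invisibly.
#' @export
write_wf_model <- function(model, path) {
  stopifnot(inherits(model, "wf_model"))
  cfg <- list(num_loci = model$num_loci,
              allele_counts = as.integer(model$allele_counts),
              rho = as.numeric(model$rho),
              theta_A = model$theta_A, theta_B = model$theta_B)
  mat2list <- function(M) lapply(seq_len(nrow(M)), function(i) as.numeric(M[i, ]))
  if (!is.null(model$P_A)) cfg$P_A <- mat2list(model$P_A)
  if (!is.null(model$P_B)) cfg$P_B <- mat2list(model$P_B)
  if (!is.null(model$selection)) {
    sel <- model$selection
    cfg$selection <- switch(sel$type,
      genic = list(type = "genic", locus = sel$locus, s = as.numeric(sel$s)),
      additive = list(type = "additive", s_A = mat2list(sel$s_A),
                      s_B = mat2list(sel$s_B)),
      epistatic = list(type = "epistatic", S = mat2list(sel$S)))
  }
  yaml::write_yaml(cfg, path, precision = 17L)
  invisible(path)
}

#' @rdname write_wf_model
#' @export
read_wf_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  list2mat <- function(l) do.call(rbind, lapply(l, as.numeric))
  sel <- NULL
  if (!is.null(cfg$selection)) {
    sc <- cfg$selection
    sel <- switch(sc$type,
      genic = selection_genic(as.numeric(sc$s), sc$locus),
      additive = selection_additive(list2mat(sc$s_A), list2mat(sc$s_B)),
      epistatic = selection_epistatic(list2mat(sc$S)),
      stop("unknown selection type in config: ", sc$type))
  }
  wf_model(allele_counts = cfg$allele_counts, rho = cfg$rho,
           theta_A = cfg$theta_A %||% 0, theta_B = cfg$theta_B %||% 0,
           P_A = if (!is.null(cfg$P_A)) list2mat(cfg$P_A),
           P_B = if (!is.null(cfg$P_B)) list2mat(cfg$P_B),
           selection = sel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
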