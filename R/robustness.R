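## Confounder robustness.  A drift contribution c(x) outside the estimated
## part leaves the linear-drift MLE unchanged iff, for every parameter k,
##    sum_i (1/x_i) (da_i/dphi_k)(x) c_i(x) = 0   on the simplex interior.
## The checks here are numeric: the condition is evaluated at many random
## interior states and a problem is declared robust only if it vanishes (to
## rounding) at every sampled point.

#' Evaluate the confounder-robustness condition at a state
#'
#' Computes \eqn{\sum_i Z_{ik}(x) c_i(x) / x_i} for each column \eqn{k} of
#' the target score matrix.  The estimation problem with score \eqn{Z} is
#' robust to the confounding drift \eqn{c} at \eqn{x} iff all entries vanish.
#'
#' @param Z function mapping a state to its \eqn{d \times r} score matrix.
#' @param c_fun confounding drift function of the state.
#' @param x interior frequency vector.
#' @return numeric vector of length \eqn{r}.
#' @export
robustness_condition <- function(Z, c_fun, x) {
  if (any(x <= 0)) stop("robustness condition is evaluated at interior states")
  as.vector(crossprod(as.matrix(Z(x)) / x, c_fun(x)))
}

## ---- score and confounder factories (two-locus) ---------------------------

#' Score and confounder drift factories
#'
#' Building blocks for robustness checks: each returns a function of the
#' state.  Scores are the parameter-derivatives of the corresponding drift
#' component (\code{score_*}, \eqn{d \times r}); confounders are fixed drift
#' contributions (\code{confounder_*}, length \eqn{d}).
#'
#' @param model a two-locus \code{"wf_model"} (supplies allele counts and
#'   mutation transition matrices).
#' @param locus which locus the component acts on.
#' @param s selection coefficients (length = allele count at \code{locus})
#'   for the selection confounder.
#' @param rho rate for the recombination confounder.
#' @return a function of the state vector.
#' @export
score_recombination <- function(model) {
  K <- model$K; L <- model$L
  function(x) matrix(marginal_product(x, K, L) - x, ncol = 1)
}

#' @rdname score_recombination
#' @export
score_mutation <- function(model, locus = c("A", "B")) {
  locus <- match.arg(locus)
  K <- model$K; L <- model$L
  P <- if (locus == "A") model$P_A else model$P_B
  function(x) {
    X <- matrix(x, K, L, byrow = TRUE)
    Zm <- if (locus == "A") 0.5 * (t(P) %*% X - X) else 0.5 * (X %*% P - X)
    matrix(as.vector(t(Zm)), ncol = 1)
  }
}

#' @rdname score_recombination
#' @export
score_selection_genic <- function(model, locus = c("A", "B")) {
  locus <- match.arg(locus)
  K <- model$K; L <- model$L
  nk <- if (locus == "A") K else L
  iA <- rep(seq_len(K), each = L)
  iB <- rep(seq_len(L), times = K)
  hap <- if (locus == "A") iA else iB
  function(x) {
    marg <- if (locus == "A") marginals(x, K, L)$A else marginals(x, K, L)$B
    ## Z_{(ij),k} = (x_ij/2)(delta_{hap,k} - marg_k)
    Zc <- vapply(seq_len(nk), function(k) x / 2 * ((hap == k) - marg[k]),
                 numeric(K * L))
    Zc
  }
}

#' @rdname score_recombination
#' @export
confounder_mutation <- function(model, locus = c("A", "B")) {
  locus <- match.arg(locus)
  theta <- if (locus == "A") model$theta_A else model$theta_B
  if (theta <= 0) theta <- 1
  sc <- score_mutation(model, locus)
  function(x) theta * as.vector(sc(x))
}

#' @rdname score_recombination
#' @export
confounder_recombination <- function(model, rho = 1) {
  sc <- score_recombination(model)
  function(x) rho * as.vector(sc(x))
}

#' @rdname score_recombination
#' @export
confounder_selection_genic <- function(model, s, locus = c("A", "B")) {
  locus <- match.arg(locus)
  K <- model$K; L <- model$L
  function(x) drift_selection(x, selection_genic(s, locus), K, L)
}

#' Numeric catalog of robust and non-robust estimation problems
#'
#' Classifies the canonical two-locus confounding problems by evaluating the
#' robustness condition at random interior states.  Robust: (i) mutation at
#' locus A confounded by selection at locus B, (ii) genic selection at locus
#' A confounded by mutation at locus B.  Not robust: (iii) recombination
#' confounded by mutation at either locus, (iv) mutation at A confounded by
#' mutation at B, (v) mutation at A confounded by recombination, (vi)
#' mutation at A confounded by selection at A, (vii) genic selection at A
#' confounded by mutation at A.  (Also classified, as a check: genic
#' selection confounded by recombination, which is robust.)  The
#' classification is invariant to interchanging the two loci.
#'
#' @param model a two-locus \code{"wf_model"} (defaults to the diallelic
#'   symmetric-mutation model).
#' @param n_points number of random interior evaluation states.
#' @param seed RNG seed for the evaluation states.
#' @param tol relative threshold for declaring a numeric zero.
#' @return data.frame with columns \code{label}, \code{target},
#'   \code{confounder}, \code{robust}, \code{max_abs} (largest absolute
#'   condition value seen, relative to the typical term magnitude).
#' @export
robustness_catalog <- function(model = wf_model(theta_A = 1, theta_B = 1),
                               n_points = 100, seed = 1, tol = 1e-10) {
  stopifnot(model$num_loci == 2L)
  sA <- seq_len(model$K) / model$K          # generic selection coefficients
  sB <- seq_len(model$L) / model$L
  problems <- list(
    list(label = "(i)", target = "mutation at A",
         confounder = "selection at B",
         Z = score_mutation(model, "A"),
         c_fun = confounder_selection_genic(model, sB, "B")),
    list(label = "(ii)", target = "genic selection at A",
         confounder = "mutation at B",
         Z = score_selection_genic(model, "A"),
         c_fun = confounder_mutation(model, "B")),
    list(label = "(iii)", target = "recombination",
         confounder = "mutation at A",
         Z = score_recombination(model),
         c_fun = confounder_mutation(model, "A")),
    list(label = "(iv)", target = "mutation at A",
         confounder = "mutation at B",
         Z = score_mutation(model, "A"),
         c_fun = confounder_mutation(model, "B")),
    list(label = "(v)", target = "mutation at A",
         confounder = "recombination",
         Z = score_mutation(model, "A"),
         c_fun = confounder_recombination(model)),
    list(label = "(vi)", target = "mutation at A",
         confounder = "selection at A",
         Z = score_mutation(model, "A"),
         c_fun = confounder_selection_genic(model, sA, "A")),
    list(label = "(vii)", target = "genic selection at A",
         confounder = "mutation at A",
         Z = score_selection_genic(model, "A"),
         c_fun = confounder_mutation(model, "A")),
    list(label = "(sel-vs-rec)", target = "genic selection at A",
         confounder = "recombination",
         Z = score_selection_genic(model, "A"),
         c_fun = confounder_recombination(model)))
  set.seed(seed)
  pts <- rsimplex(n_points, model$d)
  rows <- lapply(problems, function(p) {
    rel <- vapply(seq_len(n_points), function(i) {
      x <- pts[i, ]
      v <- robustness_condition(p$Z, p$c_fun, x)
      scale <- max(sum(abs(as.matrix(p$Z(x)) / x) *
                         abs(p$c_fun(x))), .Machine$double.eps)
      max(abs(v)) / scale
    }, numeric(1))
    data.frame(label = p$label, target = p$target,
               confounder = p$confounder,
               robust = all(rel < tol), max_abs = max(rel))
  })
  do.call(rbind, rows)
}

#' Selection-adjusted recombination estimator
#'
#' When the generating model carries (possibly epistatic) selection that the
#' analyst wants to account for, the estimator acquires the correction
#' \deqn{\hat\rho_{sel} = \hat\rho - \frac{1}{I_T}\int_0^T
#'   \sum_{ij}\big(X_{i\cdot}X_{\cdot j} - X_{ij}\big)
#'   \sum_{kl}\frac{s_{ij,kl}}{2}X_{kl}\,dt.}
#' For non-epistatic selection (\eqn{s_{ij,kl} = s^A_{ik} + s^B_{jl}}) the
#' integrand vanishes identically, so \eqn{\hat\rho_{sel} = \hat\rho}: the
#' recombination estimator is immune to misspecified additive selection.
#'
#' @param path a \code{"wf_path"}.
#' @param model the assumed model (mutation compensator).
#' @param selection the selection scheme to adjust for (defaults to the
#'   model's own).
#' @return list with \code{raw} (unadjusted \eqn{\hat\rho}),
#'   \code{adjusted} (\eqn{\hat\rho_{sel}}), \code{adjustment}
#'   (the subtracted term) and \code{I}.
#' @export
rho_selection_adjusted <- function(path, model = path$model,
                                   selection = model$selection) {
  stopifnot(inherits(path, "wf_path"), model$num_loci == 2L)
  if (is.null(selection)) selection <- selection_epistatic(
    matrix(0, model$d, model$d))
  S <- selection_tensor(selection, model$K, model$L)
  base <- wf_model(allele_counts = model$allele_counts, rho = model$rho,
                   theta_A = model$theta_A, theta_B = model$theta_B,
                   P_A = model$P_A, P_B = model$P_B)
  fn <- path_functionals(path, base)
  X <- path$X
  dts <- diff(path$times)
  lef <- which(usable_intervals(path))
  XL <- X[lef, , drop = FALSE]
  M <- t(apply(XL, 1, marginal_product, K = model$K, L = model$L))
  half_sx <- XL %*% t(S) / 2                   # sum_kl s_{ij,kl} x_kl / 2
  adj_int <- sum(rowSums((M - XL) * half_sx) * dts[lef])
  raw <- fn$Y / fn$I
  list(raw = raw, adjusted = raw - adj_int / fn$I,
       adjustment = adj_int / fn$I, I = fn$I)
}
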