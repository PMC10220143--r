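#' Likelihood-ratio test for the presence of recombination
#'
#' Tests the boundary null hypothesis \eqn{\rho_0 = 0} (complete linkage)
#' against \eqn{\rho > 0}.  On paths with finite information the statistic is
#' \deqn{\Lambda = 2\log\frac{L_T(\hat\rho_{MLE})}{L_T(0)}
#'   = \hat\rho_{MLE}^2\, I_T,}
#' whose asymptotic null law is the equal mixture
#' \eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1} because the null value sits on
#' the boundary of the parameter space.  When the information has exploded
#' the two path measures are mutually singular and the statistic is set to
#' \eqn{+\infty} if \eqn{\hat\rho_{MLE} > 0} and to 0 if
#' \eqn{\hat\rho_{MLE} = 0}; retaining the mixture null in that regime is
#' conservative.
#'
#' @param fit a \code{"rho_mle"} fit (scalar).
#' @param level test size (default 0.05).
#' @return an object of class \code{"wf_lrt"}: list with \code{lambda},
#'   \code{threshold}, \code{reject}, \code{level}.
#' @examples
#' mixture_quantile(0.95)   # = 90th percentile of a chi-squared_1, ~2.706
#' @export
lrt_recombination <- function(fit, level = 0.05) {
  stopifnot(inherits(fit, "rho_mle"), length(fit$estimate) == 1L)
  lambda <- if (fit$exploded) {
    if (fit$estimate > 0) Inf else 0
  } else {
    fit$estimate^2 * fit$I_T
  }
  threshold <- mixture_quantile(1 - level)
  structure(list(lambda = lambda, threshold = threshold,
                 reject = lambda > threshold, level = level),
            class = "wf_lrt")
}

#' @export
print.wf_lrt <- function(x, ...) {
  cat("Likelihood-ratio test of rho_0 = 0 (boundary chi-squared mixture null)\n")
  cat("  Lambda =", format(x$lambda), " threshold at level",
      format(x$level), "=", format(x$threshold), "\n")
  cat("  decision:", if (x$reject) "reject" else "do not reject",
      "the no-recombination null\n")
  invisible(x)
}

#' Quantile and CDF of the boundary mixture null
#'
#' The null law of the likelihood-ratio statistic for a parameter on the
#' boundary is \eqn{F_m = \tfrac12\chi^2_0 + \tfrac12\chi^2_1}; its
#' \eqn{p}-quantile (for \eqn{p > 1/2}) equals the \eqn{(2p-1)}-quantile of
#' a \eqn{\chi^2_1}.  In particular a level-5\% test uses the 95th percentile
#' of the mixture, i.e. the 90th percentile of a \eqn{\chi^2_1}
#' (\eqn{\approx 2.706}).
#'
#' @param p probability in \eqn{(1/2, 1)} (below 1/2 the quantile is inside
#'   the point mass at 0 and the test is degenerate).
#' @param q nonnegative quantile.
#' @return numeric scalar.
#' @export
mixture_quantile <- function(p) {
  if (any(p <= 0.5 | p >= 1))
    stop("level must give a quantile above the mixture's atom at 0 ",
         "(p in (0.5, 1))")
  stats::qchisq(2 * p - 1, df = 1)
}

#' @rdname mixture_quantile
#' @export
mixture_cdf <- function(q) {
  ifelse(q < 0, 0, 0.5 + 0.5 * stats::pchisq(q, df = 1))
}
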