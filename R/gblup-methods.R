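#' Estimate variance components only
#'
#' Runs the restricted-likelihood step of [fit_gblup()] without solving the
#' mixed model equations.  Degenerate data (e.g. a constant response) yield
#' a zero genetic variance with `converged = FALSE` rather than an error.
#'
#' @inheritParams fit_gblup
#' @return list with `sigma2_g`, `sigma2_e`, `loglik`, `converged`,
#'   `boundary`.
#' @export
reml_gblup <- function(drp, rel, K, ids = names(drp)) {
  if (is.null(ids)) stop("record animal IDs are required (ids or names(drp))")
  ids <- as.character(ids)
  ai <- match(ids, rownames(K))
  if (anyNA(ai)) stop("records refer to animals absent from K")
  if (length(drp) < 10L) {
    warning("variance components from fewer than 10 records are unreliable")
  }
  .reml_ratio(drp, drp_weights(rel), unclass(K)[ai, ai, drop = FALSE])
}

#' @export
print.gblup <- function(x, ...) {
  cat(sprintf("%s fit (K kind: %s)\n", x$label, x$kind %||% "?"))
  cat(sprintf("  %d records on %d animals in K\n",
              nrow(x$records), length(x$g)))
  cat(sprintf("  sigma2_g = %.4f, sigma2_e = %.4f (lambda = %.3f)%s\n",
              x$vc$sigma2_g, x$vc$sigma2_e, x$vc$sigma2_e / x$vc$sigma2_g,
              if (isTRUE(x$vc$converged)) "" else "  [not converged]"))
  cat(sprintf("  mu = %.4f\n", x$mu))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.gblup <- function(object, ...) {
  s <- list(label = object$label, kind = object$kind,
            n_records = nrow(object$records), n_animals = length(object$g),
            mu = object$mu, vc = object$vc, jitter = object$jitter,
            acc = summary(object$accuracy),
            g = summary(object$g))
  class(s) <- "summary.gblup"
  s
}

#' @export
print.summary.gblup <- function(x, ...) {
  cat(sprintf("%s mixed-model fit\n", x$label))
  cat(sprintf("Records: %d   Animals in K: %d\n", x$n_records, x$n_animals))
  cat(sprintf("Variance components: sigma2_g = %.4f, sigma2_e = %.4f",
              x$vc$sigma2_g, x$vc$sigma2_e))
  if (!is.na(x$vc$loglik)) cat(sprintf("  (REML loglik %.3f)", x$vc$loglik))
  cat("\n")
  if (x$jitter > 0) cat(sprintf("K inverted with diagonal jitter %g\n", x$jitter))
  cat("Predictions (g-hat):\n"); print(x$g)
  cat("Theoretical accuracy:\n"); print(x$acc)
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) c(mu = object$mu)

#' Breeding-value predictions from a fit
#'
#' @param object a `gblup` fit.
#' @param ids animals to predict (default: every animal in K).  Animals
#'   without records are predicted through their relationships.
#' @param ... unused.
#' @return named vector of DGV/GEBV.
#' @export
predict.gblup <- function(object, ids = NULL, ...) {
  if (is.null(ids)) return(object$g)
  ids <- as.character(ids)
  if (!all(ids %in% names(object$g))) {
    stop("some requested animals are not in the fitted relationship matrix")
  }
  object$g[ids]
}

#' @export
fitted.gblup <- function(object, ...) {
  stats::setNames(object$records$fitted, object$records$animal)
}

#' @export
residuals.gblup <- function(object, ...) {
  stats::setNames(object$records$resid, object$records$animal)
}

#' Simulate response vectors from a fitted model
#'
#' Draws \eqn{y^* = 1\hat\mu + Zg^* + e^*} with \eqn{g^* \sim
#' N(0, K\hat\sigma^2_g)} and independent residuals
#' \eqn{e^*_i \sim N(0, \hat\sigma^2_e / w_i)}; useful for parametric
#' bootstrap checks.  K is reconstructed only up to the record animals.
#'
#' @param object a `gblup` fit that still has access to its K (pass `K`).
#' @param nsim number of simulated response vectors.
#' @param seed optional seed.
#' @param K the relationship matrix used in the fit.
#' @param ... unused.
#' @return data frame with one column per simulation, rows aligned with the
#'   fit's records.
#' @export
simulate.gblup <- function(object, nsim = 1, seed = NULL, K, ...) {
  if (!is.null(seed)) set.seed(seed)
  ai <- match(object$records$animal, rownames(K))
  L <- chol(unclass(K) + diag(1e-10, nrow(K)))
  n <- nrow(object$records)
  out <- replicate(nsim, {
    gstar <- drop(crossprod(L, stats::rnorm(nrow(K)))) * sqrt(object$vc$sigma2_g)
    object$mu + gstar[ai] +
      stats::rnorm(n, 0, sqrt(object$vc$sigma2_e / object$records$w))
  })
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- make.unique(object$records$animal)
  out
}

#' Diagnostic plot: observed DRP against fitted values
#'
#' @param x a `gblup` fit.
#' @param ... passed to [plot()].
#' @export
plot.gblup <- function(x, ...) {
  graphics::plot(x$records$fitted, x$records$drp,
                 xlab = "fitted (mu + g-hat)", ylab = "observed DRP",
                 main = sprintf("%s: observed vs fitted", x$label), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
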