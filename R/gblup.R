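#' Weights from DRP reliability
#'
#' Each record enters the mixed model with weight
#' \eqn{w_i = r^2_{DRP,i} / (1 - r^2_{DRP,i})}; the residual covariance is
#' \eqn{D\sigma^2_e} with \eqn{d_{ii} = 1/w_i}, so reliable proofs carry
#' small residual variance.
#'
#' @param rel_drp vector of DRP reliabilities, each strictly inside (0, 1).
#' @return vector of positive weights.
#' @export
drp_weights <- function(rel_drp) {
  if (any(rel_drp <= 0 | rel_drp >= 1)) {
    stop("DRP reliabilities must lie strictly inside (0, 1)")
  }
  rel_drp / (1 - rel_drp)
}

#' Fit the weighted relationship-matrix BLUP model
#'
#' Fits \eqn{y = 1\mu + Zg + e} with \eqn{g \sim N(0, K\sigma^2_g)} and
#' \eqn{e \sim N(0, D\sigma^2_e)}, \eqn{d_{ii} = 1/w_i}, for any
#' relationship matrix K: genomic G (predictions are direct genomic values,
#' DGV), hybrid H (genomically enhanced breeding values, GEBV), or
#' adjusted-G variants.  Animals present in K without records (e.g. a
#' validation cohort) receive predictions through their relationships.
#'
#' Variance components are estimated by restricted maximum likelihood on
#' the variance ratio \eqn{\delta = \sigma^2_e/\sigma^2_g}: after
#' whitening the residual scale by \eqn{W^{1/2}} and rotating onto an
#' orthonormal basis of error contrasts, the restricted likelihood is a
#' smooth one-dimensional function of \eqn{\delta} evaluated in O(n) per
#' point from one symmetric eigendecomposition, and is maximised by a grid
#' bracket followed by golden-section refinement.  With the components in
#' hand, Henderson's mixed model equations
#' \deqn{\begin{pmatrix} 1'W1 & 1'WZ \\ Z'W1 & Z'WZ + K^{-1}\lambda
#'   \end{pmatrix} \begin{pmatrix} \hat\mu \\ \hat g \end{pmatrix}
#'   = \begin{pmatrix} 1'Wy \\ Z'Wy \end{pmatrix}, \qquad
#'   \lambda = \sigma^2_e/\sigma^2_g,}
#' are solved densely; the g-block of the inverse coefficient matrix gives
#' prediction-error variances \eqn{PEV_i = C^{gg}_{ii}\sigma^2_e} and
#' theoretical accuracies \eqn{\sqrt{1 - PEV_i/(K_{ii}\sigma^2_g)}}.
#'
#' @param drp numeric vector of de-regressed proofs (one record per
#'   reference animal).
#' @param rel vector of DRP reliabilities matching `drp`.
#' @param K relationship matrix (a [new_relmat()] or plain symmetric matrix
#'   with animal dimnames) over all modelled animals.
#' @param ids animal ID for each record; defaults to `names(drp)`.
#' @param var_components optional list with `sigma2_g` and `sigma2_e` to
#'   skip REML (e.g. to reuse components across scenarios).
#' @param label free-text label (`"GBLUP"`, `"one-step"`, ...).
#' @return an object of class `gblup` with components `mu`, `g` (named
#'   predictions for every animal in K), `pev`, `accuracy`, `vc`
#'   (`sigma2_g`, `sigma2_e`, `loglik`, `converged`), `records`, `jitter`.
#' @seealso [accuracy_rv()] for validation accuracy, [blend_H()] for the
#'   hybrid matrix.
#' @export
fit_gblup <- function(drp, rel, K, ids = names(drp),
                      var_components = NULL, label = "GBLUP") {
  cl <- match.call()
  if (is.null(ids)) stop("record animal IDs are required (ids or names(drp))")
  ids <- as.character(ids)
  stopifnot(length(drp) == length(rel), length(drp) == length(ids))
  keep <- !is.na(drp) & !is.na(rel)
  drp <- drp[keep]; rel <- rel[keep]; ids <- ids[keep]
  n <- length(drp)
  if (n < 1L) stop("at least one record is required")
  if (n < 2L && is.null(var_components)) {
    stop("variance components cannot be estimated from a single record; ",
         "supply var_components")
  }
  kid <- rownames(K)
  ai <- match(ids, kid)
  if (anyNA(ai)) {
    stop("records refer to animals absent from K: ",
         paste(utils::head(ids[is.na(ai)], 5), collapse = ", "))
  }
  w <- drp_weights(rel)

  if (is.null(var_components)) {
    vc <- .reml_ratio(drp, w, unclass(K)[ai, ai, drop = FALSE])
  } else {
    vc <- list(sigma2_g = var_components$sigma2_g,
               sigma2_e = var_components$sigma2_e,
               loglik = NA_real_, converged = TRUE, boundary = FALSE)
  }
  if (!is.finite(vc$sigma2_g) || vc$sigma2_g <= 0) {
    stop("genetic variance collapsed to the zero boundary; ",
         "the data carry no genetic signal to fit")
  }
  sol <- .solve_mme(drp, w, ai, unclass(K), vc)
  fit <- structure(list(
    call = cl, label = label, kind = attr(K, "kind"),
    ids = kid, mu = sol$mu, g = sol$g, pev = sol$pev,
    accuracy = sol$acc, vc = vc, jitter = sol$jitter,
    records = data.frame(animal = ids, drp = drp, rel_drp = rel, w = w,
                         fitted = sol$mu + sol$g[ai],
                         resid = drp - sol$mu - sol$g[ai],
                         stringsAsFactors = FALSE),
    Kdiag = diag(K)), class = "gblup")
  fit
}

# Restricted likelihood for (sigma2_g, sigma2_e) via the variance ratio.
# y: records; w: weights (D^-1); Krec: K restricted to record animals.
.reml_ratio <- function(y, w, Krec, log_delta_range = c(-18, 18)) {
  n <- length(y)
  sw <- sqrt(w)
  yt <- sw * y
  Kt <- Krec * tcrossprod(sw)
  # orthonormal basis of the error contrasts (complement of the whitened mean)
  B <- qr.Q(qr(matrix(sw, n, 1)), complete = TRUE)[, -1, drop = FALSE]
  Kc <- crossprod(B, Kt %*% B)
  e <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
  xi <- pmax(e$values, 0)
  eta2 <- drop(crossprod(e$vectors, drop(crossprod(B, yt))))^2
  m <- n - 1L
  # contrasts numerically zero (e.g. a constant response): no signal to fit
  if (sum(eta2) <= max(sum(yt^2), 1) * 1e-20) {
    return(list(sigma2_g = 0, sigma2_e = 0, loglik = NA_real_,
                converged = FALSE, boundary = TRUE))
  }
  nll <- function(t) {
    d <- exp(t)
    q <- sum(eta2 / (xi + d))
    0.5 * (m * log(2 * pi * q / m) + sum(log(xi + d)) + m)
  }
  grid <- seq(log_delta_range[1], log_delta_range[2], length.out = 49)
  vals <- vapply(grid, nll, numeric(1))
  i0 <- which.min(vals)
  lo <- grid[max(1L, i0 - 1L)]
  hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(nll, c(lo, hi), tol = 1e-10)
  t_hat <- opt$minimum
  delta <- exp(t_hat)
  s2g <- sum(eta2 / (xi + delta)) / m
  boundary <- t_hat <= log_delta_range[1] + 1e-4 ||
    t_hat >= log_delta_range[2] - 1e-4 || i0 %in% c(1L, length(grid))
  list(sigma2_g = s2g, sigma2_e = delta * s2g, loglik = -opt$objective,
       converged = !boundary, boundary = boundary, delta = delta)
}

# Dense Henderson MME with a single mean; returns solutions, PEV, accuracy.
.solve_mme <- function(y, w, ai, K, vc) {
  q <- nrow(K)
  lambda <- vc$sigma2_e / vc$sigma2_g
  inv <- .chol_inverse(K)
  ZtW <- numeric(q)
  ZtWy <- numeric(q)
  agg_w <- rowsum(w, ai)
  agg_wy <- rowsum(w * y, ai)
  rows <- as.integer(rownames(agg_w))
  ZtW[rows] <- agg_w
  ZtWy[rows] <- agg_wy
  C <- matrix(0, q + 1L, q + 1L)
  C[1L, 1L] <- sum(w)
  C[1L, -1L] <- ZtW
  C[-1L, 1L] <- ZtW
  C[-1L, -1L] <- inv$Kinv * lambda
  diag(C)[-1L] <- diag(C)[-1L] + ZtW
  rhs <- c(sum(w * y), ZtWy)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    stop("mixed-model coefficient matrix is singular in the random-effect ",
         "block; check K for repeated animals or zero rows")
  }
  Cinv <- chol2inv(ch)
  coefs <- drop(Cinv %*% rhs)
  g <- coefs[-1L]
  names(g) <- rownames(K)
  pev <- diag(Cinv)[-1L] * vc$sigma2_e
  denom <- diag(K) * vc$sigma2_g
  if (any(denom <= 0)) stop("non-positive diagonal in K; accuracy undefined")
  acc <- sqrt(pmin(1, pmax(0, 1 - pev / denom)))
  names(pev) <- names(acc) <- rownames(K)
  list(mu = coefs[1L], g = g, pev = pev, acc = acc, jitter = inv$jitter)
}

# Symmetric inverse with a jitter ladder for near-singular K.
.chol_inverse <- function(K, ladder = c(0, 1e-8, 1e-6, 1e-4)) {
  for (j in ladder) {
    ch <- tryCatch(chol(K + diag(j, nrow(K))), error = function(e) NULL)
    if (!is.null(ch)) {
      return(list(Kinv = chol2inv(ch), jitter = j))
    }
  }
  stop("relationship matrix is not positive definite even after diagonal ",
       "jitter up to ", max(ladder))
}
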