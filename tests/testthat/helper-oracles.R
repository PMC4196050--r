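# Independent oracles and small generators used across the test files.
# These deliberately take different computational routes than the package
# (dense V-matrix likelihoods, explicit element loops, closed-form GLS)
# so that agreement is evidence, not tautology.

# Random valid pedigree: founders first, then animals whose parents are
# drawn among earlier animals of the right sex.
random_pedigree <- function(n, n_founders = max(4L, n %/% 5L),
                            p_parent = 0.8, p_geno = 0.5) {
  id <- sprintf("A%04d", seq_len(n))
  sex <- c(rep(c("M", "F"), length.out = n_founders),
           sample(c("M", "F"), n - n_founders, replace = TRUE))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq(n_founders + 1L, n)) {
    prev <- seq_len(i - 1L)
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (length(males) && stats::runif(1) < p_parent) {
      sire[i] <- id[males[sample.int(length(males), 1L)]]
    }
    if (length(females) && stats::runif(1) < p_parent) {
      dam[i] <- id[females[sample.int(length(females), 1L)]]
    }
  }
  geno <- stats::runif(n) < p_geno
  # at least two genotyped animals so A22/G blocks are non-trivial
  if (sum(geno) < 2L) geno[sample.int(n, 2L)] <- TRUE
  as_pedigree(data.frame(animal = id, sire = sire, dam = dam,
                         order = seq_len(n), genotyped = geno,
                         cohort = "ref_cow", sex = sex,
                         stringsAsFactors = FALSE))
}

# Random symmetric positive-definite relationship-like matrix.
random_K <- function(q, ids = sprintf("K%03d", seq_len(q))) {
  B <- matrix(stats::rnorm(q * (q + 2L)), q)
  K <- tcrossprod(B) / (q + 2L) + diag(0.5, q)
  dimnames(K) <- list(ids, ids)
  K
}

# Dense-V restricted log-likelihood for y = 1*mu + Zg + e,
# g ~ N(0, K s2g), e ~ N(0, D s2e), D = diag(1/w); Z maps records to
# animals via index vector ai.
reml_oracle <- function(y, w, K, ai = seq_along(y)) {
  n <- length(y)
  X <- matrix(1, n, 1)
  D <- diag(1 / w, n)
  ZKZ <- K[ai, ai, drop = FALSE]
  nll <- function(par) {
    s2g <- exp(par[1]); s2e <- exp(par[2])
    V <- s2g * ZKZ + s2e * D
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Vi <- chol2inv(ch)
    XVX <- crossprod(X, Vi %*% X)
    beta <- solve(XVX, crossprod(X, Vi %*% y))
    r <- y - X %*% beta
    0.5 * (2 * sum(log(diag(ch))) + log(det(XVX)) +
             drop(crossprod(r, Vi %*% r)))
  }
  o <- stats::optim(c(0, 0), nll, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  list(sigma2_g = exp(o$par[1]), sigma2_e = exp(o$par[2]))
}

# Closed-form GLS/BLUP solution and PEV by explicit covariance algebra.
gls_oracle <- function(y, w, K, ai, s2g, s2e) {
  n <- length(y)
  X <- matrix(1, n, 1)
  D <- diag(1 / w, n)
  Z <- matrix(0, n, nrow(K))
  Z[cbind(seq_len(n), ai)] <- 1
  V <- s2g * Z %*% K %*% t(Z) + s2e * D
  Vi <- solve(V)
  XVX <- crossprod(X, Vi %*% X)
  mu <- drop(solve(XVX, crossprod(X, Vi %*% y)))
  ghat <- drop(s2g * K %*% t(Z) %*% Vi %*% (y - X %*% mu))
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  pev <- diag(s2g * K - s2g^2 * K %*% t(Z) %*% P %*% Z %*% K)
  list(mu = unname(mu), g = unname(ghat), pev = unname(pev))
}

# Wright-style expectation check helper: mean A between members of each
# paternal half-sib family.
halfsib_mean_A <- function(A, ped) {
  out <- c()
  for (s in unique(stats::na.omit(ped$sire))) {
    kids <- ped$animal[!is.na(ped$sire) & ped$sire == s & is.na(ped$dam)]
    if (length(kids) >= 2L) {
      sub <- A[kids, kids]
      out <- c(out, sub[upper.tri(sub)])
    }
  }
  mean(out)
}
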