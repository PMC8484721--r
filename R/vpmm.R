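#' Prior specification for the phylogenetic mixed model
#'
#' Covariance matrices get parameter-expanded priors: an inner
#' inverse-Wishart with `nu` degrees of freedom and scale `nu * V0` on the
#' working covariance, multiplied by independent working parameters with
#' variance `alpha_var`, which yields heavy-tailed multivariate-F-type
#' marginals with variance distributions scaled by `alpha_var` (default
#' 1000). Residual variances get inverse-gamma priors with shape and scale
#' 0.002. Fixed effects have an improper flat prior.
#'
#' @param nu Inner inverse-Wishart degrees of freedom; default the number of
#'   responses `d` (set when the model is built if `NULL`).
#' @param V0 Inner inverse-Wishart scale basis (default identity); the scale
#'   matrix used is `nu * V0`.
#' @param alpha_var Variance of the working-parameter expansion (default 1000).
#' @param resid_shape,resid_scale Inverse-gamma hyperparameters for residual
#'   variances (default 0.002 each).
#' @return An object of class `vpmm_prior`.
#' @export
vpmm_prior <- function(nu = NULL, V0 = NULL, alpha_var = 1000,
                       resid_shape = 0.002, resid_scale = 0.002) {
  stopifnot(alpha_var > 0, resid_shape > 0, resid_scale > 0)
  structure(list(nu = nu, V0 = V0, alpha_var = alpha_var,
                 resid_shape = resid_shape, resid_scale = resid_scale),
            class = "vpmm_prior")
}

#' MCMC settings for [vpmm()]
#'
#' The `"desk"` scale (default) runs 130,000 iterations with a burn-in of
#' 30,000, sampling every 50 iterations (2,000 retained draws) — a 1:100
#' scale-down of the `"paper"` scale (13 million iterations, 3 million
#' burn-in, sampled every 5,000).
#'
#' @param n_iter,burn_in,thin Chain length, burn-in, thinning interval.
#' @param scale `"desk"` or `"paper"` preset; explicit arguments override.
#' @param ess_gate Warn after fitting if any reported parameter has effective
#'   sample size below this (default 200); 0 disables the gate.
#' @return An object of class `vpmm_mcmc`.
#' @export
vpmm_mcmc <- function(n_iter = NULL, burn_in = NULL, thin = NULL,
                      scale = c("desk", "paper"), ess_gate = 200) {
  scale <- match.arg(scale)
  preset <- switch(scale,
    desk  = list(n_iter = 130000L, burn_in = 30000L, thin = 50L),
    paper = list(n_iter = 13e6, burn_in = 3e6, thin = 5000L))
  out <- list(n_iter = if (is.null(n_iter)) preset$n_iter else n_iter,
              burn_in = if (is.null(burn_in)) preset$burn_in else burn_in,
              thin = if (is.null(thin)) preset$thin else thin,
              ess_gate = ess_gate)
  stopifnot(out$burn_in < out$n_iter, out$thin >= 1)
  structure(out, class = "vpmm_mcmc")
}

# Shared design construction: per-virus intercepts plus optional per-virus
# covariate slopes; species and virus indices aligned to A and the virus
# level order.
build_design <- function(obs, A, covariates = NULL) {
  al <- align_species(A, obs)
  obs <- al$obs
  A <- al$A
  viruses <- unique(as.character(obs$virus))
  species <- rownames(A)
  sp <- match(obs$species, species)
  vir <- match(as.character(obs$virus), viruses)
  d <- length(viruses)
  X <- matrix(0, nrow(obs), d,
              dimnames = list(NULL, paste0("beta_", viruses)))
  X[cbind(seq_len(nrow(obs)), vir)] <- 1
  if (!is.null(covariates)) {
    for (cv in covariates) {
      if (!cv %in% names(obs)) stop("covariate not in observations: ", cv)
      Xc <- matrix(0, nrow(obs), d,
                   dimnames = list(NULL, paste0(cv, "_", viruses)))
      Xc[cbind(seq_len(nrow(obs)), vir)] <- obs[[cv]]
      X <- cbind(X, Xc)
    }
  }
  list(obs = obs, A = A, X = X, sp = sp, vir = vir,
       viruses = viruses, species = species, d = d)
}

#' Fit the multi-response phylogenetic mixed model by MCMC
#'
#' Fits, to long-format log2 fold-change observations, the model
#' `y_hiv = beta_v (+ covariates) + u_p[h,v] (+ u_s[h,v]) + e_hiv`
#' where phylogenetic effects `u_p` have covariance `V_p %x% A` (Brownian
#' motion on the host tree), optional non-phylogenetic species effects `u_s`
#' have covariance `V_s %x% I`, and residuals are independent with
#' virus-specific variances (residual covariances between viruses are fixed
#' at zero: each biological replicate is tested with a single virus, so they
#' are not estimable). Sampling is by the parameter-expanded Gibbs scheme
#' described in [vpmm_prior()].
#'
#' @param obs Observation table: columns species, virus, bio_rep, y, plus any
#'   covariates.
#' @param tree Host phylogeny (`phylo`); ignored if `A` is given.
#' @param A Phylogenetic relatedness matrix (unit diagonal); computed from
#'   `tree` if missing.
#' @param species_effect Include the free species effect `u_s` (the model
#'   used to estimate phylogenetic heritability). `FALSE` gives the reduced
#'   model used for repeatability and interspecific correlations.
#' @param phylo_effect Include the phylogenetic effect `u_p`. Setting both
#'   effects `FALSE` reduces to independent per-virus intercept models
#'   (useful for conjugate validation).
#' @param covariates Optional character vector of column names entered as
#'   per-virus fixed-effect slopes (e.g. a wing-length body-size proxy).
#' @param prior A [vpmm_prior()].
#' @param mcmc A [vpmm_mcmc()].
#' @param seed Integer seed; the full draw sequence is reproducible.
#' @param sample_prior If `TRUE`, ignore the data and sample the variance
#'   components from their prior (fixed effects are held at zero; the flat
#'   prior is improper). Used for prior-predictive checks.
#' @param verbose Print progress.
#' @return An object of class `vpmm` with posterior draws: `beta` (draws x
#'   fixed effects), `Vp`, `Vs` (d x d x draws arrays), `ve` (draws x d),
#'   posterior-mean random effects, ESS per reported parameter, and the
#'   aligned data.
#' @export
vpmm <- function(obs, tree = NULL, A = NULL,
                 species_effect = TRUE, phylo_effect = TRUE,
                 covariates = NULL, prior = vpmm_prior(),
                 mcmc = vpmm_mcmc(), seed = 1L,
                 sample_prior = FALSE, verbose = FALSE) {
  cl <- match.call()
  stopifnot(inherits(prior, "vpmm_prior"), inherits(mcmc, "vpmm_mcmc"))
  if (is.null(A)) {
    if (is.null(tree)) stop("supply either a tree or a relatedness matrix A")
    A <- relatedness_matrix(tree)
  }
  if (!all(c("species", "virus", "y") %in% names(obs))) {
    stop("obs must have columns species, virus, y")
  }
  if (any(!is.finite(obs$y))) stop("non-finite y in observations")
  de <- build_design(obs, A, covariates)
  d <- de$d
  nu_p <- if (is.null(prior$nu)) d else prior$nu
  if (nu_p < d) stop("prior degrees of freedom must be >= number of responses")
  V0 <- if (is.null(prior$V0)) diag(d) else prior$V0
  S0 <- nu_p * V0
  Ainv <- chol2inv(chol_jitter(de$A))

  set.seed(seed)
  t0 <- proc.time()[["elapsed"]]
  raw <- gibbs_vpmm_cpp(
    y = de$obs$y, X = de$X, sp = de$sp - 1L, vir = de$vir - 1L,
    A = de$A, Ainv = Ainv, d = d,
    use_phylo = phylo_effect, use_species = species_effect,
    sample_prior = sample_prior,
    n_iter = as.integer(mcmc$n_iter), burn_in = as.integer(mcmc$burn_in),
    thin = as.integer(mcmc$thin),
    nu_p = nu_p, S0p = S0, nu_s = nu_p, S0s = S0,
    alpha_var = prior$alpha_var,
    resid_shape = prior$resid_shape, resid_scale = prior$resid_scale)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (verbose) message(sprintf("MCMC finished: %d draws in %.1fs",
                               raw$n_kept, elapsed))

  colnames(raw$beta) <- colnames(de$X)
  dimnames(raw$Vp) <- list(de$viruses, de$viruses, NULL)
  if (species_effect) dimnames(raw$Vs) <- list(de$viruses, de$viruses, NULL)
  colnames(raw$ve) <- de$viruses
  dimnames(raw$u_p_mean) <- dimnames(raw$u_s_mean) <-
    list(de$species, de$viruses)

  fit <- structure(list(
    beta = raw$beta,
    Vp = if (phylo_effect) raw$Vp else NULL,
    Vs = if (species_effect) raw$Vs else NULL,
    ve = raw$ve,
    u_p_mean = if (phylo_effect) raw$u_p_mean else NULL,
    u_s_mean = if (species_effect) raw$u_s_mean else NULL,
    viruses = de$viruses, species = de$species,
    obs = de$obs, X = de$X, A = de$A, sp = de$sp, vir = de$vir,
    species_effect = species_effect, phylo_effect = phylo_effect,
    covariates = covariates, prior = prior, mcmc = mcmc, seed = seed,
    sample_prior = sample_prior, n_draws = raw$n_kept,
    elapsed = elapsed, call = cl
  ), class = "vpmm")
  fit$ess <- vpmm_ess(fit)
  if (!sample_prior && mcmc$ess_gate > 0 && min(fit$ess) < mcmc$ess_gate) {
    warning(sprintf(
      "effective sample size below gate (%g): min ESS %.0f for %s",
      mcmc$ess_gate, min(fit$ess), names(fit$ess)[which.min(fit$ess)]))
  }
  fit
}

# ESS for every reported scalar parameter (fixed effects, Vp/Vs variances,
# residual variances).
vpmm_ess <- function(fit) {
  chains <- list()
  for (j in seq_len(ncol(fit$beta))) {
    chains[[colnames(fit$beta)[j]]] <- fit$beta[, j]
  }
  if (!is.null(fit$Vp)) {
    for (v in seq_along(fit$viruses)) {
      chains[[paste0("vp_", fit$viruses[v])]] <- fit$Vp[v, v, ]
    }
  }
  if (!is.null(fit$Vs)) {
    for (v in seq_along(fit$viruses)) {
      chains[[paste0("vs_", fit$viruses[v])]] <- fit$Vs[v, v, ]
    }
  }
  for (v in seq_along(fit$viruses)) {
    chains[[paste0("ve_", fit$viruses[v])]] <- fit$ve[, v]
  }
  vapply(chains, function(x) {
    suppressWarnings(effective_sample_size(x))
  }, numeric(1))
}

#' Effective sample size of an MCMC chain
#'
#' Geyer's initial-positive-sequence estimator: autocorrelations are summed
#' in adjacent pairs and the sum truncated at the first non-positive pair,
#' giving `ESS = n / (-1 + 2 * sum(pair sums))`.
#'
#' @param x Numeric vector of at least 10 draws.
#' @return Estimated effective sample size. A constant chain returns the
#'   draw count with a warning.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10) stop("need at least 10 draws")
  if (stats::var(x) == 0 || !all(is.finite(x))) {
    warning("constant or non-finite chain; ESS set to draw count")
    return(n)
  }
  rho <- stats::acf(x, lag.max = n - 1, plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
  m_max <- floor((length(rho) - 1) / 2)
  tau <- -1
  for (m in 0:m_max) {
    g <- rho[2 * m + 1] + if (2 * m + 2 <= length(rho)) rho[2 * m + 2] else 0
    if (g <= 0) break
    tau <- tau + 2 * g
  }
  n / max(tau, 1e-12)
}

#' Exact marginal log-likelihood of the phylogenetic mixed model
#'
#' Evaluates the Gaussian log-likelihood of the observations with the random
#' effects integrated out: `y ~ N(X beta, Sigma)` with
#' `Sigma = Z_p (V_p (x) A) Z_p' + Z_s (V_s (x) I) Z_s' + diag(v_e)`.
#' The evaluation exploits the low-rank Kronecker structure via the
#' matrix-inversion and determinant lemmas (a factor `B = Z L` with
#' `L = chol(V) (x) chol(A)` and the capacitance `I + B' D^-1 B`), so
#' singular `V_p`/`V_s` (e.g. perfectly correlated viruses) are handled
#' exactly.
#'
#' @param beta Fixed-effect vector matching the design built from `obs`
#'   (per-virus intercepts, then per-virus covariate slopes).
#' @param V_p Phylogenetic covariance (d x d), or `NULL` to omit the term.
#' @param V_s Species-effect covariance, or `NULL`.
#' @param v_e Per-virus residual variances (named by virus or in virus order
#'   of first appearance in `obs`).
#' @param obs Observation table.
#' @param A Relatedness matrix.
#' @param covariates Optional covariate names (as in [vpmm()]).
#' @return Scalar log-likelihood.
#' @export
vpmm_loglik <- function(beta, V_p, V_s = NULL, v_e, obs, A,
                        covariates = NULL) {
  de <- build_design(obs, A, covariates)
  y <- de$obs$y
  N <- length(y)
  if (length(beta) != ncol(de$X)) stop("beta has wrong length")
  r <- y - as.vector(de$X %*% beta)
  Dinv <- 1 / v_e[de$vir]
  if (any(v_e <= 0)) stop("residual variances must be positive")

  B <- NULL
  n <- nrow(de$A)
  if (!is.null(V_p)) {
    L_A <- t(chol_jitter(de$A))
    L_V <- psd_sqrt(V_p)
    # row i of Z_p L_G is kron(L_V[vir_i, ], L_A[sp_i, ])
    B <- L_V[de$vir, , drop = FALSE][, rep(seq_len(de$d), each = n)] *
         L_A[de$sp, , drop = FALSE][, rep(seq_len(n), times = de$d)]
  }
  if (!is.null(V_s)) {
    L_Vs <- psd_sqrt(V_s)
    Bs <- matrix(0, N, n * de$d)
    for (j in seq_len(de$d)) {
      cols <- (j - 1) * n
      Bs[cbind(seq_len(N), cols + de$sp)] <- L_Vs[de$vir, j]
    }
    B <- cbind(B, Bs)
  }
  ld_D <- -sum(log(Dinv))
  if (is.null(B)) {
    return(-0.5 * (N * log(2 * pi) + ld_D + sum(r^2 * Dinv)))
  }
  BtDi <- t(B * Dinv)
  M <- diag(ncol(B)) + BtDi %*% B
  R <- chol_jitter(M)
  ld <- ld_D + 2 * sum(log(diag(R)))
  btr <- BtDi %*% r
  w <- backsolve(R, backsolve(R, btr, transpose = TRUE))
  quad <- sum(r^2 * Dinv) - sum(btr * w)
  -0.5 * (N * log(2 * pi) + ld + quad)
}

#' Maximum-likelihood point estimates (cross-check optimizer)
#'
#' Direct numerical optimization of the marginal likelihood from
#' [vpmm_loglik()] over fixed effects, Cholesky-parameterized covariance
#' components, and log residual variances. Intended as an independent
#' point-estimate cross-check of the sampler on small simulated instances;
#' not a substitute for the posterior.
#'
#' @param obs Observation table.
#' @param A Relatedness matrix.
#' @param species_effect Include `V_s`.
#' @param covariates Optional covariate names.
#' @param maxit Optimizer iteration budget.
#' @return List with `beta`, `V_p`, `V_s`, `v_e`, `loglik`, `convergence`
#'   (0 = converged; non-convergence is reported, not raised).
#' @export
vpmm_ml <- function(obs, A, species_effect = FALSE, covariates = NULL,
                    maxit = 500) {
  de <- build_design(obs, A, covariates)
  d <- de$d
  p <- ncol(de$X)
  nch <- d * (d + 1) / 2
  unpack_chol <- function(th) {
    L <- matrix(0, d, d)
    L[lower.tri(L, diag = TRUE)] <- th
    diag(L) <- exp(diag(L))
    L %*% t(L)
  }
  negll <- function(th) {
    beta <- th[seq_len(p)]
    o <- p
    V_p <- unpack_chol(th[o + seq_len(nch)]); o <- o + nch
    V_s <- NULL
    if (species_effect) { V_s <- unpack_chol(th[o + seq_len(nch)]); o <- o + nch }
    v_e <- exp(th[o + seq_len(d)])
    ll <- tryCatch(
      vpmm_loglik(beta, V_p, V_s, v_e, de$obs, de$A, covariates),
      error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  vbar <- stats::var(de$obs$y)
  th0 <- c(tapply(de$obs$y, de$vir, mean), rep(0, p - d),
           {s <- rep(0, nch); s[cumsum(c(1, rev(seq_len(d - 1) + 1))[seq_len(d)])] <-
              0.5 * log(vbar / 2); s},
           if (species_effect) {s <- rep(0, nch);
             s[cumsum(c(1, rev(seq_len(d - 1) + 1))[seq_len(d)])] <-
               0.5 * log(vbar / 4); s},
           rep(log(vbar / 4), d))
  opt <- stats::optim(th0, negll, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  beta <- opt$par[seq_len(p)]
  o <- p
  V_p <- unpack_chol(opt$par[o + seq_len(nch)]); o <- o + nch
  V_s <- NULL
  if (species_effect) { V_s <- unpack_chol(opt$par[o + seq_len(nch)]); o <- o + nch }
  v_e <- exp(opt$par[o + seq_len(d)])
  names(beta) <- colnames(de$X)
  dimnames(V_p) <- list(de$viruses, de$viruses)
  names(v_e) <- de$viruses
  list(beta = beta, V_p = V_p, V_s = V_s, v_e = v_e,
       loglik = -opt$value, convergence = opt$convergence)
}
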