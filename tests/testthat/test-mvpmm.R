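test_that("structured likelihood equals a closed-form normal density", {
  A <- matrix(1, 1, 1, dimnames = list("s1", "s1"))
  obs <- data.frame(species = "s1", virus = "v1", bio_rep = "r1", y = 0.7)
  ll <- vpmm_loglik(beta = 1.2, V_p = matrix(0, 1, 1), V_s = matrix(0, 1, 1),
                    v_e = 0.5, obs = obs, A = A)
  expect_equal(ll, dnorm(0.7, 1.2, sqrt(0.5), log = TRUE), tolerance = 1e-9)
})

test_that("structured likelihood equals the dense-matrix oracle", {
  tree <- simulate_host_tree(4, seed = 21)
  A <- relatedness_matrix(tree)
  obs <- expand.grid(species = rownames(A), virus = c("x", "y"),
                     bio_rep = c("r1", "r2"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(22)
  obs$y <- rnorm(nrow(obs))
  Vp <- matrix(c(1.3, 0.8, 0.8, 0.9), 2)
  Vs <- matrix(c(0.4, 0.1, 0.1, 0.2), 2)
  ve <- c(0.3, 0.6)
  beta <- c(0.5, -0.2)
  expect_equal(vpmm_loglik(beta, Vp, Vs, ve, obs, A),
               dense_loglik(beta, Vp, Vs, ve, obs, A), tolerance = 1e-8)
  # without the species effect
  expect_equal(vpmm_loglik(beta, Vp, NULL, ve, obs, A),
               dense_loglik(beta, Vp, NULL, ve, obs, A), tolerance = 1e-8)
  # with a covariate entering as per-virus slopes
  obs$wing <- rnorm(nrow(obs))
  beta_w <- c(beta, 0.3, -0.1)
  expect_equal(vpmm_loglik(beta_w, Vp, Vs, ve, obs, A, covariates = "wing"),
               dense_loglik(beta_w, Vp, Vs, ve, obs, A, covariates = "wing"),
               tolerance = 1e-8)
})

test_that("perfectly related duplicate tips equal a merged-tip model", {
  A2 <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  A1 <- matrix(1, 1, 1, dimnames = list("m", "m"))
  y <- c(0.3, -0.5, 1.1, 0.2)
  obs2 <- data.frame(species = c("a", "b", "a", "b"),
                     virus = c("x", "x", "y", "y"),
                     bio_rep = c("r1", "r1", "r1", "r1"), y = y)
  obs1 <- data.frame(species = rep("m", 4), virus = c("x", "x", "y", "y"),
                     bio_rep = paste0("r", 1:4), y = y)
  Vp <- matrix(c(0.8, 0.3, 0.3, 0.5), 2)
  ve <- c(0.4, 0.7)
  expect_equal(vpmm_loglik(c(0.1, -0.2), Vp, NULL, ve, obs2, A2),
               vpmm_loglik(c(0.1, -0.2), Vp, NULL, ve, obs1, A1),
               tolerance = 1e-7)
})

test_that("the sampler is deterministic given a seed", {
  tree <- simulate_host_tree(6, seed = 30)
  cfg <- sim_config(n_species = 6, viruses = c("x", "y"),
                    intercepts = c(0, 1),
                    V_p = matrix(c(1, .5, .5, 1), 2),
                    V_s = matrix(0.2 * diag(2), 2), v_e = c(.3, .3),
                    reps_per_combo = 2, missing_fraction = 0, seed = 31)
  obs <- simulate_viral_load(tree, cfg)
  m <- vpmm_mcmc(n_iter = 400, burn_in = 100, thin = 2, ess_gate = 0)
  f1 <- vpmm(obs, tree = tree, mcmc = m, seed = 5)
  f2 <- vpmm(obs, tree = tree, mcmc = m, seed = 5)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$Vp, f2$Vp)
  expect_identical(f1$ve, f2$ve)
  f3 <- vpmm(obs, tree = tree, mcmc = m, seed = 6)
  expect_false(identical(f1$beta, f3$beta))
  expect_equal(f1$n_draws, 150)
})

test_that("every posterior draw satisfies the parameter constraints", {
  tree <- simulate_host_tree(8, seed = 40)
  cfg <- sim_config(n_species = 8, viruses = c("x", "y"),
                    intercepts = c(1, 2), V_p = matrix(c(2, 1, 1, 2), 2),
                    V_s = 0.5 * diag(2), v_e = c(.5, .5),
                    reps_per_combo = 3, missing_fraction = 0, seed = 41)
  obs <- simulate_viral_load(tree, cfg)
  fit <- vpmm(obs, tree = tree,
              mcmc = vpmm_mcmc(n_iter = 1500, burn_in = 300, thin = 3,
                               ess_gate = 0), seed = 7)
  expect_true(all(fit$ve > 0))
  min_eig <- function(V) min(eigen(V, symmetric = TRUE,
                                   only.values = TRUE)$values)
  for (k in seq_len(fit$n_draws)) {
    expect_gte(min_eig(fit$Vp[, , k]), -1e-8)
    expect_gte(min_eig(fit$Vs[, , k]), -1e-8)
  }
  expect_equal(fit$Vp[1, 2, ], fit$Vp[2, 1, ])
})

test_that("with no data the sampler reproduces the stated prior", {
  # Gibbs draws of V_p under sample_prior must match direct Monte Carlo from
  # the expansion prior: V = diag(alpha) IW(nu, nu I) diag(alpha),
  # alpha ~ N(0, 1000)
  A <- relatedness_matrix(simulate_host_tree(5, seed = 50))
  obs <- data.frame(species = rownames(A)[c(1, 2)], virus = c("x", "y"),
                    bio_rep = "r1", y = c(0, 0))
  fit <- vpmm(obs, A = A, species_effect = FALSE, sample_prior = TRUE,
              mcmc = vpmm_mcmc(n_iter = 21000, burn_in = 1000, thin = 10,
                               ess_gate = 0), seed = 8)
  d <- 2
  nu <- 2
  set.seed(99)
  n_mc <- 4000
  direct <- vapply(seq_len(n_mc), function(i) {
    W <- stats::rWishart(1, nu, solve(nu * diag(d)))[, , 1]
    Vt <- solve(W)
    a <- rnorm(d, 0, sqrt(1000))
    (diag(a) %*% Vt %*% diag(a))[1, 1]
  }, 1.0)
  g <- fit$Vp[1, 1, ]
  # heavy-tailed prior: compare on log scale at several quantiles
  qs <- c(0.25, 0.5, 0.75)
  expect_equal(log(quantile(g, qs)), log(quantile(direct, qs)),
               tolerance = 0.25, ignore_attr = TRUE)
})

test_that("effective sample size matches closed forms", {
  set.seed(60)
  white <- rnorm(2000)
  expect_equal(effective_sample_size(white), 2000, tolerance = 0.15)

  n <- 10000
  rho <- 0.5
  ar <- as.numeric(stats::arima.sim(list(ar = rho), n))
  expect_equal(effective_sample_size(ar), n * (1 - rho) / (1 + rho),
               tolerance = 0.15)

  expect_warning(ess_c <- effective_sample_size(rep(3, 500)), "constant")
  expect_equal(ess_c, 500)
  expect_error(effective_sample_size(1:5), "at least 10")
})

test_that("posterior concentrates near the maximum-likelihood estimate", {
  tree <- simulate_host_tree(25, seed = 70)
  cfg <- sim_config(n_species = 25, viruses = c("x", "y"),
                    intercepts = c(2, -1),
                    V_p = matrix(c(3, 1.5, 1.5, 2), 2),
                    V_s = matrix(0, 2, 2), v_e = c(0.4, 0.4),
                    reps_per_combo = 4, missing_fraction = 0, seed = 71)
  obs <- simulate_viral_load(tree, cfg)
  A <- relatedness_matrix(tree)
  ml <- vpmm_ml(obs, A, species_effect = FALSE)
  expect_equal(ml$convergence, 0)
  fit <- vpmm(obs, A = A, species_effect = FALSE,
              mcmc = vpmm_mcmc(n_iter = 6000, burn_in = 1500, thin = 5,
                               ess_gate = 0), seed = 9)
  expect_equal(unname(coef(fit)), unname(ml$beta), tolerance = 0.15)
  expect_equal(mean(fit$ve[, 1]), ml$v_e[[1]], tolerance = 0.35)
  # variance components: posterior mean within a loose factor of the MLE
  expect_equal(mean(fit$Vp[1, 1, ]), ml$V_p[1, 1], tolerance = 0.5)
  # and the ML estimate itself recovers the simulation truth reasonably
  expect_equal(ml$beta[[1]], 2, tolerance = 0.75)
})

test_that("model variants share the confounded between-species variance", {
  # data generated without a free species effect: the full model splits the
  # between-species variance between u_p and u_s, but their sum tracks the
  # reduced model's phylogenetic variance
  tree <- simulate_host_tree(45, seed = 80)
  obs <- simulate_viral_load(tree, sim_config(seed = 81))
  m <- vpmm_mcmc(n_iter = 5000, burn_in = 1500, thin = 5, ess_gate = 0)
  f2 <- vpmm(obs, tree = tree, species_effect = FALSE, mcmc = m, seed = 10)
  f1 <- vpmm(obs, tree = tree, species_effect = TRUE, mcmc = m, seed = 11)
  for (v in 1:4) {
    total1 <- mean(f1$Vp[v, v, ] + f1$Vs[v, v, ])
    total2 <- mean(f2$Vp[v, v, ])
    expect_gt(total1 / total2, 0.6)
    expect_lt(total1 / total2, 1.7)
  }
})

test_that("wing-size covariates enter as per-virus fixed effects", {
  tree <- simulate_host_tree(12, seed = 90)
  cfg <- sim_config(n_species = 12, viruses = c("x", "y"),
                    intercepts = c(0, 0), V_p = 0.5 * diag(2),
                    V_s = matrix(0, 2, 2), v_e = c(.2, .2),
                    reps_per_combo = 3, missing_fraction = 0, seed = 91)
  obs <- simulate_viral_load(tree, cfg)
  set.seed(92)
  obs$wing <- rnorm(nrow(obs))
  obs$y <- obs$y + 1.5 * obs$wing        # same true slope for both viruses
  fit <- vpmm(obs, tree = tree, species_effect = FALSE, covariates = "wing",
              mcmc = vpmm_mcmc(n_iter = 3000, burn_in = 1000, thin = 4,
                               ess_gate = 0), seed = 12)
  slopes <- coef(fit)[c("wing_x", "wing_y")]
  expect_equal(unname(slopes), c(1.5, 1.5), tolerance = 0.15)
})
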