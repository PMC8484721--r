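test_that("HPD intervals match order-statistics expectations", {
  expect_equal(hpd_interval(rep(2.5, 50)), c(lower = 2.5, upper = 2.5))

  set.seed(100)
  u <- runif(10000)
  h <- hpd_interval(u, 0.95)
  expect_equal(unname(h[2] - h[1]), 0.95, tolerance = 0.02)

  z <- rnorm(20000)
  hz <- hpd_interval(z, 0.95)
  expect_equal(unname(hz[1]), -1.96, tolerance = 0.1)
  expect_equal(unname(hz[2]), 1.96, tolerance = 0.1)

  expect_error(hpd_interval(rnorm(19)), "at least 20")
})

test_that("HPD is the shortest interval on skewed posteriors", {
  set.seed(101)
  x <- rexp(20000)
  h <- hpd_interval(x, 0.9)
  q <- quantile(x, c(0.05, 0.95))
  expect_lt(h[2] - h[1], q[2] - q[1])     # beats the equal-tail interval
  expect_lt(h[1], 0.05)                    # hugs the mode at 0
})

test_that("heritability ratios hit the closed forms", {
  V1 <- const_V_array(diag(2), 100)
  expect_equal(heritability(V1, Vs_draws = V1)$mean, c(0.5, 0.5))

  V0 <- const_V_array(matrix(0, 2, 2) + diag(1e-300, 2), 100)
  expect_equal(heritability(V0, Vs_draws = V1)$mean, c(0, 0),
               tolerance = 1e-12)
})

test_that("repeatability ratios hit the closed forms", {
  Vp <- const_V_array(diag(2), 100)
  ve_eq <- matrix(1, 100, 2)
  expect_equal(repeatability(Vp, ve_draws = ve_eq)$mean, c(0.5, 0.5))
  ve_0 <- matrix(1e-300, 100, 2)
  expect_equal(repeatability(Vp, ve_draws = ve_0)$mean, c(1, 1))
})

test_that("interspecific correlations are exact for constant matrices", {
  I2 <- const_V_array(diag(2), 100)
  expect_equal(interspecific_correlations(I2)$mean, 0)
  ones <- const_V_array(matrix(1, 2, 2), 100)
  expect_equal(interspecific_correlations(ones)$mean, 1)
  # the printed sum-denominator variant is not a correlation
  expect_equal(interspecific_correlations(ones, denominator = "sum")$mean,
               1 / sqrt(2))
})

test_that("correlations from PSD draws lie in [-1, 1] exactly", {
  set.seed(110)
  k <- 500
  V <- array(NA_real_, c(3, 3, k))
  for (i in seq_len(k)) V[, , i] <- stats::rWishart(1, 4, diag(3))[, , 1]
  r <- attr(interspecific_correlations(V), "draws")
  expect_true(all(r >= -1 & r <= 1))
  h <- heritability(V, Vs_draws = V)
  expect_true(all(attr(h, "draws") >= 0 & attr(h, "draws") <= 1))
})

test_that("per-draw transforms commute with draw subsetting", {
  set.seed(111)
  k <- 400
  V <- array(NA_real_, c(2, 2, k))
  for (i in seq_len(k)) V[, , i] <- stats::rWishart(1, 3, diag(2))[, , 1]
  idx <- 51:250
  full <- attr(interspecific_correlations(V), "draws")
  sub <- attr(interspecific_correlations(V[, , idx, drop = FALSE]), "draws")
  expect_equal(sub[, 1], full[idx, 1])
  expect_equal(mean(sub), mean(full[idx, ]))
})

test_that("correlation differences and pMCMC follow the tail rule", {
  set.seed(120)
  k <- 4000
  # build V_p draws with two pairs of known, distinct correlations
  V <- array(NA_real_, c(3, 3, k))
  for (i in seq_len(k)) {
    r12 <- 0.9; r13 <- 0.5 + rnorm(1, 0, 0.02); r23 <- 0.1
    R <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3)
    V[, , i] <- R
  }
  dimnames(V) <- list(c("a", "b", "c"), c("a", "b", "c"), NULL)
  same <- correlation_difference(V, "a:b", "a:b")
  expect_equal(same$delta_r, 0)
  expect_equal(same$pmcmc, 1)

  allpos <- correlation_difference(V, "a:b", "a:c")
  expect_equal(allpos$pmcmc, 1 / k)        # floor rule
  expect_equal(allpos$delta_r, 0.4, tolerance = 0.01)
})

test_that("pMCMC approximates the two-sided normal tail", {
  # delta-r draws ~ N(0.4, 0.15^2) against an exactly-zero reference pair
  set.seed(121)
  k <- 20000
  dr <- rnorm(k, 0.4, 0.15)
  V3 <- array(0, c(3, 3, k),
              dimnames = list(c("a", "b", "c"), c("a", "b", "c"), NULL))
  for (i in seq_len(k)) {
    V3[, , i] <- diag(3)
    V3[1, 2, i] <- V3[2, 1, i] <- dr[i]
  }
  cd <- correlation_difference(V3, "a:b", "a:c")
  expect_equal(cd$delta_r, 0.4, tolerance = 0.01)
  # closed form: 2 * pnorm(0, 0.4, 0.15) = 0.0077
  expect_equal(cd$pmcmc, 2 * pnorm(0, 0.4, 0.15), tolerance = 0.35)
  expect_lt(cd$pmcmc, 0.02)
  expect_gt(cd$pmcmc, 0.002)
})

test_that("HPD exclusion of zero implies a small pMCMC", {
  set.seed(122)
  k <- 3000
  shift <- rnorm(k, 0.25, 0.05)
  V3 <- array(0, c(3, 3, k),
              dimnames = list(c("a", "b", "c"), c("a", "b", "c"), NULL))
  for (i in seq_len(k)) {
    V3[, , i] <- diag(3)
    V3[1, 2, i] <- V3[2, 1, i] <- shift[i]
  }
  cd <- correlation_difference(V3, "a:b", "a:c")
  expect_gt(cd$lower, 0)                   # HPD excludes zero ...
  expect_lt(cd$pmcmc, 0.05)                # ... so pMCMC is below 0.05
})

test_that("mean fold change back-transforms to fold units", {
  b0 <- matrix(0, 100, 1, dimnames = list(NULL, "v"))
  expect_equal(mean_fold_change(b0)$mean, 1)
  b10 <- matrix(10, 100, 1, dimnames = list(NULL, "v"))
  expect_equal(mean_fold_change(b10)$mean, 1024)

  set.seed(130)
  bn <- matrix(rnorm(5000, 3, 1), ncol = 1, dimnames = list(NULL, "v"))
  fc <- mean_fold_change(bn)
  expect_equal(fc$mean, mean(2^bn), tolerance = 1e-12)
  expect_gt(fc$mean, 2^mean(bn))          # Jensen
})

test_that("the combined report assembles both model variants", {
  tree <- simulate_host_tree(10, seed = 140)
  obs <- simulate_viral_load(tree, sim_config(
    n_species = 10, viruses = c("x", "y"), intercepts = c(3, 1),
    V_p = matrix(c(2, 1, 1, 2), 2), V_s = 0.3 * diag(2), v_e = c(.4, .4),
    reps_per_combo = 3, missing_fraction = 0, seed = 141))
  m <- vpmm_mcmc(n_iter = 1200, burn_in = 400, thin = 4, ess_gate = 0)
  f1 <- vpmm(obs, tree = tree, species_effect = TRUE, mcmc = m, seed = 1)
  f2 <- vpmm(obs, tree = tree, species_effect = FALSE, mcmc = m, seed = 2)
  rep <- viral_load_report(f1, f2)
  expect_s3_class(rep, "viral_load_report")
  expect_setequal(rep$table$virus, c("x", "y"))
  expect_true(all(rep$repeatability$mean >= 0 & rep$repeatability$mean <= 1))
  expect_true(all(rep$heritability$mean >= 0 & rep$heritability$mean <= 1))
  expect_true(all(abs(rep$correlations$mean) <= 1))
  expect_null(rep$correlation_differences)  # single pair, no contrasts
  expect_output(print(rep), "Interspecific correlations")

  f2_swapped <- f2
  f2_swapped$viruses <- c("p", "q")
  expect_error(viral_load_report(f1, f2_swapped), "virus labels")
})
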