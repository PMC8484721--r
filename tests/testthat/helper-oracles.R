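# Independent oracles used across test files. These deliberately take the
# brute-force route (dense covariance, explicit traversal) so they share no
# code path with the structured implementations they check.

# Dense multivariate-normal log-likelihood: builds the full stacked
# observation covariance Z (V (x) A) Z' + D explicitly and evaluates the
# Gaussian density by Cholesky.
dense_loglik <- function(beta, Vp, Vs, ve, obs, A, covariates = NULL) {
  viruses <- unique(as.character(obs$virus))
  species <- rownames(A)
  sp <- match(obs$species, species)
  vir <- match(as.character(obs$virus), viruses)
  n <- nrow(A)
  d <- length(viruses)
  N <- nrow(obs)
  Z <- matrix(0, N, n * d)
  Z[cbind(seq_len(N), (vir - 1) * n + sp)] <- 1
  Sig <- matrix(0, N, N)
  if (!is.null(Vp)) Sig <- Sig + Z %*% kronecker(Vp, A) %*% t(Z)
  if (!is.null(Vs)) Sig <- Sig + Z %*% kronecker(Vs, diag(n)) %*% t(Z)
  diag(Sig) <- diag(Sig) + ve[vir]
  X <- matrix(0, N, d)
  X[cbind(seq_len(N), vir)] <- 1
  if (!is.null(covariates)) {
    for (cv in covariates) {
      Xc <- matrix(0, N, d)
      Xc[cbind(seq_len(N), vir)] <- obs[[cv]]
      X <- cbind(X, Xc)
    }
  }
  r <- obs$y - as.vector(X %*% beta)
  R <- tryCatch(chol(Sig), error = function(e) chol(Sig + diag(1e-12, N)))
  -0.5 * (N * log(2 * pi) + 2 * sum(log(diag(R))) +
          sum(backsolve(R, r, transpose = TRUE)^2))
}

# Shared root-to-MRCA path length by explicit traversal of root-to-tip node
# paths (common-prefix edge sum), independent of ape::vcv.
traversal_relatedness <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  elen <- function(child) tree$edge.length[match(child, tree$edge[, 2])]
  paths <- lapply(seq_len(n), function(tip) ape::nodepath(tree, root, tip))
  depth <- vapply(paths, function(p) sum(vapply(p[-1], elen, 1.0)), 1.0)
  h <- max(depth)
  A <- diag(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pi_ <- paths[[i]]; pj <- paths[[j]]
    k <- 1L
    while (k < min(length(pi_), length(pj)) && pi_[k + 1L] == pj[k + 1L]) {
      k <- k + 1L
    }
    shared <- if (k == 1L) 0 else sum(vapply(pi_[2:k], elen, 1.0))
    A[i, j] <- A[j, i] <- shared / h
  }
  dimnames(A) <- list(tree$tip.label, tree$tip.label)
  A
}

# Random small model instance for likelihood-oracle comparisons.
random_instance <- function(seed, max_obs = 200) {
  set.seed(seed)
  n <- sample(3:10, 1)
  d <- sample(1:3, 1)
  tree <- simulate_host_tree(n, seed = seed + 1000)
  A <- relatedness_matrix(tree)
  viruses <- paste0("v", seq_len(d))
  Vp <- crossprod(matrix(rnorm(d * d), d)) + diag(0.1, d)
  use_vs <- runif(1) < 0.5
  Vs <- if (use_vs) crossprod(matrix(rnorm(d * d), d)) * 0.3 + diag(0.05, d)
  ve <- runif(d, 0.1, 2)
  reps <- sample(1:3, 1)
  obs <- expand.grid(species = rownames(A), virus = viruses,
                     bio_rep = paste0("r", seq_len(reps)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keep <- runif(nrow(obs)) > 0.2                         # sporadic missingness
  keep[match(viruses, obs$virus)] <- TRUE                # every virus observed
  obs <- obs[keep, , drop = FALSE]
  if (nrow(obs) > max_obs) obs <- obs[seq_len(max_obs), , drop = FALSE]
  obs$y <- rnorm(nrow(obs), 0, 2)
  beta <- rnorm(d)
  list(obs = obs, A = A, beta = beta, Vp = Vp, Vs = Vs, ve = ve)
}

# A deterministic tiny observation table used in qPCR tests.
tiny_obs <- function() {
  data.frame(
    species = rep(c("spA", "spB"), each = 4),
    virus = rep(rep(c("v1", "v2"), each = 2), 2),
    bio_rep = rep(c("rep1", "rep2"), 4),
    y = c(3.2, 2.8, -0.5, 0.1, 7.4, 6.9, 1.1, 0.6),
    stringsAsFactors = FALSE)
}

# Fake vpmm-like draw arrays for derived-quantity tests.
const_V_array <- function(V, k = 100) {
  d <- nrow(V)
  array(rep(V, k), dim = c(d, d, k),
        dimnames = list(rownames(V), colnames(V), NULL))
}
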