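#' Simulate an ultrametric host tree
#'
#' Pure-birth (Yule) tree rescaled so every root-to-tip path equals 1. Any
#' ultrametric tree satisfies the mixed model's requirement of equal root-tip
#' distances; the unit rescaling makes the relatedness matrix have unit
#' diagonal exactly, so variance-component ratios are unaffected by the choice
#' of time units.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Optional integer seed for exact reproducibility.
#' @return A `phylo` object with tip labels `sp01`, `sp02`, ...
#' @export
simulate_host_tree <- function(n_species, seed = NULL) {
  if (!is.numeric(n_species) || n_species < 2) {
    stop("n_species must be an integer >= 2")
  }
  n_species <- as.integer(n_species)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  h <- max(tip_depths(tree))
  tree$edge.length <- tree$edge.length / h
  tree$tip.label <- sprintf("sp%0*d", nchar(as.character(n_species)),
                            seq_len(n_species))
  tree
}

default_viruses <- c("DCV-C", "DCV-EB", "DCV-M", "CrPV")

#' Default between-species covariance for the study design
#'
#' Four viruses: three closely related isolates mutually correlated at 0.97
#' and a more divergent fourth correlated at 0.55 with each, on the log2
#' fold-change scale. Variances (25, 25, 25, 12) give between-species standard
#' deviations of roughly 3.5-5 log2 units, matching host panels where mean
#' loads span declines to billion-fold increases.
#'
#' @param viruses Virus labels (length 4 for the default structure).
#' @return Covariance matrix with `viruses` as dimnames.
#' @export
default_Vp <- function(viruses = default_viruses) {
  stopifnot(length(viruses) == 4L)
  R <- matrix(0.55, 4, 4)
  R[1:3, 1:3] <- 0.97
  diag(R) <- 1
  s <- sqrt(c(25, 25, 25, 12))
  V <- outer(s, s) * R
  dimnames(V) <- list(viruses, viruses)
  V
}

#' Simulation configuration for species-level viral load data
#'
#' Defaults reproduce the study design: 45 host species, 4 viruses with
#' per-virus intercepts on the log2 fold-change scale (around 13.5-14 for the
#' three close isolates, 10.7 for the outgroup virus, i.e. mean fold increases
#' of roughly 1600-19,000), phylogenetic covariance [default_Vp()], no
#' free species effect (`V_s = 0`), residual variances chosen so repeatability
#' v_p/(v_p+v_e) is (0.96, 0.96, 0.92, 0.66), 3 biological replicates per
#' species x virus combination, and sporadic missingness mirroring an
#' attrition pattern in which ~10% of combinations lose one replicate and
#' rarely two.
#'
#' @param n_species Number of host species.
#' @param viruses Character vector of virus labels.
#' @param intercepts Per-virus fixed effects, log2 fold-change units.
#' @param V_p Phylogenetic between-species covariance (viruses x viruses),
#'   symmetric positive semidefinite.
#' @param V_s Non-phylogenetic species-effect covariance; may be 0.
#' @param v_e Per-virus residual variances (> 0).
#' @param reps_per_combo Target biological replicates per species x virus.
#' @param missing_fraction Probability that a combination is hit by replicate
#'   attrition (an affected combination loses one replicate, or two with
#'   conditional probability 1/19).
#' @param seed Integer seed stored in the config (used by the simulator).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_species = 45L,
                       viruses = default_viruses,
                       intercepts = c(13.5, 14.2, 13.6, 10.7),
                       V_p = default_Vp(viruses),
                       V_s = matrix(0, length(viruses), length(viruses)),
                       v_e = c(25, 25, 25, 12) * c(1 / 0.96, 1 / 0.96, 1 / 0.92, 1 / 0.66) -
                         c(25, 25, 25, 12),
                       reps_per_combo = 3L,
                       missing_fraction = 19 / 180,
                       seed = 1L) {
  d <- length(viruses)
  stopifnot(length(intercepts) == d, length(v_e) == d,
            is.matrix(V_p), all(dim(V_p) == d),
            is.matrix(V_s), all(dim(V_s) == d))
  if (n_species < 2) stop("n_species must be >= 2")
  if (reps_per_combo < 1) stop("reps_per_combo must be >= 1")
  if (any(v_e <= 0)) stop("residual variances must be positive")
  check_psd(V_p, "V_p")
  check_psd(V_s, "V_s")
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("missing_fraction must be in [0, 1)")
  }
  structure(list(
    n_species = as.integer(n_species), viruses = viruses,
    intercepts = stats::setNames(intercepts, viruses),
    V_p = V_p, V_s = V_s, v_e = stats::setNames(v_e, viruses),
    reps_per_combo = as.integer(reps_per_combo),
    missing_fraction = missing_fraction, seed = as.integer(seed)
  ), class = "sim_config")
}

check_psd <- function(V, name, tol = 1e-8) {
  if (max(abs(V - t(V))) > tol * max(1, max(abs(V)))) {
    stop(name, " must be symmetric")
  }
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev)))) {
    stop(name, " must be positive semidefinite (min eigenvalue ",
         format(min(ev)), ")")
  }
  invisible(TRUE)
}

# Matrix square root tolerant of exact semidefiniteness (correlation-1 pairs,
# zero species effects).
psd_sqrt <- function(V) {
  e <- eigen(V, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate species-level viral load observations
#'
#' Generates a long-format observation table from the generative model: for
#' species h, virus v, replicate i,
#' `y = intercept_v + u_p[h, v] + u_s[h, v] + e`, where the matrix of
#' phylogenetic effects `u_p` is drawn from a matrix normal with row
#' covariance `A` (the tree's relatedness matrix) and column covariance `V_p`
#' (i.e. `vec(u_p) ~ N(0, V_p %x% A)`), species effects have covariance
#' `V_s %x% I`, and residuals are independent with virus-specific variance.
#'
#' @param tree Host phylogeny (`phylo`), or a precomputed relatedness matrix.
#' @param config A [sim_config()].
#' @return A `data.frame` (species, virus, bio_rep, y) with attribute
#'   `"effects"` holding the true `u_p`, `u_s` matrices and intercepts.
#' @export
simulate_viral_load <- function(tree, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  A <- if (is.matrix(tree)) tree else relatedness_matrix(tree)
  n <- nrow(A)
  if (n < 2) stop("need at least 2 species")
  if (n != config$n_species) {
    stop("tree has ", n, " tips but config$n_species = ", config$n_species)
  }
  d <- length(config$viruses)
  set.seed(config$seed)

  # u ~ matrix normal: U = t(L_A) Z L_V  =>  Cov(vec U) = V %x% A
  L_A <- t(chol_jitter(A))
  u_p <- L_A %*% matrix(stats::rnorm(n * d), n, d) %*% t(psd_sqrt(config$V_p))
  u_s <- matrix(stats::rnorm(n * d), n, d) %*% t(psd_sqrt(config$V_s))
  dimnames(u_p) <- dimnames(u_s) <- list(rownames(A), config$viruses)

  combos <- expand.grid(species = rownames(A), virus = config$viruses,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_reps <- rep(config$reps_per_combo, nrow(combos))
  if (config$missing_fraction > 0 && config$reps_per_combo > 1) {
    hit <- stats::runif(nrow(combos)) < config$missing_fraction
    lose <- ifelse(hit, ifelse(stats::runif(nrow(combos)) < 1 / 19, 2L, 1L), 0L)
    n_reps <- pmax(1L, n_reps - lose)
  }
  idx <- rep(seq_len(nrow(combos)), n_reps)
  obs <- combos[idx, , drop = FALSE]
  obs$bio_rep <- paste0("rep", unlist(lapply(n_reps, seq_len)))
  hi <- match(obs$species, rownames(A))
  vi <- match(obs$virus, config$viruses)
  obs$y <- config$intercepts[vi] + u_p[cbind(hi, vi)] + u_s[cbind(hi, vi)] +
    stats::rnorm(nrow(obs), 0, sqrt(config$v_e[vi]))
  rownames(obs) <- NULL
  attr(obs, "effects") <- list(u_p = u_p, u_s = u_s,
                               intercepts = config$intercepts)
  obs
}

#' Configuration for Ct-level simulation
#'
#' Describes the measurement layer on top of species-level observations: the
#' housekeeping (RpL32) Ct level, the day-0 viral-minus-housekeeping delta Ct,
#' additive per-plate Ct offsets, and technical-replicate noise.
#'
#' @param plate_offsets Named numeric vector of per-plate additive Ct shifts;
#'   names are plate labels, and the number of plates is its length.
#' @param tech_rep_sd Ct-scale standard deviation of technical replicates
#'   (>= 0; 0 gives an exact round trip through the qPCR module).
#' @param baseline_delta_ct_day0 Day-0 delta Ct (viral minus housekeeping),
#'   recycled over species x virus combinations.
#' @param rpl32_ct_mean Housekeeping Ct level.
#' @return An object of class `ct_sim_config`.
#' @export
ct_sim_config <- function(plate_offsets = c(P1 = 0, P2 = 0, P3 = 0),
                          tech_rep_sd = 0,
                          baseline_delta_ct_day0 = 10,
                          rpl32_ct_mean = 18) {
  if (tech_rep_sd < 0) stop("tech_rep_sd must be >= 0")
  if (is.null(names(plate_offsets))) {
    names(plate_offsets) <- paste0("P", seq_along(plate_offsets))
  }
  structure(list(plate_offsets = plate_offsets, tech_rep_sd = tech_rep_sd,
                 baseline_delta_ct_day0 = baseline_delta_ct_day0,
                 rpl32_ct_mean = rpl32_ct_mean),
            class = "ct_sim_config")
}

#' Simulate a Ct-level qPCR experiment from species-level observations
#'
#' Inverse of the delta-delta-Ct computation: each observation row becomes a
#' biological replicate with day-0 and day-2 samples, each measured for the
#' viral and housekeeping amplicons in two technical replicates. The day-2
#' viral Ct is set to `baseline_delta_ct_day0 - y` above the housekeeping
#' level, so that averaging technical replicates, normalizing to RpL32, and
#' differencing days recovers `y` exactly when `tech_rep_sd = 0` and plate
#' offsets are zero. All four measurements of one biological replicate share a
#' plate; plates rotate across species x virus combinations, so plate offsets
#' cancel within each delta-delta-Ct group while remaining estimable by the
#' two-factor plate correction.
#'
#' @param obs Observation table (species, virus, bio_rep, y).
#' @param config A [ct_sim_config()].
#' @param seed Optional integer seed (technical-replicate noise).
#' @return A `data.frame` in raw Ct layout: sample_id, species, virus, day,
#'   bio_rep, plate, amplicon, ct1, ct2, melt_peak, qc_flag.
#' @export
simulate_ct_experiment <- function(obs, config = ct_sim_config(), seed = NULL) {
  stopifnot(inherits(config, "ct_sim_config"),
            all(c("species", "virus", "bio_rep", "y") %in% names(obs)))
  if (!is.null(seed)) set.seed(seed)
  plates <- names(config$plate_offsets)
  combo <- interaction(obs$species, obs$virus, obs$bio_rep, drop = TRUE)
  plate_of <- plates[(as.integer(combo) - 1L) %% length(plates) + 1L]

  grid <- expand.grid(row = seq_len(nrow(obs)), day = c(0L, 2L),
                      amplicon = c("viral", "housekeeping"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  r <- grid$row
  hk <- config$rpl32_ct_mean
  true_ct <- ifelse(grid$amplicon == "housekeeping", hk,
             ifelse(grid$day == 0L, hk + config$baseline_delta_ct_day0,
                    hk + config$baseline_delta_ct_day0 - obs$y[r]))
  true_ct <- true_ct + config$plate_offsets[plate_of[r]]
  noise <- function() if (config$tech_rep_sd > 0) {
    stats::rnorm(nrow(grid), 0, config$tech_rep_sd)
  } else 0
  ct <- data.frame(
    sample_id = paste(obs$species[r], obs$virus[r], obs$bio_rep[r],
                      paste0("d", grid$day), sep = "|"),
    species = obs$species[r], virus = obs$virus[r], day = grid$day,
    bio_rep = obs$bio_rep[r], plate = plate_of[r], amplicon = grid$amplicon,
    ct1 = true_ct + noise(), ct2 = true_ct + noise(),
    melt_peak = ifelse(grid$amplicon == "viral", 82, 78),
    qc_flag = "", stringsAsFactors = FALSE
  )
  ct <- ct[order(ct$species, ct$virus, ct$bio_rep, ct$day, ct$amplicon), ,
           drop = FALSE]
  rownames(ct) <- NULL
  ct
}

#' Read or write a simulation configuration as YAML
#'
#' Covariance matrices are stored as nested lists of rows; vectors keep
#' their names. Requires the `yaml` package.
#'
#' @param path YAML file path.
#' @return For `read_sim_config`, a [sim_config()]; `write_sim_config`
#'   returns the path invisibly.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files")
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop("unknown config fields: ", paste(extra, collapse = ", "))
  d <- length(raw$viruses)
  for (m in c("V_p", "V_s")) {
    if (!is.null(raw[[m]])) {
      raw[[m]] <- matrix(unlist(raw[[m]]), nrow = d, byrow = TRUE,
                         dimnames = list(raw$viruses, raw$viruses))
    }
  }
  for (v in c("intercepts", "v_e")) {
    if (!is.null(raw[[v]])) raw[[v]] <- unlist(raw[[v]])
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config A [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to write config files")
  }
  out <- unclass(config)
  out$intercepts <- as.numeric(out$intercepts)
  out$v_e <- as.numeric(out$v_e)
  for (m in c("V_p", "V_s")) {
    out[[m]] <- lapply(seq_len(nrow(out[[m]])), function(i)
      as.numeric(out[[m]][i, ]))
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write/read the long observation table as TSV
#' @param obs Observation table.
#' @param path File path.
#' @export
write_observation_tsv <- function(obs, path) {
  utils::write.table(obs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observation_tsv
#' @export
read_observation_tsv <- function(path) {
  obs <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "virus", "bio_rep", "y")
  if (!all(need %in% names(obs))) {
    stop("observation table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(obs$y))) stop("non-finite y in observation table")
  obs
}

#' Write/read a raw Ct table as TSV
#' @param ct Ct table.
#' @param path File path.
#' @export
write_ct_tsv <- function(ct, path) {
  utils::write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_tsv
#' @export
read_ct_tsv <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "virus", "day", "bio_rep", "plate", "amplicon", "ct1")
  if (!all(need %in% names(ct))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(ct$qc_flag)) ct$qc_flag <- ""
  ct$qc_flag[is.na(ct$qc_flag)] <- ""
  ct
}
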