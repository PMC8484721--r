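#' @export
print.vpmm <- function(x, ...) {
  cat("Multi-response phylogenetic mixed model (MCMC)\n")
  cat(sprintf("  responses: %s\n", paste(x$viruses, collapse = ", ")))
  cat(sprintf("  %d observations, %d species, %d retained draws\n",
              nrow(x$obs), length(x$species), x$n_draws))
  cat(sprintf("  phylogenetic effect: %s; species effect: %s\n",
              x$phylo_effect, x$species_effect))
  if (x$sample_prior) cat("  (prior-only sample: data ignored)\n")
  cat(sprintf("  min ESS: %.0f (%s)\n", min(x$ess),
              names(x$ess)[which.min(x$ess)]))
  invisible(x)
}

#' @export
coef.vpmm <- function(object, ...) colMeans(object$beta)

#' @export
vcov.vpmm <- function(object, component = c("Vp", "Vs"), ...) {
  component <- match.arg(component)
  V <- object[[component]]
  if (is.null(V)) stop("component ", component, " not in the fitted model")
  apply(V, c(1, 2), mean)
}

#' @export
fitted.vpmm <- function(object, ...) {
  f <- as.vector(object$X %*% coef(object))
  idx <- cbind(object$sp, object$vir)
  if (!is.null(object$u_p_mean)) f <- f + object$u_p_mean[idx]
  if (!is.null(object$u_s_mean)) f <- f + object$u_s_mean[idx]
  f
}

#' @export
residuals.vpmm <- function(object, ...) object$obs$y - fitted(object)

#' @export
logLik.vpmm <- function(object, ...) {
  ll <- vpmm_loglik(
    beta = coef(object),
    V_p = if (object$phylo_effect) vcov(object, "Vp") else NULL,
    V_s = if (object$species_effect) vcov(object, "Vs") else NULL,
    v_e = colMeans(object$ve),
    obs = object$obs, A = object$A, covariates = object$covariates)
  structure(ll, df = NA_integer_, class = "logLik")
}

#' @export
summary.vpmm <- function(object, prob = 0.95, ...) {
  one <- function(draws, name) {
    h <- hpd_interval(draws, prob)
    data.frame(parameter = name, mean = mean(draws),
               lower = h[[1]], upper = h[[2]],
               ess = suppressWarnings(effective_sample_size(draws)))
  }
  rows <- list()
  for (j in seq_len(ncol(object$beta))) {
    rows[[length(rows) + 1L]] <- one(object$beta[, j], colnames(object$beta)[j])
  }
  for (comp in c("Vp", "Vs")) {
    V <- object[[comp]]
    if (is.null(V)) next
    for (v in seq_along(object$viruses)) {
      rows[[length(rows) + 1L]] <-
        one(V[v, v, ], sprintf("%s_var_%s", tolower(comp), object$viruses[v]))
    }
  }
  for (v in seq_along(object$viruses)) {
    rows[[length(rows) + 1L]] <-
      one(object$ve[, v], paste0("ve_", object$viruses[v]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(table = out, n_draws = object$n_draws,
                 viruses = object$viruses, prob = prob),
            class = "summary.vpmm")
}

#' @export
print.summary.vpmm <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior summary (%d draws, %.0f%% HPD intervals)\n",
              x$n_draws, 100 * x$prob))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) signif(v, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Trace and density plots for key variance components
#' @param x A `vpmm` fit.
#' @param pars Parameter group to plot: `"Vp"` diagonal (default) or `"ve"`.
#' @param ... Unused.
#' @export
plot.vpmm <- function(x, pars = c("Vp", "ve"), ...) {
  pars <- match.arg(pars)
  d <- length(x$viruses)
  old <- graphics::par(mfrow = c(d, 2), mar = c(3, 3, 2, 1), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(old))
  for (v in seq_len(d)) {
    draws <- if (pars == "Vp") x$Vp[v, v, ] else x$ve[, v]
    lab <- sprintf("%s[%s]", if (pars == "Vp") "v_p" else "v_e", x$viruses[v])
    graphics::plot(draws, type = "l", xlab = "draw", ylab = lab,
                   main = paste("trace:", lab))
    graphics::plot(stats::density(draws), main = paste("density:", lab),
                   xlab = lab)
  }
  invisible(x)
}

#' Posterior draws as a flat data frame
#'
#' One row per retained draw; columns are flattened parameter names
#' (`beta_<virus>`, `vp_<v1>.<v2>`, `vs_<v1>.<v2>`, `ve_<virus>`), suitable
#' for TSV export.
#'
#' @param fit A `vpmm` fit.
#' @return A `data.frame` with `n_draws` rows.
#' @export
posterior_draws <- function(fit) {
  stopifnot(inherits(fit, "vpmm"))
  out <- as.data.frame(fit$beta)
  vn <- fit$viruses
  flat <- function(V, prefix) {
    cols <- list()
    for (a in seq_along(vn)) for (b in a:length(vn)) {
      cols[[sprintf("%s_%s.%s", prefix, vn[a], vn[b])]] <- V[a, b, ]
    }
    as.data.frame(cols, check.names = FALSE)
  }
  if (!is.null(fit$Vp)) out <- cbind(out, flat(fit$Vp, "vp"))
  if (!is.null(fit$Vs)) out <- cbind(out, flat(fit$Vs, "vs"))
  ve <- as.data.frame(fit$ve)
  names(ve) <- paste0("ve_", vn)
  cbind(out, ve)
}
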