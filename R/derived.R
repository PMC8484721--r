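#' Highest posterior density interval
#'
#' The shortest interval containing `ceiling(prob * n)` of the sorted draws.
#'
#' @param draws Numeric vector of at least 20 posterior draws.
#' @param prob Interval probability (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  n <- length(draws)
  if (n < 20) stop("need at least 20 draws for an HPD interval")
  stopifnot(prob > 0, prob <= 1)
  x <- sort(draws)
  m <- ceiling(prob * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  width <- x[seq(m, n)] - x[seq_len(n - m + 1)]
  i <- which.min(width)
  c(lower = x[i], upper = x[i + m - 1])
}

# shared per-draw summarizer
summarize_draws <- function(draws, prob = 0.95) {
  h <- hpd_interval(draws, prob)
  c(mean = mean(draws), h)
}

draws_or_fit <- function(x, component) {
  if (inherits(x, "vpmm")) {
    V <- x[[component]]
    if (is.null(V)) {
      stop("fit does not contain component ", component,
           " (was the model fitted with the right effects?)")
    }
    V
  } else x
}

#' Phylogenetic heritability per virus
#'
#' The proportion of between-species variance in viral load attributable to
#' the host phylogeny, `v_p / (v_p + v_s)`, computed per posterior draw from
#' the model that separates phylogenetic and free species effects, then
#' summarized as posterior mean and HPD interval.
#'
#' @param fit A `vpmm` fit with `species_effect = TRUE`, or a d x d x draws
#'   array of `V_p` draws (then `Vs_draws` must be supplied).
#' @param Vs_draws Optional `V_s` draw array when `fit` is an array.
#' @param prob HPD probability.
#' @return A `data.frame` (virus, mean, lower, upper) with attribute
#'   `"draws"` (draws x virus matrix of per-draw ratios).
#' @export
heritability <- function(fit, Vs_draws = NULL, prob = 0.95) {
  Vp <- draws_or_fit(fit, "Vp")
  Vs <- if (inherits(fit, "vpmm")) draws_or_fit(fit, "Vs") else Vs_draws
  if (is.null(Vs)) stop("heritability requires V_s draws (model with species effect)")
  d <- dim(Vp)[1]
  viruses <- dimnames(Vp)[[1]] %||% paste0("virus", seq_len(d))
  ratio <- sapply(seq_len(d), function(v) {
    Vp[v, v, ] / (Vp[v, v, ] + Vs[v, v, ])
  })
  colnames(ratio) <- viruses
  out <- as.data.frame(t(apply(ratio, 2, summarize_draws, prob = prob)))
  out <- cbind(virus = viruses, out, row.names = NULL)
  attr(out, "draws") <- ratio
  out
}

#' Repeatability of viral load across host species
#'
#' `v_p / (v_p + v_e)` per posterior draw: the fraction of total variance
#' among species means relative to within-species and measurement variance,
#' from the model without a free species effect.
#'
#' @param fit A `vpmm` fit (typically `species_effect = FALSE`), or a
#'   d x d x draws `V_p` array (then `ve_draws` must be supplied).
#' @param ve_draws Optional draws x d matrix of residual variances.
#' @param prob HPD probability.
#' @return As [heritability()].
#' @export
repeatability <- function(fit, ve_draws = NULL, prob = 0.95) {
  Vp <- draws_or_fit(fit, "Vp")
  ve <- if (inherits(fit, "vpmm")) fit$ve else ve_draws
  if (is.null(ve)) stop("repeatability requires residual variance draws")
  d <- dim(Vp)[1]
  viruses <- dimnames(Vp)[[1]] %||% paste0("virus", seq_len(d))
  ratio <- sapply(seq_len(d), function(v) Vp[v, v, ] / (Vp[v, v, ] + ve[, v]))
  colnames(ratio) <- viruses
  out <- as.data.frame(t(apply(ratio, 2, summarize_draws, prob = prob)))
  out <- cbind(virus = viruses, out, row.names = NULL)
  attr(out, "draws") <- ratio
  out
}

#' Interspecific correlations in viral load between viruses
#'
#' Per posterior draw, the correlation of species-level effects between each
#' pair of viruses from the `V_p` matrix. The default denominator is the
#' standard `cov_xy / sqrt(var_x * var_y)`, which is bounded in [-1, 1]. The
#' alternative `denominator = "sum"` divides by `sqrt(var_x + var_y)`; it is
#' not a correlation and is provided only for comparison with analyses that
#' used that expression.
#'
#' @param fit A `vpmm` fit or a d x d x draws `V_p` array.
#' @param denominator `"geometric"` (default, true correlation) or `"sum"`.
#' @param prob HPD probability.
#' @return A `data.frame` (pair, virus_x, virus_y, mean, lower, upper) with
#'   attribute `"draws"` (draws x pair matrix).
#' @export
interspecific_correlations <- function(fit,
                                       denominator = c("geometric", "sum"),
                                       prob = 0.95) {
  denominator <- match.arg(denominator)
  Vp <- draws_or_fit(fit, "Vp")
  d <- dim(Vp)[1]
  if (d < 2) stop("need at least two responses for correlations")
  viruses <- dimnames(Vp)[[1]] %||% paste0("virus", seq_len(d))
  pairs <- utils::combn(d, 2)
  r <- apply(pairs, 2, function(ij) {
    cov_xy <- Vp[ij[1], ij[2], ]
    vx <- Vp[ij[1], ij[1], ]
    vy <- Vp[ij[2], ij[2], ]
    den <- if (denominator == "geometric") sqrt(vx * vy) else sqrt(vx + vy)
    cov_xy / den
  })
  pair_names <- apply(pairs, 2, function(ij) {
    paste(viruses[ij[1]], viruses[ij[2]], sep = ":")
  })
  colnames(r) <- pair_names
  out <- as.data.frame(t(apply(r, 2, summarize_draws, prob = prob)))
  out <- cbind(pair = pair_names,
               virus_x = viruses[pairs[1, ]], virus_y = viruses[pairs[2, ]],
               out, row.names = NULL)
  attr(out, "draws") <- r
  out
}

#' Posterior difference between two interspecific correlations
#'
#' Computes `delta_r = r(pair_a) - r(pair_b)` per draw, its posterior mean,
#' HPD interval, and a two-sided pMCMC: twice the smaller tail fraction of
#' draws at or beyond zero, floored at `1/n_draws` and capped at 1.
#'
#' @param fit A `vpmm` fit or `V_p` draw array.
#' @param pair_a,pair_b Pairs as `"X:Y"` strings or length-2 character
#'   vectors of virus names.
#' @param prob HPD probability.
#' @param denominator Passed to [interspecific_correlations()].
#' @return List with `delta_r` (mean), `lower`, `upper`, `pmcmc`, and
#'   `draws`.
#' @export
correlation_difference <- function(fit, pair_a, pair_b, prob = 0.95,
                                   denominator = "geometric") {
  rr <- interspecific_correlations(fit, denominator = denominator, prob = prob)
  draws <- attr(rr, "draws")
  norm_pair <- function(p) {
    if (length(p) == 2) p else strsplit(p, ":", fixed = TRUE)[[1]]
  }
  find_pair <- function(p) {
    p <- norm_pair(p)
    hit <- which(rr$virus_x == p[1] & rr$virus_y == p[2] |
                 rr$virus_x == p[2] & rr$virus_y == p[1])
    if (!length(hit)) stop("unknown virus pair: ", paste(p, collapse = ":"))
    hit[1]
  }
  dr <- draws[, find_pair(pair_a)] - draws[, find_pair(pair_b)]
  n <- length(dr)
  pm <- 2 * min(mean(dr <= 0), mean(dr >= 0))
  pm <- min(1, max(1 / n, pm))
  h <- hpd_interval(dr, prob)
  list(delta_r = mean(dr), lower = unname(h[1]), upper = unname(h[2]),
       pmcmc = pm, draws = dr)
}

#' Mean fold change in viral load per virus
#'
#' Back-transforms per-virus intercept draws from the log2 working scale to
#' fold units (`2^beta`) and summarizes with posterior mean and HPD. Note the
#' posterior mean in fold units exceeds `2^mean(beta)` (Jensen's inequality).
#'
#' @param fit A `vpmm` fit, or a draws x d matrix of intercept draws.
#' @param prob HPD probability.
#' @return A `data.frame` (virus, mean, lower, upper) in fold units, with
#'   attribute `"draws"`.
#' @export
mean_fold_change <- function(fit, prob = 0.95) {
  beta <- if (inherits(fit, "vpmm")) {
    fit$beta[, seq_along(fit$viruses), drop = FALSE]
  } else fit
  fold <- 2^beta
  viruses <- if (inherits(fit, "vpmm")) fit$viruses else
    colnames(beta) %||% paste0("virus", seq_len(ncol(beta)))
  colnames(fold) <- viruses
  out <- as.data.frame(t(apply(fold, 2, summarize_draws, prob = prob)))
  out <- cbind(virus = viruses, out, row.names = NULL)
  attr(out, "draws") <- fold
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combined report of derived quantities from both model variants
#'
#' Mirrors the standard reporting layout: mean fold change and repeatability
#' from the reduced model (no free species effect), phylogenetic
#' heritability from the full model, plus all pairwise interspecific
#' correlations and their pairwise differences with pMCMC values.
#'
#' @param fit_full `vpmm` fit with `species_effect = TRUE` (model for
#'   heritability); may be `NULL` to skip heritability.
#' @param fit_reduced `vpmm` fit with `species_effect = FALSE` (model for
#'   fold change, repeatability, correlations).
#' @param prob HPD probability.
#' @return An object of class `viral_load_report`: list with `table`
#'   (per-virus data.frame), `correlations`, `correlation_differences`.
#' @export
viral_load_report <- function(fit_full, fit_reduced, prob = 0.95) {
  stopifnot(inherits(fit_reduced, "vpmm"))
  if (!is.null(fit_full) &&
      !identical(sort(fit_full$viruses), sort(fit_reduced$viruses))) {
    stop("the two fits do not share virus labels")
  }
  fc <- mean_fold_change(fit_reduced, prob)
  rp <- repeatability(fit_reduced, prob = prob)
  hr <- if (!is.null(fit_full)) heritability(fit_full, prob = prob) else NULL
  fmt <- function(df) sprintf("%.3g (%.3g, %.3g)", df$mean, df$lower, df$upper)
  tab <- data.frame(
    virus = fc$virus,
    mean_fold_change = fmt(fc),
    repeatability = fmt(rp),
    heritability = if (is.null(hr)) NA_character_ else
      fmt(hr[match(fc$virus, hr$virus), ]),
    stringsAsFactors = FALSE)
  corr <- interspecific_correlations(fit_reduced, prob = prob)
  pairs <- corr$pair
  diffs <- NULL
  if (length(pairs) > 1) {
    cmb <- utils::combn(length(pairs), 2)
    diffs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      a <- pairs[cmb[1, j]]; b <- pairs[cmb[2, j]]
      cd <- correlation_difference(fit_reduced, a, b, prob)
      data.frame(pair_a = a, pair_b = b, delta_r = cd$delta_r,
                 lower = cd$lower, upper = cd$upper, pmcmc = cd$pmcmc,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(table = tab,
                 fold_change = fc, repeatability = rp, heritability = hr,
                 correlations = corr, correlation_differences = diffs,
                 prob = prob),
            class = "viral_load_report")
}

#' @export
print.viral_load_report <- function(x, ...) {
  cat(sprintf("Per-virus summary (posterior mean, %.0f%% HPD):\n", 100 * x$prob))
  print(x$table, row.names = FALSE)
  cat("\nInterspecific correlations:\n")
  print(data.frame(pair = x$correlations$pair,
                   r = sprintf("%.2f (%.2f, %.2f)", x$correlations$mean,
                               x$correlations$lower, x$correlations$upper)),
        row.names = FALSE)
  if (!is.null(x$correlation_differences)) {
    cat("\nCorrelation differences (delta r, pMCMC):\n")
    d <- x$correlation_differences
    print(data.frame(contrast = paste(d$pair_a, "vs", d$pair_b),
                     delta_r = sprintf("%.2f (%.2f, %.2f)", d$delta_r,
                                       d$lower, d$upper),
                     pMCMC = signif(d$pmcmc, 2)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Plot interspecific correlation posteriors
#'
#' Horizontal point-interval panel of the pairwise correlations (posterior
#' mean with HPD bars), analogous to rank-correlation summaries of
#' cross-species susceptibility.
#'
#' @param x A `viral_load_report`.
#' @param ... Unused.
#' @export
plot.viral_load_report <- function(x, ...) {
  co <- x$correlations
  k <- nrow(co)
  old <- graphics::par(mar = c(4, 9, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(co$mean, seq_len(k), xlim = c(-1, 1), ylim = c(0.5, k + 0.5),
                 yaxt = "n", xlab = "interspecific correlation r", ylab = "",
                 pch = 19, main = "Between-virus correlations")
  graphics::axis(2, at = seq_len(k), labels = co$pair, las = 1)
  graphics::segments(co$lower, seq_len(k), co$upper, seq_len(k))
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}
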