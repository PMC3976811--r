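# Codon site-model selection analysis: ML fitting of GY94 site models
# M0 (one ratio), M3 (K = 3 discrete classes), M7 (beta) and M8
# (beta + a class with omega >= 1), likelihood-ratio tests, and naive
# empirical Bayes (NEB) identification of positively selected sites.

.beta_categories <- function(p, q, n_cat = 10L) {
  qbeta((2 * seq_len(n_cat) - 1) / (2 * n_cat), p, q)
}

.KAPPA_BOUNDS <- c(0.1, 20)
.OMEGA_BOUNDS <- c(1e-4, 50)
.BETA_BOUNDS <- c(0.05, 99)
.SCALE_BOUNDS <- c(0.02, 50)

#' Fit a GY94 site model by maximum likelihood
#'
#' Fits one of the site models M0, M3 (K = 3), M7 (beta discretized into
#' 10 equal-probability categories) or M8 (beta plus a selection class
#' with omega >= 1) to a codon alignment on a fixed tree topology.
#' Under M0, kappa, omega and all branch lengths are optimized jointly.
#' For the mixture models, branch lengths are taken from an M0 pre-fit
#' (run internally when not supplied) and rescaled by one free
#' multiplier while kappa and the omega-distribution parameters are
#' optimized; `optimize_branches = TRUE` switches to full joint branch
#' optimization. Each model is fitted from `n_starts` fixed starting
#' points; mixture models always include a start equal to the nested
#' null's optimum, so `lnL(M3) >= lnL(M0)` and `lnL(M8) >= lnL(M7)` by
#' construction.
#'
#' @param aln A `codon_alignment`.
#' @param tree `ape::phylo` topology (branch lengths, when present, are
#'   used as the optimizer start).
#' @param model One of `"M0"`, `"M3"`, `"M7"`, `"M8"`.
#' @param codon_freqs Codon frequencies; default F3x4 from the data.
#' @param n_starts Number of fixed starting points (default 3).
#' @param m0 Optional previously fitted M0 `site_model_fit` reused for
#'   branch lengths and starts.
#' @param m7 Optional fitted M7 reused as an M8 start.
#' @param optimize_branches Optimize all branch lengths for mixture
#'   models too (slower).
#' @param maxit Iteration cap per start.
#' @return A `site_model_fit`: `model`, `kappa`, `omegas`, `weights`,
#'   `omega_spec`, `tree` (fitted branch lengths), `lnL`,
#'   `class_site_loglik`, `pi`, `converged`, `note`.
#' @export
fit_site_model <- function(aln, tree, model = c("M0", "M3", "M7", "M8"),
                           codon_freqs = NULL, n_starts = 3, m0 = NULL,
                           m7 = NULL, optimize_branches = FALSE,
                           maxit = 300) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "codon_alignment"))
  if (length(aln$taxa) < 2L) .stopf("fit_site_model: need >= 2 taxa")
  idx <- .codon_index(aln)
  pi <- if (is.null(codon_freqs)) estimate_f3x4(aln) else codon_freqs
  phy <- tree
  n_edge <- nrow(phy$edge)
  t0 <- if (!is.null(phy$edge.length)) pmax(phy$edge.length, 1e-4) else {
    p <- .mean_pairwise_codon_diff(idx)
    rep(max(min(p, 1.5), 0.05), n_edge)
  }

  lb_t <- 1e-6; ub_t <- 20
  obj_env <- new.env()
  obj_env$evals <- 0L

  run <- function(par, lower, upper, fn) {
    optim(par, fn, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = maxit, fnscale = 1, factr = 1e8))
  }

  if (model == "M0") {
    fn <- function(par) {
      k <- exp(par[1L]); w <- exp(par[2L]); t <- exp(par[-(1:2)])
      ph <- phy; ph$edge.length <- t
      -.codon_loglik(idx, ph, k, w, 1, pi)$lnL
    }
    starts <- list(c(log(2), log(0.2), log(t0)),
                   c(log(5), log(1), log(t0 * 2)),
                   c(log(1.2), log(0.05), log(t0 * 0.5)))[seq_len(n_starts)]
    lower <- c(log(.KAPPA_BOUNDS[1]), log(.OMEGA_BOUNDS[1]), rep(log(lb_t), n_edge))
    upper <- c(log(.KAPPA_BOUNDS[2]), log(.OMEGA_BOUNDS[2]), rep(log(ub_t), n_edge))
    best <- NULL
    for (s in starts) {
      res <- run(s, lower, upper, fn)
      if (is.null(best) || res$value < best$value) best <- res
    }
    k <- exp(best$par[1L]); w <- exp(best$par[2L]); t <- exp(best$par[-(1:2)])
    ph <- phy; ph$edge.length <- t
    ll <- .codon_loglik(idx, ph, k, w, 1, pi)
    note <- if (sum(t) < 1e-3)
      "total tree length ~ 0: omega is unidentifiable" else NA_character_
    return(.mk_fit("M0", kappa = k, omegas = w, weights = 1,
                   omega_spec = list(omega = w), tree = ph, lnL = ll$lnL,
                   ll = ll, pi = pi, converged = best$convergence == 0,
                   note = note))
  }

  # Mixture models ride on M0 branch lengths (times a free scale) unless
  # full branch optimization is requested.
  if (is.null(m0)) {
    start_tree <- phy; start_tree$edge.length <- t0
    m0 <- fit_site_model(aln, start_tree, "M0", codon_freqs = pi,
                         n_starts = n_starts, maxit = maxit)
  }
  base_t <- m0$tree$edge.length
  k0 <- m0$kappa; w0 <- m0$omega_spec$omega

  mk_eval <- function(classes_fn) {
    function(par) {
      cl <- classes_fn(par)
      t <- if (optimize_branches) exp(par[cl$t_idx]) else base_t * cl$scale
      ph <- phy; ph$edge.length <- t
      -.codon_loglik(idx, ph, cl$kappa, cl$omegas, cl$weights, pi)$lnL
    }
  }
  t_par <- function() if (optimize_branches) log(base_t) else NULL
  t_lower <- function() if (optimize_branches) rep(log(lb_t), n_edge) else NULL
  t_upper <- function() if (optimize_branches) rep(log(ub_t), n_edge) else NULL
  n_fixed <- function(nf) if (optimize_branches) nf + seq_len(n_edge) else integer(0)

  if (model == "M3") {
    K <- 3L
    classes_fn <- function(par) {
      w1 <- exp(par[3L]); w2 <- w1 + par[4L]; w3 <- w2 + par[5L]
      a <- c(0, par[6L], par[7L])
      wts <- exp(a - max(a)); wts <- wts / sum(wts)
      list(kappa = exp(par[1L]), scale = exp(par[2L]),
           omegas = c(w1, w2, w3), weights = wts, t_idx = n_fixed(7L))
    }
    starts <- list(
      c(log(k0), log(1), log(w0), 0, 0, 0, 0, t_par()),             # == M0 optimum
      c(log(k0), log(1), log(max(w0 / 4, 1e-4)), 0.75 * w0, 3 * w0, 0, 0, t_par()),
      c(log(2), log(1), log(0.01), 0.5, 1.5, 0, 0, t_par()))[seq_len(n_starts)]
    lower <- c(log(.KAPPA_BOUNDS[1]), log(.SCALE_BOUNDS[1]),
               log(.OMEGA_BOUNDS[1]), 0, 0, -15, -15, t_lower())
    upper <- c(log(.KAPPA_BOUNDS[2]), log(.SCALE_BOUNDS[2]),
               log(.OMEGA_BOUNDS[2]), 49, 49, 15, 15, t_upper())
  } else if (model == "M7") {
    classes_fn <- function(par) {
      p <- exp(par[3L]); q <- exp(par[4L])
      list(kappa = exp(par[1L]), scale = exp(par[2L]),
           omegas = .beta_categories(p, q), weights = rep(0.1, 10L),
           p = p, q = q, t_idx = n_fixed(4L))
    }
    starts <- list(c(log(k0), log(1), log(0.5), log(1.5), t_par()),
                   c(log(k0), log(1), log(2), log(2), t_par()),
                   c(log(2), log(1), log(0.2), log(0.8), t_par()))[seq_len(n_starts)]
    lower <- c(log(.KAPPA_BOUNDS[1]), log(.SCALE_BOUNDS[1]),
               rep(log(.BETA_BOUNDS[1]), 2), t_lower())
    upper <- c(log(.KAPPA_BOUNDS[2]), log(.SCALE_BOUNDS[2]),
               rep(log(.BETA_BOUNDS[2]), 2), t_upper())
  } else { # M8
    classes_fn <- function(par) {
      p <- exp(par[3L]); q <- exp(par[4L]); p0 <- par[5L]; ws <- exp(par[6L])
      list(kappa = exp(par[1L]), scale = exp(par[2L]),
           omegas = c(.beta_categories(p, q), ws),
           weights = c(rep(p0 / 10, 10L), 1 - p0),
           p = p, q = q, p0 = p0, omega_s = ws, t_idx = n_fixed(6L))
    }
    if (!is.null(m7)) {
      p7 <- m7$omega_spec$p; q7 <- m7$omega_spec$q
      k7 <- m7$kappa; sc7 <- m7$omega_spec$scale
    } else {
      p7 <- 0.5; q7 <- 1.5; k7 <- k0; sc7 <- 1
    }
    starts <- list(
      c(log(k7), log(sc7), log(p7), log(q7), 1, log(1), t_par()),   # == M7 optimum
      c(log(k7), log(sc7), log(p7), log(q7), 0.9, log(2), t_par()),
      c(log(2), log(1), log(1), log(1), 0.8, log(3), t_par()))[seq_len(n_starts)]
    lower <- c(log(.KAPPA_BOUNDS[1]), log(.SCALE_BOUNDS[1]),
               rep(log(.BETA_BOUNDS[1]), 2), 1e-6, log(1), t_lower())
    upper <- c(log(.KAPPA_BOUNDS[2]), log(.SCALE_BOUNDS[2]),
               rep(log(.BETA_BOUNDS[2]), 2), 1, log(50), t_upper())
  }

  fn <- mk_eval(classes_fn)
  best <- NULL
  for (s in starts) {
    res <- tryCatch(run(s, lower, upper, fn), error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) .stopf("fit_site_model: all starts failed for %s", model)
  cl <- classes_fn(best$par)
  t <- if (optimize_branches) exp(best$par[cl$t_idx]) else base_t * cl$scale
  ph <- phy; ph$edge.length <- t
  ll <- .codon_loglik(idx, ph, cl$kappa, cl$omegas, cl$weights, pi)
  spec <- switch(model,
    M3 = list(omegas = cl$omegas, weights = cl$weights, scale = cl$scale),
    M7 = list(p = cl$p, q = cl$q, scale = cl$scale),
    M8 = list(p = cl$p, q = cl$q, p0 = cl$p0, omega_s = cl$omega_s,
              scale = cl$scale))
  .mk_fit(model, kappa = cl$kappa, omegas = cl$omegas, weights = cl$weights,
          omega_spec = spec, tree = ph, lnL = ll$lnL, ll = ll, pi = pi,
          converged = best$convergence == 0, note = NA_character_)
}

.mk_fit <- function(model, kappa, omegas, weights, omega_spec, tree, lnL,
                    ll, pi, converged, note) {
  structure(list(model = model, kappa = kappa, omegas = omegas,
                 weights = weights, omega_spec = omega_spec, tree = tree,
                 lnL = lnL, class_site_loglik = ll$class_site_loglik,
                 site_loglik = ll$site_loglik, pi = pi,
                 converged = converged, note = note),
            class = "site_model_fit")
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat(sprintf("<site_model_fit> %s  lnL = %.4f  kappa = %.3f%s\n",
              x$model, x$lnL, x$kappa,
              if (x$model == "M0") sprintf("  omega = %.4f", x$omegas) else ""))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

.mean_pairwise_codon_diff <- function(idx) {
  n <- nrow(idx)
  if (n < 2L) return(0.1)
  tot <- 0; cnt <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(idx[i, ]) & !is.na(idx[j, ])
      if (any(ok)) { tot <- tot + mean(idx[i, ok] != idx[j, ok]); cnt <- cnt + 1 }
    }
  }
  if (cnt == 0) 0.1 else tot / cnt
}

#' Likelihood-ratio test between nested site models
#'
#' Supported pairs: M0 vs M3 (df = 4) and M7 vs M8 (df = 2). The
#' statistic `2 * (lnL_alt - lnL_null)` is compared to the chi-squared
#' upper tail; a slightly negative statistic (optimizer tolerance) is
#' clamped to zero.
#'
#' @param fit_null,fit_alt `site_model_fit` objects (or bare lnL values
#'   together with an explicit `df`).
#' @param df Degrees of freedom; inferred from the model pair when both
#'   fits are `site_model_fit`s.
#' @return List with `stat`, `df`, `p_value`.
#' @export
lrt <- function(fit_null, fit_alt, df = NULL) {
  pairs <- list(M0 = c("M3", 4L), M7 = c("M8", 2L))
  if (inherits(fit_null, "site_model_fit") && inherits(fit_alt, "site_model_fit")) {
    pr <- pairs[[fit_null$model]]
    if (is.null(pr) || pr[1L] != fit_alt$model)
      .stopf("lrt: %s vs %s is not a supported nested pair",
             fit_null$model, fit_alt$model)
    if (is.null(df)) df <- as.integer(pr[2L])
    ln0 <- fit_null$lnL; ln1 <- fit_alt$lnL
  } else {
    if (is.null(df)) .stopf("lrt: df required for bare log-likelihoods")
    ln0 <- fit_null; ln1 <- fit_alt
  }
  stat <- 2 * (ln1 - ln0)
  if (stat < 0) {
    if (stat < -0.1)
      warning(sprintf("LRT statistic %.4f < 0: alternative fit likely not converged", stat),
              call. = FALSE)
    stat <- 0
  }
  list(stat = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Per-site posterior class probabilities (NEB)
#'
#' Naive empirical Bayes: Bayes' rule over the mixture classes at the
#' maximum-likelihood parameter estimates.
#'
#' @param fit A `site_model_fit` for a mixture model.
#' @return Matrix (classes x sites) of posterior probabilities; columns
#'   sum to 1.
#' @export
site_posteriors <- function(fit) {
  stopifnot(inherits(fit, "site_model_fit"))
  lw <- log(fit$weights)
  lp <- fit$class_site_loglik + lw
  post <- exp(sweep(lp, 2L, fit$site_loglik, `-`))
  post[is.na(post)] <- 0
  post
}

#' Sites under positive selection (NEB posterior)
#'
#' Sites whose total posterior probability of belonging to a class with
#' omega > 1 exceeds `cutoff`.
#'
#' @param fit A fitted M8 (or M3) `site_model_fit`.
#' @param cutoff Posterior probability threshold (default 0.95).
#' @return Data frame with `site` (codon column index) and
#'   `prob_positive` for qualifying sites; zero rows when none.
#' @export
positive_sites <- function(fit, cutoff = 0.95) {
  post <- site_posteriors(fit)
  sel <- fit$omegas > 1
  prob <- if (any(sel)) colSums(post[sel, , drop = FALSE]) else
    rep(0, ncol(post))
  hit <- which(prob > cutoff)
  data.frame(site = hit, prob_positive = prob[hit])
}

#' Selection analysis summary table
#'
#' One row per dataset, in the customary layout of codon site-model
#' reports: dN/dS under M0, the two LRT statistics with significance
#' stars (chi-squared, * P < 0.05, ** P < 0.01), the M8 estimates, and
#' the count of NEB positive-selection sites.
#'
#' @param fits Named list; each element a list with components `M0`,
#'   `M3`, `M7`, `M8` (`site_model_fit` objects).
#' @param cutoff Posterior cutoff for positive sites.
#' @return Data frame with columns `dataset`, `omega_M0`,
#'   `lrt_M3_vs_M0`, `stars_M3_vs_M0`, `lrt_M8_vs_M7`, `stars_M8_vs_M7`,
#'   `M8_omega`, `M8_p`, `M8_q`, `n_positive_sites`.
#' @export
selection_report <- function(fits, cutoff = 0.95) {
  if (!length(fits))
    return(data.frame(dataset = character(0), omega_M0 = numeric(0),
                      lrt_M3_vs_M0 = numeric(0), stars_M3_vs_M0 = character(0),
                      lrt_M8_vs_M7 = numeric(0), stars_M8_vs_M7 = character(0),
                      M8_omega = numeric(0), M8_p = numeric(0),
                      M8_q = numeric(0), n_positive_sites = integer(0)))
  stars <- function(p) if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    l1 <- lrt(f$M0, f$M3)
    l2 <- lrt(f$M7, f$M8)
    pos <- positive_sites(f$M8, cutoff)
    data.frame(dataset = nm, omega_M0 = f$M0$omega_spec$omega,
               lrt_M3_vs_M0 = l1$stat, stars_M3_vs_M0 = stars(l1$p_value),
               lrt_M8_vs_M7 = l2$stat, stars_M8_vs_M7 = stars(l2$p_value),
               M8_omega = f$M8$omega_spec$omega_s, M8_p = f$M8$omega_spec$p,
               M8_q = f$M8$omega_spec$q, n_positive_sites = nrow(pos),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
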