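## Maximum-likelihood codon site models (M0, M1a, M2a, M7, M8): a mixture of
## omega classes shared across sites, on a fixed tree topology whose relative
## branch lengths are taken from the input tree (or an internal NJ tree) and
## rescaled by one free multiplier per model. Free parameters are optimized
## on log/logit scales by nlminb, with per-class likelihood memoisation so
## finite-difference gradient steps only recompute the classes they touch.

#' Discretize a beta(p, q) distribution into equal-probability categories
#'
#' Used by models M7 and M8; returns the category medians
#' `qbeta((k - 0.5)/n, p, q)`.
#'
#' @param p,q beta shape parameters (> 0).
#' @param n number of categories (default 10, the conventional choice).
#' @return numeric vector of `n` omega values in (0, 1).
#' @export
discretize_beta <- function(p, q, n = 10L) {
  stopifnot(p > 0, q > 0, n >= 1L)
  stats::qbeta((seq_len(n) - 0.5) / n, p, q)
}

## ---- model parameterizations -------------------------------------------

## Each model maps a transformed parameter vector to (kappa, omegas,
## proportions, nu, extras). Bounded quantities use log / logit transforms.
.model_def <- function(model_id, n_beta = 10L) {
  switch(model_id,
    M0 = list(
      np = 3L,
      init = c(lkappa = log(2), lomega = log(0.3), lnu = 0),
      unpack = function(par) {
        list(
          kappa = exp(par[1L]), omegas = exp(par[2L]),
          props = 1, nu = exp(par[3L])
        )
      }
    ),
    M1a = list(
      np = 4L,
      init = c(lkappa = log(2), qp0 = stats::qlogis(0.7),
               qw0 = stats::qlogis(0.2), lnu = 0),
      unpack = function(par) {
        p0 <- stats::plogis(par[2L])
        list(
          kappa = exp(par[1L]),
          omegas = c(stats::plogis(par[3L]), 1),
          props = c(p0, 1 - p0), nu = exp(par[4L])
        )
      }
    ),
    M2a = list(
      np = 6L,
      init = c(lkappa = log(2), qp0 = stats::qlogis(0.7),
               qp1 = stats::qlogis(0.6), qw0 = stats::qlogis(0.2),
               lwpos = log(2), lnu = 0),
      unpack = function(par) {
        p0 <- stats::plogis(par[2L])
        p1 <- (1 - p0) * stats::plogis(par[3L])
        wpos <- 1 + exp(par[5L])
        list(
          kappa = exp(par[1L]),
          omegas = c(stats::plogis(par[4L]), 1, wpos),
          props = c(p0, p1, 1 - p0 - p1), nu = exp(par[6L]),
          omega_pos = wpos, p_pos = 1 - p0 - p1
        )
      }
    ),
    M7 = list(
      np = 4L,
      init = c(lkappa = log(2), lp = log(0.5), lq = log(1.5), lnu = 0),
      unpack = function(par) {
        p <- exp(par[2L])
        q <- exp(par[3L])
        list(
          kappa = exp(par[1L]),
          omegas = discretize_beta(p, q, n_beta),
          props = rep(1 / n_beta, n_beta), nu = exp(par[4L]),
          beta_p = p, beta_q = q
        )
      }
    ),
    M8 = list(
      np = 6L,
      init = c(lkappa = log(2), qp0 = stats::qlogis(0.9), lp = log(0.5),
               lq = log(1.5), lwpos = log(2), lnu = 0),
      unpack = function(par) {
        p0 <- stats::plogis(par[2L])
        p <- exp(par[3L])
        q <- exp(par[4L])
        wpos <- 1 + exp(par[5L])
        list(
          kappa = exp(par[1L]),
          omegas = c(discretize_beta(p, q, n_beta), wpos),
          props = c(rep(p0 / n_beta, n_beta), 1 - p0), nu = exp(par[6L]),
          beta_p = p, beta_q = q, omega_pos = wpos, p_pos = 1 - p0
        )
      }
    ),
    stop2("unknown model: ", model_id)
  )
}

SITE_MODELS <- c("M0", "M1a", "M2a", "M7", "M8")

## Neighbor-joining tree on codon p-distances (relative branch lengths only;
## the site-model fit rescales them).
nj_codon_tree <- function(alignment) {
  n <- alignment$n
  if (n < 3L) stop2("need >= 3 sequences to build a tree internally")
  d <- matrix(0, n, n, dimnames = list(alignment$ids, alignment$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- mean(alignment$states[i, ] != alignment$states[j, ])
    }
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  tr
}

#' Fit a codon site model by maximum likelihood
#'
#' Fits one of M0, M1a, M2a, M7, M8 to an in-frame codon alignment on a fixed
#' tree. Relative branch lengths come from `tree` (or an internal NJ tree on
#' codon p-distances) and a single global scale is re-estimated for every
#' model; `kappa`, the class proportions and the class omega values (beta
#' shape parameters for M7/M8, the extra omega >= 1 for M2a/M8) are free.
#'
#' @param alignment a [codon_alignment] (gap-free; see
#'   [remove_gapped_columns()]).
#' @param tree ape `phylo` with branch lengths, or `NULL` for an internal NJ
#'   tree.
#' @param model_id one of `"M0"`, `"M1a"`, `"M2a"`, `"M7"`, `"M8"`.
#' @param frequencies `"F3x4"` (default), `"F61"`, or a vector of 61 codon
#'   frequencies.
#' @param options list of optimizer options: `n_extra_starts` (jittered
#'   restarts attempted when the first optimization does not converge or on
#'   request, default 2), `always_restart` (force the extra starts, default
#'   FALSE), `jitter_sd` (default 0.5), `seed` (seeds the jitter, default 1),
#'   `n_beta_classes` (default 10), `init` (named numeric vector of
#'   transformed starting values, advanced), `max_iter` (default 500).
#' @return an object of class `site_model_fit`: `model_id`, `lnL`, `kappa`,
#'   `class_omegas`, `class_proportions`, `beta_p`, `beta_q`, `omega_pos`,
#'   `p_pos`, `np` (free parameter count), `tree_scale` (fitted branch-length
#'   multiplier in expected substitutions per codon under the mixture),
#'   `converged`, plus the tree, frequencies and transformed MLE vector used.
#' @export
fit_site_model <- function(alignment, tree = NULL, model_id = "M2a",
                           frequencies = "F3x4", options = list()) {
  stopifnot(inherits(alignment, "codon_alignment"))
  model_id <- match.arg(model_id, SITE_MODELS)
  opts <- utils::modifyList(
    list(
      n_extra_starts = 2L, always_restart = FALSE, jitter_sd = 0.5,
      seed = 1L, n_beta_classes = 10L, init = NULL, max_iter = 500L
    ),
    options
  )
  def <- .model_def(model_id, opts$n_beta_classes)
  pi <- resolve_frequencies(frequencies, alignment)
  if (is.null(tree)) tree <- nj_codon_tree(alignment)
  ts <- tree_struct(tree, alignment$ids)
  pat <- compress_patterns(alignment$states)
  w <- pat$weights

  cache <- new.env(parent = emptyenv())
  nll <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 30)) return(1e10)
    m <- def$unpack(par)
    if ((cache$.n_entries %||% 0L) > 1500L) {
      rm(list = ls(cache), envir = cache)
      cache$.n_entries <- 0L
    }
    ll <- class_site_logliks(pat, ts, pi, m$kappa, m$omegas, m$nu, cache)
    val <- -sum(w * row_logsumexp(ll, log(m$props + 1e-300)))
    if (!is.finite(val)) 1e10 else val
  }

  run <- function(par0) {
    stats::nlminb(par0, nll,
      control = list(iter.max = opts$max_iter, eval.max = 4L * opts$max_iter,
                     rel.tol = 1e-10)
    )
  }

  par0 <- def$init
  if (!is.null(opts$init)) par0[names(opts$init)] <- opts$init
  best <- run(par0)
  tries <- 1L
  if (opts$always_restart || best$convergence != 0 || best$objective >= 1e10) {
    starts <- with_seed(opts$seed, replicate(
      opts$n_extra_starts,
      par0 + stats::rnorm(length(par0), sd = opts$jitter_sd),
      simplify = FALSE
    ))
    for (s in starts) {
      cand <- run(s)
      tries <- tries + 1L
      if (cand$objective < best$objective) best <- cand
    }
  }

  m <- def$unpack(best$par)
  m <- lapply(m, unname)
  mean_rate <- sum(
    m$props * vapply(m$omegas, codon_mean_rate, numeric(1), kappa = m$kappa, pi = pi)
  )
  structure(
    list(
      model_id = model_id, lnL = -best$objective, kappa = m$kappa,
      class_omegas = m$omegas, class_proportions = m$props,
      beta_p = m$beta_p %||% NA_real_, beta_q = m$beta_q %||% NA_real_,
      omega_pos = m$omega_pos %||% NA_real_, p_pos = m$p_pos %||% NA_real_,
      np = def$np, nu = m$nu, tree_scale = m$nu * mean_rate,
      converged = best$convergence == 0, n_starts = tries,
      message = best$message, par = best$par,
      tree = tree, frequencies = pi, n = alignment$n, c = alignment$c,
      n_beta_classes = opts$n_beta_classes
    ),
    class = "site_model_fit"
  )
}

#' @export
print.site_model_fit <- function(x, digits = 4, ...) {
  cat("Codon site model ", x$model_id, " (n = ", x$n, ", c = ", x$c, ")\n",
    sep = ""
  )
  cat("  lnL =", format(x$lnL, digits = 10), " kappa =", round(x$kappa, digits),
      " tree scale =", round(x$tree_scale, digits), "\n")
  cat("  omega:", paste(round(x$class_omegas, digits), collapse = " "), "\n")
  cat("  prop: ", paste(round(x$class_proportions, digits), collapse = " "), "\n")
  if (!is.na(x$beta_p)) {
    cat("  beta(p, q) = (", round(x$beta_p, digits), ",",
        round(x$beta_q, digits), ")\n")
  }
  if (!is.na(x$omega_pos)) {
    cat("  omega_pos =", round(x$omega_pos, digits),
        " p_pos =", round(x$p_pos, digits), "\n")
  }
  if (!x$converged) cat("  [warning] optimizer did not report convergence\n")
  invisible(x)
}

## nested (null, alt) pairs accepted by lrt()
.nested_pairs <- list(
  c("M0", "M1a"), c("M1a", "M2a"), c("M7", "M8"), c("M0", "M2a")
)

#' Likelihood-ratio test between nested codon site models
#'
#' Twice the log-likelihood difference is compared to a chi-square
#' distribution with degrees of freedom equal to the difference in free
#' parameters (2 for M1a vs M2a and M7 vs M8). Small negative values of
#' 2\eqn{\Delta}lnL (optimizer noise) are clipped to 0 with a warning.
#'
#' @param null_fit,alt_fit `site_model_fit` objects for a nested pair
#'   (M0 in M1a, M1a in M2a, M7 in M8, M0 in M2a).
#' @return an object of class `lrt_result`: `null_model`, `alt_model`,
#'   `two_delta_lnl`, `df`, `p_value`.
#' @export
lrt <- function(null_fit, alt_fit) {
  stopifnot(inherits(null_fit, "site_model_fit"), inherits(alt_fit, "site_model_fit"))
  pair <- c(null_fit$model_id, alt_fit$model_id)
  ok <- any(vapply(.nested_pairs, identical, logical(1), y = pair))
  if (!ok) stop2("models not nested (in this order): ", pair[1], " vs ", pair[2])
  two_d <- 2 * (alt_fit$lnL - null_fit$lnL)
  if (two_d < 0) {
    warning(sprintf("negative 2*delta-lnL (%.3g) clipped to 0", two_d))
    two_d <- 0
  }
  df <- alt_fit$np - null_fit$np
  structure(
    list(
      null_model = pair[1], alt_model = pair[2],
      two_delta_lnl = two_d, df = df,
      p_value = stats::pchisq(two_d, df, lower.tail = FALSE)
    ),
    class = "lrt_result"
  )
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf(
    "LRT %s vs %s: 2*delta-lnL = %.4f, df = %d, p = %.4g\n",
    x$null_model, x$alt_model, x$two_delta_lnl, x$df, x$p_value
  ))
  invisible(x)
}

#' Posterior identification of positively selected sites
#'
#' For a fitted M2a or M8 model, computes per-site posterior probabilities of
#' the positively selected class. `method = "NEB"` evaluates the posterior at
#' the maximum-likelihood estimates; `method = "BEB"` (Bayes empirical Bayes)
#' integrates over a discrete grid prior on the mixture weights and the
#' positive-class omega (10 points per dimension; for M2a the triangular
#' (p0, p1) grid with omega0 on (0,1) and omega+ on (1,11); for M8 a grid on
#' (p0, omega+) with the beta shape fixed at its MLE), with kappa and branch
#' lengths fixed at their MLEs. Sites with posterior > 0.95 are flagged
#' significant.
#'
#' @param fit a `site_model_fit` for M2a or M8.
#' @param alignment the [codon_alignment] the model was fitted to.
#' @param tree the tree used for the fit; defaults to the tree stored in the
#'   fit.
#' @param method `"BEB"` (default for M2a) or `"NEB"` (default for M8).
#' @return a data.frame with columns `site` (1-based codon index),
#'   `posterior`, `mean_omega`, `method`, `significant`.
#' @export
site_posteriors <- function(fit, alignment, tree = NULL, method = NULL) {
  stopifnot(inherits(fit, "site_model_fit"), inherits(alignment, "codon_alignment"))
  if (!fit$model_id %in% c("M2a", "M8")) {
    stop2("site posteriors require an M2a or M8 fit, got ", fit$model_id)
  }
  method <- method %||% (if (fit$model_id == "M2a") "BEB" else "NEB")
  method <- match.arg(method, c("NEB", "BEB"))
  tree <- tree %||% fit$tree
  pi <- fit$frequencies
  ts <- tree_struct(tree, alignment$ids)
  pat <- compress_patterns(alignment$states)
  cache <- new.env(parent = emptyenv())

  if (method == "NEB") {
    ll <- class_site_logliks(pat, ts, pi, fit$kappa, fit$class_omegas, fit$nu, cache)
    # log(0) = -Inf is deliberate: a zero-weight class gets exactly zero posterior
    lw <- sweep(ll, 2L, log(fit$class_proportions), "+")
    tot <- apply(lw, 1L, logsumexp)
    post <- exp(lw - tot)
    kpos <- length(fit$class_omegas) # positive class is last for M2a/M8
    p_pos <- post[, kpos]
    mean_om <- as.vector(post %*% fit$class_omegas)
  } else {
    res <- .beb_posteriors(fit, pat, ts, pi, cache)
    p_pos <- res$p_pos
    mean_om <- res$mean_omega
  }
  idx <- pat$index
  data.frame(
    site = seq_len(alignment$c),
    posterior = p_pos[idx],
    mean_omega = mean_om[idx],
    method = method,
    significant = p_pos[idx] > 0.95
  )
}

## Bayes empirical Bayes over the discrete grid prior. Distinct omega values
## are pruned once; the grid loop then works on per-pattern vectors.
.beb_posteriors <- function(fit, pat, ts, pi, cache) {
  gp <- (2 * (1:10) - 1) / 20 # 0.05 .. 0.95
  wpos_grid <- 1 + (2 * (1:10) - 1) / 2 # 1.5 .. 10.5

  if (fit$model_id == "M2a") {
    w0_grid <- gp
    pgrid <- expand.grid(p0 = gp, p1 = gp)
    pgrid <- pgrid[pgrid$p0 + pgrid$p1 <= 1, ]
    omegas <- c(w0_grid, 1, wpos_grid)
    ll <- class_site_logliks(pat, ts, pi, fit$kappa, omegas, fit$nu, cache)
    ll_w0 <- ll[, 1:10, drop = FALSE]
    ll_1 <- ll[, 11L]
    ll_wp <- ll[, 12:21, drop = FALSE]
    configs <- expand.grid(
      ip = seq_len(nrow(pgrid)), i0 = 1:10, ipos = 1:10
    )
    mix <- function(k) {
      p0 <- pgrid$p0[configs$ip[k]]
      p1 <- pgrid$p1[configs$ip[k]]
      p2 <- max(1 - p0 - p1, 0) # guard the p0 + p1 = 1 edge of the triangle
      l1 <- log(p0) + ll_w0[, configs$i0[k]]
      l2 <- log(p1) + ll_1
      l3 <- log(p2 + 1e-300) + ll_wp[, configs$ipos[k]]
      m <- pmax(l1, l2, l3)
      lsite <- m + log(exp(l1 - m) + exp(l2 - m) + exp(l3 - m))
      list(lsite = lsite, lpos = l3, wpos = wpos_grid[configs$ipos[k]])
    }
  } else { # M8: beta(p, q) fixed at MLE, grid on (p0, omega_pos)
    beta_om <- discretize_beta(fit$beta_p, fit$beta_q, fit$n_beta_classes)
    omegas <- c(beta_om, wpos_grid)
    ll <- class_site_logliks(pat, ts, pi, fit$kappa, omegas, fit$nu, cache)
    nb <- fit$n_beta_classes
    ll_beta <- ll[, seq_len(nb), drop = FALSE]
    ll_wp <- ll[, nb + (1:10), drop = FALSE]
    # per-site log-likelihood of the beta component (equal class weights)
    lbeta <- apply(ll_beta, 1L, logsumexp) - log(nb)
    configs <- expand.grid(ip = 1:10, ipos = 1:10)
    mix <- function(k) {
      p0 <- gp[configs$ip[k]]
      l1 <- log(p0) + lbeta
      l3 <- log(1 - p0) + ll_wp[, configs$ipos[k]]
      m <- pmax(l1, l3)
      lsite <- m + log(exp(l1 - m) + exp(l3 - m))
      list(lsite = lsite, lpos = l3, wpos = wpos_grid[configs$ipos[k]])
    }
  }

  ng <- nrow(configs)
  w <- pat$weights
  lmarg <- numeric(ng)
  parts <- vector("list", ng)
  for (k in seq_len(ng)) {
    parts[[k]] <- mix(k)
    lmarg[k] <- sum(w * parts[[k]]$lsite)
  }
  post_g <- exp(lmarg - logsumexp(lmarg))
  S <- length(parts[[1L]]$lsite)
  p_pos <- numeric(S)
  mean_om <- numeric(S)
  for (k in seq_len(ng)) {
    if (post_g[k] < 1e-12) next
    pk <- exp(parts[[k]]$lpos - parts[[k]]$lsite)
    p_pos <- p_pos + post_g[k] * pk
    # mean omega: positive class at its grid omega, remainder approximated by
    # the fit's non-positive class mean
    bg <- sum(utils::head(fit$class_proportions, -1) *
                utils::head(fit$class_omegas, -1)) /
      sum(utils::head(fit$class_proportions, -1))
    mean_om <- mean_om + post_g[k] * (pk * parts[[k]]$wpos + (1 - pk) * bg)
  }
  list(p_pos = p_pos, mean_omega = mean_om)
}
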