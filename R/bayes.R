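# Dirichlet measurement likelihood and adaptive-Metropolis posterior
# sampling of fluxes over the permissible space.

#' Variance of a Dirichlet-distributed abundance
#'
#' For a compositional measurement with precision parameter `NC` ("number of
#' counts"), the element with abundance `Mi` has variance
#' `Mi (1 - Mi) / (NC + 1)`.
#'
#' @param mi abundance in `[0, 1]`.
#' @param nc positive precision parameter.
#' @return the variance.
#' @export
dirichlet_variance <- function(mi, nc) {
  stopifnot(all(mi >= 0), all(mi <= 1), all(nc > 0))
  mi * (1 - mi) / (nc + 1)
}

# Dirichlet log-density of x under concentration a
ddirichlet_log <- function(x, a) {
  lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * log(x))
}

floor_renorm <- function(x, eps) {
  x <- pmax(x, eps)
  x / sum(x)
}

#' Dirichlet log-likelihood of a measured CMD
#'
#' Probability that a measured carbon mass distribution is explained by a
#' model-predicted one: the measured vector is scored under a Dirichlet
#' distribution with concentration `nc * predicted`.  Zero-abundance
#' categories are floored at `eps` and renormalized (the Dirichlet density
#' is undefined at exact zeros).
#'
#' @param measured,predicted CMD vectors of equal length.
#' @param nc precision parameter of the fragment.
#' @param eps zero-category floor.
#' @return scalar log-likelihood.
#' @export
mfa_loglik <- function(measured, predicted, nc, eps = 1e-6) {
  if (length(measured) != length(predicted))
    stop("measured and predicted CMDs must have equal length")
  ddirichlet_log(floor_renorm(measured, eps),
                 nc * floor_renorm(predicted, eps))
}

# Dirichlet sampler (gamma representation)
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  x / rowSums(x)
}

#' Sampler configuration for [mfa_fit()]
#'
#' @param chains number of MCMC chains (>= 2 for convergence diagnostics).
#' @param warmup adaptation iterations discarded per chain.
#' @param iter retained iterations per chain.
#' @param seed master seed; per-chain seeds are derived deterministically.
#' @param sampler `"ensemble"` (affine-invariant stretch-move ensemble, the
#'   default; robust for the diffuse posteriors of sparse fragment panels)
#'   or `"am"` (adaptive random-walk Metropolis with prior-refresh moves, a
#'   cheaper alternative for well-identified fits).  For the ensemble,
#'   `warmup` and `iter` count ensemble sweeps and every walker contributes
#'   draws.
#' @param walkers ensemble size (default `2 * npar + 4`).
#' @param exchange_bounds range of the exchange fluxes (log-uniform prior).
#' @param box_net,box_input bounding box of the independent net and input
#'   fluxes (uniform prior over the feasible part).
#' @param eps zero-category floor of the Dirichlet likelihood.
#' @param init_exchange starting value of the exchange fluxes.
#' @param init_tries number of feasible draws screened for the
#'   posterior-mode search that initializes the chains.
#' @param init_optim iteration budget of the mode-polishing optimizer.
#' @return list of class `mfa_config`.
#' @export
mfa_config <- function(chains = 2, warmup = 1000, iter = 1000, seed = 1,
                       sampler = c("ensemble", "am"), walkers = NULL,
                       exchange_bounds = c(1e-2, 5000),
                       box_net = c(-300, 300), box_input = c(0, 100),
                       eps = 1e-6, init_exchange = 10, init_tries = 100,
                       init_optim = 200) {
  stopifnot(chains >= 1, warmup >= 10, iter >= 1,
            exchange_bounds[1] > 0, diff(exchange_bounds) > 0)
  structure(list(chains = chains, warmup = warmup, iter = iter, seed = seed,
                 sampler = match.arg(sampler), walkers = walkers,
                 exchange_bounds = exchange_bounds, box_net = box_net,
                 box_input = box_input, eps = eps,
                 init_exchange = init_exchange, init_tries = init_tries,
                 init_optim = init_optim),
            class = "mfa_config")
}

# fragment table induced by the measurement rows themselves
fragments_from_data <- function(data) {
  u <- unique(data[, c("metabolite", "carbon_first", "carbon_last")])
  rownames(u) <- NULL
  u
}

#' Fit fluxes to labeling measurements by MCMC
#'
#' Samples the posterior of the independent net fluxes (uniform prior over
#' the permissible polytope) and the exchange fluxes (log-uniform prior)
#' under the Dirichlet likelihood of the measured CMDs, with model CMDs
#' computed by the EMU cascade across all tracers jointly.  Sampling is
#' performed in a reparameterized space (logit transforms of the box for
#' net fluxes, with infeasible proposals rejected, and log transforms for
#' exchanges) by an affine-invariant stretch-move ensemble or an adaptive
#' random-walk Metropolis, both initialized at the posterior mode found by
#' a screened quasi-Newton search.
#'
#' @param data long-format measurement table (see [read_measurements()]);
#'   one sample, one or more tracers and fragments.
#' @param model a [ppp_network()] model.
#' @param tracers named list of tracer mixtures covering the `tracer_id`
#'   values in `data`.
#' @param config a [mfa_config()].
#' @param p5p_weights see [simulate_cmds()].
#' @return object of class `mfa_fit` with per-chain draws of all net fluxes,
#'   exchange fluxes and the triose condensation flux `QR`, plus split-Rhat,
#'   effective sample size and acceptance diagnostics.
#' @export
mfa_fit <- function(data, model = ppp_network(),
                    tracers = default_tracer_panel(),
                    config = mfa_config(), p5p_weights = "flux") {
  blocks <- measurement_blocks(data)
  used <- unique(vapply(blocks, `[[`, "", "tracer_id"))
  missing <- setdiff(used, names(tracers))
  if (length(missing))
    stop("no tracer definition for tracer_id(s): ",
         paste(missing, collapse = ", "))
  tr <- tracers[used]
  fragments <- fragments_from_data(data)
  system <- emu_decompose(model, fragments)
  dep <- split_dependency(model)
  space <- permissible_space(model, box_net = config$box_net,
                             box_input = config$box_input)

  free <- space$free                      # independent fluxes except Z1
  exch <- model$rev_names
  lo <- space$box["lower", ]; hi <- space$box["upper", ]
  elo <- log(config$exchange_bounds[1]); ehi <- log(config$exchange_bounds[2])
  npar <- length(free) + length(exch)
  ifree <- seq_along(free); iex <- length(free) + seq_along(exch)
  nonneg <- intersect(NONNEG_DEPENDENT, dep$dependent)
  Mrow <- dep$M
  z1 <- model$z1
  ind_order <- dep$independent
  ext_cache <- make_ext_dists(system, tr)

  # blocks indexed for the likelihood loop
  b_tr <- match(vapply(blocks, `[[`, "", "tracer_id"), names(tr))
  b_fr <- vapply(blocks, `[[`, "", "fragment")
  b_cmd <- lapply(blocks, function(b) floor_renorm(b$cmd, config$eps))
  b_nc <- vapply(blocks, `[[`, 0, "nc")

  rev_syms <- vapply(model$reactions[exch], `[[`, "", "flux")
  irr <- setdiff(names(model$reactions), exch)
  irr_syms <- vapply(model$reactions[irr], `[[`, "", "flux")

  uni_from <- function(net, ex) {
    v <- net[rev_syms]
    uni <- c(stats::setNames(c(pmax(v, 0) + ex, pmax(-v, 0) + ex),
                             c(paste0(exch, ".f"), paste0(exch, ".b"))),
             stats::setNames(net[irr_syms], irr),
             stats::setNames(net[model$active_inputs], model$active_inputs))
    uni
  }

  logpost <- function(theta) {
    pf <- stats::plogis(theta[ifree])
    x <- lo + (hi - lo) * pf
    phi <- theta[iex]
    if (any(phi < elo) || any(phi > ehi)) return(-Inf)
    vind <- c(Z1 = z1, x)[ind_order]
    vdep <- drop(Mrow %*% vind)
    names(vdep) <- dep$dependent
    if (any(vdep[nonneg] < 0)) return(-Inf)
    net <- c(vind, vdep)
    ex <- stats::setNames(exp(phi), exch)
    uni <- uni_from(net, ex)
    pred <- tryCatch(
      sim_targets(system, uni, tr, p5p_weights, ext_cache),
      error = function(e) NULL)
    if (is.null(pred)) return(-Inf)
    ll <- 0
    for (i in seq_along(blocks)) {
      p <- floor_renorm(pred[[b_tr[i]]][[b_fr[i]]], config$eps)
      ll <- ll + ddirichlet_log(b_cmd[[i]], b_nc[i] * p)
    }
    # Jacobian of the logit reparameterization (uniform prior on x)
    ll + sum(log(pf) + log1p(-pf))
  }

  # posterior-mode search shared by all chains: screen feasible draws,
  # polish by Nelder-Mead, and take the local curvature as the initial
  # proposal covariance
  find_mode <- function() {
    set.seed(config$seed)
    starts <- sample_feasible(model, config$init_tries, space = space)
    best <- NULL; best_lp <- -Inf
    for (st0 in starts) {
      th <- c(stats::qlogis(pmin(pmax((st0$net[free] - lo) / (hi - lo),
                                      1e-6), 1 - 1e-6)),
              rep(log(config$init_exchange), length(exch)))
      l <- logpost(th)
      if (is.finite(l) && l > best_lp) { best <- th; best_lp <- l }
    }
    if (!is.finite(best_lp))
      stop("could not find a feasible starting point")
    f <- function(th) {
      l <- logpost(th)
      if (is.finite(l)) -l else 1e12
    }
    opt <- tryCatch(
      stats::optim(best, f, method = "BFGS",
                   control = list(maxit = config$init_optim,
                                  reltol = 1e-9)),
      error = function(e)
        stats::optim(best, f, method = "Nelder-Mead",
                     control = list(maxit = 20 * config$init_optim,
                                    reltol = 1e-10)))
    C0 <- tryCatch({
      H <- stats::optimHess(opt$par, f)
      V <- solve(H)
      ev <- eigen(V, symmetric = TRUE)
      if (any(ev$values <= 0)) stop("not positive definite")
      V
    }, error = function(e) diag(0.01, npar))
    list(theta = opt$par, C = C0)
  }
  mode <- find_mode()

  run_chain <- function(chain) {
    set.seed(config$seed * 1000L + chain)
    theta <- drop(mode$theta +
                    t(chol(mode$C + diag(1e-10, npar))) %*%
                      stats::rnorm(npar, 0, 0.5))
    names(theta) <- names(mode$theta)
    lp <- logpost(theta)
    for (try in 1:20) {           # jitter may have left the feasible set
      if (is.finite(lp)) break
      theta <- drop(mode$theta +
                      t(chol(mode$C + diag(1e-10, npar))) %*%
                        stats::rnorm(npar, 0, 0.1))
      names(theta) <- names(mode$theta)
      lp <- logpost(theta)
    }
    if (!is.finite(lp)) { theta <- mode$theta; lp <- logpost(theta) }
    if (!is.finite(lp)) stop("could not initialize chain ", chain)
    total <- config$warmup + config$iter
    draws <- matrix(NA_real_, config$iter, npar)
    lps <- numeric(config$iter)
    # block-wise random walk: separate proposal scales for the net-flux
    # and exchange blocks, covariances adapted during warmup
    nf <- length(ifree); ne <- length(iex)
    scale_f <- 2.38; scale_e <- 2.38; scale_j <- 2.38
    C <- mode$C
    mu <- theta; Ssum <- diag(1e-4, npar); nadapt <- 1
    acc <- 0L
    rw_try <- c(f = 0L, e = 0L, j = 0L)
    rw_acc <- c(f = 0L, e = 0L, j = 0L)
    Lf <- Le <- Lj <- NULL
    for (it in seq_len(total)) {
      if (it %% 25 == 1 || is.null(Lf)) {
        Lf <- t(chol(scale_f^2 / nf *
                       (C[ifree, ifree, drop = FALSE] + diag(1e-8, nf))))
        Le <- t(chol(scale_e^2 / ne *
                       (C[iex, iex, drop = FALSE] + diag(1e-8, ne))))
        Lj <- t(chol(scale_j^2 / npar * (C + diag(1e-8, npar))))
      }
      # kernel mixture: random-walk moves plus prior-refresh independence
      # moves, which mix directions the data leave flat (e.g. exchanges
      # under sparse fragment panels)
      kind <- stats::runif(1)
      lqdiff <- 0
      if (kind < 0.05) {
        # refresh the net-flux block uniformly over the polytope; the
        # proposal equals the prior, so only the likelihood ratio remains
        prop <- theta
        for (try in 1:500) {
          xn <- stats::runif(length(free), lo, hi)
          vin <- c(Z1 = z1, stats::setNames(xn, free))[ind_order]
          if (all(space$A %*% vin >= 0)) break
        }
        pn <- pmin(pmax((xn - lo) / (hi - lo), 1e-12), 1 - 1e-12)
        prop[ifree] <- stats::qlogis(pn)
        jac <- function(th) sum(stats::plogis(th, log.p = TRUE) +
                                  stats::plogis(-th, log.p = TRUE))
        lqdiff <- jac(prop[ifree]) - jac(theta[ifree])
      } else if (kind < 0.15) {
        prop <- theta
        prop[iex] <- stats::runif(length(iex), elo, ehi)
      } else if (kind < 0.25) {
        j <- sample.int(npar, 1)
        prop <- theta
        if (j %in% iex) {
          prop[j] <- stats::runif(1, elo, ehi)
        } else {
          # draw from the coordinate's prior (standard logistic in the
          # transformed space); the density difference cancels the prior
          prop[j] <- stats::rlogis(1)
          lqdiff <- stats::dlogis(prop[j], log = TRUE) -
            stats::dlogis(theta[j], log = TRUE)
        }
      } else if (kind < 0.45) {
        # joint random walk over all parameters
        prop <- theta + drop(Lj %*% stats::rnorm(npar))
        rw_try["j"] <- rw_try["j"] + 1L
      } else if (kind < 0.75) {
        prop <- theta
        prop[ifree] <- theta[ifree] + drop(Lf %*% stats::rnorm(nf))
        rw_try["f"] <- rw_try["f"] + 1L
      } else {
        prop <- theta
        prop[iex] <- theta[iex] + drop(Le %*% stats::rnorm(ne))
        rw_try["e"] <- rw_try["e"] + 1L
      }
      lpp <- logpost(prop)
      if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp - lqdiff) {
        theta <- prop; lp <- lpp
        acc <- acc + 1L
        if (kind >= 0.25 && kind < 0.45) rw_acc["j"] <- rw_acc["j"] + 1L
        if (kind >= 0.45 && kind < 0.75) rw_acc["f"] <- rw_acc["f"] + 1L
        if (kind >= 0.75) rw_acc["e"] <- rw_acc["e"] + 1L
      }
      if (it <= config$warmup) {
        # Haario-style covariance adaptation plus acceptance tuning
        nadapt <- nadapt + 1
        dlt <- theta - mu
        mu <- mu + dlt / nadapt
        Ssum <- Ssum + tcrossprod(dlt, theta - mu)
        if (it %% 50 == 0) {
          if (rw_try["f"] > 0)
            scale_f <- scale_f * exp(0.5 * (rw_acc["f"] / rw_try["f"] - 0.3))
          if (rw_try["e"] > 0)
            scale_e <- scale_e * exp(0.5 * (rw_acc["e"] / rw_try["e"] - 0.3))
          if (rw_try["j"] > 0)
            scale_j <- scale_j * exp(0.5 * (rw_acc["j"] / rw_try["j"] - 0.25))
          rw_try[] <- 0L; rw_acc[] <- 0L
          if (it >= 200) C <- Ssum / (nadapt - 1)
        }
      } else {
        draws[it - config$warmup, ] <- theta
        lps[it - config$warmup] <- lp
      }
    }
    natural <- cbind(
      sweep(sweep(stats::plogis(draws[, ifree, drop = FALSE]), 2, hi - lo,
                  `*`), 2, lo, `+`),
      exp(draws[, iex, drop = FALSE]))
    colnames(natural) <- c(free, paste0("ex.", exch))
    list(params = natural, lp = lps, accept = acc / total)
  }

  # affine-invariant stretch-move ensemble (one ensemble per "chain"),
  # initialized around the posterior mode; exchange-block prior refreshes
  # are mixed in to traverse data-flat directions
  run_ensemble <- function(chain) {
    set.seed(config$seed * 1000L + chain)
    K <- config$walkers
    if (is.null(K)) K <- 2L * npar + 4L
    W <- matrix(NA_real_, K, npar)
    lps <- numeric(K)
    for (k in seq_len(K)) {
      for (try in 1:50) {
        W[k, ] <- mode$theta +
          drop(t(chol(mode$C + diag(1e-10, npar))) %*%
                 stats::rnorm(npar, 0, 0.5))
        lps[k] <- logpost(W[k, ])
        if (is.finite(lps[k])) break
      }
      if (!is.finite(lps[k])) { W[k, ] <- mode$theta; lps[k] <- mode_lp }
    }
    a <- 2
    total <- config$warmup + config$iter
    draws <- matrix(NA_real_, config$iter * K, npar)
    lpout <- numeric(config$iter * K)
    acc <- 0L; ntry <- 0L
    for (sweep in seq_len(total)) {
      for (k in seq_len(K)) {
        ntry <- ntry + 1L
        if (stats::runif(1) < 0.1) {          # prior refresh, flat dims
          prop <- W[k, ]
          prop[iex] <- stats::runif(length(iex), elo, ehi)
          lpp <- logpost(prop)
          if (is.finite(lpp) && log(stats::runif(1)) < lpp - lps[k]) {
            W[k, ] <- prop; lps[k] <- lpp; acc <- acc + 1L
          }
        } else {                               # stretch move
          j <- sample.int(K - 1L, 1L); if (j >= k) j <- j + 1L
          z <- (stats::runif(1) * (sqrt(a) - 1 / sqrt(a)) + 1 / sqrt(a))^2
          prop <- W[j, ] + z * (W[k, ] - W[j, ])
          lpp <- logpost(prop)
          if (is.finite(lpp) &&
              log(stats::runif(1)) < (npar - 1) * log(z) + lpp - lps[k]) {
            W[k, ] <- prop; lps[k] <- lpp; acc <- acc + 1L
          }
        }
      }
      if (sweep > config$warmup) {
        rows <- (sweep - config$warmup - 1L) * K + seq_len(K)
        draws[rows, ] <- W
        lpout[rows] <- lps
      }
    }
    natural <- cbind(
      sweep(sweep(stats::plogis(draws[, ifree, drop = FALSE]), 2, hi - lo,
                  `*`), 2, lo, `+`),
      exp(draws[, iex, drop = FALSE]))
    colnames(natural) <- c(free, paste0("ex.", exch))
    list(params = natural, lp = lpout, accept = acc / ntry)
  }
  mode_lp <- logpost(mode$theta)

  runner <- if (config$sampler == "ensemble") run_ensemble else run_chain
  chains <- lapply(seq_len(config$chains), runner)

  # expand each draw to the full flux set: nets, unidirectional pairs
  # (the backward triose condensation is reported as QR) and exchanges
  expand <- function(par) {
    xind <- cbind(Z1 = z1, par[, free, drop = FALSE])[, ind_order,
                                                      drop = FALSE]
    vdep <- xind %*% t(Mrow)
    nets <- cbind(xind, vdep)
    uni <- matrix(NA_real_, nrow(par), 2 * length(exch))
    unames <- character(2 * length(exch))
    for (i in seq_along(exch)) {
      v <- nets[, rev_syms[i]]
      e <- par[, paste0("ex.", exch[i])]
      uni[, 2 * i - 1] <- pmax(v, 0) + e
      uni[, 2 * i] <- pmax(-v, 0) + e
      unames[2 * i - 1] <- paste0(exch[i], ".f")
      unames[2 * i] <- if (exch[i] == "Q2") "QR" else paste0(exch[i], ".b")
    }
    colnames(uni) <- unames
    cbind(nets, uni, par[, paste0("ex.", exch), drop = FALSE])
  }
  flux_chains <- lapply(chains, function(ch) expand(ch$params))
  fluxes <- colnames(flux_chains[[1]])
  rhat <- vapply(fluxes, function(f)
    split_rhat(lapply(flux_chains, function(m) m[, f])), 0)
  ess <- vapply(fluxes, function(f)
    ess_acf(lapply(flux_chains, function(m) m[, f])), 0)
  fit <- structure(
    list(flux_chains = flux_chains,
         flux_draws = do.call(rbind, flux_chains),
         lp = lapply(chains, `[[`, "lp"),
         accept = vapply(chains, `[[`, 0, "accept"),
         rhat = rhat, ess = ess,
         model = model, config = config, data = data,
         tracers = tr, free = free, exch = exch),
    class = "mfa_fit")
  bad <- fluxes[is.finite(rhat) & rhat > 1.1]
  if (length(bad))
    warning("split-Rhat > 1.1 for: ", paste(bad, collapse = ", "),
            "; chains may not have converged")
  fit
}

# internal: target CMDs from a uni flux vector (shared with simulate_cmds)
sim_targets <- function(system, uni, tracers, p5p_weights, ext_cache) {
  dists <- solve_emu_dists(system, uni, tracers, ext_cache)
  p5w <- if (identical(p5p_weights, "flux")) {
    p5p_flux_weights(uni, system$consumption)
  } else p5p_weights[c("XuP", "R5P")] / sum(p5p_weights[c("XuP", "R5P")])
  idx_of <- system$plan$idx_of
  lapply(seq_along(tracers), function(ti) {
    res <- lapply(system$targets, function(tg) {
      cmd <- 0
      for (part in tg$parts) {
        w <- if (identical(part$w, "flux")) p5w[[part$pool]] else part$w
        d <- if (is_external(part$pool))
          input_emu_dist(tracers[[ti]], part$pool, part$pos)
        else dists[[ti]][[idx_of[[emu_id(part$pool, part$pos)]]]]
        cmd <- cmd + w * d
      }
      cmd / sum(cmd)
    })
    names(res) <- names(system$targets)
    res
  })
}

split_rhat <- function(chains) {
  halves <- list()
  for (x in chains) {
    n <- length(x) %/% 2
    halves <- c(halves, list(x[1:n], x[(n + 1):(2 * n)]))
  }
  n <- length(halves[[1]])
  mns <- vapply(halves, mean, 0)
  vrs <- vapply(halves, stats::var, 0)
  W <- mean(vrs)
  B <- n * stats::var(mns)
  if (W <= 1e-300) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_acf <- function(chains, max_lag = 200) {
  n <- min(lengths(chains))
  m <- length(chains)
  lag_max <- min(max_lag, n - 2)
  rho <- rowMeans(vapply(chains, function(x) {
    a <- stats::acf(x[1:n], lag.max = lag_max, plot = FALSE,
                    demean = TRUE)$acf[-1]
    as.numeric(a)
  }, numeric(lag_max)))
  s <- 0
  for (t in seq(1, lag_max - 1, by = 2)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
  }
  max(m * n / (1 + 2 * s), 1)
}

#' @export
print.mfa_fit <- function(x, ...) {
  cat(sprintf("MFA posterior fit: %d chain(s) x %d draws, %d fragments\n",
              length(x$flux_chains), nrow(x$flux_chains[[1]]),
              length(unique(interaction(x$data$metabolite,
                                        x$data$carbon_first)))))
  cat(sprintf("  acceptance: %s\n",
              paste(sprintf("%.2f", x$accept), collapse = " ")))
  cat(sprintf("  max split-Rhat: %.3f (min ESS %.0f)\n",
              max(x$rhat, na.rm = TRUE), min(x$ess, na.rm = TRUE)))
  cat("Posterior means:\n")
  print(round(stats::coef(x), 3))
  invisible(x)
}

#' @export
coef.mfa_fit <- function(object, ...) colMeans(object$flux_draws)

#' Posterior summaries of all fluxes
#'
#' Means, medians, standard deviations and central 68%/95% intervals per
#' flux, computed on the draws (dependent fluxes are summarized from
#' transformed draws, not transforms of summaries).
#'
#' @param object an `mfa_fit`.
#' @param ... unused.
#' @return data frame of class `summary.mfa_fit`.
#' @export
summary.mfa_fit <- function(object, ...) {
  d <- object$flux_draws
  q <- t(apply(d, 2, stats::quantile,
               probs = c(0.16, 0.84, 0.025, 0.975), names = FALSE))
  out <- data.frame(flux = colnames(d), mean = colMeans(d),
                    median = apply(d, 2, stats::median),
                    sd = apply(d, 2, stats::sd),
                    ci68_low = q[, 1], ci68_high = q[, 2],
                    ci2.5 = q[, 3], ci97.5 = q[, 4],
                    rhat = object$rhat[colnames(d)],
                    ess = object$ess[colnames(d)],
                    row.names = NULL)
  class(out) <- c("summary.mfa_fit", "data.frame")
  out
}

#' @export
print.summary.mfa_fit <- function(x, digits = 3, ...) {
  y <- x
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  NextMethod(object = y)
}

#' Export a posterior fit as a flux table
#'
#' @param fit an `mfa_fit`.
#' @param sample_id identifier recorded in the table.
#' @return data frame in the flux-table layout of [write_flux_table()] plus
#'   the interval columns used by the precision score.
#' @export
flux_table <- function(fit, sample_id = "sample1") {
  s <- summary(fit)
  data.frame(sample_id = sample_id, flux_symbol = s$flux, value = s$mean,
             sd = s$sd, lower_ci = s$ci68_low, upper_ci = s$ci68_high,
             ci2.5 = s$ci2.5, ci97.5 = s$ci97.5)
}

#' @export
plot.mfa_fit <- function(x, fluxes = c("dQ2", "dTAL", "Z3"),
                         type = c("trace", "pairs"), ...) {
  type <- match.arg(type)
  fluxes <- intersect(fluxes, colnames(x$flux_draws))
  if (type == "trace") {
    old <- graphics::par(mfrow = c(length(fluxes), 1),
                         mar = c(2, 4, 1, 1))
    on.exit(graphics::par(old))
    for (f in fluxes) {
      rng <- range(vapply(x$flux_chains, function(m) range(m[, f]),
                          numeric(2)))
      graphics::plot(x$flux_chains[[1]][, f], type = "l", ylab = f,
                     xlab = "", ylim = rng, ...)
      for (i in seq_along(x$flux_chains)[-1])
        graphics::lines(x$flux_chains[[i]][, f], col = i)
    }
  } else {
    graphics::pairs(x$flux_draws[, fluxes, drop = FALSE], pch = ".", ...)
  }
  invisible(x)
}

#' Pairwise posterior confidence region of two fluxes
#'
#' Mean vector, covariance and the level-scaled ellipse of two fluxes'
#' joint posterior.  Nearly perfectly correlated pairs (|rho| ~ 1, e.g.
#' pairs linked by an exact balance) are flagged and returned as a segment.
#'
#' @param fit an `mfa_fit`.
#' @param flux_a,flux_b flux names.
#' @param level coverage of the region (default 68%).
#' @return list of class `mfa_region`: `mean`, `cov`, `correlation`,
#'   `axes` (ellipse half-axes), `angle`, `degenerate` flag and `level`.
#' @export
pairwise_region <- function(fit, flux_a, flux_b, level = 0.68) {
  d <- fit$flux_draws[, c(flux_a, flux_b), drop = FALSE]
  mu <- colMeans(d)
  S <- stats::cov(d)
  sds <- sqrt(diag(S))
  rho <- if (all(sds > 0)) S[1, 2] / prod(sds) else sign(S[1, 2])
  ev <- eigen(S, symmetric = TRUE)
  r2 <- stats::qchisq(level, df = 2)
  degenerate <- !all(sds > 0) || abs(rho) > 1 - 1e-9 ||
    ev$values[2] <= 1e-12 * ev$values[1]
  structure(list(fluxes = c(flux_a, flux_b), mean = mu, cov = S,
                 correlation = rho,
                 axes = sqrt(pmax(ev$values, 0) * r2),
                 angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
                 degenerate = degenerate, level = level),
            class = "mfa_region")
}

#' @export
print.mfa_region <- function(x, ...) {
  cat(sprintf("%.0f%% confidence region of (%s, %s)\n", 100 * x$level,
              x$fluxes[1], x$fluxes[2]))
  cat(sprintf("  mean (%.3f, %.3f), correlation %.4f%s\n",
              x$mean[1], x$mean[2], x$correlation,
              if (x$degenerate) " [degenerate: segment]" else ""))
  cat(sprintf("  half-axes %.3f / %.3f, angle %.1f deg\n",
              x$axes[1], x$axes[2], 180 / pi * x$angle))
  invisible(x)
}

#' Calibrate per-fragment measurement precision
#'
#' Iterates: fit, compare the mean squared residual between measured and
#' posterior-mean predicted CMDs per fragment to the Dirichlet's average
#' theoretical variance, reset `NC` so the two match, refit.  Stops when
#' every `NC` changes by less than `tol` (relative) or after `max_iter`
#' rounds; an `NC` hitting `nc_cap` (near-exact data) warns.
#'
#' @inheritParams mfa_fit
#' @param max_iter maximum calibration rounds.
#' @param tol relative NC change below which the iteration stops.
#' @param nc_cap upper cap on calibrated NC.
#' @return list with the calibrated `nc` per fragment, the final `fit`, the
#'   iteration `history` and a `converged` flag.
#' @export
calibrate_precision <- function(data, model = ppp_network(),
                                tracers = default_tracer_panel(),
                                config = mfa_config(), max_iter = 5,
                                tol = 0.1, nc_cap = 1e7) {
  frag_key <- sprintf("%s C%d-C%d", data$metabolite, data$carbon_first,
                      data$carbon_last)
  history <- list()
  converged <- FALSE
  fit <- NULL
  for (round in seq_len(max_iter)) {
    fit <- mfa_fit(data, model, tracers, config)
    pred <- stats::predict(fit)
    nc_new <- stats::setNames(numeric(0), character(0))
    for (fr in unique(frag_key)) {
      res2 <- c(); pv <- c()
      rows <- which(frag_key == fr)
      for (tr_id in unique(data$tracer_id[rows])) {
        sel <- rows[data$tracer_id[rows] == tr_id]
        sel <- sel[order(data$mass_offset[sel])]
        meas <- data$fraction[sel] / sum(data$fraction[sel])
        p <- pred[[tr_id]][[fr]]
        res2 <- c(res2, (meas - p)^2)
        pv <- c(pv, p * (1 - p))
      }
      msr <- mean(res2)
      est <- if (msr <= 0) nc_cap else mean(pv) / msr - 1
      nc_new[fr] <- min(max(est, 1), nc_cap)
    }
    if (any(nc_new >= nc_cap))
      warning("calibrated NC hit the cap for: ",
              paste(names(nc_new)[nc_new >= nc_cap], collapse = ", "),
              " (near-exact data)")
    old <- vapply(unique(frag_key), function(fr)
      data$nc[frag_key == fr][1], 0)
    history[[round]] <- nc_new
    rel <- abs(nc_new - old[names(nc_new)]) / old[names(nc_new)]
    data$nc <- nc_new[frag_key]
    if (all(rel < tol)) { converged <- TRUE; break }
  }
  list(nc = nc_new, fit = fit, history = history, converged = converged)
}

#' Posterior-mean predicted CMDs
#'
#' @param object an `mfa_fit`.
#' @param ... unused.
#' @return nested list `tracer id -> fragment id -> CMD` at the posterior
#'   mean fluxes.
#' @export
predict.mfa_fit <- function(object, ...) {
  mu <- stats::coef(object)
  st <- complete_net_fluxes(object$model,
                           mu[setdiff(object$free, "Z1")])
  st <- add_exchange(st, mu[paste0("ex.", object$exch)] |>
                       stats::setNames(object$exch))
  sim <- simulate_cmds(st, object$tracers,
                       fragments = fragments_from_data(object$data))
  unclass(sim)
}
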