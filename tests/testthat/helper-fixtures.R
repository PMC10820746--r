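# shared fixtures: models, flux states and small sampler settings

closed_model <- function() ppp_network(active_inputs = character())

# the documented synthetic truth (S7P input active)
fixture_truth <- function(model = ppp_network()) default_truth(model)

# a feasible closed-system state with mild exchanges (QR = 0)
closed_state <- function(dQ2 = 85, dTAL = 5, q2_exchange = 0) {
  st <- complete_net_fluxes(closed_model(), c(dQ2 = dQ2, dTAL = dTAL))
  add_exchange(st, c(GPI = 30, Q2 = q2_exchange, TPI = 30, P_ex = 10,
                     TKT1 = 5, TKT2 = 5, TAL = 5))
}

# single-species tracer with exact purity and no natural abundance
pure_tracer <- function(positions, purity = 1) {
  tracer_mixture(tracer_species(1, positions, purity = purity, natural = 0),
                 natural = 0)
}

# small sampler settings for fast test fits
quick_config <- function(warmup = 300, iter = 400, seed = 1,
                         init_tries = 50, init_optim = 80, ...) {
  mfa_config(chains = 2, warmup = warmup, iter = iter, seed = seed,
             init_tries = init_tries, init_optim = init_optim, ...)
}

fragment_row <- function(metabolite, first, last, formula = NA) {
  data.frame(metabolite = metabolite, carbon_first = first,
             carbon_last = last, formula = formula,
             stringsAsFactors = FALSE)
}

panel_fragment <- function(id) {
  p <- fragment_panel()
  ids <- vapply(seq_len(nrow(p)), function(i) fragment_id(p[i, ]), "")
  p[ids == id, , drop = FALSE]
}

# simple simplex draw for round-trip tests
rdirichlet_test <- function(k) {
  g <- stats::rgamma(k, 1)
  g / sum(g)
}

# shared generative fixture: three orthogonal-ish factors, nine fluxes
make_factor_data <- function(n = 28, noise = 0.02, seed = 57) {
  set.seed(seed)
  # factors of clearly different strength so component order is stable
  L <- matrix(0, 9, 3, dimnames = list(paste0("f", 1:9), NULL))
  L[1:4, 1] <- c(1, 0.9, 0.8, -0.9)
  L[5:7, 2] <- c(1, -0.8, 0.7)
  L[8:9, 3] <- c(0.9, -1)
  scores <- matrix(stats::rnorm(n * 3), n, 3)
  X <- scores %*% t(L) + noise * matrix(stats::rnorm(n * 9), n, 9)
  colnames(X) <- rownames(L)
  list(X = X, L = L)
}
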