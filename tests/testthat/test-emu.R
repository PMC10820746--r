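test_that("carbon transitions follow the Katz/Rognstad chemistry", {
  tt <- carbon_transition_table(ppp_network())
  # transaldolase moves only S7P C1-C3 onto F6P C1-C3
  tal <- tt[tt$flux_key == "TAL.f" & tt$sub_pool == "S7P" &
              tt$prod_pool == "F6P", ]
  expect_setequal(tal$sub_carbon, 1:3)
  expect_setequal(tal$prod_carbon, 1:3)
  # every reaction's maps are carbon-preserving bijections up to CO2
  for (k in unique(tt$flux_key)) {
    sub <- tt[tt$flux_key == k, ]
    expect_false(any(duplicated(sub[, c("sub_pool", "sub_carbon")])))
    tracked <- sub[!is.na(sub$prod_carbon), ]
    expect_false(any(duplicated(tracked[, c("prod_pool", "prod_carbon")])))
  }
  # only the oxidative step loses a carbon, C1 of G6P
  co2 <- tt[tt$prod_pool == "CO2", ]
  expect_equal(co2$flux_key, "Z3")
  expect_equal(co2$sub_carbon, 1)
  # composing the oxidative step with transketolase 1: G6P C3 -> S7P C2
  z3 <- tt[tt$flux_key == "Z3" & tt$sub_carbon == 3, ]
  expect_equal(z3$prod_pool, "XuP")
  hop <- tt[tt$flux_key == "TKT1.f" & tt$sub_pool == "XuP" &
              tt$sub_carbon == z3$prod_carbon & tt$prod_pool == "S7P", ]
  expect_equal(hop$prod_carbon, 2)
})

test_that("EMU decomposition tracks targets backward with bounded size", {
  m <- ppp_network()
  sys <- emu_decompose(m, fragment_row("G6P", 5, 6))
  ids <- unlist(lapply(sys$blocks, `[[`, "unknowns"))
  expect_true("F6P|5,6" %in% ids)
  expect_lte(max(vapply(sys$blocks, `[[`, 0L, "size")), 7)
  # single-carbon target decomposes into size-1 EMUs only
  sys1 <- emu_decompose(m, fragment_row("GAP", 1, 1))
  expect_equal(vapply(sys1$blocks, `[[`, 0L, "size"), 1L)
  expect_error(emu_decompose(m, fragment_row("GAP", 1, 5)),
               "exceeds")
})

test_that("degenerate tracers give degenerate CMDs", {
  st <- closed_state()
  unl <- tracer_mixture(tracer_species(1, integer(), natural = 0),
                        natural = 0)
  sim <- simulate_cmds(st, unl, fragments = mfa_fragments())
  for (cmd in sim) {
    expect_equal(cmd[1], 1, tolerance = 1e-12)
    expect_equal(sum(cmd), 1, tolerance = 1e-12)
  }
  # a fully labeled pure tracer concentrates all mass at M+n
  stS <- complete_net_fluxes(ppp_network(), c(dQ2 = 85, dTAL = 5,
                                              S_Input = 0))
  stS <- add_exchange(stS, c(GPI = 20, TPI = 20, P_ex = 5, TKT1 = 5,
                             TKT2 = 5, TAL = 5))
  u13 <- pure_tracer(1:6)
  simU <- simulate_cmds(stS, u13, fragments = mfa_fragments())
  for (id in names(simU)) {
    n <- length(simU[[id]]) - 1L
    expect_equal(simU[[id]][n + 1], 1, tolerance = 1e-9, label = id)
  }
})

test_that("EMU cascade matches the full-isotopomer solver", {
  m <- ppp_network()
  panel <- default_tracer_panel()
  sys <- emu_decompose(m, mfa_fragments())
  states <- sample_feasible(m, 5, seed = 21)
  set.seed(22)
  for (st in states) {
    ex <- stats::runif(7, 0, 40)
    names(ex) <- names(st$exch)
    st <- add_exchange(st, ex)
    emu <- simulate_cmds(st, panel, system = sys)
    iso <- isotopomer_oracle(st, panel)
    for (tr in names(emu))
      for (fr in names(emu[[tr]]))
        expect_lt(max(abs(emu[[tr]][[fr]] - iso[[tr]][[fr]])), 1e-8)
  }
})

test_that("all simulated CMDs are normalized and nonnegative", {
  panel <- default_tracer_panel()
  for (st in sample_feasible(ppp_network(), 5, seed = 31)) {
    st <- add_exchange(st, c(GPI = 15, Q2 = 5, TPI = 15, P_ex = 5,
                             TKT1 = 5, TKT2 = 5, TAL = 5))
    sim <- simulate_cmds(st, panel)
    for (tr in sim) for (cmd in tr) {
      expect_true(all(cmd >= 0))
      expect_equal(sum(cmd), 1, tolerance = 1e-9)
    }
  }
})

test_that("lower-half tracer without condensation leaves no M+1 or M+4", {
  st <- closed_state(q2_exchange = 0)     # QR = 0
  sim <- simulate_cmds(st, pure_tracer(4:6, purity = 1),
                       fragments = panel_fragment("G6P C3-C6"))
  cmd <- sim[["G6P C3-C6"]]
  expect_equal(cmd[2], 0, tolerance = 1e-12)   # M+1
  expect_equal(cmd[5], 0, tolerance = 1e-12)   # M+4
  # and the derived upper-half enrichment is exactly zero
  full <- simulate_cmds(st, pure_tracer(4:6, purity = 1),
                        fragments = rbind(panel_fragment("G6P C1-C6"),
                                          panel_fragment("G6P C3-C6")))
  tc12 <- complement_enrichment(total_enrichment(full[["G6P C1-C6"]]),
                                total_enrichment(full[["G6P C3-C6"]]))
  expect_equal(tc12, 0, tolerance = 1e-12)
})

test_that("enrichment additivity closes for simulated fragment families", {
  st <- add_exchange(fixture_truth(), c(Q2 = 25))
  frs <- rbind(fragment_row("G6P", 1, 6), fragment_row("G6P", 3, 6),
               fragment_row("G6P", 1, 2))
  panel <- default_tracer_panel()
  sim <- simulate_cmds(st, panel, fragments = frs)
  for (tr in names(sim)) {
    t16 <- total_enrichment(sim[[tr]][["G6P C1-C6"]])
    t36 <- total_enrichment(sim[[tr]][["G6P C3-C6"]])
    t12 <- total_enrichment(sim[[tr]][["G6P C1-C2"]])
    expect_equal(t12 + t36, t16, tolerance = 1e-8)
    expect_equal(complement_enrichment(t16, t36), t12, tolerance = 1e-8)
  }
})

test_that("labeled carbon is conserved from tracer inflow to outflow", {
  model <- ppp_network()
  st <- fixture_truth(model)
  panel <- default_tracer_panel()
  frs <- rbind(fragment_row("G6P", 1, 1), fragment_row("3PG", 1, 3),
               fragment_row("R5P", 1, 5))
  sim <- simulate_cmds(st, panel, fragments = frs)
  for (tr in names(panel)) {
    mix <- panel[[tr]]
    glc_in <- sum(vapply(mix$species, function(sp)
      sp$fraction * sum(sp$probs), 0))
    inflow <- st$net[["Z1"]] * glc_in +
      st$net[["S_Input"]] * 7 * mix$natural
    # outflow: trioses (Q11), pentoses (Q4) and the decarboxylated C1
    outflow <- st$net[["Q11"]] * total_enrichment(sim[[tr]][["3PG C1-C3"]]) +
      st$net[["Q4"]] * total_enrichment(sim[[tr]][["R5P C1-C5"]]) +
      st$net[["Z3"]] * total_enrichment(sim[[tr]][["G6P C1-C1"]])
    expect_equal(outflow / inflow, 1, tolerance = 1e-6, label = tr)
  }
})

test_that("large exchange equilibrates paired pool distributions", {
  m <- ppp_network()
  st <- complete_net_fluxes(m, c(dQ2 = 85, dTAL = 5, S_Input = 3))
  frs <- rbind(fragment_row("G6P", 1, 6), fragment_row("F6P", 1, 6))
  tr <- default_tracer_panel()[["1,2-13C"]]
  lo <- simulate_cmds(add_exchange(st, c(GPI = 1)), tr, fragments = frs)
  hi <- simulate_cmds(add_exchange(st, c(GPI = 4000)), tr, fragments = frs)
  d_lo <- max(abs(lo[["G6P C1-C6"]] - lo[["F6P C1-C6"]]))
  d_hi <- max(abs(hi[["G6P C1-C6"]] - hi[["F6P C1-C6"]]))
  expect_lt(d_hi, d_lo / 20)
  expect_lt(d_hi, 1e-3)
})

test_that("derived proxy patterns mirror their source pools", {
  st <- add_exchange(fixture_truth(), c(Q2 = 20))
  frs <- rbind(fragment_row("G6P", 1, 6), fragment_row("F6P", 1, 6),
               fragment_row("DHAP", 1, 3), fragment_row("3PG", 1, 3))
  tr <- default_tracer_panel()[["U-13C"]]
  sim <- simulate_cmds(st, tr, fragments = frs)
  out <- derived_patterns(sim)
  expect_equal(out[["6PG C1-C6"]], out[["G6P C1-C6"]])
  expect_equal(sum(out[["6PG C1-C6"]]), 1, tolerance = 1e-12)
  expect_equal(out[["FBP C1-C6"]], out[["F6P C1-C6"]])
  conv <- derived_patterns(sim, fbp = "triose_convolution")
  expect_equal(sum(conv[["FBP C1-C6"]]), 1, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(conv[["FBP C1-C6"]], out[["FBP C1-C6"]])))
})

test_that("pools without flux raise a singular-system error", {
  st <- complete_net_fluxes(closed_model(), c(dQ2 = 100, dTAL = 0))
  expect_error(simulate_cmds(st, default_tracer_panel()[[1]]),
               "without outgoing flux")
})
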