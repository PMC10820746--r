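test_that("default network has the expected pools, reactions and inputs", {
  m <- closed_model()
  expect_length(m$pools, 8)
  expect_length(m$reactions, 11)
  expect_identical(m$active_inputs, character(0))
  S <- stoichiometric_matrix(m)
  expect_equal(nrow(S), 8)
  # one extra input adds exactly one column
  Ss <- stoichiometric_matrix(ppp_network("S_Input"))
  expect_equal(ncol(Ss), ncol(S) + 1)
  # E4P balance touches only the transaldolase and second transketolase
  e4p <- S["E4P", ]
  expect_equal(unname(e4p[c("dTAL", "dTKT2")]), c(1, -1))
  expect_true(all(e4p[setdiff(names(e4p), c("dTAL", "dTKT2"))] == 0))
  expect_error(ppp_network("X_Input"), "unknown input")
})

test_that("default configuration enumerates 19 unidirectional fluxes", {
  st <- fixture_truth()
  expect_length(st$uni, 7 * 2 + 4 + 1)
})

test_that("flux completion agrees with an independent linear solve", {
  m <- closed_model()
  S <- stoichiometric_matrix(m)
  indep <- c("Z1", "dQ2", "dTAL")
  dep_cols <- setdiff(colnames(S), indep)
  for (vals in list(c(dQ2 = 85, dTAL = 5), c(dQ2 = 40, dTAL = 20),
                    c(dQ2 = -10, dTAL = 30))) {
    st <- complete_net_fluxes(m, vals)
    # oracle: solve the dependent block directly by QR
    rhs <- -S[, indep] %*% c(100, vals[c("dQ2", "dTAL")])
    v_oracle <- qr.solve(S[, dep_cols], rhs)
    expect_equal(unname(st$net[dep_cols]), unname(drop(v_oracle)),
                 tolerance = 1e-10)
    expect_lt(max(abs(S %*% st$net[colnames(S)])), 1e-9)
  }
  # frozen worked example
  st <- complete_net_fluxes(m, c(dQ2 = 85, dTAL = 5))
  expect_equal(unname(st$net[c("Z3", "Q4", "Q11", "dGPI", "dTPI",
                               "dTKT1", "dTKT2")]),
               c(25, 10, 175, 75, 85, 5, 5))
})

test_that("pure glycolysis yields no PPP flux and complete triose yield", {
  st <- complete_net_fluxes(closed_model(), c(dQ2 = 100, dTAL = 0))
  expect_equal(unname(st$net[c("Z3", "Q4", "Q11")]), c(0, 0, 200))
})

test_that("infeasible independent values raise a named feasibility error", {
  expect_error(complete_net_fluxes(closed_model(), c(dQ2 = 101, dTAL = 0)),
               "Z3")
  expect_error(complete_net_fluxes(ppp_network(), c(dQ2 = 50, dTAL = 5,
                                                    S_Input = -1)),
               "nonnegative")
})

test_that("dependency split is consistent and flags bad choices", {
  m <- ppp_network()
  dep <- split_dependency(m)
  expect_setequal(dep$dependent, c("Z3", "Q4", "Q11", "dGPI", "dTKT2",
                                   "dTKT1", "dTPI", "dP_ex"))
  # identity by construction: S_dep M + S_indep = 0
  expect_lt(max(abs(dep$S_dep %*% dep$M + dep$S_indep)), 1e-9)
  # first dependency row: Z3 = Z1 - dQ2 + 2 dTAL
  expect_equal(unname(dep$M["Z3", c("Z1", "dQ2", "dTAL")]), c(1, -1, 2))
  # adding Z3 to the chosen controls demotes the input and is singular
  expect_error(split_dependency(m, c("Z1", "dQ2", "dTAL", "Z3")),
               "non-invertible")
  # non-square dependent block
  expect_error(split_dependency(m, c("Z1", "dQ2")), "square")
  expect_error(split_dependency(m, c("dQ2", "dTAL", "S_Input")), "Z1")
})

test_that("permissible-space dimension is 2 plus the number of inputs", {
  inputs <- c("P_Input", "T_Input", "S_Input", "F_Input")
  for (k in 0:4) {
    for (sub in utils::combn(inputs, k, simplify = FALSE)) {
      m <- ppp_network(active_inputs = sub)
      expect_equal(permissible_space(m)$dimension, 2 + k)
    }
  }
})

test_that("acceptance region matches the analytic closed-system inequalities", {
  m <- closed_model()
  dep <- split_dependency(m)
  grid <- expand.grid(dQ2 = seq(-60, 140, by = 20),
                      dTAL = seq(-60, 140, by = 20))
  for (i in seq_len(nrow(grid))) {
    q2 <- grid$dQ2[i]; tal <- grid$dTAL[i]
    analytic <- (q2 <= 100 + 2 * tal) && (q2 + tal <= 100) &&
      (2 * q2 + tal >= 0)
    feasible <- !inherits(try(complete_net_fluxes(
      m, c(dQ2 = q2, dTAL = tal), dep = dep), silent = TRUE), "try-error")
    expect_identical(feasible, analytic,
                     label = sprintf("dQ2=%g dTAL=%g", q2, tal))
  }
})

test_that("classic PPP stoichiometry is recovered on the Q4 = 0 face", {
  m <- closed_model()
  for (tal in seq(5, 95, by = 10)) {
    st <- complete_net_fluxes(m, c(dQ2 = 100 - tal, dTAL = tal))
    expect_equal(unname(st$net["Q4"]), 0, tolerance = 1e-9)
    expect_equal(unname(st$net["Z3"]), 3 * tal, tolerance = 1e-9)
    expect_equal(unname(st$net["dTKT1"]), tal, tolerance = 1e-9)
    expect_equal(unname(st$net["dTKT2"]), tal, tolerance = 1e-9)
  }
})

test_that("feasible sampling is uniform-rejection, reproducible and valid", {
  m <- ppp_network()
  S <- stoichiometric_matrix(m)
  s1 <- sample_feasible(m, 25, seed = 11)
  s2 <- sample_feasible(m, 25, seed = 11)
  expect_equal(s1, s2)
  for (st in s1) {
    expect_true(all(st$net[c("Z3", "Q4", "Q11")] >= 0))
    expect_lt(max(abs(S %*% st$net[colnames(S)])), 1e-9)
  }
})

test_that("exchange parameterization preserves net flux and nonnegativity", {
  st <- complete_net_fluxes(closed_model(), c(dQ2 = 85, dTAL = 5))
  st1 <- add_exchange(st, c(GPI = 0))
  expect_equal(unname(st1$uni[c("GPI.f", "GPI.b")]), c(75, 0))
  st2 <- complete_net_fluxes(closed_model(), c(dQ2 = 96, dTAL = -2))
  expect_equal(unname(st2$net["dGPI"]), -10 + 110)  # dGPI = dQ2 - 2 dTAL
  # hand case: negative net with exchange 5
  st3 <- add_exchange(st, c(TAL = 5))
  v <- st3$net[["dTAL"]]
  expect_equal(unname(st3$uni[c("TAL.f", "TAL.b")]), c(max(v, 0) + 5,
                                                       max(-v, 0) + 5))
  for (r in names(st3$exch)) {
    f <- st3$uni[[paste0(r, ".f")]]; b <- st3$uni[[paste0(r, ".b")]]
    expect_equal(f - b, st3$net[[c(GPI = "dGPI", Q2 = "dQ2", TPI = "dTPI",
                                   P_ex = "dP_ex", TKT1 = "dTKT1",
                                   TKT2 = "dTKT2", TAL = "dTAL")[[r]]]])
    expect_equal(min(f, b), unname(st3$exch[r]))
  }
  expect_error(add_exchange(st, c(GPI = -1)), "nonnegative")
  expect_error(add_exchange(st, c(BOGUS = 1)), "unknown")
})

test_that("network JSON and flux-table CSV round-trip", {
  m <- ppp_network(c("S_Input", "P_Input"), pX = 0.55, pR = 0.45)
  js <- network_to_json(m)
  m2 <- network_from_json(js)
  expect_equal(stoichiometric_matrix(m2), stoichiometric_matrix(m))
  expect_equal(m2$pX, 0.55)

  tab <- data.frame(sample_id = "s1", flux_symbol = c("Z3", "dTAL"),
                    value = c(25, 5), lower_ci = c(20, 3),
                    upper_ci = c(30, 7))
  path <- tempfile(fileext = ".csv")
  write_flux_table(tab, path)
  expect_equal(read_flux_table(path), tab)
  expect_error(write_flux_table(tab[, 1:3], path), "lacks column")
})
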