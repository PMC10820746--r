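# Synthetic measurement generation with the Dirichlet noise structure, and
# the tracer/fragment scenario suites used for design comparison.

#' Default synthetic truth flux state
#'
#' A documented package convention (not a literature value): closed
#' glycolysis/PPP system plus an unlabeled S7P input, with `dQ2 = 85`,
#' `dTAL = 5`, `S_Input = 3` and moderate exchange fluxes.
#'
#' @param model a [ppp_network()] model with `S_Input` active.
#' @return a feasible `flux_state`.
#' @export
default_truth <- function(model = ppp_network()) {
  st <- complete_net_fluxes(model, c(dQ2 = 85, dTAL = 5, S_Input = 3))
  add_exchange(st, c(GPI = 50, Q2 = 10, TPI = 50, P_ex = 20,
                     TKT1 = 10, TKT2 = 10, TAL = 10))
}

#' Default per-fragment precision parameters
#'
#' `NC = 5000` for the high-intensity fragments and `NC = 500` for the weak
#' full-skeleton G6P fragment (m/z 720), mirroring its reduced GC-MS
#' measurement precision.
#'
#' @param fragments fragment table.
#' @return named numeric vector keyed by fragment id.
#' @export
default_nc <- function(fragments = mfa_fragments()) {
  ids <- vapply(seq_len(nrow(fragments)), function(i)
    fragment_id(fragments[i, ]), "")
  nc <- stats::setNames(rep(5000, length(ids)), ids)
  nc[ids == "G6P C1-C6"] <- 500
  nc
}

#' Generate a synthetic measurement table
#'
#' Simulates steady-state CMDs for a known flux state under the tracer
#' panel, then draws one noisy CMD per tracer x fragment from
#' `Dirichlet(NC * CMD)`.
#'
#' @param truth a feasible `flux_state` (e.g. [default_truth()]).
#' @param panel named list of tracer mixtures.
#' @param fragments fragment table.
#' @param nc named per-fragment precision vector (see [default_nc()]), or a
#'   single value recycled to all fragments.
#' @param seed optional integer seed.
#' @param sample_id sample identifier written into the table.
#' @return long-format measurement data frame (see [write_measurements()]).
#' @export
generate_measurements <- function(truth, panel = default_tracer_panel(),
                                  fragments = mfa_fragments(),
                                  nc = default_nc(fragments), seed = NULL,
                                  sample_id = "synthetic") {
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_cmds(truth, panel, fragments = fragments)
  ids <- vapply(seq_len(nrow(fragments)), function(i)
    fragment_id(fragments[i, ]), "")
  if (length(nc) == 1 && is.null(names(nc)))
    nc <- stats::setNames(rep(nc, length(ids)), ids)
  missing <- setdiff(ids, names(nc))
  if (length(missing))
    stop("no NC for fragment(s): ", paste(missing, collapse = ", "))
  rows <- list()
  for (tr in names(panel)) {
    for (i in seq_len(nrow(fragments))) {
      id <- ids[i]
      cmd <- sim[[tr]][[id]]
      noisy <- drop(rdirichlet(1, nc[[id]] * pmax(cmd, 1e-12)))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, tracer_id = tr,
        metabolite = fragments$metabolite[i],
        carbon_first = fragments$carbon_first[i],
        carbon_last = fragments$carbon_last[i],
        mass_offset = seq_along(cmd) - 1L,
        fraction = noisy, nc = nc[[id]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Measurement-design scenario suite
#'
#' The fragment scenarios: (i) 3PG only — the common PPP determination
#' strategy; (ii)-(iv) 3PG plus one G6P fragment each; (v) 3PG plus all
#' three G6P fragments; (vi) plus DHAP; (vii) all seven fragments; and the
#' starred variant of (ii) in which the weak G6P C1-C6 fragment is assigned
#' the same precision as the other G6P fragments.  The tracer scenarios:
#' each single tracer, each tracer pair, and the complete panel (all with
#' the full fragment set).
#'
#' @return named list of scenarios, each with `name`, `kind`, `tracers`,
#'   `fragments` (fragment ids) and `nc_override`.
#' @export
scenario_suite <- function() {
  all_tracers <- c("1,2-13C", "4,5,6-13C", "U-13C")
  g6p <- c("G6P C1-C6", "G6P C3-C6", "G6P C5-C6")
  all_frags <- c("3PG C1-C3", "DHAP C1-C3", g6p, "P5P C1-C5", "R5P C3-C5")
  fs <- function(name, frags, nc_override = NULL)
    list(name = name, kind = "fragments", tracers = all_tracers,
         fragments = frags, nc_override = nc_override)
  ts <- function(name, tracers)
    list(name = name, kind = "tracers", tracers = tracers,
         fragments = all_frags, nc_override = NULL)
  out <- list(
    fs("i_3PG", "3PG C1-C3"),
    fs("ii_3PG+G6P_C1-C6", c("3PG C1-C3", "G6P C1-C6")),
    fs("ii_star_3PG+G6P_C1-C6hi", c("3PG C1-C3", "G6P C1-C6"),
       nc_override = c("G6P C1-C6" = 5000)),
    fs("iii_3PG+G6P_C3-C6", c("3PG C1-C3", "G6P C3-C6")),
    fs("iv_3PG+G6P_C5-C6", c("3PG C1-C3", "G6P C5-C6")),
    fs("v_3PG+G6P_all", c("3PG C1-C3", g6p)),
    fs("vi_3PG+DHAP+G6P", c("3PG C1-C3", "DHAP C1-C3", g6p)),
    fs("vii_all", all_frags),
    ts("t_1,2", "1,2-13C"),
    ts("t_4,5,6", "4,5,6-13C"),
    ts("t_U", "U-13C"),
    ts("t_1,2+4,5,6", c("1,2-13C", "4,5,6-13C")),
    ts("t_1,2+U", c("1,2-13C", "U-13C")),
    ts("t_4,5,6+U", c("4,5,6-13C", "U-13C")),
    ts("t_complete", all_tracers)
  )
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

#' Generate synthetic data for one scenario
#'
#' Regenerates measurements under the scenario's tracer subset, fragment
#' subset and precision overrides (so a precision override affects the noise
#' actually drawn, as in the elevated-precision G6P variant).
#'
#' @param truth a feasible `flux_state`.
#' @param scenario one element of [scenario_suite()].
#' @param seed optional integer seed.
#' @param panel full tracer panel to subset.
#' @return measurement data frame.
#' @export
generate_scenario_data <- function(truth, scenario, seed = NULL,
                                   panel = default_tracer_panel()) {
  frg <- mfa_fragments()
  ids <- vapply(seq_len(nrow(frg)), function(i) fragment_id(frg[i, ]), "")
  frg <- frg[ids %in% scenario$fragments, , drop = FALSE]
  nc <- default_nc(frg)
  for (fr in names(scenario$nc_override))
    if (fr %in% names(nc)) nc[fr] <- scenario$nc_override[[fr]]
  generate_measurements(truth, panel[scenario$tracers], frg, nc, seed,
                        sample_id = scenario$name)
}

#' Restrict a measurement table to a scenario
#'
#' @param data full measurement table covering the panel.
#' @param scenario one element of [scenario_suite()].
#' @return the subset table with any scenario NC overrides applied.
#' @export
apply_scenario <- function(data, scenario) {
  id <- sprintf("%s C%d-C%d", data$metabolite, data$carbon_first,
                data$carbon_last)
  keep <- data$tracer_id %in% scenario$tracers & id %in% scenario$fragments
  out <- data[keep, , drop = FALSE]
  if (!nrow(out)) stop("scenario selects no measurements")
  for (fr in names(scenario$nc_override))
    out$nc[id[keep] == fr] <- scenario$nc_override[[fr]]
  rownames(out) <- NULL
  out
}
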