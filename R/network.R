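# Metabolic network of upper glucose metabolism: pools, reactions with
# carbon atom maps, stoichiometric balance and dependency analysis, and the
# permissible flux polytope.

PPP_POOLS <- c(G6P = 6L, F6P = 6L, XuP = 5L, R5P = 5L, S7P = 7L,
               E4P = 4L, DHAP = 3L, GAP = 3L)

INPUT_FLUXES <- c("P_Input", "T_Input", "S_Input", "F_Input")

# external (untracked) carbon sources feeding the network
EXT_GLUCOSE <- "EXT:glc"

ext_pool <- function(n) paste0("EXT:unl", n)
is_external <- function(pool) startsWith(pool, "EXT:")

#' Construct the default glycolysis/pentose phosphate network
#'
#' Builds the eight-pool model of upper glucose metabolism: G6P, F6P, a
#' lumped Ru5P+X5P pool (`XuP`), R5P, S7P, E4P, DHAP and GAP, joined by
#' glycolysis (`Z1`, `dGPI`, `dQ2`, `dTPI`, `Q11`), the oxidative pentose
#' phosphate pathway (`Z3`, releasing C1 of G6P as CO2), the non-oxidative
#' PPP (`dTKT1`, `dTAL`, `dTKT2`), the pentose sub-pool exchange (`dP_ex`),
#' the R5P drain (`Q4`) and optional unlabeled input fluxes into the pentose
#' (`P_Input`), triose (`T_Input`), S7P (`S_Input`) and F6P (`F_Input`)
#' pools.  Reversible reactions carry a net flux (prefix `d`) plus a
#' nonnegative exchange magnitude.  All fluxes are normalized to the hexose
#' uptake `Z1 = 100`.
#'
#' @param active_inputs character vector, subset of
#'   `c("P_Input","T_Input","S_Input","F_Input")`.  Default `"S_Input"`,
#'   the configuration suited to granulocyte-type glucose metabolism
#'   (an endogenous S7P source, no triose or pentose influx).
#' @param pX,pR fractional split of `P_Input` between the XuP and R5P
#'   sub-pools; must sum to 1.  Default 2/3 and 1/3, the transketolase
#'   demand ratio of X5P to R5P.
#' @param z1 fixed hexose input flux (normalization), default 100.
#' @return an object of class `ppp_network`.
#' @examples
#' net <- ppp_network()
#' net_closed <- ppp_network(active_inputs = character())
#' @export
ppp_network <- function(active_inputs = "S_Input", pX = 2/3, pR = 1/3,
                        z1 = 100) {
  active_inputs <- as.character(active_inputs)
  bad <- setdiff(active_inputs, INPUT_FLUXES)
  if (length(bad))
    stop("unknown input flux(es): ", paste(bad, collapse = ", "),
         "; valid inputs are ", paste(INPUT_FLUXES, collapse = ", "))
  if (abs(pX + pR - 1) > 1e-12 || pX < 0 || pR < 0)
    stop("pX and pR must be nonnegative and sum to 1")

  rx <- function(name, flux, reversible, substrates, products, origin) {
    list(name = name, flux = flux, reversible = reversible,
         substrates = substrates, products = products, origin = origin)
  }
  om <- function(sub, pos) cbind(sub = sub, pos = pos)

  reactions <- list(
    rx("Z1", "Z1", FALSE, EXT_GLUCOSE, "G6P",
       list(G6P = om(1L, 1:6))),
    rx("Z3", "Z3", FALSE, "G6P", "XuP",               # C1 released as CO2
       list(XuP = om(1L, 2:6))),
    rx("GPI", "dGPI", TRUE, "G6P", "F6P",
       list(F6P = om(1L, 1:6))),
    rx("Q2", "dQ2", TRUE, "F6P", c("DHAP", "GAP"),
       list(DHAP = om(1L, c(3L, 2L, 1L)), GAP = om(1L, 4:6))),
    rx("TPI", "dTPI", TRUE, "DHAP", "GAP",
       list(GAP = om(1L, 1:3))),
    rx("P_ex", "dP_ex", TRUE, "XuP", "R5P",
       list(R5P = om(1L, 1:5))),
    rx("TKT1", "dTKT1", TRUE, c("XuP", "R5P"), c("S7P", "GAP"),
       list(S7P = om(c(1L, 1L, 2L, 2L, 2L, 2L, 2L), c(1L, 2L, 1:5)),
            GAP = om(1L, 3:5))),
    rx("TAL", "dTAL", TRUE, c("S7P", "GAP"), c("E4P", "F6P"),
       list(E4P = om(1L, 4:7),
            F6P = om(c(1L, 1L, 1L, 2L, 2L, 2L), c(1:3, 1:3)))),
    rx("TKT2", "dTKT2", TRUE, c("XuP", "E4P"), c("F6P", "GAP"),
       list(F6P = om(c(1L, 1L, 2L, 2L, 2L, 2L), c(1L, 2L, 1:4)),
            GAP = om(1L, 3:5))),
    rx("Q4", "Q4", FALSE, "R5P", character(), list()),
    rx("Q11", "Q11", FALSE, "GAP", character(), list())
  )
  names(reactions) <- vapply(reactions, `[[`, "", "name")

  input_defs <- list(
    P_Input = list(products = c(XuP = NA, R5P = NA), n_carbons = 5L),
    T_Input = list(products = c(DHAP = 1), n_carbons = 3L),
    S_Input = list(products = c(S7P = 1), n_carbons = 7L),
    F_Input = list(products = c(F6P = 1), n_carbons = 6L)
  )
  input_defs$P_Input$products <- c(XuP = pX, R5P = pR)

  model <- structure(
    list(pools = PPP_POOLS,
         reactions = reactions,
         input_defs = input_defs[active_inputs],
         active_inputs = active_inputs,
         z1 = z1, pX = pX, pR = pR),
    class = "ppp_network")
  model$flux_symbols <- net_flux_symbols(model)
  model$rev_names <- names(reactions)[vapply(reactions, `[[`, TRUE,
                                             "reversible")]
  model
}

net_flux_symbols <- function(model) {
  c(vapply(model$reactions, `[[`, "", "flux"), model$active_inputs)
}

#' @export
print.ppp_network <- function(x, ...) {
  cat("Glycolysis/PPP network model\n")
  cat("  pools:    ", paste(sprintf("%s(%d)", names(x$pools), x$pools),
                            collapse = " "), "\n")
  cat("  reactions:", paste(names(x$reactions), collapse = " "), "\n")
  cat("  inputs:   ",
      if (length(x$active_inputs)) paste(x$active_inputs, collapse = " ")
      else "(closed system)", "\n")
  cat(sprintf("  Z1 = %g, pX = %.4g, pR = %.4g\n", x$z1, x$pX, x$pR))
  invisible(x)
}

#' Stoichiometric balance matrix
#'
#' One row per metabolite pool and one column per net or irreversible flux
#' (consumption negative, production positive).  CO2 and the triose/R5P
#' drains are untracked sinks with no balance row.  `S %*% v = 0` for every
#' completed flux state.
#'
#' @param model a [ppp_network()] model.
#' @return numeric matrix with pool row names and flux column names.
#' @export
stoichiometric_matrix <- function(model) {
  stopifnot(inherits(model, "ppp_network"))
  syms <- model$flux_symbols
  S <- matrix(0, length(model$pools), length(syms),
              dimnames = list(names(model$pools), syms))
  for (r in model$reactions) {
    for (p in r$substrates)
      if (!is_external(p)) S[p, r$flux] <- S[p, r$flux] - 1
    for (p in r$products)
      S[p, r$flux] <- S[p, r$flux] + 1
  }
  for (nm in model$active_inputs) {
    prods <- model$input_defs[[nm]]$products
    for (p in names(prods)) S[p, nm] <- S[p, nm] + prods[[p]]
  }
  S
}

default_independent <- function(model)
  c("Z1", "dQ2", "dTAL", model$active_inputs)

#' Split fluxes into independent and dependent sets
#'
#' Partitions the balance equations `S v = 0` into
#' `S_dep v_dep + S_indep v_indep = 0` and solves for the dependent block,
#' returning the matrix `M` with `v_dep = M v_indep`.
#'
#' @param model a [ppp_network()] model.
#' @param independent character vector of independent flux symbols; must
#'   contain `"Z1"` and leave exactly as many dependent fluxes as there are
#'   pools.  Default: `Z1`, `dQ2`, `dTAL` and the active inputs.
#' @return object of class `mfa_dependency`: list with `M` (dependent x
#'   independent), `independent`, `dependent`, and the two stoichiometric
#'   blocks.
#' @export
split_dependency <- function(model, independent = NULL) {
  S <- stoichiometric_matrix(model)
  if (is.null(independent)) independent <- default_independent(model)
  if (!"Z1" %in% independent)
    stop("the independent set must contain the fixed input flux Z1")
  bad <- setdiff(independent, colnames(S))
  if (length(bad))
    stop("unknown flux symbol(s): ", paste(bad, collapse = ", "))
  dependent <- setdiff(colnames(S), independent)
  if (length(dependent) != nrow(S))
    stop(sprintf(paste0("independent set {%s} leaves %d dependent fluxes ",
                        "for %d pool balances; the dependent block must be ",
                        "square"),
                 paste(independent, collapse = ", "),
                 length(dependent), nrow(S)))
  Sdep <- S[, dependent, drop = FALSE]
  Sind <- S[, independent, drop = FALSE]
  if (rcond(Sdep) < 1e-12)
    stop(sprintf(paste0("non-invertible dependent block: the choice of ",
                        "independent fluxes {%s} makes the dependent ",
                        "stoichiometric submatrix singular"),
                 paste(independent, collapse = ", ")))
  M <- -solve(Sdep, Sind)
  dimnames(M) <- list(dependent, independent)
  structure(list(M = M, independent = independent, dependent = dependent,
                 S_dep = Sdep, S_indep = Sind),
            class = "mfa_dependency")
}

#' @export
print.mfa_dependency <- function(x, ...) {
  cat("Flux dependency split: v_dep = M v_indep\n")
  cat("  independent:", paste(x$independent, collapse = " "), "\n")
  cat("  dependent:  ", paste(x$dependent, collapse = " "), "\n")
  print(round(x$M, 6))
  invisible(x)
}

# fluxes that must stay nonnegative among the dependent set
NONNEG_DEPENDENT <- c("Z3", "Q4", "Q11")

#' Complete a full net flux vector from independent fluxes
#'
#' Applies the dependency matrix to a set of independent flux values and
#' checks feasibility: the irreversible fluxes `Z3`, `Q4` and `Q11` must be
#' nonnegative, as must every active input.
#'
#' @param model a [ppp_network()] model.
#' @param indep_values named numeric vector covering the independent fluxes
#'   (`Z1` defaults to the model normalization when omitted).
#' @param dep optional precomputed [split_dependency()] result.
#' @return object of class `flux_state` with components `net` (all net
#'   fluxes), `exch` (exchange magnitudes, initially zero), `uni`
#'   (unidirectional fluxes) and the generating model.
#' @export
complete_net_fluxes <- function(model, indep_values, dep = NULL) {
  if (is.null(dep)) dep <- split_dependency(model)
  if (!"Z1" %in% names(indep_values))
    indep_values <- c(Z1 = model$z1, indep_values)
  missing <- setdiff(dep$independent, names(indep_values))
  if (length(missing))
    stop("missing independent flux value(s): ",
         paste(missing, collapse = ", "))
  v_ind <- indep_values[dep$independent]
  inp <- intersect(names(v_ind), INPUT_FLUXES)
  if (length(inp) && any(v_ind[inp] < 0))
    stop("input fluxes must be nonnegative: ",
         paste(inp[v_ind[inp] < 0], collapse = ", "))
  v_dep <- drop(dep$M %*% v_ind)
  names(v_dep) <- dep$dependent
  tol <- 1e-9
  for (f in intersect(NONNEG_DEPENDENT, names(v_dep)))
    if (v_dep[f] < -tol)
      stop(sprintf("infeasible flux point: dependent flux %s = %.6g < 0",
                   f, v_dep[f]))
  v_dep[intersect(NONNEG_DEPENDENT, names(v_dep))] <-
    pmax(v_dep[intersect(NONNEG_DEPENDENT, names(v_dep))], 0)
  net <- c(v_ind, v_dep)[model$flux_symbols]
  exch <- stats::setNames(numeric(length(model$rev_names)), model$rev_names)
  st <- structure(list(net = net, exch = exch, model = model,
                       independent = dep$independent),
                  class = "flux_state")
  st$uni <- unidirectional_fluxes(st)
  st
}

#' Supplement net fluxes with exchange fluxes
#'
#' For every reversible reaction the forward flux is `max(net, 0) + exchange`
#' and the backward flux `max(-net, 0) + exchange`, so both unidirectional
#' fluxes stay nonnegative and `forward - backward` preserves the net flux.
#'
#' @param flux_state a `flux_state` from [complete_net_fluxes()].
#' @param exchange_values named nonnegative vector over (a subset of) the
#'   reversible reactions `GPI, Q2, TPI, P_ex, TKT1, TKT2, TAL`.
#' @return the updated `flux_state`.
#' @export
add_exchange <- function(flux_state, exchange_values) {
  stopifnot(inherits(flux_state, "flux_state"))
  bad <- setdiff(names(exchange_values), names(flux_state$exch))
  if (length(bad))
    stop("unknown reversible reaction(s): ", paste(bad, collapse = ", "))
  if (any(exchange_values < 0))
    stop("exchange fluxes must be nonnegative")
  flux_state$exch[names(exchange_values)] <- exchange_values
  flux_state$uni <- unidirectional_fluxes(flux_state)
  flux_state
}

unidirectional_fluxes <- function(state) {
  model <- state$model
  uni <- numeric(0)
  for (r in model$reactions) {
    v <- state$net[[r$flux]]
    if (r$reversible) {
      e <- state$exch[[r$name]]
      uni[paste0(r$name, ".f")] <- max(v, 0) + e
      uni[paste0(r$name, ".b")] <- max(-v, 0) + e
    } else {
      uni[r$name] <- v
    }
  }
  for (nm in model$active_inputs) uni[nm] <- state$net[[nm]]
  uni
}

#' @export
print.flux_state <- function(x, ...) {
  cat("Flux state (net fluxes, units of Z1 =", x$model$z1, ")\n")
  print(round(x$net, 4))
  if (any(x$exch > 0)) {
    cat("Exchange fluxes:\n")
    print(round(x$exch[x$exch > 0], 4))
  }
  invisible(x)
}

#' Characterize the permissible flux space
#'
#' The independent net fluxes are only restricted by nonnegativity of the
#' dependent irreversible fluxes `Z3`, `Q4` and `Q11`.  With `Z1` fixed,
#' the free dimension is 2 (closed system) plus one per active input.
#'
#' @param model a [ppp_network()] model.
#' @param box_net,box_input sampling bounds for independent net fluxes and
#'   input fluxes (units of `Z1 = 100`).
#' @return object of class `permissible_space`: `dimension`, the inequality
#'   rows `A` (over the independent fluxes, each row required `>= 0`), and
#'   the bounding `box` used for sampling.
#' @export
permissible_space <- function(model, box_net = c(-300, 300),
                              box_input = c(0, 100)) {
  dep <- split_dependency(model)
  A <- dep$M[intersect(NONNEG_DEPENDENT, dep$dependent), , drop = FALSE]
  free <- setdiff(dep$independent, "Z1")
  box <- sapply(free, function(f)
    if (f %in% INPUT_FLUXES) box_input else box_net)
  dimnames(box) <- list(c("lower", "upper"), free)
  structure(list(dimension = length(free), free = free, A = A,
                 independent = dep$independent, box = box,
                 z1 = model$z1, dep = dep),
            class = "permissible_space")
}

#' @export
print.permissible_space <- function(x, ...) {
  cat(sprintf("Permissible flux space: dimension %d (free: %s)\n",
              x$dimension, paste(x$free, collapse = ", ")))
  cat("Constraints (rows required >= 0 at Z1 =", x$z1, "):\n")
  print(round(x$A, 6))
  invisible(x)
}

#' Sample uniformly from the permissible flux polytope
#'
#' Rejection sampling from the bounding box of the independent fluxes;
#' accepted points satisfy `Z3, Q4, Q11 >= 0` and are completed to full
#' flux states.
#'
#' @param model a [ppp_network()] model.
#' @param n number of samples.
#' @param seed optional integer seed for reproducibility.
#' @param space optional precomputed [permissible_space()].
#' @return list of `n` `flux_state` objects.
#' @export
sample_feasible <- function(model, n, seed = NULL, space = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(space)) space <- permissible_space(model)
  out <- vector("list", n)
  got <- 0L
  lo <- space$box["lower", ]; hi <- space$box["upper", ]
  k <- length(space$free)
  while (got < n) {
    m <- max(2L * (n - got), 64L)
    pts <- matrix(stats::runif(m * k, rep(lo, each = m), rep(hi, each = m)),
                  m, k, dimnames = list(NULL, space$free))
    full <- cbind(Z1 = space$z1, pts)[, space$independent, drop = FALSE]
    ok <- which(apply(full %*% t(space$A) >= 0, 1, all))
    for (i in ok) {
      if (got == n) break
      got <- got + 1L
      out[[got]] <- complete_net_fluxes(model, full[i, ], dep = space$dep)
    }
  }
  out
}

#' Serialize a network model to JSON
#'
#' @param model a [ppp_network()] model.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
network_to_json <- function(model, path = NULL) {
  rxs <- lapply(model$reactions, function(r)
    list(name = r$name, flux = r$flux, reversible = r$reversible,
         substrates = r$substrates, products = r$products,
         origin = lapply(r$origin, function(o)
           list(sub = unname(o[, "sub"]), pos = unname(o[, "pos"])))))
  obj <- list(pools = as.list(model$pools),
              reactions = unname(rxs),
              active_inputs = model$active_inputs,
              z1 = model$z1, pX = model$pX, pR = model$pR)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a network model from JSON
#'
#' Currently supports networks of the default shape (same pool set and
#' reaction list, possibly different inputs and pentose split).
#'
#' @param path file path or JSON string produced by [network_to_json()].
#' @return a `ppp_network` model.
#' @export
network_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ppp_network(active_inputs = unlist(obj$active_inputs %||% character()),
              pX = obj$pX, pR = obj$pR, z1 = obj$z1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a per-sample flux table
#'
#' CSV with columns `sample_id, flux_symbol, value, lower_ci, upper_ci`.
#'
#' @param x data frame with the columns above.
#' @param path CSV path.
#' @return `read_flux_table` returns the data frame.
#' @export
write_flux_table <- function(x, path) {
  need <- c("sample_id", "flux_symbol", "value", "lower_ci", "upper_ci")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("flux table lacks column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(x[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flux_table
#' @export
read_flux_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "flux_symbol", "value", "lower_ci", "upper_ci")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("flux table lacks column(s): ", paste(missing, collapse = ", "))
  x
}
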