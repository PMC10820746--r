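# Elementary metabolite unit (EMU) simulation of steady-state carbon mass
# distributions (CMDs) for the GC-MS fragment panel.

emu_id <- function(pool, pos) paste0(pool, "|", paste(pos, collapse = ","))

emu_parse <- function(id) {
  sp <- strsplit(id, "|", fixed = TRUE)[[1]]
  list(pool = sp[1], pos = as.integer(strsplit(sp[2], ",")[[1]]))
}

# Expand reactions into unidirectional "instances".  Each instance carries a
# flux key (matching names of flux_state$uni), a stoichiometric weight, its
# substrate pools and, per product pool, an atom-origin table whose row r
# gives (substrate index, substrate carbon) for product carbon r.
flux_instances <- function(model) {
  inst <- list()
  add <- function(key, weight, substrates, products, origin) {
    inst[[length(inst) + 1L]] <<- list(key = key, weight = weight,
                                       substrates = substrates,
                                       products = products, origin = origin)
  }
  for (r in model$reactions) {
    if (r$reversible) {
      add(paste0(r$name, ".f"), 1, r$substrates, r$products, r$origin)
      # invert the atom maps for the backward direction
      borigin <- lapply(r$substrates, function(s)
        matrix(NA_integer_, model$pools[[s]], 2,
               dimnames = list(NULL, c("sub", "pos"))))
      names(borigin) <- r$substrates
      for (pi in seq_along(r$products)) {
        p <- r$products[pi]
        o <- r$origin[[p]]
        for (row in seq_len(nrow(o))) {
          s <- r$substrates[o[row, "sub"]]
          borigin[[s]][o[row, "pos"], ] <- c(pi, row)
        }
      }
      for (s in r$substrates)
        if (anyNA(borigin[[s]]))
          stop("reaction ", r$name, " atom map is not a bijection")
      add(paste0(r$name, ".b"), 1, r$products, r$substrates, borigin)
    } else {
      add(r$name, 1, r$substrates, r$products, r$origin)
    }
  }
  for (nm in model$active_inputs) {
    def <- model$input_defs[[nm]]
    src <- ext_pool(def$n_carbons)
    for (p in names(def$products)) {
      n <- model$pools[[p]]
      add(nm, def$products[[p]], src, p,
          stats::setNames(list(cbind(sub = 1L, pos = seq_len(n))), p))
    }
  }
  inst
}

# flux keys of instances consuming each pool (sinks included)
pool_consumption <- function(model, instances) {
  cons <- lapply(names(model$pools), function(p) {
    hits <- Filter(function(i) p %in% i$substrates, instances)
    list(keys = vapply(hits, `[[`, "", "key"),
         w = vapply(hits, `[[`, 0, "weight"))
  })
  names(cons) <- names(model$pools)
  cons
}

#' Carbon transition table of the default network
#'
#' Explicit atom maps of every unidirectional reaction: which substrate
#' carbon ends up on which product carbon.  The C1 of G6P lost in the
#' oxidative PPP step is reported as a `CO2` row.
#'
#' @param model a [ppp_network()] model.
#' @return data frame with columns `reaction, flux_key, sub_pool,
#'   sub_carbon, prod_pool, prod_carbon`.
#' @export
carbon_transition_table <- function(model = ppp_network()) {
  rows <- list()
  for (i in flux_instances(model)) {
    mapped <- list()
    for (p in i$products) {
      o <- i$origin[[p]]
      for (r in seq_len(nrow(o))) {
        s <- i$substrates[o[r, "sub"]]
        rows[[length(rows) + 1L]] <-
          data.frame(flux_key = i$key, sub_pool = s,
                     sub_carbon = o[r, "pos"], prod_pool = p,
                     prod_carbon = r)
        mapped[[s]] <- c(mapped[[s]], o[r, "pos"])
      }
    }
    if (!length(i$products)) next   # drains export intact skeletons
    for (si in seq_along(i$substrates)) {   # untracked sink carbons (CO2)
      s <- i$substrates[si]
      if (is_external(s)) next
      lost <- setdiff(seq_len(model$pools[[s]]), mapped[[s]])
      for (c in lost)
        rows[[length(rows) + 1L]] <-
          data.frame(flux_key = i$key, sub_pool = s, sub_carbon = c,
                     prod_pool = "CO2", prod_carbon = NA_integer_)
    }
  }
  out <- do.call(rbind, rows)
  out$reaction <- sub("\\.[fb]$", "", out$flux_key)
  out[, c("reaction", "flux_key", "sub_pool", "sub_carbon",
          "prod_pool", "prod_carbon")]
}

#' Decompose fragment targets into an EMU system
#'
#' Walks backward from the fragments' carbon ranges through the atom maps,
#' collecting the minimal set of EMUs (pool carbon subsets) whose mass
#' distributions determine the targets, organized in blocks of ascending
#' size.  Condensation reactions couple an EMU to the convolution of two
#' strictly smaller EMUs, so the blocks can be solved in ascending order as
#' linear systems.
#'
#' @param model a [ppp_network()] model.
#' @param fragments fragment definition table (see [mfa_fragments()]).
#' @return object of class `emu_system`.
#' @export
emu_decompose <- function(model, fragments) {
  instances <- flux_instances(model)
  targets <- fragment_targets(model, fragments)
  # producers of each pool
  producers <- lapply(names(model$pools), function(p)
    Filter(function(i) p %in% i$products, instances))
  names(producers) <- names(model$pools)

  terms <- list()      # emu id -> list of production terms
  queue <- character()
  for (tg in targets)
    for (part in tg$parts)
      if (!is_external(part$pool))
        queue <- c(queue, emu_id(part$pool, part$pos))
  queue <- unique(queue)
  seen <- character()
  while (length(queue)) {
    id <- queue[[1]]; queue <- queue[-1]
    if (id %in% seen) next
    seen <- c(seen, id)
    e <- emu_parse(id)
    if (max(e$pos) > model$pools[[e$pool]])
      stop("fragment carbon range exceeds pool size for ", e$pool)
    tl <- list()
    for (i in producers[[e$pool]]) {
      o <- i$origin[[e$pool]][e$pos, , drop = FALSE]
      srcs <- character()
      for (si in sort(unique(o[, "sub"]))) {
        sp <- i$substrates[si]
        srcs <- c(srcs, emu_id(sp, sort(o[o[, "sub"] == si, "pos"])))
      }
      tl[[length(tl) + 1L]] <- list(key = i$key, weight = i$weight,
                                    srcs = srcs)
      for (s in srcs) {
        spool <- emu_parse(s)$pool
        if (!is_external(spool) && !(s %in% seen)) queue <- c(queue, s)
      }
    }
    terms[[id]] <- tl
  }
  sizes <- vapply(seen, function(id) length(emu_parse(id)$pos), 0L)
  blocks <- lapply(sort(unique(sizes)), function(k) {
    ids <- seen[sizes == k]
    tl <- terms[ids]
    # pre-classify terms: same-size internal sources enter the system
    # matrix, everything else the (known) right-hand side
    for (i in seq_along(tl)) {
      tl[[i]] <- lapply(tl[[i]], function(tm) {
        tm$j <- if (length(tm$srcs) == 1L) match(tm$srcs, ids) else NA_integer_
        tm
      })
    }
    list(size = k, unknowns = ids,
         pools = vapply(ids, function(id) emu_parse(id)$pool, ""),
         terms = tl)
  })
  # compiled evaluation plan: integer-indexed storage slots and flat term
  # arrays, so the per-draw solve avoids name lookups
  unk_ids <- unlist(lapply(blocks, `[[`, "unknowns"), use.names = FALSE)
  ext_ids <- character()
  for (b in blocks)
    for (tl in b$terms)
      for (tm in tl)
        for (src in tm$srcs)
          if (is_external(emu_parse(src)$pool))
            ext_ids <- c(ext_ids, src)
  ext_ids <- unique(ext_ids)
  all_ids <- c(unk_ids, ext_ids)
  idx_of <- stats::setNames(seq_along(all_ids), all_ids)
  pblocks <- lapply(blocks, function(b) {
    m <- length(b$unknowns)
    A_i <- integer(); A_j <- integer(); A_key <- character(); A_w <- numeric()
    R_i <- integer(); R_key <- character(); R_w <- numeric()
    R_s1 <- integer(); R_s2 <- integer()
    for (i in seq_len(m)) {
      for (tm in b$terms[[i]]) {
        if (!is.na(tm$j)) {
          A_i <- c(A_i, i); A_j <- c(A_j, tm$j)
          A_key <- c(A_key, tm$key); A_w <- c(A_w, tm$weight)
        } else {
          R_i <- c(R_i, i); R_key <- c(R_key, tm$key); R_w <- c(R_w, tm$weight)
          R_s1 <- c(R_s1, idx_of[[tm$srcs[1]]])
          R_s2 <- c(R_s2, if (length(tm$srcs) > 1L) idx_of[[tm$srcs[2]]]
                    else NA_integer_)
        }
      }
    }
    # group duplicate A cells for vectorized accumulation
    if (length(A_i)) {
      cell_key <- paste(A_i, A_j)
      ucell <- !duplicated(cell_key)
      gid <- match(cell_key, cell_key[ucell])
      ord <- order(gid[ucell])           # rowsum returns groups in order
      A_cells <- cbind(A_i[ucell], A_j[ucell])[ord, , drop = FALSE]
    } else {
      gid <- integer(); A_cells <- matrix(0L, 0, 2)
    }
    list(size = b$size, m = m, pools = unname(b$pools),
         slots = unname(idx_of[b$unknowns]),
         A_key = A_key, A_w = A_w, A_gid = gid, A_cells = A_cells,
         R_i = R_i, R_key = R_key, R_w = R_w, R_s1 = R_s1, R_s2 = R_s2)
  })
  plan <- list(n_ids = length(all_ids), idx_of = idx_of,
               ext_ids = ext_ids, ext_slots = unname(idx_of[ext_ids]),
               blocks = pblocks)
  structure(list(model = model, instances = instances,
                 consumption = pool_consumption(model, instances),
                 blocks = blocks, targets = targets,
                 fragments = fragments, plan = plan),
            class = "emu_system")
}

# per-tracer distributions of the external-source EMUs, in plan slot order
make_ext_dists <- function(system, tracers) {
  lapply(tracers, function(mix)
    lapply(system$plan$ext_ids, function(id) {
      e <- emu_parse(id)
      input_emu_dist(mix, e$pool, e$pos)
    }))
}

#' @export
print.emu_system <- function(x, ...) {
  cat("EMU system for", length(x$targets), "fragment target(s)\n")
  for (b in x$blocks)
    cat(sprintf("  size %d: %d EMU(s)\n", b$size, length(b$unknowns)))
  invisible(x)
}

# map fragments to simulation targets; each target is a weighted mixture of
# pool EMUs (weight "flux" = proportional to sub-pool turnover)
fragment_targets <- function(model, fragments) {
  met_pool <- c(G6P = "G6P", F6P = "F6P", DHAP = "DHAP", GAP = "GAP",
                `3PG` = "GAP", R5P = "R5P", S7P = "S7P", E4P = "E4P",
                `6PG` = "G6P", FBP = "F6P", `F-1,6-BP` = "F6P")
  out <- list()
  for (r in seq_len(nrow(fragments))) {
    met <- fragments$metabolite[r]
    pos <- fragments$carbon_first[r]:fragments$carbon_last[r]
    id <- fragment_id(fragments[r, ])
    if (met == "Glucose") {
      parts <- list(list(pool = EXT_GLUCOSE, pos = pos, w = 1))
    } else if (met == "P5P") {
      parts <- list(list(pool = "XuP", pos = pos, w = "flux"),
                    list(pool = "R5P", pos = pos, w = "flux"))
    } else if (met %in% names(met_pool)) {
      parts <- list(list(pool = met_pool[[met]], pos = pos, w = 1))
    } else stop("no pool mapping for metabolite ", met)
    for (p in parts)
      if (!is_external(p$pool) && max(p$pos) > model$pools[[p$pool]])
        stop("carbon range of ", id, " exceeds the ", p$pool, " pool")
    out[[id]] <- list(id = id, parts = parts)
  }
  out
}

# mass distribution of an external-source EMU under a tracer mixture
input_emu_dist <- function(mixture, pool, pos) {
  if (pool == EXT_GLUCOSE) {
    out <- 0
    for (sp in mixture$species) {
      d <- 1
      for (p in sp$probs[pos]) d <- convolve_dist(d, c(1 - p, p))
      out <- out + sp$fraction * d
    }
    return(out)
  }
  a <- mixture$natural
  d <- 1
  for (i in seq_along(pos)) d <- convolve_dist(d, c(1 - a, a))
  d
}

convolve_dist <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

# turnover weights of the co-eluting pentose phosphate sub-pools
p5p_flux_weights <- function(uni, consumption) {
  w <- vapply(c("XuP", "R5P"), function(p)
    sum(uni[consumption[[p]]$keys] * consumption[[p]]$w), 0)
  if (sum(w) <= 0) stop("pentose sub-pools carry no flux")
  w / sum(w)
}

#' Simulate steady-state fragment CMDs via the EMU cascade
#'
#' Solves the EMU balance systems in ascending size for the given flux state
#' and tracer mixture(s) and returns the carbon mass distribution of every
#' fragment.  The co-eluting pentose phosphate measurement (`P5P C1-C5`) is
#' returned as a mixture of the XuP and R5P sub-pool distributions.
#'
#' @param flux_state a feasible `flux_state` with unidirectional fluxes
#'   (see [complete_net_fluxes()] and [add_exchange()]).
#' @param tracer a `tracer_mixture` or a named list of mixtures (a parallel
#'   tracer panel, see [default_tracer_panel()]).
#' @param fragments fragment table, default the 7-fragment MFA panel.
#' @param system optional precomputed [emu_decompose()] result.
#' @param p5p_weights `"flux"` (default: proportional to sub-pool turnover)
#'   or a numeric vector `c(XuP =, R5P =)` of fixed mixing weights.
#' @param ext_cache optional per-tracer list of external-source EMU
#'   distributions from `make_ext_dists()` (used by the samplers to avoid
#'   recomputation; only valid for a fixed tracer list).
#' @return for a single mixture, a named list `fragment id -> CMD`; for a
#'   panel, a named list of such lists (class `simulated_cmds`).
#' @export
simulate_cmds <- function(flux_state, tracer, fragments = mfa_fragments(),
                          system = NULL, p5p_weights = "flux",
                          ext_cache = NULL) {
  stopifnot(inherits(flux_state, "flux_state"))
  single <- inherits(tracer, "tracer_mixture")
  tracers <- if (single) list(tracer = tracer) else tracer
  if (is.null(system)) system <- emu_decompose(flux_state$model, fragments)
  uni <- flux_state$uni
  if (any(uni < -1e-9)) stop("unidirectional fluxes must be nonnegative")
  dists <- solve_emu_dists(system, uni, tracers, ext_cache)
  cons <- system$consumption
  if (identical(p5p_weights, "flux")) {
    p5w <- p5p_flux_weights(uni, cons)
  } else {
    p5w <- p5p_weights[c("XuP", "R5P")] / sum(p5p_weights[c("XuP", "R5P")])
  }
  out <- lapply(seq_along(tracers), function(ti) {
    res <- lapply(system$targets, function(tg) {
      cmd <- 0
      for (part in tg$parts) {
        w <- if (identical(part$w, "flux")) p5w[[part$pool]] else part$w
        d <- if (is_external(part$pool))
          input_emu_dist(tracers[[ti]], part$pool, part$pos)
        else dists[[ti]][[system$plan$idx_of[[emu_id(part$pool, part$pos)]]]]
        cmd <- cmd + w * d
      }
      cmd / sum(cmd)
    })
    names(res) <- names(system$targets)
    res
  })
  names(out) <- names(tracers)
  if (single) return(out[[1]])
  structure(out, class = "simulated_cmds")
}

# core linear-algebra cascade over the compiled plan; returns per-tracer
# slot-indexed lists of EMU mass distributions
solve_emu_dists <- function(system, uni, tracers, ext_cache = NULL) {
  nt <- length(tracers)
  plan <- system$plan
  outflux <- vapply(names(system$model$pools), function(p)
    sum(uni[system$consumption[[p]]$keys] * system$consumption[[p]]$w), 0)
  if (is.null(ext_cache)) ext_cache <- make_ext_dists(system, tracers)
  stores <- vector("list", nt)
  for (ti in seq_len(nt)) {
    st <- vector("list", plan$n_ids)
    st[plan$ext_slots] <- ext_cache[[ti]]
    stores[[ti]] <- st
  }
  for (b in plan$blocks) {
    k <- b$size
    dg <- outflux[b$pools]
    if (any(dg <= 0))
      stop("pool without outgoing flux makes the EMU system singular: ",
           paste(unique(b$pools[dg <= 0]), collapse = ", "))
    A <- diag(dg, nrow = b$m)
    if (length(b$A_gid)) {
      av <- rowsum(unname(uni[b$A_key]) * b$A_w, b$A_gid)
      A[b$A_cells] <- A[b$A_cells] - as.vector(av)
    }
    R <- matrix(0, b$m, (k + 1L) * nt)
    rv <- unname(uni[b$R_key]) * b$R_w
    for (ti in seq_len(nt)) {
      st <- stores[[ti]]
      off <- (ti - 1L) * (k + 1L)
      cols <- (off + 1L):(off + k + 1L)
      for (q in seq_along(rv)) {
        v <- rv[q]
        if (v == 0) next
        d <- st[[b$R_s1[q]]]
        if (!is.na(b$R_s2[q])) d <- convolve_dist(d, st[[b$R_s2[q]]])
        R[b$R_i[q], cols] <- R[b$R_i[q], cols] + v * d
      }
    }
    X <- solve(A, R)
    for (ti in seq_len(nt)) {
      off <- (ti - 1L) * (k + 1L)
      for (i in seq_len(b$m)) {
        d <- X[i, (off + 1L):(off + k + 1L)]
        d[d < 0 & d > -1e-9] <- 0
        stores[[ti]][[b$slots[i]]] <- d / sum(d)
      }
    }
  }
  stores
}

#' Derived proxy patterns for LC-MS-compatible model configurations
#'
#' Adds the 6-phosphogluconate (`6PG C1-C6`) and fructose-1,6-bisphosphate
#' (`FBP C1-C6`) patterns estimated from the simulated pools: 6PG is proxied
#' by the G6P skeleton; FBP either by the F6P skeleton (`"passthrough"`,
#' default) or by the convolution of the two triose distributions
#' (`"triose_convolution"`).
#'
#' @param simulated result of [simulate_cmds()] containing `G6P C1-C6` and
#'   `F6P C1-C6` (and, for the convolution proxy, `DHAP C1-C3` and
#'   `3PG C1-C3`).
#' @param fbp proxy rule for FBP.
#' @return the input with `6PG C1-C6` and `FBP C1-C6` entries added.
#' @export
derived_patterns <- function(simulated,
                             fbp = c("passthrough", "triose_convolution")) {
  fbp <- match.arg(fbp)
  one <- function(res) {
    if (is.null(res[["G6P C1-C6"]]) || is.null(res[["F6P C1-C6"]]))
      stop("derived patterns need simulated G6P C1-C6 and F6P C1-C6")
    res[["6PG C1-C6"]] <- res[["G6P C1-C6"]]
    res[["FBP C1-C6"]] <- if (fbp == "passthrough") {
      res[["F6P C1-C6"]]
    } else {
      if (is.null(res[["DHAP C1-C3"]]) || is.null(res[["3PG C1-C3"]]))
        stop("triose convolution proxy needs DHAP C1-C3 and 3PG C1-C3")
      convolve_dist(res[["DHAP C1-C3"]], res[["3PG C1-C3"]])
    }
    res
  }
  if (inherits(simulated, "simulated_cmds")) {
    out <- lapply(simulated, one)
    class(out) <- "simulated_cmds"
    out
  } else one(simulated)
}
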