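# Brute-force positional-isotopomer reference solver.  Maintains the full
# 2^n isotopomer distribution of every pool and iterates the steady-state
# balance to a fixed point; used as an independent check of the EMU cascade.

# bit value of carbon `pos` (1-based) across states 0..2^n-1
state_bits <- function(n, pos) {
  states <- 0:(2L^n - 1L)
  (states %/% 2L^(pos - 1L)) %% 2L
}

# per-substrate additive contribution to the product state index
origin_index <- function(origin, sub_index, n_sub) {
  rows <- which(origin[, "sub"] == sub_index)
  f <- integer(2L^n_sub)
  for (r in rows)
    f <- f + state_bits(n_sub, origin[r, "pos"]) * 2L^(r - 1L)
  f
}

ext_n_carbons <- function(pool)
  if (pool == EXT_GLUCOSE) 6L else as.integer(sub("EXT:unl", "", pool))

# full 2^6 isotopomer distribution of the glucose tracer mixture
iso_input_dist <- function(mixture, pool) {
  n <- ext_n_carbons(pool)
  if (pool == EXT_GLUCOSE) {
    out <- numeric(2L^n)
    for (sp in mixture$species) {
      d <- 1
      for (p in sp$probs) d <- c(d * (1 - p), d * p)
      out <- out + sp$fraction * d
    }
    return(out)
  }
  a <- mixture$natural
  d <- 1
  for (i in seq_len(n)) d <- c(d * (1 - a), d * a)
  d
}

aggregate_by <- function(values, index, n_out) {
  out <- numeric(n_out)
  agg <- rowsum(values, index)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Full-isotopomer reference simulation of fragment CMDs
#'
#' Independent of the EMU cascade: tracks the complete positional-isotopomer
#' distribution (2^n states) of every pool and iterates the steady-state
#' balance equations to a fixed point, then marginalizes fragment carbon
#' mass distributions.  Intended for validation on the default-size network.
#'
#' @inheritParams simulate_cmds
#' @param tol fixed-point tolerance on the maximum isotopomer change per
#'   sweep.
#' @param max_iter iteration cap; exceeding it raises an error (e.g. for
#'   flux states with closed label loops such as `Q4 = Q11 = 0`).
#' @return same structure as [simulate_cmds()].
#' @export
isotopomer_oracle <- function(flux_state, tracer,
                              fragments = mfa_fragments(),
                              p5p_weights = "flux",
                              tol = 1e-13, max_iter = 50000) {
  stopifnot(inherits(flux_state, "flux_state"))
  single <- inherits(tracer, "tracer_mixture")
  tracers <- if (single) list(tracer = tracer) else tracer
  model <- flux_state$model
  uni <- flux_state$uni
  instances <- flux_instances(model)
  cons <- pool_consumption(model, instances)
  outflux <- vapply(names(model$pools), function(p)
    sum(uni[cons[[p]]$keys] * cons[[p]]$w), 0)
  if (any(outflux <= 0))
    stop("closed label loop: pool(s) without outgoing flux: ",
         paste(names(outflux)[outflux <= 0], collapse = ", "),
         " (e.g. Q4 = Q11 = 0)")

  # precompile production terms: per pool, (flux key, weight, substrate
  # pools, additive state-index vectors)
  prod_terms <- lapply(names(model$pools), function(p) {
    terms <- list()
    for (i in instances) {
      if (!p %in% i$products) next
      o <- i$origin[[p]]
      fs <- lapply(seq_along(i$substrates), function(si) {
        s <- i$substrates[si]
        n_s <- if (is_external(s)) ext_n_carbons(s) else model$pools[[s]]
        origin_index(o, si, n_s)
      })
      terms[[length(terms) + 1L]] <-
        list(key = i$key, w = i$weight, subs = i$substrates, fs = fs)
    }
    terms
  })
  names(prod_terms) <- names(model$pools)

  targets <- fragment_targets(model, fragments)
  p5w <- if (identical(p5p_weights, "flux")) {
    p5p_flux_weights(uni, cons)
  } else p5p_weights[c("XuP", "R5P")] / sum(p5p_weights[c("XuP", "R5P")])

  out <- lapply(tracers, function(mix) {
    ext <- list()
    dist <- lapply(names(model$pools), function(p) {
      d <- numeric(2L^model$pools[[p]]); d[1] <- 1; d
    })
    names(dist) <- names(model$pools)
    get_dist <- function(s) {
      if (is_external(s)) {
        if (is.null(ext[[s]])) ext[[s]] <<- iso_input_dist(mix, s)
        ext[[s]]
      } else dist[[s]]
    }
    for (it in seq_len(max_iter)) {
      delta <- 0
      for (p in names(model$pools)) {
        acc <- numeric(2L^model$pools[[p]])
        for (tm in prod_terms[[p]]) {
          v <- uni[[tm$key]] * tm$w
          if (v == 0) next
          if (length(tm$subs) == 1L) {
            d <- get_dist(tm$subs[1])
            acc <- acc + v * aggregate_by(d, tm$fs[[1]] + 1L, length(acc))
          } else {
            joint <- outer(get_dist(tm$subs[1]), get_dist(tm$subs[2]))
            idx <- outer(tm$fs[[1]], tm$fs[[2]], `+`) + 1L
            acc <- acc + v * aggregate_by(as.vector(joint), as.vector(idx),
                                          length(acc))
          }
        }
        # renormalize: the simplex fixed point is neutrally stable in the
        # mass direction and condensation terms amplify rounding drift
        new <- acc / sum(acc)
        delta <- max(delta, max(abs(new - dist[[p]])))
        dist[[p]] <- new
      }
      if (delta < tol) break
      if (it == max_iter)
        stop("isotopomer fixed point did not converge in ", max_iter,
             " iterations (flagging a closed or degenerate label loop)")
    }
    res <- lapply(targets, function(tg) {
      cmd <- 0
      for (part in tg$parts) {
        w <- if (identical(part$w, "flux")) p5w[[part$pool]] else part$w
        if (is_external(part$pool)) {
          d <- input_emu_dist(mix, part$pool, part$pos)
        } else {
          full <- dist[[part$pool]]
          mass <- 0L
          for (c in part$pos)
            mass <- mass + state_bits(model$pools[[part$pool]], c)
          d <- aggregate_by(full, mass + 1L, length(part$pos) + 1L)
        }
        cmd <- cmd + w * d
      }
      cmd / sum(cmd)
    })
    names(res) <- names(targets)
    res
  })
  names(out) <- names(tracers)
  if (single) return(out[[1]])
  structure(out, class = "simulated_cmds")
}
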