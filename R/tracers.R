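# Glucose tracer species and mixtures.

#' Natural 13C abundance used throughout the package
#' @export
NATURAL_13C <- 0.0107

#' Define a glucose tracer species
#'
#' A species is a fraction of the glucose pool with a per-carbon-position
#' probability of being 13C.  Labeled positions carry the isotopic purity of
#' the tracer; all other positions carry the natural 13C abundance.
#'
#' @param fraction mole fraction of the glucose pool.
#' @param label_positions integer vector of labeled carbon positions (1-6);
#'   empty for unlabeled glucose.
#' @param purity atom fraction 13C at the labeled positions.
#' @param natural 13C probability at unlabeled positions.
#' @return list with `fraction` and `probs` (length 6).
#' @export
tracer_species <- function(fraction, label_positions = integer(),
                           purity = 0.99, natural = NATURAL_13C) {
  stopifnot(fraction >= 0, fraction <= 1,
            all(label_positions %in% 1:6),
            purity >= 0, purity <= 1)
  probs <- rep(natural, 6)
  probs[label_positions] <- purity
  list(fraction = fraction, probs = probs)
}

#' Combine tracer species into a mixture
#'
#' @param ... tracer species from [tracer_species()]; their fractions must
#'   sum to 1.
#' @param natural natural 13C abundance, also used for the unlabeled input
#'   fluxes of the network.
#' @return object of class `tracer_mixture`.
#' @export
tracer_mixture <- function(..., natural = NATURAL_13C) {
  species <- list(...)
  fr <- vapply(species, `[[`, 0, "fraction")
  if (abs(sum(fr) - 1) > 1e-9)
    stop("species fractions must sum to 1 (got ", sum(fr), ")")
  structure(list(species = species, natural = natural),
            class = "tracer_mixture")
}

#' @export
print.tracer_mixture <- function(x, ...) {
  cat("Tracer mixture (natural 13C =", x$natural, ")\n")
  for (sp in x$species)
    cat(sprintf("  %.3f  [%s]\n", sp$fraction,
                paste(format(sp$probs, digits = 3), collapse = " ")))
  invisible(x)
}

#' The parallel tracer panel
#'
#' Three mixtures, each 50% labeled glucose plus 50% unlabeled glucose:
#' `[1,2-13C]` (purity 0.99), `[4,5,6-13C]` (purity 0.995) and `[U-13C]`
#' (purity 0.99).  Unlabeled positions and unlabeled glucose carry natural
#' 13C abundance.
#'
#' @param natural natural 13C abundance.
#' @return named list of three `tracer_mixture` objects.
#' @export
default_tracer_panel <- function(natural = NATURAL_13C) {
  mix <- function(pos, purity)
    tracer_mixture(tracer_species(0.5, pos, purity, natural),
                   tracer_species(0.5, integer(), natural = natural),
                   natural = natural)
  list("1,2-13C"   = mix(1:2, 0.99),
       "4,5,6-13C" = mix(4:6, 0.995),
       "U-13C"     = mix(1:6, 0.99))
}
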