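# Precision-score comparison of measurement designs and PCA of flux tables
# with varimax rotation and jackknife validation.

#' Default flux set for precision scoring
#'
#' The twelve fluxes over which the aggregate precision score is averaged:
#' the oxidative PPP, the non-oxidative PPP net fluxes, the drains, the
#' glycolytic fluxes, the pentose exchange and the S7P and hexose inputs.
#' @export
PRECISION_FLUXES <- c("Z3", "dTAL", "dTKT1", "dTKT2", "Q4", "Q11",
                      "dGPI", "dTPI", "dQ2", "dP_ex", "S_Input", "F_Input")

#' Precision score of a single flux
#'
#' Squared ratio of the reference to the experimental central 95% interval
#' width: values above 1 mean the experimental design determines the flux
#' more precisely than the reference.
#'
#' @param ci_ref,ci_exp length-2 vectors `(2.5%, 97.5%)`.
#' @return scalar score.
#' @export
precision_score_flux <- function(ci_ref, ci_exp) {
  wr <- diff(range(ci_ref)); we <- diff(range(ci_exp))
  if (we <= 0) stop("experimental interval has zero width")
  if (wr <= 0) stop("reference interval has zero width")
  (wr / we)^2
}

#' Aggregate precision score
#'
#' Arithmetic mean of per-flux precision scores.
#'
#' @param p_values numeric vector of per-flux scores.
#' @return scalar.
#' @export
precision_score_metric <- function(p_values) {
  if (!length(p_values)) stop("no precision scores supplied")
  mean(p_values)
}

#' Precision report of an experimental design against a reference
#'
#' Computes per-flux precision scores from the 2.5-97.5% interval columns of
#' two flux tables (see [flux_table()]) and their aggregate mean.
#'
#' @param ref,exp flux tables with columns `flux_symbol, ci2.5, ci97.5`.
#' @param fluxes flux set to score (defaults to the fluxes present in both
#'   tables among [PRECISION_FLUXES]).
#' @return list of class `precision_report` with `p` (per flux), `P`
#'   (aggregate) and the flux list.
#' @export
precision_report <- function(ref, exp, fluxes = NULL) {
  if (is.null(fluxes))
    fluxes <- intersect(PRECISION_FLUXES,
                        intersect(ref$flux_symbol, exp$flux_symbol))
  miss_r <- setdiff(fluxes, ref$flux_symbol)
  miss_e <- setdiff(fluxes, exp$flux_symbol)
  if (length(miss_r) || length(miss_e))
    stop("flux(es) missing from ",
         if (length(miss_r)) paste("reference:",
                                   paste(miss_r, collapse = ", ")),
         if (length(miss_e)) paste(" experiment:",
                                   paste(miss_e, collapse = ", ")))
  p <- vapply(fluxes, function(f) {
    r <- ref[ref$flux_symbol == f, ][1, ]
    e <- exp[exp$flux_symbol == f, ][1, ]
    precision_score_flux(c(r$ci2.5, r$ci97.5), c(e$ci2.5, e$ci97.5))
  }, 0)
  structure(list(p = p, P = precision_score_metric(p), fluxes = fluxes),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("Precision score P = %.3f over %d fluxes\n", x$P,
              length(x$fluxes)))
  print(round(x$p, 3))
  invisible(x)
}

#' Default flux columns for the flux-table PCA
#' @export
PCA_FLUXES <- c("Z3", "Q4", "S_Input", "Q11", "dQ2", "dTAL",
                "dTKT1", "dTKT2", "dGPI")

#' Principal component analysis of a per-sample flux table
#'
#' Columns are standardized to zero mean and unit variance; the SVD-based
#' principal components are computed, the leading `n_components` loadings
#' are varimax-rotated, and the rotated loadings are additionally rescaled
#' by each flux's original standard deviation (back to flux units).
#' Variance shares are reported from the unrotated solution.
#'
#' @param flux_table numeric matrix or data frame, samples x fluxes.
#' @param n_components number of components retained for rotation.
#' @return object of class `flux_pca`: `variance_share`, `loadings_raw`
#'   (unrotated, scaled by component sd), `loadings_rotated`,
#'   `loadings_rescaled`, `rotation_matrix`, `scores`, `column_sd`,
#'   `column_mean`.
#' @export
pca_fluxes <- function(flux_table, n_components = 3) {
  X <- as.matrix(flux_table)
  if (!is.numeric(X)) stop("flux table must be numeric")
  if (nrow(X) < 3) stop("PCA needs at least 3 samples")
  if (nrow(X) <= n_components)
    stop("fewer samples than retained components")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant flux column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  share <- pc$sdev^2 / sum(pc$sdev^2)
  k <- n_components
  # loadings in the factor-analytic sense: eigenvector * component sd
  L <- pc$rotation[, 1:k, drop = FALSE] %*% diag(pc$sdev[1:k], k)
  vm <- stats::varimax(L, normalize = FALSE)
  Lr <- L %*% vm$rotmat
  Lr <- sign_align(Lr)
  structure(list(
    variance_share = share,
    loadings_raw = L,
    loadings_rotated = Lr,
    loadings_rescaled = Lr * sds,
    rotation_matrix = vm$rotmat,
    scores = pc$x,
    column_sd = sds,
    column_mean = colMeans(X),
    n_components = k), class = "flux_pca")
}

# make each component's largest-magnitude loading positive
sign_align <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' @export
print.flux_pca <- function(x, digits = 3, ...) {
  k <- x$n_components
  cat(sprintf("Flux PCA: %d retained components explain %.1f%% of variance\n",
              k, 100 * sum(x$variance_share[1:k])))
  cat("Variance shares:",
      paste(sprintf("%.3f", x$variance_share[1:k]), collapse = " "), "\n")
  cat("Varimax-rotated loadings (rescaled to flux units):\n")
  print(round(x$loadings_rescaled, digits))
  invisible(x)
}

# align columns of B to A by maximal absolute congruence (greedy) and sign
align_components <- function(A, B) {
  k <- ncol(A)
  congr <- abs(crossprod(A, B)) /
    outer(sqrt(colSums(A^2)), sqrt(colSums(B^2)))
  perm <- integer(k); used <- logical(k)
  ord <- order(-apply(congr, 1, max))
  for (i in ord) {
    j <- which.max(ifelse(used, -Inf, congr[i, ]))
    perm[i] <- j; used[j] <- TRUE
  }
  out <- B[, perm, drop = FALSE]
  for (j in seq_len(k))
    if (sum(out[, j] * A[, j]) < 0) out[, j] <- -out[, j]
  out
}

#' Jackknife validation of PCA loadings
#'
#' Recomputes the rotated, rescaled PCA loadings leaving out each sample in
#' turn (aligned to the full solution by congruence), derives jackknife
#' standard errors per loading, and flags a loading as significant when its
#' relative error (SE over the absolute nominal loading) is below 0.5.
#'
#' @inheritParams pca_fluxes
#' @return object of class `flux_pca_jackknife` with `se`, `significant`
#'   (logical matrix), `relative_error` and the full-solution `loadings`.
#' @export
jackknife_loadings <- function(flux_table, n_components = 3) {
  X <- as.matrix(flux_table)
  n <- nrow(X)
  if (n < 4) stop("jackknife needs at least 4 samples")
  full <- pca_fluxes(X, n_components)
  L0 <- full$loadings_rescaled
  reps <- array(NA_real_, c(nrow(L0), ncol(L0), n),
                dimnames = list(rownames(L0), colnames(L0), NULL))
  for (i in seq_len(n)) {
    pi <- pca_fluxes(X[-i, , drop = FALSE], n_components)
    reps[, , i] <- align_components(L0, pi$loadings_rescaled)
  }
  mbar <- apply(reps, c(1, 2), mean)
  se <- sqrt((n - 1) / n *
               apply(sweep(reps, c(1, 2), mbar)^2, c(1, 2), sum))
  rel <- se / abs(L0)
  structure(list(loadings = L0, se = se, relative_error = rel,
                 significant = rel < 0.5, n = n),
            class = "flux_pca_jackknife")
}

#' @export
print.flux_pca_jackknife <- function(x, digits = 3, ...) {
  cat(sprintf("Jackknife over %d samples; significant loadings (rel. error < 0.5):\n",
              x$n))
  m <- ifelse(x$significant, sprintf(paste0("%.", digits, "f"), x$loadings),
              ".")
  dimnames(m) <- dimnames(x$loadings)
  print(m, quote = FALSE)
  invisible(x)
}
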