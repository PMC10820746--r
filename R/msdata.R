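# Fragment bookkeeping, MID normalization, natural-isotope correction and
# positional enrichment arithmetic for GC-EI-MS labeling data.

# mass-offset distributions of the relevant elements (IUPAC 2021 values,
# embedded for offline reproducibility); index 1 = offset 0
ISOTOPE_ABUNDANCE <- list(
  H  = c(0.999885, 0.000115),
  C  = c(0.9893, 0.0107),
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  Si = c(0.92223, 0.04685, 0.03092),
  P  = 1
)

# integer mass of the most abundant isotope
NOMINAL_ELEMENT_MASS <- c(C = 12, H = 1, N = 14, O = 16, Si = 28, P = 31)

#' Parse an elemental formula string
#'
#' @param formula string such as `"C25H63O9NSi6P"`.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(sub("^[A-Z][a-z]?", "", toks))
  n[is.na(n)] <- 1L
  if (paste(toks, collapse = "") != formula)
    stop("cannot parse formula: ", formula)
  bad <- setdiff(el, names(NOMINAL_ELEMENT_MASS))
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  counts <- tapply(n, factor(el, levels = unique(el)), sum)[unique(el)]
  stats::setNames(as.integer(counts), unique(el))
}

#' Nominal mass of a fragment formula
#'
#' Sum of element counts times the integer mass of each element's most
#' abundant isotope (C = 12, H = 1, N = 14, O = 16, Si = 28, P = 31);
#' reproduces the m/z values of the EtOx-TMS fragment panel.
#'
#' @param formula formula string or named count vector.
#' @return integer nominal mass.
#' @examples
#' nominal_mass("C25H63O9NSi6P")  # 720, the G6P C1-C6 fragment
#' @export
nominal_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  sum(formula * NOMINAL_ELEMENT_MASS[names(formula)])
}

#' The GC-MS fragment panel
#'
#' `fragment_panel()` returns all nine EtOx-TMS fragments monitored for
#' glucose and the sugar phosphates; `mfa_fragments()` the seven fragments
#' of four intracellular metabolites used as flux-fit measurements (the
#' co-eluting X5P/Ru5P/R5P pool is reported as `P5P`).
#'
#' @return data frame with columns `metabolite, mz, carbon_first,
#'   carbon_last, formula`.
#' @export
fragment_panel <- function() {
  data.frame(
    metabolite  = c("Glucose", "Glucose", "G6P", "G6P", "G6P",
                    "P5P", "R5P", "DHAP", "3PG"),
    mz          = c(568L, 319L, 720L, 471L, 357L, 618L, 459L, 414L, 459L),
    carbon_first = c(1L, 3L, 1L, 3L, 5L, 1L, 3L, 1L, 1L),
    carbon_last  = c(6L, 6L, 6L, 6L, 6L, 5L, 5L, 3L, 3L),
    formula = c("C22H54O6NSi5", "C13H31O3Si3", "C25H63O9NSi6P",
                "C16H40O6Si4P", "C11H30O5Si3P", "C21H53O8NSi5P",
                "C15H40O6Si4P", "C13H33O6NSi3P", "C14H36O7Si4P"),
    stringsAsFactors = FALSE)
}

#' @rdname fragment_panel
#' @export
mfa_fragments <- function() {
  p <- fragment_panel()
  p[p$metabolite != "Glucose", , drop = FALSE]
}

#' Identifier of a fragment row
#' @param fragment one-row fragment data frame.
#' @return string such as `"G6P C1-C6"`.
#' @export
fragment_id <- function(fragment) {
  sprintf("%s C%d-C%d", fragment$metabolite,
          fragment$carbon_first, fragment$carbon_last)
}

n_skeleton <- function(fragment)
  fragment$carbon_last - fragment$carbon_first + 1L

#' Normalize peak areas to a mass isotopomer distribution
#'
#' @param areas nonnegative peak areas over mass offsets M+0, M+1, ...
#' @return numeric vector summing to 1.
#' @export
normalize_areas <- function(areas) {
  if (any(areas < 0)) stop("peak areas must be nonnegative")
  tot <- sum(areas)
  if (tot <= 0) stop("all peak areas are zero")
  areas / tot
}

# distribution of one element's natural mass offsets over `count` atoms
element_offset_dist <- function(element, count) {
  d <- 1
  base <- ISOTOPE_ABUNDANCE[[element]]
  for (i in seq_len(count)) d <- convolve_dist(d, base)
  d
}

#' Natural-isotope correction matrix of a fragment
#'
#' Column `j` (for `j = 0..N` artificial 13C labels on the `N` tracked
#' skeleton carbons) is the mass-offset distribution contributed by the
#' naturally occurring isotopes of the fragment's other atoms: H, N, O, Si
#' and P always, the derivatization carbons (formula carbons beyond the
#' skeleton) always, and the remaining unlabeled skeleton carbons only when
#' `correct_carbon` is set (model-free evaluation).  Columns are truncated
#' to `n_mass` offsets and renormalized.
#'
#' @param fragment one-row fragment definition with a formula.
#' @param correct_carbon also correct natural 13C on the skeleton carbons.
#' @param n_mass number of mass offsets (rows); default `N + 2`
#'   (M+0 .. M+(N+1)).
#' @return `n_mass` x `(N+1)` matrix; each column a probability vector.
#' @export
correction_matrix <- function(fragment, correct_carbon = FALSE,
                              n_mass = NULL) {
  counts <- parse_formula(fragment$formula)
  N <- n_skeleton(fragment)
  nC <- if ("C" %in% names(counts)) counts[["C"]] else 0L
  if (nC < N)
    stop("formula carbon count (", nC,
         ") is smaller than the tracked skeleton (", N, ")")
  if (is.null(n_mass)) n_mass <- N + 2L
  base <- 1
  for (el in setdiff(names(counts), "C"))
    base <- convolve_dist(base, element_offset_dist(el, counts[[el]]))
  base <- convolve_dist(base, element_offset_dist("C", nC - N))
  K <- matrix(0, n_mass, N + 1L)
  for (j in 0:N) {
    col <- base
    if (correct_carbon && N - j > 0)
      col <- convolve_dist(col, element_offset_dist("C", N - j))
    col <- c(rep(0, j), col)                 # shift by the j labels
    col <- col[seq_len(min(length(col), n_mass))]
    col <- c(col, rep(0, n_mass - length(col)))
    K[, j + 1L] <- col / sum(col)
  }
  dimnames(K) <- list(paste0("M+", 0:(n_mass - 1L)), paste0("x", 0:N))
  K
}

#' Correct a measured MID to a carbon mass distribution
#'
#' Solves `K r = m` for the carbon-label distribution `r` by nonnegative
#' least squares, where `K` is the fragment's [correction_matrix()].
#' `correct_carbon = TRUE` removes natural 13C from the skeleton as well
#' (model-free evaluation); leave it `FALSE` for flux-fit inputs, whose
#' label definition retains natural 13C.
#'
#' @param mid measured mass isotopomer distribution (length >= N+1).
#' @param fragment one-row fragment definition with a formula.
#' @param correct_carbon see [correction_matrix()].
#' @return CMD vector of length N+1, summing to 1.
#' @export
correct_to_cmd <- function(mid, fragment, correct_carbon = FALSE) {
  N <- n_skeleton(fragment)
  if (length(mid) < N + 1L)
    stop("MID must cover at least offsets M+0 .. M+", N)
  K <- correction_matrix(fragment, correct_carbon, n_mass = length(mid))
  if (kappa(K) > 1e10) stop("ill-conditioned correction matrix")
  r <- pracma::lsqnonneg(K, as.numeric(mid))$x
  r / sum(r)
}

#' Forward-convolve a CMD into a raw MID
#'
#' Inverse of [correct_to_cmd()]: applies the natural-isotope correction
#' matrix to a known carbon-label distribution.
#'
#' @inheritParams correct_to_cmd
#' @param cmd carbon mass distribution of length N+1.
#' @param n_mass output length, default N+2.
#' @return MID vector.
#' @export
cmd_to_mid <- function(cmd, fragment, correct_carbon = FALSE,
                       n_mass = NULL) {
  N <- n_skeleton(fragment)
  stopifnot(length(cmd) == N + 1L)
  K <- correction_matrix(fragment, correct_carbon, n_mass = n_mass)
  drop(K %*% cmd)
}

#' Total and fractional 13C enrichment of a fragment
#'
#' `total_enrichment` is the mean number of labeled carbons,
#' `sum(i * r_i)`; `fractional_enrichment` divides by the carbon count and
#' doubles as the fractional contribution (FC) under a uniformly labeled
#' tracer.
#'
#' @param cmd carbon mass distribution (offset 0..N).
#' @return scalar enrichment.
#' @export
total_enrichment <- function(cmd) sum((seq_along(cmd) - 1) * cmd)

#' @rdname total_enrichment
#' @export
fractional_enrichment <- function(cmd) {
  N <- length(cmd) - 1L
  if (N < 1) stop("fragment must have at least one carbon")
  total_enrichment(cmd) / N
}

#' Positional enrichment of an unmeasured complement fragment
#'
#' When a parent fragment splits into a measured child plus an unmeasured
#' complement (e.g. G6P C1-C6 into C3-C6 and C1-C2), enrichment additivity
#' gives the complement as the difference of total enrichments.  Small
#' negative differences (measurement noise) are clipped to zero; differences
#' below `-tol` additionally warn.
#'
#' @param t_parent,t_child total enrichments of the parent and measured
#'   child fragments.
#' @param tol clipping tolerance.
#' @return nonnegative complement enrichment.
#' @export
complement_enrichment <- function(t_parent, t_child, tol = 1e-6) {
  d <- t_parent - t_child
  if (d < -tol)
    warning(sprintf("complement enrichment %.4g < 0 beyond tolerance; %s",
                    d, "clipped to 0"))
  max(d, 0)
}

#' Classify measurement accuracy of a fragment MID
#'
#' Maximum absolute elementwise difference between a measured and a
#' theoretical MID, in mol%: `optimal` up to 0.8 mol%, `acceptable` up to
#' 1.5 mol%, `rejected` beyond.
#'
#' @param measured,theoretical MID vectors of equal length (fractions).
#' @return list with `max_error_molpct` and `classification`.
#' @export
accuracy_check <- function(measured, theoretical) {
  if (length(measured) != length(theoretical))
    stop("measured and theoretical MIDs must have equal length")
  err <- max(abs(measured - theoretical)) * 100
  cls <- if (err <= 0.8) "optimal" else if (err <= 1.5) "acceptable"
         else "rejected"
  list(max_error_molpct = err, classification = cls)
}

#' Write / read a long-format measurement table
#'
#' CSV with one row per mass offset and columns `sample_id, tracer_id,
#' metabolite, carbon_first, carbon_last, mass_offset, fraction, nc`.
#'
#' @param x measurement data frame.
#' @param path CSV path.
#' @return `read_measurements` returns the validated data frame.
#' @export
write_measurements <- function(x, path) {
  validate_measurements(x)
  utils::write.csv(x[, MEASUREMENT_COLS], path, row.names = FALSE)
  invisible(path)
}

MEASUREMENT_COLS <- c("sample_id", "tracer_id", "metabolite",
                      "carbon_first", "carbon_last", "mass_offset",
                      "fraction", "nc")

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_measurements(x)
  x
}

validate_measurements <- function(x) {
  missing <- setdiff(MEASUREMENT_COLS, names(x))
  if (length(missing))
    stop("measurement table lacks column(s): ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(x$fraction)) || any(x$fraction < 0))
    stop("fractions must be finite and nonnegative")
  if (any(x$nc <= 0)) stop("nc (precision parameter) must be positive")
  key <- interaction(x$sample_id, x$tracer_id, x$metabolite,
                     x$carbon_first, x$carbon_last, x$mass_offset,
                     drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (sample, tracer, fragment, mass offset) rows")
  invisible(x)
}

# measurement table -> list of (tracer_id, fragment id, cmd, nc) blocks
measurement_blocks <- function(x, sample = NULL) {
  validate_measurements(x)
  if (!is.null(sample)) x <- x[x$sample_id == sample, , drop = FALSE]
  if (length(unique(x$sample_id)) > 1)
    stop("measurement table contains several samples; pick one")
  sp <- split(x, interaction(x$tracer_id, x$metabolite, x$carbon_first,
                             x$carbon_last, drop = TRUE))
  lapply(unname(sp), function(b) {
    b <- b[order(b$mass_offset), ]
    N <- b$carbon_last[1] - b$carbon_first[1] + 1L
    if (!identical(as.integer(b$mass_offset), 0:N))
      stop("fragment ", b$metabolite[1], " C", b$carbon_first[1], "-C",
           b$carbon_last[1], ": mass offsets must be 0..", N)
    list(tracer_id = b$tracer_id[1],
         fragment = sprintf("%s C%d-C%d", b$metabolite[1],
                            b$carbon_first[1], b$carbon_last[1]),
         cmd = b$fraction / sum(b$fraction),
         nc = b$nc[1])
  })
}

#' Write / read a fragment panel CSV
#'
#' Columns `metabolite, mz, carbon_first, carbon_last, formula`; the shipped
#' default panel is also available as
#' `system.file("extdata", "fragment_panel.csv", package = "pppmfa")`.
#'
#' @param x fragment panel data frame (see [fragment_panel()]).
#' @param path CSV path.
#' @return `read_fragment_panel` returns the validated data frame.
#' @export
write_fragment_panel <- function(x, path) {
  need <- c("metabolite", "mz", "carbon_first", "carbon_last", "formula")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("fragment panel lacks column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(x[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragment_panel
#' @export
read_fragment_panel <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "mz", "carbon_first", "carbon_last", "formula")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("fragment panel lacks column(s): ", paste(missing, collapse = ", "))
  for (i in seq_len(nrow(x)))
    if (nominal_mass(x$formula[i]) != x$mz[i])
      stop("formula/mass mismatch for ", fragment_id(x[i, ]))
  x
}

#' Convert simulated CMDs to the measurement table layout
#'
#' Noise-free counterpart of [generate_measurements()]: writes simulated
#' fragment CMDs in the long measurement format, e.g. for export or for use
#' as exact reference data.
#'
#' @param simulated result of [simulate_cmds()] for a tracer panel.
#' @param fragments the fragment table that was simulated.
#' @param nc precision parameter recorded in the table.
#' @param sample_id sample identifier.
#' @return measurement data frame (see [write_measurements()]).
#' @export
cmds_to_table <- function(simulated, fragments = mfa_fragments(),
                          nc = default_nc(fragments),
                          sample_id = "simulated") {
  if (!inherits(simulated, "simulated_cmds"))
    stop("expected a multi-tracer simulate_cmds() result")
  ids <- vapply(seq_len(nrow(fragments)), function(i)
    fragment_id(fragments[i, ]), "")
  if (length(nc) == 1 && is.null(names(nc)))
    nc <- stats::setNames(rep(nc, length(ids)), ids)
  rows <- list()
  for (tr in names(simulated)) {
    for (i in seq_len(nrow(fragments))) {
      cmd <- simulated[[tr]][[ids[i]]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, tracer_id = tr,
        metabolite = fragments$metabolite[i],
        carbon_first = fragments$carbon_first[i],
        carbon_last = fragments$carbon_last[i],
        mass_offset = seq_along(cmd) - 1L,
        fraction = cmd, nc = nc[[ids[i]]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
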