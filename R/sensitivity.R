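#' Log-uniform factor grid for the parameter sweep
#'
#' Parameters are varied over two orders of magnitude, one above and one
#' below the physiological value, on a uniform logarithmic grid. The
#' physiological point F = 1 is excluded (the sensitivity ratio is
#' undefined there).
#'
#' @param points_per_decade grid density (>= 2); the default of 9 gives 19
#'   log-equispaced points on \[0.1, 10\], hence 18 factors after removing
#'   F = 1.
#' @return Numeric vector of scale factors, symmetric in log space about 1.
#' @export
sweep_factors <- function(points_per_decade = 9) {
  if (points_per_decade < 2) stop("points_per_decade must be >= 2")
  f <- 10^seq(-1, 1, length.out = 2 * points_per_decade + 1)
  f[abs(log10(f)) > 1e-12]
}

#' Relative sensitivity of a fold change to a parameter scaling
#'
#' `S_ij = | (fold_ij / fold_ip - 1) / (F - 1) |`, where `fold_ij` is the
#' fold change with parameter i scaled by factor F and `fold_ip` the fold
#' change at the physiological value. Built on ratios only, so invariant to
#' the units of the underlying variable; the absolute value makes rankings
#' sign-blind.
#'
#' @param fold_ij fold change at the scaled parameter value (> 0).
#' @param fold_ip fold change at the physiological value (> 0).
#' @param F scale factor (!= 1).
#' @return Nonnegative sensitivity value(s).
#' @export
relative_sensitivity <- function(fold_ij, fold_ip, F) {
  if (any(F == 1)) stop("sensitivity is undefined at F = 1")
  if (any(fold_ip <= 0)) stop("reference fold change must be > 0")
  abs((fold_ij / fold_ip - 1) / (F - 1))
}

#' Local sensitivity analysis of the network
#'
#' Sweeps each of the 33 sensitivity parameters (all parameters except the
#' total Wnt3a, which defines the fold-change metric itself, and the Hill
#' coefficient) over the factor grid. For every (parameter, factor) cell the
#' Wnt OFF and Wnt ON steady states are recomputed and the steady-state fold
#' change of every variable evaluated; sensitivities are averaged over
#' factors per (parameter, variable), then over variables to produce the
#' global ranking. Cells whose steady states fail to converge are dropped
#' from the averages with a warning.
#'
#' @param params reference parameter set (Wnt OFF; `WNT0` = 1 nM).
#' @param wnt0_on total Wnt3a of the ON state (nM).
#' @param factors sweep factors (default [sweep_factors()]).
#' @param variables state variables to analyze (default all 24).
#' @return An object of class `rcn_sensitivity`: list with `cells` (long
#'   data.frame of S_ij: parameter, factor, variable, S), `by_variable`
#'   (parameter x variable average-S matrix), `ranking` (data.frame: rank,
#'   reaction, parameter, block, avg_sensitivity), `failed` (count of
#'   dropped cells), and the sweep metadata.
#' @export
lsa <- function(params, wnt0_on = 28.062, factors = sweep_factors(),
                variables = species_names()) {
  pnames <- parameter_names(lsa_only = TRUE)
  ref_fold <- steady_fold_change(params, wnt0_on)
  ref_off <- attr(ref_fold, "off")
  ref_on <- attr(ref_fold, "on")
  fp <- ref_fold[variables]

  # sweep outward from F = 1, warm-starting each cell from its neighbor
  ord <- order(abs(log10(factors)))
  n_fail <- 0L
  cells <- vector("list", length(pnames))
  names(cells) <- pnames
  for (pn in pnames) {
    res <- matrix(NA_real_, nrow = length(factors),
                  ncol = length(variables),
                  dimnames = list(NULL, variables))
    warm_lo <- warm_hi <- list(off = ref_off, on = ref_on)
    for (i in ord) {
      F <- factors[i]
      warm <- if (F < 1) warm_lo else warm_hi
      fj <- tryCatch({
        pj <- set_parameters(params, structure(list(params[[pn]] * F),
                                               names = pn))
        steady_fold_change(pj, wnt0_on, off_init = warm$off,
                           on_init = warm$on)
      }, error = function(e) NULL)
      if (is.null(fj)) { n_fail <- n_fail + 1L; next }
      res[i, ] <- relative_sensitivity(fj[variables], fp, F)
      warm <- list(off = attr(fj, "off"), on = attr(fj, "on"))
      if (F < 1) warm_lo <- warm else warm_hi <- warm
    }
    cells[[pn]] <- res
  }
  if (n_fail > 0)
    warning(n_fail, " sweep cell(s) failed to converge and were excluded")

  by_var <- t(vapply(cells, function(m) colMeans(m, na.rm = TRUE),
                     numeric(length(variables))))
  avg <- rowMeans(by_var, na.rm = TRUE)
  reg <- parameter_registry()
  ranking <- data.frame(
    parameter = pnames,
    reaction = reg$reaction[match(pnames, reg$name)],
    block = reg$block[match(pnames, reg$name)],
    avg_sensitivity = avg[pnames],
    row.names = NULL)
  ranking <- ranking[order(-ranking$avg_sensitivity), ]
  ranking$rank <- seq_len(nrow(ranking))
  ranking <- ranking[, c("rank", "reaction", "parameter", "block",
                         "avg_sensitivity")]
  rownames(ranking) <- NULL

  long <- do.call(rbind, lapply(pnames, function(pn) {
    m <- cells[[pn]]
    data.frame(parameter = pn,
               factor = rep(factors, times = ncol(m)),
               variable = rep(colnames(m), each = nrow(m)),
               S = as.vector(m))
  }))

  structure(list(cells = long, by_variable = by_var, ranking = ranking,
                 failed = n_fail, factors = factors, wnt0_on = wnt0_on,
                 variables = variables),
            class = "rcn_sensitivity")
}

#' @export
print.rcn_sensitivity <- function(x, n = 10, ...) {
  cat("Local sensitivity analysis:", nrow(x$ranking), "parameters x",
      length(x$factors), "factors;", x$failed, "failed cells\n")
  print(utils::head(x$ranking, n), row.names = FALSE)
  invisible(x)
}

#' Classify parameters as high or low impact per variable
#'
#' A parameter is flagged `high` for a variable when its average sensitivity
#' is at least twice the variable's mean sensitivity over all parameters,
#' `low` when at most half that mean, and `neutral` otherwise. The flags are
#' invariant to a global rescaling of all sensitivities.
#'
#' @param table an `rcn_sensitivity` object (or its `by_variable` matrix).
#' @return Character matrix (parameter x variable) of
#'   `"high"`/`"low"`/`"neutral"` flags.
#' @export
classify_impact <- function(table) {
  m <- if (inherits(table, "rcn_sensitivity")) table$by_variable else table
  flags <- matrix("neutral", nrow(m), ncol(m), dimnames = dimnames(m))
  for (v in seq_len(ncol(m))) {
    mu <- mean(m[, v], na.rm = TRUE)
    if (!is.finite(mu) || mu == 0) next
    flags[m[, v] >= 2 * mu, v] <- "high"
    flags[m[, v] <= 0.5 * mu, v] <- "low"
  }
  flags
}

#' Write sensitivity results as CSV
#'
#' Writes the global ranking (mirroring the rank / reaction / parameter /
#' average-sensitivity layout) and, optionally, the full long table of
#' per-cell sensitivities.
#'
#' @param x an `rcn_sensitivity` object.
#' @param path output CSV for the ranking.
#' @param cells_path optional output CSV for the long S_ij table.
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(x, path, cells_path = NULL) {
  utils::write.csv(x$ranking, path, row.names = FALSE)
  if (!is.null(cells_path))
    utils::write.csv(x$cells, cells_path, row.names = FALSE)
  invisible(path)
}
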