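#' Behavioral constraint sets
#'
#' A constraint set is a list of named targets on computable model
#' observables, each with a target value, a relative tolerance and a
#' weight. Two target types are supported: `steady_state` (the value of a
#' state variable at the equilibrium for a given total Wnt3a) and
#' `fold_change` (the steady-state activation fold change of a variable
#' for a given ON-state total Wnt3a, relative to the parameter set's OFF
#' state).
#'
#' @param x list of constraints; each element a list with `name`, `type`
#'   (`"steady_state"` or `"fold_change"`), `variable`, `target`, `tol`
#'   (> 0), `weight` (> 0), and `wnt0` (steady_state) or `wnt0_on`
#'   (fold_change).
#' @return A validated list of class `rcn_constraints`.
#' @export
as_constraints <- function(x) {
  if (!length(x)) return(structure(list(), class = "rcn_constraints"))
  for (cst in x) {
    need <- c("name", "type", "variable", "target", "tol", "weight")
    miss <- setdiff(need, names(cst))
    if (length(miss))
      stop("constraint missing fields: ", paste(miss, collapse = ", "))
    if (!cst$type %in% c("steady_state", "fold_change"))
      stop("unsupported constraint type: ", cst$type)
    if (!cst$variable %in% species_names())
      stop("constraint on unknown observable: ", cst$variable)
    if (cst$tol <= 0 || cst$weight <= 0 || cst$target <= 0)
      stop("constraint target, tol and weight must be > 0")
  }
  structure(x, class = "rcn_constraints")
}

#' Default behavioral constraints of the reference condition
#'
#' The qualitative calibration targets stated for the reference condition:
#' the Wnt OFF cytoplasmic beta-catenin level on the scale of the published
#' reduced Wnt models (tens of nM), an approximately 3-fold increase of
#' cytoplasmic beta-catenin upon activation, DPAGT1/GPT induction above 1,
#' and reduced junction abundance and adhesivity in the activated state.
#'
#' @return An `rcn_constraints` list.
#' @export
default_constraints <- function() {
  as_constraints(list(
    list(name = "bcat_off_level", type = "steady_state", variable = "bcat",
         wnt0 = 1, target = 20, tol = 0.25, weight = 1),
    list(name = "bcat_fold", type = "fold_change", variable = "bcat",
         wnt0_on = 28.062, target = 3, tol = 0.15, weight = 2),
    list(name = "gpt_fold", type = "fold_change", variable = "gpt",
         wnt0_on = 28.062, target = 1.35, tol = 0.15, weight = 1),
    list(name = "aj_fold", type = "fold_change", variable = "ecad_aj",
         wnt0_on = 28.062, target = 0.75, tol = 0.2, weight = 1),
    list(name = "sigma_fold", type = "fold_change", variable = "sigma_aj",
         wnt0_on = 28.062, target = 0.9, tol = 0.1, weight = 1)
  ))
}

#' Read or write a constraint set as JSON
#'
#' @param path file path.
#' @param constraints an `rcn_constraints` list.
#' @return `read_constraints()` returns an `rcn_constraints` list.
#' @export
read_constraints <- function(path) {
  as_constraints(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' @rdname read_constraints
#' @export
write_constraints <- function(constraints, path) {
  jsonlite::write_json(unclass(constraints), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @keywords internal
evaluate_constraint <- function(cst, params, cache) {
  if (cst$type == "steady_state") {
    key <- paste0("ss_", cst$wnt0)
    if (is.null(cache[[key]]))
      cache[[key]] <- find_steady_state(params, wnt0 = cst$wnt0)
    list(value = cache[[key]][[cst$variable]], cache = cache)
  } else {
    key <- paste0("fold_", cst$wnt0_on)
    if (is.null(cache[[key]]))
      cache[[key]] <- steady_fold_change(params, cst$wnt0_on)
    list(value = cache[[key]][[cst$variable]], cache = cache)
  }
}

#' Evaluate a parameter set against behavioral constraints
#'
#' Simulates the conditions each constraint requires and reports the
#' observed value, the relative error against the target, and pass/fail at
#' the constraint's tolerance.
#'
#' @param params parameter set.
#' @param constraints an `rcn_constraints` list (default
#'   [default_constraints()]).
#' @return Data.frame with one row per constraint: `name`, `type`,
#'   `variable`, `target`, `observed`, `rel_error`, `tol`, `pass`.
#' @export
constraint_report <- function(params, constraints = default_constraints()) {
  if (!length(constraints))
    return(data.frame(name = character(), type = character(),
                      variable = character(), target = numeric(),
                      observed = numeric(), rel_error = numeric(),
                      tol = numeric(), pass = logical()))
  cache <- list()
  rows <- lapply(constraints, function(cst) {
    ev <- evaluate_constraint(cst, params, cache)
    cache <<- ev$cache
    rel <- abs(ev$value - cst$target) / abs(cst$target)
    data.frame(name = cst$name, type = cst$type, variable = cst$variable,
               target = cst$target, observed = ev$value, rel_error = rel,
               tol = cst$tol, pass = rel <= cst$tol)
  })
  do.call(rbind, rows)
}

#' Fit free parameters to behavioral constraints
#'
#' Weighted least squares on log-scale residuals `log(observed/target)`,
#' optimized over the logarithms of the free parameters with box bounds
#' (factor 0.01 to 100 around the starting set) by seeded multi-start
#' Nelder-Mead local search. Deterministic for a given seed.
#'
#' @param params starting parameter set (also supplies the fixed values).
#' @param free character vector of parameter names to fit (excluding
#'   `WNT0`).
#' @param constraints an `rcn_constraints` list (>= 1 target).
#' @param seed RNG seed for the multi-start jitter.
#' @param n_starts number of local searches (first start is the input
#'   set).
#' @param maxit Nelder-Mead iteration budget per start.
#' @return Fitted `rcn_parameters` with attributes `objective` (final
#'   weighted residual), `start_objective`, and `trace` (per-start
#'   objectives). Warns when the objective surface is flat (non-identifiable
#'   free parameters).
#' @export
fit_parameters <- function(params, free, constraints, seed = 1,
                           n_starts = 5, maxit = 200) {
  if (!length(constraints)) stop("need at least one constraint")
  if (!length(free)) return(params)
  bad <- setdiff(free, setdiff(parameter_names(), "WNT0"))
  if (length(bad)) stop("cannot fit: ", paste(bad, collapse = ", "))
  p0 <- unclass(params)
  lo <- log(p0[free] / 100); hi <- log(p0[free] * 100)

  objective <- function(theta) {
    th <- pmin(pmax(theta, lo), hi)
    pen <- sum((theta - th)^2) * 100
    p <- p0; p[free] <- exp(th)
    rep <- tryCatch(
      constraint_report(as_rcn_parameters(p), constraints),
      error = function(e) NULL)
    if (is.null(rep)) return(1e6 + pen)
    w <- vapply(constraints, function(cc) cc$weight, numeric(1))
    sum(w * log(rep$observed / rep$target)^2) + pen
  }

  set.seed(seed)
  theta0 <- log(p0[free])
  starts <- list(theta0)
  if (n_starts > 1)
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- theta0 + stats::rnorm(length(free), 0, 0.5)
  f0 <- objective(theta0)
  best <- list(par = theta0, value = f0)
  trace <- numeric(0)
  for (st in starts) {
    fit <- if (length(free) == 1L)
      stats::optim(st, objective, method = "Brent",
                   lower = lo, upper = hi)
    else
      stats::optim(st, objective, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-10))
    trace <- c(trace, fit$value)
    if (fit$value < best$value) best <- fit
  }
  if (stats::sd(c(trace, f0)) < 1e-12 && f0 > 1e-10)
    warning("objective is flat over the starts: free parameters may be ",
            "non-identifiable")
  p <- p0; p[free] <- exp(pmin(pmax(best$par, lo), hi))
  out <- as_rcn_parameters(p)
  attr(out, "objective") <- best$value
  attr(out, "start_objective") <- f0
  attr(out, "trace") <- trace
  out
}
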