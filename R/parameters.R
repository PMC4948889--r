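#' Parameter registry for the regulatory cell network
#'
#' The network dynamics are governed by 35 named parameters: 31 kinetic
#' constants attached to the 26 processes of the reaction scheme plus the 4
#' conserved totals of the constitutively expressed molecules (Wnt3a, APC,
#' TCF, and the Axin/GSK-3beta complex). Two of the 35 (the total Wnt3a
#' concentration `WNT0`, which defines the ON/OFF contrast itself, and the
#' Hill coefficient `n_hill`) are excluded from local sensitivity analysis,
#' leaving 33 sweepable parameters.
#'
#' @return A data.frame with one row per parameter: `name`, `reaction`
#'   (process label; `"0"` marks conserved totals, letter suffixes separate
#'   multiple parameters of one process), `block` (pathway block:
#'   `"signaling"`, `"glycosylation"`, `"adhesion"`), `units`, `lsa`
#'   (logical; swept in sensitivity analysis), and `description`.
#' @seealso [reference_parameters()], [reaction_scheme()]
#' @export
parameter_registry <- function() {
  p <- function(name, reaction, block, units, lsa, description) {
    data.frame(name = name, reaction = reaction, block = block,
               units = units, lsa = lsa, description = description,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    p("K1",    "1",      "signaling", "nM", TRUE,
      "Wnt3a / LRP5-6 binding, rapid-equilibrium dissociation constant"),
    p("K2",    "2",      "signaling", "nM", TRUE,
      "Wnt3a-LRP / Axin-GSK3 recruitment, rapid-equilibrium dissociation constant"),
    p("k3",    "3 (a)",  "signaling", "1/(nM min)", TRUE,
      "destruction-complex assembly (APC + Axin/GSK3), association rate"),
    p("km3",   "3 (b)",  "signaling", "1/min", TRUE,
      "destruction-complex disassembly, dissociation rate"),
    p("k4",    "4",      "signaling", "1/min", TRUE,
      "dephosphorylation of free phospho-beta-catenin"),
    p("k5",    "5",      "signaling", "1/min", TRUE,
      "proteasomal degradation of phospho-beta-catenin"),
    p("K6",    "6",      "signaling", "nM", TRUE,
      "beta-catenin / destruction-complex binding, rapid-equilibrium dissociation constant"),
    p("k7",    "7",      "signaling", "1/min", TRUE,
      "phosphorylation of destruction-complex-bound beta-catenin"),
    p("K8",    "8",      "signaling", "nM", TRUE,
      "phospho-beta-catenin / destruction-complex binding, rapid-equilibrium dissociation constant"),
    p("nu9",   "9",      "signaling", "nM/min", TRUE,
      "beta-catenin synthesis rate"),
    p("k10",   "10",     "signaling", "1/min", TRUE,
      "axin-independent beta-catenin degradation"),
    p("K11",   "11",     "glycosylation", "nM", TRUE,
      "beta-catenin / TCF binding, rapid-equilibrium dissociation constant"),
    p("Tmax",  "12 (a)", "glycosylation", "nM/min", TRUE,
      "maximal DPAGT1 transcription rate (Hill activation)"),
    p("KTmRNA","12 (b)", "glycosylation", "nM", TRUE,
      "beta-catenin/TCF concentration at half-maximal DPAGT1 transcription"),
    p("n_hill","12 (c)", "glycosylation", "-", FALSE,
      "Hill coefficient of DPAGT1 transcriptional activation"),
    p("k13",   "13",     "glycosylation", "1/min", TRUE,
      "DPAGT1 mRNA degradation"),
    p("Pmax",  "14",     "glycosylation", "1/min", TRUE,
      "GPT translation rate constant (per unit DPAGT1 mRNA)"),
    p("nu15",  "15",     "glycosylation", "nM/min", TRUE,
      "LRP5/6 synthesis rate (immature pool)"),
    p("k16",   "16",     "glycosylation", "1/min", TRUE,
      "degradation of immature LRP5/6"),
    p("k17",   "17",     "glycosylation", "1/(nM min)", TRUE,
      "GPT-dependent N-glycosylation/maturation of LRP5/6 to the membrane"),
    p("k18",   "18",     "glycosylation", "1/min", TRUE,
      "turnover of mature membrane LRP5/6"),
    p("k19",   "19",     "glycosylation", "1/min", TRUE,
      "GPT degradation"),
    p("nu20",  "20 (a)", "adhesion", "nM/min", TRUE,
      "co-synthesis of E-cadherin/beta-catenin complex in the ER"),
    p("lambda20", "20 (b)", "adhesion", "-", TRUE,
      "lumped maximal ER N-glycosylation extent, Vmax t / Gmax"),
    p("KM20",  "20 (c)", "adhesion", "nM", TRUE,
      "GPT concentration at half-maximal E-cadherin N-glycosylation"),
    p("K21",   "21",     "adhesion", "1/min", TRUE,
      "E-cadherin export ER -> membrane"),
    p("k22",   "22",     "adhesion", "1/min", TRUE,
      "internalization of membrane E-cadherin to the ERC"),
    p("k23",   "23",     "adhesion", "1/min", TRUE,
      "recycling of ERC E-cadherin back to the membrane"),
    p("c24",   "24",     "adhesion", "1/min", TRUE,
      "adherens-junction coupling scale: assembly c24*sigma_M, disassembly c24*(1-sigma_AJ)"),
    p("k25",   "25",     "adhesion", "1/min", TRUE,
      "lysosomal degradation of ERC E-cadherin/beta-catenin complex"),
    p("k26",   "26",     "adhesion", "1/min", TRUE,
      "ERC complex degradation with release of beta-catenin to the cytoplasm"),
    p("WNT0",  "0 (d)",  "signaling", "nM", FALSE,
      "conserved total Wnt3a (defines the ON/OFF stimulus)"),
    p("APC0",  "0 (a)",  "signaling", "nM", TRUE,
      "conserved total APC"),
    p("TCF0",  "0 (b)",  "signaling", "nM", TRUE,
      "conserved total TCF"),
    p("AG0",   "0 (c)",  "signaling", "nM", TRUE,
      "conserved total Axin/GSK-3beta complex")
  ))
}

#' Names of the model parameters
#'
#' @param lsa_only if `TRUE`, return only the 33 parameters varied in local
#'   sensitivity analysis (excludes `WNT0` and the Hill coefficient).
#' @return Character vector of parameter names.
#' @export
parameter_names <- function(lsa_only = FALSE) {
  reg <- parameter_registry()
  if (lsa_only) reg$name[reg$lsa] else reg$name
}

#' Reference (physiological) parameter set
#'
#' Literature-anchored parameter values for the reference condition of the
#' network in an MDCK-like epithelial cell. The Wnt/beta-catenin block
#' (processes 1-10) is anchored to the published reduced models of canonical
#' Wnt signaling (beta-catenin synthesis 0.423 nM/min; TCF and APC totals 15
#' and 100 nM; beta-catenin/TCF dissociation constant 30 nM); the remaining
#' values are derived from the behavioral constraints of the reference
#' condition: a Wnt OFF cytoplasmic beta-catenin level of roughly 25 nM, an
#' approximately 3-fold increase of active beta-catenin upon stepping total
#' Wnt3a from 1 to 28.062 nM, relaxation to steady state detected at about
#' 35 h, and slower equilibration of adhesivity than of junction abundance.
#' The default total Wnt3a is 1 nM (Wnt OFF).
#'
#' @param wnt0 total Wnt3a concentration (nM); default 1 (Wnt OFF).
#' @return A named numeric vector of class `rcn_parameters` with exactly 35
#'   entries.
#' @examples
#' p <- reference_parameters()
#' length(p)          # 35
#' p[["WNT0"]]        # 1
#' @export
reference_parameters <- function(wnt0 = 1) {
  p <- c(
    K1     = 5,
    K2     = 0.125,
    k3     = 0.01,
    km3    = 0.1,
    k4     = 0.01,
    k5     = 0.1,
    K6     = 50,
    k7     = 0.095,
    K8     = 50,
    nu9    = 0.423,
    k10    = 1e-4,
    K11    = 30,
    Tmax   = 0.02,
    KTmRNA = 5,
    n_hill = 2,
    k13    = 0.0085,
    Pmax   = 0.03,
    nu15   = 0.05,
    k16    = 0.01,
    k17    = 0.02,
    k18    = 0.03,
    k19    = 0.0065,
    nu20   = 0.25,
    lambda20 = 0.85,
    KM20   = 12,
    K21    = 0.15,
    k22    = 0.0675,
    k23    = 0.06,
    c24    = 0.052,
    k25    = 0.015,
    k26    = 0.06,
    WNT0   = wnt0,
    APC0   = 100,
    TCF0   = 15,
    AG0    = 30
  )
  as_rcn_parameters(p)
}

#' Construct and validate a parameter set
#'
#' @param x named numeric vector or list holding all 35 model parameters.
#' @return A named numeric vector of class `rcn_parameters`.
#' @export
as_rcn_parameters <- function(x) {
  x <- unlist(x)
  nm <- parameter_names()
  missing <- setdiff(nm, names(x))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(x), nm)
  if (length(extra))
    stop("unknown parameters: ", paste(extra, collapse = ", "))
  p <- x[nm]
  validate_parameters(p)
  class(p) <- "rcn_parameters"
  p
}

#' @keywords internal
validate_parameters <- function(p) {
  if (any(!is.finite(p))) stop("parameters must be finite")
  if (any(p < 0)) stop("parameters must be nonnegative")
  eq <- c("K1", "K2", "K6", "K8", "K11", "KTmRNA", "KM20")
  if (any(p[eq] <= 0)) stop("equilibrium/saturation constants must be > 0")
  if (p[["n_hill"]] < 1) stop("Hill coefficient must be >= 1")
  if (p[["lambda20"]] > 1)
    stop("lambda20 (Vmax t / Gmax) must be <= 1: larger values would drive ",
         "the ER adhesivity target below 0 at saturating GPT")
  invisible(p)
}

#' Apply named overrides to a parameter set
#'
#' @param params an `rcn_parameters` vector.
#' @param ... named scalar overrides (e.g. `WNT0 = 28.062`), or a single
#'   named list/vector.
#' @return The modified, re-validated parameter set.
#' @export
set_parameters <- function(params, ...) {
  ov <- list(...)
  if (length(ov) == 1L && is.null(names(ov)) ||
      (length(ov) == 1L && (is.list(ov[[1]]) || length(ov[[1]]) > 1)))
    ov <- as.list(unlist(ov))
  p <- unclass(params)
  for (nm in names(ov)) {
    if (!nm %in% names(p)) stop("unknown parameter: ", nm)
    p[[nm]] <- as.numeric(ov[[nm]])
  }
  as_rcn_parameters(p)
}

#' Read or write a parameter set as JSON
#'
#' Parameter files are flat JSON objects keyed by parameter name; partial
#' files are interpreted as overrides of the reference set.
#'
#' @param path file path.
#' @param params parameter set to write.
#' @param base parameter set that partial files override (default the
#'   reference set).
#' @return `read_parameters()` returns an `rcn_parameters` vector;
#'   `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path, base = reference_parameters()) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  set_parameters(base, as.list(unlist(vals)))
}

#' @rdname read_parameters
#' @export
write_parameters <- function(params, path) {
  jsonlite::write_json(as.list(unclass(params)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
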