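#' The 26-process reaction scheme
#'
#' Machine-readable description of the network: Wnt/beta-catenin signaling
#' and beta-catenin regulation (processes 1-10), genetic activation of DPAGT1
#' and N-glycosylation (11-19), and E-cadherin recycling and adherens
#' junction formation (20-26). Processes 1, 2, 6, 8 and 11 are treated in
#' rapid equilibrium in the reduced (DAE) system.
#'
#' @return A data.frame with columns `id` (1-26), `category`, `reactants`,
#'   `products` (species names separated by `" + "`; empty string for
#'   synthesis sources and degradation sinks), `parameters` (names separated
#'   by `";"`), and `rapid_equilibrium` (logical).
#' @seealso [scheme_summary()], [write_scheme()]
#' @export
reaction_scheme <- function() {
  r <- function(id, category, reactants, products, parameters, re = FALSE) {
    data.frame(id = id, category = category, reactants = reactants,
               products = products, parameters = parameters,
               rapid_equilibrium = re, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    r(1L,  "binding",       "wnt + lrp_m",          "wnt_lrp",        "K1",  TRUE),
    r(2L,  "binding",       "wnt_lrp + axin_gsk",   "wnt_lrp_ag",     "K2",  TRUE),
    r(3L,  "binding",       "apc + axin_gsk",       "bdc",            "k3;km3"),
    r(4L,  "linear",        "bcat_p",               "bcat",           "k4"),
    r(5L,  "linear",        "bcat_p",               "",               "k5"),
    r(6L,  "binding",       "bcat + bdc",           "bdc_bcat",       "K6",  TRUE),
    r(7L,  "linear",        "bdc_bcat",             "bdc_bcatp",      "k7"),
    r(8L,  "binding",       "bcat_p + bdc",         "bdc_bcatp",      "K8",  TRUE),
    r(9L,  "synthesis",     "",                     "bcat",           "nu9"),
    r(10L, "linear",        "bcat",                 "",               "k10"),
    r(11L, "binding",       "bcat + tcf",           "bcat_tcf",       "K11", TRUE),
    r(12L, "transcription", "",                     "dpagt1_mrna",    "Tmax;KTmRNA;n_hill"),
    r(13L, "linear",        "dpagt1_mrna",          "",               "k13"),
    r(14L, "translation",   "dpagt1_mrna",          "dpagt1_mrna + gpt", "Pmax"),
    r(15L, "synthesis",     "",                     "lrp_i",          "nu15"),
    r(16L, "linear",        "lrp_i",                "",               "k16"),
    r(17L, "conversion",    "lrp_i + gpt",          "lrp_m + gpt",    "k17"),
    r(18L, "linear",        "lrp_m",                "",               "k18"),
    r(19L, "linear",        "gpt",                  "",               "k19"),
    r(20L, "synthesis",     "",                     "ecad_er",        "nu20;lambda20;KM20"),
    r(21L, "transport",     "ecad_er",              "ecad_m",         "K21"),
    r(22L, "transport",     "ecad_m",               "ecad_erc",       "k22"),
    r(23L, "transport",     "ecad_erc",             "ecad_m",         "k23"),
    r(24L, "aj_assembly",   "ecad_m",               "ecad_aj",        "c24"),
    r(25L, "linear",        "ecad_erc",             "",               "k25"),
    r(26L, "linear",        "ecad_erc",             "bcat",           "k26")
  ))
}

#' Structural counts of the reduced model
#'
#' @return A list: `n_processes` (26), `n_parameters` (35), `n_ode` (15
#'   differential equations of the reduced system, including the four
#'   adhesivity factors), `n_algebraic` (9 relations: 5 rapid equilibria + 4
#'   conservation laws), `n_independent` (15), `n_dependent` (9),
#'   `n_lsa_parameters` (33).
#' @export
scheme_summary <- function() {
  list(n_processes = nrow(reaction_scheme()),
       n_parameters = length(parameter_names()),
       n_ode = length(independent_names()),
       n_algebraic = length(dependent_names()),
       n_independent = length(independent_names()),
       n_dependent = length(dependent_names()),
       n_lsa_parameters = length(parameter_names(lsa_only = TRUE)))
}

#' Export the reaction scheme as CSV
#'
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(path) {
  utils::write.csv(reaction_scheme(), path, row.names = FALSE)
  invisible(path)
}
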