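#' Toy models with closed-form expectations
#'
#' Small fixture models used to validate every stage of the pipeline against
#' hand-computable answers:
#' \describe{
#'   \item{single_site}{One site \{empty, L\}. With binding rate D and bound
#'     Boltzmann weight w, the unbinding rate is D/w, so the chain alternates
#'     exponential intervals; persistence and exchange times have closed
#'     forms. The default \code{bound_weight = 3} makes the rates (3, 1)
#'     under D = 3.}
#'   \item{independent_pair}{Two uncoupled sites with distinct species and
#'     weights: the chain is a product of two single-site chains, so all
#'     cross conditional activities are exactly 0 and the mutual information
#'     vanishes.}
#'   \item{cooperative_pair}{Two sites plus a pairwise cooperativity term;
#'     the 4-state Boltzmann weights are hand-computable.}
#'   \item{blocker_pair}{Two sites whose bound configurations sterically
#'     exclude one another (the promoter/operator overlap motif); with both
#'     sites strongly favoured bound, the pair is near-perfectly
#'     anticorrelated.}
#'   \item{chain_n}{n two-configuration sites with nearest-neighbour
#'     cooperativity.}
#' }
#'
#' @param kind Fixture kind, see above.
#' @param ... Parameters by kind: \code{bound_weight} (single_site);
#'   \code{bound_weight_a}, \code{bound_weight_b} (independent_pair);
#'   \code{delta_g_a}, \code{delta_g_b}, \code{delta_g_coop}, \code{conc}
#'   (cooperative_pair); \code{delta_g_a}, \code{delta_g_b}, \code{conc}
#'   (blocker_pair); \code{n}, \code{delta_g_site}, \code{delta_g_coop},
#'   \code{conc} (chain_n). All energies kcal/mol, concentrations molar.
#' @param temperature_K Temperature (default 310).
#' @return List with elements \code{model} ([binding_model()]) and
#'   \code{cond} ([condition()]).
#' @examples
#' fx <- make_fixture("independent_pair")
#' n_microstates(fx$model)  # 4
#' @export
make_fixture <- function(kind = c("single_site", "independent_pair",
                                  "cooperative_pair", "blocker_pair", "chain_n"),
                         ..., temperature_K = 310) {
  kind <- match.arg(kind)
  p <- list(...)
  rt <- GAS_CONSTANT_KCAL * temperature_K
  arg <- function(name, default) if (is.null(p[[name]])) default else p[[name]]
  two_state_site <- function(name, species) {
    list(site = site_spec(name, c("empty", species)),
         ligand = ligand_spec(species, data.frame(site = name, configuration = species)))
  }

  switch(kind,
    single_site = {
      w <- arg("bound_weight", 3)
      a <- two_state_site("a", "L")
      model <- binding_model(list(a$site), list(a$ligand),
                             energy_terms = list(energy_term(
                               data.frame(site = "a", configuration = "L"),
                               -rt * log(w))))
      list(model = model, cond = condition(c(L = 1), temperature_K))
    },
    independent_pair = {
      wa <- arg("bound_weight_a", 3)
      wb <- arg("bound_weight_b", 0.5)
      a <- two_state_site("a", "La"); b <- two_state_site("b", "Lb")
      model <- binding_model(list(a$site, b$site), list(a$ligand, b$ligand),
                             energy_terms = list(
        energy_term(data.frame(site = "a", configuration = "La"), -rt * log(wa)),
        energy_term(data.frame(site = "b", configuration = "Lb"), -rt * log(wb))))
      list(model = model, cond = condition(c(La = 1, Lb = 1), temperature_K))
    },
    cooperative_pair = {
      dga <- arg("delta_g_a", -1); dgb <- arg("delta_g_b", -0.5)
      dgc <- arg("delta_g_coop", -2); conc <- arg("conc", 1e-3)
      a <- two_state_site("a", "L"); b <- site_spec("b", c("empty", "L2"))
      lb <- ligand_spec("L2", data.frame(site = "b", configuration = "L2"))
      model <- binding_model(list(a$site, b), list(a$ligand, lb),
                             energy_terms = list(
        energy_term(data.frame(site = "a", configuration = "L"), dga),
        energy_term(data.frame(site = "b", configuration = "L2"), dgb),
        energy_term(data.frame(site = c("a", "b"), configuration = c("L", "L2")), dgc)))
      list(model = model, cond = condition(c(L = conc, L2 = conc), temperature_K))
    },
    blocker_pair = {
      dga <- arg("delta_g_a", -5); dgb <- arg("delta_g_b", -5)
      conc <- arg("conc", 1)
      a <- two_state_site("a", "La"); b <- two_state_site("b", "Lb")
      model <- binding_model(list(a$site, b$site), list(a$ligand, b$ligand),
                             exclusions = list(exclusion_rule("a", "La", "b", "Lb")),
                             energy_terms = list(
        energy_term(data.frame(site = "a", configuration = "La"), dga),
        energy_term(data.frame(site = "b", configuration = "Lb"), dgb)))
      list(model = model, cond = condition(c(La = conc, Lb = conc), temperature_K))
    },
    chain_n = {
      n <- arg("n", 3)
      dgs <- arg("delta_g_site", -1); dgc <- arg("delta_g_coop", -1.5)
      conc <- arg("conc", 1)
      nm <- paste0("s", seq_len(n))
      sites <- lapply(nm, function(s) site_spec(s, c("empty", "L")))
      lig <- ligand_spec("L", data.frame(site = nm, configuration = "L"))
      terms <- lapply(nm, function(s)
        energy_term(data.frame(site = s, configuration = "L"), dgs))
      for (i in seq_len(n - 1))
        terms[[length(terms) + 1L]] <- energy_term(
          data.frame(site = nm[i:(i + 1)], configuration = "L"), dgc)
      model <- binding_model(sites, list(lig), energy_terms = terms)
      list(model = model, cond = condition(c(L = conc), temperature_K))
    })
}
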