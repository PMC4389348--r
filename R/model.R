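#' Declare a binding site
#'
#' A binding site is a DNA segment (or any discrete degree of freedom) that is
#' always in exactly one of a small set of binding configurations. The first
#' configuration must be \code{"empty"}; the remaining configurations name the
#' bound ligand (e.g. \code{"CI2"}, \code{"RNAP"}).
#'
#' @param name Site label, unique within a model.
#' @param configurations Character vector of configuration labels; the first
#'   must be \code{"empty"} and there must be at least two.
#' @param kind One of \code{"operator"}, \code{"promoter"}, \code{"other"};
#'   purely descriptive.
#' @return An object of class \code{"site_spec"}.
#' @examples
#' site_spec("O_R1", c("empty", "CI2", "Cro2"), kind = "operator")
#' @export
site_spec <- function(name, configurations, kind = c("other", "operator", "promoter")) {
  kind <- match.arg(kind)
  structure(list(name = as.character(name),
                 configurations = as.character(configurations),
                 kind = kind),
            class = "site_spec")
}

#' Declare a ligand species
#'
#' A ligand species (e.g. a CI dimer) is defined by the set of
#' (site, configuration) pairs at which one molecule of the species counts as
#' bound. Stoichiometries of microstates -- the exponents of the concentration
#' factors in the equilibrium weights -- are derived from these maps.
#'
#' @param species Species label.
#' @param occupancy Data frame with columns \code{site} and
#'   \code{configuration}: each row is one assignment counting as one bound
#'   molecule of this species.
#' @return An object of class \code{"ligand_spec"}.
#' @export
ligand_spec <- function(species, occupancy) {
  occupancy <- as.data.frame(occupancy)
  stopifnot(all(c("site", "configuration") %in% names(occupancy)))
  structure(list(species = as.character(species),
                 occupancy = occupancy[, c("site", "configuration")]),
            class = "ligand_spec")
}

#' Declare a steric exclusion rule
#'
#' Forbids two site assignments from co-occurring in any microstate, e.g. RNA
#' polymerase at a promoter excluding a ligand at an overlapping operator.
#' Rules are symmetric in their two assignments.
#'
#' @param site_a,config_a First assignment.
#' @param site_b,config_b Second assignment (a different site).
#' @return An object of class \code{"exclusion_rule"}.
#' @export
exclusion_rule <- function(site_a, config_a, site_b, config_b) {
  structure(list(site_a = as.character(site_a), config_a = as.character(config_a),
                 site_b = as.character(site_b), config_b = as.character(config_b)),
            class = "exclusion_rule")
}

#' Declare an additive free-energy term
#'
#' A term contributes \code{delta_g} to the free energy of every microstate in
#' which all of its condition assignments hold: a singleton condition is an
#' intrinsic binding energy, a two-assignment condition is a pairwise
#' cooperativity, and multi-assignment conditions encode e.g. DNA-looping
#' octamer stabilisation. Terms are strictly additive and each term matches at
#' most once per microstate.
#'
#' @param assignments Data frame with columns \code{site} and
#'   \code{configuration}; all must hold for the term to contribute.
#' @param delta_g Free energy in kcal/mol (negative = stabilising).
#' @param label Optional description (e.g. a provenance note).
#' @return An object of class \code{"energy_term"}.
#' @export
energy_term <- function(assignments, delta_g, label = NULL) {
  assignments <- as.data.frame(assignments)
  stopifnot(all(c("site", "configuration") %in% names(assignments)))
  structure(list(assignments = assignments[, c("site", "configuration")],
                 delta_g = as.numeric(delta_g),
                 label = label),
            class = "energy_term")
}

#' Assemble an unvalidated model description
#'
#' Collects sites, ligands, exclusions and energy terms without checking them;
#' use [validate_model()] to obtain diagnostics and [binding_model()] to
#' validate and enumerate in one step.
#'
#' @param sites List of [site_spec()] objects.
#' @param ligands List of [ligand_spec()] objects.
#' @param exclusions List of [exclusion_rule()] objects.
#' @param energy_terms List of [energy_term()] objects.
#' @return An object of class \code{"binding_spec"}.
#' @export
binding_spec <- function(sites, ligands = list(), exclusions = list(),
                         energy_terms = list()) {
  as_list_of <- function(x, cls) {
    if (inherits(x, cls)) x <- list(x)
    x
  }
  structure(list(sites = as_list_of(sites, "site_spec"),
                 ligands = as_list_of(ligands, "ligand_spec"),
                 exclusions = as_list_of(exclusions, "exclusion_rule"),
                 energy_terms = as_list_of(energy_terms, "energy_term")),
            class = "binding_spec")
}

#' Validate a model description
#'
#' Checks every structural invariant of a model description: unique site
#' names, "empty" listed first, ligand occupancy maps referencing existing
#' non-empty assignments and claimed by at most one species, exclusion rules
#' spanning two distinct sites, and energy terms with non-empty conditions on
#' existing assignments.
#'
#' @param spec A [binding_spec()] or [binding_model()].
#' @return Character vector of diagnostics, each naming the offending element;
#'   empty if the model is well-formed.
#' @export
validate_model <- function(spec) {
  d <- character()
  say <- function(...) d <<- c(d, sprintf(...))

  nm <- vapply(spec$sites, function(s) s$name, "")
  if (anyDuplicated(nm))
    say("duplicate site name(s): %s", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  for (s in spec$sites) {
    if (length(s$configurations) < 2)
      say("site '%s' has fewer than 2 configurations", s$name)
    if (sum(s$configurations == "empty") != 1L)
      say("site '%s' must list 'empty' exactly once", s$name)
    else if (s$configurations[1] != "empty")
      say("site '%s' must list 'empty' first", s$name)
    if (anyDuplicated(s$configurations))
      say("site '%s' has duplicate configurations", s$name)
  }

  has_assignment <- function(site, config) {
    i <- match(site, nm)
    !is.na(i) && config %in% spec$sites[[i]]$configurations
  }

  claimed <- character()
  for (lg in spec$ligands) {
    occ <- lg$occupancy
    for (r in seq_len(nrow(occ))) {
      if (!has_assignment(occ$site[r], occ$configuration[r]))
        say("ligand '%s' references unknown assignment (%s, %s)",
            lg$species, occ$site[r], occ$configuration[r])
      if (identical(occ$configuration[r], "empty"))
        say("ligand '%s' claims the 'empty' configuration at site '%s'",
            lg$species, occ$site[r])
      key <- paste(occ$site[r], occ$configuration[r], sep = "\r")
      if (key %in% claimed)
        say("assignment (%s, %s) is claimed by two ligand species",
            occ$site[r], occ$configuration[r])
      claimed <- c(claimed, key)
    }
  }
  lnm <- vapply(spec$ligands, function(l) l$species, "")
  if (anyDuplicated(lnm))
    say("duplicate ligand species: %s", paste(unique(lnm[duplicated(lnm)]), collapse = ", "))

  for (ex in spec$exclusions) {
    if (identical(ex$site_a, ex$site_b))
      say("exclusion rule on a single site '%s'", ex$site_a)
    for (side in list(c(ex$site_a, ex$config_a), c(ex$site_b, ex$config_b)))
      if (!has_assignment(side[1], side[2]))
        say("exclusion rule references unknown assignment (%s, %s)", side[1], side[2])
  }

  for (k in seq_along(spec$energy_terms)) {
    tm <- spec$energy_terms[[k]]
    if (nrow(tm$assignments) == 0)
      say("energy term %d has an empty condition", k)
    for (r in seq_len(nrow(tm$assignments)))
      if (!has_assignment(tm$assignments$site[r], tm$assignments$configuration[r]))
        say("energy term %d references unknown assignment (%s, %s)",
            k, tm$assignments$site[r], tm$assignments$configuration[r])
    if (!is.finite(tm$delta_g))
      say("energy term %d has a non-finite delta_g", k)
  }
  d
}

#' Build and enumerate a binding-site model
#'
#' Validates a model description and enumerates its microstates: all joint
#' assignments of one configuration per site that violate no exclusion rule.
#' Enumeration is lexicographic over sites in declaration order (first site
#' most significant) with configurations in declared order, so indices are
#' deterministic; they are reported 0-based in exports. Each microstate
#' carries its per-species stoichiometry and its additive free energy in
#' kcal/mol.
#'
#' @param sites A [binding_spec()], or a list of [site_spec()] objects.
#' @param ligands,exclusions,energy_terms Passed to [binding_spec()] when
#'   \code{sites} is not already a spec.
#' @param state_cap Refuse to enumerate when the unconstrained product of
#'   configuration counts exceeds this guard (default \code{1e6}).
#' @return An object of class \code{"binding_model"}: the validated description plus
#'   \code{$states} (integer matrix, one row per microstate, entries are
#'   1-based configuration indices), \code{$stoichiometry}, \code{$delta_g},
#'   \code{$site_names}, \code{$configurations}.
#' @seealso [equilibrium()], [rate_matrix()], [microstates()]
#' @export
binding_model <- function(sites, ligands = list(), exclusions = list(),
                          energy_terms = list(), state_cap = 1e6) {
  spec <- if (inherits(sites, "binding_spec")) sites
          else binding_spec(sites, ligands, exclusions, energy_terms)
  diag <- validate_model(spec)
  if (length(diag))
    stop("invalid model:\n  ", paste(diag, collapse = "\n  "), call. = FALSE)

  site_names <- vapply(spec$sites, function(s) s$name, "")
  configs <- lapply(spec$sites, function(s) s$configurations)
  names(configs) <- site_names
  n_cfg <- lengths(configs)
  if (prod(n_cfg) > state_cap)
    stop(sprintf("unconstrained state count %.0f exceeds state_cap = %.0f; raise state_cap if intended",
                 prod(n_cfg), state_cap), call. = FALSE)

  # expand.grid varies its first factor fastest; reverse so the first declared
  # site is the most significant digit of the lexicographic order
  grid <- do.call(expand.grid, c(rev(lapply(n_cfg, seq_len)),
                                 KEEP.OUT.ATTRS = FALSE))
  states <- as.matrix(grid[, rev(seq_len(ncol(grid))), drop = FALSE])
  colnames(states) <- site_names
  storage.mode(states) <- "integer"

  for (ex in spec$exclusions) {
    ia <- match(ex$site_a, site_names); ib <- match(ex$site_b, site_names)
    ca <- match(ex$config_a, configs[[ia]]); cb <- match(ex$config_b, configs[[ib]])
    keep <- !(states[, ia] == ca & states[, ib] == cb)
    states <- states[keep, , drop = FALSE]
  }

  species <- vapply(spec$ligands, function(l) l$species, "")
  stoich <- matrix(0L, nrow(states), length(species),
                   dimnames = list(NULL, species))
  for (lg in spec$ligands) {
    occ <- lg$occupancy
    cnt <- integer(nrow(states))
    for (r in seq_len(nrow(occ))) {
      i <- match(occ$site[r], site_names)
      cnt <- cnt + (states[, i] == match(occ$configuration[r], configs[[i]]))
    }
    stoich[, lg$species] <- cnt
  }

  dg <- numeric(nrow(states))
  for (tm in spec$energy_terms) {
    hit <- rep(TRUE, nrow(states))
    for (r in seq_len(nrow(tm$assignments))) {
      i <- match(tm$assignments$site[r], site_names)
      hit <- hit & states[, i] == match(tm$assignments$configuration[r], configs[[i]])
    }
    dg <- dg + tm$delta_g * hit
  }

  structure(c(unclass(spec),
              list(site_names = site_names, configurations = configs,
                   states = states, stoichiometry = stoich, delta_g = dg)),
            class = c("binding_model", "binding_spec"))
}

#' Number of microstates of a model
#' @param model A [binding_model()].
#' @return Integer microstate count.
#' @export
n_microstates <- function(model) {
  stopifnot(inherits(model, "binding_model"))
  nrow(model$states)
}

#' Microstate table of a model
#'
#' @param model A [binding_model()].
#' @return Data frame with 0-based \code{index}, one column per site holding
#'   the configuration label, one count column per ligand species, and
#'   \code{delta_g} (kcal/mol).
#' @export
microstates <- function(model) {
  stopifnot(inherits(model, "binding_model"))
  lab <- vapply(seq_along(model$site_names), function(i)
    model$configurations[[i]][model$states[, i]],
    character(nrow(model$states)))
  if (nrow(model$states) == 1L) lab <- matrix(lab, nrow = 1L)
  colnames(lab) <- model$site_names
  cbind(data.frame(index = seq_len(nrow(model$states)) - 1L),
        as.data.frame(lab),
        as.data.frame(model$stoichiometry),
        data.frame(delta_g = model$delta_g))
}

#' Free energy of one assignment under a set of energy terms
#'
#' Sums \code{delta_g} over all terms whose condition is fully satisfied by
#' the assignment; an assignment matching no term has energy 0.
#'
#' @param assignment Named character vector mapping site name to configuration
#'   label.
#' @param energy_terms List of [energy_term()] objects.
#' @return Free energy in kcal/mol.
#' @export
microstate_energy <- function(assignment, energy_terms) {
  if (inherits(energy_terms, "energy_term")) energy_terms <- list(energy_terms)
  total <- 0
  for (tm in energy_terms) {
    a <- tm$assignments
    ok <- all(!is.na(assignment[a$site]) & assignment[a$site] == a$configuration)
    if (ok) total <- total + tm$delta_g
  }
  total
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf("Binding-site model: %d sites, %d ligand species, %d exclusion rules, %d energy terms\n",
              length(x$site_names), length(x$ligands), length(x$exclusions),
              length(x$energy_terms)))
  cat(sprintf("Microstates: %d\n", nrow(x$states)))
  for (i in seq_along(x$site_names))
    cat(sprintf("  %-6s [%s] {%s}\n", x$site_names[i], x$sites[[i]]$kind,
                paste(x$configurations[[i]], collapse = ", ")))
  invisible(x)
}

#' Export the microstate table as TSV
#' @param model A [binding_model()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_microstates <- function(model, path) {
  utils::write.table(microstates(model), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# match site name -> column index, with a helpful error
site_index <- function(model, site) {
  i <- match(site, model$site_names)
  if (is.na(i)) stop(sprintf("unknown site '%s'", site), call. = FALSE)
  i
}
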