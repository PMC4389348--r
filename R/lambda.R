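LAMBDA_OPERATORS <- c("O_R1", "O_R2", "O_R3", "O_L1", "O_L2", "O_L3")
LAMBDA_PROMOTERS <- c("P_R", "P_RM", "P_L")
LAMBDA_RIGHT_SITES <- c("O_R1", "O_R2", "O_R3", "P_R", "P_RM")
# promoter/operator steric overlaps: RNAP at a promoter excludes any ligand
# at the listed operators (and vice versa)
LAMBDA_OVERLAPS <- list(P_R = c("O_R1", "O_R2"), P_RM = "O_R3",
                        P_L = c("O_L1", "O_L2"))

#' The phage-lambda switch model
#'
#' Builds the standard thermodynamic model of the lambda lysogeny/lysis
#' switch: six operator sites (\code{O_R1..3}, \code{O_L1..3}), each empty or
#' bound by a CI or Cro dimer, and three promoters (\code{P_R}, \code{P_RM},
#' \code{P_L}), each empty or bound by RNA polymerase. RNAP at \code{P_R}
#' sterically excludes ligands at \code{O_R1}/\code{O_R2}, RNAP at
#' \code{P_RM} excludes \code{O_R3}, and RNAP at \code{P_L} excludes
#' \code{O_L1}/\code{O_L2}; both promoters of the right complex may carry
#' RNAP simultaneously. The exclusions leave 1200 of the 5832 unconstrained
#' joint configurations: 40 right-operator-complex states times 30
#' left-operator states.
#'
#' Free energies come from a [lambda_params()] set: intrinsic binding
#' energies per (site, species), pairwise cooperativities, and multi-site
#' DNA-looping terms (e.g. the CI octamer bridging \code{O_R1},\code{O_R2}
#' and \code{O_L1},\code{O_L2}). The package ships a schema-complete
#' parameter file with empty values and per-entry provenance slots
#' (\code{inst/extdata/lambda/parameters_template.yaml}); numerical values
#' must be transcribed from the experimental literature.
#'
#' @param params A [lambda_params()] set, or NULL for a purely structural
#'   model with all energies 0.
#' @param allow_placeholder Permit unset (placeholder) energy values, which
#'   are taken as 0. Default FALSE: an incomplete parameter set is an error.
#' @return A [binding_model()] with attribute \code{"placeholder"} marking
#'   whether any energy was a placeholder.
#' @examples
#' m <- lambda_model()           # structural model, all energies 0
#' n_microstates(m)              # 1200
#' @export
lambda_model <- function(params = NULL, allow_placeholder = is.null(params)) {
  sites <- c(lapply(LAMBDA_OPERATORS, function(s)
               site_spec(s, c("empty", "CI2", "Cro2"), kind = "operator")),
             lapply(LAMBDA_PROMOTERS, function(s)
               site_spec(s, c("empty", "RNAP"), kind = "promoter")))
  # declaration order: right complex first, then the left operator
  ord <- c("O_R1", "O_R2", "O_R3", "P_R", "P_RM", "O_L1", "O_L2", "O_L3", "P_L")
  names(sites) <- c(LAMBDA_OPERATORS, LAMBDA_PROMOTERS)
  sites <- sites[ord]

  ligands <- list(
    ligand_spec("CI2", data.frame(site = LAMBDA_OPERATORS, configuration = "CI2")),
    ligand_spec("Cro2", data.frame(site = LAMBDA_OPERATORS, configuration = "Cro2")),
    ligand_spec("RNAP", data.frame(site = LAMBDA_PROMOTERS, configuration = "RNAP")))

  exclusions <- list()
  for (p in names(LAMBDA_OVERLAPS))
    for (o in LAMBDA_OVERLAPS[[p]])
      for (cfg in c("CI2", "Cro2"))  # "blocks anything" = one rule per ligand
        exclusions[[length(exclusions) + 1L]] <- exclusion_rule(p, "RNAP", o, cfg)

  terms <- list()
  if (!is.null(params)) {
    stopifnot(inherits(params, "lambda_params"))
    missing <- lambda_missing_entries(params)
    if (length(missing) && !allow_placeholder)
      stop("lambda parameter set has unset values (transcribe them or set allow_placeholder = TRUE):\n  ",
           paste(missing, collapse = "\n  "), call. = FALSE)
    val <- function(x) if (is.null(x) || is.na(x)) 0 else x
    for (r in seq_len(nrow(params$intrinsic))) {
      e <- params$intrinsic[r, ]
      terms[[length(terms) + 1L]] <- energy_term(
        data.frame(site = e$site, configuration = e$species),
        val(e$delta_g), label = e$provenance)
    }
    for (r in seq_len(nrow(params$pairs))) {
      e <- params$pairs[r, ]
      terms[[length(terms) + 1L]] <- energy_term(
        data.frame(site = c(e$site_a, e$site_b),
                   configuration = c(e$species_a, e$species_b)),
        val(e$delta_g), label = e$provenance)
    }
    for (lp in params$looping)
      terms[[length(terms) + 1L]] <- energy_term(lp$assignments, val(lp$delta_g),
                                                 label = lp$provenance)
  }

  m <- binding_model(binding_spec(unname(sites), ligands, exclusions, terms))
  attr(m, "placeholder") <- is.null(params) || length(lambda_missing_entries(params)) > 0
  m
}

#' Lambda energy-parameter set
#'
#' Container for the free-energy parameters of the lambda switch, with a
#' provenance slot per value. Intrinsic entries must cover every allowed
#' (site, species) pair: the six operators for CI2 and Cro2 and the three
#' promoters for RNAP. Values left as \code{NA} are placeholders.
#'
#' @param intrinsic Data frame with columns \code{site}, \code{species},
#'   \code{delta_g} (kcal/mol), \code{provenance}.
#' @param pairs Data frame with columns \code{site_a}, \code{species_a},
#'   \code{site_b}, \code{species_b}, \code{delta_g}, \code{provenance}
#'   (pairwise cooperativities).
#' @param looping List of multi-site terms, each a list with
#'   \code{assignments} (data frame site/configuration, CI configurations
#'   spanning the two operators), \code{delta_g}, \code{provenance}.
#' @return An object of class \code{"lambda_params"}.
#' @export
lambda_params <- function(intrinsic, pairs = NULL, looping = list()) {
  intrinsic <- as.data.frame(intrinsic)
  stopifnot(all(c("site", "species", "delta_g") %in% names(intrinsic)))
  if (is.null(intrinsic$provenance)) intrinsic$provenance <- NA_character_
  if (is.null(pairs))
    pairs <- data.frame(site_a = character(), species_a = character(),
                        site_b = character(), species_b = character(),
                        delta_g = numeric(), provenance = character())
  pairs <- as.data.frame(pairs)
  if (is.null(pairs$provenance)) pairs$provenance <- rep(NA_character_, nrow(pairs))
  for (lp in looping) {
    a <- as.data.frame(lp$assignments)
    bad <- !(a$site %in% LAMBDA_OPERATORS & a$configuration == "CI2")
    if (any(bad))
      stop("looping terms may only reference CI2 configurations at operator sites",
           call. = FALSE)
  }
  structure(list(intrinsic = intrinsic, pairs = pairs, looping = looping),
            class = "lambda_params")
}

lambda_required_entries <- function() {
  rbind(expand.grid(site = LAMBDA_OPERATORS, species = c("CI2", "Cro2"),
                    stringsAsFactors = FALSE),
        data.frame(site = LAMBDA_PROMOTERS, species = "RNAP"))
}

lambda_missing_entries <- function(params) {
  req <- lambda_required_entries()
  key <- function(d) paste(d$site, d$species)
  have <- params$intrinsic[!is.na(params$intrinsic$delta_g), , drop = FALSE]
  miss <- setdiff(key(req), key(have))
  unset_pairs <- which(is.na(params$pairs$delta_g))
  unset_loop <- which(vapply(params$looping,
                             function(lp) is.null(lp$delta_g) || is.na(lp$delta_g), TRUE))
  c(if (length(miss)) paste("intrinsic:", miss),
    if (length(unset_pairs)) paste("pair cooperativity row", unset_pairs),
    if (length(unset_loop)) paste("looping term", unset_loop))
}

#' Read a lambda parameter file
#'
#' Parses the YAML schema shipped at
#' \code{inst/extdata/lambda/parameters_template.yaml}: sections
#' \code{intrinsic}, \code{pair_cooperativities}, \code{looping}, each entry
#' carrying \code{delta_g} (kcal/mol; \code{null} = placeholder) and a
#' \code{provenance} citation slot.
#'
#' @param path YAML file.
#' @return A [lambda_params()] object.
#' @export
read_lambda_params <- function(path) {
  y <- yaml::read_yaml(path)
  if (!identical(y$energy_units, "kcal/mol"))
    stop("parameter file must declare energy_units: kcal/mol", call. = FALSE)
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  chr <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  intrinsic <- do.call(rbind, lapply(y$intrinsic, function(e)
    data.frame(site = e$site, species = e$species, delta_g = num(e$delta_g),
               provenance = chr(e$provenance))))
  pairs <- do.call(rbind, lapply(y$pair_cooperativities, function(e)
    data.frame(site_a = e$site_a, species_a = e$species_a,
               site_b = e$site_b, species_b = e$species_b,
               delta_g = num(e$delta_g), provenance = chr(e$provenance))))
  looping <- lapply(y$looping, function(e)
    list(assignments = do.call(rbind, lapply(e$assignments, function(a)
           data.frame(site = a$site, configuration = a$configuration))),
         delta_g = num(e$delta_g), provenance = chr(e$provenance)))
  lambda_params(intrinsic, pairs, looping)
}

#' Marginal distribution over the right-operator complex
#'
#' Projects the full 1200-state equilibrium distribution onto the joint
#' configuration of the right-operator complex (\code{O_R1}, \code{O_R2},
#' \code{O_R3}, \code{P_R}, \code{P_RM}). Each of the 40 projected
#' configurations aggregates the 30 full microstates that differ only in the
#' left-operator configuration.
#'
#' @param eq An [equilibrium()] of a [lambda_model()].
#' @return Data frame with one row per right-complex configuration, its
#'   \code{probability}, and \code{n_aggregated}.
#' @export
project_to_right_operator <- function(eq) {
  model <- eq$model
  if (!all(LAMBDA_RIGHT_SITES %in% model$site_names))
    stop("not a lambda model (right-operator sites missing)", call. = FALSE)
  cols <- match(LAMBDA_RIGHT_SITES, model$site_names)
  lab <- vapply(cols, function(i) model$configurations[[i]][model$states[, i]],
                character(nrow(model$states)))
  colnames(lab) <- LAMBDA_RIGHT_SITES
  key <- apply(lab, 1, paste, collapse = "|")
  agg <- rowsum(eq$probabilities, key)
  cnt <- table(key)
  parts <- do.call(rbind, strsplit(rownames(agg), "|", fixed = TRUE))
  colnames(parts) <- LAMBDA_RIGHT_SITES
  out <- cbind(as.data.frame(parts),
               data.frame(probability = as.numeric(agg),
                          n_aggregated = as.integer(cnt[rownames(agg)])))
  out[order(-out$probability), ]
}

#' Full lysogenic/lytic pathway report
#'
#' Runs the complete analysis of the lambda switch under one fixed-protein
#' -concentration condition: equilibrium occupancies, per-site marginals and
#' entropies, the mutual-information matrix, the analytic conditional-
#' activity matrix, the top-occupancy microstates, and the promoter
#' occupancies \eqn{P(\mathrm{RNAP\ at\ } P_R)} (the proxy for the drive
#' toward lysis: the more often RNAP occupies P_R, the faster Cro is made)
#' and \eqn{P(\mathrm{RNAP\ at\ } P_{RM})}.
#'
#' @param params A [lambda_params()] set; placeholder values are refused
#'   unless \code{allow_placeholder = TRUE}.
#' @param cond A [condition()] with concentrations for CI2, Cro2, RNAP.
#' @param pathway Label stored in the report ("lysogenic" or "lytic").
#' @param D Binding rate for the kinetic model.
#' @param allow_placeholder Permit unset energies (taken as 0).
#' @param out_dir Optional directory: writes the TSV tables and DOT/GraphML
#'   graphs there.
#' @return An object of class \code{"lambda_report"}.
#' @export
pathway_report <- function(params, cond, pathway = c("lysogenic", "lytic"),
                           D = 1, allow_placeholder = FALSE, out_dir = NULL) {
  pathway <- match.arg(pathway)
  model <- lambda_model(params, allow_placeholder = allow_placeholder)
  eq <- equilibrium(model, cond)
  rm <- rate_matrix(eq, D = D)
  marg <- lapply(model$site_names, function(s) site_marginal(eq, s))
  names(marg) <- model$site_names
  top <- microstates(model)
  top$probability <- eq$probabilities
  top <- top[order(-top$probability), ][seq_len(10), ]
  rep <- structure(list(
    pathway = pathway, condition = cond, model = model, equilibrium = eq,
    marginals = marg, entropies = site_entropies(eq), mi = mi_matrix(eq),
    ca = ca_matrix(rm), top_states = top,
    p_rnap_pr = unname(marg$P_R["RNAP"]), p_rnap_prm = unname(marg$P_RM["RNAP"]),
    rate_matrix = rm), class = "lambda_report")
  if (!is.null(out_dir)) write_report(rep, out_dir)
  rep
}

#' @export
print.lambda_report <- function(x, ...) {
  cat(sprintf("Lambda switch report (%s pathway)\n", x$pathway))
  cat(sprintf("  P(RNAP at P_R)  = %.3g\n", x$p_rnap_pr))
  cat(sprintf("  P(RNAP at P_RM) = %.3g\n", x$p_rnap_prm))
  cat(sprintf("  top microstate occupancy = %.3g\n", x$top_states$probability[1]))
  cat(sprintf("  CA[P_R <- P_R] = %.4g\n", x$ca$ca["P_R", "P_R"]))
  invisible(x)
}

#' Write the report tables and graphs to a directory
#' @param rep A \code{"lambda_report"}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(rep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  utils::write.table(rep$top_states, p("top_states.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_site_matrix(rep$mi, p("mi.tsv"))
  write_ca_table(rep$ca, p("ca.tsv"), long_path = p("ca_long.tsv"))
  write_ca_diagnostics(rep$ca, p("ca_diagnostics.tsv"))
  utils::write.table(
    data.frame(site = names(rep$entropies), entropy_bits = rep$entropies),
    p("entropies.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  proj <- project_to_right_operator(rep$equilibrium)
  utils::write.table(proj, p("right_operator_occupancy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  export_microstate_graph(rep$rate_matrix, p("microstates.dot"), format = "dot")
  export_microstate_graph(rep$rate_matrix, p("microstates.graphml"), format = "graphml")
  export_site_graph(rep$mi, p("mi.graphml"), directed = FALSE)
  export_site_graph(rep$ca$ca, p("ca.graphml"), directed = TRUE)
  invisible(dir)
}
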