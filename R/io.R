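#' Write a model description file
#'
#' YAML with sections \code{sites}, \code{ligands}, \code{exclusions},
#' \code{energy_terms} and a checked \code{energy_units: kcal/mol} header.
#'
#' @param spec A [binding_spec()] or [binding_model()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(spec, path) {
  y <- list(
    energy_units = "kcal/mol",
    sites = lapply(spec$sites, function(s)
      list(name = s$name, configurations = as.list(s$configurations), kind = s$kind)),
    ligands = lapply(spec$ligands, function(l)
      list(species = l$species,
           occupancy = lapply(seq_len(nrow(l$occupancy)), function(r)
             list(site = l$occupancy$site[r],
                  configuration = l$occupancy$configuration[r])))),
    exclusions = lapply(spec$exclusions, function(ex)
      list(site_a = ex$site_a, config_a = ex$config_a,
           site_b = ex$site_b, config_b = ex$config_b)),
    energy_terms = lapply(spec$energy_terms, function(tm)
      list(assignments = lapply(seq_len(nrow(tm$assignments)), function(r)
             list(site = tm$assignments$site[r],
                  configuration = tm$assignments$configuration[r])),
           delta_g = tm$delta_g)))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read a model description file
#'
#' @param path YAML (or JSON) model file in the dialect of [write_model()].
#' @param enumerate Validate and enumerate into a [binding_model()] (default);
#'   FALSE returns the raw [binding_spec()] for [validate_model()].
#' @param state_cap Passed to [binding_model()].
#' @return A [binding_model()] or [binding_spec()].
#' @export
read_model <- function(path, enumerate = TRUE, state_cap = 1e6) {
  y <- if (grepl("\\.json$", path)) jsonlite::read_json(path) else yaml::read_yaml(path)
  if (!identical(y$energy_units, "kcal/mol"))
    stop(sprintf("model file '%s' must declare energy_units: kcal/mol", path),
         call. = FALSE)
  sites <- lapply(y$sites, function(s)
    site_spec(s$name, unlist(s$configurations),
              kind = if (is.null(s$kind)) "other" else s$kind))
  ligands <- lapply(y$ligands, function(l)
    ligand_spec(l$species, do.call(rbind, lapply(l$occupancy, function(o)
      data.frame(site = o$site, configuration = o$configuration)))))
  exclusions <- lapply(y$exclusions, function(ex)
    exclusion_rule(ex$site_a, ex$config_a, ex$site_b, ex$config_b))
  terms <- lapply(y$energy_terms, function(tm)
    energy_term(do.call(rbind, lapply(tm$assignments, function(a)
      data.frame(site = a$site, configuration = a$configuration))),
      tm$delta_g))
  spec <- binding_spec(sites, ligands, exclusions, terms)
  if (enumerate) binding_model(spec, state_cap = state_cap) else spec
}

#' Read a condition file
#'
#' YAML with \code{temperature_K} and a \code{concentrations_M} map; unset
#' (null) concentrations are an error naming the species.
#'
#' @param path YAML file.
#' @return A [condition()].
#' @export
read_condition <- function(path) {
  y <- yaml::read_yaml(path)
  conc <- y$concentrations_M
  unset <- names(conc)[vapply(conc, is.null, TRUE)]
  if (length(unset))
    stop(sprintf("condition file '%s' has unset concentrations for: %s",
                 path, paste(unset, collapse = ", ")), call. = FALSE)
  condition(unlist(conc),
            temperature_K = if (is.null(y$temperature_K)) 310 else y$temperature_K)
}

#' Write a condition file
#' @param cond A [condition()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_condition <- function(cond, path) {
  yaml::write_yaml(list(temperature_K = cond$temperature_K,
                        concentrations_M = as.list(cond$concentrations)), path)
  invisible(path)
}

#' Write a site-by-site matrix (MI, entropy) as TSV
#' @param m Named square matrix.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_site_matrix <- function(m, path) {
  utils::write.table(cbind(site = rownames(m), as.data.frame(m)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Export the microstate transition graph
#'
#' Writes the microstate graph with node attribute \code{log10_occupancy}
#' and edge attribute \code{log10_flux} (plus the transitioning site and
#' event type), for rendering with Graphviz or any GraphML consumer.
#'
#' @param rm A [rate_matrix()].
#' @param path Output file.
#' @param format \code{"dot"} or \code{"graphml"}.
#' @return \code{path}, invisibly.
#' @export
export_microstate_graph <- function(rm, path, format = c("dot", "graphml")) {
  format <- match.arg(format)
  e <- rm$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$from, to = e$to,
               log10_flux = log10(rm$K[e$from] * e$rate),
               site = rm$model$site_names[e$site], type = e$type),
    directed = TRUE,
    vertices = data.frame(name = seq_along(rm$K),
                          log10_occupancy = log10(rm$K)))
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Export a site-level graph (MI network or CA digraph)
#'
#' Off-diagonal entries become edges with attribute \code{weight}; the
#' diagonal (entropy or self-CA) becomes the node attribute \code{self}.
#'
#' @param m Named square site matrix.
#' @param path Output file.
#' @param directed TRUE for the (asymmetric) CA digraph: entry \code{[a, b]}
#'   becomes an arrow from b to a. FALSE keeps each unordered pair once.
#' @param format \code{"graphml"} or \code{"dot"}.
#' @param drop_below Omit edges with |weight| below this (default 0: keep all
#'   finite off-diagonal entries).
#' @return \code{path}, invisibly.
#' @export
export_site_graph <- function(m, path, directed = FALSE,
                              format = c("graphml", "dot"), drop_below = 0) {
  format <- match.arg(format)
  sites <- rownames(m)
  idx <- which(if (directed) row(m) != col(m) else upper.tri(m), arr.ind = TRUE)
  w <- m[idx]
  keep <- is.finite(w) & abs(w) >= drop_below
  idx <- idx[keep, , drop = FALSE]
  edges <- if (directed) {
    # m[a, b] = CA[a <- b]: influence flows b -> a
    data.frame(from = sites[idx[, 2]], to = sites[idx[, 1]], weight = m[idx])
  } else {
    data.frame(from = sites[idx[, 1]], to = sites[idx[, 2]], weight = m[idx])
  }
  g <- igraph::graph_from_data_frame(edges, directed = directed,
                                     vertices = data.frame(name = sites,
                                                           self = diag(m)))
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
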