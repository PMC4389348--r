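#' Detailed-balance transition-rate matrix over microstates
#'
#' Builds the generator of a continuous-time Markov chain whose stationary
#' distribution is the supplied equilibrium distribution. Two microstates are
#' adjacent when they differ at exactly one site and one of the two differing
#' configurations is "empty": every transition is a single binding or
#' unbinding event (ligand substitution is two transitions). All binding
#' transitions share the diffusion-limited rate \code{D}; each unbinding rate
#' is fixed by detailed balance, \eqn{q_{ij} = D K_j / K_i}. Time units are
#' set by \code{D} and are otherwise arbitrary; the conditional activity is
#' invariant to \code{D}.
#'
#' @param eq An [equilibrium()] with strictly positive probabilities.
#' @param D Binding rate (inverse time units), default 1.
#' @param dense_cap Store the generator as a dense base matrix up to this
#'   state count, as a sparse \code{Matrix} above it.
#' @return An object of class \code{"rate_matrix"}: \code{$Q} (generator, rows
#'   sum to 0), \code{$edges} (one row per allowed ordered transition: from,
#'   to, site, type, rate), \code{$K}, \code{$D}, \code{$model}.
#' @examples
#' m <- binding_model(list(site_spec("a", c("empty", "L"))),
#'                    ligands = ligand_spec("L", data.frame(site = "a", configuration = "L")))
#' eq <- equilibrium(m, condition(c(L = 2)))
#' rate_matrix(eq, D = 1)$Q
#' @export
rate_matrix <- function(eq, D = 1, dense_cap = 5000) {
  stopifnot(inherits(eq, "equilibrium"), D > 0)
  model <- eq$model
  K <- eq$probabilities
  if (any(K == 0))
    stop("equilibrium probability is exactly 0 for some microstate; ",
         "use a non-zero concentration or reduce the model before building kinetics",
         call. = FALSE)
  n <- nrow(model$states)

  from <- integer(); to <- integer(); site <- integer(); type <- character()
  for (s in seq_along(model$site_names)) {
    key <- apply(model$states[, -s, drop = FALSE], 1, paste, collapse = ",")
    for (grp in split(seq_len(n), key)) {
      if (length(grp) < 2) next
      e <- grp[model$states[grp, s] == 1L]  # the "empty" member, if present
      if (length(e) != 1L) next
      others <- setdiff(grp, e)
      from <- c(from, rep(e, length(others)), others)
      to <- c(to, others, rep(e, length(others)))
      site <- c(site, rep(s, 2L * length(others)))
      type <- c(type, rep("binding", length(others)), rep("unbinding", length(others)))
    }
  }
  rate <- ifelse(type == "binding", D, D * K[to] / K[from])
  edges <- data.frame(from = from, to = to, site = site, type = type, rate = rate)

  if (n <= dense_cap) {
    Q <- matrix(0, n, n)
  } else {
    Q <- Matrix::Matrix(0, n, n, sparse = TRUE)
  }
  Q[cbind(edges$from, edges$to)] <- edges$rate
  diag(Q) <- -rowSums(Q)

  structure(list(Q = Q, edges = edges, K = K, D = D, model = model),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("CTMC generator: %d microstates, %d transitions, D = %g\n",
              length(x$K), nrow(x$edges), x$D))
  cat(sprintf("Stationarity residual max |K Q| = %.3g\n", stationarity_check(x)))
  invisible(x)
}

#' Stationarity residual of the generator
#'
#' Detailed balance implies \eqn{K Q = 0}; this returns the largest violation,
#' \eqn{\max_j |\sum_i K_i q_{ij}|}, as a numerical diagnostic.
#'
#' @param rm A [rate_matrix()].
#' @param K Optional alternative distribution to test (defaults to the one the
#'   generator was built from).
#' @return Maximum absolute residual.
#' @export
stationarity_check <- function(rm, K = rm$K) {
  max(abs(as.numeric(K %*% rm$Q)))
}

#' Probability flux along one transition
#'
#' The equilibrium flux \eqn{K_i q_{ij}}. At detailed balance forward and
#' backward fluxes across every edge are equal.
#'
#' @param rm A [rate_matrix()].
#' @param i,j Microstate row positions (1-based, as in \code{rm$K}).
#' @return \eqn{K_i q_{ij}}; 0 with a warning for a non-adjacent pair.
#' @export
flux <- function(rm, i, j) {
  q <- rm$Q[i, j]
  if (i == j || q == 0) {
    warning("states are not adjacent; flux is 0")
    return(0)
  }
  rm$K[i] * q
}

#' Is the microstate graph a single communicating class?
#' @param rm A [rate_matrix()].
#' @return TRUE if every microstate is reachable from every other.
#' @export
is_irreducible <- function(rm) {
  g <- igraph::graph_from_edgelist(as.matrix(rm$edges[, c("from", "to")]),
                                   directed = TRUE)
  g <- igraph::add_vertices(g, max(0, length(rm$K) - igraph::vcount(g)))
  igraph::components(g, mode = "strong")$no == 1L
}

#' Relabel the microstates of a generator
#'
#' Applies a permutation to the microstate indices of a rate matrix (and its
#' embedded model), leaving the chain itself unchanged. Site-level statistics
#' such as the conditional-activity matrix are invariant under relabelling.
#'
#' @param rm A [rate_matrix()].
#' @param perm A permutation of \code{seq_along(rm$K)}; new position k holds
#'   old state \code{perm[k]}.
#' @return A relabelled \code{"rate_matrix"}.
#' @export
permute_states <- function(rm, perm) {
  stopifnot(sort(perm) == seq_along(rm$K))
  inv <- order(perm)
  edges <- rm$edges
  edges$from <- inv[edges$from]
  edges$to <- inv[edges$to]
  model <- rm$model
  model$states <- model$states[perm, , drop = FALSE]
  model$stoichiometry <- model$stoichiometry[perm, , drop = FALSE]
  model$delta_g <- model$delta_g[perm]
  structure(list(Q = rm$Q[perm, perm], edges = edges, K = rm$K[perm],
                 D = rm$D, model = model),
            class = "rate_matrix")
}

#' Export the generator as a TSV edge list
#'
#' Writes one row per allowed transition with 0-based microstate indices,
#' the rate, the transitioning site and the event type.
#'
#' @param rm A [rate_matrix()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_rate_matrix <- function(rm, path) {
  e <- rm$edges
  out <- data.frame(i = e$from - 1L, j = e$to - 1L, q_ij = e$rate,
                    site = rm$model$site_names[e$site], type = e$type)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
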