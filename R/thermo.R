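GAS_CONSTANT_KCAL <- 1.9872e-3  # kcal mol^-1 K^-1

#' Thermodynamic condition
#'
#' Temperature and the concentrations of the binding species. Concentrations
#' are those of the species that actually bind (dimers for CI and Cro);
#' monomer-dimer equilibria are not modelled.
#'
#' @param concentrations Named numeric vector, molar, one entry per ligand
#'   species of the model.
#' @param temperature_K Absolute temperature in kelvin (default 310).
#' @return An object of class \code{"thermo_condition"}.
#' @export
condition <- function(concentrations = numeric(), temperature_K = 310) {
  concentrations <- unlist(concentrations)
  if (temperature_K <= 0) stop("temperature must be positive", call. = FALSE)
  if (length(concentrations) && (is.null(names(concentrations)) || any(!nzchar(names(concentrations)))))
    stop("concentrations must be a named vector", call. = FALSE)
  if (any(concentrations < 0)) stop("concentrations must be >= 0", call. = FALSE)
  structure(list(temperature_K = as.numeric(temperature_K),
                 concentrations = concentrations),
            class = "thermo_condition")
}

#' @export
print.thermo_condition <- function(x, ...) {
  cat(sprintf("Condition: T = %g K\n", x$temperature_K))
  for (s in names(x$concentrations))
    cat(sprintf("  [%s] = %g M\n", s, x$concentrations[[s]]))
  invisible(x)
}

#' Equilibrium distribution over microstates
#'
#' Boltzmann-weighted occupancies: each microstate i receives weight
#' \deqn{K_i \propto e^{-\Delta G_i / RT} \prod_s [s]^{n_{is}}}
#' where \eqn{n_{is}} is the stoichiometry of species s in microstate i and
#' \eqn{[s]} its molar concentration. Weights are accumulated in log space
#' with max-subtraction before normalisation, so very stable states do not
#' overflow.
#'
#' @param model A [binding_model()].
#' @param cond A [condition()] covering every ligand species of the model.
#' @return An object of class \code{"equilibrium"} with \code{$probabilities}
#'   (normalised, one per microstate), \code{$log_partition} (log of the
#'   partition function Z), \code{$model}, \code{$condition}.
#' @examples
#' m <- binding_model(list(site_spec("a", c("empty", "L"))),
#'                    ligands = ligand_spec("L", data.frame(site = "a", configuration = "L")),
#'                    energy_terms = energy_term(data.frame(site = "a", configuration = "L"), -8))
#' eq <- equilibrium(m, condition(c(L = 1e-6)))
#' eq$probabilities
#' @export
equilibrium <- function(model, cond) {
  stopifnot(inherits(model, "binding_model"), inherits(cond, "thermo_condition"))
  species <- colnames(model$stoichiometry)
  missing <- setdiff(species, names(cond$concentrations))
  if (length(missing))
    stop("condition lacks concentrations for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rt <- GAS_CONSTANT_KCAL * cond$temperature_K
  logw <- -model$delta_g / rt
  for (s in species) {
    n <- model$stoichiometry[, s]
    cs <- cond$concentrations[[s]]
    # 0 M with zero stoichiometry contributes a factor 1, not 0^0 trouble
    contrib <- ifelse(n == 0, 0, n * log(cs))
    logw <- logw + contrib
  }
  m <- max(logw)
  if (!is.finite(m))
    stop("all microstate weights are zero under this condition", call. = FALSE)
  w <- exp(logw - m)
  z <- sum(w)
  structure(list(probabilities = w / z,
                 log_partition = m + log(z),
                 model = model, condition = cond),
            class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium distribution over %d microstates (log Z = %.4f)\n",
              length(x$probabilities), x$log_partition))
  top <- order(x$probabilities, decreasing = TRUE)[seq_len(min(5, length(x$probabilities)))]
  tab <- microstates(x$model)[top, , drop = FALSE]
  tab$probability <- signif(x$probabilities[top], 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Marginal configuration distribution of one site
#'
#' \eqn{P(a = x) = \sum_i K_i \chi^i_{a,x}} where the indicator
#' \eqn{\chi^i_{a,x}} is 1 when microstate i has site a in configuration x.
#'
#' @param eq An [equilibrium()] (or a probability vector, in which case
#'   \code{model} must be supplied).
#' @param site Site name.
#' @param model Optional [binding_model()] when \code{eq} is a bare vector.
#' @return Named probability vector over the site's configurations.
#' @export
site_marginal <- function(eq, site, model = NULL) {
  if (inherits(eq, "equilibrium")) { model <- eq$model; p <- eq$probabilities }
  else p <- eq
  i <- site_index(model, site)
  cfg <- model$configurations[[i]]
  out <- vapply(seq_along(cfg), function(k) sum(p[model$states[, i] == k]), 0)
  names(out) <- cfg
  out
}

#' Shannon entropy of a marginal, in bits
#'
#' @param marginal Normalised probability vector; \eqn{0 \log 0} is taken as 0.
#' @return Entropy in bits (log base 2).
#' @export
site_entropy <- function(marginal) {
  p <- marginal[marginal > 0]
  -sum(p * log2(p))
}

#' Entropies of every site
#' @param eq An [equilibrium()].
#' @return Named vector of per-site entropies in bits.
#' @export
site_entropies <- function(eq) {
  vapply(eq$model$site_names, function(s) site_entropy(site_marginal(eq, s)), 0)
}

#' Joint configuration distribution of two sites
#'
#' @param eq An [equilibrium()].
#' @param a,b Site names.
#' @return Matrix P(a = x, b = y) with a's configurations as rows.
#' @export
joint_marginal <- function(eq, a, b) {
  model <- eq$model
  ia <- site_index(model, a); ib <- site_index(model, b)
  ca <- model$configurations[[ia]]; cb <- model$configurations[[ib]]
  j <- matrix(0, length(ca), length(cb), dimnames = list(ca, cb))
  for (x in seq_along(ca)) for (y in seq_along(cb))
    j[x, y] <- sum(eq$probabilities[model$states[, ia] == x & model$states[, ib] == y])
  j
}

#' Mutual information between two binding sites, in bits
#'
#' \eqn{MI(a,b) = H(a) + H(b) - H(a,b)}, computed from the joint marginal of
#' the two sites under the equilibrium distribution. MI is symmetric,
#' non-negative, and bounded by each site's entropy; tiny negative values from
#' floating-point rounding are clamped to 0.
#'
#' @param eq An [equilibrium()].
#' @param a,b Distinct site names.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(eq, a, b) {
  if (identical(a, b))
    stop("mutual_information requires two distinct sites; use site_entropy for one site",
         call. = FALSE)
  j <- joint_marginal(eq, a, b)
  mi <- site_entropy(rowSums(j)) + site_entropy(colSums(j)) - site_entropy(as.vector(j))
  max(mi, 0)
}

#' Mutual-information matrix over all site pairs
#'
#' @param eq An [equilibrium()].
#' @return Symmetric matrix of pairwise MI in bits; the diagonal holds the
#'   site entropies.
#' @export
mi_matrix <- function(eq) {
  s <- eq$model$site_names
  m <- matrix(0, length(s), length(s), dimnames = list(s, s))
  diag(m) <- site_entropies(eq)
  if (length(s) > 1)
    for (i in seq_len(length(s) - 1)) for (k in (i + 1):length(s))
      m[i, k] <- m[k, i] <- mutual_information(eq, s[i], s[k])
  m
}
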