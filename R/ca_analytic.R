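#' Masked chain of one binding site
#'
#' For a site \eqn{a}, disallow every transition that changes \eqn{a}'s
#' configuration while keeping the full exit rates on the diagonal. The
#' resulting generator \eqn{Q^a} is block diagonal over the connected
#' components of the masked transition graph; each block is an absorbing
#' chain whose fundamental matrix \eqn{N^a = -(Q^a)^{-1}} holds the expected
#' occupation times before the site's next transition. The complementary
#' matrix \eqn{R^a} holds the disallowed (site-changing) rates, so
#' \eqn{B^a = N^a R^a} is the first-passage distribution over the states
#' entered when the site next changes, and the flux-weighted distribution
#' \deqn{K^a_i = \sum_j K_j (R^a)_{ji} \big/ \sum_{jk} K_j (R^a)_{jk}}
#' is the stationary distribution of the microstate just after an
#' \eqn{a}-transition.
#'
#' All fundamental-matrix contractions are evaluated by per-block LU solves
#' against the needed right-hand sides; no explicit inverse is formed. A
#' block whose condition-number estimate exceeds \code{cond_cap} triggers a
#' warning naming the block.
#'
#' @param rm A [rate_matrix()].
#' @param site Site name.
#' @param cond_cap Condition-estimate threshold for the per-block warning.
#' @return An object of class \code{"masked_chain"} holding the per-site
#'   contractions used by [analytic_persistence()] and
#'   [analytic_exchange()]: \code{m} (\eqn{N^a} row sums: mean time to the
#'   site's next transition from each state), \code{x1} (\eqn{K^a N^a}),
#'   \code{x2} (\eqn{K^a N^a N^a}), \code{Ka}, \code{tau_mean} (\eqn{\tau^a},
#'   the mean interval between the site's transitions), block structure and
#'   diagnostics.
#' @export
masked_chain <- function(rm, site, cond_cap = 1e12) {
  stopifnot(inherits(rm, "rate_matrix"))
  s <- site_index(rm$model, site)
  n <- length(rm$K)
  e <- rm$edges
  is_r <- e$site == s

  # flux-weighted post-transition distribution K^a
  numer <- numeric(n)
  agg <- rowsum(rm$K[e$from[is_r]] * e$rate[is_r], e$to[is_r])
  numer[as.integer(rownames(agg))] <- agg
  total_flux <- sum(numer)
  if (total_flux <= 0)
    stop(sprintf("site '%s' never transitions under this condition (zero flux)", site),
         call. = FALSE)
  Ka <- numer / total_flux

  # rate of leaving via an a-transition, per state (the R^a row sums)
  exit_a <- numeric(n)
  agg <- rowsum(e$rate[is_r], e$from[is_r])
  exit_a[as.integer(rownames(agg))] <- agg

  # connected components of the masked graph = blocks of Q^a
  g <- igraph::graph_from_edgelist(as.matrix(e[!is_r, c("from", "to")]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  blocks <- split(seq_len(n), comp)

  m <- x1 <- x2 <- b1 <- numeric(n)
  cond_max <- 0
  for (bi in seq_along(blocks)) {
    idx <- blocks[[bi]]
    if (all(exit_a[idx] == 0))
      stop(sprintf("site '%s' is frozen in the subspace of states {%s}: the masked block has no %s-changing exit and its sub-generator is singular",
                   site, paste(idx, collapse = ","), site), call. = FALSE)
    # every state of one masked component shares the site's configuration, so
    # the submatrix of the full generator IS the Q^a block (diagonal included)
    M <- as.matrix(rm$Q[idx, idx, drop = FALSE])
    kap <- kappa(M, exact = FALSE)
    cond_max <- max(cond_max, kap)
    if (kap > cond_cap)
      warning(sprintf("masked block %d of site '%s' (%d states) has condition estimate %.3g; rate spread %.3g..%.3g",
                      bi, site, length(idx), kap, min(abs(M[M != 0])), max(abs(M))))
    fw <- solve(M, cbind(rep(-1, length(idx)), -exit_a[idx]))
    m[idx] <- fw[, 1]
    b1[idx] <- fw[, 2]                      # B^a row sums, must be 1
    Mt <- t(M)
    v1 <- solve(Mt, -Ka[idx])
    x1[idx] <- v1
    x2[idx] <- solve(Mt, -v1)
  }

  structure(list(site = site, site_idx = s, blocks = blocks,
                 m = m, x1 = x1, x2 = x2, Ka = Ka,
                 tau_mean = sum(x1), total_flux = total_flux,
                 exit_a = exit_a, r_edges = e[is_r, , drop = FALSE],
                 b_rowsum_max_dev = max(abs(b1 - 1)), cond_max = cond_max,
                 n = n),
            class = "masked_chain")
}

#' @export
print.masked_chain <- function(x, ...) {
  cat(sprintf("Masked chain for site '%s': %d states in %d blocks\n",
              x$site, x$n, length(x$blocks)))
  cat(sprintf("  mean transition interval tau = %.6g, max|rowsum(B)-1| = %.3g\n",
              x$tau_mean, x$b_rowsum_max_dev))
  invisible(x)
}

#' Post-transition microstate distribution of a site
#' @param chain A [masked_chain()].
#' @return The flux-weighted probability vector over microstates entered just
#'   after the site's configuration changes.
#' @export
post_transition_distribution <- function(chain) chain$Ka

#' Dense masked generator and coupling matrix (small models)
#'
#' Materialises \eqn{Q^a} and \eqn{R^a} as dense matrices, mainly for
#' inspection and testing on small models; the production path never forms
#' them (or \eqn{N^a}) explicitly.
#'
#' @param rm A [rate_matrix()].
#' @param site Site name.
#' @return List with dense \code{Qa}, \code{Ra}, and \code{Na}
#'   (\eqn{-(Q^a)^{-1}}).
#' @export
masked_generator <- function(rm, site) {
  s <- site_index(rm$model, site)
  n <- length(rm$K)
  if (n > 2000) stop("masked_generator is for small models; use masked_chain")
  e <- rm$edges
  Qa <- matrix(0, n, n); Ra <- matrix(0, n, n)
  sel <- e$site == s
  Ra[cbind(e$from[sel], e$to[sel])] <- e$rate[sel]
  Qa[cbind(e$from[!sel], e$to[!sel])] <- e$rate[!sel]
  diag(Qa) <- -(rowSums(Qa) + rowSums(Ra))
  list(Qa = Qa, Ra = Ra, Na = -solve(Qa))
}

#' Analytic persistence time from the rate matrix
#'
#' Exact stationary persistence time of a site, computed from the masked
#' chain: with \eqn{T} the time to the site's next transition started from
#' the post-transition distribution \eqn{K^a}, the fundamental-matrix
#' identities \eqn{E[T] = K^a N^a \mathbf{1}} and
#' \eqn{E[T^2]/2 = K^a N^a N^a \mathbf{1}} give
#' \deqn{\tau_p[a] = \frac{1}{\tau^a} K^a N^a N^a \mathbf{1}, \qquad
#'   \tau^a = K^a N^a \mathbf{1}.}
#'
#' @param chain A [masked_chain()].
#' @return Persistence time in the model's time units.
#' @export
analytic_persistence <- function(chain) sum(chain$x2) / chain$tau_mean

#' Analytic exchange time from the rate matrix
#'
#' Exact stationary exchange time of site a following site b:
#' \deqn{\tau_x[a \leftarrow b] = \frac{1}{\tau^b} K^b N^b B^b m^a, \qquad
#'   m^a = N^a \mathbf{1},}
#' the expectation of (waiting time of b) times (mean residual time to a's
#' next transition, evaluated at the state reached by b's next transition).
#' The contraction follows from the occupation-time identity
#' \eqn{E_i[\text{time in } j \cdot 1(\text{absorb at } k)] =
#' (N^b)_{ij}(B^b)_{jk}}. \code{form = "printed"} interposes an additional
#' elementwise \eqn{K^a_k} weight between \eqn{B^b} and \eqn{m^a}; it is kept
#' for comparison only and does not reproduce the simulation estimator (see
#' the methods vignette).
#'
#' @param chain_a,chain_b [masked_chain()] objects for the two sites (pass
#'   the same chain twice for the self exchange time).
#' @param form Contraction variant, \code{"occupation"} (default) or
#'   \code{"printed"}.
#' @return Exchange time in the model's time units.
#' @export
analytic_exchange <- function(chain_a, chain_b, form = c("occupation", "printed")) {
  form <- match.arg(form)
  v <- if (form == "printed") chain_a$Ka * chain_a$m else chain_a$m
  re <- chain_b$r_edges
  rv <- numeric(chain_b$n)
  agg <- rowsum(re$rate * v[re$to], re$from)
  rv[as.integer(rownames(agg))] <- agg
  sum(chain_b$x2 * rv) / chain_b$tau_mean
}

#' @rdname ca_matrix
#' @param form Contraction variant for the analytic exchange time, see
#'   [analytic_exchange()].
#' @param zero_tol Analytic CA values with magnitude below this are reported
#'   as exactly 0.
#' @export
ca_matrix.rate_matrix <- function(x, form = "occupation", zero_tol = 1e-9, ...) {
  sites <- x$model$site_names
  k <- length(sites)
  chains <- vector("list", k)
  reasons <- character(k)
  for (i in seq_len(k)) {
    chains[[i]] <- tryCatch(masked_chain(x, sites[i]),
                            error = function(e) {
                              reasons[i] <<- conditionMessage(e)
                              NULL
                            })
  }
  ca <- tau_x <- matrix(NA_real_, k, k, dimnames = list(sites, sites))
  tau_p <- stats::setNames(rep(NA_real_, k), sites)
  for (a in seq_len(k)) {
    if (is.null(chains[[a]])) next
    tau_p[a] <- analytic_persistence(chains[[a]])
    for (b in seq_len(k)) {
      if (is.null(chains[[b]])) next
      tau_x[a, b] <- analytic_exchange(chains[[a]], chains[[b]], form = form)
      ca[a, b] <- -log10(tau_x[a, b] / tau_p[a])
    }
  }
  ca[!is.na(ca) & abs(ca) < zero_tol] <- 0
  structure(list(ca = ca, tau_p = tau_p, tau_x = tau_x, se = NULL,
                 method = "analytic", na_reasons = reasons[nzchar(reasons)],
                 diagnostics = data.frame(
                   site = sites,
                   n_blocks = vapply(chains, function(ch) if (is.null(ch)) NA_integer_ else length(ch$blocks), 0L),
                   cond_max = vapply(chains, function(ch) if (is.null(ch)) NA_real_ else ch$cond_max, 0),
                   tau_mean = vapply(chains, function(ch) if (is.null(ch)) NA_real_ else ch$tau_mean, 0),
                   tau_p = as.numeric(tau_p))),
            class = "ca_table")
}

#' Export per-site analytic diagnostics
#' @param tab An analytic \code{"ca_table"}.
#' @param path Output TSV.
#' @return \code{path}, invisibly.
#' @export
write_ca_diagnostics <- function(tab, path) {
  stopifnot(identical(tab$method, "analytic"))
  utils::write.table(tab$diagnostics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
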