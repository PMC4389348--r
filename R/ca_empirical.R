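#' Empirical persistence time of a binding site
#'
#' Half the mean squared waiting time between the site's transitions,
#' normalised by the observation time:
#' \deqn{\tau_p[a] = \frac{1}{2\tau} \sum_t W(a, T(a,t))^2}
#' where \eqn{W(a, T)} is the time from \eqn{T} to the site's next transition.
#' The sum runs over events with a defined next event; \eqn{\tau} is the
#' duration of the observation window. For long stationary records this
#' converges to the mean residual time to the site's next transition seen by
#' a random observer (the inspection-paradox mean \eqn{E[W^2]/2E[W]}).
#'
#' @param series A [site_events()] object.
#' @return Persistence time (same units as the event times); \code{NA} when
#'   the series has fewer than 2 events.
#' @export
persistence_time <- function(series) {
  stopifnot(inherits(series, "site_events"))
  if (length(series$times) < 2) return(NA_real_)
  w <- diff(series$times)
  tau <- diff(series$window)
  sum(w^2) / (2 * tau)
}

#' Empirical exchange time of site a following site b
#'
#' For each pair of consecutive transitions of \eqn{b}, multiplies the waiting
#' time of \eqn{b} by the residual time until \eqn{a}'s next transition after
#' \eqn{b}'s second transition, normalised by the observation time:
#' \deqn{\tau_x[a \leftarrow b] = \frac{1}{\tau} \sum_{t=1}^{N(b)-1}
#'   W(a, T(b,t+1))\, W(b, T(b,t))}
#' Terms whose next \eqn{a}-event falls beyond the window are dropped (their
#' count is attached as attribute \code{n_dropped}; a warning triggers when
#' more than 1\% are dropped). When \eqn{a} and \eqn{b} are independent the
#' exchange time converges to the persistence time of \eqn{a}, making the
#' conditional activity vanish.
#'
#' @param series_a,series_b [site_events()] sharing one observation window.
#' @return Exchange time with attributes \code{n_terms} and \code{n_dropped};
#'   \code{NA} when there are too few events.
#' @export
exchange_time <- function(series_a, series_b) {
  stopifnot(inherits(series_a, "site_events"), inherits(series_b, "site_events"))
  if (!isTRUE(all.equal(series_a$window, series_b$window)))
    stop("event series have different observation windows", call. = FALSE)
  tb <- series_b$times; ta <- series_a$times
  if (length(tb) < 2 || length(ta) < 1) return(NA_real_)
  tau <- diff(series_b$window)
  wb <- diff(tb)               # W(b, T(b,t)), t = 1..N(b)-1
  anchor <- tb[-1]             # T(b,t+1)
  nxt <- findInterval(anchor, ta) + 1L  # first a-event strictly after anchor
  ok <- nxt <= length(ta)
  dropped <- sum(!ok)
  if (dropped > 0.01 * length(anchor))
    warning(sprintf("%d of %d exchange terms truncated by the window end",
                    dropped, length(anchor)))
  wa <- ta[nxt[ok]] - anchor[ok]
  structure(sum(wa * wb[ok]) / tau, n_terms = sum(ok), n_dropped = dropped)
}

#' Empirical conditional activity of a following b
#'
#' The conditional activity is the waiting-time correlation function
#' \deqn{CA[a \leftarrow b] = -\log_{10}\left(\tau_x[a \leftarrow b] /
#'   \tau_p[a]\right).}
#' It vanishes for independent sites and for Poisson (i.i.d.
#' exponential-interval) transition processes, and is positive when a
#' transition of \eqn{b} hastens the next transition of \eqn{a}. Unlike
#' mutual information it is asymmetric in (a, b), because it is sensitive to
#' the time-ordering of events.
#'
#' Standard errors come from a joint non-overlapping block bootstrap: the
#' window is cut into \code{blocks} equal subwindows, the persistence and
#' exchange sums are accumulated per subwindow, and whole subwindows are
#' resampled with replacement (terms of a point process are serially
#' correlated, so a plain bootstrap over terms would be too optimistic).
#'
#' @param series_a,series_b [site_events()] sharing one observation window;
#'   pass the same series twice for the self conditional activity.
#' @param n_boot Bootstrap replicates for the standard error (0 to skip).
#' @param blocks Number of bootstrap subwindows.
#' @return An object of class \code{"ca_estimate"}: \code{value} (log10
#'   units), \code{tau_p}, \code{tau_x}, \code{n_a}, \code{n_b}, \code{se}
#'   (NA when not bootstrapped), \code{defined}.
#' @examples
#' a <- site_events("a", c(1, 3, 3.5, 6), c("L", "empty", "L", "empty"), c(0, 6))
#' conditional_activity(a, a)
#' @export
conditional_activity <- function(series_a, series_b, n_boot = 0, blocks = 50) {
  tau_p <- persistence_time(series_a)
  tau_x <- exchange_time(series_a, series_b)
  defined <- !is.na(tau_p) && !is.na(tau_x)
  value <- if (!defined) NA_real_
           else if (tau_x == 0) Inf
           else -log10(as.numeric(tau_x) / tau_p)
  se <- NA_real_
  if (defined && n_boot > 0 && is.finite(value))
    se <- ca_block_bootstrap(series_a, series_b, n_boot, blocks)
  structure(list(value = value, tau_p = tau_p, tau_x = as.numeric(tau_x),
                 n_a = length(series_a$times), n_b = length(series_b$times),
                 n_dropped = if (is.na(tau_x)) NA_integer_ else attr(tau_x, "n_dropped"),
                 se = se, defined = defined),
            class = "ca_estimate")
}

#' @export
print.ca_estimate <- function(x, ...) {
  if (!x$defined) {
    cat("CA estimate: undefined (fewer than 2 events in a series)\n")
  } else {
    cat(sprintf("CA = %.4f  (tau_p = %.6g, tau_x = %.6g, n_a = %d, n_b = %d%s)\n",
                x$value, x$tau_p, x$tau_x, x$n_a, x$n_b,
                if (is.na(x$se)) "" else sprintf(", se = %.4f", x$se)))
  }
  invisible(x)
}

# joint block bootstrap over subwindows of the observation window
ca_block_bootstrap <- function(series_a, series_b, n_boot, blocks) {
  win <- series_a$window
  breaks <- seq(win[1], win[2], length.out = blocks + 1)
  tau_blk <- diff(win) / blocks

  ta <- series_a$times
  wa2 <- diff(ta)^2
  blk_p <- findInterval(ta[-length(ta)], breaks, rightmost.closed = TRUE)
  sp <- numeric(blocks)
  if (length(wa2)) { agg <- rowsum(wa2, blk_p); sp[as.integer(rownames(agg))] <- agg }

  tb <- series_b$times
  wb <- diff(tb); anchor <- tb[-1]
  nxt <- findInterval(anchor, ta) + 1L
  ok <- nxt <= length(ta)
  terms <- (ta[nxt[ok]] - anchor[ok]) * wb[ok]
  blk_x <- findInterval(tb[-length(tb)][ok], breaks, rightmost.closed = TRUE)
  sx <- numeric(blocks)
  if (length(terms)) { agg <- rowsum(terms, blk_x); sx[as.integer(rownames(agg))] <- agg }

  reps <- vapply(seq_len(n_boot), function(k) {
    pick <- sample.int(blocks, blocks, replace = TRUE)
    tp <- sum(sp[pick]) / (2 * blocks * tau_blk)
    tx <- sum(sx[pick]) / (blocks * tau_blk)
    if (tp <= 0 || tx <= 0) NA_real_ else -log10(tx / tp)
  }, 0)
  stats::sd(reps, na.rm = TRUE)
}

#' Conditional-activity matrix
#'
#' Computes the full asymmetric site-by-site table of conditional activities,
#' \code{ca[a, b] = CA[a <- b]} (row = target site, column = conditioning
#' site; the diagonal holds the self conditional activity). Dispatches on the
#' input: a [rate_matrix()] gives the exact analytic table via absorbing-chain
#' algebra, a trajectory or list of [site_events()] gives the empirical
#' estimate.
#'
#' @param x A [rate_matrix()], a trajectory, or a named list of
#'   [site_events()] sharing one window.
#' @param ... Method arguments.
#' @return An object of class \code{"ca_table"} with components \code{ca},
#'   \code{tau_p}, \code{tau_x}, \code{se} (empirical only), \code{method}.
#' @export
ca_matrix <- function(x, ...) UseMethod("ca_matrix")

#' @rdname ca_matrix
#' @param n_boot,blocks Bootstrap settings passed to
#'   [conditional_activity()] (empirical methods).
#' @export
ca_matrix.trajectory <- function(x, n_boot = 0, blocks = 50, ...) {
  ca_matrix(project_all_events(x), n_boot = n_boot, blocks = blocks)
}

#' @rdname ca_matrix
#' @export
ca_matrix.list <- function(x, n_boot = 0, blocks = 50, ...) {
  stopifnot(length(x) > 0, all(vapply(x, inherits, TRUE, "site_events")))
  win <- x[[1]]$window
  for (e in x) if (!isTRUE(all.equal(e$window, win)))
    stop("event series have different observation windows", call. = FALSE)
  sites <- unname(vapply(x, function(e) e$site, ""))
  names(x) <- sites
  k <- length(sites)
  ca <- tau_x <- se <- matrix(NA_real_, k, k, dimnames = list(sites, sites))
  tau_p <- stats::setNames(vapply(x, persistence_time, 0), sites)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    est <- conditional_activity(x[[a]], x[[b]], n_boot = n_boot, blocks = blocks)
    ca[a, b] <- est$value
    tau_x[a, b] <- est$tau_x
    se[a, b] <- est$se
  }
  structure(list(ca = ca, tau_p = tau_p, tau_x = tau_x,
                 se = if (n_boot > 0) se else NULL, method = "empirical"),
            class = "ca_table")
}

#' @export
print.ca_table <- function(x, digits = 4, ...) {
  cat(sprintf("Conditional-activity table (%s), ca[a, b] = CA[a <- b]:\n", x$method))
  print(round(x$ca, digits))
  invisible(x)
}

#' Export a conditional-activity table
#'
#' Writes the site-by-site matrix (4 decimal places, undefined cells as
#' \code{NA}) and, optionally, a long-format table with per-pair persistence
#' time, exchange time, and standard error.
#'
#' @param tab A \code{"ca_table"}.
#' @param path Output TSV for the matrix.
#' @param long_path Optional output TSV for the long format.
#' @return \code{path}, invisibly.
#' @export
write_ca_table <- function(tab, path, long_path = NULL) {
  m <- round(tab$ca, 4)
  utils::write.table(cbind(site = rownames(m), as.data.frame(m)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  if (!is.null(long_path)) {
    sites <- rownames(tab$ca)
    g <- expand.grid(a = sites, b = sites, stringsAsFactors = FALSE)
    long <- data.frame(a = g$a, b = g$b,
                       ca = round(tab$ca[cbind(g$a, g$b)], 4),
                       tau_x = tab$tau_x[cbind(g$a, g$b)],
                       tau_p = tab$tau_p[g$a],
                       se = if (is.null(tab$se)) NA_real_ else tab$se[cbind(g$a, g$b)])
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  invisible(path)
}
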