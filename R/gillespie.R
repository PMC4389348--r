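#' Exact stochastic simulation of the binding chain
#'
#' Samples a trajectory of the continuous-time Markov chain with the Gillespie
#' algorithm: in each state the holding time is exponential with the state's
#' total exit rate and the jump target is chosen proportionally to the
#' individual transition rates. Simulation stops at whichever of \code{t_max}
#' or \code{n_events} is reached first (at least one must be finite).
#'
#' @param object A [rate_matrix()].
#' @param nsim Number of independent trajectories (default 1; a list is
#'   returned when \code{nsim > 1}).
#' @param seed Integer seed recorded in the trajectory; when non-NULL the RNG
#'   is seeded with it.
#' @param initial Starting microstate (1-based row position). Default samples
#'   from the equilibrium distribution, so the trajectory is stationary from
#'   time 0 and estimators need no burn-in.
#' @param t_max Stop after this much simulated time.
#' @param n_events Stop after this many jumps.
#' @param burn_in Time discarded from the start of the record (default 0;
#'   useful with a fixed non-stationary \code{initial}).
#' @param ... Unused.
#' @return An object of class \code{"trajectory"}: \code{$jump_times},
#'   \code{$states} (microstate after each jump), \code{$site_changed}
#'   (which site each jump toggled), \code{$initial_state}, \code{$t_end},
#'   \code{$seed}, \code{$model}.
#' @examples
#' m <- binding_model(list(site_spec("a", c("empty", "L"))),
#'                    ligands = ligand_spec("L", data.frame(site = "a", configuration = "L")))
#' rm <- rate_matrix(equilibrium(m, condition(c(L = 1))))
#' tr <- simulate(rm, seed = 1, n_events = 100)
#' @export
simulate.rate_matrix <- function(object, nsim = 1, seed = NULL, initial = NULL,
                                 t_max = Inf, n_events = Inf, burn_in = 0, ...) {
  if (!is.finite(t_max) && !is.finite(n_events))
    stop("one of t_max or n_events must be finite", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (nsim > 1) {
    return(lapply(seq_len(nsim), function(k)
      simulate.rate_matrix(object, nsim = 1, seed = NULL, initial = initial,
                           t_max = t_max, n_events = n_events, burn_in = burn_in)))
  }
  n <- length(object$K)
  if (is.null(initial)) initial <- sample.int(n, 1, prob = object$K)
  stopifnot(initial >= 1, initial <= n)

  csr <- edges_to_csr(object$edges, n)
  res <- ssa_run_cpp(csr$ptr, csr$idx, csr$rate, csr$exit,
                     as.integer(initial) - 1L, t_max, n_events)
  t_end <- if (res$hit_tmax) t_max else
    (if (length(res$times)) res$times[length(res$times)] else 0)

  sc <- site_change_lookup(object)
  prev <- c(initial, res$states[-length(res$states)])
  site_changed <- if (length(res$states)) sc[cbind(prev, res$states)] else integer()

  traj <- structure(list(jump_times = res$times, states = res$states,
                         site_changed = site_changed,
                         initial_state = as.integer(initial), t_end = t_end,
                         seed = seed, model = object$model),
                    class = "trajectory")
  if (burn_in > 0) traj <- trim_trajectory(traj, burn_in)
  traj
}

edges_to_csr <- function(edges, n) {
  o <- order(edges$from, edges$to)
  from <- edges$from[o]; to <- edges$to[o]; rate <- edges$rate[o]
  cnt <- tabulate(from, n)
  ptr <- c(0L, cumsum(cnt))
  exit <- as.numeric(rowsum(rate, factor(from, levels = seq_len(n))))
  exit[is.na(exit)] <- 0
  list(ptr = as.integer(ptr), idx = as.integer(to - 1L), rate = rate, exit = exit)
}

# dense lookup: which site changes between two adjacent states (0 otherwise)
site_change_lookup <- function(rm) {
  n <- length(rm$K)
  m <- matrix(0L, n, n)
  m[cbind(rm$edges$from, rm$edges$to)] <- rm$edges$site
  m
}

trim_trajectory <- function(traj, burn_in) {
  keep <- traj$jump_times > burn_in
  if (!any(keep)) stop("burn_in discards the whole trajectory", call. = FALSE)
  first <- which(keep)[1]
  init <- if (first == 1L) traj$initial_state else traj$states[first - 1L]
  structure(list(jump_times = traj$jump_times[keep] - burn_in,
                 states = traj$states[keep],
                 site_changed = traj$site_changed[keep],
                 initial_state = init, t_end = traj$t_end - burn_in,
                 seed = traj$seed, model = traj$model),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d jumps over [0, %g] (seed %s)\n",
              length(x$jump_times), x$t_end,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Binding-event series of one site
#'
#' Container for the ordered transition times of one binding site within an
#' observation window, the substrate of the empirical conditional-activity
#' estimators; build one by hand for experimental records or via
#' [project_events()] from a simulated trajectory.
#'
#' @param site Site label.
#' @param times Strictly increasing event times within the window.
#' @param new_config Configuration label after each event; consecutive values
#'   must differ.
#' @param window Length-2 numeric, the observation window.
#' @return An object of class \code{"site_events"}.
#' @export
site_events <- function(site, times, new_config, window) {
  stopifnot(length(times) == length(new_config), length(window) == 2)
  if (length(times)) {
    if (any(diff(times) <= 0)) stop("event times must be strictly increasing", call. = FALSE)
    if (any(times < window[1] | times > window[2]))
      stop("event times outside the observation window", call. = FALSE)
    if (length(times) > 1 && any(new_config[-1] == new_config[-length(new_config)]))
      stop("consecutive events must change the configuration", call. = FALSE)
  }
  structure(list(site = site, times = as.numeric(times),
                 new_config = new_config, window = as.numeric(window)),
            class = "site_events")
}

#' @export
print.site_events <- function(x, ...) {
  cat(sprintf("Site '%s': %d events in [%g, %g]\n", x$site, length(x$times),
              x$window[1], x$window[2]))
  invisible(x)
}

#' Project a trajectory onto one binding site
#'
#' Retains exactly the jumps that change the site's configuration. Each jump
#' of the microstate chain changes exactly one site, so the per-site event
#' counts sum to the total jump count.
#'
#' @param traj A [simulate.rate_matrix()] trajectory.
#' @param site Site name.
#' @return A [site_events()] object with window \code{[0, t_end]}.
#' @export
project_events <- function(traj, site) {
  stopifnot(inherits(traj, "trajectory"))
  s <- site_index(traj$model, site)
  sel <- traj$site_changed == s
  cfg <- traj$model$configurations[[s]][traj$model$states[traj$states[sel], s]]
  site_events(site, traj$jump_times[sel], cfg, c(0, traj$t_end))
}

#' Project a trajectory onto every site
#' @param traj A trajectory.
#' @return Named list of [site_events()], one per site.
#' @export
project_all_events <- function(traj) {
  out <- lapply(traj$model$site_names, function(s) project_events(traj, s))
  names(out) <- traj$model$site_names
  out
}

#' Time-weighted empirical state occupancy
#'
#' Fraction of elapsed time the trajectory spent in each microstate; by
#' ergodicity this converges to the equilibrium distribution.
#'
#' @param traj A trajectory with \code{t_end > 0}.
#' @return Probability vector over microstates.
#' @export
empirical_occupancy <- function(traj) {
  stopifnot(traj$t_end > 0)
  n <- nrow(traj$model$states)
  seq_states <- c(traj$initial_state, traj$states)
  dur <- diff(c(0, traj$jump_times, traj$t_end))
  occ <- numeric(n)
  agg <- rowsum(dur, seq_states)
  occ[as.integer(rownames(agg))] <- agg
  occ / traj$t_end
}

#' Time-weighted empirical marginal of one site
#' @param traj A trajectory.
#' @param site Site name.
#' @return Named probability vector over the site's configurations.
#' @export
empirical_site_marginal <- function(traj, site) {
  occ <- empirical_occupancy(traj)
  site_marginal(occ, site, model = traj$model)
}

#' Write binding-event series as TSV
#'
#' One row per event with columns \code{time}, \code{site},
#' \code{new_configuration}; header comment lines record the observation
#' window and the seed. Times are written with 15 significant digits. The
#' same dialect is accepted for experimental event records.
#'
#' @param x A trajectory or a (list of) [site_events()].
#' @param path Output file.
#' @param seed Seed recorded in the header (taken from a trajectory
#'   automatically).
#' @return \code{path}, invisibly.
#' @export
write_events <- function(x, path, seed = NULL) {
  if (inherits(x, "trajectory")) { seed <- x$seed; x <- project_all_events(x) }
  if (inherits(x, "site_events")) x <- list(x)
  win <- x[[1]]$window
  tab <- do.call(rbind, lapply(x, function(e)
    data.frame(time = e$times, site = e$site, new_configuration = e$new_config)))
  tab <- tab[order(tab$time), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# window\t%.15g\t%.15g", win[1], win[2]), con)
  writeLines(sprintf("# seed\t%s", if (is.null(seed)) "NA" else seed), con)
  writeLines("time\tsite\tnew_configuration", con)
  if (nrow(tab))
    writeLines(sprintf("%.15g\t%s\t%s", tab$time, tab$site, tab$new_configuration), con)
  invisible(path)
}

#' Read binding-event series from TSV
#'
#' Parses the dialect written by [write_events()]. Times must be strictly
#' increasing per site, and duplicate timestamps across sites are rejected:
#' in a continuous-time model simultaneous transitions have measure zero, so
#' coincident times indicate an export problem (jitter or re-export).
#'
#' @param path Input file.
#' @return Named list of [site_events()] sharing one window, with the seed
#'   (if recorded) as attribute \code{"seed"}.
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  win <- c(0, NA)
  seed <- NULL
  for (h in hdr) {
    f <- strsplit(sub("^#\\s*", "", h), "\t")[[1]]
    if (f[1] == "window") win <- as.numeric(f[2:3])
    if (f[1] == "seed" && f[2] != "NA") seed <- as.integer(f[2])
  }
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           colClasses = c("numeric", "character", "character"))
  if (anyDuplicated(tab$time))
    stop("duplicate timestamps in event file; continuous-time records must have ",
         "distinct event times -- jitter or re-export", call. = FALSE)
  if (is.unsorted(tab$time)) stop("event times must be increasing", call. = FALSE)
  if (is.na(win[2])) win[2] <- max(tab$time, 0)
  out <- lapply(split(tab, tab$site), function(d)
    site_events(d$site[1], d$time, d$new_configuration, win))
  attr(out, "seed") <- seed
  out
}
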