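#' Reaction propensities of the full stochastic model
#'
#' Mass-action propensities of the twelve reactions: substrate binding
#' and unbinding, forward and reverse catalysis, translation,
#' transcription, promoter activation/deactivation, metabolite
#' consumption, mRNA degradation, and dilution of free enzyme and
#' complex. The substrate copy number `n_s` is constant. Total enzyme
#' `n_e + n_c` changes only through translation and the two dilution
#' reactions; mRNA is removed by degradation only and the metabolite by
#' consumption only.
#'
#' @param state named list or vector with `dna_on` (0/1), `n_m`, `n_e`,
#'   `n_c`, `n_p` (non-negative integers).
#' @param rc a [rate_constants()] object.
#' @return Named numeric vector of 12 rates (s^-1), in the order
#'   `binding, unbinding, catalysis, reverse_catalysis, translation,
#'   transcription, promoter_on, promoter_off, consumption,
#'   mrna_degradation, enzyme_dilution, complex_dilution`.
#' @examples
#' rc <- preset_rate_constants("table1")
#' ssa_propensities(list(dna_on = 1, n_m = 1, n_e = 100, n_c = 0, n_p = 0), rc)
#' @export
ssa_propensities <- function(state, rc) {
  stopifnot(inherits(rc, "rate_constants"))
  s <- as.list(state)
  with(s, {
    stopifnot(dna_on %in% c(0, 1), n_m >= 0, n_e >= 0, n_c >= 0, n_p >= 0)
    c(binding = rc$k_1 * rc$n_s * n_e,
      unbinding = rc$k_m1 * n_c,
      catalysis = rc$k_cat * n_c,
      reverse_catalysis = rc$k_rev * n_e * n_p,
      translation = rc$k_tl * n_m,
      transcription = rc$k_tx * dna_on,
      promoter_on = rc$k_on * (1 - dna_on),
      promoter_off = rc$k_off * dna_on,
      consumption = rc$k_c * n_p,
      mrna_degradation = rc$k_deg * n_m,
      enzyme_dilution = rc$delta * n_e,
      complex_dilution = rc$delta * n_c)
  })
}

#' State-change vectors matching [ssa_propensities()]
#'
#' @return A 5 x 12 integer matrix (rows: `dna_on`, `n_m`, `n_e`, `n_c`,
#'   `n_p`; columns in propensity order).
#' @export
ssa_stoichiometry <- function() {
  m <- matrix(c(
    0, 0, -1, 1, 0,
    0, 0, 1, -1, 0,
    0, 0, 1, -1, 1,
    0, 0, -1, 1, -1,
    0, 0, 1, 0, 0,
    0, 1, 0, 0, 0,
    1, 0, 0, 0, 0,
    -1, 0, 0, 0, 0,
    0, 0, 0, 0, -1,
    0, -1, 0, 0, 0,
    0, 0, -1, 0, 0,
    0, 0, 0, -1, 0), nrow = 5)
  dimnames(m) <- list(c("dna_on", "n_m", "n_e", "n_c", "n_p"),
                      c("binding", "unbinding", "catalysis",
                        "reverse_catalysis", "translation", "transcription",
                        "promoter_on", "promoter_off", "consumption",
                        "mrna_degradation", "enzyme_dilution",
                        "complex_dilution"))
  m
}

#' Exact Gillespie simulation of the full model
#'
#' Direct-method stochastic simulation of all twelve reactions. The
#' trajectory is thinned onto a uniform recording grid for storage, but
#' stationary occupancy histograms are accumulated from the exact event
#' holding times (after `burn_in`) during the run, so histograms do not
#' suffer from thinning.
#'
#' @param rc a [rate_constants()] object.
#' @param t_end simulated time (s). A convenient unit is cell cycles of
#'   `log(2)/delta` seconds.
#' @param seed integer seed for the simulator's own reproducible RNG
#'   (independent of R's RNG state).
#' @param burn_in time (s) excluded from the stationary histograms
#'   (default 20 cell cycles).
#' @param init initial state `c(dna_on, n_m, n_e, n_c, n_p)`; default
#'   all-zero with the promoter off. Stationary summaries must not
#'   depend on this choice (only on `burn_in` being long enough).
#' @param record_dt recording grid spacing (s); default `t_end/1000`.
#'   Set `0` to record only the initial and final states.
#' @param max_events abort if the event count exceeds this budget
#'   (default `6e10`).
#' @return An object of class `trajectory`: list with `times` and the
#'   five species columns, plus attributes `rc`, `seed`, `burn_in`,
#'   `events`, and the exact holding-time histograms used by
#'   [stationary_histogram()].
#' @examples
#' rc <- preset_rate_constants("table1")
#' rc_small <- update_rate_constants(rc, n_s = 30, k_m1 = 10, k_cat = 0.5)
#' traj <- ssa_simulate(rc_small, t_end = 2e4, seed = 1, burn_in = 5e3)
#' @export
ssa_simulate <- function(rc, t_end, seed, burn_in = 20 * log(2) / rc$delta,
                         init = c(0L, 0L, 0L, 0L, 0L),
                         record_dt = t_end / 1000, max_events = 6e10) {
  stopifnot(inherits(rc, "rate_constants"), t_end > 0,
            burn_in >= 0, burn_in < t_end, length(init) == 5L)
  seed <- as.numeric(seed)
  stopifnot(length(seed) == 1L, is.finite(seed))
  pars <- unlist(unclass(rc))
  res <- .ssa_run(pars, t_end, burn_in, as.integer(init), record_dt,
                  seed, max_events)
  hist <- list(n_m = res$hist_m, n_e = res$hist_ne, n_c = res$hist_nc,
               n_p = res$hist_np, n_etot = res$hist_etot)
  structure(list(times = res$times, dna_on = res$dna_on, n_m = res$n_m,
                 n_e = res$n_e, n_c = res$n_c, n_p = res$n_p),
            class = "trajectory",
            rc = rc, seed = seed, burn_in = burn_in,
            t_end = t_end, events = res$events,
            exact_hist = hist, hist_time = res$hist_time,
            final_state = res$final_state)
}

#' @method print trajectory
#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(paste0("SSA trajectory: %d recorded points over %.4g s ",
                     "(%.3g events, seed %g, burn-in %.4g s)\n"),
              length(x$times), attr(x, "t_end"), attr(x, "events"),
              attr(x, "seed"), attr(x, "burn_in")))
  invisible(x)
}

#' Construct a trajectory from explicit event times and states
#'
#' Mainly for tests and for loading externally produced piecewise-constant
#' sample paths. States hold from each time until the next; the last
#' state holds until `t_end`.
#'
#' @param times strictly increasing event times (first `>= 0`).
#' @param states data frame or matrix with columns `dna_on`, `n_m`,
#'   `n_e`, `n_c`, `n_p` (one row per time).
#' @param t_end end of the observation window (default: last time).
#' @return A `trajectory` object (without exact histograms; see
#'   [stationary_histogram()]).
#' @export
new_trajectory <- function(times, states, t_end = max(times)) {
  stopifnot(length(times) >= 1L, all(diff(times) > 0), times[1] >= 0,
            t_end >= max(times))
  states <- as.data.frame(states)
  need <- c("dna_on", "n_m", "n_e", "n_c", "n_p")
  stopifnot(all(need %in% names(states)), nrow(states) == length(times))
  structure(c(list(times = as.numeric(times)),
              lapply(states[need], as.integer)),
            class = "trajectory", t_end = t_end, burn_in = NA_real_)
}

#' Stationary occupancy histogram of one species
#'
#' Time-weighted occupancy over `[burn_in, t_end]`: each state is
#' weighted by its holding time, not by event counts. For trajectories
#' produced by [ssa_simulate()], the exact histograms accumulated during
#' the run are used whenever `burn_in` matches the simulation's; for
#' trajectories built with [new_trajectory()] (or a different burn-in on
#' an unthinned trajectory) the histogram is integrated from the stored
#' piecewise-constant path.
#'
#' @param traj a `trajectory`.
#' @param species one of `"n_m"`, `"n_e"`, `"n_c"`, `"n_p"`, `"n_etot"`.
#' @param burn_in initial time span to discard (default: the
#'   trajectory's own burn-in, else 0).
#' @return A [discrete_pmf()] with provenance `"ssa"`.
#' @export
stationary_histogram <- function(traj, species = "n_p",
                                 burn_in = attr(traj, "burn_in")) {
  stopifnot(inherits(traj, "trajectory"),
            species %in% c("n_m", "n_e", "n_c", "n_p", "n_etot"))
  if (is.null(burn_in) || is.na(burn_in)) burn_in <- 0
  t_end <- attr(traj, "t_end")
  if (burn_in >= t_end) stop("burn_in leaves an empty window", call. = FALSE)
  eh <- attr(traj, "exact_hist")
  bi <- attr(traj, "burn_in")
  if (!is.null(eh) && !is.na(bi) && isTRUE(all.equal(burn_in, bi))) {
    w <- eh[[species]]
    w <- w[seq_len(max(which(w > 0)))]   # drop preallocated trailing zeros
    return(discrete_pmf(w / sum(w), provenance = "ssa"))
  }
  # integrate the stored piecewise-constant path
  vals <- if (species == "n_etot") traj$n_e + traj$n_c else traj[[species]]
  times <- traj$times
  # clip each holding interval to [burn_in, t_end]
  starts <- times
  ends <- c(times[-1], t_end)
  w <- pmax(0, pmin(ends, t_end) - pmax(starts, burn_in))
  if (sum(w) <= 0) stop("empty post-burn-in window", call. = FALSE)
  agg <- rowsum(w, vals)
  probs <- numeric(max(vals) + 1L)
  probs[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  discrete_pmf(probs / sum(probs), provenance = "ssa")
}

#' Write / read a trajectory as a tab-separated table
#'
#' Six columns (`time, dna_on, n_m, n_e, n_c, n_p`) with a `#` metadata
#' header carrying the seed and a parameter fingerprint.
#'
#' @param traj a `trajectory` from [ssa_simulate()].
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly;
#'   `read_trajectory` a `trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  rc <- attr(traj, "rc")
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(sprintf("# seed: %g", attr(traj, "seed") %||% NA),
            sprintf("# t_end: %.17g", attr(traj, "t_end")),
            sprintf("# burn_in: %.17g", attr(traj, "burn_in") %||% NA),
            if (!is.null(rc))
              sprintf("# params: %s",
                      paste(sprintf("%s=%.17g", names(unclass(rc)),
                                    unlist(unclass(rc))), collapse = " ")),
            "# time\tdna_on\tn_m\tn_e\tn_c\tn_p")
  writeLines(meta, con)
  writeLines(sprintf("%.17g\t%d\t%d\t%d\t%d\t%d", traj$times, traj$dna_on,
                     traj$n_m, traj$n_e, traj$n_c, traj$n_p), con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_meta <- function(key) {
    v <- sub(paste0("^# ", key, ": "), "",
             grep(paste0("^# ", key, ":"), hdr, value = TRUE))
    if (length(v) == 1L) as.numeric(v) else NA_real_
  }
  df <- utils::read.table(text = body, sep = "\t",
                          col.names = c("time", "dna_on", "n_m", "n_e",
                                        "n_c", "n_p"))
  t_end <- get_meta("t_end")
  if (is.na(t_end)) t_end <- max(df$time)
  tr <- new_trajectory(df$time, df[-1], t_end = t_end)
  attr(tr, "seed") <- get_meta("seed")
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
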