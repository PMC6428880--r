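#' Stationary distribution of a truncated chemical master equation
#'
#' Finite-state projection used as an independent validation oracle: the
#' state space is a box (a Cartesian product of integer ranges), the
#' generator is assembled from a stoichiometry matrix and a vectorised
#' propensity function, transitions that would leave the box are dropped
#' (reflecting truncation), and the stationary law solves
#' \eqn{\pi Q = 0} with \eqn{\sum \pi = 1} by sparse LU factorisation.
#'
#' This is exact for the truncated chain; adequacy of the truncation is
#' monitored through the probability mass on the box boundary, and the
#' solve aborts if it exceeds `boundary_tol`.
#'
#' @param stoich integer matrix, species x reactions: net state change of
#'   each reaction.
#' @param propensity function taking an integer state matrix (states x
#'   species) and returning a non-negative rate matrix (states x
#'   reactions).
#' @param caps integer vector of per-species maximum copy numbers (the
#'   box is `0..caps[i]` in each coordinate).
#' @param boundary_tol maximal tolerated stationary mass on boundary
#'   states, checked for every species with `caps > 1` whose cap can be
#'   hit (default `1e-6`).
#' @param max_states refuse larger truncated spaces (default `2e6`).
#' @param method `"lu"` (sparse direct solve; accurate but can be
#'   memory-hungry on high-dimensional boxes), `"power"` (uniformised
#'   power iteration; slower but with linear memory), or `"auto"`
#'   (default: LU up to 20000 states, power iteration beyond).
#' @param power_tol stationary residual `max|Q' pi|/Lambda` at which the
#'   power iteration stops (default `1e-10`).
#' @return A list of class `cme_solution`: `pi` (stationary probability
#'   per state), `states` (states x species integer matrix), `caps`,
#'   `boundary_mass`, and `marginal(expr)` is available via
#'   [cme_marginal()].
#' @examples
#' # birth-death: birth 5/s, per-molecule death 1/s -> Poisson(5)
#' sol <- cme_stationary(matrix(c(1, -1), 1), function(s)
#'   cbind(5, 1 * s[, 1]), caps = 60)
#' @export
cme_stationary <- function(stoich, propensity, caps,
                           boundary_tol = 1e-6, max_states = 2e6,
                           method = c("auto", "lu", "power"),
                           power_tol = 1e-10) {
  method <- match.arg(method)
  stoich <- as.matrix(stoich)
  n_species <- nrow(stoich)
  n_reactions <- ncol(stoich)
  caps <- as.integer(caps)
  stopifnot(length(caps) == n_species, all(caps >= 1))
  dims <- caps + 1L
  n_states <- prod(dims)
  if (n_states > max_states)
    stop("truncated state space has ", n_states, " states (> max_states)",
         call. = FALSE)
  # enumerate states; column-major strides
  states <- arrayInd(seq_len(n_states), dims) - 1L
  strides <- c(1, cumprod(dims[-n_species]))
  rates <- propensity(states)
  if (is.null(dim(rates))) rates <- matrix(rates, ncol = n_reactions)
  stopifnot(ncol(rates) == n_reactions, nrow(rates) == n_states)
  if (any(rates < 0)) stop("negative propensity", call. = FALSE)
  ii <- jj <- xx <- vector("list", n_reactions)
  idx <- seq_len(n_states)
  for (r in seq_len(n_reactions)) {
    a <- rates[, r]
    ok <- a > 0
    for (sp in which(stoich[, r] != 0L)) {
      tgt <- states[, sp] + stoich[sp, r]
      ok <- ok & tgt >= 0L & tgt <= caps[sp]
    }
    if (!any(ok)) next
    shift <- sum(stoich[, r] * strides)
    ii[[r]] <- idx[ok]
    jj[[r]] <- idx[ok] + shift
    xx[[r]] <- a[ok]
  }
  from <- unlist(ii); to <- unlist(jj); val <- unlist(xx)
  # Q[s, s'] off-diagonal rates; diagonal = -rowSums
  outflow <- numeric(n_states)
  tab <- rowsum(val, from)
  outflow[as.integer(rownames(tab))] <- tab[, 1]
  Q <- Matrix::sparseMatrix(i = c(from, idx), j = c(to, idx),
                            x = c(val, -outflow),
                            dims = c(n_states, n_states))
  if (method == "auto") method <- if (n_states <= 20000) "lu" else "power"
  Lambda <- max(outflow) * 1.05 + 1e-12
  P <- Matrix::Diagonal(n_states) + Q / Lambda
  if (method == "lu") {
    # shifted inverse iteration: Q^T has the stationary law as its null
    # vector, so solving (Q^T - eps I) x = v amplifies the null
    # component by 1/eps; a couple of iterations on one sparse LU
    # factorisation converge to machine precision without having to
    # single out a reference state
    A <- Matrix::t(Q) - Matrix::Diagonal(n_states, Lambda * 1e-10)
    fac <- Matrix::lu(A)
    pi_hat <- rep(1 / n_states, n_states)
    for (it in 1:4) {
      pi_hat <- as.numeric(Matrix::solve(fac, pi_hat))
      pi_hat <- pi_hat / sum(pi_hat)
      res0 <- max(abs(as.numeric(Matrix::crossprod(Q, pi_hat)))) / Lambda
      if (res0 < 1e-12) break
    }
    pi_hat[pi_hat < 0 | !is.finite(pi_hat)] <- 0
    pi_hat <- pi_hat / sum(pi_hat)
  } else {
    # uniformised power iteration: pi <- pi (I + Q/Lambda); linear
    # memory, convergence governed by the slowest relaxation rate
    pi_hat <- rep(1 / n_states, n_states)
    max_iter <- 5e5
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      pi_hat <- as.numeric(pi_hat %*% P)
      pi_hat[pi_hat < 0] <- 0
      pi_hat <- pi_hat / sum(pi_hat)
      if (it %% 200 == 0) {
        res_rel <- max(abs(as.numeric(Matrix::crossprod(Q, pi_hat)))) /
          Lambda
        if (res_rel < power_tol) { converged <- TRUE; break }
      }
    }
    if (!converged)
      warning("power iteration stopped at max_iter without reaching ",
              "power_tol")
  }
  # residual check on the balance equations
  res <- max(abs(as.numeric(Matrix::crossprod(Q, pi_hat)))) / Lambda
  if (res > 1e-8)
    warning(sprintf("stationary residual %.3g exceeds 1e-8", res))
  check_sp <- which(caps > 1L)
  boundary <- rep(FALSE, n_states)
  for (sp in check_sp) boundary <- boundary | states[, sp] == caps[sp]
  boundary_mass <- sum(pi_hat[boundary])
  if (boundary_mass > boundary_tol)
    stop(sprintf(paste0("boundary mass %.3g exceeds tolerance %.3g: ",
                        "state-space caps too small"),
                 boundary_mass, boundary_tol), call. = FALSE)
  structure(list(pi = pi_hat, states = states, caps = caps,
                 boundary_mass = boundary_mass, residual = res),
            class = "cme_solution")
}

#' Marginal pmf of a species (or species combination) from a CME solution
#'
#' @param sol a [cme_stationary()] solution.
#' @param species integer index (column of the state matrix) or a vector
#'   of indices whose copy numbers are summed (e.g. free enzyme +
#'   complex for total enzyme).
#' @return A [discrete_pmf()] with provenance `"cme"`.
#' @export
cme_marginal <- function(sol, species) {
  stopifnot(inherits(sol, "cme_solution"))
  value <- if (length(species) == 1L) sol$states[, species]
           else rowSums(sol$states[, species, drop = FALSE])
  agg <- rowsum(sol$pi, value)
  probs <- numeric(max(value) + 1L)
  probs[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  discrete_pmf(probs, tail_mass_bound = 0, provenance = "cme")
}

#' CME oracle for a linear birth-death process
#'
#' Birth at constant rate `birth`, death at `death * n` per state `n`
#' (optionally plus `death0` independent of `n`). The untruncated chain
#' with `death0 = 0` is the Poisson(`birth/death`) law.
#'
#' @param birth zero-order birth rate (s^-1).
#' @param death per-molecule death rate constant (s^-1).
#' @param cap state-space cap.
#' @return A [discrete_pmf()].
#' @export
cme_birth_death <- function(birth, death, cap) {
  sol <- cme_stationary(matrix(c(1, -1), 1), function(s)
    cbind(rep(birth, nrow(s)), death * s[, 1]), caps = cap)
  cme_marginal(sol, 1)
}

#' CME oracle for the three-stage gene expression subnetwork
#'
#' Promoter switching, transcription, mRNA degradation, translation and
#' protein dilution only (no catalysis): the exact finite-state reference
#' for [three_stage_pmf()]. Species order: promoter state (0/1), mRNA,
#' protein.
#'
#' @param rc a [rate_constants()] object (only the expression constants
#'   are used).
#' @param cap_mrna,cap_protein state-space caps.
#' @param ... passed to [cme_stationary()].
#' @return A list with `protein` and `mrna` marginal [discrete_pmf()]s
#'   and the full `solution`.
#' @export
cme_three_stage <- function(rc, cap_mrna, cap_protein, ...) {
  stopifnot(inherits(rc, "rate_constants"))
  # reactions: activate, deactivate, transcribe, degrade mRNA, translate,
  # dilute protein
  stoich <- matrix(c(
    1, 0, 0,
    -1, 0, 0,
    0, 1, 0,
    0, -1, 0,
    0, 0, 1,
    0, 0, -1), nrow = 3)
  prop <- function(s) cbind(
    rc$k_on * (1 - s[, 1]),
    rc$k_off * s[, 1],
    rc$k_tx * s[, 1],
    rc$k_deg * s[, 2],
    rc$k_tl * s[, 2],
    rc$delta * s[, 3])
  sol <- cme_stationary(stoich, prop, caps = c(1L, cap_mrna, cap_protein),
                        ...)
  list(protein = cme_marginal(sol, 3), mrna = cme_marginal(sol, 2),
       solution = sol)
}

#' CME oracle for the full coupled reaction network
#'
#' All twelve reactions (binding/unbinding, reversible catalysis,
#' consumption, expression, degradation, dilution) on a truncated box.
#' Only feasible for down-scaled parameter sets with small copy numbers.
#' Species order: promoter state, mRNA, free enzyme, complex, metabolite.
#'
#' @param rc a [rate_constants()] object.
#' @param caps integer vector `c(mrna, enzyme, complex, metabolite)`.
#' @param ... passed to [cme_stationary()].
#' @return A list with marginal [discrete_pmf()]s `enzyme_total`,
#'   `metabolite`, and the full `solution`.
#' @export
cme_full_network <- function(rc, caps, ...) {
  stopifnot(inherits(rc, "rate_constants"), length(caps) == 4L)
  # species: d, m, e, c, p; reactions follow ssa_propensities() order
  stoich <- matrix(c(
    0, 0, -1, 1, 0,   # binding: E + S -> C
    0, 0, 1, -1, 0,   # unbinding: C -> E + S
    0, 0, 1, -1, 1,   # catalysis: C -> E + P
    0, 0, -1, 1, -1,  # reverse catalysis: E + P -> C
    0, 0, 1, 0, 0,    # translation
    0, 1, 0, 0, 0,    # transcription
    1, 0, 0, 0, 0,    # promoter on
    -1, 0, 0, 0, 0,   # promoter off
    0, 0, 0, 0, -1,   # consumption
    0, -1, 0, 0, 0,   # mRNA degradation
    0, 0, -1, 0, 0,   # enzyme dilution
    0, 0, 0, -1, 0),  # complex dilution
    nrow = 5)
  prop <- function(s) cbind(
    rc$k_1 * rc$n_s * s[, 3],
    rc$k_m1 * s[, 4],
    rc$k_cat * s[, 4],
    rc$k_rev * s[, 3] * s[, 5],
    rc$k_tl * s[, 2],
    rc$k_tx * s[, 1],
    rc$k_on * (1 - s[, 1]),
    rc$k_off * s[, 1],
    rc$k_c * s[, 5],
    rc$k_deg * s[, 2],
    rc$delta * s[, 3],
    rc$delta * s[, 4])
  sol <- cme_stationary(stoich, prop, caps = c(1L, caps), ...)
  list(enzyme_total = cme_marginal(sol, c(3, 4)),
       metabolite = cme_marginal(sol, 5),
       solution = sol)
}
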