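#' Poisson parameter map lambda(n_etot)
#'
#' The conditional stationary distribution of the metabolite given total
#' enzyme `n_etot` is Poisson with parameter `lambda(n_etot)`. For a
#' reversible reaction (`k_rev > 0`) the parameter saturates,
#' \deqn{\lambda(n) = \frac{\lambda_\infty}{1 + K/n},}
#' while for an irreversible one (`k_rev = 0`) it grows linearly,
#' \deqn{\lambda(n) = \frac{k_1 n_s k_{cat}}{(k_1 n_s + k_{-1}) k_c} n,}
#' producing equi-spaced Poisson modes. In both modes `lambda(0) = 0`
#' (no enzyme, no metabolite).
#'
#' @param rc a [rate_constants()] object, or (reversible mode only) an
#'   [effective_kinetics()] object / a list with `lambda_inf` and `K`
#'   when only the effective parameters are known.
#' @return An object of class `lambda_map`: list with `mode`
#'   (`"reversible"` or `"irreversible"`), `lambda_inf`/`K` or
#'   `linear_slope`, and `lambda(n_etot)`, a vectorised accessor.
#' @examples
#' lm <- poisson_parameter(preset_rate_constants("table1"))
#' lm$lambda(8)  # lambda_inf / 2 = 540 at n_etot = K
#' @export
poisson_parameter <- function(rc) {
  if (inherits(rc, "rate_constants")) {
    if (rc$k_rev > 0) {
      ek <- effective_kinetics(rc)
      return(lambda_map_reversible(ek$lambda_inf, ek$K))
    }
    slope <- rc$k_1 * rc$n_s * rc$k_cat /
      ((rc$k_1 * rc$n_s + rc$k_m1) * rc$k_c)
    lam <- function(n_etot) {
      stopifnot(all(n_etot >= 0))
      slope * n_etot
    }
    return(structure(list(mode = "irreversible", linear_slope = slope,
                          lambda = lam), class = "lambda_map"))
  }
  if (!is.null(rc$lambda_inf) && !is.null(rc$K))
    return(lambda_map_reversible(rc$lambda_inf, rc$K))
  stop("need a rate_constants object or lambda_inf/K pair", call. = FALSE)
}

lambda_map_reversible <- function(lambda_inf, K) {
  stopifnot(lambda_inf > 0, K > 0)
  lam <- function(n_etot) {
    stopifnot(all(n_etot >= 0))
    ifelse(n_etot == 0, 0, lambda_inf / (1 + K / n_etot))
  }
  structure(list(mode = "reversible", lambda_inf = lambda_inf, K = K,
                 lambda = lam), class = "lambda_map")
}

#' @method print lambda_map
#' @export
print.lambda_map <- function(x, ...) {
  if (x$mode == "reversible")
    cat(sprintf("Poisson parameter map: lambda(n) = %g / (1 + %g/n)\n",
                x$lambda_inf, x$K))
  else
    cat(sprintf("Poisson parameter map (irreversible): lambda(n) = %g * n\n",
                x$linear_slope))
  invisible(x)
}

#' Effective birth-death propensities of the reduced metabolite process
#'
#' On the catalytic timescale the total enzyme is frozen and fast
#' substrate binding/unbinding is equilibrated, leaving the metabolite a
#' birth-death process with a zero-order birth propensity
#' `k_cat * E(n_c | n_etot) = k_cat * (k_1 n_s/(k_1 n_s + k_m1)) * n_etot`
#' and a per-molecule death rate
#' `k_rev * E(n_e | n_etot) + k_c =
#'  k_rev * (k_m1/(k_1 n_s + k_m1)) * n_etot + k_c`
#' (the quasi-equilibrium conditional expectations split `n_etot` into
#' bound fraction `epsilon` and free fraction `1 - epsilon`, independent
#' of the metabolite count). The stationary law is Poisson with
#' `lambda = birth / death_coef`, identical to
#' `poisson_parameter(rc)$lambda(n_etot)`.
#'
#' @param rc a [rate_constants()] object.
#' @param n_etot total enzyme copy number (non-negative integer).
#' @return List with `birth` (s^-1), `death_coef` (s^-1, per metabolite
#'   molecule), the conditional expectations `E_complex` and `E_free`,
#'   and `lambda = birth/death_coef`.
#' @examples
#' reduced_propensities(preset_rate_constants("table1"), 1)$lambda  # 120
#' @export
reduced_propensities <- function(rc, n_etot) {
  stopifnot(inherits(rc, "rate_constants"), n_etot >= 0,
            n_etot == round(n_etot))
  eps <- rc$k_1 * rc$n_s / (rc$k_1 * rc$n_s + rc$k_m1)
  E_complex <- eps * n_etot
  E_free <- (1 - eps) * n_etot
  birth <- rc$k_cat * E_complex
  death_coef <- rc$k_rev * E_free + rc$k_c
  list(birth = birth, death_coef = death_coef,
       E_complex = E_complex, E_free = E_free,
       lambda = birth / death_coef)
}

#' Poisson Mixture Model for the stationary metabolite distribution
#'
#' Assembles the metabolite pmf by the law of total probability,
#' \deqn{P(n_p) = \sum_{n_{etot}} P(n_{etot})\,
#'   \mathrm{Poisson}(n_p;\, \lambda(n_{etot})),}
#' mixing the Poisson conditional modes over an enzyme distribution. The
#' `n_etot = 0` term is the point mass `Poisson(n_p; 0)` at zero, so
#' `P(0)` always contains the full probability of having no enzyme.
#'
#' Each Poisson mode is accumulated over the window where its mass
#' exceeds the per-mode tolerance (at least `mean + 12 sqrt(mean) + 30`
#' wide); the neglected Poisson tails and the truncated enzyme tail are
#' added to the result's `tail_mass_bound` rather than lumped into the
#' last mode.
#'
#' @param enzyme_pmf a [discrete_pmf()] for total enzyme copy number.
#' @param map a [lambda_map()] from [poisson_parameter()] (or a
#'   [rate_constants()] object, converted internally).
#' @param truncation_tol permitted combined tail mass (default `1e-8`).
#' @return A [discrete_pmf()] with provenance `"pmm"`.
#' @examples
#' rc <- preset_rate_constants("table1")
#' pmm <- pmm_distribution(three_stage_pmf(rc), poisson_parameter(rc))
#' @export
pmm_distribution <- function(enzyme_pmf, map, truncation_tol = 1e-8) {
  stopifnot(inherits(enzyme_pmf, "discrete_pmf"))
  if (inherits(map, "rate_constants")) map <- poisson_parameter(map)
  stopifnot(inherits(map, "lambda_map"), truncation_tol > 0)
  ns <- seqemp(enzyme_pmf)
  w <- enzyme_pmf$probs
  lam <- map$lambda(ns)
  active <- which(w > 0)
  # support: union of per-mode windows
  hi_all <- max(ceiling(lam[active] + 12 * sqrt(lam[active]) + 30))
  probs <- numeric(hi_all + 1L)
  poisson_tail <- 0
  for (i in active) {
    l <- lam[i]
    if (l == 0) {
      probs[1L] <- probs[1L] + w[i]
      next
    }
    hw <- 12 * sqrt(l) + 30
    lo <- max(0, floor(l - hw))
    hi <- min(hi_all, ceiling(l + hw))
    xs <- lo:hi
    d <- stats::dpois(xs, l)
    probs[xs + 1L] <- probs[xs + 1L] + w[i] * d
    poisson_tail <- poisson_tail + w[i] * max(0, 1 - sum(d))
  }
  tail_bound <- enzyme_pmf$tail_mass_bound + poisson_tail
  if (tail_bound > truncation_tol)
    warning(sprintf(paste0("combined tail bound %.3g exceeds truncation_tol ",
                           "%.3g; re-truncate the enzyme pmf more finely"),
                    tail_bound, truncation_tol))
  # trim trailing zeros beyond the last non-negligible entry
  nz <- which(probs > 0)
  probs <- probs[seq_len(max(nz))]
  discrete_pmf(probs, tail_mass_bound = max(0, 1 - sum(probs)),
               provenance = "pmm")
}
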