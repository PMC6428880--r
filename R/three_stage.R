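#' @useDynLib metanoise, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Gauss hypergeometric 2F1(A, B; C; x) for A > 0, B >= 0, C > 0, 0 <= x < 1,
# returned as log(2F1). All series terms are non-negative, so plain
# accumulation is numerically benign; the running sum is rescaled into log
# space when it grows large. Signals an error if the series has not
# converged after max_terms.
log_hyp2f1 <- function(A, B, C, x, rel_tol = 1e-15, max_terms = 1e6L) {
  stopifnot(A > 0, B >= 0, C > 0, x >= 0, x < 1)
  if (B == 0 || x == 0) return(0)
  log_scale <- 0
  term <- 1
  total <- 1
  k <- 0
  repeat {
    term <- term * (A + k) * (B + k) / ((C + k) * (k + 1)) * x
    total <- total + term
    k <- k + 1
    if (term <= rel_tol * total && (A + k) * x / (k + 1) < 1) break
    if (k >= max_terms)
      stop(sprintf("2F1 series did not converge (A=%g, B=%g, C=%g, x=%g)",
                   A, B, C, x), call. = FALSE)
    if (total > 1e280) {
      log_scale <- log_scale + log(total)
      term <- term / total
      total <- 1
    }
  }
  log_scale + log(total)
}

#' Stationary enzyme distribution of the three-stage expression model
#'
#' Evaluates the closed-form stationary distribution of protein (total
#' enzyme) copy number under promoter switching, transcription,
#' translation, fast mRNA turnover and protein dilution:
#' \deqn{P(n) = \frac{\Gamma(\alpha_+ + n)\Gamma(\alpha_- + n)\Gamma(\gamma)}
#'   {\Gamma(n+1)\Gamma(\alpha_+)\Gamma(\alpha_-)\Gamma(\gamma + n)}
#'   \left(\frac{b}{1+b}\right)^n \left(\frac{1}{1+b}\right)^{\alpha_+}
#'   {}_2F_1\!\left(\alpha_+ + n,\, \gamma - \alpha_-;\, \gamma + n;\,
#'   \frac{b}{1+b}\right),}
#' valid when mRNA turnover is fast relative to dilution
#' (`k_deg >> delta`). The Gamma-function ratio is evaluated with
#' `lgamma` and the hypergeometric factor by its positive-term Gauss
#' series; the support is extended until the accumulated mass reaches
#' `1 - truncation_tol`.
#'
#' Degenerate promoters short-circuit the formula: `k_on = 0` returns a
#' point mass at zero and `k_off = 0` the negative binomial with shape
#' `a` and success probability `b/(1+b)`.
#'
#' @param tsp a [three_stage_params()] object (or a [rate_constants()]
#'   object, converted internally).
#' @param truncation_tol permitted truncated tail mass (default `1e-8`).
#' @param max_support hard cap on the support (default `2e5`); exceeding
#'   it is an error.
#' @return A [discrete_pmf()] with provenance `"three-stage"`.
#' @examples
#' pmf <- three_stage_pmf(preset_rate_constants("table1"))
#' pmf_mean(pmf)  # ~ a * b * p_on = 81
#' @export
three_stage_pmf <- function(tsp, truncation_tol = 1e-8, max_support = 2e5) {
  if (inherits(tsp, "rate_constants")) tsp <- three_stage_params(tsp)
  stopifnot(inherits(tsp, "three_stage_params"),
            truncation_tol > 0, truncation_tol < 1)
  if (tsp$k_on == 0)
    return(discrete_pmf(1, provenance = "three-stage"))
  x <- tsp$b / (1 + tsp$b)
  if (tsp$k_off == 0) {
    # always-on promoter: negative binomial, shape a, success prob x
    mean_n <- tsp$a * tsp$b
    n_max <- stats::qnbinom(truncation_tol, size = tsp$a, prob = 1 - x,
                            lower.tail = FALSE) + 1
    if (n_max > max_support) stop("support exceeds max_support")
    p <- stats::dnbinom(0:n_max, size = tsp$a, prob = 1 - x)
    return(discrete_pmf(p, tail_mass_bound = max(0, 1 - sum(p)),
                        provenance = "three-stage"))
  }
  ap <- tsp$alpha_plus; am <- tsp$alpha_minus; g <- tsp$gamma
  B <- max(g - am, 0)
  log_pref0 <- lgamma(g) - lgamma(ap) - lgamma(am) + ap * log1p(-x)
  mean_n <- tsp$a * tsp$b * tsp$p_on
  chunk <- max(64L, ceiling(mean_n))
  probs <- numeric(0)
  cum <- 0
  n0 <- 0L
  repeat {
    ns <- n0:(n0 + chunk - 1L)
    lp <- vapply(ns, function(n) {
      log_pref0 + lgamma(ap + n) + lgamma(am + n) -
        lgamma(n + 1) - lgamma(g + n) + n * log(x) +
        log_hyp2f1(ap + n, B, g + n, x)
    }, numeric(1))
    p_chunk <- exp(lp)
    probs <- c(probs, p_chunk)
    cum <- cum + sum(p_chunk)
    n0 <- n0 + chunk
    if (1 - cum <= truncation_tol) break
    if (n0 > max_support)
      stop("support exceeds max_support before reaching truncation_tol")
  }
  # trim trailing support that was not needed to reach the tolerance
  csum <- cumsum(probs)
  keep <- which(1 - csum <= truncation_tol)[1]
  probs <- probs[seq_len(keep)]
  discrete_pmf(probs, tail_mass_bound = max(0, 1 - sum(probs)),
               provenance = "three-stage")
}

#' Empirical enzyme distribution from a copy-number/weight table
#'
#' Builds a [discrete_pmf()] from measured single-cell abundances given
#' as (copy number, weight) pairs, e.g. a flow-cytometry histogram.
#' Weights are normalised to probabilities; copy numbers absent from the
#' table get zero mass.
#'
#' @param table a two-column matrix or data frame: integer copy numbers
#'   (non-negative, no duplicates) and non-negative weights (at least one
#'   positive).
#' @return A [discrete_pmf()] with provenance `"empirical"` and zero tail
#'   bound.
#' @examples
#' empirical_pmf(cbind(c(0, 10), c(1, 1)))  # mass 0.5 at 0 and at 10
#' @export
empirical_pmf <- function(table) {
  table <- as.matrix(table)
  if (ncol(table) != 2L) stop("'table' must have two columns", call. = FALSE)
  n <- table[, 1]; w <- table[, 2]
  if (any(n < 0) || any(n != round(n)))
    stop("copy numbers must be non-negative integers", call. = FALSE)
  if (anyDuplicated(n))
    stop("duplicate copy numbers in table", call. = FALSE)
  if (any(w < 0)) stop("negative weight in table", call. = FALSE)
  if (all(w == 0)) stop("at least one weight must be positive", call. = FALSE)
  keep <- w > 0
  n <- n[keep]; w <- w[keep]
  probs <- numeric(max(n) + 1L)
  probs[n + 1L] <- w / sum(w)
  discrete_pmf(probs, tail_mass_bound = 0, provenance = "empirical")
}

#' Integer-discretised Gamma distribution
#'
#' Discretises a Gamma(shape, scale) density onto non-negative integers
#' by integrating the density over `[n, n+1)` (so `n = 0` receives the
#' mass of `[0, 1)`), mirroring the common practice of standing a fitted
#' Gamma distribution in for a measured single-cell enzyme distribution.
#'
#' @param shape,scale Gamma parameters (both `> 0`); the continuous mean
#'   is `shape * scale`.
#' @param truncation_tol permitted truncated tail mass (default `1e-8`).
#' @return A [discrete_pmf()] with provenance `"gamma"`.
#' @examples
#' g <- gamma_discretized_pmf(2, 10)
#' pmf_mean(g)  # ~ shape*scale - 0.5 + O(1/mean) discretisation shift
#' @export
gamma_discretized_pmf <- function(shape, scale, truncation_tol = 1e-8) {
  stopifnot(shape > 0, scale > 0, truncation_tol > 0, truncation_tol < 1)
  n_max <- ceiling(stats::qgamma(truncation_tol, shape, scale = scale,
                                 lower.tail = FALSE)) + 1
  edges <- stats::pgamma(0:(n_max + 1L), shape, scale = scale)
  probs <- diff(edges)
  discrete_pmf(probs, tail_mass_bound = max(0, 1 - edges[n_max + 2L]),
               provenance = "gamma")
}
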