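#' Effective kinetic parameters of the metabolite birth-death reduction
#'
#' Under the separation between fast substrate binding/unbinding and the
#' slower catalytic and consumption steps, the metabolite conditioned on
#' the total enzyme copy number `n_etot` is Poisson with parameter
#' `lambda(n_etot) = lambda_inf / (1 + K / n_etot)`, where
#' \deqn{\lambda_\infty = n_s k_{cat} k_1 / (k_{rev} k_{-1}), \quad
#'       K = k_c (k_1 n_s + k_{-1}) / (k_{rev} k_{-1}),}
#' both in molecules/cell. The enzyme saturation is
#' `epsilon = k_1 n_s / (k_1 n_s + k_m1)` (the equilibrium bound fraction),
#' and the three quantities satisfy the identity
#' `lambda_inf / K = epsilon * k_cat / k_c`.
#'
#' The reversible parameters are only defined for `k_rev > 0`; in the
#' irreversible regime the Poisson parameter grows linearly with enzyme
#' abundance (see [poisson_parameter()]) and this function signals an
#' error rather than returning infinities.
#'
#' @param rc a [rate_constants()] object with `k_rev > 0`.
#' @return An object of class `effective_kinetics`: a list with fields
#'   `lambda_inf`, `K` (molecules) and `epsilon` (dimensionless, in (0,1)).
#' @examples
#' ek <- effective_kinetics(preset_rate_constants("table1"))
#' ek$lambda_inf  # 1080
#' ek$K           # 8
#' @export
effective_kinetics <- function(rc) {
  stopifnot(inherits(rc, "rate_constants"))
  if (rc$k_rev <= 0)
    stop("irreversible regime (k_rev = 0): lambda_inf and K are undefined; ",
         "use poisson_parameter() for the linear form", call. = FALSE)
  structure(list(
    lambda_inf = rc$n_s * rc$k_cat * rc$k_1 / (rc$k_rev * rc$k_m1),
    K = rc$k_c * (rc$k_1 * rc$n_s + rc$k_m1) / (rc$k_rev * rc$k_m1),
    epsilon = rc$k_1 * rc$n_s / (rc$k_1 * rc$n_s + rc$k_m1)),
    class = "effective_kinetics")
}

#' @method print effective_kinetics
#' @export
print.effective_kinetics <- function(x, ...) {
  cat(sprintf(paste0("Effective kinetics: lambda_inf = %g molecules, ",
                     "K = %g molecules, saturation epsilon = %g\n"),
              x$lambda_inf, x$K, x$epsilon))
  invisible(x)
}

#' Dimensionless parameters of the three-stage gene expression model
#'
#' The stationary distribution of protein number in the three-stage model
#' (promoter switching `k_on`/`k_off`, transcription `k_tx`, translation
#' `k_tl`, mRNA degradation `k_deg`, protein dilution `delta`) is governed
#' by `gamma = (k_on + k_off)/delta`, `a = k_tx/delta`, the mean burst
#' size `b = k_tl/k_deg`, and the roots
#' \deqn{\alpha_\pm = \left(a + \gamma \pm
#'   \sqrt{(a+\gamma)^2 - 4 a k_{on}/\delta}\right)/2,}
#' which satisfy `alpha_plus + alpha_minus = a + gamma` and
#' `alpha_plus * alpha_minus = a * k_on / delta` (Vieta), with
#' `alpha_minus <= min(a, gamma)` and `alpha_plus >= max(a, gamma)`.
#'
#' The placement of the activation rate `k_on` in the product of roots is
#' fixed by the analytic limits of the stationary law: a permanently
#' active promoter (`k_off = 0`) makes the roots collapse to `{a, gamma}`
#' and the protein distribution to the negative binomial with shape `a`,
#' while a permanently silent one (`k_on = 0`) gives `alpha_minus = 0`
#' and a point mass at zero. (Some published statements of the solution
#' carry a typo with `k_off` in this position; that variant fails both
#' limits and disagrees with the master equation.)
#'
#' @param rc a [rate_constants()] object (`delta > 0`, `k_deg > 0`).
#' @return An object of class `three_stage_params`: list with fields
#'   `gamma`, `a`, `b`, `alpha_plus`, `alpha_minus`, and `p_on =
#'   k_on/(k_on+k_off)` (promoter activity; `0` if both rates are zero).
#' @examples
#' three_stage_params(preset_rate_constants("table1"))
#' @export
three_stage_params <- function(rc) {
  stopifnot(inherits(rc, "rate_constants"))
  gamma <- (rc$k_on + rc$k_off) / rc$delta
  a <- rc$k_tx / rc$delta
  b <- rc$k_tl / rc$k_deg
  # Vieta: roots of z^2 - (a+gamma) z + a*k_on/delta; the discriminant
  # equals (a - gamma)^2 + 4*a*k_off/delta >= 0 for valid inputs.
  disc <- (a + gamma)^2 - 4 * a * rc$k_on / rc$delta
  if (disc < 0) {
    if (disc > -1e-9 * (a + gamma)^2) disc <- 0
    else stop("internal error: negative discriminant in alpha_pm")
  }
  s <- sqrt(disc)
  alpha_plus <- (a + gamma + s) / 2
  # small root from the product to avoid cancellation
  alpha_minus <- if (alpha_plus > 0) (a * rc$k_on / rc$delta) / alpha_plus
                 else 0
  p_on <- if (rc$k_on + rc$k_off > 0) rc$k_on / (rc$k_on + rc$k_off) else 0
  structure(list(gamma = gamma, a = a, b = b, alpha_plus = alpha_plus,
                 alpha_minus = alpha_minus, p_on = p_on,
                 k_on = rc$k_on, k_off = rc$k_off, delta = rc$delta),
            class = "three_stage_params")
}

#' @method print three_stage_params
#' @export
print.three_stage_params <- function(x, ...) {
  cat(sprintf(paste0("Three-stage parameters: gamma = %g, a = %g, b = %g, ",
                     "alpha+ = %g, alpha- = %g (mean protein = %g)\n"),
              x$gamma, x$a, x$b, x$alpha_plus, x$alpha_minus,
              x$a * x$b * x$p_on))
  invisible(x)
}

#' Timescale-separation diagnostics
#'
#' The reduction of the full network to the Poisson mixture relies on
#' three well-separated timescales: fast substrate binding/unbinding
#' (rate scale `k_1 n_s + k_m1`), intermediate catalysis and consumption
#' (scale `max(k_cat, k_c, k_rev * n_p_typ)` where `n_p_typ` is a typical
#' metabolite copy number, by default the quasi-stationary mean), and slow
#' enzyme expression/dilution (scale `delta`). This reports the three
#' scales and flags the ratios that fall below a configurable validity
#' factor (default 10x).
#'
#' @param rc a [rate_constants()] object.
#' @param factor minimum acceptable ratio between consecutive timescales
#'   before a flag is raised (default `10`).
#' @return A list of class `timescale_diagnostics` with fields
#'   `binding_scale`, `catalytic_scale`, `expression_scale` (s^-1),
#'   `ratio_fast_catalytic`, `ratio_catalytic_slow`, `factor`, and logical
#'   flags `fast_binding_ok`, `slow_expression_ok`.
#' @export
timescale_diagnostics <- function(rc, factor = 10) {
  stopifnot(inherits(rc, "rate_constants"), factor > 0)
  binding_scale <- rc$k_1 * rc$n_s + rc$k_m1
  # typical metabolite level for the reverse-flux scale k_rev * n_p
  n_p_typ <- if (rc$k_rev > 0) {
    ek <- effective_kinetics(rc)
    tsp <- three_stage_params(rc)
    mean_e <- tsp$a * tsp$b * tsp$p_on
    if (mean_e > 0) ek$lambda_inf / (1 + ek$K / mean_e) else 0
  } else 0
  catalytic_scale <- max(rc$k_cat, rc$k_c, rc$k_rev * n_p_typ)
  expression_scale <- max(rc$delta, rc$k_on + rc$k_off)
  r1 <- binding_scale / catalytic_scale
  r2 <- catalytic_scale / expression_scale
  structure(list(binding_scale = binding_scale,
                 catalytic_scale = catalytic_scale,
                 expression_scale = expression_scale,
                 ratio_fast_catalytic = r1,
                 ratio_catalytic_slow = r2,
                 factor = factor,
                 fast_binding_ok = r1 >= factor,
                 slow_expression_ok = r2 >= factor),
            class = "timescale_diagnostics")
}

#' @method print timescale_diagnostics
#' @export
print.timescale_diagnostics <- function(x, ...) {
  cat(sprintf("Timescales (s^-1): binding %g | catalysis/consumption %g | expression %g\n",
              x$binding_scale, x$catalytic_scale, x$expression_scale))
  cat(sprintf("  fast/intermediate ratio %.3g (%s), intermediate/slow ratio %.3g (%s); validity factor %gx\n",
              x$ratio_fast_catalytic,
              if (x$fast_binding_ok) "ok" else "FLAGGED",
              x$ratio_catalytic_slow,
              if (x$slow_expression_ok) "ok" else "FLAGGED",
              x$factor))
  invisible(x)
}
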