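#' Promoter-switching regime map
#'
#' Evaluates the Poisson Mixture Model over a grid of promoter switching
#' timescale (`k_on + k_off`, log-spaced axis) and promoter activity
#' (`k_on / (k_on + k_off)`, linear axis), for one or more values of
#' `lambda_inf` at fixed `K`. Varying `lambda_inf` corresponds to
#' increasing the turnover rate constant `k_cat`, which leaves `K`
#' unchanged. At each grid point the enzyme distribution (three-stage
#' model with the base expression constants), the metabolite PMM and
#' both modality classifications are computed, and the joint regime is
#' labelled:
#' \itemize{
#'   \item `"unimodal"`: enzyme and metabolite unimodal;
#'   \item `"switching-induced"`: bimodality propagates from a bimodal
#'     enzyme to a bimodal metabolite (slow switching);
#'   \item `"catalytically-induced"`: a unimodal enzyme yields a bimodal
#'     metabolite (fast switching, weak expression, strong timescale
#'     separation);
#'   \item `"multimodal"`: metabolite with three or more qualifying
#'     modes;
#'   \item `"enzyme-only"`: bimodal enzyme, unimodal metabolite.
#' }
#'
#' @param base_rc a [rate_constants()] object supplying the expression
#'   constants (`k_tx`, `k_tl`, `k_deg`, `delta`).
#' @param switching_timescale numeric vector of `k_on + k_off` values
#'   (s^-1).
#' @param activity numeric vector of `k_on/(k_on + k_off)` values in
#'   (0, 1).
#' @param lambda_inf numeric vector of saturation parameters (molecules).
#' @param K kinetic half-saturation parameter (molecules), fixed across
#'   the grid.
#' @param truncation_tol tail tolerance for the pmfs (default `1e-8`).
#' @return An object of class `regime_map`: list with `grid` (a long
#'   data frame: `switching_timescale`, `activity`, `lambda_inf`, `K`,
#'   `enzyme_label`, `metabolite_label`, `regime`, `n_peaks`, `failed`,
#'   `reason`) and `points` (per-row details: classifications with full
#'   rule traces, or the failure condition).
#' @examples
#' rc <- preset_rate_constants("table1")
#' sw <- switching_sweep(rc, switching_timescale = c(1e-5, 1e-2),
#'                       activity = c(0.1, 0.9), lambda_inf = 300,
#'                       K = 0.1333)
#' sw$grid$regime
#' @export
switching_sweep <- function(base_rc, switching_timescale, activity,
                            lambda_inf, K, truncation_tol = 1e-8) {
  stopifnot(inherits(base_rc, "rate_constants"),
            all(switching_timescale > 0),
            all(activity > 0), all(activity < 1),
            all(lambda_inf > 0), K > 0)
  grid <- expand.grid(switching_timescale = switching_timescale,
                      activity = activity, lambda_inf = lambda_inf,
                      KEEP.OUT.ATTRS = FALSE)
  grid$K <- K
  points <- vector("list", nrow(grid))
  cols <- data.frame(enzyme_label = character(nrow(grid)),
                     metabolite_label = character(nrow(grid)),
                     regime = character(nrow(grid)),
                     n_peaks = NA_integer_, failed = FALSE,
                     reason = NA_character_)
  enzyme_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      ts <- grid$switching_timescale[i]
      act <- grid$activity[i]
      key <- sprintf("%.17g|%.17g", ts, act)
      enz <- get0(key, enzyme_cache)
      if (is.null(enz)) {
        rc_i <- update_rate_constants(base_rc, k_on = act * ts,
                                      k_off = (1 - act) * ts)
        enz <- list(pmf = three_stage_pmf(rc_i, truncation_tol),
                    cls = NULL)
        enz$cls <- classify_modality(enz$pmf)
        assign(key, enz, enzyme_cache)
      }
      map <- poisson_parameter(list(lambda_inf = grid$lambda_inf[i], K = K))
      pmm <- pmm_distribution(enz$pmf, map, truncation_tol)
      met_cls <- classify_modality(pmm)
      list(enzyme = enz$cls, metabolite = met_cls,
           regime = joint_regime(enz$cls$label, met_cls$label))
    }, error = function(e) list(failed = TRUE, reason = conditionMessage(e)))
    points[[i]] <- res
    if (isTRUE(res$failed)) {
      cols$failed[i] <- TRUE
      cols$reason[i] <- res$reason
      cols$enzyme_label[i] <- cols$metabolite_label[i] <-
        cols$regime[i] <- NA_character_
    } else {
      cols$enzyme_label[i] <- res$enzyme$label
      cols$metabolite_label[i] <- res$metabolite$label
      cols$regime[i] <- res$regime
      cols$n_peaks[i] <- nrow(res$metabolite$peaks)
    }
  }
  structure(list(grid = cbind(grid, cols), points = points,
                 axes = list(
                   switching_timescale = "k_on + k_off (s^-1, log scale)",
                   activity = "k_on / (k_on + k_off)")),
            class = "regime_map")
}

joint_regime <- function(enzyme_label, metabolite_label) {
  if (metabolite_label == "multimodal") return("multimodal")
  if (metabolite_label == "bimodal") {
    if (enzyme_label == "unimodal") return("catalytically-induced")
    return("switching-induced")
  }
  if (enzyme_label != "unimodal") return("enzyme-only")
  "unimodal"
}

#' @method print regime_map
#' @export
print.regime_map <- function(x, ...) {
  cat(sprintf("Regime map over %d grid points:\n", nrow(x$grid)))
  print(table(x$grid$regime, useNA = "ifany"))
  invisible(x)
}

#' Kinetic-parameter regime map over (lambda_inf, K)
#'
#' Holds the enzyme distribution fixed (the PMM depends on the kinetics
#' only through `lambda_inf` and `K`) and classifies the metabolite PMM
#' at each point of a `(lambda_inf, K)` grid.
#'
#' @param enzyme_pmf a [discrete_pmf()] for total enzyme.
#' @param lambda_inf,K numeric grid axes (molecules).
#' @param truncation_tol tail tolerance (default `1e-8`).
#' @return A `regime_map` whose `grid` has columns `lambda_inf`, `K`,
#'   `enzyme_label`, `metabolite_label`, `regime`, `n_peaks`, `failed`,
#'   `reason`.
#' @examples
#' enz <- three_stage_pmf(preset_rate_constants("fig4b_enzyme"))
#' km <- kinetic_sweep(enz, lambda_inf = c(100, 750), K = c(0.5, 10))
#' @export
kinetic_sweep <- function(enzyme_pmf, lambda_inf, K,
                          truncation_tol = 1e-8) {
  stopifnot(inherits(enzyme_pmf, "discrete_pmf"),
            all(lambda_inf > 0), all(K > 0))
  enzyme_cls <- classify_modality(enzyme_pmf)
  grid <- expand.grid(lambda_inf = lambda_inf, K = K,
                      KEEP.OUT.ATTRS = FALSE)
  points <- vector("list", nrow(grid))
  cols <- data.frame(enzyme_label = enzyme_cls$label,
                     metabolite_label = character(nrow(grid)),
                     regime = character(nrow(grid)),
                     n_peaks = NA_integer_, failed = FALSE,
                     reason = NA_character_)
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      map <- poisson_parameter(list(lambda_inf = grid$lambda_inf[i],
                                    K = grid$K[i]))
      pmm <- pmm_distribution(enzyme_pmf, map, truncation_tol)
      met_cls <- classify_modality(pmm)
      list(enzyme = enzyme_cls, metabolite = met_cls,
           regime = joint_regime(enzyme_cls$label, met_cls$label))
    }, error = function(e) list(failed = TRUE, reason = conditionMessage(e)))
    points[[i]] <- res
    if (isTRUE(res$failed)) {
      cols$failed[i] <- TRUE
      cols$reason[i] <- res$reason
      cols$metabolite_label[i] <- cols$regime[i] <- NA_character_
    } else {
      cols$metabolite_label[i] <- res$metabolite$label
      cols$regime[i] <- res$regime
      cols$n_peaks[i] <- nrow(res$metabolite$peaks)
    }
  }
  structure(list(grid = cbind(grid, cols), points = points,
                 axes = list(lambda_inf = "molecules", K = "molecules")),
            class = "regime_map")
}

#' Constant lambda_inf/K lines from measurable kinetic parameters
#'
#' The ratio of the two effective kinetic parameters satisfies
#' `lambda_inf / K = epsilon * k_cat / k_c`, with `epsilon` the enzyme
#' saturation. Since `k_cat` is the only commonly measured rate
#' constant, a fixed `(epsilon, k_cat, k_c)` combination defines a
#' straight line through the `(K, lambda_inf)` plane; a `k_cat` range
#' maps to a band of slopes.
#'
#' @param epsilon enzyme saturation in (0, 1].
#' @param k_cat turnover rate constant (s^-1).
#' @param k_c metabolite consumption rate constant (s^-1).
#' @param k_cat_range optional `c(low, high)` k_cat band (s^-1).
#' @return An object of class `kinetic_line`: list with `slope`
#'   (`= epsilon * k_cat / k_c`), the inputs, and `band_slopes` when a
#'   range is given.
#' @examples
#' kinetic_line(epsilon = 1, k_cat = 16.5, k_c = 0.025)$slope  # 660
#' @export
kinetic_line <- function(epsilon, k_cat, k_c, k_cat_range = NULL) {
  stopifnot(epsilon > 0, epsilon <= 1, k_cat > 0, k_c > 0)
  slope <- epsilon * k_cat / k_c
  band <- NULL
  if (!is.null(k_cat_range)) {
    stopifnot(length(k_cat_range) == 2L, all(k_cat_range > 0))
    band <- epsilon * sort(k_cat_range) / k_c
  }
  structure(list(epsilon = epsilon, k_cat = k_cat, k_c = k_c,
                 slope = slope, band_slopes = band),
            class = "kinetic_line")
}

#' @method print kinetic_line
#' @export
print.kinetic_line <- function(x, ...) {
  cat(sprintf("lambda_inf/K line: slope %g (epsilon %g, k_cat %g, k_c %g)\n",
              x$slope, x$epsilon, x$k_cat, x$k_c))
  if (!is.null(x$band_slopes))
    cat(sprintf("  band: slopes %g to %g\n", x$band_slopes[1],
                x$band_slopes[2]))
  invisible(x)
}

#' Write a regime map as a tab-separated table with a JSON sidecar
#'
#' The long-format grid goes to `<path>`; grids, axis definitions and
#' settings go to `<path>.json`.
#'
#' @param map a `regime_map`.
#' @param path output path for the TSV table.
#' @return `path`, invisibly.
#' @export
write_regime_map <- function(map, path) {
  stopifnot(inherits(map, "regime_map"))
  utils::write.table(map$grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sidecar <- list(axes = map$axes,
                  n_points = nrow(map$grid),
                  regimes = as.list(table(map$grid$regime)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
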