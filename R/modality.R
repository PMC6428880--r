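#' Peaks and troughs of a discrete pmf
#'
#' A peak is an index `i` with `probs[i] >= probs[i-1]` and
#' `probs[i] > probs[i+1]`; runs of equal mass (plateaus) collapse to
#' their leftmost index, index 0 is a peak when `probs[0] > probs[1]`,
#' and the right boundary when it exceeds its left neighbour run. The
#' trough between two adjacent peaks is the minimum mass strictly
#' between them.
#'
#' @param pmf a [discrete_pmf()] (or bare numeric mass vector).
#' @param min_height discard peaks below this absolute mass (default 0,
#'   i.e. keep all).
#' @param smooth_window odd integer width of a centred moving average
#'   applied before detection; `1` (default) disables smoothing. Only
#'   intended for finite-sample SSA histograms.
#' @return A list with data frames `peaks` and `troughs`, each with
#'   columns `location` (copy number) and `height` (mass). Troughs lie
#'   between consecutive retained peaks.
#' @examples
#' find_peaks(discrete_pmf(c(0.5, 0.01, 0.01, 0.01, 0.3),
#'                         tail_mass_bound = 0.17, normalize = FALSE))
#' @export
find_peaks <- function(pmf, min_height = 0, smooth_window = 1L) {
  p <- if (inherits(pmf, "discrete_pmf")) pmf$probs else as.numeric(pmf)
  stopifnot(length(p) >= 1L, smooth_window >= 1L, smooth_window %% 2 == 1)
  if (smooth_window > 1L && length(p) > smooth_window) {
    # centred moving average with partial windows at the boundaries, so
    # a genuine boundary mode (e.g. the no-production spike at 0) is
    # attenuated, not erased
    half <- (smooth_window - 1L) / 2L
    sm <- as.numeric(stats::filter(p, rep(1 / smooth_window, smooth_window),
                                   sides = 2))
    n <- length(p)
    for (i in c(seq_len(half), (n - half + 1L):n)) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      sm[i] <- mean(p[lo:hi])
    }
    p <- sm
  }
  if (length(p) == 1L) {
    return(list(peaks = data.frame(location = 0, height = p),
                troughs = data.frame(location = numeric(0),
                                     height = numeric(0))))
  }
  # run-length encode plateaus; a run is a peak iff it rises from the
  # previous run (or starts the support) and falls to the next (or ends it
  # with positive mass relative to its neighbour)
  r <- rle(p)
  vals <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n_runs <- length(vals)
  is_peak <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    up <- i == 1L || vals[i] > vals[i - 1L]
    down <- i == n_runs || vals[i] > vals[i + 1L]
    # a single plateau covering everything is its own peak
    is_peak[i] <- up && down && !(i == 1L && n_runs == 1L && vals[i] == 0)
  }
  locs <- starts[is_peak] - 1L   # copy numbers are 0-based
  heights <- vals[is_peak]
  keep <- heights >= min_height & heights > 0
  locs <- locs[keep]; heights <- heights[keep]
  troughs <- if (length(locs) >= 2L) {
    t_loc <- numeric(length(locs) - 1L)
    t_h <- numeric(length(locs) - 1L)
    for (i in seq_len(length(locs) - 1L)) {
      span <- (locs[i] + 2L):(locs[i + 1L])  # strictly between, 1-based
      j <- span[which.min(p[span])]
      t_loc[i] <- j - 1L
      t_h[i] <- p[j]
    }
    data.frame(location = t_loc, height = t_h)
  } else data.frame(location = numeric(0), height = numeric(0))
  list(peaks = data.frame(location = locs, height = heights),
       troughs = troughs)
}

#' Classify a discrete distribution as unimodal, bimodal or multimodal
#'
#' Applies the two detection rules used for the regime maps, with
#' precedence multimodal > bimodal > unimodal:
#' \itemize{
#'   \item \strong{bimodal}: some pair of peaks has smaller height at
#'     least 10\% of the larger, and the trough between them at most
#'     10\% of the smaller height;
#'   \item \strong{multimodal}: beyond a bimodal pair, at least one
#'     additional peak exceeds the absolute height `1e-4` and the trough
#'     to a neighbouring peak is at most 90\% of the smaller of the two
#'     neighbouring peak heights.
#' }
#' The bimodality rule is scale-free (invariant under rescaling of the
#' masses); the multimodality rule is not, because of its absolute
#' height threshold.
#'
#' @param pmf a [discrete_pmf()] or numeric mass vector.
#' @param height_ratio smaller/larger peak threshold of the bimodality
#'   rule (default `0.10`).
#' @param trough_ratio trough/smaller-peak threshold of the bimodality
#'   rule (default `0.10`).
#' @param multi_height absolute height threshold for an additional peak
#'   (default `1e-4`).
#' @param multi_trough_ratio trough threshold relative to the smaller
#'   neighbouring peak for the multimodality rule (default `0.90`).
#' @param min_rel_height visibility floor: peaks lower than this
#'   fraction of the highest mass are ignored by all rules (default
#'   `1e-4`, mirroring the absolute height below which the
#'   multimodality rule never counts a peak). Analytic mixture pmfs
#'   resolve arbitrarily small side-modes (e.g. masses of `1e-7` and
#'   below at the first few Poisson modes when the no-enzyme
#'   probability is negligible) that no finite-sample histogram could
#'   exhibit; without a floor such invisible mode pairs would satisfy
#'   the bimodality rule, which has no absolute scale of its own. The
#'   floor is relative to the highest mass, so the bimodality rule
#'   remains scale-free.
#' @param smooth_window passed to [find_peaks()].
#' @return An object of class `regime_label`: list with `label` (factor
#'   level `"unimodal"`, `"bimodal"` or `"multimodal"`), `peaks`,
#'   `troughs`, and `rule_trace` (character vector of the threshold
#'   decisions that fired).
#' @examples
#' rc <- preset_rate_constants("table1")
#' classify_modality(pmm_distribution(three_stage_pmf(rc), rc))
#' @export
classify_modality <- function(pmf, height_ratio = 0.10, trough_ratio = 0.10,
                              multi_height = 1e-4, multi_trough_ratio = 0.90,
                              min_rel_height = 1e-4, smooth_window = 1L) {
  p <- if (inherits(pmf, "discrete_pmf")) pmf$probs else as.numeric(pmf)
  pt <- find_peaks(pmf, min_height = min_rel_height * max(p),
                   smooth_window = smooth_window)
  pk <- pt$peaks
  tr <- pt$troughs
  trace <- character(0)
  n_pk <- nrow(pk)
  label <- "unimodal"
  bimodal_pair <- NULL
  if (n_pk >= 2L) {
    # trough between peaks i < j: minimum over intermediate troughs
    trough_between <- function(i, j) min(tr$height[i:(j - 1L)])
    for (i in seq_len(n_pk - 1L)) {
      for (j in (i + 1L):n_pk) {
        hs <- sort(c(pk$height[i], pk$height[j]))
        if (hs[1] >= height_ratio * hs[2] &&
            trough_between(i, j) <= trough_ratio * hs[1]) {
          bimodal_pair <- c(i, j)
          trace <- c(trace, sprintf(
            paste0("bimodal pair (%d, %d): smaller/larger = %.3g >= %.2g; ",
                   "trough/smaller = %.3g <= %.2g"),
            pk$location[i], pk$location[j], hs[1] / hs[2], height_ratio,
            trough_between(i, j) / hs[1], trough_ratio))
          break
        }
      }
      if (!is.null(bimodal_pair)) break
    }
    if (!is.null(bimodal_pair)) label <- "bimodal"
  }
  if (!is.null(bimodal_pair) && n_pk >= 3L) {
    for (k in setdiff(seq_len(n_pk), bimodal_pair)) {
      if (pk$height[k] <= multi_height) next
      # neighbouring peaks in index order; "its height" read as the
      # smaller of the two neighbouring peak heights
      for (nb in c(k - 1L, k + 1L)) {
        if (nb < 1L || nb > n_pk) next
        i <- min(k, nb); j <- max(k, nb)
        sm <- min(pk$height[k], pk$height[nb])
        if (tr$height[i] <= multi_trough_ratio * sm) {
          label <- "multimodal"
          trace <- c(trace, sprintf(
            paste0("additional peak at %d (height %.3g > %.2g); trough to ",
                   "neighbour %d = %.3g <= %.2g * %.3g"),
            pk$location[k], pk$height[k], multi_height, pk$location[nb],
            tr$height[i], multi_trough_ratio, sm))
          break
        }
      }
      if (label == "multimodal") break
    }
  }
  if (label == "unimodal")
    trace <- c(trace, if (n_pk < 2L) "single peak"
               else "no peak pair satisfied the bimodality thresholds")
  structure(list(label = label, peaks = pk, troughs = tr,
                 rule_trace = trace),
            class = "regime_label")
}

#' @rdname classify_modality
#' @details `classify_bimodal()` applies only the bimodality rule (never
#'   returning `"multimodal"`); `classify_multimodal()` is an alias for
#'   the full rule with precedence.
#' @export
classify_bimodal <- function(pmf, height_ratio = 0.10, trough_ratio = 0.10,
                             min_rel_height = 1e-4, smooth_window = 1L) {
  res <- classify_modality(pmf, height_ratio = height_ratio,
                           trough_ratio = trough_ratio,
                           min_rel_height = min_rel_height,
                           smooth_window = smooth_window)
  if (res$label == "multimodal") res$label <- "bimodal"
  res
}

#' @rdname classify_modality
#' @export
classify_multimodal <- classify_modality

#' @method print regime_label
#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("Modality: %s (%d peak%s)\n", x$label, nrow(x$peaks),
              if (nrow(x$peaks) == 1L) "" else "s"))
  for (tr in x$rule_trace) cat("  -", tr, "\n")
  invisible(x)
}

#' JSON record of a classification (for the command-line interface)
#'
#' @param label a `regime_label`.
#' @return A JSON string.
#' @export
regime_label_json <- function(label) {
  stopifnot(inherits(label, "regime_label"))
  jsonlite::toJSON(list(label = label$label, peaks = label$peaks,
                        troughs = label$troughs,
                        rule_trace = label$rule_trace),
                   auto_unbox = TRUE, digits = NA)
}
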