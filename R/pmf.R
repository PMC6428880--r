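#' Discrete probability mass function on non-negative copy numbers
#'
#' Normalised probability mass on copy numbers `0..support_max`, with an
#' explicit upper bound on the truncated tail mass so downstream
#' consumers can account for what was cut off. The stored masses plus the
#' tail bound always sum to 1 within `1e-9`.
#'
#' @param probs numeric vector of masses for copy numbers `0, 1, ...,
#'   length(probs) - 1`; all non-negative.
#' @param tail_mass_bound upper bound on the probability mass beyond
#'   `support_max` (default `0`).
#' @param provenance free-text label recording how the pmf was produced
#'   (e.g. `"three-stage"`, `"empirical"`, `"pmm"`, `"ssa"`).
#' @param normalize if `TRUE` (default), rescale `probs` so that the
#'   total including `tail_mass_bound` is exactly 1; if the raw total
#'   deviates from 1 by more than `1e-6` a numerical-quality warning is
#'   raised first.
#' @return An object of class `discrete_pmf`: list with fields `probs`,
#'   `support_max`, `tail_mass_bound`, `provenance`.
#' @examples
#' p <- discrete_pmf(dpois(0:30, 5), provenance = "poisson")
#' pmf_mean(p)
#' @export
discrete_pmf <- function(probs, tail_mass_bound = 0,
                         provenance = "unspecified", normalize = TRUE) {
  stopifnot(is.numeric(probs), length(probs) >= 1L,
            is.numeric(tail_mass_bound), length(tail_mass_bound) == 1L,
            tail_mass_bound >= 0)
  if (any(!is.finite(probs)) || any(probs < 0))
    stop("pmf masses must be finite and non-negative", call. = FALSE)
  tot <- sum(probs) + tail_mass_bound
  if (tot <= 0) stop("pmf has no mass", call. = FALSE)
  if (normalize) {
    if (abs(tot - 1) > 1e-6)
      warning(sprintf("pmf mass deviates from 1 by %.3g; renormalising",
                      tot - 1))
    if (abs(tot - 1) > 1e-15) {
      probs <- probs / tot
      tail_mass_bound <- tail_mass_bound / tot
    }
  } else if (abs(tot - 1) > 1e-9) {
    stop("pmf mass plus tail bound must equal 1 within 1e-9", call. = FALSE)
  }
  structure(list(probs = as.numeric(probs),
                 support_max = length(probs) - 1L,
                 tail_mass_bound = tail_mass_bound,
                 provenance = provenance),
            class = "discrete_pmf")
}

#' @method print discrete_pmf
#' @export
print.discrete_pmf <- function(x, ...) {
  cat(sprintf("Discrete pmf [%s]: support 0..%d, tail bound %.3g, mean %.4g, sd %.4g\n",
              x$provenance, x$support_max, x$tail_mass_bound,
              pmf_mean(x), sqrt(pmf_var(x))))
  invisible(x)
}

#' Moments of a discrete pmf
#'
#' Mean and variance over the stored support (the truncated tail is
#' ignored; keep `tail_mass_bound` small if moments matter).
#'
#' @param pmf a [discrete_pmf()] object.
#' @return A single number.
#' @export
pmf_mean <- function(pmf) {
  stopifnot(inherits(pmf, "discrete_pmf"))
  sum(pmf$probs * seqemp(pmf))
}

#' @rdname pmf_mean
#' @export
pmf_var <- function(pmf) {
  stopifnot(inherits(pmf, "discrete_pmf"))
  n <- seqemp(pmf)
  m <- sum(pmf$probs * n)
  sum(pmf$probs * (n - m)^2)
}

seqemp <- function(pmf) seq.int(0L, pmf$support_max)

#' Total variation distance between two discrete pmfs
#'
#' Half the L1 distance, with the shorter support zero-padded. Truncated
#' tail bounds contribute at most their sum, which is reported separately.
#'
#' @param p,q [discrete_pmf()] objects.
#' @return Numeric TV distance over the stored supports.
#' @export
tv_distance <- function(p, q) {
  stopifnot(inherits(p, "discrete_pmf"), inherits(q, "discrete_pmf"))
  n <- max(p$support_max, q$support_max) + 1L
  pp <- c(p$probs, numeric(n - length(p$probs)))
  qq <- c(q$probs, numeric(n - length(q$probs)))
  sum(abs(pp - qq)) / 2
}

#' Read and write pmf tables
#'
#' Two-column tab-separated tables `(copy_number, probability)` with a
#' `#`-prefixed header carrying provenance and the tail mass bound.
#' Values round-trip at 17 significant digits (bit-identical doubles).
#'
#' @param pmf a [discrete_pmf()] object.
#' @param path file path.
#' @return `write_pmf` returns `path` invisibly; `read_pmf` returns a
#'   [discrete_pmf()].
#' @export
write_pmf <- function(pmf, path) {
  stopifnot(inherits(pmf, "discrete_pmf"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# provenance: %s", pmf$provenance),
               sprintf("# tail_mass_bound: %.17g", pmf$tail_mass_bound),
               "# copy_number\tprobability"), con)
  writeLines(sprintf("%d\t%.17g", seqemp(pmf), pmf$probs), con)
  invisible(path)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  prov <- sub("^# provenance: ", "", grep("^# provenance:", hdr, value = TRUE))
  tail_bound <- as.numeric(sub("^# tail_mass_bound: ", "",
                               grep("^# tail_mass_bound:", hdr, value = TRUE)))
  if (length(prov) != 1L) prov <- "unspecified"
  if (length(tail_bound) != 1L) tail_bound <- 0
  parts <- strsplit(body, "\t", fixed = TRUE)
  ns <- as.integer(vapply(parts, `[[`, "", 1L))
  ps <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (any(ns != seq_along(ns) - 1L))
    stop("pmf table must list consecutive copy numbers from 0", call. = FALSE)
  discrete_pmf(ps, tail_mass_bound = tail_bound, provenance = prov,
               normalize = FALSE)
}
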