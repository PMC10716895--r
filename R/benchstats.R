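# Enrichment-curve evaluation of a ranked, labeled ligand list against a
# random-selection baseline, the area between curves as a single performance
# number, and Tanimoto fingerprint similarity.

#' Enrichment curve of a ranked, labeled list
#'
#' For each prefix of the ranking, the fraction of all known actives found so
#' far. `x` is the fraction of the list examined (strictly increasing, step
#' 1/n) and `y` the cumulative active fraction (non-decreasing, reaching 1
#' when every active is in the list).
#'
#' @param ranked_labels logical vector (TRUE = active) or character vector
#'   with values "active"/"decoy", in rank order (best first).
#' @return List of class `enrichment_curve` with `x` and `y`.
#' @export
enrichment_curve <- function(ranked_labels) {
  if (is.character(ranked_labels) || is.factor(ranked_labels))
    ranked_labels <- as.character(ranked_labels) == "active"
  lab <- as.logical(ranked_labels)
  n <- length(lab)
  if (!n) stop("empty label list")
  na <- sum(lab)
  if (!na) stop("enrichment curve undefined: no actives in the list")
  structure(list(x = seq_len(n) / n, y = cumsum(lab) / na),
            class = "enrichment_curve")
}

#' Random-selection baseline enrichment curve
#'
#' `expected` mode returns the diagonal y = x (the expectation over uniform
#' orderings); `sampled` mode returns the curve of one seeded uniform shuffle
#' of the labels.
#'
#' @param n_active,n_total counts with 0 < n_active <= n_total.
#' @param mode "expected" or "sampled".
#' @param seed RNG seed for sampled mode.
#' @return An `enrichment_curve`.
#' @export
random_baseline <- function(n_active, n_total, mode = c("expected", "sampled"),
                            seed = 1) {
  mode <- match.arg(mode)
  if (n_active <= 0 || n_active > n_total)
    stop("need 0 < n_active <= n_total")
  if (mode == "expected") {
    x <- seq_len(n_total) / n_total
    return(structure(list(x = x, y = x), class = "enrichment_curve"))
  }
  lab <- c(rep(TRUE, n_active), rep(FALSE, n_total - n_active))
  enrichment_curve(with_seed(seed, sample(lab)))
}

#' Area between two enrichment curves
#'
#' Trapezoidal integral of (y_a - y_b) over the fractional axis [0, 1], with
#' the implicit origin (0, 0) prepended to both curves. Positive values mean
#' curve `a` finds actives earlier than curve `b`; antisymmetric under
#' exchange of the curves.
#'
#' @param curve_a,curve_b `enrichment_curve`s over rankings of equal length.
#' @return Dimensionless signed area.
#' @export
difference_integral <- function(curve_a, curve_b) {
  if (length(curve_a$x) != length(curve_b$x))
    stop("curves have different ranked-list lengths")
  x <- c(0, curve_a$x)
  dy <- c(0, curve_a$y - curve_b$y)
  sum(diff(x) * (dy[-1] + dy[-length(dy)]) / 2)
}

#' Tanimoto similarity of two fingerprints
#'
#' |a AND b| / |a OR b| for equal-length bitsets; undefined (error) when both
#' fingerprints are empty.
#'
#' @param fp_a,fp_b logical (or 0/1) vectors of equal length.
#' @return Similarity in [0, 1].
#' @export
tanimoto <- function(fp_a, fp_b) {
  a <- as.logical(fp_a); b <- as.logical(fp_b)
  if (length(a) != length(b)) stop("fingerprints differ in length")
  un <- sum(a | b)
  if (un == 0) stop("Tanimoto undefined for two empty fingerprints")
  sum(a & b) / un
}

#' Chance of randomly picking an active ligand from a screened pool
#'
#' Stage composition arithmetic: 100 * n_active / n_pool, the percentage a
#' uniformly random single pick from the pool is active.
#'
#' @param n_active number of actives in the pool.
#' @param n_pool pool size.
#' @return Percentage.
#' @export
random_pick_rate <- function(n_active, n_pool) {
  if (n_pool <= 0) stop("pool must be non-empty")
  100 * n_active / n_pool
}

#' Fraction of a ligand set promoted to a later stage
#'
#' @param n_promoted number promoted.
#' @param n_total full set size.
#' @return Fraction in [0, 1].
#' @export
promotion_fraction <- function(n_promoted, n_total) {
  if (n_total <= 0) stop("set must be non-empty")
  n_promoted / n_total
}
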