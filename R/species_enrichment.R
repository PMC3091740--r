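#' Species representation statistic for matched miRNA sets
#'
#' Assesses whether a species contributes more or fewer mature sequences to
#' the matched set than expected from its share of the initial reference set.
#' With \code{q = m/M} (the species' share of the initial redundant set) and
#' \code{k} of \code{K} matched records, the default statistic is the exact
#' binomial point probability
#' \deqn{P(X = k) = {K \choose k} q^k (1-q)^{K-k},}
#' evaluated in log space. Direction is \code{"over"} when \code{k/K > q},
#' \code{"under"} when smaller, \code{"none"} when equal.
#'
#' The point mass is not a calibrated tail probability; \code{mode = "tail"}
#' returns the one-sided tail (\eqn{P(X \ge k)} for over-representation,
#' \eqn{P(X \le k)} for under-representation) for calibration studies. The
#' point-mass mode is the default because it is the form that reproduces the
#' published species-representation tables this statistic is modelled on.
#'
#' @param m species count in the initial redundant set.
#' @param M total size of the initial redundant set.
#' @param k species count in the matched redundant set.
#' @param K total size of the matched redundant set.
#' @param mode \code{"point_mass"} (default) or \code{"tail"}.
#' @return List with \code{p_value} (in (0, 1]) and \code{direction}
#'   (\code{"over"}, \code{"under"} or \code{"none"}).
#' @examples
#' representation_stat(32, 1929, 20, 497)  # p ~ 2.0e-4, over
#' @export
representation_stat <- function(m, M, k, K, mode = c("point_mass", "tail")) {
  mode <- match.arg(mode)
  stopifnot(M > 0, K > 0, m >= 0, m <= M, k >= 0, k <= K)
  q <- m / M
  if (q == 0 && k > 0) stop("species absent from initial set")
  direction <- if (k / K > q) "over" else if (k / K < q) "under" else "none"
  p <- if (mode == "point_mass") {
    if (q == 0) 1 else if (q == 1) {
      if (k == K) 1 else stop("species is the whole initial set but k < K")
    } else
      exp(lchoose(K, k) + k * log(q) + (K - k) * log1p(-q))
  } else {
    switch(direction,
           over  = pbinom(k - 1, K, q, lower.tail = FALSE),
           under = pbinom(k, K, q),
           none  = 1)
  }
  list(p_value = p, direction = direction)
}

#' Round a ratio to a one-decimal percentage
#'
#' Half-away-from-zero rounding, matching how representation tables are
#' conventionally printed (e.g. 48/497 -> 9.7).
#'
#' @param x numerator.
#' @param total denominator (> 0).
#' @return Percentage rounded to one decimal.
#' @export
percent <- function(x, total) {
  stopifnot(total > 0)
  v <- 100 * x / total
  sign(v) * floor(abs(v) * 10 + 0.5) / 10
}

#' Build a per-species enrichment table
#'
#' One row per species in the initial set, with redundant counts, one-decimal
#' percentages, the representation statistic and its direction. Totals
#' \code{M} and \code{K} are the sums of the supplied counts.
#'
#' @param initial_counts named integer vector: species -> initial redundant
#'   count.
#' @param matched_counts named integer vector: species -> matched redundant
#'   count; species absent default to 0. Must be a subset of
#'   \code{initial_counts} species.
#' @param mode passed to \code{\link{representation_stat}}.
#' @return data.frame with columns \code{species}, \code{m}, \code{pct_initial},
#'   \code{k}, \code{pct_matched}, \code{p_value}, \code{direction}; totals
#'   attached as attributes \code{M} and \code{K}.
#' @export
build_enrichment_table <- function(initial_counts, matched_counts,
                                   mode = c("point_mass", "tail")) {
  mode <- match.arg(mode)
  stopifnot(length(initial_counts) > 0, !is.null(names(initial_counts)))
  extra <- setdiff(names(matched_counts), names(initial_counts))
  if (length(extra))
    stop("matched species not in initial set: ", paste(extra, collapse = ", "))
  k <- setNames(rep(0L, length(initial_counts)), names(initial_counts))
  k[names(matched_counts)] <- matched_counts
  m <- initial_counts
  if (any(k > m))
    warning("matched count exceeds initial count for: ",
            paste(names(m)[k > m], collapse = ", "))
  M <- sum(m); K <- sum(k)
  if (K == 0) stop("no matched records; enrichment undefined")
  stat <- lapply(seq_along(m), function(i)
    representation_stat(m[[i]], M, k[[i]], K, mode = mode))
  out <- data.frame(
    species = names(m),
    m = as.integer(m),
    pct_initial = percent(as.integer(m), M),
    k = as.integer(k),
    pct_matched = percent(as.integer(k), K),
    p_value = vapply(stat, `[[`, numeric(1), "p_value"),
    direction = vapply(stat, `[[`, character(1), "direction"),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "M") <- M
  attr(out, "K") <- K
  out
}

#' Threshold sweep over an enrichment table
#'
#' Lists over- and under-represented species at each p-value threshold.
#' Stricter thresholds always yield subsets of looser ones.
#'
#' @param rows data.frame from \code{\link{build_enrichment_table}}.
#' @param thresholds decreasing vector of thresholds in (0, 1].
#' @return List of class \code{threshold_sweep}: per threshold, character
#'   vectors \code{over} and \code{under}.
#' @export
threshold_sweep <- function(rows, thresholds = c(0.05, 0.01, 0.005, 0.001)) {
  stopifnot(all(thresholds > 0), all(thresholds <= 1))
  out <- lapply(thresholds, function(t) {
    sel <- rows$p_value <= t
    list(threshold = t,
         over = rows$species[sel & rows$direction == "over"],
         under = rows$species[sel & rows$direction == "under"])
  })
  names(out) <- format(thresholds, trim = TRUE)
  class(out) <- "threshold_sweep"
  out
}

#' @export
print.threshold_sweep <- function(x, ...) {
  for (lev in x) {
    cat(sprintf("p <= %s\n  over:  %s\n  under: %s\n", format(lev$threshold),
                paste(lev$over, collapse = ", "),
                paste(lev$under, collapse = ", ")))
  }
  invisible(x)
}

#' Format a p-value the way enrichment tables print it
#'
#' Two significant digits; plain decimal at 1e-3 and above, scientific below.
#'
#' @param p numeric vector of p-values.
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x >= 1e-3) format(signif(x, 2), scientific = FALSE)
    else sprintf("%.1e", x)
  }, character(1))
}
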