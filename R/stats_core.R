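#' Upper-tail cumulative hypergeometric probability
#'
#' Computes \eqn{P(X \ge x)} where \eqn{X} is the number of shared genes
#' between a reference set of size \eqn{j} and a query set of size \eqn{n}
#' drawn without replacement from a universe of \eqn{m} genes:
#' \deqn{P = \sum_{i=x}^{\min(j,n)} \frac{\binom{j}{i}\binom{m-j}{n-i}}{\binom{m}{n}}.}
#'
#' This is the over-representation tail used for every enrichment and
#' crosstalk test in the package. Terms are accumulated on the log scale
#' (via `lchoose`) with a max-shift so genome-scale universes do not
#' overflow.
#'
#' All four arguments are recycled to a common length, so the function can
#' score a whole table of tests in one call.
#'
#' @param m Universe size (total genes).
#' @param j Reference (pathway) set size.
#' @param n Query set size (a second pathway, or a miRNA target set).
#' @param x Observed overlap between the two sets.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @seealso [hypergeom_lower()] for the lower tail, [bh_adjust()] for FDR
#'   control across a family of such tests.
#' @examples
#' hypergeom_upper(m = 100, j = 10, n = 5, x = 0) # certain event: 1
#' hypergeom_upper(m = 5, j = 2, n = 2, x = 1)    # 1 - C(3,2)/C(5,2) = 0.7
#' @export
hypergeom_upper <- function(m, j, n, x) {
  params <- check_hypergeom_params(m, j, n, x)
  with(params, {
    vapply(seq_along(m), function(k) {
      hi <- min(j[k], n[k])
      if (x[k] > hi) return(0)
      if (x[k] == 0) return(1) # X >= 0 is certain
      hyper_tail_sum(m[k], j[k], n[k], x[k]:hi)
    }, numeric(1))
  })
}

#' Lower-tail cumulative hypergeometric probability
#'
#' Computes \eqn{P(X \le x) = \sum_{i=0}^{x} \binom{j}{i}\binom{m-j}{n-i} /
#' \binom{m}{n}}, the literal printed form of the cumulative hypergeometric
#' sum. It is provided for fidelity and for the complement identity
#' `hypergeom_upper(..., x) == 1 - hypergeom_lower(..., x - 1)`; enrichment
#' testing should use [hypergeom_upper()], since the lower tail is small for
#' *under*-represented overlaps, not over-represented ones.
#'
#' @inheritParams hypergeom_upper
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
hypergeom_lower <- function(m, j, n, x) {
  params <- check_hypergeom_params(m, j, n, x)
  with(params, {
    vapply(seq_along(m), function(k) {
      if (x[k] >= min(j[k], n[k])) return(1) # full support is certain
      hyper_tail_sum(m[k], j[k], n[k], 0:x[k])
    }, numeric(1))
  })
}

# sum of hypergeometric pmf terms over indices `idx`, on the log scale
hyper_tail_sum <- function(m, j, n, idx) {
  lg <- lchoose(j, idx) + lchoose(m - j, n - idx) - lchoose(m, n)
  lg <- lg[is.finite(lg)]
  if (length(lg) == 0) return(0)
  shift <- max(lg)
  min(1, exp(shift) * sum(exp(lg - shift)))
}

check_hypergeom_params <- function(m, j, n, x) {
  len <- max(length(m), length(j), length(n), length(x))
  m <- rep_len(m, len); j <- rep_len(j, len)
  n <- rep_len(n, len); x <- rep_len(x, len)
  for (field in c("m", "j", "n", "x")) {
    v <- get(field)
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != round(v))) {
      abort(paste0("`", field, "` must be a non-negative integer"),
            class = "mirsnpnet_domain_error")
    }
  }
  if (any(j > m)) abort("`j` must not exceed `m`", class = "mirsnpnet_domain_error")
  if (any(n > m)) abort("`n` must not exceed `m`", class = "mirsnpnet_domain_error")
  if (any(x > pmin(j, n))) {
    abort("`x` must not exceed min(j, n)", class = "mirsnpnet_domain_error")
  }
  list(m = m, j = j, n = n, x = x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment. A thin validating wrapper around
#' `stats::p.adjust(method = "BH")` that rejects p-values outside `[0, 1]`
#' rather than propagating them. Adjustment never decreases a p-value,
#' preserves input order, and yields values non-decreasing in raw-p rank.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.001, 0.5)) # c(0.002, 0.5)
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric", class = "mirsnpnet_domain_error")
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]", class = "mirsnpnet_domain_error")
  }
  stats::p.adjust(p, method = "BH")
}
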