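## Differential expression between risk subgroups and gene-set enrichment.

#' Storey q-values
#'
#' Step-up FDR estimates with the null proportion estimated at a single
#' tuning point lambda: pi0 = min(1, mean(p > lambda) / (1 - lambda)),
#' clipped away from zero; q(i) = min over j with p(j) >= p(i) of
#' pi0 * m * p(j) / rank(j).
#'
#' @param p P-values.
#' @param lambda Tuning point for the pi0 estimate.
#' @return Q-values, monotone in the p-value ranking.
#' @export
storey_qvalue <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  pi0 <- max(pi0, 1 / m)
  ord <- order(p, decreasing = TRUE)
  q <- pi0 * m * p[ord] / rank(p, ties.method = "max")[ord]
  q <- cummin(pmin(q, 1))
  q[order(ord)]
}

#' Differential expression between binary patient classes
#'
#' Per-feature Welch two-sample t-test between the class-1 (high-risk) and
#' class-0 samples, with Storey q-values; a feature is significant at
#' `q_value < q_threshold`.  Direction is the sign of the class-1 minus
#' class-0 mean difference.
#'
#' @param expr Expression matrix (features x samples).
#' @param assignment Binary class per sample (same order as columns); both
#'   classes need at least 3 samples.
#' @param q_threshold Q-value threshold for the significant set.
#' @return Data frame with feature_id, t_stat, p_value, q_value, direction
#'   and significant columns.
#' @export
deg_test <- function(expr, assignment, q_threshold = 0.01) {
  if (ncol(expr) != length(assignment))
    stop("assignment length must match sample count", call. = FALSE)
  g1 <- assignment == 1
  g0 <- assignment == 0
  n1 <- sum(g1); n0 <- sum(g0)
  if (n1 < 3L || n0 < 3L)
    stop("each class needs at least 3 samples", call. = FALSE)
  m1 <- rowMeans(expr[, g1, drop = FALSE])
  m0 <- rowMeans(expr[, g0, drop = FALSE])
  v1 <- rowSums((expr[, g1, drop = FALSE] - m1)^2) / (n1 - 1)
  v0 <- rowSums((expr[, g0, drop = FALSE] - m0)^2) / (n0 - 1)
  sem2 <- v1 / n1 + v0 / n0
  tt <- (m1 - m0) / sqrt(sem2)
  df <- sem2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  # degenerate zero-variance features: identical values => null
  tt[sem2 == 0 & m1 == m0] <- 0
  df[!is.finite(df)] <- n1 + n0 - 2
  p <- 2 * pt(-abs(tt), df = df)
  p[is.infinite(tt)] <- 0
  q <- storey_qvalue(p)
  data.frame(feature_id = rownames(expr), t_stat = tt, p_value = p,
             q_value = q,
             direction = ifelse(m1 >= m0, "up_in_HR", "down_in_HR"),
             significant = q < q_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect significant gene sets across cohorts
#'
#' @param sets List (>= 2) of id vectors.
#' @return The common ids.
#' @export
intersect_deg <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 sets", call. = FALSE)
  Reduce(intersect, sets)
}

#' Fraction of differentially expressed genes up-regulated in high risk
#'
#' @param records Data frame with a `direction` column ([deg_test()] rows).
#' @return List with frac_up, n_up, n_total.
#' @export
updown_fraction <- function(records) {
  if (nrow(records) < 1L) stop("no records", call. = FALSE)
  n_up <- sum(records$direction == "up_in_HR")
  list(frac_up = n_up / nrow(records), n_up = n_up, n_total = nrow(records))
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric probability of the observed overlap between a
#' hit list and a gene set within a universe; shares its kernel with
#' [cooccurrence_hypergeom()].
#'
#' @param hits,geneset Character vectors, subsets of `universe`.
#' @param universe All tested ids.
#' @return Enrichment p-value.
#' @export
geneset_enrichment <- function(hits, geneset, universe) {
  cooccurrence_hypergeom(hits, geneset, universe)
}
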