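## Correlation screening of gene pairs within clinical subgroups.

#' Kendall's tau-b with a two-sided p-value
#'
#' Tie-corrected tau-b.  The p-value is exact (enumeration over
#' permutations) for n < 10 with tie-free data and uses the tie-corrected
#' normal approximation otherwise, as provided by [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return A list with elements `tau`, `p` and `n`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  has_ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  tau <- cor(x, y, method = "kendall")
  exact <- n < 10L && !has_ties
  p <- suppressWarnings(
    cor.test(x, y, method = "kendall", exact = exact)$p.value
  )
  list(tau = unname(tau), p = unname(min(p, 1)), n = n)
}

subgroup_samples <- function(clinical, subgroup) {
  if (is.null(subgroup)) return(clinical$sample_id)
  if (is.character(subgroup) && is.null(names(subgroup)))
    return(intersect(subgroup, clinical$sample_id))
  keep <- rep(TRUE, nrow(clinical))
  for (nm in names(subgroup)) {
    if (!nm %in% names(clinical))
      stop("unknown clinical column in subgroup filter: ", nm, call. = FALSE)
    keep <- keep & clinical[[nm]] %in% subgroup[[nm]]
  }
  clinical$sample_id[keep]
}

#' Pick the representative feature pair for a gene pair
#'
#' When several candidate feature (probe-set) pairs map to one gene pair,
#' the pair with the strongest tau by magnitude (positive or negative)
#' within the subgroup is kept; ties break lexicographically on
#' (feature_a, feature_b).
#'
#' @param candidates Data frame with columns `feature_a`, `feature_b`.
#' @param bundle A [cohort_bundle()].
#' @param subgroup Sample selector: NULL (all clinical samples), a character
#'   vector of sample ids, or a named list of clinical filters such as
#'   `list(grade = "G3", subtype = "basal")`.
#' @return The selected row of `candidates`, with `tau` and `p` appended.
#' @export
select_representative <- function(candidates, bundle, subgroup = NULL) {
  if (nrow(candidates) < 1L) stop("no candidate feature pairs", call. = FALSE)
  ids <- subgroup_samples(bundle$clinical, subgroup)
  stats_list <- lapply(seq_len(nrow(candidates)), function(i) {
    kendall_tau(bundle$expression[candidates$feature_a[i], ids],
                bundle$expression[candidates$feature_b[i], ids])
  })
  taus <- vapply(stats_list, `[[`, numeric(1), "tau")
  ord <- order(-abs(taus), candidates$feature_a, candidates$feature_b)
  best <- ord[1L]
  out <- candidates[best, , drop = FALSE]
  out$tau <- taus[best]
  out$p <- stats_list[[best]]$p
  out
}

#' Screen gene pairs for correlated partners within a subgroup
#'
#' Computes Kendall's tau-b between the two partner features of every pair,
#' restricted to the subgroup's samples.  Pairs represented by several
#' candidate feature mappings (duplicated `pair_id` rows) are first reduced
#' with [select_representative()].
#'
#' @param bundle A [cohort_bundle()].
#' @param pairs Gene-pair annotation data frame ([as_gene_pairs()]); the
#'   `gene_a`/`gene_b` columns name expression features.
#' @param subgroup Sample selector (see [select_representative()]); must
#'   select at least 3 samples.
#' @param alpha Significance threshold on the correlation p-value.
#' @return A list with `records` (one row per pair: pair_id, cohort,
#'   subgroup, tau, p_value, n) and `significant` (the subset with
#'   p_value < alpha).
#' @export
screen_pairs <- function(bundle, pairs, subgroup = NULL, alpha = 0.05) {
  ids <- subgroup_samples(bundle$clinical, subgroup)
  if (length(ids) < 3L)
    stop("subgroup selects fewer than 3 samples", call. = FALSE)
  sub_label <- if (is.null(subgroup)) "all"
               else paste(unlist(subgroup), collapse = "+")
  recs <- lapply(unique(pairs$pair_id), function(pid) {
    cand <- pairs[pairs$pair_id == pid, , drop = FALSE]
    cand2 <- data.frame(feature_a = cand$gene_a, feature_b = cand$gene_b,
                        stringsAsFactors = FALSE)
    rep_row <- select_representative(cand2, bundle, ids)
    data.frame(pair_id = pid, cohort = bundle$name, subgroup = sub_label,
               feature_a = rep_row$feature_a, feature_b = rep_row$feature_b,
               tau = rep_row$tau, p_value = rep_row$p, n = length(ids),
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  list(records = records,
       significant = records[records$p_value < alpha, , drop = FALSE])
}

#' Upper-tail hypergeometric co-occurrence test
#'
#' Probability of observing at least the actual overlap between two id sets
#' drawn from a common universe: P(X >= |A intersect B|) with N = |universe|,
#' K = |A|, n = |B|.
#'
#' @param setA,setB Character vectors, subsets of `universe`.
#' @param universe Character vector of all ids.
#' @return The upper-tail p-value.
#' @export
cooccurrence_hypergeom <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (length(setdiff(setA, universe)) || length(setdiff(setB, universe)))
    stop("setA and setB must be subsets of the universe", call. = FALSE)
  k <- length(intersect(setA, setB))
  N <- length(universe); K <- length(setA); n <- length(setB)
  unname(phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Compare two tau distributions by a two-sample KS test
#'
#' Used to contrast the correlation-coefficient distributions of a pair set
#' between tissue classes (e.g. tumor vs normal) or grades.  Also returns
#' the two empirical CDFs for cumulative-curve plots.
#'
#' @param recordsA,recordsB Data frames with a `tau` column (>= 2 rows each),
#'   e.g. the `records` element of [screen_pairs()].
#' @return A list with `D`, `p`, and `ecdf_a`/`ecdf_b` data frames
#'   (tau, cumulative frequency).
#' @export
compare_tau_distributions <- function(recordsA, recordsB) {
  ta <- recordsA$tau; tb <- recordsB$tau
  if (length(ta) < 2L || length(tb) < 2L)
    stop("need at least 2 records per side", call. = FALSE)
  ks <- suppressWarnings(ks.test(ta, tb, alternative = "two.sided"))
  step <- function(v) {
    v <- sort(v)
    data.frame(tau = v, cum_freq = seq_along(v) / length(v))
  }
  list(D = unname(ks$statistic), p = unname(ks$p.value),
       ecdf_a = step(ta), ecdf_b = step(tb))
}
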