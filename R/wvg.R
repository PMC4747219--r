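## Majority-voting integration of per-pair risk assignments (WVG).

#' Apply a fitted partition model to a cohort
#'
#' Standardizes the model's two partner genes across the cohort's clinical
#' samples, rotates, converts the model's quantile-scale cutoffs into
#' values on the rotated axes of this cohort, and assigns each patient to
#' the high- or low-risk sector.  Quantile-scale cutoffs are what makes a
#' configuration transferable across cohorts measured on different
#' absolute intensity scales.
#'
#' @param model One row of [fit_pair()] / [select_signature()] output,
#'   carrying `gene_a` and `gene_b` columns.
#' @param bundle A [cohort_bundle()].
#' @return Named integer vector of 0/1 risk labels over the cohort's
#'   clinical samples.
#' @export
apply_model <- function(model, bundle) {
  genes <- c(model$gene_a, model$gene_b)
  missing_genes <- setdiff(genes, rownames(bundle$expression))
  if (length(missing_genes))
    stop("pair ", model$pair_id, ": gene(s) not in expression matrix: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  ids <- bundle$clinical$sample_id
  ex <- standardize(bundle$expression[, ids, drop = FALSE], genes)
  rc <- rotate_coords(ex[model$gene_a, ], ex[model$gene_b, ], model$angle_index)
  m <- list(angle_index = 0L,
            c1 = unname(quantile(rc$x, model$c1_q, type = 7)),
            c2 = unname(quantile(rc$y, model$c2_q, type = 7)),
            hr_mask = model$hr_mask, sub_design = model$sub_design)
  setNames(assign_risk(m, rc$x, rc$y), ids)
}

#' Build the vote matrix of a model list over a cohort
#'
#' One row per partition model, one column per clinical sample; rows are
#' ordered by ascending training p-value (`train_p_max` when present,
#' otherwise `p_value`), most significant first, so the voting order is
#' deterministic.
#'
#' @param models Data frame of partition models (rows as returned by
#'   [select_signature()] or stacked [fit_pair()] rows with gene columns).
#' @param bundle A [cohort_bundle()].
#' @return Object of class `vote_matrix`: list(votes, pair_order,
#'   sample_ids, rank_p).
#' @export
build_vote_matrix <- function(models, bundle) {
  if (nrow(models) < 1L) stop("no models to vote with", call. = FALSE)
  rank_p <- if ("train_p_max" %in% names(models)) models$train_p_max
            else models$p_value
  ord <- order(rank_p, models$pair_id)
  models <- models[ord, , drop = FALSE]
  votes <- t(vapply(seq_len(nrow(models)),
                    function(i) apply_model(models[i, , drop = FALSE], bundle),
                    integer(nrow(bundle$clinical))))
  rownames(votes) <- models$pair_id
  structure(list(votes = votes, pair_order = models$pair_id,
                 sample_ids = bundle$clinical$sample_id,
                 rank_p = rank_p[ord]),
            class = "vote_matrix")
}

#' Majority vote over a vote matrix
#'
#' Each patient receives the predominant class over all pairs' votes; an
#' exact tie resolves to the most significant (first-ranked) pair's vote.
#' Optional per-pair weights (default 1, i.e. simple majority) are exposed
#' as an extension hook.
#'
#' @param matrix A `vote_matrix` from [build_vote_matrix()].
#' @param weights Optional non-negative per-pair weights in matrix row
#'   order.
#' @return Named integer vector of final 0/1 assignments.
#' @export
vote <- function(matrix, weights = NULL) {
  v <- matrix$votes
  if (nrow(v) < 1L) stop("vote matrix has no rows", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(v))
  if (length(weights) != nrow(v) || any(weights < 0))
    stop("weights must be non-negative, one per pair", call. = FALSE)
  score <- colSums(v * weights)
  half <- sum(weights) / 2
  out <- ifelse(score > half, 1L, ifelse(score < half, 0L, v[1L, ]))
  setNames(as.integer(out), matrix$sample_ids)
}

#' Evaluate a patient stratification against survival
#'
#' Cox Wald test of the high- versus low-risk assignment and the
#' prognostic accuracy, defined as the fraction of patients whose assigned
#' class equals their observed full-follow-up event indicator.
#'
#' @param assignment Binary risk assignment (1 = high risk).
#' @param times,events Survival outcome.
#' @return List with `fit` (a `cox_fit`) and `accuracy`.
#' @export
evaluate_stratification <- function(assignment, times, events) {
  if (length(unique(assignment)) < 2L)
    stop("assignment places all patients in one class", call. = FALSE)
  fit <- fit_cox_binary(times, events, assignment)
  list(fit = fit, accuracy = mean(assignment == events))
}

#' Cohen's kappa for two binary ratings
#'
#' Chance-corrected agreement with the standard marginal expected
#' agreement; used for cross-platform concordance of stratifications.
#'
#' @param a,b Binary vectors of equal length (>= 2).
#' @return Kappa in [-1, 1].
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  po <- mean(a == b)
  pe <- mean(a == 1) * mean(b == 1) + mean(a == 0) * mean(b == 0)
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}
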