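## End-to-end orchestration: screen -> fit -> select -> stratify -> DEG.

tumor_subset <- function(bundle) {
  keep <- bundle$clinical$subtype != "normal_tissue"
  if (!any(keep)) stop("cohort ", bundle$name, " has no tumor samples", call. = FALSE)
  cl <- bundle$clinical[keep, , drop = FALSE]
  cohort_bundle(bundle$expression[, cl$sample_id, drop = FALSE], cl, bundle$name)
}

load_cohort <- function(x) {
  if (inherits(x, "cohort_bundle")) return(x)
  if (is.list(x) && !is.null(x$expression) && is.character(x$expression)) {
    expr <- read_expression(x$expression)
    clin <- read_clinical(x$clinical)
    return(cohort_bundle(expr, clin, if (!is.null(x$name)) x$name else clin$cohort[1L]))
  }
  stop("cohort must be a cohort_bundle or a list of file paths", call. = FALSE)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full screening and stratification pipeline
#'
#' Orchestrates, over two or more training cohorts: (1) Kendall-tau
#' screening of gene pairs among tumor samples, keeping pairs positively
#' and significantly correlated in every training cohort; (2) exhaustive
#' 2-D (R)DDg partition scans plus per-gene 1-D groupings; (3) selection of
#' the cross-cohort synergistic signature; (4) majority-voting (WVG)
#' stratification of every cohort with Wald-test and accuracy evaluation;
#' (5) differential expression between the voted subgroups per cohort,
#' cross-cohort intersection and the up-regulated fraction.
#'
#' @param cohorts List of [cohort_bundle()] objects (or lists with
#'   `expression`/`clinical` file paths); the first `n_train` are the
#'   training cohorts.
#' @param pairs Gene-pair annotation data frame or TSV path.
#' @param n_train Number of training cohorts (>= 2).
#' @param mode Partition search mode, `"RDDG2D"` or `"DDG2D"`.
#' @param alpha_corr Screening threshold on the correlation p-value.
#' @param alpha_pair Per-cohort Wald threshold for signature selection.
#' @param alpha_wvg Significance threshold reported for the WVG Wald test.
#' @param q_deg Q-value threshold for differential expression.
#' @param quantile_grid Cutoff quantile grid of the partition searches.
#' @param min_group Minimum group size (default `max(5, 10%% of n)`).
#' @param out_dir Optional directory for stage TSV outputs.
#' @return A list of class `sagp_run`: per-stage tables and a `summary`
#'   with counts per stage, the signature table and per-cohort
#'   stratification results.
#' @export
run_pipeline <- function(cohorts, pairs, n_train = 2L,
                         mode = c("RDDG2D", "DDG2D"),
                         alpha_corr = 0.05, alpha_pair = 0.05,
                         alpha_wvg = 0.01, q_deg = 0.01,
                         quantile_grid = seq(0.10, 0.90, by = 0.05),
                         min_group = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(alpha_corr > 0, alpha_corr < 1, alpha_pair > 0, alpha_pair < 1,
            alpha_wvg > 0, alpha_wvg < 1, q_deg > 0, q_deg < 1)

  cohorts <- with_stage("load", lapply(cohorts, load_cohort))
  names(cohorts) <- vapply(cohorts, `[[`, "", "name")
  if (is.character(pairs)) pairs <- with_stage("load", read_gene_pairs(pairs))
  pairs <- as_gene_pairs(pairs)
  if (n_train < 2L || n_train > length(cohorts))
    stop("need at least 2 training cohorts", call. = FALSE)
  train <- names(cohorts)[seq_len(n_train)]
  tumors <- lapply(cohorts, tumor_subset)

  screen <- with_stage("screen", lapply(tumors, function(b)
    screen_pairs(b, pairs, subgroup = NULL, alpha = alpha_corr)))
  passing <- lapply(screen[train], function(s)
    s$records$pair_id[s$records$tau > 0 & s$records$p_value < alpha_corr])
  candidates <- Reduce(intersect, passing)

  scans <- list(); ddg1 <- NULL; signature <- NULL
  if (length(candidates)) {
    fit_stage <- with_stage("fit-pairs", {
      sc <- list(); d1 <- list()
      for (co in train) {
        b <- tumors[[co]]
        ex <- standardize(b$expression)
        tt <- b$clinical$dfs_years; ev <- b$clinical$event
        per_pair <- lapply(candidates, function(pid) {
          pr <- pairs[pairs$pair_id == pid, , drop = FALSE][1L, ]
          s <- scan_pair(tt, ev, ex[pr$gene_a, ], ex[pr$gene_b, ],
                         mode = mode, quantile_grid = quantile_grid,
                         min_group = min_group)
          cbind(pair_id = pid, gene_a = pr$gene_a, gene_b = pr$gene_b, s,
                stringsAsFactors = FALSE)
        })
        sc[[co]] <- do.call(rbind, per_pair)
        d1[[co]] <- do.call(rbind, lapply(candidates, function(pid) {
          pr <- pairs[pairs$pair_id == pid, , drop = FALSE][1L, ]
          data.frame(cohort = co, pair_id = pid,
                     p_a = ddg_1d(tt, ev, ex[pr$gene_a, ], quantile_grid,
                                  min_group)$p_value,
                     p_b = ddg_1d(tt, ev, ex[pr$gene_b, ], quantile_grid,
                                  min_group)$p_value,
                     stringsAsFactors = FALSE)
        }))
      }
      list(scans = sc, ddg1 = do.call(rbind, d1))
    })
    scans <- fit_stage$scans
    ddg1 <- fit_stage$ddg1
    signature <- with_stage("select-signature",
      select_signature(scans, ddg1, alpha = alpha_pair))
  }

  strat <- NULL; assignments <- NULL; deg <- NULL
  if (!is.null(signature) && nrow(signature)) {
    strat_stage <- with_stage("stratify", {
      res <- lapply(tumors, function(b) {
        vm <- build_vote_matrix(signature, b)
        a <- vote(vm)
        ev <- evaluate_stratification(a, b$clinical$dfs_years, b$clinical$event)
        list(assignment = a, wald_p = ev$fit$p_value, beta = ev$fit$beta,
             accuracy = ev$accuracy, n_hr = sum(a == 1), n_lr = sum(a == 0),
             significant = ev$fit$p_value < alpha_wvg)
      })
      res
    })
    assignments <- lapply(strat_stage, `[[`, "assignment")
    strat <- do.call(rbind, lapply(names(strat_stage), function(co) {
      s <- strat_stage[[co]]
      data.frame(cohort = co, wald_p = s$wald_p, beta = s$beta,
                 accuracy = s$accuracy, n_hr = s$n_hr, n_lr = s$n_lr,
                 significant = s$significant, stringsAsFactors = FALSE)
    }))
    deg <- with_stage("deg", {
      per <- lapply(names(tumors), function(co) {
        b <- tumors[[co]]
        deg_test(b$expression, assignments[[co]], q_threshold = q_deg)
      })
      names(per) <- names(tumors)
      sig_sets <- lapply(per, function(d) d$feature_id[d$significant])
      common <- if (length(sig_sets) >= 2L) intersect_deg(sig_sets)
                else sig_sets[[1L]]
      first <- per[[1L]]
      common_rec <- first[first$feature_id %in% common, , drop = FALSE]
      ud <- if (nrow(common_rec)) updown_fraction(common_rec) else NULL
      list(per_cohort = per, common = common, updown = ud)
    })
  }

  summary <- list(
    thresholds = list(alpha_corr = alpha_corr, alpha_pair = alpha_pair,
                      alpha_wvg = alpha_wvg, q_deg = q_deg, mode = mode),
    n_pairs_input = length(unique(pairs$pair_id)),
    n_pairs_screened = length(candidates),
    n_signature = if (is.null(signature)) 0L else nrow(signature),
    signature = signature,
    stratification = strat,
    n_deg_common = if (is.null(deg)) NA_integer_ else length(deg$common),
    deg_frac_up = if (is.null(deg) || is.null(deg$updown)) NA_real_
                  else deg$updown$frac_up)

  run <- list(cohorts = names(cohorts), train = train,
              screen = lapply(screen, `[[`, "records"),
              candidates = candidates, scans = scans, ddg1d = ddg1,
              signature = signature, stratification = strat,
              assignments = assignments, deg = deg, summary = summary)
  class(run) <- "sagp_run"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (co in names(run$screen))
      write.table(run$screen[[co]], file.path(out_dir, paste0("screen_", co, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(signature) && nrow(signature))
      write.table(signature, file.path(out_dir, "signature.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(strat))
      write.table(strat, file.path(out_dir, "stratification.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(assignments)) {
      adf <- do.call(rbind, lapply(names(assignments), function(co)
        data.frame(cohort = co, sample_id = names(assignments[[co]]),
                   risk_class = unname(assignments[[co]]),
                   stringsAsFactors = FALSE)))
      write.table(adf, file.path(out_dir, "assignments.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  run
}

#' @export
print.sagp_run <- function(x, ...) {
  s <- x$summary
  cat("<sagp_run> ", length(x$cohorts), " cohorts (training: ",
      paste(x$train, collapse = ", "), ")\n", sep = "")
  cat("  pairs: ", s$n_pairs_input, " input -> ", s$n_pairs_screened,
      " screened -> ", s$n_signature, " in signature\n", sep = "")
  if (!is.null(s$stratification)) {
    for (i in seq_len(nrow(s$stratification))) {
      r <- s$stratification[i, ]
      cat(sprintf("  %s: WVG Wald p = %.3g, accuracy = %.1f%%, HR/LR = %d/%d\n",
                  r$cohort, r$wald_p, 100 * r$accuracy, r$n_hr, r$n_lr))
    }
  }
  if (!is.na(s$n_deg_common))
    cat(sprintf("  DEGs common across cohorts: %d (%.0f%% up in HR)\n",
                s$n_deg_common, 100 * s$deg_frac_up))
  invisible(x)
}
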