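## 2-D data-driven grouping (DDg) and its rotated extension (RDDg).
##
## A gene pair spans a plane of standardized expression.  Two cutoffs split
## the (optionally rotated) plane into four quadrants; a design assigns a
## non-trivial subset of quadrants to the high-risk sector, and each design
## has two sub-designs (the two risk-label orientations).  The fit is an
## exhaustive search over designs x rotation angles x cutoff pairs for the
## partition minimizing the binary-Cox Wald p-value.
##
## Quadrants: Q1 = (x' <= c1, y' <= c2), Q2 = (<=, >), Q3 = (>, <=),
## Q4 = (>, >); a design's HR set is encoded as a bitmask with bit q-1 set
## when quadrant q is high-risk.  Boundary points (x' == c1) fall on the
## low ("<=") side.

N_ANGLES <- 16L
ANGLE_STEP_DEG <- 90 / N_ANGLES  # 5.625 degrees

# design_id 1..7; designs 6 and 7 are the single-axis splits used only by
# the rotated search (at angle 0 they duplicate the 1-D grouping).
DESIGN_MASKS <- c(1L, 2L, 4L, 8L, 9L, 3L, 5L)
DDG2D_DESIGNS <- 1:5

mask_label <- function(mask) {
  paste(paste0("Q", which(bitwAnd(mask, 2L^(0:3)) > 0L)), collapse = "+")
}

#' Enumerate the quadrant bipartition designs
#'
#' The rotated 2-D grouping uses all 7 non-trivial bipartitions of the four
#' quadrants into two sectors (14 sub-designs); the plain 2-D grouping uses
#' the 5 bipartitions whose boundary involves both cutoffs (10 sub-designs),
#' excluding the two single-axis splits.
#'
#' @param mode `"RDDG2D"` or `"DDG2D"`.
#' @return Data frame with columns design_id, hr_quadrants, hr_mask,
#'   sub_design; one row per (design, sub-design).
#' @export
enumerate_designs <- function(mode = c("RDDG2D", "DDG2D")) {
  mode <- match.arg(mode)
  ids <- if (mode == "DDG2D") DDG2D_DESIGNS else seq_along(DESIGN_MASKS)
  base <- data.frame(design_id = ids,
                     hr_quadrants = vapply(DESIGN_MASKS[ids], mask_label, ""),
                     hr_mask = DESIGN_MASKS[ids],
                     stringsAsFactors = FALSE)
  out <- rbind(transform(base, sub_design = "as_is"),
               transform(base, sub_design = "flipped"))
  out <- out[order(out$design_id, out$sub_design), ]
  rownames(out) <- NULL
  out
}

#' Angle grid of the rotated grouping
#'
#' @return The 16 rotation angles in degrees: 0, 5.625, ..., 84.375.
#'   Angles of 90 degrees and beyond only permute quadrants and would
#'   duplicate existing sub-designs.
#' @export
rotation_angles <- function() ANGLE_STEP_DEG * (0:(N_ANGLES - 1L))

#' Rotate standardized coordinates
#'
#' Rotates points by minus the model angle (equivalently, rotates the
#' cutoff axes by plus the angle) about the origin.
#'
#' @param x,y Standardized coordinates.
#' @param angle_index Integer 0..15; the angle is `angle_index * 5.625`
#'   degrees.
#' @return List with rotated `x` and `y`.
#' @export
rotate_coords <- function(x, y, angle_index) {
  theta <- angle_index * ANGLE_STEP_DEG * pi / 180
  list(x = x * cos(theta) + y * sin(theta),
       y = -x * sin(theta) + y * cos(theta))
}

quadrant_of <- function(x, y, c1, c2) {
  1L + 2L * (x > c1) + (y > c2)
}

#' Assign samples to the high-risk sector of a fitted partition
#'
#' @param model A partition model (one row of [fit_pair()] output or a list
#'   with angle_index, c1, c2, hr_mask, sub_design).
#' @param x,y Standardized expression of the two partner genes.
#' @return Integer vector: 1 = high risk, 0 = low risk.
#' @export
assign_risk <- function(model, x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  rc <- rotate_coords(x, y, model$angle_index)
  q <- quadrant_of(rc$x, rc$y, model$c1, model$c2)
  lab <- as.integer(bitwAnd(model$hr_mask, 2L^(q - 1L)) > 0L)
  if (identical(model$sub_design, "flipped")) lab <- 1L - lab
  lab
}

#' Exhaustively scan all partition configurations of a gene pair
#'
#' Evaluates the binary Cox fit (Breslow ties) of every admissible
#' combination of design, rotation angle (rotated mode only) and cutoff
#' pair, where cutoffs are the empirical quantiles of the rotated
#' coordinates.  A configuration is admissible when both sides have at
#' least `min_group` patients and the fit is well defined.
#'
#' @param times,events Survival outcome.
#' @param x,y Standardized expression of the two partner genes.
#' @param mode `"RDDG2D"` (7 designs x 16 angles) or `"DDG2D"` (5 designs,
#'   angle 0 only).
#' @param quantile_grid Candidate cutoff quantiles on each rotated axis.
#' @param min_group Minimum patients per side; default `max(5, 10%% of n)`.
#' @return Data frame of admissible configurations in canonical search
#'   order (angle, then design, then cutoff indices): angle_index,
#'   design_id, sub_design, c1_q, c2_q, c1, c2, beta, se, p_value.  `beta`
#'   is the log hazard ratio of the HR sector after the sub-design choice,
#'   so it is always positive.
#' @export
scan_pair <- function(times, events, x, y, mode = c("RDDG2D", "DDG2D"),
                      quantile_grid = seq(0.10, 0.90, by = 0.05),
                      min_group = NULL) {
  mode <- match.arg(mode)
  n <- length(times)
  stopifnot(length(events) == n, length(x) == n, length(y) == n)
  if (is.null(min_group)) min_group <- default_min_group(n)
  ids <- if (mode == "DDG2D") DDG2D_DESIGNS else seq_along(DESIGN_MASKS)
  masks <- DESIGN_MASKS[ids]
  angles <- if (mode == "DDG2D") 0L else 0:(N_ANGLES - 1L)

  ord <- order(times)
  t_s <- as.numeric(times[ord])
  e_s <- as.integer(events[ord])

  res <- vector("list", length(angles))
  for (ai in seq_along(angles)) {
    a <- angles[ai]
    rc <- rotate_coords(x, y, a)
    c1g <- unname(quantile(rc$x, quantile_grid, type = 7))
    c2g <- unname(quantile(rc$y, quantile_grid, type = 7))
    fits <- .cpp_scan_partitions(t_s, e_s, rc$x[ord], rc$y[ord],
                                 c1g, c2g, masks, as.integer(min_group))
    grid <- expand.grid(i2 = seq_along(c2g), i1 = seq_along(c1g),
                        m = seq_along(masks), KEEP.OUT.ATTRS = FALSE)
    keep <- !is.na(fits[, 1L])
    if (!any(keep)) next
    beta <- fits[keep, 1L]
    se <- fits[keep, 2L]
    g <- grid[keep, , drop = FALSE]
    res[[ai]] <- data.frame(
      angle_index = a,
      design_id = ids[g$m],
      sub_design = ifelse(beta > 0, "as_is", "flipped"),
      hr_mask = masks[g$m],
      c1_q = quantile_grid[g$i1], c2_q = quantile_grid[g$i2],
      c1 = c1g[g$i1], c2 = c2g[g$i2],
      beta = abs(beta), se = se,
      p_value = pchisq((beta / se)^2, df = 1, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) stop("no admissible partition configuration", call. = FALSE)
  out <- do.call(rbind, res)
  out <- out[order(out$angle_index, out$design_id, out$c1_q, out$c2_q), ]
  rownames(out) <- NULL
  out
}

#' Fit the optimal 2-D (R)DDg partition for one gene pair
#'
#' Runs [scan_pair()] and returns the configuration minimizing the Wald
#' p-value; ties resolve to the smallest angle index, then lowest design
#' id, then lowest cutoff grid indices.  The sub-design is oriented so the
#' high-risk sector has the elevated hazard (beta > 0), and the winning
#' partition is refit with [fit_cox_binary()] for the reported estimates.
#'
#' @inheritParams scan_pair
#' @param pair_id Optional pair identifier carried into the result.
#' @return A one-row data frame of class `partition_model`.
#' @export
fit_pair <- function(times, events, x, y, mode = c("RDDG2D", "DDG2D"),
                     quantile_grid = seq(0.10, 0.90, by = 0.05),
                     min_group = NULL, pair_id = NA_character_) {
  mode <- match.arg(mode)
  sc <- scan_pair(times, events, x, y, mode, quantile_grid, min_group)
  best <- sc[which.min(sc$p_value), , drop = FALSE]
  fit <- fit_cox_binary(times, events, assign_risk(best, x, y))
  out <- data.frame(pair_id = pair_id, mode = mode, best,
                    stringsAsFactors = FALSE)
  out$beta <- fit$beta
  out$se <- fit$se
  out$p_value <- fit$p_value
  rownames(out) <- NULL
  class(out) <- c("partition_model", "data.frame")
  out
}

config_key <- function(df) {
  paste(df$angle_index, df$design_id, df$sub_design,
        format(df$c1_q, nsmall = 2), format(df$c2_q, nsmall = 2), sep = "|")
}

#' Select the cross-cohort synergistic gene-pair signature
#'
#' Training is performed independently in every cohort: each cohort's
#' optimal configuration (design, sub-design, rotation angle,
#' quantile-scale cutoffs) is a candidate "best training parameter set".
#' A pair enters the signature when one candidate configuration, held
#' fixed, is survival significant (Wald p < alpha) in every training
#' cohort and synergistic there: its p-value in each cohort is strictly
#' smaller than the best 1-D grouping p-value of both partner genes in
#' that cohort.  Restricting candidates to the trained optima makes the
#' cross-cohort requirement a genuine validation (a configuration
#' optimized in one cohort faces the other cohort as a single fixed
#' test), which is what keeps the false-selection rate of null pairs near
#' alpha^2 rather than inflated by the size of the search grid.  Among
#' qualifying candidates the one minimizing the maximum over-cohort
#' p-value is kept.
#'
#' @param scans_by_cohort Named list (>= 2 cohorts) of scan tables: each a
#'   data frame of [scan_pair()] rows with an additional `pair_id` column
#'   (and optionally gene annotations).
#' @param ddg1d_by_cohort Data frame with columns cohort, pair_id, p_a,
#'   p_b: the best 1-D DDg p-values of the two partner genes per cohort.
#' @param alpha Per-cohort significance threshold.
#' @return Data frame of selected models, one row per pair, with per-cohort
#'   p-value columns `p_<cohort>` and `train_p_max`; zero rows when nothing
#'   qualifies.
#' @export
select_signature <- function(scans_by_cohort, ddg1d_by_cohort, alpha = 0.05) {
  if (length(scans_by_cohort) < 2L)
    stop("need at least 2 training cohorts", call. = FALSE)
  cohorts <- names(scans_by_cohort)
  pair_sets <- lapply(scans_by_cohort, function(s) unique(s$pair_id))
  shared <- Reduce(intersect, pair_sets)
  if (!length(shared))
    stop("training cohorts have disjoint pair sets", call. = FALSE)

  selected <- list()
  for (pid in shared) {
    tabs <- lapply(cohorts, function(co) {
      s <- scans_by_cohort[[co]]
      s[s$pair_id == pid, , drop = FALSE]
    })
    keys <- lapply(tabs, config_key)
    # candidate configurations: each cohort's trained optimum
    cand_keys <- unique(vapply(tabs, function(tb) {
      if (!nrow(tb)) return(NA_character_)
      config_key(tb[which.min(tb$p_value), , drop = FALSE])
    }, character(1)))
    cand_keys <- cand_keys[!is.na(cand_keys)]
    # keep candidates admissible in every cohort
    common <- cand_keys[vapply(cand_keys, function(k)
      all(vapply(keys, function(kk) k %in% kk, TRUE)), TRUE)]
    if (!length(common)) next
    base <- tabs[[1L]][match(common, keys[[1L]]), , drop = FALSE]
    pmat <- vapply(seq_along(cohorts), function(i) {
      tabs[[i]]$p_value[match(common, keys[[i]])]
    }, numeric(length(common)))
    pmat <- matrix(pmat, nrow = length(common))
    ok <- rowSums(pmat < alpha) == length(cohorts)
    for (i in seq_along(cohorts)) {
      d1 <- ddg1d_by_cohort[ddg1d_by_cohort$cohort == cohorts[i] &
                            ddg1d_by_cohort$pair_id == pid, , drop = FALSE]
      if (nrow(d1) != 1L)
        stop("missing 1-D grouping p-values for pair ", pid,
             " in cohort ", cohorts[i], call. = FALSE)
      ok <- ok & pmat[, i] < d1$p_a & pmat[, i] < d1$p_b
    }
    if (!any(ok)) next
    cand <- base[ok, , drop = FALSE]
    cand_p <- pmat[ok, , drop = FALSE]
    ordx <- order(cand$angle_index, cand$design_id, cand$c1_q, cand$c2_q)
    cand <- cand[ordx, , drop = FALSE]
    cand_p <- cand_p[ordx, , drop = FALSE]
    pmax_coh <- apply(cand_p, 1L, max)
    ibest <- which.min(pmax_coh)
    row <- cand[ibest, , drop = FALSE]
    for (i in seq_along(cohorts)) row[[paste0("p_", cohorts[i])]] <- cand_p[ibest, i]
    row$train_p_max <- pmax_coh[ibest]
    selected[[pid]] <- row
  }
  if (!length(selected)) {
    out <- scans_by_cohort[[1L]][0, , drop = FALSE]
    out$train_p_max <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, selected)
  rownames(out) <- NULL
  out
}
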