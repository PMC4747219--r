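test_that("design enumeration matches the brute-force bipartition count", {
  r <- enumerate_designs("RDDG2D")
  d <- enumerate_designs("DDG2D")
  expect_equal(length(unique(r$design_id)), 7L)
  expect_equal(nrow(r), 14L)
  expect_equal(length(unique(d$design_id)), 5L)
  expect_equal(nrow(d), 10L)

  # oracle: enumerate all 2^4 quadrant labelings, drop the two trivial
  # ones, collapse complements
  labelings <- setdiff(0:15, c(0, 15))
  expect_equal(length(labelings), 14L)
  reps <- unique(pmin(labelings, 15 - labelings))
  expect_equal(length(reps), 7L)
  my_masks <- unique(r$hr_mask)
  expect_setequal(pmin(my_masks, 15 - my_masks), reps)

  # the designs excluded from the plain 2-D mode are the single-axis splits
  excluded <- setdiff(unique(r$hr_mask), unique(d$hr_mask))
  expect_setequal(excluded, c(3L, 5L))  # {Q1,Q2} and {Q1,Q3}
})

test_that("the rotation grid holds exactly 16 angles over [0, 90)", {
  a <- rotation_angles()
  expect_length(a, 16L)
  expect_equal(a[1], 0)
  expect_equal(diff(a), rep(5.625, 15))
  expect_lt(max(a), 90)
})

test_that("assign_risk follows the quadrant, boundary and flip conventions", {
  m <- true_partition(hr_mask = 8L)  # HR = Q4 = (x > c1, y > c2)
  expect_equal(assign_risk(m, c(1, -1), c(1, -1)), c(1L, 0L))
  # boundary point x' == c1 belongs to the low side
  expect_equal(assign_risk(m, 0, 1), 0L)
  expect_equal(assign_risk(m, 1e-12, 1), 1L)
  mf <- true_partition(hr_mask = 8L, sub_design = "flipped")
  expect_equal(assign_risk(mf, c(1, -1), c(1, -1)), c(0L, 1L))
})

test_that("rotating the data by 90 degrees permutes quadrants consistently", {
  set.seed(17)
  x <- rnorm(100); y <- rnorm(100)
  # data rotated by +90 degrees: (x, y) -> (-y, x); quadrant permutation
  # Q1->Q3, Q2->Q1, Q3->Q4, Q4->Q2 in mask space
  perm_mask <- function(mask) {
    to <- c(3L, 1L, 4L, 2L)  # image of Q1..Q4
    Reduce(bitwOr, ifelse(bitwAnd(mask, 2L^(0:3)) > 0L, 2L^(to - 1L), 0L))
  }
  for (mask in c(1L, 8L, 9L, 3L, 5L)) {
    lab0 <- assign_risk(true_partition(hr_mask = mask), x, y)
    lab90 <- assign_risk(true_partition(hr_mask = perm_mask(mask)), -y, x)
    expect_equal(lab90, lab0)
  }
})

test_that("scan tables of the plain mode embed in the rotated mode at angle 0", {
  sp <- make_survival_pair(n = 80, seed = 5)
  s2 <- scan_pair(sp$times, sp$events, sp$x, sp$y, "DDG2D")
  sr <- scan_pair(sp$times, sp$events, sp$x, sp$y, "RDDG2D")
  sr0 <- sr[sr$angle_index == 0 & sr$design_id <= 5, ]
  key <- function(s) paste(s$design_id, s$c1_q, s$c2_q)
  expect_equal(key(s2), key(sr0))
  expect_equal(s2$p_value, sr0$p_value, tolerance = 1e-12)
})

test_that("fit_pair equals an independent exhaustive loop on a reduced grid", {
  sp <- make_survival_pair(n = 60, seed = 9)
  grid <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  for (mode in c("DDG2D", "RDDG2D")) {
    best <- fit_pair(sp$times, sp$events, sp$x, sp$y, mode, quantile_grid = grid)
    ids <- if (mode == "DDG2D") 1:5 else 1:7
    masks <- c(1L, 2L, 4L, 8L, 9L, 3L, 5L)[ids]
    angles <- if (mode == "DDG2D") 0L else 0:15
    min_group <- max(5, ceiling(0.1 * 60))
    pmin_oracle <- Inf
    for (a in angles) {
      rc <- rotate_coords(sp$x, sp$y, a)
      c1g <- quantile(rc$x, grid, type = 7)
      c2g <- quantile(rc$y, grid, type = 7)
      for (m in masks) for (c1 in c1g) for (c2 in c2g) {
        q <- 1L + 2L * (rc$x > c1) + (rc$y > c2)
        g <- as.integer(bitwAnd(m, 2L^(q - 1L)) > 0L)
        if (sum(g) < min_group || sum(1 - g) < min_group) next
        p <- tryCatch(fit_cox_binary(sp$times, sp$events, g)$p_value,
                      error = function(e) NA_real_)
        if (!is.na(p) && p < pmin_oracle) pmin_oracle <- p
      }
    }
    expect_equal(best$p_value, pmin_oracle, tolerance = 1e-6)
  }
})

test_that("the rotated pair fit never trails the better partner's 1-D grouping", {
  for (seed in c(2, 12, 22)) {
    sp <- make_survival_pair(n = 150, seed = seed)
    p1 <- ddg_1d(sp$times, sp$events, sp$x)$p_value
    p2 <- ddg_1d(sp$times, sp$events, sp$y)$p_value
    pp <- fit_pair(sp$times, sp$events, sp$x, sp$y, "RDDG2D")$p_value
    expect_lte(pp, min(p1, p2) + 1e-12)
  }
})

test_that("plain 2-D fit recovers a generated single-quadrant design", {
  # each coordinate is a latent binary indicator plus measurement noise;
  # the true HR sector is the upper-right quadrant at boundary (0.5, 0.5)
  within1 <- function(v, level, boundary) {
    lo <- quantile(v, max(level - 0.05, 0.10), type = 7)
    hi <- quantile(v, min(level + 0.05, 0.90), type = 7)
    lo <= boundary && boundary <= hi
  }
  hits <- 0; design_hits <- 0
  for (r in 1:20) {
    set.seed(600 + r)
    n <- 200
    u <- rbinom(n, 1, 0.5); v <- rbinom(n, 1, 0.5)
    x <- u + rnorm(n, sd = 0.15); y <- v + rnorm(n, sd = 0.15)
    risk <- as.integer(u == 1 & v == 1)
    tt <- rexp(n, 0.08 * exp(1.5 * risk))
    pm <- fit_pair(tt, rep(1L, n), x, y, "DDG2D")
    design_hits <- design_hits + (pm$design_id == 4 && pm$sub_design == "as_is")
    hits <- hits + (pm$design_id == 4 && pm$sub_design == "as_is" &&
                      within1(x, pm$c1_q, 0.5) && within1(y, pm$c2_q, 0.5))
  }
  expect_gte(design_hits, 19)  # the design itself is essentially always found
  expect_gte(hits, 13)         # cutoffs localize in a clear majority
})

test_that("signature selection demands cross-cohort significance and synergy", {
  cfg <- function(pid, p, c1q = 0.5) {
    data.frame(pair_id = pid, angle_index = 0L, design_id = 4L,
               sub_design = "as_is", hr_mask = 8L, c1_q = c1q, c2_q = 0.5,
               c1 = 0, c2 = 0, beta = 1, se = 0.3, p_value = p,
               stringsAsFactors = FALSE)
  }
  d1 <- function(coh, pid, pa, pb)
    data.frame(cohort = coh, pair_id = pid, p_a = pa, p_b = pb,
               stringsAsFactors = FALSE)

  # all criteria met
  scans <- list(A = cfg("p1", 0.01), B = cfg("p1", 0.02))
  dd <- rbind(d1("A", "p1", 0.2, 0.3), d1("B", "p1", 0.15, 0.4))
  sel <- select_signature(scans, dd)
  expect_equal(sel$pair_id, "p1")
  expect_equal(sel$train_p_max, 0.02)

  # significant in one cohort only
  scans$B$p_value <- 0.30
  expect_equal(nrow(select_signature(scans, dd)), 0L)

  # non-synergistic: one partner's 1-D grouping is already better
  scans$B$p_value <- 0.02
  dd2 <- rbind(d1("A", "p1", 0.005, 0.3), d1("B", "p1", 0.15, 0.4))
  expect_equal(nrow(select_signature(scans, dd2)), 0L)

  # a candidate must be one cohort's trained optimum to qualify
  scansA <- rbind(cfg("p1", 0.001, c1q = 0.2), cfg("p1", 0.04, c1q = 0.5))
  scansB <- rbind(cfg("p1", 0.90, c1q = 0.2), cfg("p1", 0.04, c1q = 0.5))
  sel2 <- select_signature(list(A = scansA, B = scansB), dd)
  expect_equal(sel2$c1_q, 0.5)  # B's optimum validated in A, not A's in B

  expect_error(select_signature(list(A = cfg("p1", 0.01), B = cfg("p2", 0.01)), dd),
               "disjoint")
})
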