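# Fixture builders shared across test files.  All data is generated in code.

make_expr <- function(nf = 4, ns = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nf * ns, mean = 8), nrow = nf,
              dimnames = list(paste0("g", seq_len(nf)), paste0("S", seq_len(ns))))
  m
}

make_clinical <- function(ids, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = ids,
             dfs_years = round(runif(length(ids), 0.5, 10), 3),
             event = rbinom(length(ids), 1, 0.5),
             grade = sample(c("G1", "G3"), length(ids), replace = TRUE),
             subtype = sample(c("basal", "non_basal"), length(ids), replace = TRUE),
             cohort = "test", stringsAsFactors = FALSE)
}

make_bundle <- function(nf = 4, ns = 12, seed = 1, name = "test") {
  expr <- make_expr(nf, ns, seed)
  cohort_bundle(expr, make_clinical(colnames(expr), seed), name)
}

true_partition <- function(hr_mask = 8L, angle_index = 0L, c1 = 0, c2 = 0,
                           sub_design = "as_is") {
  list(angle_index = angle_index, c1 = c1, c2 = c2, hr_mask = hr_mask,
       sub_design = sub_design)
}

# one simulated pair with survival tied to a single-quadrant HR sector
make_survival_pair <- function(n = 200, beta = 1.5, tau = 0.5, seed = 1,
                               hazard = 0.08, censor_max = 12) {
  set.seed(seed)
  pe <- simulate_pair_expression(n, tau)
  sv <- simulate_survival(pe$x, pe$y, true_partition(), beta, hazard, censor_max)
  list(x = pe$x, y = pe$y, times = sv$times, events = sv$events, risk = sv$risk)
}

# brute-force Kendall tau-b by pair counting (independent oracle)
brute_tau_b <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[j] - x[i]); b <- sign(y[j] - y[i])
    if (a == 0 || b == 0) next
    if (a == b) C <- C + 1 else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx_total(x)) * (n0 - tx_total(y)))
}

tx_total <- function(v) {
  tab <- table(v)
  sum(tab * (tab - 1) / 2)
}
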