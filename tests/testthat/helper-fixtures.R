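# Shared fixtures and small simulation helpers (all generated in code).

five_delays <- c(1, 7, 30, 182, 365)

make_profile <- function(points, llr = 100, id = "p1",
                         delays = five_delays[seq_along(points)]) {
  dd_profile(id, delays, points, llr)
}

# random indifference-point profiles (rows) in [0, llr]
random_profiles <- function(n, n_delays = 5, llr = 100) {
  matrix(runif(n * n_delays, 0, llr), nrow = n)
}

# stacked rows for model tests: parent slope `b_parent`, child slope
# `b_child` on a shared family-level predictor, family random intercept sd
# `tau`, residual sd `sigma`
make_stacked <- function(n_fam, b_parent = 0, b_child = 0,
                         tau = 0.1, sigma = 0.2) {
  x <- rnorm(n_fam)
  u <- rnorm(n_fam, 0, tau)
  mk <- function(role, b, mu) {
    data.frame(family_id = sprintf("F%04d", seq_len(n_fam)),
               member = role,
               auc_ord = mu + b * x + u + rnorm(n_fam, 0, sigma),
               x = x,
               age = if (role == "parent") rnorm(n_fam, 41, 7)
                     else rnorm(n_fam, 9, 2),
               sex_code = sample(1:2, n_fam, replace = TRUE),
               minority = rbinom(n_fam, 1, 0.3))
  }
  rbind(mk("parent", b_parent, 0.7), mk("child", b_child, 0.55))
}

# interaction row of the stacked scarcity model for a scored cohort
scarcity_interaction <- function(scored) {
  d <- scored[, c("family_id", "member_role", "auc_ord", "scarcity_z")]
  names(d)[2] <- "member"
  fit_stacked_hlm(d, "scarcity_z")$interaction
}
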