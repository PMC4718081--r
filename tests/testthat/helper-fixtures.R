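# Shared fixtures: all built in code, sized for fast tests.

small_cohort_config <- function(seed = 11, ...) {
  cohort_config(group_sizes = c(Normal = 30, MCI = 30, AD = 15),
                seed = seed, ...)
}

# a tiny reference vector on the raw CSF scale
ref_fixture <- c(abeta = 205, tau = 70, ptau = 25)

# Normal-vs-AD feature table where the group signal sits only in chosen
# columns; everything else is seeded noise
signal_feature_cohort <- function(n = 40, signal_cols = "U", sep = 4,
                                  seed = 5) {
  set.seed(seed)
  groups <- rep(c("Normal", "AD"), each = n)
  tbl <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(2 * n)),
    group = factor(groups, levels = c("Normal", "MCI", "AD")),
    month = 12,
    abeta = rnorm(2 * n), tau = rnorm(2 * n), ptau = rnorm(2 * n),
    U = rnorm(2 * n), K = rnorm(2 * n), phi = rnorm(2 * n),
    pf = rnorm(2 * n)
  )
  for (cl in signal_cols) {
    tbl[[cl]] <- tbl[[cl]] + ifelse(groups == "AD", sep, 0)
  }
  tbl
}

# closed-form disruption probability for: static mode, only abeta perturbed
# with lognormal sigma (mean-1 parameterization), subject at the reference,
# rule U > u_max alone
lognormal_u_tail <- function(sigma, u_max) {
  r <- sqrt(u_max)
  mlog <- -sigma^2 / 2
  1 - plnorm(1 + r, mlog, sigma) + plnorm(max(0, 1 - r), mlog, sigma)
}
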