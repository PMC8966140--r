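make_design <- function(n_per_group = 10, groups = c("a", "b"), n_env = 6,
                        effect = 1, sd = 0.1, seed = 1) {
  selfmotion:::with_seed(seed, {
    d <- expand.grid(
      participant_id = paste0("p", seq_len(n_per_group * length(groups))),
      environment = paste0("e", seq_len(n_env)))
    d$group <- rep(rep(groups, each = n_per_group), n_env)
    d$y <- rnorm(nrow(d), 0, sd) +
      effect * (match(d$group, groups) - 1)
    d
  })
}

test_that("mixed ANOVA: degenerate, high-power, and correction behaviour", {
  d0 <- make_design()
  d0$y <- 1
  r0 <- mixed_anova(d0, "y", within = "environment")
  expect_true(all(r0$F == 0))
  expect_true(all(r0$p == 1))

  d <- make_design(effect = 1, sd = 0.1)
  r <- mixed_anova(d, "y", within = "environment")
  expect_lt(r$p[r$factor == "group"], 0.001)
  expect_gt(r$effect_size[r$factor == "group"], 0.9)

  # sphericity-violating covariance with a real within effect (F > 1):
  # shrinking the degrees of freedom can only make the p-value larger
  dv <- make_design(n_per_group = 12, sd = 1, effect = 0, seed = 4)
  base <- selfmotion:::with_seed(5, rnorm(24))
  scale_env <- c(0.2, 0.4, 1, 2, 4, 8)
  env_idx <- match(dv$environment, unique(dv$environment))
  dv$y <- base[match(dv$participant_id, unique(dv$participant_id))] *
    scale_env[env_idx] + 0.8 * env_idx + rnorm(nrow(dv), 0, 0.2)
  always <- mixed_anova(dv, "y", within = "environment",
                        sphericity_alpha = 1)
  never <- mixed_anova(dv, "y", within = "environment",
                       sphericity_alpha = 0)
  fac <- "environment"
  expect_gt(never$F[never$factor == fac], 1)
  expect_gte(always$p[always$factor == fac], never$p[never$factor == fac])
  expect_lt(always$df1[always$factor == fac], never$df1[never$factor == fac])
  expect_true(any(always$gg_applied))
})

test_that("between-groups F matches a from-scratch sums-of-squares oracle", {
  d <- make_design(n_per_group = 6, groups = c("a", "b", "c"), n_env = 4,
                   effect = 0.5, sd = 0.3, seed = 7)
  r <- mixed_anova(d, "y", within = "environment")
  expect_equal(r$F[r$factor == "group"],
               brute_between_F(d, "y", "group", "participant_id"),
               tolerance = 1e-8)
})

test_that("participants with too many missing cells are excluded", {
  d <- make_design()
  d$y[d$participant_id == "p1" & d$environment != "e1"] <- NA
  expect_warning(r <- mixed_anova(d, "y", within = "environment"),
                 "50%")
  expect_true(is.finite(r$F[r$factor == "group"]))
})

test_that("Benjamini-Hochberg adjustment matches the step-up rule", {
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(numeric(0)), "empty")
  for (seed in 1:10) {
    p <- selfmotion:::with_seed(seed, runif(sample(2:20, 1)))
    expect_equal(bh_adjust(p), brute_bh(p))
    expect_true(all(bh_adjust(p) >= p))
  }
})

test_that("pairwise Bonferroni comparisons count pairs and cap at one", {
  d <- make_design(n_per_group = 5,
                   groups = c("g1", "g2", "g3", "g4", "g5"),
                   n_env = 2, effect = 0, sd = 1, seed = 9)
  pw <- pairwise_bonferroni(d, "y")
  expect_equal(nrow(pw), 10 * 2)  # choose(5,2) pairs per environment
  expect_true(all(pw$m == 10))
  expect_equal(pw$p_adj, pmin(1, pw$p * 10))
  expect_gt(min(pw$p_adj), 0.05)  # identical populations: nothing significant

  d2 <- make_design(n_per_group = 8, groups = c("a", "b"), n_env = 2,
                    effect = 3, sd = 0.3, seed = 10)
  pw2 <- pairwise_bonferroni(d2, "y")
  expect_true(all(pw2$p_adj < 0.01))

  d3 <- d2[!(d2$group == "b" & d2$participant_id != "p9"), ]
  w <- capture_warnings(pairwise_bonferroni(d3, "y"))  # one per environment
  expect_true(all(grepl("n < 2", w)) && length(w) >= 1)
})

test_that("grouped ANOVAs share one BH family across measures", {
  d <- make_design(effect = 2, sd = 0.5, seed = 11)
  d$z <- selfmotion:::with_seed(12, rnorm(nrow(d)))
  res <- grouped_anovas(d, c("y", "z"), within = "environment")
  expect_equal(nrow(res), 6)
  expect_equal(res$p_adj, bh_adjust(res$p))
})
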