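test_that("signed-rank test reproduces hand-enumerated cases", {
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))
  expect_equal(r$W, 21)
  expect_equal(r$p_value, 2 / 64)  # all-positive extreme of 2^6 assignments
  r2 <- wilcoxon_signed_rank(c(2, -2))
  expect_equal(r2$W, 1.5)  # midranks under the tie
  expect_equal(r2$p_value, 1)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "degenerate")
})

test_that("exact branch equals independent null-distribution oracles", {
  withr::with_seed(11, {
    for (i in 1:40) {
      n <- sample(2:10, 1)
      d <- sample(c(-4:-1, 1:4), n, replace = TRUE) + round(runif(n), 1)
      d <- d[d != 0]
      if (length(d) == 0) next
      r <- wilcoxon_signed_rank(d)
      expect_equal(r$p_value, signed_rank_null_p(d), tolerance = 1e-12)
    }
    # tie-free inputs also agree with the reference implementation
    for (i in 1:20) {
      n <- sample(4:10, 1)
      d <- sample(seq(0.5, 20, by = 0.5), n) * sample(c(-1, 1), n, TRUE)
      r <- wilcoxon_signed_rank(d)
      ref <- stats::wilcox.test(d, exact = TRUE)
      expect_equal(r$W, unname(ref$statistic))
      expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("large-sample branch matches the tie-corrected normal approximation", {
  withr::with_seed(3, {
    d <- rnorm(40)
    r <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = FALSE, correct = FALSE)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
  })
})

test_that("welch test matches the closed form and degenerate conventions", {
  r <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  # closed form: t = (2 - 5) / sqrt(1/3 + 1/3)
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4, tolerance = 1e-9)
  rid <- welch_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(rid$t, 0)
  expect_equal(rid$p_value, 1)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  # pooled option equals the classic Student test
  a <- c(1.2, 3.4, 2.2, 4.1); b <- c(2.0, 5.5, 4.4)
  expect_equal(welch_t_test(a, b, pooled = TRUE)$p_value,
               stats::t.test(a, b, var.equal = TRUE)$p.value)
})

test_that("alpha summary follows the star conventions", {
  s <- summarize_alpha(c(0.004, 0.04, 0.5, NA))
  expect_equal(s$sig_05, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(s$sig_005, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(s$stars, c("**", "*", "", ""))
  sbh <- summarize_alpha(c(0.01, 0.02, 0.03, 0.04), adjust = "BH")
  expect_equal(sbh$sig_05, rep(TRUE, 4))
})

test_that("enrollment-era split applies the boundary rule", {
  meta <- data.frame(participant_id = c("A", "B", "C", "D"),
                     enrollment_date = c("2023-05-11", "2023-05-12",
                                         "2022-12-01", NA))
  expect_warning(sp <- covid_subgroup_split(meta), "without enrollment date")
  expect_setequal(sp$during, c("A", "C"))  # boundary day belongs to during
  expect_equal(sp$post, "B")
  # all-post cohort leaves the during group empty
  sp2 <- covid_subgroup_split(data.frame(participant_id = "X",
                                         enrollment_date = "2023-06-01"))
  expect_length(sp2$during, 0)
})

test_that("ablation comparisons flag the expected patterns", {
  coh <- generate_cohort(generator_config(n_participants = 8, beta_time = 6,
                                          rho_redundancy = 1, seed = 91))
  g <- ablation_grid(coh, half_times = 15, spatial_methods = "dbscan",
                     families = "lr", seed = 91)
  cmp <- compare_ablations(g)
  expect_s3_class(cmp, "ablation_comparison")
  expect_setequal(unique(cmp$excluded), c("NO_LOCATION", "NO_TIME"))
  nt <- cmp[cmp$excluded == "NO_TIME", ]
  expect_gt(nt$mean_drop, 0.05)
  expect_lt(nt$p_value, 0.05)
  # degenerate identical vectors are reported as NA with a reason
  g2 <- g
  g2$results$mean_score[g2$results$ablation == "NO_LOCATION"] <-
    g2$results$mean_score[g2$results$ablation == "ALL"]
  cmp2 <- compare_ablations(g2)
  expect_true(is.na(cmp2$p_value[cmp2$excluded == "NO_LOCATION"]))
  expect_match(cmp2$note[cmp2$excluded == "NO_LOCATION"], "degenerate")
})

test_that("a perfectly associated feature recovers a unit slope", {
  withr::with_seed(5, {
    n <- 400
    d <- data.frame(participant_id = rep(c("A", "B"), each = n / 2),
                    bin = sample(0:95, n, TRUE), label = 1L)
    d$feature <- rbinom(n, 1, 0.6)  # majority active, so cluster 1 is modal
    # outcome exactly equals the feature: cluster 1 iff feature active
    d$cluster <- d$feature
    fit <- fit_time_location_association(d, "modal_cluster_binary", "smoking")
    expect_lt(abs(fit$estimate - 1), 0.01)
    expect_lt(fit$p_value, 1e-6)
  })
})

test_that("null associations are significant at roughly the nominal rate", {
  hits <- withr::with_seed(29, vapply(1:300, function(i) {
    n <- 120
    d <- data.frame(participant_id = rep(c("A", "B"), each = n / 2),
                    label = 1L,
                    feature = rbinom(n, 1, 0.3),
                    cluster = rbinom(n, 1, 0.5))
    fit <- fit_time_location_association(d, "cluster_numeric", "smoking")
    if (is.data.frame(fit)) fit$p_value < 0.05 else NA
  }, logical(1)))
  rate <- mean(hits, na.rm = TRUE)
  expect_lt(abs(rate - 0.05), 0.04)
})

test_that("single-participant pooled fits reduce to ordinary least squares", {
  withr::with_seed(6, {
    d <- data.frame(participant_id = "A", label = 1L,
                    feature = rbinom(200, 1, 0.5))
    d$cluster <- d$feature + rbinom(200, 1, 0.1)
    fit <- fit_time_location_association(d, "cluster_numeric", "smoking")
    ols <- stats::lm(as.numeric(cluster) ~ feature, data = d)
    expect_equal(fit$estimate, unname(coef(ols)["feature"]), tolerance = 1e-9)
    expect_equal(fit$n_participants, 1L)
  })
})

test_that("support values count co-occurrence as a stratum percentage", {
  expect_equal(association_support(rep(1, 5), rep(1, 5)), 100)
  expect_equal(association_support(rep(0, 5), rep(1, 5)), 0)
  f <- c(1, 1, 1, 1, 0, 0, 0, 0, 1, 0)
  cl <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  expect_equal(association_support(f, cl), 40)
  expect_true(is.na(association_support(numeric(0), numeric(0))))
  # support never exceeds either marginal frequency
  withr::with_seed(10, {
    for (i in 1:50) {
      f <- rbinom(30, 1, runif(1)); cl <- rbinom(30, 1, runif(1))
      s <- association_support(f, cl)
      expect_lte(s, 100 * mean(f))
      expect_lte(s, 100 * mean(cl))
      expect_gte(s, 0)
    }
  })
})

test_that("per-participant mode fits one model per participant", {
  withr::with_seed(13, {
    d <- data.frame(participant_id = rep(c("A", "B", "C"), each = 100),
                    label = 1L, feature = rbinom(300, 1, 0.4))
    d$cluster <- rbinom(300, 1, 0.5)
    fit <- fit_time_location_association(d, "cluster_numeric", "smoking",
                                         pooled = FALSE)
    expect_equal(nrow(fit), 3)
    expect_setequal(fit$participant_id, c("A", "B", "C"))
  })
})
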