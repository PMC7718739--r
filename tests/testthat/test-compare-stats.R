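test_that("stain ratios invert exactly and equal 1 for identical groups", {
  cfg <- reporter_config(fold = 1.3, nucleus_noise_sigma = 0.3,
                         outlier_rate = 0)
  embs <- generate_stain(cfg, c("A", "B"), 4, seed = 51)
  r_ab <- stain_ratio(embs, "B", "A")
  r_ba <- stain_ratio(embs, "A", "B")
  expect_equal(r_ab * r_ba, 1, tolerance = 1e-12)

  # duplicate the A group under a second label: ratio exactly 1
  embs2 <- c(embs[1:4], lapply(embs[1:4], function(e) {
    e$genotype <- "A2"
    e
  }))
  expect_equal(stain_ratio(embs2, "A2", "A"), 1)
})

test_that("hand-built amplitudes 6 and 4 give a peak ratio of 1.5", {
  cfg <- sim_config(
    genotypes = list(P = list(lacZ = list(stripe_spec(6, 0.35, 0.45, 0.01))),
                     Q = list(lacZ = list(stripe_spec(4, 0.35, 0.45, 0.01)))),
    nucleus_noise_sigma = 0, stain_scale_sigma = 0, embryo_scale_sigma = 0,
    outlier_rate = 0, background_frac = 0)
  embs <- c(generate_stain(cfg, "P", 2, seed = 1),
            generate_stain(cfg, "Q", 2, seed = 1))
  expect_equal(stain_ratio(embs, "P", "Q"), 1.5, tolerance = 1e-9)
})

test_that("a stain missing a genotype signals a skip, not an error", {
  cfg <- reporter_config()
  embs <- generate_stain(cfg, "A", 2, seed = 3)
  expect_message(r <- stain_ratio(embs, "B", "A"), "skipping")
  expect_true(is.na(r))
})

test_that("one-sample ratio test matches the textbook formula", {
  r <- c(1.2, 1.3, 1.4, 1.5, 1.6)
  out <- one_sample_ratio_test(r)
  t_hand <- (mean(r) - 1) / (sd(r) / sqrt(5))
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  expect_equal(out$mean, 1.4)

  same <- one_sample_ratio_test(c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  off <- one_sample_ratio_test(c(1.5, 1.5))
  expect_equal(off$p, 0)
  expect_true(off$degenerate)
})

test_that("Welch test matches the hand-computed statistic and df", {
  a <- c(1.2, 1.5, 1.7, 1.1)
  b <- c(1.0, 0.9, 1.05)
  out <- two_sample_ratio_test(a, b)
  va <- var(a) / 4
  vb <- var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / 3 + vb^2 / 2)
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$df, df_hand, tolerance = 1e-12)
  expect_equal(out$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)

  expect_equal(two_sample_ratio_test(a, a)$p, 1)
})

test_that("Mann-Whitney p-values match exhaustive enumeration", {
  set.seed(63)
  for (rep in 1:25) {
    m <- sample(3:8, 1)
    n <- sample(3:8, 1)
    x <- rnorm(m)
    y <- rnorm(n, mean = sample(c(0, 1), 1))
    out <- mann_whitney_u(x, y)
    expect_equal(out$U, mwu_u_stat(x, y))
    expect_equal(out$p, mwu_enum_p(x, y), tolerance = 1e-10)
  }
})

test_that("rank-sum stripe-level test matches enumeration at n = 3 vs 3", {
  x <- c(1.02, 1.10, 0.95)
  y <- c(1.30, 1.25, 1.18)
  out <- stripe_level_test(x, y)
  expect_equal(out$p, mwu_enum_p(x, y), tolerance = 1e-12)
  ident <- stripe_level_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$p, 1, tolerance = 1e-9)
})

test_that("boundary position test applies per-strip tests with Bonferroni", {
  mk_prof <- function(ids, offset = 0, jitter = 0.001) {
    dplyr::bind_rows(lapply(seq_along(ids), function(i) {
      set.seed(1000 + i + round(offset * 1e4))
      tibble::tibble(embryo_id = ids[i], strip = 0:15,
                     position = 0.35 + offset + rnorm(16, 0, jitter))
    }))
  }
  a <- mk_prof(paste0("a", 1:6))
  b_same <- mk_prof(paste0("b", 1:6))
  out <- boundary_position_test(a, b_same)
  expect_equal(out$n_positions, 16L)
  expect_equal(out$per_position$p_bonferroni,
               pmin(1, out$per_position$p_raw * 16))
  expect_gt(out$p_min_adjusted, 0.05)

  b_shift <- mk_prof(paste0("b", 1:6), offset = 0.016)
  out2 <- boundary_position_test(a, b_shift)
  expect_lt(out2$p_min_adjusted, 0.05)

  expect_error(boundary_position_test(a[a$embryo_id %in% c("a1", "a2"), ],
                                      b_same), "3 embryos")
})

test_that("identical groups give raw p-values of 1 at every position", {
  prof <- dplyr::bind_rows(lapply(1:4, function(i) {
    tibble::tibble(embryo_id = paste0("e", i), strip = 0:15,
                   position = 0.3 + i / 100)
  }))
  out <- boundary_position_test(prof, prof)
  expect_true(all(out$per_position$p_raw > 0.99))
})

test_that("the one-sample test on per-stain ratios has power at fold 1.45", {
  # per-stain ratio variability calibrated to the generator's default noise
  set.seed(202)
  rej <- mean(vapply(1:200, function(i) {
    one_sample_ratio_test(rnorm(5, 1.45, 0.17))$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.8)
})

test_that("ratio_analysis aggregates stains and skips incomplete ones", {
  cfg <- reporter_config(fold = 1.5, nucleus_noise_sigma = 0.3,
                         outlier_rate = 0)
  embs <- c(generate_stain(cfg, c("A", "B"), 4, "stain1", seed = 61),
            generate_stain(cfg, c("A", "B"), 4, "stain2", seed = 62),
            generate_stain(cfg, "A", 4, "stain3", seed = 63))
  embs <- normalize_embryos(embs)
  suppressMessages(res <- ratio_analysis(embs, "B", "A"))
  expect_s3_class(res, "ratio_result")
  expect_equal(res$n_stains, 2L)
  expect_equal(res$mean_ratio, mean(res$per_stain$ratio))
  expect_equal(nrow(tidy(res)), 2L)
  expect_equal(glance(res)$p_value, res$p_one_sample)
})
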