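test_that("log-odds entries follow the regularized frequency formula", {
  uni <- pwm_matrix(matrix(5, 4, 3), pseudocount = 1)
  expect_true(all(abs(pwm_logodds(uni)) < 1e-12))

  single <- pwm_matrix(matrix(c(10, 0, 0, 0), 4, 1), pseudocount = 1)
  lo <- pwm_logodds(single)
  expect_equal(unname(lo["A", 1]), log((10.25 / 11) / 0.25))
  expect_equal(unname(lo["C", 1]), log((0.25 / 11) / 0.25))

  # scale invariance in the small-pseudocount limit
  cnt <- matrix(c(8, 1, 2, 4, 3, 3, 6, 1), 4, 2)
  a <- pwm_logodds(pwm_matrix(cnt, pseudocount = 1e-9))
  b <- pwm_logodds(pwm_matrix(cnt * 10, pseudocount = 1e-9))
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("a width-1 score distribution is the four-outcome distribution", {
  pwm <- pwm_matrix(matrix(c(12, 1, 3, 6), 4, 1))
  d <- score_distribution(pwm)
  lo <- sort(unname(pwm_logodds(pwm)[, 1]))
  expect_equal(length(d$score), 4L)
  expect_equal(d$score, round(lo / d$bin_width) * d$bin_width,
               tolerance = 1e-9)
  expect_equal(d$prob, rep(0.25, 4))
})

test_that("DP score distribution equals exhaustive enumeration", {
  set.seed(97)
  for (w in c(2, 4, 6)) {
    cnt <- matrix(rpois(4 * w, 6) + 1, 4, w)
    pwm <- pwm_matrix(cnt)
    d <- score_distribution(pwm)
    expect_equal(sum(d$prob), 1, tolerance = 1e-9)
    enum <- pwm_enum_scores(pwm, d$bin_width)
    # tail probabilities agree exactly at every achievable discretized score
    for (s in sort(unique(enum$score))) {
      expect_equal(score_pvalue(d, s), sum(enum$prob[enum$score >= s - 1e-9]),
                   tolerance = 1e-9)
    }
    # CDF property
    expect_true(all(diff(d$tail) <= 1e-12))
  }
})

test_that("p-value thresholds are minimal and monotone", {
  set.seed(5)
  pwm <- pwm_matrix(matrix(rpois(12, 8) + 1, 4, 3))
  d <- score_distribution(pwm)
  enum <- pwm_enum_scores(pwm, d$bin_width)
  tail_of <- function(s) sum(enum$prob[enum$score >= s - 1e-9])
  # p-values chosen above the probability of the maximal score (1/64)
  for (p in c(0.5, 0.1, 0.02)) {
    s_star <- threshold_for_pvalue(pwm, p, dist = d)
    expect_lte(tail_of(s_star), p)
    # the next discretized score down exceeds p
    lower <- d$score[d$score < s_star - 1e-12]
    if (length(lower) > 0) expect_gt(tail_of(max(lower)), p)
  }
  thr <- vapply(c(0.5, 0.2, 0.05, 0.02),
                function(p) threshold_for_pvalue(pwm, p, dist = d), numeric(1))
  expect_true(all(diff(thr) >= 0))
  expect_warning(threshold_for_pvalue(pwm, 1e-12, dist = d), "maximal")
})

test_that("scanning finds a planted dinucleotide site on both strands", {
  cnt <- matrix(0, 4, 2)
  cnt[1, 1] <- 20  # A
  cnt[2, 2] <- 20  # C
  pwm <- pwm_matrix(cnt, name = "ac")
  hits <- scan_pwm("TTACGT", pwm, p_threshold = 0.07)
  fwd <- hits[hits$strand == "+", ]
  rev <- hits[hits$strand == "-", ]
  # forward AC at 0-based start 2; GT at start 4 reads AC on the reverse strand
  expect_equal(fwd$start, 2L)
  expect_equal(rev$start, 4L)
  expect_equal(fwd$score, rev$score)
})

test_that("scan agrees with naive per-window rescoring on random sequences", {
  set.seed(140)
  for (rep in 1:3) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    cnt <- matrix(rpois(4 * 8, 4) + 1, 4, 8)
    diag_boost <- sample(1:4, 8, TRUE)
    for (j in 1:8) cnt[diag_boost[j], j] <- cnt[diag_boost[j], j] + 25
    pwm <- pwm_matrix(cnt)
    d <- score_distribution(pwm)
    got <- scan_pwm(s, pwm, p_threshold = 0.01, dist = d)
    ref <- naive_scan(s, pwm, d, 0.01)
    expect_equal(nrow(got), nrow(ref))
    expect_equal(got$start, ref$start)
    expect_equal(got$strand, ref$strand)
    expect_equal(got$score, ref$score, tolerance = 1e-9)
  }
})

test_that("hit sets mirror when the sequence is reverse-complemented", {
  set.seed(7)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  cnt <- matrix(rpois(24, 5) + 1, 4, 6)
  cnt[2, ] <- cnt[2, ] + 15
  pwm <- pwm_matrix(cnt)
  h <- scan_pwm(s, pwm, p_threshold = 0.02)
  h_rc <- scan_pwm(reverse_complement(s), pwm, p_threshold = 0.02)
  expect_equal(nrow(h), nrow(h_rc))
  mirrored <- sort(300 - h$end)
  expect_equal(sort(h_rc$start), mirrored)
})

test_that("windows containing N are excluded and short sequences warn", {
  pwm <- pwm_matrix(matrix(c(20, 0, 0, 0, 0, 20, 0, 0), 4, 2), name = "ac")
  h <- scan_pwm("ACNAC", pwm, p_threshold = 0.1)
  expect_true(all(h$start %in% c(0L, 3L)))
  expect_warning(h0 <- scan_pwm("A", pwm, p_threshold = 0.1), "shorter")
  expect_equal(nrow(h0), 0L)
})

test_that("consensus intervals require support from every PWM", {
  h <- function(starts, w = 4) {
    tibble::tibble(pwm_name = "p", start = as.integer(starts),
                   end = as.integer(starts + w), strand = "+",
                   width = as.integer(w), score = 1, p_value = 0.001)
  }
  # identical hit lists: the hits themselves
  same <- consensus_sites(list(h(c(10, 50)), h(c(10, 50))))
  expect_equal(same$start, c(10L, 50L))
  expect_equal(same$end, c(14L, 54L))

  # three lists sharing exactly one overlapping position
  tri <- consensus_sites(list(h(10), h(13), h(11)))
  expect_equal(nrow(tri), 1L)
  expect_equal(tri$start, 13L)
  expect_equal(tri$end, 14L)

  # no common position
  expect_equal(nrow(consensus_sites(list(h(10), h(40)))), 0L)
  expect_error(consensus_sites(list(h(10))), "2 PWMs")
})

test_that("scrubbing removes planted sites minimally and is idempotent", {
  set.seed(33)
  bases <- c("A", "C", "G", "T")
  site <- "TTATGTAACC"
  cons <- strsplit(site, "")[[1]]
  cnt <- matrix(2, 4, 10, dimnames = list(bases, NULL))
  for (j in 1:10) cnt[cons[j], j] <- 40
  pwm <- pwm_matrix(cnt, name = "gt_like")

  clean_bg <- function(n) {
    repeat {
      s <- paste(sample(bases, n, TRUE), collapse = "")
      if (nrow(scan_pwm(s, pwm, 0.003)) == 0) return(s)
    }
  }
  bg <- clean_bg(200)
  planted <- paste0(substr(bg, 1, 80), site, substr(bg, 91, 200))
  scrubbed <- scrub_sites(planted, list(pwm), p_threshold = 0.003)
  expect_equal(nchar(scrubbed), nchar(planted))
  expect_equal(nrow(scan_pwm(as.character(scrubbed), pwm, 0.003)), 0L)
  edits <- attr(scrubbed, "edits")
  # all edits fall inside the planted window (1-based 81..90)
  expect_true(all(edits$position >= 81 & edits$position <= 90))

  rescrub <- scrub_sites(as.character(scrubbed), list(pwm),
                         p_threshold = 0.003)
  expect_equal(as.character(rescrub), as.character(scrubbed))
  expect_equal(nrow(attr(rescrub, "edits")), 0L)

  # a sequence with no hits is returned unchanged
  untouched <- scrub_sites(bg, list(pwm), p_threshold = 0.003)
  expect_equal(as.character(untouched), bg)
})
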