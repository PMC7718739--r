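# Independent oracles used across test files. These deliberately recompute
# quantities by brute force (refits, exhaustive enumeration, naive rescans)
# so that the package's closed-form or incremental implementations are
# checked against a different route to the same number.

# Cook's distance by its leave-one-out definition:
# D_i = sum_j (yhat_j - yhat_j(i))^2 / (p * s^2), p = 2 coefficients,
# s^2 = full-model residual mean square.
cooks_loo_oracle <- function(x, y) {
  fit <- stats::lm(y ~ x)
  yhat <- stats::fitted(fit)
  p <- 2
  s2 <- sum(stats::residuals(fit)^2) / (length(x) - p)
  vapply(seq_along(x), function(i) {
    f2 <- stats::lm(y[-i] ~ x[-i])
    yhat_i <- stats::coef(f2)[1] + stats::coef(f2)[2] * x
    sum((yhat - yhat_i)^2) / (p * s2)
  }, numeric(1))
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# choose(m+n, m) group assignments of the observed values (permutation
# null); U counts pairwise wins with ties as 1/2.
mwu_u_stat <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}
mwu_enum_p <- function(x, y) {
  m <- length(x)
  vals <- c(x, y)
  u_obs <- mwu_u_stat(x, y)
  mu <- m * length(y) / 2
  combs <- utils::combn(length(vals), m)
  us <- apply(combs, 2, function(ix) mwu_u_stat(vals[ix], vals[-ix]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# All 4^w sequences of a PWM's width, scored with the per-column
# bin-rounded log-odds (same discretization as the DP), weighted by the
# background model: exact reference for tail probabilities.
pwm_enum_scores <- function(pwm, bin_width = 1e-3) {
  M <- round(pwm_logodds(pwm) / bin_width) * bin_width
  w <- ncol(M)
  grids <- rep(list(1:4), w)
  codes <- as.matrix(expand.grid(grids))
  sc <- rowSums(vapply(seq_len(w), function(j) M[codes[, j], j],
                       numeric(nrow(codes))))
  pr <- apply(codes, 1, function(cd) prod(pwm$background[cd]))
  list(score = sc, prob = pr)
}

# Naive per-window rescoring of a sequence on both strands, selecting
# windows whose tail p-value under `dist` is at most `p`.
naive_scan <- function(sequence, pwm, dist, p) {
  M <- pwm_logodds(pwm)
  Mb <- dist$logodds_binned
  w <- ncol(M)
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars) - w + 1
  rows <- list()
  for (i in seq_len(max(n, 0))) {
    win <- chars[i:(i + w - 1)]
    cf <- cbind(match(win, c("A", "C", "G", "T")), seq_len(w))
    rc <- rev(c(A = "T", C = "G", G = "C", T = "A")[win])
    cr <- cbind(match(rc, c("A", "C", "G", "T")), seq_len(w))
    sf <- sum(M[cf])
    sr <- sum(M[cr])
    if (!is.na(sf) && score_pvalue(dist, sum(Mb[cf])) <= p) {
      rows[[length(rows) + 1]] <- data.frame(start = i - 1L, strand = "+",
                                             score = sf)
    }
    if (!is.na(sr) && score_pvalue(dist, sum(Mb[cr])) <= p) {
      rows[[length(rows) + 1]] <- data.frame(start = i - 1L, strand = "-",
                                             score = sr)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(start = integer(), strand = character(),
                      score = numeric()))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# Hand-built embryo with explicit axis coordinates (bypasses the PCA
# derivation so strip/bin assignment can be dictated by the test).
make_flat_embryo <- function(ap, dv, channels, embryo_id = "hand",
                             genotype = "G", stain_id = "s1") {
  n <- length(ap)
  nuc <- tibble::tibble(nucleus_id = seq_len(n),
                        x = ap * 400, y = cos(dv), z = sin(dv),
                        ap_fraction = ap, dv_angle = dv)
  for (ch in names(channels)) nuc[[ch]] <- channels[[ch]]
  embryo(nuc, embryo_id = embryo_id, genotype = genotype, stain_id = stain_id)
}

# Embryo whose channels are constant; its q99/q95 quantiles equal the
# constants, which makes regression fixtures exact.
make_const_embryo <- function(lacz, hkb, embryo_id, genotype = "G",
                              stain_id = "s1", n = 40, seed = 1) {
  set.seed(seed)
  ap <- c(0, 1, runif(n - 2))
  dv <- runif(n, 0, 2 * pi - 1e-9)
  make_flat_embryo(ap, dv, list(lacZ = rep(lacz, n), hkb = rep(hkb, n)),
                   embryo_id = embryo_id, genotype = genotype,
                   stain_id = stain_id)
}

# Logistic-product stripe profile evaluated at the 100 bin centers.
stripe_profile_vec <- function(amplitude, anterior, posterior, k) {
  ap <- (0:99 + 0.5) / 100
  amplitude * stats::plogis((ap - anterior) / k) *
    stats::plogis((posterior - ap) / k)
}
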