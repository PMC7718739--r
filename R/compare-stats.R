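#' Peak-ratio between two genotypes within one stain
#'
#' Expression levels are only comparable between embryos stained in the same
#' in situ hybridization batch, so fold changes are estimated stain by
#' stain: within one stain, the group-average trace of each genotype is
#' computed (embryos should already be normalized and QC-passed) and the
#' ratio of the two peak levels inside the stripe window is returned.
#'
#' @param stain_embryos list of [embryo] objects from one stain containing
#'   both genotypes.
#' @param genotype_num,genotype_den numerator / denominator genotype labels.
#' @param reporter reporter channel (default `"lacZ"`).
#' @param window stripe search window (default 0.30-0.55 EL).
#' @param strips lateral strip sets.
#' @return Scalar ratio, or `NA` with a message if either genotype is
#'   absent from the stain (the stain is then skipped upstream).
#' @export
stain_ratio <- function(stain_embryos, genotype_num, genotype_den,
                        reporter = "lacZ", window = c(0.30, 0.55),
                        strips = lateral_strips_default()) {
  genos <- vapply(stain_embryos, `[[`, character(1), "genotype")
  if (!genotype_num %in% genos || !genotype_den %in% genos) {
    message("stain lacks genotype ",
            setdiff(c(genotype_num, genotype_den), genos)[1], "; skipping")
    return(NA_real_)
  }
  pk <- function(g) {
    tr <- group_average_trace(stain_embryos[genos == g], reporter, strips)
    peak_level(tr, window = window)$level
  }
  pk(genotype_num) / pk(genotype_den)
}

#' One-sample t-test of per-stain ratios against 1
#'
#' Tests whether the mean of the per-stain fold-change ratios differs from
#' `mu` (default 1, i.e. no expression difference between genotypes).
#' Two-sided by default; pass `alternative` for directional hypotheses.
#' Zero-variance input cannot support a t-test: the p-value is reported at
#' its exact limit (1 when the common value equals `mu`, 0 otherwise) with
#' `degenerate = TRUE`.
#'
#' @param ratios numeric vector of per-stain ratios (length >= 2).
#' @param mu null value (default 1).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return Named list `mean`, `t`, `df`, `p`, `n`, `degenerate`.
#' @export
one_sample_ratio_test <- function(ratios, mu = 1,
                                  alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) < 2) stop("need at least 2 ratios", call. = FALSE)
  if (stats::sd(ratios) == 0) {
    at_null <- isTRUE(all.equal(mean(ratios), mu))
    return(list(mean = mean(ratios), t = if (at_null) 0 else Inf,
                df = length(ratios) - 1, p = if (at_null) 1 else 0,
                n = length(ratios), degenerate = TRUE))
  }
  tt <- stats::t.test(ratios, mu = mu, alternative = alternative)
  list(mean = mean(ratios), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, n = length(ratios),
       degenerate = FALSE)
}

#' Welch two-sample t-test between two sets of ratios
#'
#' Compares two fold-change estimates (e.g. the deletion effect in a minimal
#' versus an extended construct) with a two-sample t-test with unequal
#' variances (Welch-Satterthwaite degrees of freedom).
#'
#' @param ratios_a,ratios_b numeric vectors (each length >= 2).
#' @param alternative `"two.sided"` (default), `"greater"` (a > b), or
#'   `"less"`.
#' @return Named list `t`, `df`, `p`, `mean_a`, `mean_b`, `degenerate`.
#' @export
two_sample_ratio_test <- function(ratios_a, ratios_b,
                                  alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  ratios_a <- ratios_a[!is.na(ratios_a)]
  ratios_b <- ratios_b[!is.na(ratios_b)]
  if (length(ratios_a) < 2 || length(ratios_b) < 2) {
    stop("need at least 2 ratios per group", call. = FALSE)
  }
  if (stats::sd(ratios_a) == 0 && stats::sd(ratios_b) == 0) {
    same <- isTRUE(all.equal(mean(ratios_a), mean(ratios_b)))
    return(list(t = if (same) 0 else Inf * sign(mean(ratios_a) - mean(ratios_b)),
                df = NA_real_, p = if (same) 1 else 0,
                mean_a = mean(ratios_a), mean_b = mean(ratios_b),
                degenerate = TRUE))
  }
  tt <- stats::t.test(ratios_a, ratios_b, var.equal = FALSE,
                      alternative = alternative)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_a = mean(ratios_a), mean_b = mean(ratios_b), degenerate = FALSE)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. The U statistic is the number of
#' (a, b) pairs with a > b, counting ties as 1/2. The p-value comes from
#' [stats::wilcox.test()]: exact when both groups have at most 8
#' observations and there are no ties, the tie-corrected normal
#' approximation with continuity correction otherwise — reproducible at the
#' group sizes these comparisons use.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return Named list `U`, `p`, `exact`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 8 && length(y) <= 8 && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Boundary-position comparison between genotypes
#'
#' Compares stripe boundary positions between two genotypes at each of the
#' 16 DV positions (8 per lateral side): at every strip, a Mann-Whitney U
#' test on the per-embryo boundary positions, with Bonferroni correction
#' over the number of positions tested. The minimum adjusted p-value
#' summarizes the genotype effect.
#'
#' @param profiles_a,profiles_b tibbles with columns `embryo_id`, `strip`,
#'   `position` — one row per embryo x strip, as from stacking
#'   [dv_boundary_profile()] results (see [boundary_profiles()]). Each group
#'   needs at least 3 embryos.
#' @return List with `per_position` (tibble: `strip`, `n_a`, `n_b`, `U`,
#'   `p_raw`, `p_bonferroni`), `p_min_adjusted`, `n_positions`.
#' @export
boundary_position_test <- function(profiles_a, profiles_b) {
  n_a <- length(unique(profiles_a$embryo_id))
  n_b <- length(unique(profiles_b$embryo_id))
  if (n_a < 3 || n_b < 3) {
    stop("sample-size error: need at least 3 embryos per group", call. = FALSE)
  }
  strips <- sort(unique(c(profiles_a$strip, profiles_b$strip)))
  rows <- lapply(strips, function(s) {
    xa <- profiles_a$position[profiles_a$strip == s]
    xb <- profiles_b$position[profiles_b$strip == s]
    xa <- xa[!is.na(xa)]
    xb <- xb[!is.na(xb)]
    if (length(xa) < 2 || length(xb) < 2) {
      return(tibble::tibble(strip = s, n_a = length(xa), n_b = length(xb),
                            U = NA_real_, p_raw = NA_real_))
    }
    mw <- mann_whitney_u(xa, xb)
    tibble::tibble(strip = s, n_a = length(xa), n_b = length(xb),
                   U = mw$U, p_raw = mw$p)
  })
  per <- dplyr::bind_rows(rows)
  m <- sum(!is.na(per$p_raw))
  per$p_bonferroni <- pmin(1, per$p_raw * m)
  list(per_position = per,
       p_min_adjusted = min(per$p_bonferroni, na.rm = TRUE),
       n_positions = m)
}

#' Collect per-embryo DV boundary profiles
#'
#' Runs [extract_pattern()] + [dv_boundary_profile()] for each embryo and
#' stacks the results with embryo ids, in the shape
#' [boundary_position_test()] consumes.
#'
#' @param embryos list of [embryo] objects.
#' @param channel expression channel.
#' @param which `"anterior"` or `"posterior"`.
#' @param window stripe AP search window.
#' @return Tibble with columns `embryo_id`, `strip`, `side`, `position`.
#' @export
boundary_profiles <- function(embryos, channel, which = "anterior",
                              window = c(0.30, 0.55)) {
  dplyr::bind_rows(lapply(embryos, function(e) {
    prof <- dv_boundary_profile(extract_pattern(e, channel), which = which,
                                window = window)
    prof$embryo_id <- e$embryo_id
    prof[c("embryo_id", "strip", "side", "position")]
  }))
}

#' Rank-sum test of stripe levels between conditions
#'
#' Two-sided rank-sum (Mann-Whitney) comparison of per-embryo stripe levels
#' (typically stripe-1-normalized peaks) between two conditions.
#'
#' @param levels_a,levels_b numeric vectors of per-embryo levels.
#' @return Named list `U`, `p`, `exact`.
#' @export
stripe_level_test <- function(levels_a, levels_b) {
  mann_whitney_u(levels_a, levels_b, alternative = "two.sided")
}

#' Per-stain fold-change analysis between two genotypes
#'
#' The full ratio pipeline for one genotype pair: for each stain that
#' contains both genotypes, compute the [stain_ratio()]; then test the mean
#' ratio against 1 with [one_sample_ratio_test()]. Stains missing a genotype
#' are skipped and `n_stains` counts usable stains only. Embryos are assumed
#' normalized and QC-filtered.
#'
#' @param embryos list of [embryo] objects across stains.
#' @param genotype_num,genotype_den numerator / denominator genotypes.
#' @param reporter reporter channel.
#' @param window stripe search window.
#' @param alternative sidedness of the one-sample test.
#' @param strips lateral strip sets.
#' @return An object of class `ratio_result`: list with `genotype_num`,
#'   `genotype_den`, `per_stain` (tibble `stain_id`, `ratio`), `mean_ratio`,
#'   `t_stat`, `df`, `p_one_sample`, `n_stains`, `alternative`.
#' @export
ratio_analysis <- function(embryos, genotype_num, genotype_den,
                           reporter = "lacZ", window = c(0.30, 0.55),
                           alternative = "two.sided",
                           strips = lateral_strips_default()) {
  stains <- vapply(embryos, `[[`, character(1), "stain_id")
  per <- dplyr::bind_rows(lapply(unique(stains), function(s) {
    r <- stain_ratio(embryos[stains == s], genotype_num, genotype_den,
                     reporter = reporter, window = window, strips = strips)
    tibble::tibble(stain_id = s, ratio = r)
  }))
  per <- per[!is.na(per$ratio), ]
  if (nrow(per) < 2) {
    stop("fewer than 2 usable stains for ", genotype_num, "/", genotype_den,
         call. = FALSE)
  }
  tst <- one_sample_ratio_test(per$ratio, mu = 1, alternative = alternative)
  structure(list(genotype_num = genotype_num, genotype_den = genotype_den,
                 per_stain = per, mean_ratio = tst$mean, t_stat = tst$t,
                 df = tst$df, p_one_sample = tst$p, n_stains = nrow(per),
                 alternative = alternative, degenerate = tst$degenerate),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("<ratio_result %s / %s>\n", x$genotype_num, x$genotype_den))
  cat(sprintf("  mean ratio %.3f over %d stains; t = %.3f, p = %.4g (%s)\n",
              x$mean_ratio, x$n_stains, x$t_stat, x$p_one_sample,
              x$alternative))
  invisible(x)
}
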