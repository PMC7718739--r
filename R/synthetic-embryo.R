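#' Specification of one expression stripe
#'
#' Ground-truth description of a single stripe along the AP axis. The
#' expression profile is a product of two logistic flanks,
#' `amplitude * plogis((ap - anterior)/k) * plogis((posterior - ap)/k)`,
#' so the anterior and posterior inflection points of the profile are
#' analytically the boundary parameters whenever the flanks are well
#' separated (`posterior - anterior >> k`). This makes boundary-calling
#' accuracy directly checkable against the generating values.
#'
#' @param amplitude peak expression in arbitrary fluorescence units (>= 0).
#' @param anterior,posterior boundary positions in fraction of egg length,
#'   `0 < anterior < posterior < 1`.
#' @param flank_scale logistic steepness `k` in fraction EL (> 0); the flank
#'   rises over roughly `4 * k`.
#' @param dv_modulation optional function of dv_angle returning a
#'   multiplicative amplitude factor (default constant 1).
#' @param dv_shift optional function of dv_angle returning a positional
#'   offset (fraction EL) added to both boundaries, to model stripes whose
#'   edges tilt around the DV circumference.
#' @return An object of class `stripe_spec`.
#' @export
stripe_spec <- function(amplitude, anterior, posterior, flank_scale = 0.01,
                        dv_modulation = NULL, dv_shift = NULL) {
  if (!(anterior > 0 && anterior < posterior && posterior < 1)) {
    stop("require 0 < anterior < posterior < 1", call. = FALSE)
  }
  if (flank_scale <= 0) stop("flank_scale must be > 0", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  structure(list(amplitude = amplitude, anterior = anterior,
                 posterior = posterior, flank_scale = flank_scale,
                 dv_modulation = dv_modulation, dv_shift = dv_shift),
            class = "stripe_spec")
}

#' Simulation configuration for synthetic blastoderm embryos
#'
#' Defines the study conditions the generator emulates: ~6000 nuclei on the
#' surface of a prolate ellipsoid (a late-blastoderm embryo), per-channel
#' stripe patterns with logistic flanks, a posterior hkb-like domain used by
#' co-stain normalization, a per-stain multiplicative staining factor shared
#' by all channels of the embryos in a stain, small per-embryo staining
#' jitter, additive per-nucleus noise, and occasional outlier embryos in
#' which one channel's staining scale is aberrant and independent.
#'
#' @param genotypes named list: for each genotype label, a named list mapping
#'   channel name to a list of [stripe_spec]s (one or several stripes).
#' @param n_nuclei nuclei per embryo (default 6000).
#' @param ellipsoid_semiaxes semi-axes (a, b, c) in micrometres, AP axis
#'   first (default 250, 110, 90).
#' @param hkb_onset,hkb_amplitude,hkb_flank_scale posterior normalization
#'   domain: `hkb_amplitude * plogis((ap - hkb_onset)/hkb_flank_scale)`,
#'   default onset 0.85 EL so the posterior 10% window is well populated.
#' @param background_frac constant background level as a fraction of the
#'   channel's maximum stripe amplitude (default 0.05).
#' @param stain_scale_sigma log-normal sigma of the per-stain staining
#'   factor (default 0.3).
#' @param embryo_scale_sigma log-normal sigma of per-embryo jitter around
#'   the stain factor, shared by all channels of the embryo (default 0.1).
#' @param nucleus_noise_sigma additive Gaussian noise per nucleus, in
#'   expression units (default 0.5).
#' @param outlier_rate probability that an embryo's first channel gets an
#'   independent aberrant staining factor (default 0.1).
#' @param seed integer default seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genotypes,
                       n_nuclei = 6000,
                       ellipsoid_semiaxes = c(250, 110, 90),
                       hkb_onset = 0.85, hkb_amplitude = 10,
                       hkb_flank_scale = 0.02,
                       background_frac = 0.05,
                       stain_scale_sigma = 0.3,
                       embryo_scale_sigma = 0.1,
                       nucleus_noise_sigma = 0.5,
                       outlier_rate = 0.1,
                       seed = 1L) {
  stopifnot(stain_scale_sigma >= 0, embryo_scale_sigma >= 0,
            nucleus_noise_sigma >= 0,
            outlier_rate >= 0, outlier_rate <= 1,
            length(ellipsoid_semiaxes) == 3, all(ellipsoid_semiaxes > 0))
  if (!is.list(genotypes) || is.null(names(genotypes))) {
    stop("genotypes must be a named list", call. = FALSE)
  }
  structure(list(genotypes = genotypes, n_nuclei = as.integer(n_nuclei),
                 ellipsoid_semiaxes = ellipsoid_semiaxes,
                 hkb_onset = hkb_onset, hkb_amplitude = hkb_amplitude,
                 hkb_flank_scale = hkb_flank_scale,
                 background_frac = background_frac,
                 stain_scale_sigma = stain_scale_sigma,
                 embryo_scale_sigma = embryo_scale_sigma,
                 nucleus_noise_sigma = nucleus_noise_sigma,
                 outlier_rate = outlier_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Two-genotype single-stripe reporter configuration
#'
#' Convenience constructor for the reporter-construct comparison: two
#' genotypes carrying a lacZ stripe with the same boundaries, the second at
#' `fold` times the amplitude of the first, plus the hkb normalization
#' domain. Defaults place the stripe at 0.35-0.45 EL with steep flanks
#' (`k = 0.01`), amplitude 10.
#'
#' @param fold amplitude ratio genotype B / genotype A (default 1).
#' @param anterior_b,posterior_b boundary positions for genotype B,
#'   defaulting to genotype A's (0.35, 0.45); offset them to simulate
#'   boundary shifts.
#' @param amplitude genotype A peak amplitude (default 10).
#' @param anterior,posterior,flank_scale genotype A stripe geometry.
#' @param names genotype labels (default "A", "B").
#' @param ... passed to [sim_config()].
#' @return A [sim_config].
#' @export
reporter_config <- function(fold = 1, anterior = 0.35, posterior = 0.45,
                            anterior_b = anterior, posterior_b = posterior,
                            amplitude = 10, flank_scale = 0.01,
                            names = c("A", "B"), ...) {
  g <- stats::setNames(list(
    list(lacZ = list(stripe_spec(amplitude, anterior, posterior, flank_scale))),
    list(lacZ = list(stripe_spec(amplitude * fold, anterior_b, posterior_b,
                                 flank_scale)))
  ), names)
  sim_config(genotypes = g, ...)
}

#' Seven-stripe pair-rule configuration
#'
#' Convenience constructor for the endogenous-locus comparison: each
#' genotype's "eve" channel carries seven stripes with centers evenly spaced
#' from 0.33 to 0.81 EL (width 0.04 EL, `k = 0.008`). `stripe2_fold` scales
#' stripe 2's amplitude in the second genotype; `stripe2_shift` offsets its
#' boundaries.
#'
#' @param stripe2_fold amplitude multiplier on stripe 2 of genotype B.
#' @param stripe2_shift positional offset (fraction EL) of genotype B's
#'   stripe-2 boundaries.
#' @param amplitudes 7 amplitudes (default all 10).
#' @param names genotype labels.
#' @param ... passed to [sim_config()].
#' @return A [sim_config].
#' @export
eve_config <- function(stripe2_fold = 1, stripe2_shift = 0,
                       amplitudes = rep(10, 7),
                       names = c("WT", "mut"), ...) {
  centers <- 0.33 + 0.08 * (0:6)
  mk <- function(fold2, shift2) {
    lapply(1:7, function(i) {
      sh <- if (i == 2) shift2 else 0
      amp <- if (i == 2) amplitudes[i] * fold2 else amplitudes[i]
      stripe_spec(amp, centers[i] - 0.02 + sh, centers[i] + 0.02 + sh,
                  flank_scale = 0.008)
    })
  }
  g <- stats::setNames(list(list(eve = mk(1, 0)),
                            list(eve = mk(stripe2_fold, stripe2_shift))),
                       names)
  sim_config(genotypes = g, ...)
}

# deterministic quasi-uniform points on the unit sphere (Fibonacci lattice),
# polar axis along x so AP coverage is even; cached per n
.stripequant_cache <- new.env(parent = emptyenv())
fibonacci_sphere <- function(n) {
  key <- as.character(n)
  if (!is.null(.stripequant_cache[[key]])) return(.stripequant_cache[[key]])
  i <- seq_len(n) - 0.5
  x <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - x^2))
  phi <- pi * (1 + sqrt(5)) * (seq_len(n) - 1)
  pts <- cbind(x = x, y = r * cos(phi), z = r * sin(phi))
  .stripequant_cache[[key]] <- pts
  pts
}

stripe_profile <- function(spec, ap, dv) {
  a <- spec$anterior
  p <- spec$posterior
  if (!is.null(spec$dv_shift)) {
    sh <- spec$dv_shift(dv)
    a <- a + sh
    p <- p + sh
  }
  v <- spec$amplitude * stats::plogis((ap - a) / spec$flank_scale) *
    stats::plogis((p - ap) / spec$flank_scale)
  if (!is.null(spec$dv_modulation)) v <- v * spec$dv_modulation(dv)
  v
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

#' Generate one synthetic embryo
#'
#' Places `n_nuclei` quasi-uniformly on the ellipsoid surface (Fibonacci
#' lattice), evaluates each channel's stripe profile at each nucleus, and
#' applies the staining model: channel value = staining factor x profile +
#' background + Gaussian noise, truncated at 0. The same staining factor is
#' shared by all channels of the embryo unless the embryo is an outlier, in
#' which case the first channel gets an independent aberrant factor
#' (uniform in [2, 3], inverted with probability 1/2) — mimicking embryos
#' whose reporter stain failed or saturated, which QC should flag.
#' Identical `(config, genotype, seed)` give bit-identical embryos.
#'
#' @param config a [sim_config]; `config$genotypes` must contain `genotype`.
#' @param genotype genotype label to simulate.
#' @param stain_id stain label to record.
#' @param seed integer seed for this embryo.
#' @param stain_factor staining factor shared with the rest of the stain
#'   (default 1; [generate_stain()] draws it).
#' @param embryo_id id to record (default derived from seed).
#' @return An [embryo]; the generating truth (stripe specs, applied factors,
#'   outlier flag) is attached as attribute `"truth"`.
#' @export
generate_embryo <- function(config, genotype, stain_id = "stain1",
                            seed = config$seed, stain_factor = 1,
                            embryo_id = paste0("sim", seed)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_nuclei < 100) {
    stop("n_nuclei < 100: AP traces are undefined at this density", call. = FALSE)
  }
  spec_set <- config$genotypes[[genotype]]
  if (is.null(spec_set)) stop("unknown genotype: ", genotype, call. = FALSE)
  with_seed(seed, {
    pts <- fibonacci_sphere(config$n_nuclei)
    ax <- config$ellipsoid_semiaxes
    xyz <- sweep(pts, 2, ax, `*`)
    ap <- (pts[, 1] + 1) / 2               # exact AP fraction on the lattice
    # dv angle with ventral (-y) at 0, matching derive_axes' convention;
    # computed on the scaled coordinates so it equals the derived angle
    dv <- atan2(-xyz[, 3], -xyz[, 2]) %% (2 * pi)

    emb_factor <- stain_factor *
      exp(stats::rnorm(1, 0, config$embryo_scale_sigma))
    is_outlier <- stats::runif(1) < config$outlier_rate
    aberrant <- if (is_outlier) {
      f <- stats::runif(1, 2, 3)
      if (stats::runif(1) < 0.5) 1 / f else f
    } else NA_real_

    chans <- list()
    chan_names <- unique(c(names(spec_set), "hkb"))
    factors <- stats::setNames(rep(emb_factor, length(chan_names)), chan_names)
    if (is_outlier) factors[[1]] <- aberrant
    for (ch in chan_names) {
      if (ch == "hkb" && is.null(spec_set[["hkb"]])) {
        profile <- config$hkb_amplitude *
          stats::plogis((ap - config$hkb_onset) / config$hkb_flank_scale)
        amp_max <- config$hkb_amplitude
      } else {
        specs <- spec_set[[ch]]
        profile <- Reduce(`+`, lapply(specs, stripe_profile, ap = ap, dv = dv))
        amp_max <- max(vapply(specs, function(s) s$amplitude, numeric(1)))
      }
      # nonspecific background scales with staining efficiency like the
      # signal does, so it sits inside the staining factor
      bg <- config$background_frac * amp_max
      noise <- if (config$nucleus_noise_sigma > 0) {
        stats::rnorm(length(ap), 0, config$nucleus_noise_sigma)
      } else 0
      chans[[ch]] <- pmax(0, factors[[ch]] * (profile + bg) + noise)
    }

    nuclei <- tibble::new_tibble(
      c(list(nucleus_id = seq_len(config$n_nuclei),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
        chans[chan_names]),
      nrow = config$n_nuclei)
    emb <- embryo(nuclei, embryo_id = embryo_id, genotype = genotype,
                  stain_id = stain_id, stage_pct = 7)
    attr(emb, "truth") <- list(specs = spec_set, stain_factor = stain_factor,
                               embryo_factor = emb_factor,
                               outlier = is_outlier,
                               aberrant_factor = aberrant,
                               factors = factors)
    emb
  })
}

#' Generate all embryos of one in situ hybridization batch
#'
#' Draws one staining factor for the whole stain (log-normal with sigma
#' `stain_scale_sigma`) and generates `n_per_genotype` embryos for each
#' requested genotype, all sharing that factor before per-embryo jitter.
#' Embryo seeds are derived deterministically from `seed`.
#'
#' @param config a [sim_config].
#' @param genotypes character vector of genotype labels (must be non-empty
#'   and present in `config$genotypes`).
#' @param n_per_genotype embryos per genotype.
#' @param stain_id stain label.
#' @param seed integer seed for the stain.
#' @return List of [embryo] objects, each carrying its `"truth"` attribute.
#' @export
generate_stain <- function(config, genotypes, n_per_genotype,
                           stain_id = "stain1", seed = config$seed) {
  if (length(genotypes) == 0) stop("genotypes must be non-empty", call. = FALSE)
  stain_factor <- with_seed(seed, exp(stats::rnorm(1, 0, config$stain_scale_sigma)))
  embryos <- list()
  k <- 0
  for (g in genotypes) {
    for (i in seq_len(n_per_genotype)) {
      k <- k + 1
      embryos[[k]] <- generate_embryo(
        config, g, stain_id = stain_id,
        seed = (seed * 1000L + k) %% .Machine$integer.max,
        stain_factor = stain_factor,
        embryo_id = sprintf("%s_%s_%02d", stain_id, g, i)
      )
    }
  }
  embryos
}

#' Ground truth of a generated embryo
#'
#' @param embryo an embryo from [generate_embryo()].
#' @return The truth list (specs, factors, outlier flag).
#' @export
embryo_truth <- function(embryo) attr(embryo, "truth")
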