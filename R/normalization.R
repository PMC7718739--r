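#' Co-stain normalization scale of an embryo
#'
#' Staining intensity varies between embryos and batches, so reporter levels
#' are made comparable by dividing by the level of a co-stained gene with a
#' stereotyped domain: the 95% quantile of `hkb` expression among nuclei in
#' the posterior 10% of the embryo (`ap_fraction > 0.9`). Quantiles use
#' linear interpolation between order statistics ([stats::quantile()] type
#' 7); this choice is pinned for reproducibility.
#'
#' @param embryo an [embryo] with an `hkb` channel (name configurable).
#' @param channel normalization channel name (default `"hkb"`).
#' @param probs quantile level (default 0.95).
#' @param window posterior AP window, strictly greater than this fraction
#'   (default 0.9).
#' @return Positive scalar scale.
#' @export
hkb_scale <- function(embryo, channel = "hkb", probs = 0.95, window = 0.9) {
  stopifnot(inherits(embryo, "embryo"))
  if (!channel %in% channels(embryo)) {
    stop("embryo has no '", channel, "' channel", call. = FALSE)
  }
  post <- embryo$nuclei$ap_fraction > window
  if (sum(post) < 20) {
    stop("data error: fewer than 20 nuclei posterior of ap_fraction = ",
         window, call. = FALSE)
  }
  s <- unname(stats::quantile(embryo$nuclei[[channel]][post], probs, type = 7))
  if (s <= 0) {
    stop("degenerate-stain error: normalization scale is 0", call. = FALSE)
  }
  s
}

#' Divide one channel of an embryo by a scale
#'
#' @param embryo an [embryo].
#' @param channel channel to normalize.
#' @param scale positive scalar, typically from [hkb_scale()].
#' @return The embryo with `channel` divided by `scale`; other channels
#'   untouched.
#' @export
normalize_channel <- function(embryo, channel, scale) {
  stopifnot(inherits(embryo, "embryo"))
  if (!channel %in% channels(embryo)) {
    stop("unknown channel: ", channel, call. = FALSE)
  }
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    stop("scale must be a positive scalar", call. = FALSE)
  }
  embryo$nuclei[[channel]] <- embryo$nuclei[[channel]] / scale
  embryo
}

#' Normalize the reporter channel of every embryo by its co-stain
#'
#' Convenience wrapper applying [normalize_channel()] with each embryo's own
#' [hkb_scale()].
#'
#' @param embryos list of [embryo] objects.
#' @param reporter reporter channel (default `"lacZ"`).
#' @param channel co-stain channel (default `"hkb"`).
#' @return List of normalized embryos.
#' @export
normalize_embryos <- function(embryos, reporter = "lacZ", channel = "hkb") {
  lapply(embryos, function(e) {
    normalize_channel(e, reporter, hkb_scale(e, channel = channel))
  })
}

#' Flag outlier embryos by Cook's distance
#'
#' Within a group of embryos that share a stain and genetic background the
#' reporter and co-stain intensities should be correlated; embryos that do
#' not fit this relationship (failed or aberrant stains) are flagged. Fits
#' an ordinary least-squares regression of the 99% quantile of the reporter
#' on the 95% quantile of the co-stain (both over all nuclei of the embryo),
#' computes Cook's distance for each embryo, and flags embryos whose
#' distance exceeds the threshold (default `4/n`, the common convention; the
#' source analyses report only that a sizeable fraction of embryos is
#' discarded, not a cutoff, so the threshold is exposed).
#'
#' Groups of fewer than 4 embryos cannot support outlier detection: records
#' are returned with `flagged = FALSE` and a warning.
#'
#' @param stain_group list of [embryo] objects sharing `stain_id` and
#'   genotype.
#' @param reporter reporter channel (default `"lacZ"`).
#' @param channel co-stain channel (default `"hkb"`).
#' @param threshold Cook's distance cutoff; default `4 / n`.
#' @return Tibble with columns `embryo_id`, `genotype`, `stain_id`,
#'   `q99_reporter`, `q95_costain`, `cooks_d`, `flagged`.
#' @export
qc_regression <- function(stain_group, reporter = "lacZ", channel = "hkb",
                          threshold = NULL) {
  stopifnot(length(stain_group) >= 1)
  if (length(unique(vapply(stain_group, `[[`, character(1), "stain_id"))) > 1 ||
      length(unique(vapply(stain_group, `[[`, character(1), "genotype"))) > 1) {
    stop("qc_regression operates within one stain and one genotype; ",
         "split the embryos first", call. = FALSE)
  }
  rec <- tibble::tibble(
    embryo_id = vapply(stain_group, `[[`, character(1), "embryo_id"),
    genotype = vapply(stain_group, `[[`, character(1), "genotype"),
    stain_id = vapply(stain_group, `[[`, character(1), "stain_id"),
    q99_reporter = vapply(stain_group, function(e) {
      unname(stats::quantile(e$nuclei[[reporter]], 0.99, type = 7))
    }, numeric(1)),
    q95_costain = vapply(stain_group, function(e) {
      unname(stats::quantile(e$nuclei[[channel]], 0.95, type = 7))
    }, numeric(1))
  )
  n <- nrow(rec)
  if (n < 4) {
    warning("fewer than 4 embryos in the stain group; not flagging outliers")
    rec$cooks_d <- NA_real_
    rec$flagged <- FALSE
    return(rec)
  }
  fit <- stats::lm(q99_reporter ~ q95_costain, data = rec)
  d <- unname(stats::cooks.distance(fit))
  d[!is.finite(d)] <- 0
  # an (all but) exact fit has no residual variance to judge influence by
  s2 <- sum(stats::residuals(fit)^2) / (n - 2)
  if (s2 <= (1e-10 * (max(abs(rec$q99_reporter)) + 1))^2) d <- rep(0, n)
  if (is.null(threshold)) threshold <- 4 / n
  rec$cooks_d <- d
  rec$flagged <- d > threshold
  rec
}

#' Run QC over a mixed collection of embryos
#'
#' Splits embryos by (stain, genotype), applies [qc_regression()] to each
#' group, and returns the combined record table.
#'
#' @inheritParams qc_regression
#' @param embryos list of [embryo] objects (any stains/genotypes).
#' @return Tibble of QC records for all embryos.
#' @export
qc_embryos <- function(embryos, reporter = "lacZ", channel = "hkb",
                       threshold = NULL) {
  key <- vapply(embryos, function(e) paste(e$stain_id, e$genotype, sep = "\r"),
                character(1))
  dplyr::bind_rows(lapply(split(embryos, key), qc_regression,
                          reporter = reporter, channel = channel,
                          threshold = threshold))
}
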