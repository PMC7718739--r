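#' Peak expression within an AP window
#'
#' Maximum of a trace over the bins whose centers fall inside the window,
#' with the position of that bin center.
#'
#' @param trace a `lateral_trace` (or 100-bin numeric vector).
#' @param window `(lo, hi)` fraction of egg length; default the stripe-2
#'   search window 0.30-0.55 (single-stripe reporter constructs effectively
#'   have one global peak; the window guards against anterior artifacts).
#' @return Named list `level`, `pos` (bin-center fraction EL), `bin`.
#' @export
peak_level <- function(trace, window = c(0.30, 0.55)) {
  tr <- as_lateral_trace(trace)
  stopifnot(length(window) == 2, window[1] < window[2])
  peak_level_core(tr$value, window)
}

# bare-vector peak finder shared by the tibble-facing wrappers and the hot
# per-strip loops; ap positions are the fixed bin centers
peak_level_core <- function(v, window) {
  ap <- bin_centers()
  inside <- which(ap >= window[1] & ap <= window[2])
  if (length(inside) == 0) stop("window excludes all bins", call. = FALSE)
  i <- inside[which.max(v[inside])]
  list(level = v[i], pos = ap[i], bin = i - 1L)
}

# parabolic sub-bin refinement of an extremum of a discrete sequence
refine_parabolic <- function(y, j) {
  if (j <= 1 || j >= length(y)) return(0)
  denom <- y[j - 1] - 2 * y[j] + y[j + 1]
  if (abs(denom) < 1e-300) return(0)
  off <- 0.5 * (y[j - 1] - y[j + 1]) / denom
  max(-0.5, min(0.5, off))
}

#' Inflection-point stripe boundaries
#'
#' Calls the anterior and posterior boundaries of a stripe as the inflection
#' points of the expression trace: the trace is smoothed with a centered
#' moving average (default width 3 bins), first differences are taken, and
#' the anterior boundary is the position of the maximum difference on the
#' rising flank anterior of the peak while the posterior boundary is the
#' position of the minimum difference posterior of the peak. The extremum
#' position is refined to sub-bin resolution by parabolic interpolation of
#' the difference sequence.
#'
#' @param trace a `lateral_trace` (or 100-bin numeric vector).
#' @param peak_pos peak position (fraction EL), strictly inside the axis;
#'   defaults to the trace's global argmax.
#' @param window optional `(lo, hi)` restricting the search (used when the
#'   trace holds several stripes).
#' @param smooth moving-average width in bins (odd; default 3).
#' @return Named list `anterior`, `posterior` (fraction EL).
#' @export
boundaries <- function(trace, peak_pos = NULL, window = c(0, 1), smooth = 3) {
  tr <- as_lateral_trace(trace)
  boundaries_core(tr$value, peak_pos, window, smooth)
}

boundaries_core <- function(v, peak_pos = NULL, window = c(0, 1), smooth = 3) {
  ap <- bin_centers()
  if (smooth > 1) {
    sm <- stats::filter(v, rep(1 / smooth, smooth), sides = 2)
    v[!is.na(sm)] <- sm[!is.na(sm)]
  }
  inside <- which(ap >= window[1] & ap <= window[2])
  if (length(inside) < 4) stop("window too narrow for boundary calling", call. = FALSE)
  if (is.null(peak_pos)) peak_pos <- ap[inside][which.max(v[inside])]
  if (peak_pos <= ap[inside][1] || peak_pos >= ap[inside][length(inside)]) {
    stop("peak must lie strictly inside the axis window", call. = FALSE)
  }
  d <- diff(v)                        # d[j] sits between bin centers j, j+1
  dpos <- (seq_len(length(d))) / 100  # its AP position (edge between bins)

  lo <- inside[1]
  hi <- inside[length(inside)]
  ant_idx <- which(dpos < peak_pos & seq_along(d) >= lo)
  post_idx <- which(dpos > peak_pos & seq_along(d) <= hi - 1)
  if (length(ant_idx) == 0 || all(d[ant_idx] <= 0)) {
    stop("boundary undefined: no rising flank anterior of the peak", call. = FALSE)
  }
  if (length(post_idx) == 0 || all(d[post_idx] >= 0)) {
    stop("boundary undefined: no falling flank posterior of the peak", call. = FALSE)
  }
  ja <- ant_idx[which.max(d[ant_idx])]
  jp <- post_idx[which.min(d[post_idx])]
  ant <- dpos[ja] + refine_parabolic(d, ja) / 100
  post <- dpos[jp] + refine_parabolic(d, jp) / 100
  list(anterior = ant, posterior = post)
}

#' Positional shift in cell widths
#'
#' Converts a change in AP position to cell widths using the approximation
#' that one cell length is one percent of egg length. Signed: negative means
#' `pos_b` is anterior of `pos_a`.
#'
#' @param pos_a,pos_b positions in fraction of egg length.
#' @return `(pos_b - pos_a) * 100`, in cell widths.
#' @export
shift_in_cells <- function(pos_a, pos_b) {
  stopifnot(all(pos_a >= 0 & pos_a <= 1), all(pos_b >= 0 & pos_b <= 1))
  (pos_b - pos_a) * 100
}

# prominence of a local maximum: height above the higher of the two valley
# minima separating it from higher ground (or the trace ends)
peak_prominence <- function(v, i) {
  left_min <- v[i]
  j <- i
  while (j > 1) {
    j <- j - 1
    if (v[j] > v[i]) break
    left_min <- min(left_min, v[j])
  }
  right_min <- v[i]
  j <- i
  while (j < length(v)) {
    j <- j + 1
    if (v[j] > v[i]) break
    right_min <- min(right_min, v[j])
  }
  v[i] - max(left_min, right_min)
}

#' Segment a seven-stripe trace and normalize to stripe 1
#'
#' Finds up to seven local maxima (minimum prominence 10% of the global
#' maximum, minimum separation 3 bins), ordered anterior to posterior;
#' assigns the minima between consecutive peaks as stripe window edges;
#' computes each stripe's peak, inflection boundaries, and its peak level
#' normalized to stripe 1 — the internal normalization used when absolute
#' staining levels are not comparable between embryos. Fewer than seven
#' detected stripes (early embryos) yields the found subset with a warning.
#'
#' @param trace a `lateral_trace` (or 100-bin numeric vector).
#' @param max_stripes maximum stripes to report (default 7).
#' @param min_separation minimum peak separation in bins (default 3).
#' @param min_prominence_frac minimum prominence as a fraction of the global
#'   maximum (default 0.1).
#' @return An object of class `stripe_set`: a tibble with one row per
#'   stripe: `stripe`, `peak_level`, `peak_pos`, `anterior`, `posterior`,
#'   `window_lo`, `window_hi`, `norm_peak` (peak / stripe-1 peak).
#' @export
segment_eve_stripes <- function(trace, max_stripes = 7, min_separation = 3,
                                min_prominence_frac = 0.1) {
  tr <- as_lateral_trace(trace)
  v <- tr$value
  n <- length(v)
  cand <- which(vapply(2:(n - 1), function(i) {
    v[i] > v[i - 1] && v[i] >= v[i + 1]
  }, logical(1))) + 1
  prom <- vapply(cand, function(i) peak_prominence(v, i), numeric(1))
  cand <- cand[prom >= min_prominence_frac * max(v)]
  if (length(cand) < 2) {
    stop("fewer than 2 local maxima found; not a multi-stripe trace", call. = FALSE)
  }
  # enforce separation, keeping higher peaks first
  keep <- integer(0)
  for (i in cand[order(-v[cand])]) {
    if (all(abs(i - keep) >= min_separation)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  if (length(keep) > max_stripes) {
    keep <- sort(keep[order(-v[keep])][seq_len(max_stripes)])
  }
  if (length(keep) < max_stripes) {
    warning("found ", length(keep), " stripes (expected up to ", max_stripes,
            "); reporting the subset")
  }
  # window edges at inter-peak minima
  edges <- numeric(length(keep) + 1)
  edges[1] <- max(1, keep[1] - 8)
  edges[length(edges)] <- min(n, keep[length(keep)] + 8)
  if (length(keep) > 1) {
    for (i in seq_len(length(keep) - 1)) {
      seg <- keep[i]:keep[i + 1]
      edges[i + 1] <- seg[which.min(v[seg])]
    }
  }
  rows <- lapply(seq_along(keep), function(i) {
    w <- c(tr$ap[edges[i]], tr$ap[edges[i + 1]])
    pk <- peak_level(tr, window = w)
    b <- tryCatch(boundaries(tr, peak_pos = pk$pos, window = w),
                  error = function(e) list(anterior = NA_real_,
                                           posterior = NA_real_))
    tibble::tibble(stripe = i, peak_level = pk$level, peak_pos = pk$pos,
                   anterior = b$anterior, posterior = b$posterior,
                   window_lo = w[1], window_hi = w[2])
  })
  out <- dplyr::bind_rows(rows)
  out$norm_peak <- out$peak_level / out$peak_level[1]
  structure(out, class = c("stripe_set", class(out)))
}

#' Per-strip boundary positions around the DV circumference
#'
#' Applies [boundaries()] to each of the 16 DV strips of a [trace_matrix]
#' separately (each strip trace is background-subtracted first), returning
#' the requested boundary for the 8 strips of the left lateral half (strips
#' 0-7, ventral through dorsal) and the 8 of the right half (strips 8-15),
#' plus their mean. Strips where the boundary is undefined are excluded and
#' reported as `NA`.
#'
#' @param matrix a [trace_matrix] from [extract_pattern()].
#' @param which `"anterior"` or `"posterior"`.
#' @param window AP search window for the stripe (default 0.30-0.55).
#' @return Tibble with columns `strip` (0-15), `side` (`"left"`/`"right"`),
#'   `position` (fraction EL, `NA` if undefined); attribute `mean_position`.
#' @export
dv_boundary_profile <- function(matrix, which = c("anterior", "posterior"),
                                window = c(0.30, 0.55)) {
  stopifnot(inherits(matrix, "trace_matrix"))
  which <- match.arg(which)
  pos <- vapply(seq_len(N_STRIPS), function(s) {
    v <- matrix$values[s, ]
    v <- v - min(v)
    b <- tryCatch({
      pk <- peak_level_core(v, window)
      boundaries_core(v, peak_pos = pk$pos, window = window)
    }, error = function(e) NULL)
    if (is.null(b)) NA_real_ else b[[which]]
  }, numeric(1))
  out <- tibble::tibble(strip = 0:(N_STRIPS - 1L),
                        side = rep(c("left", "right"), each = 8),
                        position = pos)
  attr(out, "mean_position") <- mean(pos, na.rm = TRUE)
  attr(out, "which") <- which
  out
}
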