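N_STRIPS <- 16L
N_BINS <- 100L

#' Strip-by-bin expression matrix of an embryo
#'
#' Re-implementation of the PointCloud toolbox's extractpattern step: the
#' embryo surface is divided into 16 strips around the DV circumference
#' (strip `s` covers dv_angle in `[s, s+1) * 2*pi/16`, strip 0 starting at
#' the ventral midline) and each strip into 100 AP bins (bin `b` covers
#' ap_fraction in `[b, b+1)/100`, half-open, last bin closed). The cell
#' value is the mean expression of the nuclei assigned to it. Cells with no
#' nuclei are filled by linear interpolation along the AP axis within the
#' strip (constant extension at the ends) and are identifiable by
#' `counts == 0`.
#'
#' @param embryo an [embryo].
#' @param channel channel to extract.
#' @return An object of class `trace_matrix`: fields `values` and `counts`
#'   (16 x 100 matrices, strips in rows), `channel`, `label`.
#' @export
extract_pattern <- function(embryo, channel) {
  stopifnot(inherits(embryo, "embryo"))
  if (!channel %in% channels(embryo)) {
    stop("unknown channel: ", channel, call. = FALSE)
  }
  nuc <- embryo$nuclei
  strip <- pmin(floor(nuc$dv_angle / (2 * pi / N_STRIPS)), N_STRIPS - 1L)
  bin <- pmin(floor(nuc$ap_fraction * N_BINS), N_BINS - 1L)
  idx <- strip * N_BINS + bin + 1L
  ncell <- N_STRIPS * N_BINS
  counts <- tabulate(idx, ncell)
  # pad with a zero for every cell so rowsum returns a dense sorted vector
  sums <- rowsum(c(nuc[[channel]], numeric(ncell)),
                 c(idx, seq_len(ncell)))[, 1]
  values <- sums / counts                       # NaN where empty
  values <- matrix(values, nrow = N_STRIPS, ncol = N_BINS, byrow = TRUE)
  counts <- matrix(counts, nrow = N_STRIPS, ncol = N_BINS, byrow = TRUE)
  sparse <- rowSums(counts) < 10
  if (any(sparse)) {
    warning("strip(s) ", paste(which(sparse) - 1, collapse = ", "),
            " have fewer than 10 nuclei")
  }
  bx <- bin_centers()
  for (s in seq_len(N_STRIPS)) {
    row <- values[s, ]
    if (anyNA(row)) {
      ok <- !is.na(row)
      if (sum(ok) >= 2) {
        values[s, !ok] <- stats::approx(bx[ok], row[ok], xout = bx[!ok],
                                        rule = 2)$y
      } else if (sum(ok) == 1) {
        values[s, !ok] <- row[ok]
      } else {
        values[s, ] <- 0
      }
    }
  }
  structure(list(values = values, counts = counts, channel = channel,
                 label = embryo$embryo_id),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix %s/%s>  16 strips x 100 bins, %d nuclei\n",
              x$label, x$channel, sum(x$counts)))
  invisible(x)
}

bin_centers <- function() (seq_len(N_BINS) - 0.5) / N_BINS

#' Default lateral strip sets
#'
#' Strips whose angular centers lie within pi/8 of the left (pi/2) and right
#' (3*pi/2) equators of the DV circumference: strips 3-4 and 11-12 (0-based)
#' under the ventral-at-0 convention. The toolbox being mirrored does not
#' name its lateral strips, so the choice is exposed.
#'
#' @return Named list with integer vectors `left` and `right` (0-based).
#' @export
lateral_strips_default <- function() list(left = c(3L, 4L), right = c(11L, 12L))

#' Lateral-averaged, background-subtracted AP trace
#'
#' Averages the designated left- and right-lateral strip sets of a
#' [trace_matrix] (mean within each side, then mean of the two sides) and
#' subtracts the minimum over the 100 bins to remove background, so the
#' trace minimum is exactly 0.
#'
#' @param matrix a [trace_matrix].
#' @param strips lateral strip sets; see [lateral_strips_default()].
#' @return An object of class `lateral_trace`: a tibble with columns `bin`
#'   (0-99), `ap` (bin center, fraction EL), `value`; attributes `channel`,
#'   `label`, `source` (strips used), `background` (subtracted minimum).
#' @export
lateral_trace <- function(matrix, strips = lateral_strips_default()) {
  stopifnot(inherits(matrix, "trace_matrix"))
  left <- strips$left + 1L
  right <- strips$right + 1L
  if (all(matrix$counts[c(left, right), ] == 0)) {
    stop("data error: all lateral strips are empty", call. = FALSE)
  }
  side_mean <- function(rows) colMeans(matrix$values[rows, , drop = FALSE])
  v <- (side_mean(left) + side_mean(right)) / 2
  bg <- min(v)
  new_lateral_trace(v - bg, channel = matrix$channel, label = matrix$label,
                    source = strips, background = bg)
}

new_lateral_trace <- function(values, channel = NA_character_,
                              label = NA_character_, source = NULL,
                              background = NA_real_, sem = NULL) {
  cols <- list(bin = 0:(N_BINS - 1L), ap = bin_centers(),
               value = as.numeric(values))
  if (!is.null(sem)) cols$sem <- as.numeric(sem)
  out <- tibble::new_tibble(cols, nrow = N_BINS)
  structure(out, channel = channel, label = label, source = source,
            background = background,
            class = c("lateral_trace", class(out)))
}

#' Coerce to a lateral trace
#'
#' Accepts a `lateral_trace`, or a bare numeric vector of 100 bin values
#' (assumed already background-subtracted or not, as given).
#'
#' @param x object to coerce.
#' @return A `lateral_trace`.
#' @export
as_lateral_trace <- function(x) {
  if (inherits(x, "lateral_trace")) return(x)
  if (is.numeric(x) && length(x) == N_BINS) return(new_lateral_trace(x))
  stop("cannot coerce to lateral_trace: need 100 bin values", call. = FALSE)
}

#' Per-embryo lateral trace
#'
#' Convenience composition of [extract_pattern()] and [lateral_trace()].
#'
#' @param embryo an [embryo].
#' @param channel channel name.
#' @param strips lateral strip sets.
#' @return A `lateral_trace`.
#' @export
embryo_trace <- function(embryo, channel, strips = lateral_strips_default()) {
  lateral_trace(extract_pattern(embryo, channel), strips = strips)
}

# bare 100-vector version of embryo_trace for hot loops
embryo_trace_values <- function(embryo, channel,
                                strips = lateral_strips_default()) {
  m <- extract_pattern(embryo, channel)
  left <- strips$left + 1L
  right <- strips$right + 1L
  v <- (colMeans(m$values[left, , drop = FALSE]) +
          colMeans(m$values[right, , drop = FALSE])) / 2
  v - min(v)
}

#' Group-average AP trace with standard errors
#'
#' Averages per-embryo lateral traces bin-wise across embryos of one
#' genotype (and, when used for staining-batch ratios, one stain), and
#' reports the per-bin standard error of the mean. The averaged trace is
#' re-anchored so its minimum is exactly 0.
#'
#' @param embryos non-empty list of [embryo] objects of one genotype.
#' @param channel channel name.
#' @param strips lateral strip sets.
#' @return A `lateral_trace` with an extra `sem` column and attribute
#'   `n_embryos`.
#' @export
group_average_trace <- function(embryos, channel,
                                strips = lateral_strips_default()) {
  if (length(embryos) == 0) stop("empty embryo list", call. = FALSE)
  genos <- unique(vapply(embryos, `[[`, character(1), "genotype"))
  if (length(genos) > 1) {
    stop("group_average_trace: embryos span genotypes ",
         paste(genos, collapse = ", "), call. = FALSE)
  }
  traces <- vapply(embryos, function(e) embryo_trace_values(e, channel, strips),
                   numeric(N_BINS))
  m <- rowMeans(traces)
  sem <- if (length(embryos) > 1) {
    apply(traces, 1, stats::sd) / sqrt(length(embryos))
  } else {
    rep(0, N_BINS)
  }
  out <- new_lateral_trace(m - min(m), channel = channel,
                           label = genos, source = strips,
                           background = min(m), sem = sem)
  attr(out, "n_embryos") <- length(embryos)
  out
}
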