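#' Position count matrix with background model
#'
#' Container for a transcription-factor position weight matrix given as base
#' counts: a 4 x w grid (rows A, C, G, T; columns 5' to 3'), a positive
#' pseudocount distributed across bases by the background frequencies, and a
#' 4-vector background model. Scoring is by natural-log odds of the
#' regularized frequency over the background, as in classic PATSER-style
#' scanners.
#'
#' @param counts numeric 4 x w matrix of non-negative counts; rows must be
#'   in A, C, G, T order (or carry those rownames, in which case they are
#'   reordered).
#' @param name matrix name.
#' @param pseudocount total pseudocount added per column (> 0), split across
#'   bases proportionally to `background`.
#' @param background length-4 probabilities (A, C, G, T) summing to 1.
#' @return An object of class `pwm_matrix` with fields `name`, `counts`,
#'   `pseudocount`, `background`, `width`.
#' @export
pwm_matrix <- function(counts, name = "pwm", pseudocount = 1,
                       background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("counts must have 4 rows (A, C, G, T)", call. = FALSE)
  if (!is.null(rownames(counts)) && setequal(rownames(counts), c("A", "C", "G", "T"))) {
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  }
  rownames(counts) <- c("A", "C", "G", "T")
  if (any(counts < 0)) stop("negative counts in PWM", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9) {
    stop("background must be 4 positive probabilities summing to 1", call. = FALSE)
  }
  if (any(colSums(counts) + pseudocount <= 0)) {
    stop("degenerate PWM column: non-positive total after pseudocount", call. = FALSE)
  }
  structure(list(name = name, counts = counts, pseudocount = pseudocount,
                 background = as.numeric(background), width = ncol(counts)),
            class = "pwm_matrix")
}

#' @export
print.pwm_matrix <- function(x, ...) {
  cat(sprintf("<pwm_matrix %s>  width %d, pseudocount %g\n",
              x$name, x$width, x$pseudocount))
  print(round(x$counts, 3))
  invisible(x)
}

#' Log-odds scoring matrix of a PWM
#'
#' Converts counts to a 4 x w natural-log-odds grid: entry (b, j) is
#' `ln( (counts[b,j] + pseudocount*background[b]) / (colsum[j] + pseudocount)
#' / background[b] )`, i.e. the log ratio of the regularized base frequency
#' to the background frequency.
#'
#' @param pwm a [pwm_matrix].
#' @return 4 x w numeric matrix with rownames A, C, G, T.
#' @export
pwm_logodds <- function(pwm) {
  stopifnot(inherits(pwm, "pwm_matrix"))
  cs <- colSums(pwm$counts)
  freq <- sweep(pwm$counts, 1, pwm$pseudocount * pwm$background, `+`)
  freq <- sweep(freq, 2, cs + pwm$pseudocount, `/`)
  log(sweep(freq, 1, pwm$background, `/`))
}

#' Exact score distribution of a PWM under its background
#'
#' Computes the distribution of the log-odds score of a random sequence drawn
#' from the background model, by dynamic programming: the score distribution
#' after column j is the distribution after column j-1 convolved with column
#' j's four-outcome distribution, discretized to a fixed bin width. Tail
#' probabilities from this distribution are the "exact" p-values used by
#' PATSER-style scanners.
#'
#' @param pwm a [pwm_matrix].
#' @param bin_width discretization step in log-odds units (default 1e-3).
#' @return An object of class `score_distribution`: fields `score` (bin
#'   values), `prob` (probabilities summing to 1), `tail` (`P(S >= score)`),
#'   `bin_width`.
#' @export
score_distribution <- function(pwm, bin_width = 1e-3) {
  stopifnot(inherits(pwm, "pwm_matrix"), bin_width > 0)
  lo <- pwm_logodds(pwm)
  ibins <- round(lo / bin_width)          # integer bin index per entry
  offsets <- apply(ibins, 2, min)
  spans <- apply(ibins, 2, max) - offsets # per-column spread in bins
  # probability vector over bins, index 1 = running minimum score
  p <- 1
  for (j in seq_len(ncol(lo))) {
    newp <- numeric(length(p) + spans[j])
    rel <- ibins[, j] - offsets[j]
    for (b in 1:4) {
      idx <- seq_along(p) + rel[b]
      newp[idx] <- newp[idx] + p * pwm$background[b]
    }
    p <- newp
  }
  min_bin <- sum(offsets)
  score <- (min_bin + seq_along(p) - 1) * bin_width
  keep <- p > 0
  score <- score[keep]; p <- p[keep]
  structure(list(score = score, prob = p,
                 tail = rev(cumsum(rev(p))), bin_width = bin_width,
                 # the discretized matrix itself: summing its entries lands
                 # exactly on this distribution's bin grid, which is how
                 # scanners must score windows for consistent p-values
                 logodds_binned = ibins * bin_width),
            class = "score_distribution")
}

#' Tail p-value of a score
#'
#' `P(S >= s)` under a PWM's background score distribution. Scores above the
#' maximal achievable score get the probability of that maximum (p-values are
#' never 0).
#'
#' @param dist a [score_distribution].
#' @param s numeric vector of scores.
#' @return Numeric vector of tail probabilities in `(0, 1]`.
#' @export
score_pvalue <- function(dist, s) {
  stopifnot(inherits(dist, "score_distribution"))
  # first bin with score >= s - half bin (guard against rounding at bin edges)
  idx <- findInterval(s - dist$bin_width / 2, dist$score) + 1
  idx[idx < 1] <- 1
  idx[idx > length(dist$tail)] <- length(dist$tail)
  dist$tail[idx]
}

#' Score threshold for a target p-value
#'
#' Smallest discretized score whose tail probability does not exceed `p`.
#' If `p` is below the probability of the maximal score, the maximal score is
#' returned with a warning.
#'
#' @param pwm a [pwm_matrix].
#' @param p target p-value in (0, 1).
#' @param dist optionally a precomputed [score_distribution] for `pwm`.
#' @return Numeric score threshold.
#' @export
threshold_for_pvalue <- function(pwm, p, dist = NULL) {
  stopifnot(p > 0, p < 1)
  if (is.null(dist)) dist <- score_distribution(pwm)
  ok <- dist$tail <= p
  if (!any(ok)) {
    warning("requested p-value below probability of the maximal score; ",
            "returning the maximal score")
    return(dist$score[length(dist$score)])
  }
  dist$score[which(ok)[1]]
}

#' Per-column information content of a PWM
#'
#' Information content in bits per column of the regularized frequency
#' matrix, used to pick which position of a binding site to mutate when
#' scrubbing.
#'
#' @param pwm a [pwm_matrix].
#' @return Numeric vector of length `width`.
#' @export
pwm_information <- function(pwm) {
  cs <- colSums(pwm$counts)
  freq <- sweep(pwm$counts, 1, pwm$pseudocount * pwm$background, `+`)
  freq <- sweep(freq, 2, cs + pwm$pseudocount, `/`)
  apply(freq, 2, function(f) sum(f * log2(f / pwm$background)))
}
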