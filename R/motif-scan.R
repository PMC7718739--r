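DNA_BASES <- c("A", "C", "G", "T")

seq_to_codes <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- !(chars %in% c(DNA_BASES, "N"))
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(chars[bad]), collapse = ""), call. = FALSE)
  }
  match(chars, DNA_BASES)  # N -> NA
}

#' Reverse complement of a DNA string
#'
#' @param sequence character scalar over A, C, G, T, N.
#' @return Character scalar.
#' @export
reverse_complement <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

# sum of M[code, j] over aligned windows; windows containing N score -Inf
score_windows <- function(codes, M) {
  w <- ncol(M)
  n <- length(codes) - w + 1
  if (n < 1) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(w)) {
    v <- M[cbind(codes[j:(j + n - 1)], j)]
    v[is.na(v)] <- -Inf
    s <- s + v
  }
  s
}

#' Scan a sequence with a PWM
#'
#' Scores every window of a sequence on both strands with a PWM's log-odds
#' matrix and reports windows whose tail p-value is at most `p_threshold`.
#' Coordinates are 0-based, half-open, on the forward strand for both
#' strands. Windows containing `N` are excluded.
#'
#' @param sequence character scalar over A, C, G, T, N.
#' @param pwm a [pwm_matrix].
#' @param p_threshold report hits with p-value `<=` this (default 0.001, the
#'   usual cutoff for calling candidate binding sites).
#' @param dist optionally a precomputed [score_distribution] for `pwm`.
#' @return Tibble with columns `pwm_name`, `start`, `end`, `strand`, `width`,
#'   `score`, `p_value`, sorted by `start`. Zero rows (with a warning) when
#'   the sequence is shorter than the PWM.
#' @export
scan_pwm <- function(sequence, pwm, p_threshold = 0.001, dist = NULL) {
  stopifnot(inherits(pwm, "pwm_matrix"))
  w <- pwm$width
  codes <- seq_to_codes(sequence)
  empty <- tibble::tibble(pwm_name = character(), start = integer(),
                          end = integer(), strand = character(),
                          width = integer(), score = numeric(),
                          p_value = numeric())
  if (length(codes) < w) {
    warning("sequence shorter than PWM width; no windows to scan")
    return(empty)
  }
  if (is.null(dist)) dist <- score_distribution(pwm)
  M <- pwm_logodds(pwm)
  # p-values are computed from window scores summed over the *discretized*
  # log-odds matrix, so they sit exactly on the score distribution's bin
  # grid (per-column rounding errors of the exact sums can span several
  # bins and would make tail lookups inconsistent); the exact scores are
  # what gets reported
  Mb <- dist$logodds_binned
  # reverse-strand hits at forward start i score the reverse complement of
  # the window: equivalent to scanning forward with the column-reversed,
  # base-complemented matrix
  flip <- function(m) m[4:1, w:1, drop = FALSE]
  fwd <- score_windows(codes, M)
  rev <- score_windows(codes, flip(M))
  fwd_b <- score_windows(codes, Mb)
  rev_b <- score_windows(codes, flip(Mb))
  hit_tbl <- function(scores, binned, strand) {
    pv <- score_pvalue(dist, binned)
    idx <- which(is.finite(scores) & pv <= p_threshold)
    tibble::tibble(pwm_name = pwm$name, start = idx - 1L,
                   end = idx - 1L + w, strand = strand, width = w,
                   score = scores[idx], p_value = pv[idx])
  }
  out <- dplyr::bind_rows(hit_tbl(fwd, fwd_b, "+"), hit_tbl(rev, rev_b, "-"))
  dplyr::arrange(out, .data$start, .data$strand)
}

#' Consensus intervals supported by every PWM
#'
#' Given hit tables from two or more PWMs over the same sequence, returns the
#' maximal intervals in which every PWM has at least one overlapping hit
#' (either strand), keeping only runs of joint coverage at least
#' `min_overlap` bp long. This is how a binding site "common to all the PWMs"
#' is called when the individual matrices disagree on exact boundaries.
#'
#' @param hits_per_pwm list of >= 2 hit tables as returned by [scan_pwm()].
#' @param min_overlap minimum width (bp) of a joint-coverage run (default 1).
#' @return Tibble with columns `start`, `end` (0-based half-open), `width`,
#'   `n_pwms`.
#' @export
consensus_sites <- function(hits_per_pwm, min_overlap = 1) {
  if (length(hits_per_pwm) < 2) stop("need hits from at least 2 PWMs", call. = FALSE)
  empty <- tibble::tibble(start = integer(), end = integer(),
                          width = integer(), n_pwms = integer())
  if (any(vapply(hits_per_pwm, nrow, integer(1)) == 0)) return(empty)
  L <- max(vapply(hits_per_pwm, function(h) max(h$end), numeric(1)))
  covered_by_all <- rep(TRUE, L)
  for (h in hits_per_pwm) {
    cov <- rep(FALSE, L)
    for (i in seq_len(nrow(h))) cov[(h$start[i] + 1):h$end[i]] <- TRUE
    covered_by_all <- covered_by_all & cov
  }
  r <- rle(covered_by_all)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_overlap
  if (!any(keep)) return(empty)
  tibble::tibble(start = starts[keep] - 1L, end = as.integer(ends[keep]),
                 width = as.integer(r$lengths[keep]),
                 n_pwms = length(hits_per_pwm))
}

#' Remove high-affinity binding sites from a sequence
#'
#' Iteratively mutates a sequence until no PWM in `pwms` has a hit at
#' p-value `<= p_threshold` on either strand, preserving length. At each
#' step the strongest remaining hit (smallest p-value; ties broken by
#' position, matrix order, then strand) is weakened by mutating the
#' highest-information-content position of its window that is not already at
#' its score-minimizing base, then the sequence is rescanned. Used to
#' design neutral spacer sequences free of sites for the scanned factors.
#'
#' @param sequence character scalar over A, C, G, T.
#' @param pwms list of [pwm_matrix] objects.
#' @param p_threshold scrub hits with p-value at or below this (default
#'   0.003, a permissive cutoff so even moderate-affinity sites are removed).
#' @param rng_seed integer kept for interface stability; the procedure is
#'   deterministic (all ties are broken by fixed ordering rules).
#' @param max_iter maximum mutations; default 10 x the initial hit count.
#' @return The scrubbed sequence (same length), with attribute `edits`: a
#'   tibble of (position, from, to) for each mutation made.
#' @export
scrub_sites <- function(sequence, pwms, p_threshold = 0.003, rng_seed = 1L,
                        max_iter = NULL) {
  stopifnot(length(pwms) >= 1)
  dists <- lapply(pwms, score_distribution)
  infos <- lapply(pwms, pwm_information)
  logodds <- lapply(pwms, pwm_logodds)
  all_hits <- function(s) {
    dplyr::bind_rows(lapply(seq_along(pwms), function(k) {
      h <- scan_pwm(s, pwms[[k]], p_threshold, dist = dists[[k]])
      h$pwm_index <- rep(k, nrow(h))
      h
    }))
  }
  hits <- all_hits(sequence)
  if (nrow(hits) == 0) {
    attr(sequence, "edits") <- tibble::tibble(position = integer(),
                                              from = character(),
                                              to = character())
    return(sequence)
  }
  if (is.null(max_iter)) max_iter <- max(10L, 10L * nrow(hits))
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  edits <- list()
  for (iter in seq_len(max_iter)) {
    if (nrow(hits) == 0) break
    hits <- dplyr::arrange(hits, .data$p_value, .data$start, .data$pwm_index,
                           dplyr::desc(.data$strand))
    h <- hits[1, ]
    k <- h$pwm_index
    M <- logodds[[k]]
    w <- pwms[[k]]$width
    # most informative PWM column whose current base is not already the
    # score-minimizing one (a still-hot site may need several edits)
    seq_pos_of <- function(j) if (h$strand == "+") h$start + j else h$start + w - j + 1
    base_for_min <- function(j) {
      if (h$strand == "+") DNA_BASES[which.min(M[, j])]
      else unname(comp[DNA_BASES[which.min(M[, j])]])
    }
    editable <- which(vapply(seq_len(w), function(j) {
      chars[seq_pos_of(j)] != base_for_min(j)
    }, logical(1)))
    if (length(editable) == 0) {
      stop("scrub_sites: window at start ", h$start,
           " is a hit even at its minimal score", call. = FALSE)
    }
    jstar <- editable[which.max(infos[[k]][editable])]
    pos <- seq_pos_of(jstar)
    best <- base_for_min(jstar)
    edits[[length(edits) + 1]] <- tibble::tibble(position = pos,
                                                 from = chars[pos], to = best)
    chars[pos] <- best
    hits <- all_hits(paste(chars, collapse = ""))
  }
  out <- paste(chars, collapse = "")
  if (nrow(hits) > 0) {
    stop("scrub_sites: could not clear all sites within ", max_iter,
         " mutations; residual hits at starts ",
         paste(utils::head(hits$start, 10), collapse = ", "), call. = FALSE)
  }
  attr(out, "edits") <- dplyr::bind_rows(edits)
  out
}
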