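#' Per-genotype stripe metrics pooled across stains
#'
#' Boundary positions do not depend on staining intensity, so they are
#' estimated from embryos pooled over stains: for each genotype, every
#' embryo's lateral trace is computed, its peak and inflection boundaries
#' called, and the per-embryo values averaged with standard errors.
#'
#' @param embryos list of [embryo] objects (mixed genotypes allowed).
#' @param channel expression channel.
#' @param window stripe search window (fraction EL).
#' @param strips lateral strip sets.
#' @return Tibble with one row per genotype: `genotype`, `n_embryos`,
#'   `peak_level`, `peak_se`, `anterior`, `anterior_se`, `posterior`,
#'   `posterior_se`.
#' @export
stripe_metrics_by_genotype <- function(embryos, channel = "lacZ",
                                       window = c(0.30, 0.55),
                                       strips = lateral_strips_default()) {
  per <- dplyr::bind_rows(lapply(embryos, function(e) {
    v <- embryo_trace_values(e, channel, strips)
    pk <- peak_level_core(v, window)
    b <- tryCatch(boundaries_core(v, peak_pos = pk$pos, window = window),
                  error = function(err) list(anterior = NA_real_,
                                             posterior = NA_real_))
    tibble::tibble(genotype = e$genotype, embryo_id = e$embryo_id,
                   peak_level = pk$level, anterior = b$anterior,
                   posterior = b$posterior)
  }))
  summarise_metrics(per)
}

# shared per-genotype summary of per-embryo peak/boundary tables
summarise_metrics <- function(per) {
  se <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  }
  dplyr::summarise(
    dplyr::group_by(per, .data$genotype),
    n_embryos = dplyr::n(),
    peak_se = se(.data$peak_level),
    peak_level = mean(.data$peak_level, na.rm = TRUE),
    anterior_se = se(.data$anterior),
    anterior = mean(.data$anterior, na.rm = TRUE),
    posterior_se = se(.data$posterior),
    posterior = mean(.data$posterior, na.rm = TRUE),
    .groups = "drop"
  )[, c("genotype", "n_embryos", "peak_level", "peak_se",
        "anterior", "anterior_se", "posterior", "posterior_se")]
}

metrics_from_traces <- function(trace_mat, genotypes, embryo_ids, window) {
  per <- dplyr::bind_rows(lapply(seq_along(genotypes), function(i) {
    v <- trace_mat[, i]
    pk <- peak_level_core(v, window)
    b <- tryCatch(boundaries_core(v, peak_pos = pk$pos, window = window),
                  error = function(err) list(anterior = NA_real_,
                                             posterior = NA_real_))
    tibble::tibble(genotype = genotypes[i], embryo_id = embryo_ids[i],
                   peak_level = pk$level, anterior = b$anterior,
                   posterior = b$posterior)
  }))
  summarise_metrics(per)
}

load_embryo_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(txt|pc|pointcloud)$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no PointCloud files in ", dir, call. = FALSE)
  lapply(files, read_pointcloud)
}

#' Run the reporter-construct analysis end to end
#'
#' Stage order: read (or simulate) embryos, QC within each (stain, genotype)
#' group with Cook's-distance flagging, drop flagged embryos, normalize the
#' reporter by each embryo's co-stain scale, compute group-average traces,
#' per-genotype stripe metrics pooled over stains, per-stain peak ratios for
#' each requested genotype pair, and the one- and two-sample ratio tests.
#' Deterministic given the inputs and seed.
#'
#' @param config named list (or path to a YAML file; see
#'   [read_run_config()]) with elements:
#'   \describe{
#'     \item{input_dir}{directory of PointCloud files, or}
#'     \item{simulate}{list: `fold`, `n_stains`, `n_per_genotype`, optional
#'       geometry offsets (`anterior_b`, `posterior_b`) and any
#'       [sim_config()] argument.}
#'     \item{reporter}{reporter channel (default `"lacZ"`).}
#'     \item{pairs}{list of genotype pairs, each `list(num=, den=,
#'       alternative=)`.}
#'     \item{window}{stripe search window (default `c(0.30, 0.55)`).}
#'     \item{cooks_threshold}{Cook's distance cutoff (default `4/n`).}
#'     \item{output_dir}{optional; TSVs are written there when given.}
#'     \item{seed}{integer seed for simulation.}
#'   }
#' @return List with `qc_records`, `traces` (per genotype x stain bin
#'   means), `metrics`, `ratios`, `tests`, `embryos_used`, `log` (character
#'   vector of stage messages); TSVs written when `output_dir` is set.
#' @export
run_reporter_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  reporter <- config$reporter %||% "lacZ"
  window <- config$window %||% c(0.30, 0.55)
  seed <- config$seed %||% 1L
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }

  if (!is.null(config$simulate)) {
    s <- config$simulate
    cfg_args <- s[setdiff(names(s), c("fold", "n_stains", "n_per_genotype",
                                      "anterior_b", "posterior_b"))]
    cfg <- do.call(reporter_config, c(
      list(fold = s$fold %||% 1,
           anterior_b = s$anterior_b %||% 0.35,
           posterior_b = s$posterior_b %||% 0.45),
      cfg_args))
    n_stains <- s$n_stains %||% 5
    npg <- s$n_per_genotype %||% 10
    embryos <- unlist(lapply(seq_len(n_stains), function(i) {
      generate_stain(cfg, names(cfg$genotypes), npg,
                     stain_id = paste0("stain", i),
                     seed = (seed * 100L + i) %% .Machine$integer.max)
    }), recursive = FALSE)
    say("simulated %d embryos over %d stains (seed %d)", length(embryos),
        n_stains, seed)
  } else if (!is.null(config$input_dir)) {
    embryos <- load_embryo_dir(config$input_dir)
    say("read %d embryos from %s", length(embryos), config$input_dir)
  } else {
    stop("config needs either 'simulate' or 'input_dir'", call. = FALSE)
  }

  qc <- qc_embryos(embryos, reporter = reporter,
                   threshold = config$cooks_threshold)
  flagged <- qc$embryo_id[qc$flagged]
  for (id in flagged) {
    say("discarding embryo %s (Cook's distance %.3f)", id,
        qc$cooks_d[qc$embryo_id == id])
  }
  keep <- !vapply(embryos, function(e) e$embryo_id %in% flagged, logical(1))
  embryos <- embryos[keep]
  say("QC kept %d embryos (%d flagged)", sum(keep), length(flagged))

  embryos <- normalize_embryos(embryos, reporter = reporter)

  genos <- vapply(embryos, `[[`, character(1), "genotype")
  stains <- vapply(embryos, `[[`, character(1), "stain_id")
  # each embryo's lateral trace is computed once and reused by the trace
  # table, the pooled metrics, and the per-stain ratios
  trace_mat <- vapply(embryos, function(e) embryo_trace_values(e, reporter),
                      numeric(100))
  key <- paste(stains, genos, sep = "\r")
  group_trace <- function(sel) {
    m <- rowMeans(trace_mat[, sel, drop = FALSE])
    m - min(m)
  }
  traces <- dplyr::bind_rows(lapply(unique(key), function(k) {
    sel <- key == k
    cols <- trace_mat[, sel, drop = FALSE]
    m <- group_trace(sel)
    sem <- if (sum(sel) > 1) apply(cols, 1, stats::sd) / sqrt(sum(sel)) else rep(0, 100)
    tibble::tibble(stain_id = stains[sel][1], genotype = genos[sel][1],
                   bin = 0:99, ap = (0:99 + 0.5) / 100, mean = m, sem = sem)
  }))

  metrics <- metrics_from_traces(trace_mat, genos,
                                 vapply(embryos, `[[`, character(1), "embryo_id"),
                                 window)

  pairs <- config$pairs
  if (is.null(pairs)) {
    gl <- unique(genos)
    pairs <- if (length(gl) >= 2) list(list(num = gl[2], den = gl[1])) else list()
  }
  results <- lapply(pairs, function(p) {
    per <- dplyr::bind_rows(lapply(unique(stains), function(s) {
      num_sel <- stains == s & genos == p$num
      den_sel <- stains == s & genos == p$den
      if (!any(num_sel) || !any(den_sel)) {
        return(tibble::tibble(stain_id = s, ratio = NA_real_))
      }
      tibble::tibble(stain_id = s,
                     ratio = peak_level_core(group_trace(num_sel), window)$level /
                       peak_level_core(group_trace(den_sel), window)$level)
    }))
    per <- per[!is.na(per$ratio), ]
    if (nrow(per) < 2) {
      stop("fewer than 2 usable stains for ", p$num, "/", p$den, call. = FALSE)
    }
    alt <- p$alternative %||% "two.sided"
    tst <- one_sample_ratio_test(per$ratio, mu = 1, alternative = alt)
    structure(list(genotype_num = p$num, genotype_den = p$den,
                   per_stain = per, mean_ratio = tst$mean, t_stat = tst$t,
                   df = tst$df, p_one_sample = tst$p, n_stains = nrow(per),
                   alternative = alt, degenerate = tst$degenerate),
              class = "ratio_result")
  })
  ratios <- dplyr::bind_rows(lapply(results, tidy))
  tests <- dplyr::bind_rows(lapply(results, glance))
  for (i in seq_len(nrow(tests))) {
    say("ratio %s/%s = %.3f over %d stains, p = %.4g",
        tests$genotype_num[i], tests$genotype_den[i], tests$mean_ratio[i],
        tests$n_stains[i], tests$p_value[i])
  }

  out <- list(qc_records = qc, traces = traces, metrics = metrics,
              ratios = ratios, tests = tests, ratio_results = results,
              embryos_used = vapply(embryos, `[[`, character(1), "embryo_id"),
              log = log)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_tsv(qc, file.path(config$output_dir, "qc_records.tsv"))
    write_result_tsv(traces, file.path(config$output_dir, "traces.tsv"))
    write_result_tsv(metrics, file.path(config$output_dir, "metrics.tsv"))
    write_result_tsv(ratios, file.path(config$output_dir, "ratios.tsv"))
    write_result_tsv(tests, file.path(config$output_dir, "tests.tsv"))
    writeLines(log, file.path(config$output_dir, "run.log"))
  }
  invisible(out)
}

#' Run the endogenous-locus analysis end to end
#'
#' For a seven-stripe channel compared between two genotypes: per embryo,
#' the lateral trace is segmented into stripes and each stripe's peak is
#' normalized to stripe 1; stripe levels are compared between genotypes
#' with a two-sided rank-sum test; stripe-2 boundary positions are compared
#' at the 16 DV positions with per-position Mann-Whitney U tests and
#' Bonferroni adjustment.
#'
#' @param config named list (or YAML path): either `input_dir` or
#'   `simulate` (list: `stripe2_fold`, `stripe2_shift`, `n_per_genotype`,
#'   plus [sim_config()] arguments), `channel` (default `"eve"`), `stripe`
#'   (stripe index to compare, default 2), `boundary` (default
#'   `"anterior"`), `output_dir`, `seed`.
#' @return List with `stripe_levels` (per embryo x stripe normalized
#'   peaks), `level_test`, `boundary_profiles`, `boundary_test`, `log`.
#' @export
run_endogenous_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  channel <- config$channel %||% "eve"
  stripe_idx <- config$stripe %||% 2L
  which_boundary <- config$boundary %||% "anterior"
  seed <- config$seed %||% 1L
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }

  if (!is.null(config$simulate)) {
    s <- config$simulate
    cfg_args <- s[setdiff(names(s), c("stripe2_fold", "stripe2_shift",
                                      "n_per_genotype"))]
    cfg <- do.call(eve_config, c(list(stripe2_fold = s$stripe2_fold %||% 1,
                                      stripe2_shift = s$stripe2_shift %||% 0),
                                 cfg_args))
    npg <- s$n_per_genotype %||% 11
    embryos <- generate_stain(cfg, names(cfg$genotypes), npg,
                              stain_id = "stain1", seed = seed)
    say("simulated %d embryos per genotype (seed %d)", npg, seed)
  } else if (!is.null(config$input_dir)) {
    embryos <- load_embryo_dir(config$input_dir)
  } else {
    stop("config needs either 'simulate' or 'input_dir'", call. = FALSE)
  }

  genos <- vapply(embryos, `[[`, character(1), "genotype")
  gl <- unique(genos)
  if (length(gl) != 2) stop("need exactly 2 genotypes", call. = FALSE)
  say("groups: %s (n = %d) vs %s (n = %d)", gl[1], sum(genos == gl[1]),
      gl[2], sum(genos == gl[2]))

  # one extract_pattern per embryo, shared by segmentation and DV profiles
  mats <- lapply(embryos, extract_pattern, channel = channel)
  strips <- lateral_strips_default()
  stripe_levels <- dplyr::bind_rows(lapply(seq_along(embryos), function(i) {
    e <- embryos[[i]]
    ss <- tryCatch(segment_eve_stripes(lateral_trace(mats[[i]], strips)),
                   error = function(err) NULL)
    if (is.null(ss)) return(NULL)
    tibble::tibble(embryo_id = e$embryo_id, genotype = e$genotype,
                   stripe = ss$stripe, norm_peak = ss$norm_peak,
                   window_lo = ss$window_lo, window_hi = ss$window_hi)
  }))
  lv <- stripe_levels[stripe_levels$stripe == stripe_idx, ]
  level_test <- stripe_level_test(lv$norm_peak[lv$genotype == gl[1]],
                                  lv$norm_peak[lv$genotype == gl[2]])
  say("stripe %d level rank-sum p = %.4g", stripe_idx, level_test$p)

  win <- c(max(0, stats::median(lv$window_lo)),
           min(1, stats::median(lv$window_hi)))
  say("stripe %d window: %.2f-%.2f EL", stripe_idx, win[1], win[2])
  profile_of <- function(i) {
    prof <- dv_boundary_profile(mats[[i]], which = which_boundary,
                                window = win)
    prof$embryo_id <- embryos[[i]]$embryo_id
    prof[c("embryo_id", "strip", "side", "position")]
  }
  prof_a <- dplyr::bind_rows(lapply(which(genos == gl[1]), profile_of))
  prof_b <- dplyr::bind_rows(lapply(which(genos == gl[2]), profile_of))
  boundary_test <- boundary_position_test(prof_a, prof_b)
  say("%s boundary: min Bonferroni-adjusted p = %.4g over %d DV positions",
      which_boundary, boundary_test$p_min_adjusted, boundary_test$n_positions)

  out <- list(stripe_levels = stripe_levels, level_test = level_test,
              boundary_profiles = list(prof_a, prof_b),
              boundary_test = boundary_test, genotypes = gl, log = log)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_tsv(stripe_levels,
                     file.path(config$output_dir, "stripe_levels.tsv"))
    write_result_tsv(boundary_test$per_position,
                     file.path(config$output_dir, "boundary_mwu.tsv"))
    writeLines(log, file.path(config$output_dir, "run.log"))
  }
  invisible(out)
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file path.
#' @return Named list suitable for [run_reporter_analysis()] or
#'   [run_endogenous_analysis()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$window)) cfg$window <- as.numeric(cfg$window)
  cfg
}
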