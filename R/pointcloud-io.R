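#' Read a PointCloud embryo file
#'
#' Reads the plain-text PointCloud dialect used throughout this package: one
#' file per embryo, metadata in `# key=value` comment lines (`embryo_id`,
#' `genotype`, `stain_id`, `stage_pct`, optional `anterior` / `ventral` axis
#' flags), a `# columns=...` header naming the data columns, then one
#' comma-separated row per nucleus. Columns must include `nucleus_id`, `x`,
#' `y`, `z` and at least one expression channel. Axis coordinates
#' (`ap_fraction`, `dv_angle`) are derived on read; see [embryo()].
#'
#' @param path path to a PointCloud text file.
#' @return An [embryo] object.
#' @seealso [write_pointcloud()] for the inverse operation.
#' @export
read_pointcloud <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta_idx <- grepl("^#", lines)
  meta_lines <- sub("^#\\s*", "", lines[meta_idx])
  kv <- strsplit(meta_lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(p) trimws(p[[1]]), character(1))
  vals <- vapply(kv, function(p) trimws(paste(p[-1], collapse = "=")), character(1))
  meta <- stats::setNames(as.list(vals), keys)

  if (is.null(meta$columns)) {
    stop("PointCloud format error: missing '# columns=' header line", call. = FALSE)
  }
  cols <- trimws(strsplit(meta$columns, ",", fixed = TRUE)[[1]])
  required <- c("nucleus_id", "x", "y", "z")
  missing_cols <- setdiff(required, cols)
  if (length(missing_cols) > 0) {
    stop("PointCloud format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(setdiff(cols, required)) == 0) {
    stop("PointCloud format error: no expression channel column declared", call. = FALSE)
  }

  data_lines <- which(!meta_idx & nzchar(trimws(lines)))
  if (length(data_lines) == 0) stop("PointCloud file has no data rows", call. = FALSE)
  fields <- strsplit(lines[data_lines], ",", fixed = TRUE)
  bad_len <- which(lengths(fields) != length(cols))
  if (length(bad_len) > 0) {
    stop("PointCloud parse error at line ", data_lines[bad_len[1]],
         ": expected ", length(cols), " fields", call. = FALSE)
  }
  mat <- matrix(NA_real_, nrow = length(fields), ncol = length(cols),
                dimnames = list(NULL, cols))
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]]))
    if (any(is.na(v))) {
      stop("PointCloud parse error at line ", data_lines[i],
           ": non-numeric value '", fields[[i]][which(is.na(v))[1]], "'",
           call. = FALSE)
    }
    mat[i, ] <- v
  }
  nuclei <- tibble::as_tibble(as.data.frame(mat))
  nuclei$nucleus_id <- as.integer(nuclei$nucleus_id)
  if (anyDuplicated(nuclei$nucleus_id)) {
    stop("PointCloud validation error: duplicate nucleus_id", call. = FALSE)
  }
  embryo(
    nuclei,
    embryo_id = meta$embryo_id %||% basename(path),
    genotype = meta$genotype %||% "unknown",
    stain_id = meta$stain_id %||% "unknown",
    stage_pct = as.numeric(meta$stage_pct %||% NA),
    anterior = meta$anterior %||% "lowx",
    ventral = meta$ventral %||% "lowy"
  )
}

#' Write an embryo to a PointCloud file
#'
#' Inverse of [read_pointcloud()]: the written file round-trips losslessly
#' (numeric values are printed with 15 significant digits).
#'
#' @param embryo an [embryo] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pointcloud <- function(embryo, path) {
  validate_embryo(embryo)
  chans <- channels(embryo)
  cols <- c("nucleus_id", "x", "y", "z", chans)
  header <- c(
    paste0("# embryo_id=", embryo$embryo_id),
    paste0("# genotype=", embryo$genotype),
    paste0("# stain_id=", embryo$stain_id),
    paste0("# stage_pct=", format(embryo$stage_pct, digits = 15)),
    paste0("# anterior=", embryo$anterior),
    paste0("# ventral=", embryo$ventral),
    paste0("# columns=", paste(cols, collapse = ","))
  )
  m <- as.matrix(embryo$nuclei[cols])
  rows <- apply(m, 1, function(r) paste(sprintf("%.15g", r), collapse = ","))
  ok <- tryCatch({
    writeLines(c(header, rows), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("I/O error: cannot write ", path, call. = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a tibble.
#' Sequences are uppercased; characters outside `A`, `C`, `G`, `T`, `N` are
#' rejected.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `name`, `sequence`, `width`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("FASTA format error: no records in ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) stop("FASTA format error: empty record", call. = FALSE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("FASTA validation error: record '", names(set)[bad][1],
         "' contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  tibble::tibble(name = names(set), sequence = unname(seqs),
                 width = nchar(unname(seqs)))
}

#' Write sequences to a FASTA file
#'
#' @param x tibble with columns `name` and `sequence`, as from [read_fasta()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::DNAStringSet(stats::setNames(x$sequence, x$name))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a position count matrix
#'
#' Reads a plain-text PWM count file: four whitespace-separated rows labelled
#' `A`, `C`, `G`, `T` (any order; reordered on read), equal column counts,
#' non-negative counts. Lines starting `#` are comments; an optional
#' `# name=...` comment names the matrix.
#'
#' @param path PWM text file path.
#' @param pseudocount total pseudocount added per column, distributed by the
#'   background frequencies (default 1).
#' @param background length-4 background probabilities (A, C, G, T), summing
#'   to 1; default uniform.
#' @return A [pwm_matrix] object.
#' @export
read_pwm <- function(path, pseudocount = 1, background = rep(0.25, 4)) {
  lines <- readLines(path, warn = FALSE)
  name <- NA_character_
  meta <- grep("^#", lines, value = TRUE)
  nm <- grep("name=", meta, value = TRUE)
  if (length(nm) > 0) name <- trimws(sub(".*name=", "", nm[1]))
  if (is.na(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) != 4) {
    stop("PWM format error: expected 4 labelled rows, found ", length(lines),
         call. = FALSE)
  }
  parts <- strsplit(trimws(lines), "\\s+")
  labels <- toupper(vapply(parts, `[[`, character(1), 1))
  if (!setequal(labels, c("A", "C", "G", "T"))) {
    stop("PWM format error: row labels must be A, C, G, T", call. = FALSE)
  }
  vals <- lapply(parts, function(p) suppressWarnings(as.numeric(p[-1])))
  if (length(unique(lengths(vals))) != 1) {
    stop("PWM format error: rows have unequal column counts", call. = FALSE)
  }
  counts <- do.call(rbind, vals)[order(match(labels, c("A", "C", "G", "T"))), , drop = FALSE]
  rownames(counts) <- c("A", "C", "G", "T")
  if (any(is.na(counts))) stop("PWM parse error: non-numeric count", call. = FALSE)
  if (any(counts < 0)) stop("PWM validation error: negative count", call. = FALSE)
  pwm_matrix(counts, name = name, pseudocount = pseudocount,
             background = background)
}

#' Write a result table as TSV
#'
#' All result tables in this package are written as TSV with a header row.
#'
#' @param x a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
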