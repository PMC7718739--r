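#' Construct a blastoderm embryo object
#'
#' An `embryo` bundles one embryo's nuclear point cloud with its expression
#' channels and staining metadata. Nuclei live in a tibble with columns
#' `nucleus_id`, `x`, `y`, `z` (micrometres), the derived axis coordinates
#' `ap_fraction` (0 = anterior tip, 1 = posterior tip) and `dv_angle`
#' (radians in `[0, 2*pi)`, 0 = ventral midline), and one numeric column per
#' expression channel (arbitrary fluorescence units, non-negative).
#'
#' `ap_fraction` and `dv_angle` are derived from the raw coordinates: the AP
#' axis is the first principal component of the nuclear positions (blastoderm
#' embryos are strongly prolate, so this is the long axis), oriented so the
#' end flagged by `anterior` maps to 0, and min-max rescaled to `[0, 1]`.
#' `dv_angle` is the angle of the residual position in the plane orthogonal
#' to the AP axis, measured from the ventral reference direction flagged by
#' `ventral`. If the nuclei table already carries `ap_fraction`/`dv_angle`
#' columns they are kept verbatim (useful for hand-built fixtures).
#'
#' @param nuclei data frame with columns `nucleus_id`, `x`, `y`, `z` and at
#'   least one channel column; optionally precomputed `ap_fraction` and
#'   `dv_angle`.
#' @param embryo_id,genotype,stain_id character scalars identifying the
#'   embryo, its genetic background, and the in situ hybridization batch it
#'   was stained in.
#' @param stage_pct developmental stage as percent membrane invagination
#'   (0-100).
#' @param anterior which coordinate end is anterior: `"lowx"` (default),
#'   `"highx"`, `"lowy"`, `"highy"`, `"lowz"`, `"highz"`.
#' @param ventral which raw-coordinate direction is the ventral midline:
#'   `"lowy"` (default), `"highy"`, `"lowz"`, `"highz"`.
#' @return An object of class `embryo`.
#' @examples
#' nuc <- tibble::tibble(
#'   nucleus_id = 1:3, x = c(0, 125, 250), y = c(0, 10, 0), z = c(0, 0, 10),
#'   lacZ = c(1, 5, 2), hkb = c(0.1, 0.2, 9)
#' )
#' emb <- embryo(nuc, embryo_id = "e1", genotype = "minWT", stain_id = "s1")
#' emb$nuclei$ap_fraction
#' @export
embryo <- function(nuclei, embryo_id, genotype = "unknown", stain_id = "unknown",
                   stage_pct = NA_real_, anterior = "lowx", ventral = "lowy") {
  nuclei <- tibble::as_tibble(nuclei)
  required <- c("nucleus_id", "x", "y", "z")
  missing_cols <- setdiff(required, names(nuclei))
  if (length(missing_cols) > 0) {
    stop("nuclei table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(nuclei$nucleus_id)) {
    stop("duplicate nucleus_id values within an embryo", call. = FALSE)
  }
  if (!all(c("ap_fraction", "dv_angle") %in% names(nuclei))) {
    ax <- derive_axes(nuclei$x, nuclei$y, nuclei$z,
                      anterior = anterior, ventral = ventral)
    nuclei$ap_fraction <- ax$ap_fraction
    nuclei$dv_angle <- ax$dv_angle
  }
  obj <- structure(
    list(embryo_id = as.character(embryo_id),
         genotype = as.character(genotype),
         stain_id = as.character(stain_id),
         stage_pct = as.numeric(stage_pct),
         anterior = anterior, ventral = ventral,
         nuclei = nuclei),
    class = "embryo"
  )
  validate_embryo(obj)
  obj
}

#' @export
print.embryo <- function(x, ...) {
  cat(sprintf("<embryo %s>  genotype=%s  stain=%s  stage=%s%%\n",
              x$embryo_id, x$genotype, x$stain_id,
              ifelse(is.na(x$stage_pct), "?", format(x$stage_pct))))
  cat(sprintf("  %d nuclei, channels: %s\n",
              nrow(x$nuclei), paste(channels(x), collapse = ", ")))
  invisible(x)
}

#' Expression channels of an embryo
#'
#' @param embryo an [embryo] object.
#' @return Character vector of channel column names.
#' @export
channels <- function(embryo) {
  stopifnot(inherits(embryo, "embryo"))
  setdiff(names(embryo$nuclei),
          c("nucleus_id", "x", "y", "z", "ap_fraction", "dv_angle"))
}

#' Validate embryo invariants
#'
#' Checks that every channel has one finite non-negative value per nucleus,
#' that `ap_fraction` spans exactly `[0, 1]`, that `dv_angle` lies in
#' `[0, 2*pi)`, and that nucleus ids are unique. Called by [embryo()]; exported
#' so generated or hand-edited objects can be re-checked.
#'
#' @param x an [embryo] object.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_embryo <- function(x) {
  stopifnot(inherits(x, "embryo"))
  nuc <- x$nuclei
  chans <- channels(x)
  if (length(chans) == 0) stop("embryo has no expression channels", call. = FALSE)
  for (ch in chans) {
    v <- nuc[[ch]]
    if (!is.numeric(v) || length(v) != nrow(nuc)) {
      stop("channel '", ch, "' does not have one value per nucleus", call. = FALSE)
    }
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("channel '", ch, "' has non-finite or negative values", call. = FALSE)
    }
  }
  if (anyDuplicated(nuc$nucleus_id)) {
    stop("duplicate nucleus_id values within an embryo", call. = FALSE)
  }
  ap <- nuc$ap_fraction
  if (any(!is.finite(ap)) || min(ap) < -1e-12 || max(ap) > 1 + 1e-12 ||
      abs(min(ap)) > 1e-9 || abs(max(ap) - 1) > 1e-9) {
    stop("ap_fraction must span [0, 1] exactly within an embryo", call. = FALSE)
  }
  dv <- nuc$dv_angle
  if (any(dv < 0) || any(dv >= 2 * pi)) {
    stop("dv_angle must lie in [0, 2*pi)", call. = FALSE)
  }
  invisible(x)
}

reference_vector <- function(flag) {
  switch(flag,
    lowx = c(-1, 0, 0), highx = c(1, 0, 0),
    lowy = c(0, -1, 0), highy = c(0, 1, 0),
    lowz = c(0, 0, -1), highz = c(0, 0, 1),
    stop("unknown axis flag: ", flag, call. = FALSE)
  )
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# AP axis = leading principal component of the nuclear coordinates, oriented
# so the flagged anterior end projects to 0; dv angle measured in the residual
# plane from the flagged ventral direction, right-handed about the
# anterior->posterior axis.
derive_axes <- function(x, y, z, anterior = "lowx", ventral = "lowy") {
  xyz <- cbind(x, y, z)
  if (nrow(xyz) < 3) stop("need at least 3 nuclei to derive axes", call. = FALSE)
  ctr <- colMeans(xyz)
  X <- sweep(xyz, 2, ctr)
  a1 <- prcomp(X, center = FALSE, scale. = FALSE)$rotation[, 1]
  ant <- reference_vector(anterior)
  # a1 should point posterior: anterior reference must project negatively
  if (sum(a1 * ant) > 0) a1 <- -a1
  proj <- drop(X %*% a1)
  rng <- range(proj)
  if (diff(rng) <= 0) stop("degenerate point cloud: no extent along AP axis", call. = FALSE)
  ap <- (proj - rng[1]) / diff(rng)

  vref <- reference_vector(ventral)
  u <- vref - sum(vref * a1) * a1
  nu <- sqrt(sum(u^2))
  if (nu < 1e-8) stop("ventral reference is parallel to the AP axis", call. = FALSE)
  u <- u / nu
  w <- cross3(a1, u)
  resid <- X - outer(proj, a1)
  ang <- atan2(drop(resid %*% w), drop(resid %*% u))
  ang <- ang %% (2 * pi)
  list(ap_fraction = ap, dv_angle = ang)
}
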