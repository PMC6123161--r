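#' Overlap metrics against a consensus reference
#'
#' Jaccard similarity, sensitivity and specificity of an evaluated mask
#' `D` against a reference (consensus) mask `G`:
#' `Jaccard = |D n G| / |D u G|`, `sensitivity = |D n G| / |G|`,
#' `specificity = |Dc n Gc| / |Gc|`, with the complements counted inside
#' an evaluation domain (whole-grid complements saturate specificity, so
#' the domain is a per-organ box around the masks by default).
#'
#' @param D evaluated [mask3d()].
#' @param G reference [mask3d()] on the same grid.
#' @return fraction in `[0, 1]`; `jaccard` is defined as 1 when both
#'   masks are empty.
#' @export
jaccard <- function(D, G) {
  assert_same_grid(D, G)
  u <- sum(D$data | G$data)
  if (u == 0) return(1.0)
  sum(D$data & G$data) / u
}

#' @rdname jaccard
#' @export
sensitivity <- function(D, G) {
  assert_same_grid(D, G)
  g <- sum(G$data)
  if (g == 0) stop("undefined metric: sensitivity with empty reference G",
                   call. = FALSE)
  sum(D$data & G$data) / g
}

#' @rdname jaccard
#' @param domain an [evaluation_domain()] (logical array or `mask3d`)
#'   containing `D | G`, over which the complement of `G` is counted.
#' @export
specificity <- function(D, G, domain = evaluation_domain(D, G)) {
  assert_same_grid(D, G)
  dom <- if (inherits(domain, "mask3d")) domain$data else domain
  if (any((D$data | G$data) & !dom))
    stop("evaluation domain must contain D union G", call. = FALSE)
  gc <- dom & !G$data
  n_gc <- sum(gc)
  if (n_gc == 0) stop("undefined metric: specificity with empty complement of G",
                      call. = FALSE)
  sum(gc & !D$data) / n_gc
}

#' Evaluation domain for complement-based metrics
#'
#' Bounding box of `D | G`, dilated by a configurable margin (default 10
#' voxels in-plane and 2 slices), as a logical array.
#'
#' @param D,G masks on a shared grid.
#' @param dilate integer length-3 dilation in voxels per axis.
#' @return logical array of the grid dimension.
#' @export
evaluation_domain <- function(D, G, dilate = c(10L, 10L, 2L)) {
  assert_same_grid(D, G)
  u <- D$data | G$data
  dgrid <- dim(u)
  box <- mask_bbox(u)
  if (is.null(box)) return(array(TRUE, dgrid))
  bbox_to_mask(dilate_bbox(box, as.integer(dilate), dgrid), dgrid)
}

#' All three overlap metrics as one tidy row
#'
#' @inheritParams specificity
#' @param ... extra provenance columns (organ, phase, source, series,
#'   subject) appended to the row; defaults are taken from `D`'s tags.
#' @return one-row tibble with `jaccard`, `sensitivity`, `specificity`.
#' @export
sss_record <- function(D, G, domain = evaluation_domain(D, G), ...) {
  extra <- list(...)
  tag <- function(nm) {
    if (!is.null(extra[[nm]])) extra[[nm]]
    else if (!is.null(D[[nm]])) D[[nm]]
    else NA
  }
  tibble::tibble(organ = as.character(tag("organ") %||% NA_character_),
                 phase = as.integer(tag("phase") %||% NA_integer_),
                 source = as.character(tag("source") %||% NA_character_),
                 series = as.character(tag("series") %||% NA_character_),
                 jaccard = jaccard(D, G),
                 sensitivity = sensitivity(D, G),
                 specificity = specificity(D, G, domain))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Within-cycle volume variation, percent
#'
#' Sample standard deviation (n - 1) of the per-phase organ volumes
#' divided by their mean, times 100 -- the intra-observer variability
#' statistic for volume-conserving organs.
#'
#' @param volumes numeric vector of per-phase volumes (mm^3), length >= 2.
#' @return percent.
#' @export
volume_variation_pct <- function(volumes) {
  if (length(volumes) < 2)
    stop("need at least two phase volumes", call. = FALSE)
  m <- mean(volumes)
  if (!is.finite(m) || m <= 0)
    stop("volume mean must be positive", call. = FALSE)
  100 * sd(volumes) / m
}

#' Relative difference of averaged similarity between two observers
#'
#' `%S = 2 * (S_u1 - S_u2) / (S_u1 + S_u2) * 100`, the signed
#' inter-observer similarity-variation statistic.
#'
#' @param s_u1,s_u2 mean Jaccard similarity of users 1 and 2.
#' @return signed percent.
#' @export
similarity_relative_diff_pct <- function(s_u1, s_u2) {
  if ((s_u1 + s_u2) <= 0)
    stop("similarity sum must be positive", call. = FALSE)
  200 * (s_u1 - s_u2) / (s_u1 + s_u2)
}

#' Paired two-tailed Student's t-test with explicit degenerate-case rules
#'
#' Classical paired t-test on the per-subject differences. Two degenerate
#' cases are reported rather than erroring: an exact tie (`a == b`
#' elementwise) returns `p = 1` flagged `"tie"`; a constant nonzero shift
#' (zero difference variance) returns `t = +/-Inf`, `p = 0`, flagged
#' `"zero-variance-shift"`.
#'
#' @param a,b equal-length numeric vectors (length >= 2), paired by
#'   subject.
#' @return one-row tibble: `t`, `df`, `p`, `mean_diff`, `flag`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("a and b must have equal length >= 2", call. = FALSE)
  d <- a - b
  if (all(d == 0))
    return(tibble::tibble(t = 0, df = length(d) - 1L, p = 1,
                          mean_diff = 0, flag = "tie"))
  if (sd(d) == 0)
    return(tibble::tibble(t = sign(mean(d)) * Inf, df = length(d) - 1L,
                          p = 0, mean_diff = mean(d),
                          flag = "zero-variance-shift"))
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_diff = unname(tt$estimate),
                 flag = "ok")
}

# half-up (away from zero at .5) rounding, the convention of printed
# clinical tables; base round() rounds half to even
round_half_up <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Column mean and sample SD as printed in summary rows
#'
#' Arithmetic mean and sample (n - 1) standard deviation with half-up
#' rounding at the stated number of decimals, the arithmetic used in the
#' Average/Mean and SD rows of per-subject result tables. `NA` entries
#' (subjects with missing cells) are dropped.
#'
#' @param values numeric vector (at least 2 non-missing).
#' @param decimals decimals of the printed table.
#' @return one-row tibble: `n`, `mean`, `sd`, `mean_rounded`, `sd_rounded`.
#' @export
column_summary <- function(values, decimals = 2) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("need at least two values", call. = FALSE)
  tibble::tibble(n = length(v), mean = mean(v), sd = sd(v),
                 mean_rounded = round_half_up(mean(v), decimals),
                 sd_rounded = round_half_up(sd(v), decimals))
}
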