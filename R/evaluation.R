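# Registration quality metrics: Dice overlap, target registration error,
# robust (trimmed) aggregates, success rate, and per-case tables.

#' Dice similarity coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks give 1 by convention.
#'
#' @param a,b [label_mask()]s or 0/1 arrays of equal shape.
#' @return DSC in [0, 1].
#' @export
dsc <- function(a, b) {
  av <- if (inherits(a, "prostreg_mask")) a$data else a
  bv <- if (inherits(b, "prostreg_mask")) b$data else b
  if (!all(dim(av) == dim(bv))) stop("mask shapes differ")
  sa <- sum(av); sb <- sum(bv)
  if (sa + sb == 0) return(1.0)
  2 * sum(av * bv) / (sa + sb)
}

#' Target registration error (RMS landmark distance, mm)
#'
#' Voxel coordinates are converted to mm with the spacing; the error is the
#' root mean square over pairs of Euclidean distances between corresponding
#' landmarks (matched by id).
#'
#' @param fixed_lms,warped_lms [landmark_set()]s of equal cardinality.
#' @param spacing_mm voxel spacing (3 reals).
#' @return TRE in mm.
#' @export
tre <- function(fixed_lms, warped_lms, spacing_mm = c(1, 1, 1)) {
  if (length(fixed_lms$ids) != length(warped_lms$ids))
    stop("landmark sets differ in cardinality")
  ord <- match(fixed_lms$ids, warped_lms$ids)
  if (any(is.na(ord))) stop("landmark ids do not correspond")
  dp <- (fixed_lms$points - warped_lms$points[ord, , drop = FALSE]) *
    matrix(spacing_mm, nrow(fixed_lms$points), 3, byrow = TRUE)
  sqrt(mean(rowSums(dp^2)))
}

#' Robust (trimmed) aggregation of per-case metrics
#'
#' For DSC: mean of the best `keep_fraction` of cases; for TRE: mean of the
#' smallest-error `keep_fraction`.  `ceil(keep_fraction * n)` cases are kept.
#'
#' @param per_case numeric vector of per-case values.
#' @param kind "dsc" (keep largest) or "tre" (keep smallest).
#' @param keep_fraction fraction of cases kept (default 0.75).
#' @return robust mean.
#' @export
robust_aggregate <- function(per_case, kind = c("dsc", "tre"),
                             keep_fraction = 0.75) {
  kind <- match.arg(kind)
  if (length(per_case) == 0L) stop("empty metric list")
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  k <- ceiling(keep_fraction * length(per_case))
  s <- sort(per_case, decreasing = (kind == "dsc"))
  mean(s[seq_len(k)])
}

#' Registration success rate
#'
#' Fraction of cases with TRE below a threshold (default 5 mm).
#'
#' @param tre_list per-case TRE values in mm.
#' @param threshold_mm success threshold (default 5).
#' @return fraction in [0, 1].
#' @export
success_rate <- function(tre_list, threshold_mm = 5.0) {
  if (length(tre_list) == 0L) stop("empty TRE list")
  mean(tre_list < threshold_mm)
}

#' Per-case metrics and aggregates for a set of registered cases
#'
#' @param cases list; each element has `dsc`, `tre_mm`, `folding_fraction`
#'   and optionally `case_id`.
#' @param keep_fraction robust-aggregate trim (default 0.75).
#' @param threshold_mm success-rate threshold (default 5).
#' @return list with a per-case `data.frame` and an `aggregate` named vector
#'   (DSC, RDSC, TRE, RTRE, folding, success_rate).
#' @export
evaluate_cases <- function(cases, keep_fraction = 0.75, threshold_mm = 5.0) {
  df <- data.frame(
    case_id = vapply(seq_along(cases), function(i)
      as.character(cases[[i]]$case_id %||% i), ""),
    dsc = vapply(cases, function(x) x$dsc, 0),
    tre_mm = vapply(cases, function(x) x$tre_mm, 0),
    folding_fraction = vapply(cases, function(x) x$folding_fraction, 0))
  agg <- c(DSC = mean(df$dsc),
           RDSC = robust_aggregate(df$dsc, "dsc", keep_fraction),
           TRE = mean(df$tre_mm),
           RTRE = robust_aggregate(df$tre_mm, "tre", keep_fraction),
           folding = mean(df$folding_fraction),
           success_rate = success_rate(df$tre_mm, threshold_mm))
  list(per_case = df, aggregate = agg)
}
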