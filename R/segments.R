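# Segment-wise analysis of activation across the SCEF/8BM areal border.

#' Subjects x segments x contrasts table for an areal border
#'
#' Twenty ordered segments, posterior to anterior: 10 for the posterior
#' area (SCEF) then 10 for the anterior area (8BM), with the border fixed
#' between segments 10 and 11.
#'
#' @param beta Numeric array, subjects x 20 x contrasts, with dimnames.
#' @param segment_area Area label per segment (default 10x SCEF, 10x 8BM).
#' @param border_after Index of the last segment before the border (10).
#' @return A `segment_beta_table`.
#' @export
segment_beta_table <- function(beta,
                               segment_area = rep(c("SCEF", "8BM"), each = 10),
                               border_after = 10L) {
  if (!is.array(beta) || length(dim(beta)) != 3L)
    stop("beta must be a 3-d array (subjects x segments x contrasts)")
  n_seg <- dim(beta)[2]
  if (length(segment_area) != n_seg)
    stop("segment_area must have one label per segment")
  areas <- unique(segment_area)
  if (length(areas) != 2 ||
      !all(table(segment_area) == n_seg / 2))
    stop("expected exactly two areas with equal segment counts")
  if (is.null(dimnames(beta)))
    dimnames(beta) <- list(sprintf("sub%03d", seq_len(dim(beta)[1])),
                           segment_labels(), NULL)
  structure(beta, segment_area = segment_area,
            border_after = as.integer(border_after),
            class = c("segment_beta_table", "array"))
}

#' Group-mean activation profile along the border segments
#'
#' @param t A [segment_beta_table()].
#' @return Segments x contrasts matrix of subject-mean betas, preserving
#'   posterior-to-anterior order.
#' @export
segment_profile <- function(t) {
  stopifnot(inherits(t, "segment_beta_table"))
  apply(unclass(t), c(2, 3), mean)
}

#' Test whether each segment survives as an extended-MD region on its own
#'
#' Applies the same per-contrast criterion used for whole areas (one-sample
#' t against zero, positive mean, `P <= alpha/m`) to each segment, and
#' flags segments significant in all three contrasts.
#'
#' @param t A [segment_beta_table()].
#' @param alpha Significance level (default 0.05).
#' @param m Bonferroni count; defaults to the areal 180 so a segment is
#'   held to the same standard as a whole area.
#' @return data.frame with `segment`, `area`, per-contrast significance
#'   columns and the conjunction flag `significant`.
#' @export
segment_conjunction_test <- function(t, alpha = 0.05, m = 180L) {
  stopifnot(inherits(t, "segment_beta_table"))
  b <- beta_table(unclass(t),
                  hemisphere = rep("B", dim(t)[2]))
  contrasts <- dimnames(t)[[3]]
  per_contrast <- lapply(contrasts, function(cn)
    area_ttests(b, cn, alpha = alpha, m = m)$significant_positive)
  sig <- do.call(cbind, per_contrast)
  colnames(sig) <- paste0("sig_", contrasts)
  data.frame(segment = dimnames(t)[[2]],
             area = attr(t, "segment_area"),
             sig,
             significant = rowSums(sig) == length(contrasts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Combine significant border segments into one composite area
#'
#' Equal-weight mean over the significant segments, per subject and
#' contrast (delegates to [merge_areas()]). This is the rule that builds
#' the composite 8BM/SCEF area from the segments that individually survive
#' the extended-MD criterion.
#'
#' @param t A [segment_beta_table()].
#' @param flags Logical vector (one per segment) or the data.frame from
#'   [segment_conjunction_test()].
#' @param new_area Name for the composite (default `"8BM/SCEF"`).
#' @return Subjects x contrasts matrix of composite betas.
#' @export
composite_area <- function(t, flags, new_area = "8BM/SCEF") {
  stopifnot(inherits(t, "segment_beta_table"))
  if (is.data.frame(flags)) flags <- flags$significant
  if (length(flags) != dim(t)[2])
    stop("flags must have one entry per segment")
  if (!any(flags))
    stop("no significant segment: composite area would be empty")
  b <- beta_table(unclass(t), hemisphere = rep("B", dim(t)[2]))
  merged <- merge_areas(b, dimnames(t)[[2]][flags], new_area = new_area)
  out <- unclass(merged)[, new_area, ]
  matrix(out, dim(t)[1], dim(t)[3],
         dimnames = list(dimnames(t)[[1]], dimnames(t)[[3]]))
}
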