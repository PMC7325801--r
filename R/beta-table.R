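#' Subjects x areas x contrasts effect-size table
#'
#' The central task-fMRI container: a 3-d numeric array of parcel-averaged
#' GLM contrast effect sizes ("betas"), one value per subject, area and
#' contrast, with a hemisphere attribute per area. Areas may be
#' hemisphere-qualified parcels (`"L_i6-8"`, hemisphere `"L"`/`"R"`) or
#' hemisphere-averaged areas (hemisphere `"B"`).
#'
#' @param beta Numeric array, subjects x areas x contrasts, with dimnames.
#' @param hemisphere Character vector along the area dimension (`"L"`,
#'   `"R"` or `"B"`). If `NULL`, inferred from `"L_"`/`"R_"` area prefixes,
#'   defaulting to `"B"`.
#' @return A `beta_table` object.
#' @export
beta_table <- function(beta, hemisphere = NULL) {
  if (!is.array(beta) || length(dim(beta)) != 3L)
    stop("beta must be a 3-d array (subjects x areas x contrasts)")
  if (is.null(dimnames(beta)) || any(vapply(dimnames(beta), is.null, TRUE)))
    stop("beta must have complete dimnames")
  if (anyNA(beta)) stop("beta must not contain missing values")
  if (dim(beta)[1] < 2) stop("at least 2 subjects are required")
  areas <- dimnames(beta)[[2]]
  if (is.null(hemisphere)) {
    hemisphere <- rep("B", length(areas))
    hemisphere[startsWith(areas, "L_")] <- "L"
    hemisphere[startsWith(areas, "R_")] <- "R"
  }
  if (length(hemisphere) != length(areas))
    stop("hemisphere must have one entry per area")
  if (anyDuplicated(paste(hemisphere, areas)))
    stop("areas must be unique within hemisphere")
  structure(beta, hemisphere = hemisphere, class = c("beta_table", "array"))
}

#' @export
print.beta_table <- function(x, ...) {
  d <- dim(x)
  cat("beta_table: ", d[1], " subjects x ", d[2], " areas x ", d[3],
      " contrasts\n", sep = "")
  cat("  hemispheres:", paste(unique(attr(x, "hemisphere")), collapse = ", "),
      "\n")
  cat("  contrasts:  ", paste(dimnames(x)[[3]], collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.beta_table` <- function(x, i, j, k, drop = FALSE) {
  hemi <- attr(x, "hemisphere")
  out <- unclass(x)[i, j, k, drop = drop]
  if (is.array(out) && length(dim(out)) == 3L) {
    if (!missing(j)) {
      idx <- seq_along(dimnames(unclass(x))[[2]])
      names(idx) <- dimnames(unclass(x))[[2]]
      hemi <- hemi[idx[dimnames(out)[[2]]]]
    }
    return(beta_table(out, hemisphere = hemi))
  }
  out
}

#' @keywords internal
area_hemisphere <- function(b) {
  h <- attr(b, "hemisphere")
  names(h) <- dimnames(b)[[2]]
  h
}

#' Strip the hemisphere prefix from parcel ids
#' @keywords internal
base_area <- function(parcel) sub("^[LR]_", "", parcel)
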