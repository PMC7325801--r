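# TSV / JSON readers and writers. All numeric serialization uses 17
# significant digits so that write -> read round-trips doubles exactly.

#' @keywords internal
fmt_num <- function(x) sprintf("%.17g", x)

#' @keywords internal
check_fields <- function(path, n_expected) {
  cf <- utils::count.fields(path, sep = "\t", quote = "")
  bad <- which(cf != n_expected)
  if (length(bad) > 0)
    stop("malformed row in ", path, ": line ", bad[1], " has ",
         cf[bad[1]], " fields (expected ", n_expected, ")")
}

#' Write / read a beta table as long-format TSV
#'
#' Columns: `subject`, `hemisphere`, `area`, `contrast`, `beta`.
#'
#' @param b A [beta_table()].
#' @param path File path.
#' @return `read_beta_table` returns a [beta_table()]; the writer returns
#'   `path` invisibly.
#' @export
write_beta_table <- function(b, path) {
  stopifnot(inherits(b, "beta_table"))
  dn <- dimnames(b)
  hemi <- area_hemisphere(b)
  df <- expand.grid(subject = dn[[1]], area = dn[[2]], contrast = dn[[3]],
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$hemisphere <- unname(hemi[df$area])
  df$beta <- fmt_num(as.vector(unclass(b)))
  utils::write.table(df[, c("subject", "hemisphere", "area", "contrast",
                            "beta")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beta_table
#' @export
read_beta_table <- function(path) {
  check_fields(path, 5L)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "character", "character",
                                         "numeric"))
  needed <- c("subject", "hemisphere", "area", "contrast", "beta")
  if (!identical(names(df), needed))
    stop("expected columns ", paste(needed, collapse = ", "),
         " but found ", paste(names(df), collapse = ", "))
  if (anyNA(df$beta))
    stop("non-numeric beta at line ", which(is.na(df$beta))[1] + 1L)
  subjects <- unique(df$subject)
  areas <- unique(df$area)
  contrasts <- unique(df$contrast)
  arr <- array(NA_real_, dim = c(length(subjects), length(areas),
                                 length(contrasts)),
               dimnames = list(subjects, areas, contrasts))
  arr[cbind(match(df$subject, subjects), match(df$area, areas),
            match(df$contrast, contrasts))] <- df$beta
  if (anyNA(arr)) stop("incomplete table: missing subject/area/contrast cells")
  hemi <- df$hemisphere[match(areas, df$area)]
  beta_table(arr, hemisphere = hemi)
}

#' Write / read an FC matrix as dense TSV
#'
#' Dense matrix with a header row and a leading column of parcel ids. On
#' read, symmetry is validated to `tol` and the diagonal to 1.
#'
#' @param fc Square correlation matrix with parcel dimnames.
#' @param path File path.
#' @param tol Symmetry tolerance on read (default 1e-10).
#' @export
write_fc_matrix <- function(fc, path) {
  stopifnot(is.matrix(fc), nrow(fc) == ncol(fc))
  out <- cbind(parcel = rownames(fc),
               as.data.frame(matrix(fmt_num(fc), nrow(fc), ncol(fc),
                                    dimnames = dimnames(fc)),
                             check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fc_matrix
#' @export
read_fc_matrix <- function(path, tol = 1e-10) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (nrow(m) != ncol(m)) stop("FC matrix must be square")
  if (!identical(rownames(m), colnames(m)))
    stop("row and column parcel ids differ")
  asym <- max(abs(m - t(m)))
  if (asym > tol)
    stop("asymmetric FC matrix: max |r - t(r)| = ", format(asym),
         " exceeds tolerance ", format(tol))
  if (max(abs(diag(m) - 1)) > tol)
    stop("FC matrix diagonal must be 1")
  m
}

#' Write / read a subcortical voxel table as long-format TSV
#'
#' Columns: `voxel`, `structure`, `subject`, `contrast`, `beta`.
#'
#' @param v A [voxel_table()].
#' @param path File path.
#' @export
write_voxel_table <- function(v, path) {
  stopifnot(inherits(v, "voxel_table"))
  dn <- dimnames(v$beta)
  df <- expand.grid(subject = dn[[1]], voxel = dn[[2]], contrast = dn[[3]],
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$structure <- v$info$structure[match(df$voxel, v$info$voxel)]
  df$beta <- fmt_num(as.vector(v$beta))
  utils::write.table(df[, c("voxel", "structure", "subject", "contrast",
                            "beta")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_voxel_table
#' @export
read_voxel_table <- function(path) {
  check_fields(path, 5L)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "character", "character",
                                         "numeric"))
  needed <- c("voxel", "structure", "subject", "contrast", "beta")
  if (!identical(names(df), needed))
    stop("expected columns ", paste(needed, collapse = ", "))
  if (anyNA(df$beta))
    stop("non-numeric beta at line ", which(is.na(df$beta))[1] + 1L)
  voxels <- unique(df$voxel)
  subjects <- unique(df$subject)
  contrasts <- unique(df$contrast)
  arr <- array(NA_real_, dim = c(length(subjects), length(voxels),
                                 length(contrasts)),
               dimnames = list(subjects, voxels, contrasts))
  arr[cbind(match(df$subject, subjects), match(df$voxel, voxels),
            match(df$contrast, contrasts))] <- df$beta
  if (anyNA(arr)) stop("incomplete table: missing subject/voxel/contrast cells")
  info <- unique(df[, c("voxel", "structure")])
  rownames(info) <- NULL
  voxel_table(info = info, beta = arr)
}

#' Write a pipeline report (or any result list) as JSON
#'
#' @param results A list, e.g. from [run_pipeline()].
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
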