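# Manifest I/O: the manifest CSV is the unit of all dataset exchange.

manifest_cols <- c("path", "label", "is_synthetic", "mask_path")

#' Coerce a data frame to a manifest
#'
#' A manifest is a data frame with columns `path` (unique file paths),
#' `label` (class name), `is_synthetic` (logical; TRUE for rows created by
#' augmentation) and `mask_path` (optional ground-truth nucleus mask, NA if
#' absent). Extra columns (e.g. the augmentation-parameter log) are kept.
#'
#' @param df A data frame with at least `path` and `label`.
#' @return The data frame with class `c("manifest", "data.frame")`.
#' @export
as_manifest <- function(df) {
  stopifnot(is.data.frame(df))
  if (!all(c("path", "label") %in% names(df)))
    stop("a manifest needs 'path' and 'label' columns")
  if (!"is_synthetic" %in% names(df)) df$is_synthetic <- FALSE
  if (!"mask_path" %in% names(df)) df$mask_path <- NA_character_
  df$path <- as.character(df$path)
  df$label <- as.character(df$label)
  df$is_synthetic <- as.logical(df$is_synthetic)
  df$mask_path <- as.character(df$mask_path)
  if (anyDuplicated(df$path))
    stop("manifest paths must be unique")
  rownames(df) <- NULL
  class(df) <- unique(c("manifest", class(df)))
  df
}

#' Read a manifest CSV
#'
#' @param path CSV file with columns `path,label,is_synthetic,mask_path`
#'   (the last two optional).
#' @return A manifest data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  as_manifest(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a manifest CSV
#'
#' @param manifest A manifest data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- as_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Per-class row counts of a manifest
#'
#' @param manifest A manifest data frame.
#' @return Named integer vector of per-class counts.
#' @export
class_counts <- function(manifest) {
  manifest <- as_manifest(manifest)
  tab <- table(manifest$label)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.manifest <- function(x, ...) {
  cat(sprintf("Manifest: %d images, %d classes (%d synthetic)\n",
              nrow(x), length(unique(x$label)), sum(x$is_synthetic)))
  print(table(label = x$label, synthetic = x$is_synthetic))
  invisible(x)
}
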