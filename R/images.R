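# Image loading / resizing and label encoding.

#' Load an image as a `[0,1]` array
#'
#' Reads a PNG file, drops any alpha channel, replicates grayscale to three
#' channels and bilinearly resizes to `side x side`. Values are guaranteed
#' to stay within `[0, 1]`.
#'
#' @param path PNG file path.
#' @param side Target side in pixels (default 128, the standard training
#'   resolution); `NULL` keeps the native size.
#' @return Array `side x side x 3` in `[0, 1]`.
#' @export
load_image <- function(path, side = 128L) {
  if (!file.exists(path))
    stop(sprintf("cannot read image '%s': file not found", path))
  img <- tryCatch(png::readPNG(path), error = function(e)
    stop(sprintf("cannot decode image '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  d <- dim(img)
  if (is.null(d)) stop(sprintf("cannot decode image '%s'", path))
  if (length(d) == 2L) img <- array(rep(img, 3L), dim = c(d, 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1L)
    img <- array(rep(img, 3L), dim = c(dim(img)[1:2], 3L))
  if (!is.null(side)) {
    side <- check_count(side, "side", min = 1L)
    img <- bilinear_resize(img, side, side)
  }
  clip01(img)
}

# Load every image of a manifest into an H x W x 3 x B array.
load_manifest_images <- function(manifest, side) {
  manifest <- as_manifest(manifest)
  n <- nrow(manifest)
  out <- array(0, dim = c(side, side, 3L, n))
  for (i in seq_len(n)) out[, , , i] <- load_image(manifest$path[i], side)
  out
}

#' Fit a fixed label encoder
#'
#' Assigns integer codes `0..K-1` to class names by sorted lexicographic
#' order, so the encoding is stable across runs and machines.
#'
#' @param labels Character vector of observed class labels (non-empty).
#' @return An object of class `label_encoder` with elements `vocabulary`
#'   (sorted class names) and `codes` (named integer vector).
#' @seealso [encode_labels()]
#' @export
label_encoder <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("no labels supplied")
  vocab <- sort(unique(labels))
  structure(list(vocabulary = vocab,
                 codes = stats::setNames(seq_along(vocab) - 1L, vocab)),
            class = "label_encoder")
}

#' Encode class labels as stable integer codes
#'
#' @param labels Character vector to encode.
#' @param encoder Optional [label_encoder()]; by default one is fitted on
#'   `labels`. Labels outside the encoder's vocabulary are an error.
#' @return A list with `codes` (integer vector, 0-based) and `vocabulary`.
#' @examples
#' encode_labels(c("pre", "benign", "early", "pro"))$vocabulary
#' @export
encode_labels <- function(labels, encoder = NULL) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("no labels supplied")
  if (is.null(encoder)) encoder <- label_encoder(labels)
  stopifnot(inherits(encoder, "label_encoder"))
  unseen <- setdiff(unique(labels), encoder$vocabulary)
  if (length(unseen))
    stop("label(s) outside the encoder vocabulary: ",
         paste(unseen, collapse = ", "))
  list(codes = unname(encoder$codes[labels]),
       vocabulary = encoder$vocabulary)
}
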