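# Class-aware augmentation balancing: plan deficits against the majority
# class, then synthesize augmented copies of minority-class images.

#' Plan class balancing against the majority class
#'
#' Computes, for each class, how many synthetic (augmented) images are
#' needed to bring it up to the size of the largest class. The majority
#' class has deficit zero by construction.
#'
#' @param class_counts Named integer vector (or named list) of per-class
#'   image counts, all >= 1.
#' @return An object of class `augment_plan`: a list with `target_count`
#'   (the majority-class count) and `per_class_deficit` (named integer
#'   vector).
#' @examples
#' plan_balance(c(benign = 504, early = 985, pre = 963, pro = 804))
#' @export
plan_balance <- function(class_counts) {
  counts <- unlist(class_counts)
  if (length(counts) < 1L) stop("at least one class is required")
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("class counts must be named")
  if (anyDuplicated(names(counts))) stop("duplicate class names")
  counts <- vapply(counts, check_count, integer(1), field = "class_counts")
  target <- max(counts)
  structure(list(target_count = target,
                 per_class_deficit = target - counts),
            class = "augment_plan")
}

#' @export
print.augment_plan <- function(x, ...) {
  cat(sprintf("Balance plan: target %d images per class\n", x$target_count))
  for (cl in names(x$per_class_deficit))
    cat(sprintf("  %-12s +%d synthetic\n", cl, x$per_class_deficit[[cl]]))
  invisible(x)
}

#' Augmentation parameters
#'
#' One draw of the augmentation transform applied to minority-class images:
#' rotation up to +/-30 degrees, zoom up to +/-20%, optional horizontal
#' flip, and a multiplicative brightness factor between 0.8 and 1.2.
#'
#' @param rotation_deg Rotation in degrees, in `[-30, 30]`.
#' @param zoom_frac Zoom fraction in `[-0.2, 0.2]` (positive zooms in).
#' @param hflip Logical; mirror horizontally.
#' @param brightness_factor Multiplicative brightness in `[0.8, 1.2]`.
#' @return An object of class `augment_params`.
#' @export
augment_params <- function(rotation_deg = 0, zoom_frac = 0, hflip = FALSE,
                           brightness_factor = 1) {
  check_range(rotation_deg, "rotation_deg", -30, 30)
  check_range(zoom_frac, "zoom_frac", -0.2, 0.2)
  check_flag(hflip, "hflip")
  check_range(brightness_factor, "brightness_factor", 0.8, 1.2)
  structure(list(rotation_deg = rotation_deg, zoom_frac = zoom_frac,
                 hflip = hflip, brightness_factor = brightness_factor),
            class = "augment_params")
}

#' Sample augmentation parameters uniformly within their ranges
#'
#' @return An [augment_params()] object drawn from the current RNG stream.
#' @export
sample_augment_params <- function() {
  augment_params(rotation_deg = runif(1, -30, 30),
                 zoom_frac = runif(1, -0.2, 0.2),
                 hflip = runif(1) < 0.5,
                 brightness_factor = runif(1, 0.8, 1.2))
}

#' Apply an augmentation transform to an image
#'
#' Rotation and zoom are performed about the image centre in a single
#' bilinear resampling pass with reflect padding (so no black corners are
#' introduced for the model to shortcut on); the horizontal flip is exact;
#' brightness is multiplicative with clipping to `[0, 1]`.
#'
#' @param image Array `H x W` or `H x W x C` with values in `[0, 1]`.
#' @param p An [augment_params()] object.
#' @param interpolate `"bilinear"` (default) or `"nearest"` (used for
#'   masks, which must stay binary).
#' @return Augmented image, same shape, clipped to `[0, 1]`.
#' @export
augment_image <- function(image, p, interpolate = c("bilinear", "nearest")) {
  interpolate <- match.arg(interpolate)
  if (!inherits(p, "augment_params")) p <- do.call(augment_params, p)
  d <- dim(image)
  if (is.null(d) || length(d) < 2L) stop("image must be a matrix or array")
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9)
    stop("image values must lie in [0, 1]")
  h <- d[1]; w <- d[2]
  nc <- if (length(d) >= 3L) d[3] else 1L
  m <- array(image, dim = c(h, w, nc))
  if (p$hflip) m <- m[, rev(seq_len(w)), , drop = FALSE]
  theta <- p$rotation_deg * pi / 180
  scale <- 1 + p$zoom_frac
  if (abs(theta) > 0 || abs(p$zoom_frac) > 0) {
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    yy <- matrix(rep(seq_len(h), times = w), h, w) - cy
    xx <- matrix(rep(seq_len(w), each = h), h, w) - cx
    # inverse map: rotate by -theta, divide by scale
    sx <- (cos(theta) * xx + sin(theta) * yy) / scale + cx - 1
    sy <- (-sin(theta) * xx + cos(theta) * yy) / scale + cy - 1
    if (interpolate == "nearest") {
      iy <- reflect_index(round(sy), h) + 1
      ix <- reflect_index(round(sx), w) + 1
      idx <- cbind(as.vector(iy), as.vector(ix))
      for (c in seq_len(nc)) m[, , c] <- matrix(m[, , c][idx], h, w)
    } else {
      y0 <- floor(sy); x0 <- floor(sx)
      wy <- sy - y0; wx <- sx - x0
      iy0 <- reflect_index(y0, h) + 1; iy1 <- reflect_index(y0 + 1, h) + 1
      ix0 <- reflect_index(x0, w) + 1; ix1 <- reflect_index(x0 + 1, w) + 1
      i00 <- cbind(as.vector(iy0), as.vector(ix0))
      i10 <- cbind(as.vector(iy1), as.vector(ix0))
      i01 <- cbind(as.vector(iy0), as.vector(ix1))
      i11 <- cbind(as.vector(iy1), as.vector(ix1))
      w00 <- as.vector((1 - wy) * (1 - wx)); w10 <- as.vector(wy * (1 - wx))
      w01 <- as.vector((1 - wy) * wx);       w11 <- as.vector(wy * wx)
      for (c in seq_len(nc)) {
        pl <- m[, , c]
        m[, , c] <- matrix(pl[i00] * w00 + pl[i10] * w10 +
                             pl[i01] * w01 + pl[i11] * w11, h, w)
      }
    }
  }
  if (interpolate == "bilinear") m <- clip01(m * p$brightness_factor)
  out <- if (length(d) == 2L) m[, , 1] else m
  out
}

#' Apply a balance plan to a manifest
#'
#' Creates `per_class_deficit[c]` synthetic rows per class. Source images
#' are chosen by a seeded shuffle of the class's original rows followed by
#' round-robin assignment, so every original is used once before any
#' repeats; augmentation parameters are freshly sampled per synthetic
#' image and logged in the returned manifest (columns `aug_rotation_deg`,
#' `aug_zoom_frac`, `aug_hflip`, `aug_brightness`, `source_path`).
#'
#' With `materialize = TRUE` the augmented pixels (and, when the source row
#' has a mask, the geometrically co-transformed mask) are written under
#' `out_dir/<class>/`; with `materialize = FALSE` (plan-only mode) only the
#' manifest is constructed, which is enough for count-level analyses and
#' runs in milliseconds.
#'
#' @param manifest A manifest data frame.
#' @param plan An [plan_balance()] result consistent with the manifest's
#'   class counts.
#' @param seed Integer seed for source shuffling and parameter sampling.
#' @param out_dir Output directory for materialized images (required when
#'   `materialize = TRUE`).
#' @param materialize Write augmented pixels to disk? Default `FALSE`.
#' @return The balanced manifest: `target_count` rows per class, original
#'   rows first.
#' @examples
#' man <- data.frame(path = sprintf("im%d.png", 1:5),
#'                   label = c("a", "a", "a", "b", "b"))
#' plan <- plan_balance(class_counts(as_manifest(man)))
#' nrow(apply_balance(as_manifest(man), plan, seed = 1))  # 6
#' @export
apply_balance <- function(manifest, plan, seed = 1L, out_dir = NULL,
                          materialize = FALSE) {
  manifest <- as_manifest(manifest)
  stopifnot(inherits(plan, "augment_plan"))
  counts <- class_counts(manifest)
  if (!setequal(names(counts), names(plan$per_class_deficit)))
    stop("plan classes do not match manifest classes")
  for (cl in names(counts))
    if (counts[[cl]] + plan$per_class_deficit[[cl]] != plan$target_count)
      stop("plan inconsistent with manifest counts for class ", cl)
  if (materialize && is.null(out_dir))
    stop("'out_dir' is required when materialize = TRUE")
  aug_cols <- c("aug_rotation_deg", "aug_zoom_frac", "aug_hflip",
                "aug_brightness", "source_path")
  base <- manifest
  new_rows <- list()
  for (cl in sort(names(counts))) {
    deficit <- plan$per_class_deficit[[cl]]
    if (deficit == 0L) next
    cls_rows <- manifest[manifest$label == cl, , drop = FALSE]
    ord <- with_seed(derive_seed(seed, match(cl, sort(names(counts)))),
                     sample.int(nrow(cls_rows)))
    if (materialize)
      dir.create(file.path(out_dir, cl), recursive = TRUE,
                 showWarnings = FALSE)
    for (j in seq_len(deficit)) {
      src <- cls_rows[ord[(j - 1L) %% nrow(cls_rows) + 1L], , drop = FALSE]
      p <- with_seed(derive_seed(seed, 100000L + j +
                                   deficit * match(cl, sort(names(counts)))),
                     sample_augment_params())
      new_path <- file.path(if (is.null(out_dir)) dirname(src$path) else
        file.path(out_dir, cl), sprintf("%s_aug_%05d.png", cl, j))
      new_mask <- NA_character_
      if (materialize) {
        img <- load_image(src$path, side = NULL)
        png::writePNG(augment_image(img, p), new_path)
        if (!is.na(src$mask_path)) {
          mk <- load_image(src$mask_path, side = NULL)
          if (length(dim(mk)) == 3L) mk <- mk[, , 1]
          geo <- augment_params(p$rotation_deg, p$zoom_frac, p$hflip, 1)
          new_mask <- file.path(out_dir, cl,
                                sprintf("%s_aug_%05d_mask.png", cl, j))
          png::writePNG(round(augment_image(mk, geo, "nearest")), new_mask)
        }
      }
      row <- src
      row$path <- new_path
      row$is_synthetic <- TRUE
      row$mask_path <- new_mask
      row$aug_rotation_deg <- p$rotation_deg
      row$aug_zoom_frac <- p$zoom_frac
      row$aug_hflip <- p$hflip
      row$aug_brightness <- p$brightness_factor
      row$source_path <- src$path
      new_rows[[length(new_rows) + 1L]] <- row
    }
  }
  if (length(new_rows)) {
    for (col in aug_cols) if (!col %in% names(base))
      base[[col]] <- if (col == "aug_hflip") NA else
        if (col == "source_path") NA_character_ else NA_real_
    add <- do.call(rbind, new_rows)
    out <- rbind(base, add[names(base)])
  } else out <- base
  as_manifest(out)
}
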