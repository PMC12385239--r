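#' Morphological parameters of a synthetic blood cell
#'
#' Bundles the parameters the renderer uses to draw a single stained white
#' blood cell: nucleus size, chromatin texture, nucleus-to-cytoplasm ratio,
#' stain hue and slide background level. These are the cytomorphological
#' cues (nucleus size, chromatin granularity, N:C ratio) that distinguish
#' leukemic maturation stages on a peripheral blood smear.
#'
#' @param nucleus_radius_frac Nucleus radius as a fraction of the image side,
#'   in `[0, 0.5)`. `0` draws no nucleus at all.
#' @param chromatin_granularity Amplitude (>= 0) of the speckle noise added
#'   inside the nucleus, emulating chromatin texture coarseness.
#' @param nc_ratio Nucleus-to-cytoplasm area ratio proxy in `(0, 1]`; the
#'   cytoplasm disc is scaled so that nucleus_area / cytoplasm_area equals
#'   this value (capped so the cell fits in the frame).
#' @param stain_hue Stain tint in `[0, 1]`: 0 = reddish-pink (eosin-like),
#'   1 = deep blue-purple (basophilic).
#' @param background_level Background brightness in `[0, 1]`.
#' @return An object of class `cell_params`.
#' @examples
#' cell_params(nucleus_radius_frac = 0.25)
#' @export
cell_params <- function(nucleus_radius_frac = 0.2,
                        chromatin_granularity = 0.05,
                        nc_ratio = 0.5,
                        stain_hue = 0.7,
                        background_level = 0.9) {
  check_range(nucleus_radius_frac, "nucleus_radius_frac", 0, 0.5,
              hi_open = TRUE)
  check_range(chromatin_granularity, "chromatin_granularity", 0, Inf)
  check_range(nc_ratio, "nc_ratio", 0, 1, lo_open = TRUE)
  check_range(stain_hue, "stain_hue", 0, 1)
  check_range(background_level, "background_level", 0, 1)
  structure(list(nucleus_radius_frac = nucleus_radius_frac,
                 chromatin_granularity = chromatin_granularity,
                 nc_ratio = nc_ratio,
                 stain_hue = stain_hue,
                 background_level = background_level),
            class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat("Synthetic cell parameters:\n")
  for (f in names(x)) cat(sprintf("  %-22s %g\n", f, x[[f]]))
  invisible(x)
}

# Stain colours: interpolate between eosin-pink and basophilic purple.
stain_colours <- function(hue) {
  pink <- c(0.94, 0.55, 0.65)
  purple <- c(0.45, 0.25, 0.70)
  cyto <- (1 - hue) * pink + hue * purple
  nucleus <- cyto * 0.45 + c(0.10, 0.02, 0.22) * 0.55
  list(cyto = cyto, nucleus = nucleus)
}

#' Render one synthetic blood-smear cell
#'
#' Draws a single cell as layered discs: a pale background, an elliptical
#' cytoplasm, and a nucleus disc carrying additive chromatin speckle noise.
#' The nucleus pixels are returned as a ground-truth binary mask so that
#' attribution maps can be scored against a known salient region.
#'
#' @param params A [cell_params()] object.
#' @param side Image side in pixels (>= 16).
#' @param seed Integer seed; the image is a pure function of
#'   `(params, side, seed)`.
#' @return A list with `image` (array `side x side x 3` in `[0,1]`) and
#'   `mask` (integer matrix `side x side`, 1 on nucleus pixels).
#' @examples
#' cell <- render_cell(cell_params(nucleus_radius_frac = 0.25), side = 64,
#'                     seed = 1)
#' mean(cell$mask)  # nucleus area fraction
#' @export
render_cell <- function(params, side = 64L, seed = 1L) {
  if (!inherits(params, "cell_params")) params <- do.call(cell_params, params)
  side <- check_count(side, "side", min = 16L)
  with_seed(seed, {
    cx <- (side + 1) / 2 + runif(1, -0.05, 0.05) * side
    cy <- (side + 1) / 2 + runif(1, -0.05, 0.05) * side
    xs <- matrix(rep(seq_len(side), each = side), side, side)  # column index
    ys <- matrix(rep(seq_len(side), times = side), side, side) # row index
    r_nuc <- params$nucleus_radius_frac * side
    # cytoplasm area = nucleus area / nc_ratio; cap so the cell fits
    r_cyto <- if (r_nuc > 0) r_nuc / sqrt(params$nc_ratio) else 0.38 * side
    r_cyto <- min(r_cyto, 0.47 * side)
    elong <- runif(1, 0.85, 1.15)
    theta <- runif(1, 0, pi)
    dx <- xs - cx; dy <- ys - cy
    u <- cos(theta) * dx + sin(theta) * dy
    v <- -sin(theta) * dx + cos(theta) * dy
    cyto <- (u / (r_cyto * elong))^2 + (v / (r_cyto / elong))^2 <= 1
    nucleus <- if (r_nuc > 0) (dx^2 + dy^2) <= r_nuc^2 else
      matrix(FALSE, side, side)
    nucleus <- nucleus & cyto | nucleus  # nucleus always counts even at edge
    cols <- stain_colours(params$stain_hue)
    img <- array(0, dim = c(side, side, 3))
    bg_noise <- matrix(rnorm(side * side, 0, 0.01), side, side)
    for (c in 1:3) {
      plane <- params$background_level + bg_noise
      plane[cyto] <- cols$cyto[c] +
        rnorm(sum(cyto), 0, 0.015)
      if (any(nucleus)) {
        speck <- rnorm(sum(nucleus), 0, params$chromatin_granularity)
        plane[nucleus] <- cols$nucleus[c] + speck
      }
      img[, , c] <- clip01(plane)
    }
    list(image = img, mask = matrix(as.integer(nucleus), side, side))
  })
}

#' Specify a synthetic smear dataset
#'
#' A dataset specification names the classes, the number of images per
#' class, the image side, and a per-class distribution (mean and spread) of
#' [cell_params()] fields. The same spec and seed always regenerate
#' byte-identical images: each image draws from its own RNG stream derived
#' from `(seed, image index)`, so generation order is immaterial.
#'
#' @param class_names Character vector of unique class labels.
#' @param counts Integer vector (same length) of images per class.
#' @param image_side Image side in pixels (default 64; the renderer supports
#'   up to 128).
#' @param class_morphology Named list mapping each class to a list with
#'   `mean` (a [cell_params()] or plain list) and `sd` (named numeric vector
#'   of per-field spreads). Defaults to [all_morphology()] truncated to the
#'   number of classes.
#' @param seed Integer seed.
#' @return An object of class `smear_spec`.
#' @seealso [generate_dataset()], [all_morphology()]
#' @export
smear_spec <- function(class_names, counts, image_side = 64L,
                       class_morphology = NULL, seed = 1L) {
  if (length(class_names) < 1L) stop("at least one class is required")
  if (anyDuplicated(class_names)) stop("duplicate class names")
  if (length(counts) != length(class_names))
    stop("'counts' must have one entry per class")
  counts <- vapply(counts, check_count, integer(1), field = "counts")
  image_side <- check_count(image_side, "image_side", min = 16L)
  if (image_side > 128L) stop_field("image_side", "must be <= 128")
  if (is.null(class_morphology)) {
    base <- all_morphology()
    if (length(class_names) > length(base))
      stop("supply 'class_morphology' for more than ", length(base),
           " classes")
    class_morphology <- stats::setNames(base[seq_along(class_names)],
                                        class_names)
  }
  missing <- setdiff(class_names, names(class_morphology))
  if (length(missing))
    stop("missing morphology for class(es): ", paste(missing, collapse = ", "))
  structure(list(class_names = as.character(class_names),
                 counts = stats::setNames(as.integer(counts), class_names),
                 image_side = image_side,
                 class_morphology = class_morphology,
                 seed = as.integer(seed)),
            class = "smear_spec")
}

#' Default four-stage morphology ladder
#'
#' Morphology distributions for a four-class dataset emulating the benign /
#' early / pre / pro maturation ladder: nucleus size, chromatin granularity
#' and N:C ratio all increase from the benign profile to the most immature
#' blast profile. Stain hue and background are drawn from the same
#' distribution for every class: the classes differ in morphology only, so
#' a classifier cannot shortcut on colour and attribution maps are forced
#' onto the nucleus region the masks certify. The real datasets publish no
#' quantitative per-subtype morphology, so these values are the package's
#' own choices, picked to be visually plausible and machine-separable.
#'
#' @return Named list of four morphology distributions (each a list with
#'   `mean` and `sd`).
#' @export
all_morphology <- function() {
  mk <- function(r, g, nc) {
    list(mean = list(nucleus_radius_frac = r, chromatin_granularity = g,
                     nc_ratio = nc, stain_hue = 0.65,
                     background_level = 0.92),
         sd = c(nucleus_radius_frac = 0.015, chromatin_granularity = 0.01,
                nc_ratio = 0.04, stain_hue = 0.05, background_level = 0.02))
  }
  list(benign = mk(0.12, 0.02, 0.30),
       early  = mk(0.18, 0.05, 0.45),
       pre    = mk(0.25, 0.08, 0.62),
       pro    = mk(0.32, 0.12, 0.80))
}

# Draw one cell_params from a class morphology distribution.
sample_cell_params <- function(morph) {
  m <- morph$mean; s <- morph$sd
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  cell_params(
    nucleus_radius_frac = clamp(rnorm(1, m$nucleus_radius_frac,
                                      s[["nucleus_radius_frac"]]), 0, 0.45),
    chromatin_granularity = max(rnorm(1, m$chromatin_granularity,
                                      s[["chromatin_granularity"]]), 0),
    nc_ratio = clamp(rnorm(1, m$nc_ratio, s[["nc_ratio"]]), 0.05, 1),
    stain_hue = clamp(rnorm(1, m$stain_hue, s[["stain_hue"]]), 0, 1),
    background_level = clamp(rnorm(1, m$background_level,
                                   s[["background_level"]]), 0.5, 1))
}

#' Generate a synthetic smear dataset on disk
#'
#' Writes `counts[c]` PNG images per class into per-class subfolders of
#' `out_dir` (masks under `out_dir/masks/`) and returns the manifest. The
#' manifest has columns `path, label, is_synthetic, mask_path`; generated
#' cells are real dataset stand-ins, so `is_synthetic` is `FALSE` here and
#' reserved for augmentation-derived rows.
#'
#' @param spec A [smear_spec()].
#' @param out_dir Output directory (created if missing).
#' @param write_manifest Write `manifest.csv` into `out_dir` (default TRUE).
#' @return The manifest `data.frame`, invisibly classed as written by
#'   [read_manifest()].
#' @examples
#' \donttest{
#' spec <- smear_spec(c("benign", "pro"), c(3, 3), image_side = 32)
#' man <- generate_dataset(spec, tempfile("smears"))
#' table(man$label)
#' }
#' @export
generate_dataset <- function(spec, out_dir, write_manifest = TRUE) {
  stopifnot(inherits(spec, "smear_spec"))
  if (any(spec$counts < 1L)) stop("all class counts must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mask_dir <- file.path(out_dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  rows <- vector("list", sum(spec$counts))
  idx <- 0L
  for (cl in spec$class_names) {
    cls_dir <- file.path(out_dir, cl)
    dir.create(cls_dir, showWarnings = FALSE)
    morph <- spec$class_morphology[[cl]]
    for (i in seq_len(spec$counts[[cl]])) {
      idx <- idx + 1L
      img_seed <- derive_seed(spec$seed, idx)
      p <- with_seed(img_seed, sample_cell_params(morph))
      cell <- render_cell(p, side = spec$image_side,
                          seed = derive_seed(img_seed, 1L))
      path <- file.path(cls_dir, sprintf("%s_%04d.png", cl, i))
      mpath <- file.path(mask_dir, sprintf("%s_%04d_mask.png", cl, i))
      png::writePNG(cell$image, path)
      png::writePNG(cell$mask + 0, mpath)  # PNG writer wants doubles
      rows[[idx]] <- data.frame(path = path, label = cl,
                                is_synthetic = FALSE, mask_path = mpath,
                                stringsAsFactors = FALSE)
    }
  }
  man <- do.call(rbind, rows)
  man <- as_manifest(man)
  if (write_manifest)
    write_manifest(man, file.path(out_dir, "manifest.csv"))
  man
}
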