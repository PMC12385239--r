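# Internal helpers: validation, seeding, resampling.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_range <- function(x, field, lo, hi, lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  bad_lo <- if (lo_open) x <= lo else x < lo
  bad_hi <- if (hi_open) x >= hi else x > hi
  if (bad_lo || bad_hi)
    stop_field(field, sprintf("must lie in %s%g, %g%s (got %g)",
                              if (lo_open) "(" else "[", lo, hi,
                              if (hi_open) ")" else "]", x))
  invisible(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_field(field, "must be TRUE or FALSE")
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min)
    stop_field(field, sprintf("must be an integer >= %d", min))
  invisible(as.integer(x))
}

# Derive a per-item RNG seed from a base seed and an index so that item
# streams are independent of generation order. Kept below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + as.double(index) * 7919) %%
               2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Bilinear resampling of an H x W (x C) array to new spatial size.
# Half-pixel-centre convention; edge clamped.
bilinear_resize <- function(img, out_h, out_w) {
  d <- dim(img)
  if (is.null(d)) stop("image must be a matrix or array")
  in_h <- d[1]; in_w <- d[2]
  nc <- if (length(d) >= 3L) d[3] else 1L
  if (in_h == out_h && in_w == out_w) return(img)
  sy <- in_h / out_h; sx <- in_w / out_w
  yy <- pmin(pmax((seq_len(out_h) - 0.5) * sy - 0.5, 0), in_h - 1)
  xx <- pmin(pmax((seq_len(out_w) - 0.5) * sx - 0.5, 0), in_w - 1)
  y0 <- floor(yy); x0 <- floor(xx)
  y1 <- pmin(y0 + 1, in_h - 1); x1 <- pmin(x0 + 1, in_w - 1)
  wy <- yy - y0; wx <- xx - x0
  m <- array(img, dim = c(in_h, in_w, nc))
  out <- array(0, dim = c(out_h, out_w, nc))
  i00 <- outer(y0 + 1, in_h * x0, "+")
  i10 <- outer(y1 + 1, in_h * x0, "+")
  i01 <- outer(y0 + 1, in_h * x1, "+")
  i11 <- outer(y1 + 1, in_h * x1, "+")
  w00 <- outer(1 - wy, 1 - wx); w10 <- outer(wy, 1 - wx)
  w01 <- outer(1 - wy, wx);     w11 <- outer(wy, wx)
  for (c in seq_len(nc)) {
    plane <- m[, , c]
    out[, , c] <- plane[i00] * w00 + plane[i10] * w10 +
      plane[i01] * w01 + plane[i11] * w11
  }
  if (length(d) == 2L) out[, , 1] else out
}

# Reflect an index vector (0-based, real-valued) into [0, n-1].
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(0, length(i)))
  p <- 2 * (n - 1)
  i <- i %% p
  i[i > (n - 1)] <- p - i[i > (n - 1)]
  i
}

softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}
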