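# Slide preprocessing: tissue foreground detection on a thumbnail via HSV
# saturation thresholding, enumeration of the non-overlapping 896 x 896 patch
# grid at level 0 (40x), and patch encoding behind a pluggable encoder.

#' Detect tissue foreground by saturation thresholding
#'
#' Converts the thumbnail to HSV, median-filters the saturation channel
#' (0-255 scale) with a square window of the given radius, and keeps pixels
#' whose blurred saturation exceeds the threshold. White/grey background has
#' near-zero saturation while stained tissue saturates strongly, which is what
#' makes this simple rule effective on resection slides.
#'
#' @param thumbnail `h x w x 3` RGB array, values 0-255.
#' @param sat_threshold Saturation cut on the 0-255 scale (default 8).
#' @param median_radius Median filter radius in pixels (default 2, a 5x5 window).
#' @param downsample_factor Level-0 pixels per thumbnail pixel (metadata).
#' @return A `tissue_mask`: list with `mask` (0/1 matrix, thumbnail shape) and
#'   `downsample_factor`.
#' @export
detect_tissue <- function(thumbnail, sat_threshold = 8, median_radius = 2,
                          downsample_factor = 1) {
  assert_that(length(dim(thumbnail)) == 3L && all(dim(thumbnail)[1:2] > 0),
              "thumbnail must be a non-empty h x w x 3 array")
  r <- thumbnail[, , 1]; g <- thumbnail[, , 2]; b <- thumbnail[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  sat <- ifelse(mx > 0, (mx - mn) / mx * 255, 0)
  sat <- median_filter(sat, median_radius)
  structure(
    list(mask = matrix(as.integer(sat > sat_threshold), nrow(sat), ncol(sat)),
         downsample_factor = downsample_factor),
    class = "tissue_mask"
  )
}

# Median filter with replicate padding; window = (2r+1)^2.
median_filter <- function(x, radius) {
  if (radius < 1) return(x)
  h <- nrow(x); w <- ncol(x)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  stack <- matrix(0, nrow = h * w, ncol = nrow(offs))
  idx_r <- function(d) pmin(pmax(seq_len(h) + d, 1L), h)
  idx_c <- function(d) pmin(pmax(seq_len(w) + d, 1L), w)
  for (k in seq_len(nrow(offs))) {
    stack[, k] <- x[idx_r(offs$dy[k]), idx_c(offs$dx[k])]
  }
  matrix(apply(stack, 1L, stats::median), h, w)
}

#' Enumerate the non-overlapping patch grid over tissue
#'
#' Patches are axis-aligned `patch_size x patch_size` half-open rectangles
#' `[x, x + size) x [y, y + size)` in 0-based level-0 coordinates, enumerated
#' row-major. A patch is kept when its tissue coverage — the area-weighted
#' fraction of mask pixels under its footprint — reaches `min_tissue_frac`.
#'
#' @param mask A `tissue_mask` from [detect_tissue()] (or ground truth).
#' @param slide_dims `c(width, height)` in level-0 pixels.
#' @param patch_size Patch edge at level 0 (default 896, the 40x convention).
#' @param min_tissue_frac Minimum tissue coverage in `[0, 1]` (default 0.5).
#' @return A `patch_grid`: data.frame with columns `x`, `y` plus attributes
#'   `patch_size`, `slide_dims`, `slide_id`.
#' @export
enumerate_patches <- function(mask, slide_dims, patch_size = 896,
                              min_tissue_frac = 0.5, slide_id = "slide") {
  stopifnot(inherits(mask, "tissue_mask"))
  ds <- mask$downsample_factor
  w <- slide_dims[1]; h <- slide_dims[2]
  if (w < patch_size || h < patch_size) {
    xs <- ys <- numeric(0)   # patch larger than slide: empty grid, not an error
  } else {
    xs <- seq(0, w - patch_size, by = patch_size)
    ys <- seq(0, h - patch_size, by = patch_size)
  }
  keep <- list()
  for (y in ys) for (x in xs) {
    if (patch_coverage(mask$mask, ds, x, y, patch_size) >= min_tissue_frac) {
      keep[[length(keep) + 1L]] <- c(x, y)
    }
  }
  grid <- if (length(keep)) {
    as.data.frame(do.call(rbind, keep)) |> stats::setNames(c("x", "y"))
  } else {
    data.frame(x = numeric(0), y = numeric(0))
  }
  structure(grid, patch_size = patch_size, slide_dims = slide_dims,
            slide_id = slide_id, class = c("patch_grid", "data.frame"))
}

# Exact area-weighted tissue fraction of the level-0 footprint
# [x, x+size) x [y, y+size) against a mask at `ds` level-0 px per mask px.
patch_coverage <- function(mask, ds, x, y, size) {
  j0 <- floor(x / ds); j1 <- floor((x + size - 1) / ds)
  i0 <- floor(y / ds); i1 <- floor((y + size - 1) / ds)
  j1 <- min(j1, ncol(mask) - 1L); i1 <- min(i1, nrow(mask) - 1L)
  if (j0 > j1 || i0 > i1) return(0)
  wj <- pmin((j0:j1 + 1) * ds, x + size) - pmax((j0:j1) * ds, x)
  wi <- pmin((i0:i1 + 1) * ds, y + size) - pmax((i0:i1) * ds, y)
  sub <- mask[(i0:i1) + 1L, (j0:j1) + 1L, drop = FALSE]
  sum(sub * (wi %o% wj)) / (size * size)
}

#' Toy patch encoder: seeded random projection of a color histogram
#'
#' Computes the joint 8x8x8 RGB histogram (512 bins, L1-normalized) of a patch
#' and projects it with a fixed Gaussian matrix drawn once from `seed`. It is
#' deterministic, distinguishes color-distinct patches, and honors the encoder
#' contract (`$dim`, `$encode(patch)` returning a D-vector); the pretrained
#' histopathology encoder it stands in for is deliberately not bundled.
#'
#' @param dim Output embedding dimension D (default 768).
#' @param seed Seed fixing the projection matrix.
#' @return A `patch_encoder` list with fields `dim` and `encode`.
#' @export
toy_encoder <- function(dim = 768, seed = 7L) {
  nbins <- 8L
  P <- with_seed(derive_seed(seed, 90004L),
                 matrix(stats::rnorm(dim * nbins^3), nrow = dim))
  encode <- function(patch) {
    q <- function(ch) pmin(floor(patch[, , ch] / 256 * nbins), nbins - 1)
    idx <- q(1) * nbins^2 + q(2) * nbins + q(3) + 1
    hist <- tabulate(idx, nbins = nbins^3)
    as.numeric(P %*% (hist / sum(hist)))
  }
  structure(list(dim = dim, encode = encode), class = "patch_encoder")
}

#' Encode every grid patch of a slide
#'
#' Crops each patch from the level-0 image, resizes it to 224 x 224 (so the
#' 896-px 40x patch is encoded at an effective 10x), and stacks the encoder
#' outputs; row i corresponds to grid row i.
#'
#' @param grid A `patch_grid`.
#' @param image Level-0 RGB array (`h x w x 3`) — the slide reader.
#' @param encoder A `patch_encoder`.
#' @param resize_to Encoder input edge (default 224).
#' @return `n x D` numeric matrix.
#' @export
encode_patches <- function(grid, image, encoder, resize_to = 224) {
  stopifnot(inherits(grid, "patch_grid"), inherits(encoder, "patch_encoder"))
  size <- attr(grid, "patch_size")
  out <- matrix(0, nrow = nrow(grid), ncol = encoder$dim)
  for (i in seq_len(nrow(grid))) {
    x <- grid$x[i]; y <- grid$y[i]
    if (y + size > dim(image)[1] || x + size > dim(image)[2]) {
      stop_damil("patch %d footprint falls outside the slide image", i)
    }
    patch <- image[(y + 1):(y + size), (x + 1):(x + size), , drop = FALSE]
    out[i, ] <- encoder$encode(resize_nn(patch, resize_to))
  }
  out
}

# Nearest-neighbour resize to `edge x edge`; adequate for histogram encoders.
resize_nn <- function(patch, edge) {
  h <- dim(patch)[1]; w <- dim(patch)[2]
  if (h == edge && w == edge) return(patch)
  ri <- pmin(h, floor((seq_len(edge) - 0.5) * h / edge) + 1L)
  ci <- pmin(w, floor((seq_len(edge) - 0.5) * w / edge) + 1L)
  patch[ri, ci, , drop = FALSE]
}
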