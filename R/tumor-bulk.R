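# Tumor-bulk extraction. Patches are scored tumor/normal by a pluggable
# classifier, scores are rasterized to a patch-grid-resolution binary mask,
# the mask is refined morphologically (closing, small-object removal,
# per-component convex hull), and bags are restricted to the surviving cells.

#' Bundle a scoring function as a patch classifier
#'
#' A classifier maps a patch representation to a tumor probability in `[0, 1]`.
#' The trained histopathology CNN is out of scope; [toy_rgb_classifier()] is
#' bundled for tests and any function honoring the contract can be plugged in.
#'
#' @param score_fn Function taking one patch (RGB array) and returning a
#'   probability.
#' @export
patch_classifier <- function(score_fn) {
  structure(list(score = score_fn), class = "patch_classifier")
}

#' Toy tumor classifier on mean-RGB features
#'
#' Logistic score on the distance between a patch's mean color and a reference
#' tumor color; suffices to recover blob ground truth on toy slides.
#'
#' @param tumor_color RGB triplet of the tumor stain.
#' @param scale Logistic sharpness (color units).
#' @export
toy_rgb_classifier <- function(tumor_color = c(120, 60, 140), scale = 20) {
  patch_classifier(function(patch) {
    mu <- vapply(1:3, function(c) mean(patch[, , c]), numeric(1))
    d <- sqrt(sum((mu - tumor_color)^2))
    as.numeric(sigmoid((60 - d) / scale))
  })
}

#' Score every grid patch with a classifier
#'
#' @param grid A `patch_grid`.
#' @param image Level-0 RGB array the patches are cropped from.
#' @param classifier A [patch_classifier()].
#' @return Numeric vector of tumor probabilities, one per grid patch, in grid
#'   order.
#' @export
score_patches <- function(grid, image, classifier) {
  stopifnot(inherits(grid, "patch_grid"), inherits(classifier, "patch_classifier"))
  size <- attr(grid, "patch_size")
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    patch <- image[(grid$y[i] + 1):(grid$y[i] + size),
                   (grid$x[i] + 1):(grid$x[i] + size), , drop = FALSE]
    classifier$score(patch)
  }, numeric(1))
  if (length(scores) && (any(scores < 0) || any(scores > 1))) {
    stop_damil("classifier returned a score outside [0, 1]")
  }
  scores
}

#' Rasterize patch scores to a binary tumor mask
#'
#' The mask lives at patch-grid resolution: one cell per grid position within
#' the grid's bounding box; cells with no patch stay 0.
#'
#' @param scores Per-patch tumor probabilities.
#' @param grid The `patch_grid` the scores align with.
#' @param threshold Tumor call threshold (default 0.5; `score >= threshold`).
#' @return A `tumor_mask`: list with `mask` (0/1 matrix), `origin_cell`
#'   (0-based grid offset of the bounding box), `cell_index` (mask linear index
#'   of each patch), and `provenance = "raw"`.
#' @export
patches_to_mask <- function(scores, grid, threshold = 0.5) {
  assert_that(length(scores) == nrow(grid), "scores and grid are misaligned")
  size <- attr(grid, "patch_size")
  gx <- grid$x / size; gy <- grid$y / size
  if (!nrow(grid)) {
    return(structure(list(mask = matrix(0L, 0, 0), origin_cell = c(0L, 0L),
                          cell_index = integer(0), provenance = "raw"),
                     class = "tumor_mask"))
  }
  ox <- min(gx); oy <- min(gy)
  mask <- matrix(0L, nrow = max(gy) - oy + 1, ncol = max(gx) - ox + 1)
  idx <- cbind(gy - oy + 1, gx - ox + 1)
  lin <- (idx[, 2] - 1L) * nrow(mask) + idx[, 1]
  mask[lin[scores >= threshold]] <- 1L
  structure(list(mask = mask, origin_cell = c(ox, oy), cell_index = lin,
                 provenance = "raw"),
            class = "tumor_mask")
}

#' Refine a tumor mask morphologically
#'
#' Applies, in order: binary closing with a disc of `closing_radius` cells,
#' removal of 8-connected components smaller than `min_object_cells`, and a
#' per-component convex hull fill. The hull is per component so multifocal
#' tumors are never merged across the slide.
#'
#' @param tmask A `tumor_mask`.
#' @param closing_radius Disc radius in cells (default 1).
#' @param min_object_cells Minimum surviving component size (default 8).
#' @param use_convex_hull Fill each component's convex hull (default TRUE).
#' @return A refined `tumor_mask` (`provenance = "refined"`).
#' @export
refine_mask <- function(tmask, closing_radius = 1, min_object_cells = 8,
                        use_convex_hull = TRUE) {
  stopifnot(inherits(tmask, "tumor_mask"))
  m <- tmask$mask
  if (length(m)) {
    m <- binary_closing(m, closing_radius)
    lab <- label_components(m)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0])
      m[lab %in% which(sizes < min_object_cells)] <- 0L
      if (use_convex_hull) {
        lab <- label_components(m)
        for (comp in seq_len(max(lab))) {
          m <- fill_convex_hull(m, which(lab == comp, arr.ind = TRUE))
        }
      }
    }
  }
  out <- tmask
  out$mask <- m
  out$provenance <- "refined"
  out
}

disc_offsets <- function(radius) {
  g <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
}

shift_mat <- function(m, dy, dx, fill = 0L) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dy):min(h, h + dy)
  cs <- max(1, 1 + dx):min(w, w + dx)
  out[rs, cs] <- m[rs - dy, cs - dx]
  out
}

binary_closing <- function(m, radius) {
  if (radius < 1) return(m)
  offs <- disc_offsets(radius)
  dil <- matrix(0L, nrow(m), ncol(m))
  for (k in seq_len(nrow(offs))) {
    dil <- pmax(dil, shift_mat(m, offs$dy[k], offs$dx[k]))
  }
  ero <- matrix(1L, nrow(m), ncol(m))
  for (k in seq_len(nrow(offs))) {
    ero <- pmin(ero, shift_mat(dil, offs$dy[k], offs$dx[k], fill = 0L))
  }
  ero
}

# 8-connected component labelling by flood fill.
label_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  nxt <- 0L
  h <- nrow(m); w <- ncol(m)
  for (start in which(m == 1L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (cur - 1L) %% h + 1L
      j <- (cur - 1L) %/% h + 1L
      for (dj in -1:1) for (di in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
          nb <- (jj - 1L) * h + ii
          if (m[nb] == 1L && lab[nb] == 0L) {
            lab[nb] <- nxt
            queue <- c(queue, nb)
          }
        }
      }
    }
  }
  lab
}

# Fill the convex hull of a set of cells (arr.ind rows) into mask m. Cells are
# treated as lattice points; a cell is filled when its center lies inside or on
# the hull polygon (half-plane tests with a small tolerance).
fill_convex_hull <- function(m, cells) {
  if (nrow(cells) < 3) { m[cells] <- 1L; return(m) }
  pts <- cbind(cells[, 2], cells[, 1])  # (x = col, y = row)
  hull <- grDevices::chull(pts)
  if (length(hull) < 3) { m[cells] <- 1L; return(m) }
  poly <- pts[hull, , drop = FALSE]     # chull returns clockwise order
  rr <- min(cells[, 1]):max(cells[, 1])
  cc <- min(cells[, 2]):max(cells[, 2])
  cand <- expand.grid(row = rr, col = cc)
  px <- cand$col; py <- cand$row
  inside <- rep(TRUE, nrow(cand))
  nv <- nrow(poly)
  for (e in seq_len(nv)) {
    a <- poly[e, ]; b <- poly[e %% nv + 1, ]
    cross <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    inside <- inside & (cross <= 1e-9)  # clockwise: interior has cross <= 0
  }
  m[cbind(cand$row[inside], cand$col[inside])] <- 1L
  m
}

#' Restrict a bag to tumor-bulk patches
#'
#' Keeps exactly the bag rows whose grid cell is 1 in the (refined) mask,
#' preserving row order and metadata. A slide whose bag empties out is flagged
#' for exclusion, mirroring the preprocessing-failure rule for real cohorts.
#'
#' @param bag An [embedding_bag()] whose rows align with `grid`.
#' @param tmask A `tumor_mask` built from the same grid.
#' @param grid The `patch_grid`.
#' @return The filtered [embedding_bag()].
#' @export
apply_mask_to_bag <- function(bag, tmask, grid) {
  stopifnot(inherits(bag, "embedding_bag"), inherits(tmask, "tumor_mask"))
  assert_that(nrow(bag$embeddings) == nrow(grid),
              "bag rows do not align with the patch grid")
  keep <- tmask$mask[tmask$cell_index] == 1L
  if (!any(keep)) {
    stop_damil("slide %s has no tumor-bulk patches; flagged for exclusion",
               bag$slide_id, class = "damil_slide_excluded")
  }
  embedding_bag(bag$embeddings[keep, , drop = FALSE],
                bag$slide_id, bag$patient_id, bag$label, meta = bag$meta)
}

#' Save a tumor mask with its grid geometry
#'
#' Writes the 0/255 raster as ASCII PGM plus a JSON sidecar recording the
#' patch-grid geometry (origin cell, patch size, slide dims, provenance).
#'
#' @param tmask A `tumor_mask`.
#' @param grid The `patch_grid` it aligns with.
#' @param stem Output path stem (writes `<stem>.pgm` and `<stem>.json`).
#' @export
write_mask <- function(tmask, grid, stem) {
  write_mask_pgm(tmask$mask, paste0(stem, ".pgm"))
  jsonlite::write_json(
    list(origin_cell = tmask$origin_cell,
         patch_size = attr(grid, "patch_size"),
         slide_dims = attr(grid, "slide_dims"),
         slide_id = attr(grid, "slide_id"),
         provenance = tmask$provenance),
    paste0(stem, ".json"), auto_unbox = TRUE
  )
  invisible(stem)
}
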