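make_grid <- function(nx, ny, size = 16, slide = c(nx, ny) * size) {
  g <- expand.grid(x = (seq_len(nx) - 1) * size, y = (seq_len(ny) - 1) * size)
  g <- g[order(g$y, g$x), ]
  rownames(g) <- NULL
  structure(g, patch_size = size, slide_dims = slide, slide_id = "s",
            class = c("patch_grid", "data.frame"))
}

test_that("score_patches preserves order and enforces the [0,1] contract", {
  s <- std_toy_slide()
  mask <- structure(list(mask = s$slide$tissue_mask, downsample_factor = 1),
                    class = "tissue_mask")
  grid <- enumerate_patches(mask, c(256, 256), patch_size = 16,
                            min_tissue_frac = 0.5)
  const <- patch_classifier(function(p) 0.9)
  expect_equal(score_patches(grid, s$slide$image, const),
               rep(0.9, nrow(grid)))

  empty <- enumerate_patches(mask, c(8, 8), patch_size = 16)
  expect_length(score_patches(empty, s$slide$image, const), 0L)

  bad <- patch_classifier(function(p) 1.7)
  expect_error(score_patches(grid, s$slide$image, bad), "outside")
})

test_that("toy classifier recovers blob ground truth at the patch level", {
  s <- std_toy_slide()
  mask <- structure(list(mask = s$slide$tissue_mask, downsample_factor = 1),
                    class = "tissue_mask")
  grid <- enumerate_patches(mask, c(256, 256), patch_size = 16,
                            min_tissue_frac = 0.5)
  scores <- score_patches(grid, s$slide$image, toy_rgb_classifier())
  truth <- vapply(seq_len(nrow(grid)), function(i) {
    cells <- s$slide$tumor_mask[(grid$y[i] + 1):(grid$y[i] + 16),
                                (grid$x[i] + 1):(grid$x[i] + 16)]
    as.numeric(mean(cells) >= 0.5)
  }, numeric(1))
  acc <- mean((scores >= 0.5) == (truth == 1))
  expect_gte(acc, 0.95)
})

test_that("patches_to_mask is elementwise thresholding on the grid raster", {
  grid <- make_grid(4, 3)
  scores <- seq(0, 1, length.out = 12)
  m <- patches_to_mask(scores, grid, threshold = 0.5)
  expect_equal(dim(m$mask), c(3L, 4L))
  expect_equal(as.integer(t(m$mask)), as.integer(scores >= 0.5))

  expect_equal(sum(patches_to_mask(rep(1, 12), grid)$mask), 12)
  expect_equal(sum(patches_to_mask(scores, grid, threshold = 0)$mask), 12)
  expect_error(patches_to_mask(scores[-1], grid), "misaligned")
})

test_that("refine_mask applies closing, removal and per-component hulls", {
  grid <- make_grid(20, 20)
  # single small component below min_object_cells vanishes
  sc <- rep(0, 400); sc[c(21, 22)] <- 1
  small <- patches_to_mask(sc, grid)
  expect_equal(sum(refine_mask(small, min_object_cells = 8)$mask), 0)

  # solid convex rectangle is a fixed point
  rect <- matrix(0L, 20, 20); rect[5:12, 3:9] <- 1L
  tm <- patches_to_mask(as.numeric(t(rect)), grid)
  expect_equal(refine_mask(tm)$mask, rect)

  # C-shaped component: hull fill equals the exhaustive half-plane oracle
  cshape <- matrix(0L, 12, 12)
  cshape[3:10, 3:4] <- 1L; cshape[3:4, 3:10] <- 1L; cshape[9:10, 3:10] <- 1L
  g2 <- make_grid(12, 12)
  tm2 <- patches_to_mask(as.numeric(t(cshape)), g2)
  ref <- refine_mask(tm2, closing_radius = 0, min_object_cells = 1,
                     use_convex_hull = TRUE)
  cells <- which(cshape == 1L, arr.ind = TRUE)
  oracle <- matrix(0L, 12, 12)
  for (i in 1:12) for (j in 1:12) {
    oracle[i, j] <- as.integer(hull_member_oracle(cells, c(i, j)))
  }
  expect_equal(ref$mask, oracle)
})

test_that("refine_mask is idempotent on blob masks", {
  set.seed(17)
  for (rep in 1:5) {
    m <- matrix(0L, 24, 24)
    for (b in 1:3) {
      cx <- sample(5:20, 1); cy <- sample(5:20, 1); r <- sample(2:3, 1)
      xs <- matrix(1:24, 24, 24, byrow = TRUE); ys <- matrix(1:24, 24, 24)
      m[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- 1L
    }
    g <- make_grid(24, 24)
    tm <- patches_to_mask(as.numeric(t(m)), g)
    once <- refine_mask(tm)
    twice <- refine_mask(once)
    expect_equal(twice$mask, once$mask)
  }
})

test_that("apply_mask_to_bag filters rows in place and flags empty slides", {
  grid <- make_grid(4, 3)
  E <- matrix(seq_len(12 * 5), 12, 5)
  bag <- embedding_bag(E, "s1", "p1", "RC")
  allone <- patches_to_mask(rep(1, 12), grid)
  expect_equal(apply_mask_to_bag(bag, allone, grid)$embeddings, E)

  allzero <- patches_to_mask(rep(0, 12), grid)
  expect_error(apply_mask_to_bag(bag, allzero, grid),
               class = "damil_slide_excluded")

  keep <- c(1, 4, 7, 11)
  sc <- rep(0, 12); sc[keep] <- 1
  sub <- apply_mask_to_bag(bag, patches_to_mask(sc, grid), grid)
  expect_equal(sub$embeddings, E[keep, ])         # order preserved
})

test_that("tumor-bulk filtering on a toy slide matches generator bookkeeping", {
  s <- std_toy_slide()
  mask <- structure(list(mask = s$slide$tissue_mask, downsample_factor = 1),
                    class = "tissue_mask")
  grid <- enumerate_patches(mask, c(256, 256), patch_size = 16,
                            min_tissue_frac = 0.5)
  scores <- score_patches(grid, s$slide$image, toy_rgb_classifier())
  raw <- patches_to_mask(scores, grid)
  enc <- toy_encoder(dim = 16, seed = 2)
  bag <- embedding_bag(encode_patches(grid, s$slide$image, enc), "s", "p", "RC")
  kept <- apply_mask_to_bag(bag, raw, grid)
  expect_equal(nrow(kept$embeddings), sum(raw$mask))

  dir <- withr::local_tempdir()
  write_mask(refine_mask(raw), grid, file.path(dir, "mask"))
  expect_true(file.exists(file.path(dir, "mask.pgm")))
  meta <- jsonlite::read_json(file.path(dir, "mask.json"))
  expect_equal(meta$provenance, "refined")
})
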