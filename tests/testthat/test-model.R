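test_that("init_params is seed-deterministic with the declared tensor set", {
  cfg <- damil_config(d = 8, d_hidden = 4, l_gate = 3, seed = 5)
  p1 <- init_params(cfg); p2 <- init_params(cfg)
  expect_identical(p1[names(p1) != "config"], p2[names(p2) != "config"])

  p3 <- init_params(damil_config(d = 8, d_hidden = 4, l_gate = 3, seed = 6))
  expect_false(identical(p1$W_k, p3$W_k))

  arrays <- setdiff(names(p1), "config")
  expect_setequal(arrays, c("W_k", "b_k", "W_q", "b_q", "W_v", "b_v",
                            "V_gate", "U_gate", "w_gate", "W_head", "b_head"))
  expect_true(all(vapply(p1[arrays], function(x) all(is.finite(x)), logical(1))))
})

test_that("cross-attention is row-stochastic and patch-order free", {
  cfg <- damil_config(d = 6, d_hidden = 4, l_gate = 3, seed = 2)
  p <- init_params(cfg)
  K <- matrix(rnorm(6 * 5), 6, 5)
  Q <- matrix(rnorm(6 * 7), 6, 7)
  ca <- cross_attention(K, Q, p)
  expect_equal(dim(ca$H), c(5L, 4L))
  expect_equal(rowSums(ca$A), rep(1, 5), tolerance = 1e-6)

  # single key, single patch: softmax of a scalar is 1, H = Vt'
  ca1 <- cross_attention(K[, 1, drop = FALSE], Q[, 1, drop = FALSE], p)
  expect_equal(as.numeric(ca1$H), as.numeric(ca1$Vt), tolerance = 1e-12)

  perm <- sample(7)
  ca2 <- cross_attention(K, Q[, perm], p)
  expect_equal(ca2$H, ca$H, tolerance = 1e-12)

  expect_error(cross_attention(matrix(0, 5, 2), Q, p), "dimension")
})

test_that("gated attention normalizes and pools as stated", {
  cfg <- damil_config(d = 6, d_hidden = 4, l_gate = 3, seed = 2)
  p <- init_params(cfg)
  h <- matrix(rnorm(4), 1, 4)
  ga1 <- gated_attention(h, p)
  expect_equal(ga1$a, 1)
  expect_equal(as.numeric(ga1$z), as.numeric(h))

  H2 <- rbind(h, h)
  ga2 <- gated_attention(H2, p)
  expect_equal(ga2$a, c(0.5, 0.5), tolerance = 1e-12)

  expect_error(gated_attention(matrix(c(1, NaN, 0, 0), 1, 4), p), "finite")
})

test_that("vectorized forward equals the pure-loop oracle on small instances", {
  set.seed(77)
  for (i in 1:6) {
    tau <- sample(1:8, 1); n <- sample(1:8, 1)
    cfg <- damil_config(d = 5, d_hidden = 4, l_gate = 3, seed = i)
    p <- init_params(cfg)
    E <- matrix(rnorm(n * 5), n, 5)
    K <- matrix(rnorm(5 * tau), 5, tau)
    got <- damil_forward(E, K, p)
    want <- loop_forward_oracle(E, K, p)
    expect_equal(got$H, want$H, tolerance = 1e-5)
    expect_equal(got$a, want$a, tolerance = 1e-5)
    expect_equal(as.numeric(got$z), want$z, tolerance = 1e-5)
    expect_equal(unname(got$prob), want$prob, tolerance = 1e-5)
  }
})

test_that("forward output satisfies its invariants end to end", {
  set.seed(78)
  cfg <- damil_config(d = 6, d_hidden = 4, l_gate = 3, seed = 1)
  p <- init_params(cfg)
  K <- matrix(rnorm(6 * 9), 6, 9)
  bag <- embedding_bag(matrix(rnorm(11 * 6), 11, 6), "s", "p", "RC")
  out <- damil_forward(bag, K, p)
  expect_equal(sum(out$prob), 1, tolerance = 1e-6)
  expect_equal(sum(out$a), 1, tolerance = 1e-6)
  expect_equal(rowSums(out$cache$ca$A), rep(1, 9), tolerance = 1e-6)

  perm <- sample(11)
  out2 <- damil_forward(embedding_bag(bag$embeddings[perm, ], "s", "p", "RC"), K, p)
  expect_equal(out2$prob, out$prob, tolerance = 1e-5)

  expect_error(damil_forward(matrix(0, 0, 6), K, p), "empty")
})

test_that("analytic gradients match central finite differences", {
  set.seed(79)
  cfg <- damil_config(d = 4, d_hidden = 3, l_gate = 3, seed = 4)
  p <- init_params(cfg)
  K <- matrix(rnorm(4 * 5), 4, 5)
  bag <- embedding_bag(matrix(rnorm(6 * 4), 6, 4), "s", "p", "RC")
  out <- damil_forward(bag, K, p)
  g <- damil:::damil_backward(out, "RC", p)
  eps <- 1e-6
  for (nm in names(g)) {
    for (i in sample(seq_along(p[[nm]]), min(4, length(p[[nm]])))) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (damil:::damil_loss(damil_forward(bag, K, pp), "RC") -
              damil:::damil_loss(damil_forward(bag, K, pm), "RC")) / (2 * eps)
      expect_equal(as.numeric(g[[nm]])[i], num, tolerance = 1e-5)
    }
  }
})

test_that("parameter/MAC accounting matches shape enumeration and scales linearly", {
  ref <- damil_config(d = 1024, d_hidden = 512, l_gate = 256)
  counts <- count_params_flops(ref, n = 120, tau = 200)
  expect_equal(counts$params,
               3 * (1024 * 512 + 512) + 2 * (256 * 512) + 256 + (512 * 2 + 2))
  expect_lte(counts$params, 2.10e6)              # printed budget upper bound

  wider <- count_params_flops(damil_config(d = 1024, d_hidden = 1024,
                                           l_gate = 256), n = 120, tau = 200)
  expect_gt(wider$params, counts$params)
  expect_gt(wider$macs, counts$macs)

  # attention cost is linear in n at fixed tau: second differences vanish
  m <- vapply(c(100, 200, 300), function(n) {
    count_params_flops(ref, n = n, tau = 200)$macs
  }, numeric(1))
  expect_equal(m[3] - m[2], m[2] - m[1])

  # bias flags change the count by exactly the bias shapes
  nob <- count_params_flops(damil_config(d = 1024, d_hidden = 512, l_gate = 256,
                                         bias_in_embeddings = FALSE))
  expect_equal(counts$params - nob$params, 3 * 512 + 2)
})

test_that("checkpoints round-trip through plain text", {
  cfg <- damil_config(d = 5, d_hidden = 4, l_gate = 3, seed = 8)
  p <- init_params(cfg)
  dir <- withr::local_tempdir()
  write_checkpoint(p, dir)
  back <- read_checkpoint(dir)
  for (nm in setdiff(names(p), "config")) {
    expect_equal(back[[nm]], p[[nm]], tolerance = 1e-12)
  }
  expect_equal(back$config$d_hidden, 4L)
})
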