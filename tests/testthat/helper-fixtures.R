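# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

tiny_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_rc = 5, n_nrc = 5, slides_per_patient = c(1, 1),
         n_instances = c(20, 30), dim = 8, witness_rate = 0.2,
         effect_size = 4, true_hr = 2.3, seed = seed),
    list(...)
  )
  do.call(cohort_spec, args)
}

# A synthetic cohort table without bags, for split/survival tests.
fake_cohort <- function(n_rc, n_nrc, slides = 1) {
  n <- n_rc + n_nrc
  ids <- sprintf("p%04d", seq_len(n))
  lab <- c(rep("RC", n_rc), rep("NRC", n_nrc))
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(patient_id = ids[i],
               slide_id = sprintf("%s_s%d", ids[i], seq_len(slides)),
               label = lab[i], time_months = 30, event = 0L,
               stringsAsFactors = FALSE)
  }))
}

std_toy_slide <- function(seed = 3L) {
  spec <- toy_slide_spec(
    width = 256, height = 256,
    tumor_blobs = list(
      list(center = c(90, 90), radius = 45, color = c(120, 60, 140)),
      list(center = c(185, 170), radius = 30, color = c(120, 60, 140))
    ),
    seed = seed
  )
  list(spec = spec, slide = gen_toy_slide(spec))
}

# Oracle: dense hat-matrix leverage via the pseudo-inverse (full-rank case).
hat_leverage_oracle <- function(E) {
  diag(E %*% solve(crossprod(E)) %*% t(E))
}

# Oracle: pure-loop forward pass of the dual-attention aggregator, written
# with explicit scalar sums and no shared code with the package internals.
loop_forward_oracle <- function(E, K, p) {
  D <- ncol(E); n <- nrow(E); tau <- ncol(K); dh <- nrow(p$W_k); L <- nrow(p$V_gate)
  lin <- function(W, b, v) {
    out <- numeric(nrow(W))
    for (r in seq_len(nrow(W))) out[r] <- sum(W[r, ] * v) + b[r]
    out
  }
  Kt <- sapply(seq_len(tau), function(j) lin(p$W_k, p$b_k, K[, j]))   # dh x tau
  Qt <- sapply(seq_len(n), function(j) lin(p$W_q, p$b_q, E[j, ]))     # dh x n
  Vt <- sapply(seq_len(n), function(j) lin(p$W_v, p$b_v, E[j, ]))
  H <- matrix(0, tau, dh)
  for (i in seq_len(tau)) {
    s <- numeric(n)
    for (j in seq_len(n)) s[j] <- sum(Kt[, i] * Qt[, j]) / sqrt(dh)
    a <- exp(s - max(s)); a <- a / sum(a)
    for (d in seq_len(dh)) H[i, d] <- sum(a * Vt[d, ])
  }
  e <- numeric(tau)
  for (i in seq_len(tau)) {
    t_i <- tanh(as.numeric(p$V_gate %*% H[i, ]))
    s_i <- 1 / (1 + exp(-as.numeric(p$U_gate %*% H[i, ])))
    e[i] <- sum(p$w_gate * (t_i * s_i))
  }
  a <- exp(e - max(e)); a <- a / sum(a)
  z <- numeric(dh)
  for (d in seq_len(dh)) z[d] <- sum(a * H[, d])
  logits <- as.numeric(p$W_head %*% z + p$b_head)
  pr <- exp(logits - max(logits)); pr <- pr / sum(pr)
  list(H = H, a = a, z = z, prob = pr)
}

# Oracle: O(n^2) pairwise AUROC with half credit for ties, on the 0-100 scale.
pairwise_auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == "RC"]; neg <- scores[labels == "NRC"]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  100 * tot / (length(pos) * length(neg))
}

# Oracle: exhaustive half-plane convex-hull membership for a cell set.
# cell is in the hull iff it lies inside every supporting line, i.e. for every
# pair of points whose line has all points on one side.
hull_member_oracle <- function(cells, query) {
  pts <- cbind(cells[, 2], cells[, 1])  # x, y
  qx <- query[2]; qy <- query[1]
  np <- nrow(pts)
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    a <- pts[i, ]; b <- pts[j, ]
    cr <- function(px, py) (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    side <- cr(pts[, 1], pts[, 2])
    if (all(side <= 1e-9)) {                  # supporting line, interior below
      if (cr(qx, qy) > 1e-9) return(FALSE)
    } else if (all(side >= -1e-9)) {          # interior above
      if (cr(qx, qy) < -1e-9) return(FALSE)
    }
  }
  TRUE
}

# Assemble bag lists keyed by patient for fold handling in tests.
bags_for <- function(bags, ids) {
  keep <- vapply(bags, function(b) b$patient_id %in% ids, logical(1))
  bags[keep]
}
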