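# The dual-attention aggregator. A bag of n patch embeddings (D-dim) is fused
# with the tau-column key set by cross-attention — each key slot takes a convex
# combination of the bag's value embeddings — and the tau fused vectors are
# pooled by gated attention into a single slide representation z, which a
# linear head maps to RC/NRC probabilities. Everything is plain matrix code
# with an analytic backward pass; no deep-learning runtime is required.

#' Model configuration
#'
#' @param d Input embedding dimension D.
#' @param d_hidden Hidden dimension Dh of the three linear embeddings.
#' @param l_gate Gate width L of the gated-attention transforms.
#' @param n_classes Number of output classes (fixed at 2).
#' @param seed Seed for parameter initialization.
#' @param bias_in_embeddings Biases on the K/Q/V embeddings and head (default
#'   TRUE).
#' @param bias_in_gate Biases on the gate maps V, U, W (default FALSE,
#'   matching the usual gated-attention formulation).
#' @return A `damil_config` list.
#' @export
damil_config <- function(d = 768, d_hidden = 512, l_gate = 256, n_classes = 2,
                         seed = 1L, bias_in_embeddings = TRUE,
                         bias_in_gate = FALSE) {
  assert_that(is_count(d) && is_count(d_hidden) && is_count(l_gate),
              "d, d_hidden and l_gate must be positive integers")
  assert_that(n_classes == 2, "the classifier head is binary (RC vs NRC)")
  structure(list(d = as.integer(d), d_hidden = as.integer(d_hidden),
                 l_gate = as.integer(l_gate), n_classes = 2L,
                 seed = as.integer(seed),
                 bias_in_embeddings = isTRUE(bias_in_embeddings),
                 bias_in_gate = isTRUE(bias_in_gate)),
            class = "damil_config")
}

glorot <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(2 / (nin + nout))), nout, nin)
}

#' Initialize model parameters
#'
#' Glorot-scaled Gaussian weights, zero biases; deterministic given the
#' config seed.
#'
#' @param config A [damil_config()].
#' @return A `damil_params` list of named arrays plus the config.
#' @export
init_params <- function(config) {
  stopifnot(inherits(config, "damil_config"))
  d <- config$d; dh <- config$d_hidden; l <- config$l_gate
  p <- with_seed(derive_seed(config$seed, 90005L), list(
    W_k = glorot(dh, d), b_k = numeric(dh),
    W_q = glorot(dh, d), b_q = numeric(dh),
    W_v = glorot(dh, d), b_v = numeric(dh),
    V_gate = glorot(l, dh), U_gate = glorot(l, dh),
    w_gate = glorot(1, l),
    W_head = glorot(config$n_classes, dh), b_head = numeric(config$n_classes)
  ))
  structure(c(p, list(config = config)), class = "damil_params")
}

param_names <- function(config) {
  nm <- c("W_k", "W_q", "W_v", "V_gate", "U_gate", "w_gate", "W_head")
  if (config$bias_in_embeddings) nm <- c(nm, "b_k", "b_q", "b_v", "b_head")
  nm
}

#' Cross-attention of the key set against a bag
#'
#' Computes `K~ = W_k K`, `Q~ = W_q Q`, `V~ = W_v Q`, scores
#' `S = K~' Q~ / sqrt(Dh)` (tau x n), row-softmax over the n patches, and
#' `H = A V~'`. Each of the tau rows of A is a distribution over patches, so
#' each key slot aggregates a convex combination of patch values; the scale
#' factor is the transformer-decoder `1/sqrt(Dh)`.
#'
#' @param K `D x tau` key matrix.
#' @param Q `D x n` bag matrix (columns = patches).
#' @param params A `damil_params`.
#' @return List with `H` (tau x Dh), `A` (tau x n), and the projected
#'   `Kt`, `Qt`, `Vt` needed by the backward pass.
#' @export
cross_attention <- function(K, Q, params) {
  assert_that(nrow(K) == nrow(Q), "key set and bag disagree on dimension D")
  assert_that(ncol(Q) >= 1 && ncol(K) >= 1, "need at least one patch and one key")
  dh <- params$config$d_hidden
  Kt <- params$W_k %*% K + params$b_k
  Qt <- params$W_q %*% Q + params$b_q
  Vt <- params$W_v %*% Q + params$b_v
  S <- crossprod(Kt, Qt) / sqrt(dh)
  A <- softmax_rows(S)
  list(H = A %*% t(Vt), A = A, Kt = Kt, Qt = Qt, Vt = Vt)
}

#' Gated attention pooling over the key-slot outputs
#'
#' `a_i` is proportional to `exp(w (tanh(V h_i) * sigm(U h_i)))`, normalized
#' over the tau rows of H; `z = sum_i a_i h_i`.
#'
#' @param H `tau x Dh` cross-attention output.
#' @param params A `damil_params`.
#' @return List with `a` (tau weights summing to 1), `z` (1 x Dh), and the
#'   intermediates `Tn`, `Sg` for backprop.
#' @export
gated_attention <- function(H, params) {
  assert_that(all(is.finite(H)), "non-finite cross-attention output")
  Tn <- tanh(H %*% t(params$V_gate))        # tau x L
  Sg <- sigmoid(H %*% t(params$U_gate))     # tau x L
  e <- as.numeric((Tn * Sg) %*% t(params$w_gate))
  a <- softmax_vec(e)
  z <- matrix(colSums(a * H), nrow = 1)
  list(a = a, z = z, Tn = Tn, Sg = Sg)
}

#' Forward pass: bag + key set -> slide-level prediction
#'
#' @param bag An [embedding_bag()] (or bare `n x D` matrix).
#' @param keyset A `damil_keyset` (or bare `D x tau` matrix).
#' @param params A `damil_params`.
#' @return An `attention_output`: list with `H`, `a`, `z`, `logits`, `prob`
#'   (named RC/NRC probabilities summing to 1), `p_rc`, and cached
#'   intermediates.
#' @export
damil_forward <- function(bag, keyset, params) {
  E <- if (inherits(bag, "embedding_bag")) bag$embeddings else as.matrix(bag)
  K <- if (inherits(keyset, "damil_keyset")) keyset$K else as.matrix(keyset)
  assert_that(nrow(E) >= 1, "empty bag")
  assert_that(ncol(E) == params$config$d, "bag dimension != config D")
  Q <- t(E)
  ca <- cross_attention(K, Q, params)
  ga <- gated_attention(ca$H, params)
  logits <- as.numeric(params$W_head %*% t(ga$z) + params$b_head)
  prob <- softmax_vec(logits)
  names(prob) <- c("RC", "NRC")
  structure(list(H = ca$H, a = ga$a, z = ga$z, logits = logits, prob = prob,
                 p_rc = prob[["RC"]],
                 cache = list(Q = Q, K = K, ca = ca, ga = ga)),
            class = "attention_output")
}

# Cross-entropy loss of one forward pass against label ("RC" -> class 1).
damil_loss <- function(out, label) {
  y <- if (label == "RC") 1L else 2L
  -log(max(out$prob[[y]], 1e-12))
}

# Analytic gradients of the cross-entropy loss w.r.t. every parameter.
# Returns a named list matching param_names(config).
damil_backward <- function(out, label, params) {
  cfg <- params$config
  dh <- cfg$d_hidden
  Q <- out$cache$Q; K <- out$cache$K
  ca <- out$cache$ca; ga <- out$cache$ga
  H <- out$H; A <- ca$A
  a <- ga$a; Tn <- ga$Tn; Sg <- ga$Sg

  y <- if (label == "RC") c(1, 0) else c(0, 1)
  dlogits <- out$prob - y                           # softmax + CE
  g <- list()
  g$W_head <- tcrossprod(dlogits, as.numeric(out$z)) # n_classes x Dh
  g$b_head <- dlogits
  dz <- as.numeric(crossprod(params$W_head, dlogits)) # Dh

  # z = sum_i a_i h_i
  da <- as.numeric(H %*% dz)                        # tau
  dH <- a %o% dz                                    # tau x Dh
  # softmax over gate scores e
  de <- a * (da - sum(a * da))                      # tau
  G <- Tn * Sg                                      # tau x L
  g$w_gate <- matrix(colSums(de * G), nrow = 1)
  dG <- de %o% as.numeric(params$w_gate)            # tau x L
  dTn <- dG * Sg * (1 - Tn^2)
  dSg <- dG * Tn * Sg * (1 - Sg)
  g$V_gate <- crossprod(dTn, H)                     # L x Dh
  g$U_gate <- crossprod(dSg, H)
  dH <- dH + dTn %*% params$V_gate + dSg %*% params$U_gate

  # H = A Vt'
  dA <- dH %*% ca$Vt                                # tau x n
  dVt <- t(crossprod(A, dH))                        # Dh x n
  # row softmax of S
  dS <- A * (dA - rowSums(A * dA))                  # tau x n
  dS <- dS / sqrt(dh)
  dKt <- ca$Qt %*% t(dS)                            # Dh x tau
  dQt <- ca$Kt %*% dS                               # Dh x n

  g$W_k <- tcrossprod(dKt, K)                       # Dh x D
  g$W_q <- tcrossprod(dQt, Q)
  g$W_v <- tcrossprod(dVt, Q)
  g$b_k <- rowSums(dKt)
  g$b_q <- rowSums(dQt)
  g$b_v <- rowSums(dVt)
  g[param_names(cfg)]
}

#' Count trainable parameters and multiply-accumulate operations
#'
#' Parameters are an exact shape enumeration under the config's bias flags.
#' MACs cover one evaluation-mode forward pass: the three linear embeddings,
#' the tau x n x Dh attention products (scores and value aggregation), the
#' gate, and the head — linear in n at fixed tau, never O(n^2).
#'
#' @param config A [damil_config()].
#' @param n Bag size (instances).
#' @param tau Key-set size.
#' @return List with `params` (count) and `macs`.
#' @export
count_params_flops <- function(config, n = 120, tau = 200) {
  d <- config$d; dh <- config$d_hidden; l <- config$l_gate
  nc <- config$n_classes
  p <- 3 * d * dh + 2 * l * dh + l + dh * nc
  if (config$bias_in_embeddings) p <- p + 3 * dh + nc
  if (config$bias_in_gate) p <- p + 2 * l + 1
  macs <- dh * d * tau +        # key embedding
    2 * dh * d * n +            # query + value embeddings
    tau * n * dh +              # attention scores K~'Q~
    tau * n * dh +              # H = A V~'
    tau * (2 * l * dh + l) +    # gate tanh/sigm transforms + scorer
    dh * nc                     # head
  list(params = p, macs = macs)
}

#' Serialize / load model parameters
#'
#' One CSV per weight array plus a JSON config — a plain-text checkpoint.
#'
#' @param params A `damil_params`.
#' @param dir Checkpoint directory.
#' @export
write_checkpoint <- function(params, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arrays <- setdiff(names(params), "config")
  for (nm in arrays) {
    utils::write.table(as.matrix(params[[nm]]), file.path(dir, paste0(nm, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(unclass(params$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(dir) {
  cfgl <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- damil_config(d = cfgl$d, d_hidden = cfgl$d_hidden,
                         l_gate = cfgl$l_gate, n_classes = cfgl$n_classes,
                         seed = cfgl$seed,
                         bias_in_embeddings = cfgl$bias_in_embeddings,
                         bias_in_gate = cfgl$bias_in_gate)
  p <- init_params(config)
  for (nm in setdiff(names(p), "config")) {
    m <- as.matrix(utils::read.table(file.path(dir, paste0(nm, ".csv")), sep = ","))
    dimnames(m) <- NULL
    p[[nm]] <- if (is.matrix(p[[nm]])) m else as.numeric(m)
  }
  p
}
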