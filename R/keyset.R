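# Categorical representation learning: each training slide contributes its
# highest-leverage patch embeddings, and the selections from all slides (both
# classes) are concatenated into one joint key set K in R^{D x tau} that the
# cross-attention stage attends from.

#' Configuration for key-set selection
#'
#' @param rank_energy Fraction of squared spectral mass the selection rank must
#'   capture, in `(0, 1]` (default 0.90).
#' @param max_rank Cap on the selection rank r (default 32).
#' @param keys_per_slide Keys m taken from each slide (default 4).
#' @return A `crl_config` list.
#' @export
crl_config <- function(rank_energy = 0.90, max_rank = 32, keys_per_slide = 4) {
  assert_that(rank_energy > 0 && rank_energy <= 1, "rank_energy must be in (0, 1]")
  assert_that(is_count(max_rank), "max_rank must be a positive integer")
  assert_that(is_count(keys_per_slide), "keys_per_slide must be >= 1")
  structure(list(rank_energy = rank_energy, max_rank = as.integer(max_rank),
                 keys_per_slide = as.integer(keys_per_slide)),
            class = "crl_config")
}

#' Statistical leverage scores of bag instances
#'
#' The leverage score of instance i at rank r is the i-th diagonal entry of
#' the projection (hat) matrix onto the top-r left singular subspace of the
#' bag matrix: `score_i = sum_{j<=r} U[i, j]^2`. Scores lie in `[0, 1]` and sum
#' exactly to r (trace identity); large scores mark instances that the
#' low-rank summary of the slide cannot do without.
#'
#' @param E `n x D` bag matrix (rows = instances).
#' @param r Rank, `1 <= r <= min(n, D)`.
#' @return Numeric vector of n scores.
#' @export
leverage_scores <- function(E, r) {
  E <- as.matrix(E)
  n <- nrow(E); d <- ncol(E)
  assert_that(is_count(r) && r <= min(n, d), "rank r must lie in 1..min(n, D)")
  U <- svd(E, nu = r, nv = 0)$u
  rowSums(U[, seq_len(r), drop = FALSE]^2)
}

# Smallest rank capturing >= rank_energy of squared singular mass, capped.
select_rank <- function(E, config) {
  d2 <- svd(E, nu = 0, nv = 0)$d^2
  total <- sum(d2)
  r <- if (total <= 0) 1L else which(cumsum(d2) / total >= config$rank_energy - 1e-12)[1]
  min(r, config$max_rank, nrow(E), ncol(E))
}

#' Select the key rows of one bag
#'
#' Chooses the selection rank by the spectral-energy rule, computes leverage
#' scores at that rank, and returns the indices of the `keys_per_slide`
#' largest scores (ties broken toward lower row index). Bags smaller than m
#' contribute all their rows.
#'
#' @param E `n x D` bag matrix.
#' @param config A [crl_config()].
#' @return Integer row indices (1-based), in decreasing-score order.
#' @export
select_keys <- function(E, config = crl_config()) {
  E <- as.matrix(E)
  assert_that(nrow(E) >= 1, "bag is empty")
  m <- config$keys_per_slide
  if (nrow(E) <= m) return(seq_len(nrow(E)))
  r <- select_rank(E, config)
  # round away float noise so duplicated rows tie-break by row index
  s <- round(leverage_scores(E, r), 9)
  order(-s, seq_along(s))[seq_len(m)]
}

#' Build the joint key set from the training bags
#'
#' Applies [select_keys()] to every training bag — RC and NRC alike — and
#' concatenates the selected embeddings in slide order into `K` (`D x tau`),
#' recording per-key provenance `(slide_id, row)`. The key set is external
#' guidance for cross-attention and must only ever see training slides; the
#' cross-validation harness enforces this via the provenance.
#'
#' @param bags List of training [embedding_bag()]s sharing dimension D.
#' @param config A [crl_config()].
#' @return A `damil_keyset`: list with `K` (`D x tau` matrix), `tau`, and
#'   `provenance` (data.frame slide_id, row).
#' @export
build_keyset <- function(bags, config = crl_config()) {
  assert_that(length(bags) >= 1, "need at least one training bag")
  dims <- vapply(bags, bag_dim, numeric(1))
  assert_that(length(unique(dims)) == 1L, "bags have mixed embedding dimensions")
  cols <- list(); prov <- list()
  for (b in bags) {
    idx <- select_keys(b$embeddings, config)
    cols[[length(cols) + 1L]] <- t(b$embeddings[idx, , drop = FALSE])
    prov[[length(prov) + 1L]] <- data.frame(
      slide_id = b$slide_id, row = idx, stringsAsFactors = FALSE
    )
  }
  K <- do.call(cbind, cols)
  structure(
    list(K = K, tau = ncol(K), provenance = do.call(rbind, prov)),
    class = "damil_keyset"
  )
}

#' @export
print.damil_keyset <- function(x, ...) {
  cat(sprintf("<damil_keyset> D=%d tau=%d from %d slides\n",
              nrow(x$K), x$tau, length(unique(x$provenance$slide_id))))
  invisible(x)
}

#' Write / read a key set as a plain-text bundle
#'
#' `<stem>.csv` holds K (D rows, tau columns, no header); `<stem>.json` holds
#' the provenance.
#'
#' @param keyset A `damil_keyset`.
#' @param stem Path stem.
#' @export
write_keyset <- function(keyset, stem) {
  utils::write.table(keyset$K, paste0(stem, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(keyset$provenance, paste0(stem, ".json"))
  invisible(stem)
}

#' @rdname write_keyset
#' @export
read_keyset <- function(stem) {
  K <- as.matrix(utils::read.table(paste0(stem, ".csv"), sep = ","))
  dimnames(K) <- NULL
  prov <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  structure(list(K = K, tau = ncol(K), provenance = prov),
            class = "damil_keyset")
}
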