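# Training protocol and patient-level stratified five-fold cross-validation.
# One bag per optimization step (bags vary in size), inverse-frequency
# weighted sampling against class imbalance, Adam with L2 weight decay, and
# early stopping with a warm-up: 5 initial epochs, then stop once the
# validation loss has gone `patience` consecutive epochs without a strict
# improvement, capped at 50 epochs.

#' Training configuration
#'
#' Defaults are the published recipe: Adam, learning rate 8e-5, weight decay
#' 1e-5, 5 initial epochs, patience 5, at most 50 epochs, batch size one.
#'
#' @param learning_rate,weight_decay Adam step size and L2 decay.
#' @param min_epochs Warm-up epochs before early stopping may fire.
#' @param patience Consecutive non-improving epochs that trigger the stop.
#' @param max_epochs Hard cap on epochs.
#' @param batch_size Fixed at 1 (variable bag shapes).
#' @param seed Sampling/initialization seed.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 8e-5, weight_decay = 1e-5,
                         min_epochs = 5, patience = 5, max_epochs = 50,
                         batch_size = 1, seed = 1L) {
  assert_that(learning_rate > 0 && weight_decay >= 0, "rates must be positive")
  assert_that(batch_size == 1, "batch size is fixed at one for variable bag shapes")
  assert_that(is_count(min_epochs) && is_count(patience) && is_count(max_epochs),
              "epoch counts must be positive integers")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 min_epochs = as.integer(min_epochs),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = 1L, seed = as.integer(seed)),
            class = "train_config")
}

#' Patient-level stratified k-fold split plan
#'
#' Patients of each class are shuffled and dealt into k test folds whose sizes
#' differ by at most one; within each fold the remaining patients are split
#' into validation (a per-class fraction) and training, preserving class
#' ratios. All slides of a patient always travel together, so no patient ever
#' leaks across the train/validation/test boundary.
#'
#' @param cohort Slide-level cohort table (see [write_cohort()]).
#' @param k Number of folds (default 5).
#' @param val_fraction Fraction of non-test patients held out for validation,
#'   per class (default 1/6).
#' @param seed Shuffle seed.
#' @return A `split_plan`: list of k folds, each with character vectors
#'   `train`, `validation`, `test` of patient ids.
#' @export
make_splits <- function(cohort, k = 5, val_fraction = 1 / 6, seed = 1L) {
  validate_cohort(cohort)
  pat <- unique(cohort[, c("patient_id", "label")])
  for (cls in c("RC", "NRC")) {
    assert_that(sum(pat$label == cls) >= k,
                "class %s has fewer than k patients", cls)
  }
  folds_by_class <- with_seed(derive_seed(seed, 90006L), {
    lapply(c("RC", "NRC"), function(cls) {
      ids <- sample(pat$patient_id[pat$label == cls])
      split(ids, rep_len(seq_len(k), length(ids)))  # sizes differ by <= 1
    })
  })
  names(folds_by_class) <- c("RC", "NRC")
  plan <- lapply(seq_len(k), function(f) {
    test <- c(folds_by_class$RC[[f]], folds_by_class$NRC[[f]])
    rest <- lapply(c("RC", "NRC"), function(cls) {
      setdiff(pat$patient_id[pat$label == cls], folds_by_class[[cls]][[f]])
    })
    val <- with_seed(derive_seed(seed, 90007L + f), {
      unlist(lapply(rest, function(ids) {
        sample(ids, max(1L, round(val_fraction * length(ids))))
      }))
    })
    train <- setdiff(unlist(rest), val)
    list(train = train, validation = val, test = test)
  })
  structure(plan, k = k, class = "split_plan")
}

#' Inverse-frequency sampling weights per slide
#'
#' Weight is proportional to 1 / class frequency so that, sampling with
#' replacement, expected draws per class are equal — the imbalance correction
#' the training recipe uses instead of a weighted loss.
#'
#' @param labels Character vector of slide labels (RC/NRC).
#' @return Numeric weights summing to 1.
#' @export
sample_weights <- function(labels) {
  assert_that(length(unique(labels)) == 2L,
              "both classes must be present to weight the sampler")
  freq <- table(labels)
  w <- 1 / as.numeric(freq[labels])
  w / sum(w)
}

adam_state <- function(params, config) {
  arrays <- param_names(params$config)
  list(m = lapply(params[arrays], function(x) x * 0),
       v = lapply(params[arrays], function(x) x * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, state, tc) {
  arrays <- names(grads)
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  for (nm in arrays) {
    gg <- grads[[nm]] + tc$weight_decay * params[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gg
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gg^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - tc$learning_rate * mhat / (sqrt(vhat) + state$eps)
  }
  list(params = params, state = state)
}

mean_loss <- function(bags, keyset, params) {
  mean(vapply(bags, function(b) {
    damil_loss(damil_forward(b, keyset, params), b$label)
  }, numeric(1)))
}

#' Train the aggregator on one fold
#'
#' Runs the full recipe: weighted with-replacement sampling of one bag per
#' step (an epoch is `length(train_bags)` draws), Adam updates, per-epoch
#' validation loss, early stopping after the warm-up, and returns the
#' best-validation checkpoint. Refuses to run if the key set's provenance
#' mentions any validation slide (leakage guard).
#'
#' @param train_bags,val_bags Lists of [embedding_bag()]s.
#' @param keyset A `damil_keyset` built from `train_bags` only.
#' @param model_config A [damil_config()].
#' @param tc A [train_config()].
#' @return List with `params` (best checkpoint) and `state` (a `train_state`:
#'   per-epoch `train_loss`, `val_loss`, `best_epoch`, `stop_reason`).
#' @export
train_fold <- function(train_bags, val_bags, keyset, model_config,
                       tc = train_config()) {
  train_ids <- vapply(train_bags, function(b) b$slide_id, character(1))
  bad <- setdiff(unique(keyset$provenance$slide_id), train_ids)
  if (length(bad)) {
    stop_damil("key set references non-training slides (%s): data leakage",
               paste(utils::head(bad, 3), collapse = ", "))
  }
  labels <- vapply(train_bags, function(b) b$label, character(1))
  w <- sample_weights(labels)
  params <- init_params(model_config)
  opt <- adam_state(params, tc)
  arrays <- param_names(model_config)

  best_val <- Inf; best_params <- params; best_epoch <- 0L
  no_improve <- 0L; stop_reason <- "max_epochs"
  train_loss <- val_loss <- numeric(0)

  with_seed(derive_seed(tc$seed, 90008L), {
    for (epoch in seq_len(tc$max_epochs)) {
      draws <- sample.int(length(train_bags), length(train_bags),
                          replace = TRUE, prob = w)
      ep_loss <- 0
      for (i in draws) {
        out <- damil_forward(train_bags[[i]], keyset, params)
        ep_loss <- ep_loss + damil_loss(out, train_bags[[i]]$label)
        grads <- damil_backward(out, train_bags[[i]]$label, params)
        upd <- adam_step(params, grads[arrays], opt, tc)
        params <- upd$params; opt <- upd$state
      }
      train_loss[epoch] <- ep_loss / length(draws)
      val_loss[epoch] <- mean_loss(val_bags, keyset, params)

      if (val_loss[epoch] < best_val) {
        best_val <- val_loss[epoch]; best_params <- params; best_epoch <- epoch
      }
      if (epoch > tc$min_epochs) {
        no_improve <- if (val_loss[epoch] < best_val ||
                          best_epoch == epoch) 0L else no_improve + 1L
        if (no_improve >= tc$patience) { stop_reason <- "early_stop"; break }
      }
    }
  })
  state <- structure(
    list(epochs = length(train_loss), train_loss = train_loss,
         val_loss = val_loss, best_epoch = best_epoch,
         stop_reason = stop_reason),
    class = "train_state"
  )
  list(params = best_params, state = state)
}

#' Early-stopping decision on a validation-loss trace
#'
#' Pure stop-rule arithmetic, exposed so the contract can be unit-tested on
#' scripted traces: returns the 1-based epoch after which training stops for
#' the given trace, or `length(trace)` if the rule never fires.
#'
#' @param trace Numeric validation losses per epoch.
#' @param tc A [train_config()].
#' @export
early_stop_epoch <- function(trace, tc = train_config()) {
  best <- Inf; no_improve <- 0L
  for (epoch in seq_along(trace)) {
    improved <- trace[epoch] < best
    if (improved) best <- trace[epoch]
    if (epoch > tc$min_epochs) {
      no_improve <- if (improved) 0L else no_improve + 1L
      if (no_improve >= tc$patience) return(epoch)
    }
    if (epoch >= tc$max_epochs) return(epoch)
  }
  length(trace)
}

#' Run the full stratified cross-validation
#'
#' Per fold: build the key set from that fold's training slides only, train,
#' and score every test bag; returns the pooled slide-level predictions (each
#' slide predicted in exactly one fold) plus fold-wise metrics reported as
#' mean +/- sd.
#'
#' @param bags List of all [embedding_bag()]s.
#' @param cohort The slide-level cohort table.
#' @param plan A `split_plan` from [make_splits()]; built internally if NULL.
#' @param crl A [crl_config()].
#' @param model_config A [damil_config()]; its `d` must match the bags.
#' @param tc A [train_config()].
#' @param seed Seed used when `plan` is NULL and for per-fold training.
#' @return List with `predictions` (data.frame slide_id, patient_id, fold,
#'   p_rc, label), `fold_metrics`, `metrics` (mean/sd per metric), and
#'   `fold_states`.
#' @export
run_crossval <- function(bags, cohort, plan = NULL, crl = crl_config(),
                         model_config = NULL, tc = train_config(), seed = 1L) {
  validate_cohort(cohort)
  if (is.null(plan)) plan <- make_splits(cohort, seed = seed)
  d <- bag_dim(bags[[1]])
  if (is.null(model_config)) model_config <- damil_config(d = d, seed = seed)
  assert_that(model_config$d == d, "model config D does not match bag dimension")

  by_patient <- split(seq_along(bags),
                      vapply(bags, function(b) b$patient_id, character(1)))
  pick <- function(ids) bags[unlist(by_patient[ids], use.names = FALSE)]

  preds <- list(); fold_metrics <- list(); fold_states <- list()
  for (f in seq_along(plan)) {
    fold <- plan[[f]]
    train_bags <- pick(fold$train)
    val_bags <- pick(fold$validation)
    test_bags <- pick(fold$test)
    keyset <- build_keyset(train_bags, crl)
    fold_tc <- tc
    fold_tc$seed <- derive_seed(tc$seed, 90100L + f)
    fold_model <- model_config
    fold_model$seed <- derive_seed(model_config$seed, 90200L + f)
    fit <- train_fold(train_bags, val_bags, keyset, fold_model, fold_tc)
    p_rc <- vapply(test_bags, function(b) {
      damil_forward(b, keyset, fit$params)$p_rc
    }, numeric(1))
    preds[[f]] <- data.frame(
      slide_id = vapply(test_bags, function(b) b$slide_id, character(1)),
      patient_id = vapply(test_bags, function(b) b$patient_id, character(1)),
      fold = f,
      p_rc = p_rc,
      label = vapply(test_bags, function(b) b$label, character(1)),
      stringsAsFactors = FALSE
    )
    fold_metrics[[f]] <- classification_metrics(p_rc, preds[[f]]$label)
    fold_states[[f]] <- fit$state
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  mm <- do.call(rbind, lapply(fold_metrics, as.data.frame))
  metrics <- data.frame(
    metric = names(mm),
    mean = vapply(mm, mean, numeric(1)),
    sd = vapply(mm, stats::sd, numeric(1)),
    row.names = NULL
  )
  list(predictions = predictions, fold_metrics = fold_metrics,
       metrics = metrics, fold_states = fold_states)
}
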