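# Synthetic cohorts: embedding bags with a planted minority "witness" signal in
# RC slides, exponential recurrence-free times with a configurable true hazard
# ratio, and administrative censoring at the five-year horizon. Everything is
# deterministic given the spec seed so ground truth is available to every test.

#' Specification of a synthetic cohort
#'
#' Defaults describe the regime the pipeline targets: a 71 RC / 118 NRC
#' patient cohort (the scale of a single-institution resection series), one to
#' three slides per patient (~2.4 slides/patient), bags of 40-80 instance
#' embeddings, a 20% witness rate in RC bags with the signal mean separated
#' from background by 4 Euclidean units, a true hazard ratio of 2.3 between
#' RC and NRC recurrence processes, and administrative censoring at 60 months.
#' The NRC baseline rate is fixed so that ~35% of NRC patients have an event
#' before 60 months, keeping both events and censoring present in every draw.
#'
#' @param n_rc,n_nrc Patient counts per class (>= 1).
#' @param slides_per_patient Integer range `c(lo, hi)` of slides per patient.
#' @param n_instances Integer range `c(lo, hi)` of instances per bag.
#' @param dim Embedding dimension D (>= 2).
#' @param witness_rate Fraction of signal instances in RC bags, in `[0, 1]`.
#' @param effect_size Euclidean distance between signal and background means.
#' @param true_hr True hazard ratio (> 0) of RC relative to NRC.
#' @param censor_horizon Administrative censoring time in months.
#' @param seed Integer seed governing all draws.
#' @return A `synthetic_cohort_spec` list.
#' @export
cohort_spec <- function(n_rc = 71, n_nrc = 118,
                        slides_per_patient = c(1, 3),
                        n_instances = c(40, 80),
                        dim = 64,
                        witness_rate = 0.2,
                        effect_size = 4,
                        true_hr = 2.3,
                        censor_horizon = 60,
                        seed = 1L) {
  assert_that(is_count(n_rc) && is_count(n_nrc), "n_rc and n_nrc must be >= 1")
  assert_that(is_count(dim, min = 2), "dim must be an integer >= 2")
  assert_that(witness_rate >= 0 && witness_rate <= 1, "witness_rate must lie in [0, 1]")
  assert_that(is.numeric(true_hr) && true_hr > 0, "true_hr must be > 0")
  assert_that(effect_size >= 0, "effect_size must be non-negative")
  slides_per_patient <- rep_len(as.integer(slides_per_patient), 2L)
  n_instances <- rep_len(as.integer(n_instances), 2L)
  assert_that(slides_per_patient[1] >= 1 && diff(slides_per_patient) >= 0,
              "slides_per_patient must be an increasing range >= 1")
  assert_that(n_instances[1] >= 1 && diff(n_instances) >= 0,
              "n_instances must be an increasing range >= 1")
  assert_that(censor_horizon > 0, "censor_horizon must be positive")
  structure(
    list(
      n_rc = as.integer(n_rc), n_nrc = as.integer(n_nrc),
      slides_per_patient = slides_per_patient,
      n_instances = n_instances,
      dim = as.integer(dim),
      witness_rate = witness_rate,
      effect_size = effect_size,
      true_hr = true_hr,
      censor_horizon = censor_horizon,
      seed = as.integer(seed)
    ),
    class = "synthetic_cohort_spec"
  )
}

# Unit direction of the planted signal; fixed per cohort spec (depends only on
# spec$seed and dim) so all RC bags share one signal subspace.
signal_direction <- function(spec) {
  with_seed(derive_seed(spec$seed, 90001L), {
    v <- stats::rnorm(spec$dim)
    v / sqrt(sum(v^2))
  })
}

# Baseline monthly hazard for NRC patients: ~35% event probability by 60 months.
nrc_base_rate <- function(censor_horizon = 60) -log(1 - 0.35) / censor_horizon

#' Generate one embedding bag
#'
#' RC bags contain `ceiling(witness_rate * n)` signal instances drawn from an
#' isotropic Gaussian centred at `effect_size` times a fixed unit direction;
#' all remaining (and all NRC) instances come from the standard isotropic
#' Gaussian at the origin. Signal rows come first; the aggregator is
#' permutation-invariant, so order carries no information.
#'
#' @param label `"RC"` or `"NRC"`.
#' @param spec A [cohort_spec()].
#' @param seed Integer seed for this bag.
#' @param n Optional instance count; drawn from `spec$n_instances` if `NULL`.
#' @param slide_id,patient_id Identifiers stored on the bag.
#' @return An [embedding_bag()] with `meta$n_signal` ground truth.
#' @export
gen_bag <- function(label, spec, seed, n = NULL,
                    slide_id = "slide1", patient_id = "pt1") {
  assert_that(length(label) == 1L && label %in% c("RC", "NRC"),
              "label must be 'RC' or 'NRC'")
  dir <- signal_direction(spec)
  with_seed(seed, {
    if (is.null(n)) {
      n <- sample(seq(spec$n_instances[1], spec$n_instances[2]), 1L)
    }
    n_signal <- if (label == "RC") as.integer(ceiling(spec$witness_rate * n)) else 0L
    E <- matrix(stats::rnorm(n * spec$dim), nrow = n, ncol = spec$dim)
    if (n_signal > 0) {
      E[seq_len(n_signal), ] <- E[seq_len(n_signal), , drop = FALSE] +
        matrix(spec$effect_size * dir, nrow = n_signal, ncol = spec$dim, byrow = TRUE)
    }
    embedding_bag(E, slide_id, patient_id, label,
                  meta = list(n_signal = n_signal))
  })
}

#' Generate a full synthetic cohort
#'
#' Draws the per-patient slide counts, all embedding bags, and exponential
#' recurrence-free times (rate `lambda_nrc` for NRC, `lambda_nrc * true_hr`
#' for RC) censored administratively at `censor_horizon` months.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `bags` (list of [embedding_bag()]) and
#'   `cohort` (slide-level table: patient_id, slide_id, label, time_months,
#'   event).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  labels <- c(rep("RC", spec$n_rc), rep("NRC", spec$n_nrc))
  n_pat <- length(labels)
  patient_id <- sprintf("pt%03d", seq_len(n_pat))
  lambda0 <- nrc_base_rate(spec$censor_horizon)

  surv <- with_seed(derive_seed(spec$seed, 90002L), {
    n_slides <- sample(seq(spec$slides_per_patient[1], spec$slides_per_patient[2]),
                       n_pat, replace = TRUE)
    rate <- ifelse(labels == "RC", lambda0 * spec$true_hr, lambda0)
    t_raw <- stats::rexp(n_pat, rate = rate)
    list(n_slides = n_slides, t_raw = t_raw)
  })
  event <- as.integer(surv$t_raw <= spec$censor_horizon)
  time_months <- pmin(surv$t_raw, spec$censor_horizon)

  bags <- vector("list", sum(surv$n_slides))
  rows <- vector("list", sum(surv$n_slides))
  k <- 0L
  for (i in seq_len(n_pat)) {
    for (s in seq_len(surv$n_slides[i])) {
      k <- k + 1L
      sid <- sprintf("%s_s%d", patient_id[i], s)
      bags[[k]] <- gen_bag(labels[i], spec,
                           seed = derive_seed(spec$seed, 100000L + k),
                           slide_id = sid, patient_id = patient_id[i])
      rows[[k]] <- data.frame(
        patient_id = patient_id[i], slide_id = sid, label = labels[i],
        time_months = time_months[i], event = event[i],
        stringsAsFactors = FALSE
      )
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  validate_cohort(cohort)
  list(bags = bags, cohort = cohort)
}

#' Specification of a toy slide image
#'
#' A toy slide is a flat background with a textured "normal tissue" region and
#' a set of circular tumor blobs, each with known center/radius — ground truth
#' for the tissue-detection and tumor-bulk stages.
#'
#' @param width,height Image size in pixels (> 0).
#' @param background_color,normal_texture_color RGB triplets in 0-255.
#' @param tumor_blobs List of `list(center = c(x, y), radius, color)` entries
#'   (0-based pixel centers, level-0 coordinates).
#' @param seed Integer seed for the texture noise.
#' @return A `toy_slide_spec` list.
#' @export
toy_slide_spec <- function(width = 512, height = 512,
                           background_color = c(255, 255, 255),
                           tumor_blobs = list(),
                           normal_texture_color = c(230, 180, 200),
                           seed = 1L) {
  assert_that(width > 0 && height > 0, "zero-area slide spec")
  for (b in tumor_blobs) {
    assert_that(b$center[1] - b$radius >= 0 && b$center[1] + b$radius < width &&
                b$center[2] - b$radius >= 0 && b$center[2] + b$radius < height,
                "tumor blob must lie within image bounds")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         background_color = background_color, tumor_blobs = tumor_blobs,
         normal_texture_color = normal_texture_color, seed = as.integer(seed)),
    class = "toy_slide_spec"
  )
}

#' Generate a toy slide image with ground-truth masks
#'
#' The image is a `height x width x 3` array (0-255). Tissue (normal texture
#' plus tumor blobs) fills the central region; the tumor mask is the union of
#' the rasterized discs, and the tissue mask is every non-background pixel, so
#' tissue always contains tumor.
#'
#' @param spec A [toy_slide_spec()].
#' @param tissue_margin Fraction of each border left as bare background.
#' @return List with `image` (array), `tumor_mask`, `tissue_mask`
#'   (0/1 matrices, `height x width`).
#' @export
gen_toy_slide <- function(spec, tissue_margin = 0.1) {
  stopifnot(inherits(spec, "toy_slide_spec"))
  w <- spec$width; h <- spec$height
  img <- array(0, dim = c(h, w, 3))
  for (c in 1:3) img[, , c] <- spec$background_color[c]

  tissue <- matrix(0L, h, w)
  mx <- floor(w * tissue_margin); my <- floor(h * tissue_margin)
  rows <- (my + 1):(h - my); cols <- (mx + 1):(w - mx)
  tissue[rows, cols] <- 1L

  noise <- with_seed(derive_seed(spec$seed, 90003L),
                     matrix(stats::rnorm(h * w, sd = 6), h, w))
  for (c in 1:3) {
    plane <- img[, , c]
    plane[tissue == 1L] <- pmin(255, pmax(0, spec$normal_texture_color[c] +
                                               noise[tissue == 1L]))
    img[, , c] <- plane
  }

  # Rasterize tumor discs over the tissue; pixel (row i, col j) has 0-based
  # center (j - 1, i - 1) in (x, y).
  tumor <- matrix(0L, h, w)
  xs <- matrix(seq_len(w) - 1L, h, w, byrow = TRUE)
  ys <- matrix(seq_len(h) - 1L, h, w)
  for (b in spec$tumor_blobs) {
    inside <- (xs - b$center[1])^2 + (ys - b$center[2])^2 <= b$radius^2
    tumor[inside] <- 1L
    for (c in 1:3) {
      plane <- img[, , c]
      plane[inside] <- pmin(255, pmax(0, b$color[c] + noise[inside]))
      img[, , c] <- plane
    }
  }
  tissue[tumor == 1L] <- 1L
  list(image = img, tumor_mask = tumor, tissue_mask = tissue)
}
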