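#' Embedding bag: the multiple-instance unit of computation
#'
#' A bag holds the `n x D` matrix of patch embeddings from one whole-slide
#' image together with its slide/patient identity, the five-year recurrence
#' label, and (optionally) survival metadata. Every downstream stage —
#' tumor-bulk filtering, key-set selection, the dual-attention aggregator —
#' consumes bags.
#'
#' @param embeddings Numeric `n x D` matrix, one row per patch.
#' @param slide_id,patient_id Character scalars identifying the slide/patient.
#' @param label `"RC"` (recurrence within five years) or `"NRC"`.
#' @param meta Optional named list of extra per-slide metadata.
#' @return An object of class `embedding_bag`.
#' @export
embedding_bag <- function(embeddings, slide_id, patient_id, label,
                          meta = list()) {
  embeddings <- as.matrix(embeddings)
  assert_that(is.numeric(embeddings), "bag embeddings must be numeric")
  assert_that(all(is.finite(embeddings)), "bag embeddings must be finite")
  label <- match.arg(label, c("RC", "NRC"))
  structure(
    list(
      embeddings = embeddings,
      slide_id = as.character(slide_id),
      patient_id = as.character(patient_id),
      label = label,
      meta = meta
    ),
    class = "embedding_bag"
  )
}

#' @export
print.embedding_bag <- function(x, ...) {
  cat(sprintf(
    "<embedding_bag> slide=%s patient=%s label=%s n=%d D=%d\n",
    x$slide_id, x$patient_id, x$label, nrow(x$embeddings), ncol(x$embeddings)
  ))
  invisible(x)
}

#' @export
dim.embedding_bag <- function(x) dim(x$embeddings)

bag_dim <- function(bag) ncol(bag$embeddings)
bag_size <- function(bag) nrow(bag$embeddings)

#' Write / read a list of bags as a plain-text bundle
#'
#' Each slide is stored as `<slide_id>.csv` (the embedding matrix, no header)
#' plus a single `bags.json` index with per-slide ids and labels. A plain-text
#' layout replaces a binary HDF5 container so that fixtures remain
#' human-readable and portable.
#'
#' @param bags List of [embedding_bag()] objects.
#' @param dir Directory to create/populate.
#' @return `dir`, invisibly.
#' @export
write_bags <- function(bags, dir) {
  assert_that(length(bags) >= 1, "no bags to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index <- lapply(bags, function(b) {
    file <- paste0(b$slide_id, ".csv")
    utils::write.table(
      b$embeddings, file.path(dir, file),
      sep = ",", row.names = FALSE, col.names = FALSE
    )
    list(
      slide_id = b$slide_id, patient_id = b$patient_id,
      label = b$label, file = file,
      n = nrow(b$embeddings), dim = ncol(b$embeddings)
    )
  })
  jsonlite::write_json(index, file.path(dir, "bags.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_bags
#' @export
read_bags <- function(dir) {
  index_file <- file.path(dir, "bags.json")
  assert_that(file.exists(index_file), "no bags.json index under %s", dir)
  index <- jsonlite::read_json(index_file)
  lapply(index, function(rec) {
    mat <- as.matrix(utils::read.table(
      file.path(dir, rec$file), sep = ",", header = FALSE
    ))
    dimnames(mat) <- NULL
    embedding_bag(mat, rec$slide_id, rec$patient_id, rec$label)
  })
}

#' Read / write the cohort table
#'
#' The cohort CSV has one row per slide with columns `patient_id`, `slide_id`,
#' `label` (RC/NRC), `time_months`, `event` (0/1).
#'
#' @param cohort A cohort `data.frame`.
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(cohort)
  cohort
}

validate_cohort <- function(cohort) {
  needed <- c("patient_id", "slide_id", "label", "time_months", "event")
  assert_that(all(needed %in% names(cohort)),
              "cohort table must have columns %s", paste(needed, collapse = ", "))
  assert_that(all(cohort$label %in% c("RC", "NRC")), "labels must be RC or NRC")
  assert_that(all(cohort$event %in% c(0L, 1L)), "event must be 0/1")
  assert_that(all(cohort$time_months >= 0), "times must be non-negative")
  lab <- tapply(cohort$label, cohort$patient_id, function(l) length(unique(l)))
  assert_that(all(lab == 1L), "all slides of a patient must share its label")
  invisible(cohort)
}
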