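#' Labeled image dataset
#'
#' Container for graded histology-style images: a list of `H x W x 3`
#' arrays, one grade per image (e.g. OSCC differentiation grades
#' `"I"/"II"/"III"`), sample identifiers, and augmentation provenance
#' (`source_id`, `transform_tag`) used for leakage audits.
#'
#' @param images List of `H x W x 3` numeric arrays.
#' @param grades Character or factor vector, one grade per image.
#' @param ids Character sample identifiers (unique).
#' @param source_id Identifier of the originating sample; defaults to `ids`
#'   (i.e. all samples are originals).
#' @param transform_tag Augmentation tag per sample; defaults to
#'   `"original"`.
#' @return An object of class `"labeled_dataset"`.
#' @export
labeled_dataset <- function(images, grades, ids = NULL,
                            source_id = NULL, transform_tag = NULL) {
  stopifnot(is.list(images))
  n <- length(images)
  grades <- as.character(grades)
  if (length(grades) != n) stop("one grade per image required", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("s%04d", seq_len(n))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("sample ids must be unique", call. = FALSE)
  if (is.null(source_id)) source_id <- ids
  if (is.null(transform_tag)) transform_tag <- rep("original", n)
  stopifnot(length(source_id) == n, length(transform_tag) == n)
  structure(list(images = images, grades = grades, ids = ids,
                 source_id = as.character(source_id),
                 transform_tag = as.character(transform_tag)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cts <- class_counts(x)
  cat(sprintf("labeled_dataset: %d samples (%s)\n", length(x$images),
              paste(sprintf("%s=%d", names(cts), cts), collapse = ", ")))
  invisible(x)
}

#' Per-grade sample counts
#' @param dataset A `"labeled_dataset"`.
#' @return Named integer vector.
#' @export
class_counts <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  tab <- table(dataset$grades)
  stats::setNames(as.integer(tab), names(tab))
}

#' Subset a labeled dataset by index
#' @param dataset A `"labeled_dataset"`.
#' @param idx Integer or logical index vector.
#' @return A `"labeled_dataset"` restricted to `idx`.
#' @export
dataset_subset <- function(dataset, idx) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  labeled_dataset(dataset$images[idx], dataset$grades[idx], dataset$ids[idx],
                  dataset$source_id[idx], dataset$transform_tag[idx])
}

#' Stratified k-fold assignment
#'
#' Assigns every sample to exactly one of `k` folds so that, per grade,
#' fold sizes differ by at most one (each test fold carries approximately
#' the same class representation). Within each class the samples are
#' shuffled with the given seed and dealt round-robin; the round-robin
#' starting fold is staggered by class index so that the per-class
#' remainders spread over different folds rather than piling onto fold 1.
#'
#' @param dataset A `"labeled_dataset"` of original (unaugmented) samples.
#' @param k Number of folds (default 5).
#' @param seed Integer seed; the assignment is reproducible given the seed.
#' @return An object of class `"fold_assignment"`: list with `k`, `fold`
#'   (integer vector in `1..k`, aligned with the dataset and named by
#'   sample id) and `seed`.
#' @export
stratified_kfold <- function(dataset, k = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"), k >= 2L)
  cts <- class_counts(dataset)
  small <- names(cts)[cts < k]
  if (length(small) > 0L) {
    stop("stratification impossible: class(es) with fewer than k = ", k,
         " members: ", paste(small, collapse = ", "), call. = FALSE)
  }
  classes <- names(cts)
  fold <- integer(length(dataset$ids))
  rng <- .seeded_rng(seed)
  for (j in seq_along(classes)) {
    idx <- which(dataset$grades == classes[j])
    idx <- idx[rng$permutation(length(idx))]
    offset <- (j - 1L) %% k
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
  }
  structure(list(k = as.integer(k),
                 fold = stats::setNames(fold, dataset$ids),
                 seed = as.integer(seed)),
            class = "fold_assignment")
}

# local RNG stream that never touches the global .Random.seed
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    get(".Random.seed", globalenv())
  })
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    force(expr)
  }
  list(
    permutation = function(n) with_state(sample.int(n)),
    runif = function(n, min = 0, max = 1) with_state(stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(stats::rnorm(n, mean, sd)),
    rpois = function(n, lambda) with_state(stats::rpois(n, lambda)),
    sample_int = function(n, size, replace = FALSE) with_state(sample.int(n, size, replace)),
    integer_seed = function() with_state(sample.int(.Machine$integer.max, 1L))
  )
}

#' Assemble the augmented training set for one fold
#'
#' Collects the originals of all non-test folds and adds their seven
#' geometric augmentations each, so the training set is exactly 8x the
#' training partition. The test fold is untouched and never augmented;
#' augmented samples inherit their source's grade and carry provenance.
#'
#' @param dataset The original `"labeled_dataset"` used to build `folds`.
#' @param folds A `"fold_assignment"` from [stratified_kfold()].
#' @param test_fold Fold index in `1..k` held out for testing.
#' @return A `"labeled_dataset"` of originals plus augmentations.
#' @examples
#' # a 257-image training partition yields 1799 new + 257 = 2056 images
#' @export
build_training_set <- function(dataset, folds, test_fold) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(folds, "fold_assignment"))
  if (!(test_fold %in% seq_len(folds$k))) {
    stop("test_fold must be in 1..", folds$k, call. = FALSE)
  }
  if (!identical(names(folds$fold), dataset$ids)) {
    stop("fold assignment does not match dataset ids", call. = FALSE)
  }
  tr <- which(folds$fold != test_fold)
  images <- vector("list", length(tr) * 8L)
  grades <- character(length(tr) * 8L)
  ids <- character(length(tr) * 8L)
  src <- character(length(tr) * 8L)
  tag <- character(length(tr) * 8L)
  pos <- 0L
  for (i in tr) {
    pos <- pos + 1L
    images[[pos]] <- dataset$images[[i]]
    grades[pos] <- dataset$grades[i]
    ids[pos] <- dataset$ids[i]
    src[pos] <- dataset$source_id[i]
    tag[pos] <- "original"
    for (aug in augment_seven(dataset$images[[i]], dataset$ids[i])) {
      pos <- pos + 1L
      images[[pos]] <- aug$pixels
      grades[pos] <- dataset$grades[i]
      ids[pos] <- paste0(dataset$ids[i], "_", aug$transform_tag)
      src[pos] <- dataset$source_id[i]
      tag[pos] <- aug$transform_tag
    }
  }
  labeled_dataset(images, grades, ids, src, tag)
}

#' Test partition for one fold
#'
#' @inheritParams build_training_set
#' @return The (unaugmented) `"labeled_dataset"` of the held-out fold.
#' @export
build_test_set <- function(dataset, folds, test_fold) {
  stopifnot(inherits(folds, "fold_assignment"))
  if (!(test_fold %in% seq_len(folds$k))) {
    stop("test_fold must be in 1..", folds$k, call. = FALSE)
  }
  dataset_subset(dataset, which(folds$fold == test_fold))
}

#' Audit train/test disjointness at the source level
#'
#' @param train,test `"labeled_dataset"` objects.
#' @return `TRUE` invisibly if no source id is shared; otherwise an error
#'   naming the leaked ids.
#' @export
assert_no_leakage <- function(train, test) {
  shared <- intersect(unique(train$source_id), unique(test$source_id))
  if (length(shared) > 0L) {
    stop("train/test leakage via source ids: ",
         paste(utils::head(shared, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
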