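#' Stratified test hold-out before augmentation
#'
#' Marks `round(n_class * test_fraction)` images per class as the immutable
#' test split (rounding half away from zero), using a seeded shuffle over a
#' stable lexicographic ordering of ids so the assignment is reproducible
#' across platforms. The remainder stays `unassigned` and forms the
#' augmentation pool. Test images keep `provenance = "original"` and are
#' never eligible for augmentation or GAN training.
#'
#' @param manifest a [new_manifest()] with all records unassigned.
#' @param test_fraction proportion in `[0, 1)` held out per class.
#' @param seed integer seed for the stratified shuffle.
#' @return the manifest with `split` updated.
#' @export
#' @examples
#' spec <- fixture_spec(2, 10, 16, seed = 1)
#' man <- generate_fixture_dataset(spec, tempfile(), write_images = FALSE)
#' manifest_summary(holdout_test(man, 0.2, seed = 1))
holdout_test <- function(manifest, test_fraction, seed = 1) {
  stop_if_not(is_manifest(manifest), "not a manifest")
  stop_if_not(test_fraction >= 0 && test_fraction < 1,
              "test_fraction must be in [0, 1)")
  stop_if_not(all(manifest$split == "unassigned"),
              "holdout_test() requires a fully unassigned manifest")
  test_ids <- unlist(purrr::map(class_names(manifest), function(cls) {
    ids <- sort(manifest$id[manifest$class == cls])
    n_test <- round_half_up(length(ids) * test_fraction)
    if (n_test == 0) return(character())
    with_seed(derive_seed(seed, "holdout", cls), sample(ids, n_test))
  }))
  manifest$split[manifest$id %in% test_ids] <- "test"
  restore_manifest(manifest, manifest)
}

#' Stratified train/validation split after augmentation
#'
#' Splits the per-class pool (unassigned originals plus augmented and
#' GAN-generated records) into `round(n * train_fraction)` training rows and
#' the rest validation, stratified per class with a seeded shuffle. The test
#' split is untouched.
#'
#' @param manifest a manifest after [holdout_test()] (and normally after
#'   [augment_pool()]).
#' @param train_fraction proportion in `(0, 1]` sent to training per class.
#' @param seed integer seed.
#' @param strict error (`TRUE`) or warn (`FALSE`) when no augmented records
#'   are present yet.
#' @return the manifest with `split` updated.
#' @export
train_val_split <- function(manifest, train_fraction, seed = 1, strict = TRUE) {
  stop_if_not(is_manifest(manifest), "not a manifest")
  stop_if_not(train_fraction > 0 && train_fraction <= 1,
              "train_fraction must be in (0, 1]")
  stop_if_not(!any(manifest$split %in% c("train", "val")),
              "manifest already has train/val assignments")
  if (!any(manifest$provenance %in% c("augmented", "gan"))) {
    msg <- "train_val_split() called before augmentation"
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  eligible <- manifest$split == "unassigned" &
    manifest$provenance %in% c("original", "augmented", "gan")
  train_ids <- unlist(purrr::map(class_names(manifest), function(cls) {
    ids <- sort(manifest$id[eligible & manifest$class == cls])
    n_train <- round_half_up(length(ids) * train_fraction)
    if (n_train == 0) return(character())
    with_seed(derive_seed(seed, "trainval", cls), sample(ids, n_train))
  }))
  manifest$split[eligible] <- ifelse(manifest$id[eligible] %in% train_ids,
                                     "train", "val")
  # filtered renderings follow their source image's split
  is_filt <- manifest$provenance == "filtered"
  if (any(is_filt)) {
    src_split <- manifest$split[match(manifest$source_id[is_filt], manifest$id)]
    manifest$split[is_filt] <- ifelse(is.na(src_split),
                                      manifest$split[is_filt], src_split)
  }
  restore_manifest(manifest, manifest)
}

#' Check strict test isolation
#'
#' Verifies that no derived (augmented or GAN) record descends from a test
#' image and that no id sits in two splits. Report-only: the manifest is
#' never mutated.
#'
#' @param manifest a manifest with splits assigned.
#' @return a list with `pass` (logical), `violations` (tibble of offending
#'   ids and reasons) and `n_violations`.
#' @export
verify_isolation <- function(manifest) {
  stop_if_not(is_manifest(manifest), "not a manifest")
  viol <- list()
  test_ids <- manifest$id[manifest$split == "test"]
  derived <- manifest[manifest$provenance %in% c("augmented", "gan"), ]
  bad_src <- derived[!is.na(derived$source_id) &
                       derived$source_id %in% test_ids, ]
  if (nrow(bad_src) > 0) {
    viol$leak <- tibble(id = bad_src$id,
                        reason = "derived from a test image")
  }
  dup <- manifest$id[duplicated(manifest$id)]
  if (length(dup) > 0) {
    viol$dup <- tibble(id = unique(dup), reason = "id appears more than once")
  }
  # augmented/GAN samples must never sit in the test split (filter
  # renderings of test images are derived bookkeeping, not new samples)
  bad_test <- manifest[manifest$split == "test" &
                         manifest$provenance %in% c("augmented", "gan"), ]
  if (nrow(bad_test) > 0) {
    viol$test_prov <- tibble(id = bad_test$id,
                             reason = "test image is not an original")
  }
  violations <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble(id = character(), reason = character())
  list(pass = nrow(violations) == 0,
       n_violations = nrow(violations),
       violations = violations)
}
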