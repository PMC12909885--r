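#' Dataset manifests
#'
#' A manifest is the bookkeeping ledger of the pipeline: one row per image
#' with its identity, class label, split assignment and provenance. It is a
#' plain tibble (class `nut_manifest`) so it composes with dplyr verbs; the
#' ordered class names travel along as an attribute.
#'
#' Columns:
#' \describe{
#'   \item{id}{unique string id}
#'   \item{path}{file path (possibly not yet written in dry runs)}
#'   \item{class}{class label, one of the manifest's `class_names`}
#'   \item{split}{`unassigned`, `test`, `train` or `val`}
#'   \item{provenance}{`original`, `augmented`, `gan` or `filtered`}
#'   \item{source_id}{id of the originating image, or `NA` for originals}
#' }
#'
#' @param records a data frame with the columns above.
#' @param class_names character vector giving the class order.
#' @return a `nut_manifest` tibble.
#' @export
new_manifest <- function(records, class_names) {
  m <- as_tibble(records)
  required <- c("id", "path", "class", "split", "provenance", "source_id")
  stop_if_not(all(required %in% names(m)),
              "manifest records need columns: %s", paste(required, collapse = ", "))
  stop_if_not(!anyDuplicated(m$id), "duplicate ids in manifest")
  stop_if_not(all(m$class %in% class_names),
              "manifest contains classes outside class_names")
  attr(m, "class_names") <- class_names
  class(m) <- c("nut_manifest", class(m))
  m
}

#' @rdname new_manifest
#' @param x object to test or coerce.
#' @export
is_manifest <- function(x) inherits(x, "nut_manifest")

#' Ordered class names of a manifest
#' @param manifest a `nut_manifest`.
#' @export
class_names <- function(manifest) attr(manifest, "class_names")

# rebuild attributes after dplyr operations strip them
restore_manifest <- function(m, template) {
  new_manifest(m, class_names(template))
}

#' Per (class x split x provenance) counts, recomputed from the records
#'
#' Counts are always derived from the rows, never cached, so they cannot
#' drift from the record list.
#'
#' @param manifest a `nut_manifest`.
#' @return a tibble with columns `class`, `split`, `provenance`, `n`.
#' @export
manifest_counts <- function(manifest) {
  manifest %>%
    as_tibble() %>%
    dplyr::count(.data$class, .data$split, .data$provenance, name = "n")
}

#' Compact split/provenance totals for a manifest
#'
#' @param manifest a `nut_manifest`.
#' @return a named list of totals: originals, test, pool (unassigned
#'   originals), augmented, gan, train, val and total.
#' @export
manifest_summary <- function(manifest) {
  # split/provenance totals count samples; filter-bank renderings of those
  # samples are bookkeeping rows and are tallied separately
  filtered <- sum(manifest$provenance == "filtered")
  m <- manifest[manifest$provenance != "filtered", ]
  s <- m$split
  p <- m$provenance
  pool <- sum(s %in% c("unassigned", "train", "val") & p == "original")
  aug <- sum(p == "augmented")
  gan <- sum(p == "gan")
  list(
    total = nrow(m),
    originals = sum(p == "original"),
    test = sum(s == "test"),
    pool = pool,
    augmented = aug,
    gan = gan,
    # the post-augmentation working set: pool + derived images, test excluded
    total_after_augmentation = pool + aug + gan,
    train = sum(s == "train"),
    val = sum(s == "val"),
    filtered_renderings = filtered
  )
}

#' Write / read a manifest as CSV with a JSON mirror
#'
#' The CSV holds the records; the JSON sidecar (same path with extension
#' `.json`) mirrors the records together with the class order so a manifest
#' round-trips exactly.
#'
#' @param manifest a `nut_manifest`.
#' @param path CSV file path.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(as_tibble(manifest), path)
  side <- sub("\\.csv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(
    list(class_names = class_names(manifest),
         records = as.data.frame(manifest)),
    side, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  side <- sub("\\.csv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  stop_if_not(file.exists(side), "manifest JSON sidecar missing: %s", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  rec <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  new_manifest(rec, meta$class_names)
}
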