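#' Dataset manifests
#'
#' A manifest is a data frame (class `"dataset_manifest"`) with one row per
#' image and columns `id`, `image_path`, `MA_mask`, `HE_mask`, `EX_mask`,
#' `SE_mask`, `labeled`, `split`.  Mask columns are `NA` when absent; `labeled`
#' is `TRUE` iff all four lesion masks are present; `split` is one of
#' `"train"`, `"val"`, `"test"`, `"unlabeled"`.
#'
#' @param df A data frame with the columns above (mask columns may be omitted
#'   and default to `NA`).
#' @return A validated `"dataset_manifest"`.
#' @export
as_manifest <- function(df) {
  for (col in paste0(LESIONS, "_mask"))
    if (is.null(df[[col]])) df[[col]] <- NA_character_
  if (is.null(df$labeled))
    df$labeled <- !Reduce(`|`, lapply(paste0(LESIONS, "_mask"),
                                      function(c) is.na(df[[c]])))
  if (is.null(df$split)) df$split <- ifelse(df$labeled, "train", "unlabeled")
  df <- df[c("id", "image_path", paste0(LESIONS, "_mask"), "labeled", "split")]
  df$id <- as.character(df$id)
  df$labeled <- as.logical(df$labeled)
  class(df) <- c("dataset_manifest", "data.frame")
  validate_manifest(df)
  df
}

validate_manifest <- function(m) {
  stopifnot(is.data.frame(m))
  if (anyDuplicated(m$id)) stop("manifest ids are not unique")
  if (!all(m$split %in% c("train", "val", "test", "unlabeled")))
    stop("invalid split values")
  has_all <- !Reduce(`|`, lapply(paste0(LESIONS, "_mask"),
                                 function(c) is.na(m[[c]])))
  if (!identical(as.logical(m$labeled), as.logical(has_all)))
    stop("'labeled' must be TRUE iff all four lesion masks are present")
  if (any(m$split == "unlabeled" & m$labeled))
    stop("entries in the unlabeled split cannot be labeled")
  invisible(m)
}

#' Discover images and masks under a directory
#'
#' Images are PNG/TIFF/JPEG files whose base name does not end in a lesion
#' suffix; the mask of lesion `L` for image `id` is looked up as `<id>_<L>`
#' with a mask extension (template configurable via `mask_suffix`).  Entries
#' are sorted by id.  A mask file with no matching image is a hard error; an
#' image with only some of the four masks is kept with `labeled = FALSE` and a
#' warning.
#'
#' @param root_dir Directory to scan.
#' @param mask_suffix Function or template mapping `(id, lesion)` to the mask
#'   base name; default template `"{id}_{lesion}"`.
#' @return A `"dataset_manifest"` with absolute paths.
#' @export
build_manifest <- function(root_dir, mask_suffix = "{id}_{lesion}") {
  if (!dir.exists(root_dir)) stop("directory does not exist: ", root_dir)
  exts <- c("png", "tif", "tiff", "jpg", "jpeg")
  files <- list.files(root_dir)
  ext <- tolower(tools::file_ext(files))
  files <- files[ext %in% exts]
  base <- tools::file_path_sans_ext(files)
  mask_name <- function(id, lesion)
    gsub("\\{lesion\\}", lesion, gsub("\\{id\\}", id, mask_suffix, fixed = FALSE))
  is_mask <- grepl(paste0("_(", paste(LESIONS, collapse = "|"), ")$"), base)
  img_files <- files[!is_mask]
  img_ids <- base[!is_mask]
  mask_ids <- sub(paste0("_(", paste(LESIONS, collapse = "|"), ")$"), "",
                  base[is_mask])
  orphan <- setdiff(mask_ids, img_ids)
  if (length(orphan))
    stop("mask file(s) without a matching image: ", paste(orphan, collapse = ", "))
  o <- order(img_ids)
  img_ids <- img_ids[o]; img_files <- img_files[o]
  rows <- lapply(seq_along(img_ids), function(i) {
    id <- img_ids[i]
    masks <- vapply(LESIONS, function(L) {
      cand <- paste0(mask_name(id, L), ".", exts)
      hit <- cand[file.exists(file.path(root_dir, cand))]
      if (length(hit)) normalizePath(file.path(root_dir, hit[1])) else NA_character_
    }, "")
    n_masks <- sum(!is.na(masks))
    if (n_masks > 0 && n_masks < 4)
      warning("image '", id, "' has only ", n_masks,
              " of 4 lesion masks; treated as unlabeled", call. = FALSE)
    labeled <- n_masks == 4L
    data.frame(id = id,
               image_path = normalizePath(file.path(root_dir, img_files[i])),
               MA_mask = masks[["MA"]], HE_mask = masks[["HE"]],
               EX_mask = masks[["EX"]], SE_mask = masks[["SE"]],
               labeled = labeled,
               split = if (labeled) "train" else "unlabeled")
  })
  as_manifest(do.call(rbind, rows))
}

#' Split sizes under the package's rounding rule
#'
#' `train = ceiling(N * f_train)`, `val = round(N * f_val)`, `test` takes the
#' remainder (clamped so the three sizes are non-negative and sum to `N`).
#' With `N = 1842` and fractions `(0.70, 0.05, 0.25)` this yields
#' `(1290, 92, 460)`.
#'
#' @param n Number of entries.
#' @param fractions Length-3 non-negative vector `(train, val, test)` summing
#'   to 1 (tolerance 1e-9).
#' @return Named integer vector `c(train =, val =, test =)`.
#' @export
split_sizes <- function(n, fractions) {
  stopifnot(length(fractions) == 3, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  tr <- min(n, as.integer(ceiling(n * fractions[1])))
  va <- min(n - tr, as.integer(round(n * fractions[2])))
  c(train = tr, val = va, test = n - tr - va)
}

#' Deterministic train/val/test split of a labeled manifest
#'
#' Entries are shuffled with a seeded Mersenne-Twister stream and assigned to
#' the three splits by contiguous slicing, so the same `(manifest, fractions,
#' seed)` always produces the identical partition.  Sizes follow
#' [split_sizes()].
#'
#' @param m A `"dataset_manifest"`; all entries must be labeled.
#' @param fractions Train/val/test fractions (default `c(0.70, 0.05, 0.25)`).
#' @param seed Integer seed for the shuffle.
#' @return The manifest with `split` reassigned; attributes `split_seed`,
#'   `split_rng`, and `split_rule` record how the partition was made.
#' @export
split_manifest <- function(m, fractions = c(0.70, 0.05, 0.25), seed = 1L) {
  validate_manifest(m)
  if (!all(m$labeled)) stop("split_manifest requires a fully labeled manifest")
  n <- nrow(m)
  sz <- split_sizes(n, fractions)
  perm <- with_seed(seed, sample.int(n))
  split <- character(n)
  split[perm[seq_len(sz["train"])]] <- "train"
  split[perm[sz["train"] + seq_len(sz["val"])]] <- "val"
  split[perm[sz["train"] + sz["val"] + seq_len(sz["test"])]] <- "test"
  m$split <- split
  attr(m, "split_seed") <- seed
  attr(m, "split_rng") <- "Mersenne-Twister"
  attr(m, "split_rule") <- "train=ceiling(N*f1); val=round(N*f2); test=remainder"
  m
}

#' Concatenate manifests into one pool
#'
#' @param ... `"dataset_manifest"` objects with disjoint ids.
#' @return The combined manifest.
#' @export
merge_manifests <- function(...) {
  ms <- list(...)
  out <- do.call(rbind, lapply(ms, as.data.frame))
  as_manifest(out)
}

#' Read / write a manifest (CSV or JSON, chosen by file extension)
#'
#' Both formats round-trip losslessly, including absent mask paths.
#'
#' @param m A `"dataset_manifest"`.
#' @param path File path ending in `.csv` or `.json`.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` returns
#'   the manifest.
#' @export
write_manifest <- function(m, path) {
  validate_manifest(m)
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(m)
  if (ext == "csv") {
    write.csv(df, path, row.names = FALSE, na = "")
  } else if (ext == "json") {
    jsonlite::write_json(df, path, na = "null", auto_unbox = FALSE)
  } else stop("unsupported manifest format: .", ext)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "csv") {
    read.csv(path, na.strings = "", colClasses = "character")
  } else if (ext == "json") {
    jsonlite::fromJSON(path)
  } else stop("unsupported manifest format: .", ext)
  df$labeled <- as.logical(df$labeled)
  as_manifest(df)
}
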