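## Ingestion of segmentation masks and label tables, and report output.
## Mask volumes are binarized at ingestion (any nonzero voxel becomes 1);
## the core containers require strict 0/1 labels.

#' Read a pilot dataset from mask volumes
#'
#' Reads one volume per image per source and assembles a [pilot_dataset()].
#' NIfTI files (`.nii`, `.nii.gz`) are read with the RNifti package;
#' MetaImage files (`.mhd`) with a built-in reader. All volumes of one
#' image must share dimensions. Nonzero voxels binarize to 1; volumes are
#' flattened in the array's native (column-major) order. When every image
#' shares the same dimensions they are recorded as the pilot's `grid_shape`.
#'
#' @param a,b,l,h Character vectors of file paths, one per image, in
#'   matching order; `h` may be `NULL`.
#' @return A [pilot_dataset()].
#' @export
read_mask_set <- function(a, b, l, h = NULL) {
  n <- length(a)
  if (length(b) != n || length(l) != n || (!is.null(h) && length(h) != n))
    stop("each source must provide one file per image")
  read_one <- function(path) {
    if (!file.exists(path)) stop("cannot read mask file: ", path)
    if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
      arr <- as.array(RNifti::readNifti(path))
    } else if (grepl("\\.mhd$", path, ignore.case = TRUE)) {
      arr <- read_metaimage(path)
    } else stop("unsupported mask format (need .nii, .nii.gz or .mhd): ", path)
    arr
  }
  dims <- vector("list", n)
  get_labels <- function(paths) lapply(seq_len(n), function(k) {
    arr <- read_one(paths[k])
    dk <- dim(arr)
    if (is.null(dims[[k]])) dims[[k]] <<- dk
    else if (!identical(dims[[k]], dk))
      stop("dimension mismatch for image ", k, " (", paths[k], "): got ",
           paste(dk, collapse = "x"), ", expected ",
           paste(dims[[k]], collapse = "x"))
    as.integer(arr != 0)
  })
  la <- get_labels(a); lb <- get_labels(b); ll <- get_labels(l)
  lh <- if (is.null(h)) NULL else get_labels(h)
  shared <- if (n > 0 && all(vapply(dims, identical, logical(1), dims[[1]])))
    dims[[1]] else NULL
  pilot_dataset(la, lb, ll, lh, grid_shape = shared)
}

## internal: minimal MetaImage (.mhd + raw) reader/writer, sufficient for
## binary masks. Supported element types cover the common integer cases.
.met_types <- list(
  MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
  MET_INT = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE))

read_metaimage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), character(1))
  hdr <- stats::setNames(vals, trimws(keys))
  need <- c("DimSize", "ElementType", "ElementDataFile")
  if (!all(need %in% names(hdr)))
    stop("malformed MetaImage header (", path, "): missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  dims <- as.integer(strsplit(trimws(hdr[["DimSize"]]), "\\s+")[[1]])
  ty <- .met_types[[trimws(hdr[["ElementType"]])]]
  if (is.null(ty))
    stop("unsupported MetaImage element type: ", hdr[["ElementType"]])
  raw_path <- file.path(dirname(path), trimws(hdr[["ElementDataFile"]]))
  if (!file.exists(raw_path)) stop("missing MetaImage data file: ", raw_path)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  x <- readBin(con, ty$what, n = prod(dims), size = ty$size,
               signed = ty$signed, endian = "little")
  if (length(x) != prod(dims))
    stop("MetaImage data file shorter than DimSize implies: ", raw_path)
  array(x, dim = dims)
}

write_metaimage <- function(arr, path) {
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  hdr <- c("ObjectType = Image",
           paste0("NDims = ", length(dim(arr))),
           paste0("DimSize = ", paste(dim(arr), collapse = " ")),
           "ElementType = MET_UCHAR",
           "BinaryDataByteOrderMSB = False",
           paste0("ElementDataFile = ", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.integer(arr), con, size = 1L, endian = "little")
  invisible(path)
}

#' Write a pilot dataset as mask volumes
#'
#' One file per image per source, named `<source>_<k>.<ext>` under `dir`.
#' Requires a `grid_shape` on the pilot to reshape the flattened labels.
#'
#' @param pilot A [pilot_dataset()] with `grid_shape` set.
#' @param dir Output directory (created if needed).
#' @param format `"nifti"` or `"metaimage"`.
#' @return Named list of the written file paths per source.
#' @export
write_mask_set <- function(pilot, dir, format = c("nifti", "metaimage")) {
  format <- match.arg(format)
  if (is.null(pilot$grid_shape))
    stop("writing mask volumes requires a grid_shape on the pilot dataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "nifti") ".nii.gz" else ".mhd"
  write_one <- function(labels, name) {
    vapply(seq_along(labels), function(k) {
      arr <- array(labels[[k]], dim = pilot$grid_shape)
      path <- file.path(dir, paste0(name, "_", k, ext))
      if (format == "nifti") RNifti::writeNifti(RNifti::asNifti(arr), path)
      else write_metaimage(arr, path)
      path
    }, character(1))
  }
  out <- list(a = write_one(pilot$a, "A"), b = write_one(pilot$b, "B"),
              l = write_one(pilot$l, "L"))
  if (!is.null(pilot$h)) out$h <- write_one(pilot$h, "H")
  out
}

#' Read a pilot dataset from a long-format label table
#'
#' Expects a CSV with columns `image_id`, `voxel_id`, `a`, `b`, `l` and
#' optionally `h`, one row per voxel, all labels 0 or 1. Rows are ordered
#' by `voxel_id` within each image.
#'
#' @param path CSV file path.
#' @return A [pilot_dataset()].
#' @export
read_label_table <- function(path) {
  tab <- read.csv(path)
  need <- c("image_id", "voxel_id", "a", "b", "l")
  if (!all(need %in% names(tab)))
    stop("label table must have columns ", paste(need, collapse = ", "),
         " (optionally h)")
  for (col in intersect(c("a", "b", "l", "h"), names(tab))) {
    bad <- which(!(tab[[col]] %in% c(0, 1)))
    if (length(bad))
      stop("non-binary value in column '", col, "' at row ", bad[1])
  }
  ids <- unique(tab$image_id)
  per_image <- function(col) lapply(ids, function(id) {
    sub <- tab[tab$image_id == id, ]
    as.integer(sub[[col]][order(sub$voxel_id)])
  })
  pilot_dataset(per_image("a"), per_image("b"), per_image("l"),
                if ("h" %in% names(tab)) per_image("h") else NULL)
}

#' Write a pilot dataset as a long-format label table
#'
#' @param pilot A [pilot_dataset()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_label_table <- function(pilot, path) {
  rows <- do.call(rbind, lapply(seq_len(pilot$n_images), function(k) {
    d <- data.frame(image_id = k, voxel_id = seq_len(pilot$v[k]),
                    a = pilot$a[[k]], b = pilot$b[[k]], l = pilot$l[[k]])
    if (!is.null(pilot$h)) d$h <- pilot$h[[k]]
    d
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON (and optionally CSV)
#'
#' Serializes pilot estimates, sample size results or simulation results to
#' a JSON file; scalar fields are also written to a one-row CSV next to it
#' when `csv = TRUE`. Output is deterministic for fixed inputs.
#'
#' @param x A `pilot_estimates`, `sample_size_result` or
#'   `simulation_result` object (or any named list of scalars).
#' @param path Output path for the JSON file.
#' @param csv Also write `<path without .json>.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, csv = TRUE) {
  fields <- unclass(x)
  fields$d_bar_samples <- NULL
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (csv) {
    scalars <- fields[vapply(fields, function(v)
      is.atomic(v) && length(v) == 1L && !is.null(v), logical(1))]
    if (length(scalars))
      write.csv(as.data.frame(scalars),
                sub("\\.json$", ".csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path JSON file written by [write_report()].
#' @return A named list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
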