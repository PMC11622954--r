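#' Read a grayscale image
#'
#' Reads PNG or TIFF (first channel of color inputs), rescaling to `[0, 1]`.
#'
#' @param path file path ending in `.png`, `.tif`/`.tiff`.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  clip01(img)
}

#' Write a grayscale image
#'
#' PNG output is 8-bit; TIFF output is 16-bit.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param path destination ending in `.png` or `.tif`/`.tiff`.
#' @export
write_gray_image <- function(image, path) {
  check_gray_image(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    tif = ,
    tiff = tiff::writeTIFF(image, path, bits.per.sample = 16L),
    abort("unsupported image format: .", ext))
  invisible(path)
}

#' Write a phantom to disk
#'
#' The intensity image goes to a 16-bit TIFF, the label map to an 8-bit PNG
#' (labels scaled by the maximum label), and the generating configuration to
#' a JSON sidecar. Optionally also writes a single-slice NIfTI of the image
#' when the RNifti package is available.
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir output directory (created if missing).
#' @param basename file stem.
#' @param nifti also write `<basename>.nii.gz`.
#' @return invisibly, the written paths.
#' @export
write_phantom <- function(phantom, dir, basename = "phantom", nifti = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(basename, ".tiff"))
  lab_path <- file.path(dir, paste0(basename, "_labels.png"))
  cfg_path <- file.path(dir, paste0(basename, ".json"))
  write_gray_image(phantom$image, img_path)
  png::writePNG(phantom$labels / max(1L, max(phantom$labels)), lab_path)
  jsonlite::write_json(unclass(phantom$config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  paths <- c(image = img_path, labels = lab_path, config = cfg_path)
  if (nifti) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      abort("RNifti is required for NIfTI output")
    nii_path <- file.path(dir, paste0(basename, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(phantom$image), nii_path)
    paths <- c(paths, nifti = nii_path)
  }
  invisible(paths)
}

#' Write a feature table as CSV plus a JSON mask sidecar
#'
#' @param table a [generate_feature_table()] result.
#' @param csv_path destination CSV; the label column is named `label`.
#' @param mask_path optional JSON path for the informative mask.
#' @return invisibly, the CSV path.
#' @export
write_feature_table <- function(table, csv_path, mask_path = NULL) {
  df <- as.data.frame(table$matrix)
  df$label <- table$labels
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(mask_path))
    jsonlite::write_json(table$informative_mask, mask_path)
  invisible(csv_path)
}

#' Read a feature table CSV
#'
#' @param csv_path CSV with a `label` column.
#' @param label_col name of the label column.
#' @return list with `matrix` and `labels`, compatible with
#'   [bctso_select()].
#' @export
read_feature_table <- function(csv_path, label_col = "label") {
  df <- utils::read.csv(csv_path, check.names = FALSE)
  if (!label_col %in% names(df)) abort("no '", label_col, "' column in ", csv_path)
  labels <- df[[label_col]]
  df[[label_col]] <- NULL
  list(matrix = as.matrix(df), labels = labels)
}

# allowed keys per run-config section, drawn from the constructors
.config_sections <- function() list(
  phantom = names(formals(phantom_config)),
  feature_table = names(formals(feature_table_config)),
  lwifcm = names(formals(lwifcm_config)),
  csa = setdiff(names(formals(csa_config)), c("dims", "lower", "upper")),
  segmentation = setdiff(names(formals(segmentation_config)), "lwifcm"),
  bctso = names(formals(tso_config)),
  preprocess = c("median_window", "tiles", "base_clip", "nbins"),
  arch = c("num_classes", "input_shape")
)

#' Read and validate a YAML run configuration
#'
#' A run configuration is a YAML document with an optional global `seed` and
#' per-module sections (`phantom`, `feature_table`, `preprocess`, `lwifcm`,
#' `csa`, `segmentation`, `bctso`, `arch`) whose keys must match the
#' corresponding configuration constructors. Unknown sections or keys are
#' rejected.
#'
#' @param path YAML file.
#' @return named list of validated sections.
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!is.list(doc)) abort("run config must be a YAML mapping")
  sections <- .config_sections()
  allowed <- c("seed", names(sections))
  bad <- setdiff(names(doc), allowed)
  if (length(bad)) abort("unknown run-config section: ", bad[1L])
  for (nm in intersect(names(doc), names(sections))) {
    extra <- setdiff(names(doc[[nm]]), sections[[nm]])
    if (length(extra))
      abort("unknown key '", extra[1L], "' in section '", nm, "'")
  }
  doc
}
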