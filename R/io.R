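# File interfaces: magnitude images as PNG or NIfTI, k-space bundles as
# CSV + JSON sidecar (portable, text-based), configs as YAML.

#' Write a magnitude image
#'
#' PNG output rescales the magnitude to [0, 1] (the scale factor is returned
#' invisibly); NIfTI output (`.nii` / `.nii.gz`) preserves the raw floating
#' point values and is the lossless path.
#'
#' @param image real or complex matrix; `Mod()` is written.
#' @param path output path ending in `.png`, `.nii` or `.nii.gz`.
#' @return Invisibly, the scale factor applied (1 for NIfTI).
#' @export
write_image <- function(image, path) {
  mag <- Mod(image)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(RNifti::asNifti(mag), path)
    return(invisible(1))
  }
  if (grepl("\\.png$", path)) {
    top <- max(mag)
    scaled <- if (top > 0) mag / top else mag
    png::writePNG(scaled, path)
    return(invisible(if (top > 0) top else 1))
  }
  stop("unsupported image format: ", path)
}

#' Read a magnitude image written by [write_image()]
#'
#' @param path `.png`, `.nii` or `.nii.gz` file.
#' @return A real matrix.
#' @export
read_image <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    return(matrix(as.numeric(img), dim(img)[1], dim(img)[2]))
  }
  if (grepl("\\.png$", path)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    return(img)
  }
  stop("unsupported image format: ", path)
}

#' Write a k-space measurement bundle
#'
#' Stores the complex values and mask as a CSV (columns `re`, `im`,
#' `sampled`, column-major order) next to a JSON sidecar holding the shape,
#' undersampling factor, mask kind and seed.
#'
#' @param y a `kspace_grid` from [undersample()].
#' @param path CSV path; the sidecar gets the extension `.json`.
#' @export
write_kspace <- function(y, path) {
  if (!inherits(y, "kspace_grid")) stop("`y` must be a kspace_grid")
  g <- mask_grid(y$mask)
  df <- data.frame(re = as.vector(Re(y$values)),
                   im = as.vector(Im(y$values)),
                   sampled = as.integer(as.vector(g)))
  write.csv(df, path, row.names = FALSE)
  meta <- list(shape = dim(y$values),
               factor = if (inherits(y$mask, "sampling_mask")) y$mask$factor else NA,
               kind = if (inherits(y$mask, "sampling_mask")) y$mask$kind else "custom",
               seed = if (inherits(y$mask, "sampling_mask")) y$mask$seed else NA,
               is_measurement = isTRUE(y$is_measurement))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a k-space measurement bundle written by [write_kspace()]
#'
#' @param path the CSV path.
#' @return A `kspace_grid`.
#' @export
read_kspace <- function(path) {
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path), simplifyVector = TRUE)
  df <- read.csv(path)
  H <- meta$shape[1]; W <- meta$shape[2]
  values <- matrix(complex(real = df$re, imaginary = df$im), H, W)
  grid <- matrix(df$sampled == 1L, H, W)
  mask <- structure(list(grid = grid, factor = meta$factor, kind = meta$kind,
                         seed = meta$seed),
                    class = "sampling_mask")
  structure(list(values = values, mask = mask,
                 is_measurement = isTRUE(meta$is_measurement)),
            class = "kspace_grid")
}

#' Read or write a reconstruction config as YAML
#'
#' Configs round-trip losslessly: every field of [recon_config()] is written
#' and unknown fields in the file are rejected.
#'
#' @param config a `recon_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(recon_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(recon_config, vals)
}
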