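# HDF5 and TIFF interchange.
#
# Layout: /sets/<set_id>/images is an N x 512 x 512 unsigned-16-bit dataset
# holding the 12-bit counts, /sets/<set_id>/labels the parallel class-label
# strings; file-level attributes record pixel_size_um, bit_depth and an
# acquisition_day tag. Round trips are bit-identical.

#' Write fields to an HDF5 file
#'
#' @param fields List of `nm_field` objects; fields are grouped by their
#'   `set_id`.
#' @param path Output file path (overwritten).
#' @param acquisition_day Free-form acquisition tag stored as an attribute.
#' @return `path`, invisibly.
#' @export
write_fields_h5 <- function(fields, path, acquisition_day = "day0") {
  if (inherits(fields, "nm_field")) fields <- list(fields)
  labs <- vapply(fields, function(f) f$class_label, "")
  if (any(is.na(labs))) {
    abort("every field needs a class_label before writing")
  }
  shapes <- vapply(fields, function(f) paste(dim(f$pixels), collapse = "x"), "")
  if (length(unique(shapes)) > 1) abort("fields must share one frame shape")
  if (file.exists(path)) unlink(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) abort(sprintf("cannot create HDF5 file at '%s'", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "sets")
  sets <- split(seq_along(fields), vapply(fields, function(f) f$set_id, ""))
  for (sid in names(sets)) {
    grp <- paste0("sets/", sid)
    rhdf5::h5createGroup(path, grp)
    idx <- sets[[sid]]
    d <- dim(fields[[idx[1]]]$pixels)
    arr <- array(0L, c(length(idx), d))
    for (k in seq_along(idx)) arr[k, , ] <- fields[[idx[k]]]$pixels
    rhdf5::h5createDataset(path, paste0(grp, "/images"), dim(arr),
                           H5type = "H5T_STD_U16LE")
    rhdf5::h5write(arr, path, paste0(grp, "/images"))
    rhdf5::h5write(labs[idx], path, paste0(grp, "/labels"))
  }
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(0.2150, fid, "pixel_size_um")
  rhdf5::h5writeAttribute(12L, fid, "bit_depth")
  rhdf5::h5writeAttribute(acquisition_day, fid, "acquisition_day")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read fields from an HDF5 file
#'
#' @param path File written by [write_fields_h5()].
#' @return List with `fields` (list of `nm_field`) and `attributes`
#'   (pixel_size_um, bit_depth, acquisition_day).
#' @export
read_fields_h5 <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: '%s'", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  sets <- rhdf5::h5ls(path)
  set_ids <- sets$name[sets$group == "/sets" & sets$otype == "H5I_GROUP"]
  fields <- list()
  for (sid in set_ids) {
    arr <- rhdf5::h5read(path, paste0("sets/", sid, "/images"))
    labs <- as.character(rhdf5::h5read(path, paste0("sets/", sid, "/labels")))
    if (dim(arr)[1] != length(labs)) {
      abort(sprintf("set '%s': %d images but %d labels", sid,
                    dim(arr)[1], length(labs)))
    }
    for (k in seq_len(dim(arr)[1])) {
      px <- matrix(as.integer(arr[k, , ]), dim(arr)[2], dim(arr)[3])
      fields[[length(fields) + 1L]] <-
        new_field(px, set_id = sid, class_label = labs[k])
    }
  }
  fid <- rhdf5::H5Fopen(path)
  attrs <- list(
    pixel_size_um = as.numeric(rhdf5::h5readAttributes(fid, "/")$pixel_size_um),
    bit_depth = as.integer(rhdf5::h5readAttributes(fid, "/")$bit_depth),
    acquisition_day = as.character(rhdf5::h5readAttributes(fid, "/")$acquisition_day))
  rhdf5::H5Fclose(fid)
  list(fields = fields, attributes = attrs)
}

#' Export a field as 16-bit TIFF
#'
#' One frame per file; the 12-bit counts occupy the low bits of a 16-bit
#' container.
#'
#' @param field An `nm_field`.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required for TIFF export")
  }
  tiff::writeTIFF(field$pixels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit TIFF field
#'
#' @param path `.tif` file holding 12-bit counts in a 16-bit container.
#' @inheritParams new_field
#' @return An `nm_field`.
#' @export
read_field_tiff <- function(path, set_id = NA_character_,
                            class_label = NA_character_) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required for TIFF import")
  }
  px <- round(tiff::readTIFF(path) * 65535)
  new_field(matrix(as.integer(px), nrow(px), ncol(px)),
            set_id = set_id, class_label = class_label)
}
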