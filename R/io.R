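# TIFF + sidecar-JSON I/O. Images are written as 32-bit float multi-page
# TIFF normalized to [0, 1]; the scale factor and physical spacings live in
# a JSON sidecar next to the file, so values round-trip exactly up to float
# precision.

#' Write a volume (or 4-D stack) as multi-page TIFF with JSON sidecar
#'
#' 3-D input `(ny, nx, nz)` is written with z as the page axis; 4-D input
#' `(ny, nx, t, z)` is written with t fastest within a z block. Values are
#' scaled into `[0, 1]` for storage; the scale, offset, dimensions and voxel
#' spacings are recorded in `<path>.json`.
#'
#' @param x numeric array (3-D or 4-D) with optional spacing attributes.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(x, path) {
  d <- dim(x)
  if (!length(d) %in% c(2, 3, 4)) stop("expect a 2-D, 3-D or 4-D array")
  lo <- min(x); hi <- max(x)
  scale <- if (hi > lo) hi - lo else 1
  xs <- (x - lo) / scale
  pages <- if (length(d) == 2) list(xs) else {
    flat <- array(xs, c(d[1], d[2], prod(d[-(1:2)])))
    lapply(seq_len(dim(flat)[3]), function(j) flat[, , j])
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(dim = d,
               axis_order = attr(x, "axis_order") %||%
                 (if (length(d) == 4) "(y, x, t, z); t fastest within z"
                  else "(y, x, z); z is the page axis"),
               value_offset = lo, value_scale = scale,
               lateral_spacing_nm = attr(x, "lateral_spacing"),
               axial_spacing_nm = attr(x, "axial_spacing"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a TIFF stack written by [write_stack_tiff()]
#'
#' @param path `.tif` path with its `.json` sidecar alongside.
#' @return numeric array with original values, dimensions and spacing
#'   attributes restored.
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  dim(arr) <- meta$dim
  arr <- arr * meta$value_scale + meta$value_offset
  attr(arr, "lateral_spacing") <- meta$lateral_spacing_nm
  attr(arr, "axial_spacing") <- meta$axial_spacing_nm
  attr(arr, "axis_order") <- meta$axis_order
  arr
}
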