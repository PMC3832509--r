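#' Write / read histospot channels as grayscale PNG
#'
#' Channels are stored as `<spot_id>_cytokeratin.png`, `<spot_id>_dapi.png`
#' and `<spot_id>_cd31.png` in `dir`. Pixel values are clamped to \[0, 1\]
#' and quantized to 8 bits on write, so round-trips agree to 1/255.
#'
#' @param spot a [histospot()].
#' @param dir output directory (created if absent).
#' @return the spot id, invisibly.
#' @export
write_histospot <- function(spot, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (ch in c("cytokeratin", "dapi", "cd31")) {
    img <- spot[[ch]]
    img[img < 0] <- 0
    img[img > 1] <- 1
    png::writePNG(img, file.path(dir, paste0(spot$spot_id, "_", ch, ".png")))
  }
  invisible(spot$spot_id)
}

#' @rdname write_histospot
#' @param spot_id spot identifier used in the file names.
#' @export
read_histospot <- function(dir, spot_id) {
  chans <- lapply(c("cytokeratin", "dapi", "cd31"), function(ch) {
    path <- file.path(dir, paste0(spot_id, "_", ch, ".png"))
    if (!file.exists(path)) stop("channel file not found: ", path)
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  histospot(chans[[1]], chans[[2]], chans[[3]], spot_id = spot_id)
}
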