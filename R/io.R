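#' Read a grayscale image as a unit-scale intensity matrix
#'
#' Reads 8/16-bit PNG (or TIFF when the tiff package is available) into a
#' numeric matrix in `[0, 1]`. Multi-channel images are averaged to one
#' channel.
#'
#' @param path image file path.
#' @return numeric matrix.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the tiff package", call. = FALSE)
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  storage.mode(img) <- "double"
  img
}

#' Read a dataset manifest CSV into pipeline sample lists
#'
#' The manifest has columns `sample_id, label, band, split, path`; each
#' sample must provide one file per band. Paths are resolved relative to the
#' manifest's directory when not absolute.
#'
#' @param path manifest CSV file.
#' @return list with `train` and `test` sample lists (as in
#'   [generate_dataset()]).
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "label", "band", "split", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  base <- dirname(path)
  load_split <- function(split) {
    sub <- man[man$split == split, , drop = FALSE]
    lapply(split(sub, sub$sample_id), function(rows) {
      bands <- lapply(seq_len(nrow(rows)), function(i) {
        p <- rows$path[i]
        if (!file.exists(p)) p <- file.path(base, rows$path[i])
        if (!file.exists(p))
          stop(sprintf("missing image for sample %s band %s: %s",
                       rows$sample_id[i], rows$band[i], rows$path[i]),
               call. = FALSE)
        read_image(p)
      })
      names(bands) <- rows$band
      list(label = rows$label[1L], sample_id = rows$sample_id[1L],
           bands = bands)
    })
  }
  list(train = unname(load_split("train")), test = unname(load_split("test")))
}
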