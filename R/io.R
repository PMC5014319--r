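#' Read and write P1 ASCII portable bitmaps
#'
#' Pictograms are stored as plain-text PBM (magic `P1`): a width/height
#' header followed by 0/1 pixels, row by row; `#` comments are skipped.
#' The round trip is bit-exact.
#'
#' @param p A `"pictogram"` (integer 0/1 matrix, rows = y).
#' @param path File path.
#' @return `read_pbm()` returns a `"pictogram"`; `write_pbm()` returns
#'   `path` invisibly.
#' @export
write_pbm <- function(p, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("P1", con)
  writeLines(paste(ncol(p), nrow(p)), con)
  apply(unclass(p), 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' @rdname write_pbm
#' @export
read_pbm <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (lines[1] != "P1") stop("not a P1 ASCII portable bitmap: ", path, call. = FALSE)
  tokens <- unlist(strsplit(paste(lines[-1], collapse = " "), "[[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  dims <- as.integer(tokens[1:2])
  px <- as.integer(tokens[-(1:2)])
  if (length(px) != dims[1] * dims[2]) {
    stop("PBM pixel count ", length(px), " does not match ", dims[1], "x", dims[2],
         call. = FALSE)
  }
  new_pictogram(matrix(px, nrow = dims[2], ncol = dims[1], byrow = TRUE))
}

#' Read and write scenes as JSON
#'
#' The schema is an object with `canvas` (`[width, height]`) and `objects`,
#' an array of `{address, shape, x0, y0, width, height}` records (0-based
#' top-left positions, addresses `1..N`). Entities are re-encoded on read
#' from the canonical shape bitmaps; supply `pictogram` to re-extract
#' identity fields from pixels instead.
#'
#' @param scene A `"scene"`.
#' @param path File path.
#' @param pictogram Optional pictogram passed to [new_scene()] on read.
#' @return `read_scene()` returns a `"scene"`; `write_scene()` returns
#'   `path` invisibly.
#' @export
write_scene <- function(scene, path) {
  obj <- list(
    schema = "scenebind/scene/1",
    canvas = scene$canvas,
    objects = scene$objects[, c("address", "shape", "x0", "y0", "width", "height")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path, pictogram = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  objects <- tibble::as_tibble(obj$objects)
  for (col in c("address", "x0", "y0", "width", "height")) {
    objects[[col]] <- as.integer(objects[[col]])
  }
  new_scene(objects, canvas = as.integer(obj$canvas), pictogram = pictogram)
}
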