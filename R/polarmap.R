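#' Construct a perfusion polar map
#'
#' @param grid numeric matrix of perfusion values (mL/g/min); values outside
#'   the disc may be `NA`.
#' @param kind `"REST"`, `"STRESS"` or `"RESERVE"`.
#' @param center (row, column) of the disc centre; defaults to the grid
#'   centre.
#' @param radius disc radius in pixels; defaults to the largest disc fitting
#'   the grid.
#' @param mask optional logical matrix of in-disc pixels; defaults to all
#'   pixels within `radius` of `center`.
#' @return a [PolarMap-class].
#' @examples
#' g <- matrix(2, 64, 64)
#' pm <- polarMap(g, "STRESS")
#' @export
polarMap <- function(grid, kind, center = NULL, radius = NULL, mask = NULL) {
  stopifnot(is.matrix(grid))
  if (is.null(center)) center <- (dim(grid) + 1) / 2
  if (is.null(radius)) radius <- min(dim(grid) - 1) / 2
  if (is.null(mask)) mask <- .discMask(dim(grid), center, radius)
  new("PolarMap", grid = grid, mask = mask, kind = toupper(kind),
      center = as.numeric(center), radius = as.numeric(radius))
}

.discMask <- function(dims, center, radius) {
  r <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  (r - center[1])^2 + (cc - center[2])^2 <= radius^2
}

#' Read and write polar maps as plain text
#'
#' A map is stored as a whitespace-separated numeric matrix (`NA` outside
#' the disc) in `<prefix>.tsv`, with a JSON sidecar `<prefix>.json` holding
#' the kind, centre and radius.
#'
#' @param map a [PolarMap-class].
#' @param prefix file path without extension.
#' @return `writePolarMap` returns `prefix` invisibly; `readPolarMap`
#'   returns a [PolarMap-class].
#' @export
writePolarMap <- function(map, prefix) {
  g <- map@grid
  g[!map@mask] <- NA
  utils::write.table(g, paste0(prefix, ".tsv"), row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(kind = map@kind, center = map@center, radius = map@radius),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = I(17))
  invisible(prefix)
}

#' @rdname writePolarMap
#' @export
readPolarMap <- function(prefix) {
  g <- as.matrix(utils::read.table(paste0(prefix, ".tsv")))
  dimnames(g) <- NULL
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  mask <- .discMask(dim(g), meta$center, meta$radius) & !is.na(g)
  polarMap(g, meta$kind, center = meta$center, radius = meta$radius,
           mask = mask)
}
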