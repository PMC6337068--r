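#' Haematoxylin/eosin stain matrix (Ruifrok-Johnston)
#'
#' Returns the 3x3 optical-density stain matrix used for colour
#' deconvolution of H&E images. Rows are unit-normalized stain vectors in
#' RGB optical-density space: haematoxylin, eosin, and a residual channel
#' constructed as their cross product so the matrix is invertible.
#'
#' @return A 3x3 numeric matrix with rows `h`, `e`, `residual`.
#' @export
he_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  h <- h / sqrt(sum(h^2))
  e <- e / sqrt(sum(e^2))
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  r <- r / sqrt(sum(r^2))
  m <- rbind(h = h, e = e, residual = r)
  colnames(m) <- c("R", "G", "B")
  m
}

## Beer-Lambert conversion of 8-bit intensities to optical density.
## `x` in [0,1] or [0,255]; OD = -log10((I + 1) / 256) with I in 0..255.
rgb_to_od <- function(x) {
  if (max(x) <= 1) x <- x * 255
  -log10((x + 1) / 256)
}

#' Separate haematoxylin and eosin channels by colour deconvolution
#'
#' Converts an RGB image to optical density via Beer-Lambert
#' (`OD = -log10((I+1)/256)`) and unmixes it into per-stain concentration
#' rasters using the inverse of the stain matrix. Outputs are clipped at 0:
#' a pure-white pixel has (near) zero absorbance in both channels, and
#' darker pixels of the same hue have strictly larger total OD.
#'
#' @param image RGB array (`H x W x 3`), 8-bit integers or doubles in
#'   `[0,1]`.
#' @param stain_matrix 3x3 stain matrix, rows = unit OD stain vectors
#'   (default [he_stain_matrix()]).
#' @return List with `h_od` and `e_od`, numeric `H x W` matrices of
#'   non-negative stain concentrations (optical-density units).
#' @export
separate_stains <- function(image, stain_matrix = he_stain_matrix()) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  if (abs(det(stain_matrix)) < 1e-8) {
    stop("stain matrix is singular; supply three independent stain vectors")
  }
  d <- dim(image)
  od <- rgb_to_od(image)
  odm <- matrix(od, ncol = 3L)        # pixels x 3, column-major per channel
  ## od = t(M) %*% conc per pixel, so conc rows = od rows %*% solve(M)
  conc <- odm %*% solve(stain_matrix)
  list(h_od = matrix(pmax(conc[, 1], 0), d[1], d[2]),
       e_od = matrix(pmax(conc[, 2], 0), d[1], d[2]))
}

## Luminance grayscale (0..255 scale) from an RGB array.
rgb_to_gray <- function(image) {
  if (max(image) <= 1) image <- image * 255
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}
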