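#' Complex beamformed IQ frame stack
#'
#' Container for a stack of beamformed in-phase/quadrature frames, the raw
#' input of the processing chain. The array is `[depth, lateral, frames]`
#' (axial depth grows away from the transducer along the first dimension) with
#' the acquisition metadata attached. Positions are reported in micrometres at
#' pixel centers: native pixel `(i, j)` (1-based) sits at
#' `((i - 0.5) * pitch, (j - 0.5) * pitch)`.
#'
#' @param iq complex array `[depth, lateral, frames]`.
#' @param params an [acquisition_params()] object.
#' @return an object of class `iq_stack`.
#' @export
iq_stack <- function(iq, params) {
  stopifnot(is.array(iq), length(dim(iq)) == 3L)
  if (!is.complex(iq)) storage.mode(iq) <- "complex"
  structure(list(iq = iq, params = params), class = "iq_stack")
}

#' @export
print.iq_stack <- function(x, ...) {
  d <- dim(x$iq)
  cat(sprintf("iq_stack: %d (depth) x %d (lateral) x %d frames, pitch %g um\n",
              d[1], d[2], d[3], x$params$native_pixel_um))
  invisible(x)
}

#' @export
dim.iq_stack <- function(x) dim(x$iq)

#' Reshape an IQ stack into its columnized Casorati matrix
#'
#' Vectorizes space so each column is one frame; the operand of the
#' spatiotemporal SVD clutter filter. `uncasorati()` inverts the reshape
#' bit-exactly.
#'
#' @param stack an [iq_stack()].
#' @return complex matrix `(depth * lateral) x frames`.
#' @export
casorati <- function(stack) {
  d <- dim(stack$iq)
  matrix(stack$iq, nrow = d[1] * d[2], ncol = d[3])
}

#' @rdname casorati
#' @param mat Casorati matrix.
#' @param like an [iq_stack()] providing the original dimensions and metadata.
#' @export
uncasorati <- function(mat, like) {
  d <- dim(like$iq)
  iq_stack(array(mat, dim = d), like$params)
}

#' Read / write an IQ stack container
#'
#' Serializes the complex array together with all acquisition metadata using
#' R's native binary serialization. The round trip is bit-exact.
#'
#' @param stack an [iq_stack()].
#' @param path file path.
#' @export
write_iqstack <- function(stack, path) {
  stopifnot(inherits(stack, "iq_stack"))
  saveRDS(stack, path)
  invisible(path)
}

#' @rdname write_iqstack
#' @export
read_iqstack <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "iq_stack"))
  x
}
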