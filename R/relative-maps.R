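#' Relative transmit-sensitivity maps from per-channel images
#'
#' Divides each channel's reconstructed complex image voxelwise by the sum
#' of the magnitudes of all channels' images,
#' \eqn{rT_j = I_j / \sum_c |I_c|}. Because the receive weight, proton
#' density and relaxation factors are common to all channels, they cancel in
#' the ratio, leaving the relative transmit field of each channel (complex:
#' magnitude and phase). At every voxel with a nonzero denominator the
#' magnitudes sum to exactly 1 across channels.
#'
#' Voxels with a zero denominator are set to 0 (not NaN, so outputs remain
#' viewer-safe) and flagged in the `valid` mask.
#'
#' @param images Complex array `[x, y, channel]` of per-channel images
#'   (e.g. the `gamma` component of [reconstruct_stack()]), or a list of
#'   equal-sized complex matrices.
#' @param channel_ids Optional character labels, one per channel.
#' @return A `relative_maps` object: list with `rT` (complex array
#'   `[x, y, channel]`), `valid` (logical matrix, FALSE where the
#'   denominator was zero) and `channel_ids`.
#' @export
relative_map <- function(images, channel_ids = NULL) {
  images <- as_channel_array(images)
  dm <- dim(images)
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(dm[3]))
  if (length(channel_ids) != dm[3])
    stop("channel_ids length does not match the number of channels")
  denom <- apply(Mod(images), c(1, 2), sum)
  valid <- denom > 0
  denom[!valid] <- 1  # placeholder; flagged voxels are zeroed below
  rT <- images / as.vector(denom)  # denom recycles over the channel dim
  rT[array(!valid, dm)] <- 0 + 0i
  structure(list(rT = rT, valid = valid, channel_ids = channel_ids),
            class = "relative_maps")
}

#' @export
print.relative_maps <- function(x, ...) {
  dm <- dim(x$rT)
  cat(sprintf("Relative B1+ maps: %d x %d voxels, %d channels (%s)\n",
              dm[1], dm[2], dm[3], paste(x$channel_ids, collapse = ", ")))
  cat(sprintf("  %d voxel(s) with zero denominator\n", sum(!x$valid)))
  invisible(x)
}

#' Relative transmit phase maps
#'
#' Per-channel phase images \eqn{\arg(I_j) - \arg(I_{ref})}, wrapped to
#' `(-pi, pi]`. With `reference = NULL` the raw phase \eqn{\arg(I_j)} is
#' returned. Referencing removes the common-mode phase (receive chain,
#' global RF phase), so the result is invariant to a global rotation of all
#' channel images.
#'
#' @param images Complex array `[x, y, channel]` or list of matrices; a
#'   `relative_maps` object is also accepted.
#' @param reference Channel index or id to subtract, or `NULL` for raw
#'   phase.
#' @return Numeric array `[x, y, channel]` of phases in `(-pi, pi]`.
#' @export
relative_phase <- function(images, reference = NULL) {
  if (inherits(images, "relative_maps")) {
    ids <- images$channel_ids
    images <- images$rT
  } else {
    images <- as_channel_array(images)
    ids <- paste0("ch", seq_len(dim(images)[3]))
  }
  ph <- Arg(images)
  if (!is.null(reference)) {
    if (is.character(reference)) reference <- match(reference, ids)
    if (is.na(reference) || reference < 1 || reference > dim(images)[3])
      stop("reference does not name a valid channel")
    ref <- ph[, , reference]
    ph <- wrap_phase(ph - as.vector(ref))
  }
  ph
}

# wrap angles to (-pi, pi]
wrap_phase <- function(p) {
  out <- Arg(exp(1i * p))
  dim(out) <- dim(p)
  out
}

as_channel_array <- function(images) {
  if (is.list(images)) {
    dms <- lapply(images, dim)
    if (length(unique(vapply(dms, paste, "", collapse = "x"))) != 1L)
      stop("channel images have inconsistent dimensions")
    images <- array(unlist(images), c(dms[[1]], length(images)))
  }
  if (length(dim(images)) != 3L)
    stop("expected a [x, y, channel] array of channel images")
  if (!is.complex(images)) images <- array(as.complex(images), dim(images))
  images
}
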