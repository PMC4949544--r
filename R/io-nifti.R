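#' Write a multi-channel, multi-drive complex image stack to NIfTI
#'
#' Complex images are stored as paired real/imaginary NIfTI volumes
#' (`<prefix>_ch<c>_d<j>_real.nii.gz` / `..._imag.nii.gz`) for maximal
#' viewer compatibility, together with a JSON sidecar recording the drive
#' scales, the noise level, the channel ids and provenance. Orientation
#' metadata is left at the NIfTI default; the reconstruction is purely
#' voxelwise, so no resampling is ever performed.
#'
#' @param stack Complex array `[x, y, channel, drive]`.
#' @param drives A [drive_scheme()] (or ascending numeric vector) matching
#'   the drive dimension.
#' @param dir Output directory (created if missing).
#' @param sigma Optional noise standard deviation to record in the sidecar.
#' @param channel_ids Optional channel labels.
#' @param prefix File name prefix. Default `"spgr"`.
#' @param seed Optional RNG seed to record for provenance.
#' @return Invisibly, the path of the sidecar JSON.
#' @export
write_stack <- function(stack, drives, dir, sigma = NULL,
                        channel_ids = NULL, prefix = "spgr", seed = NULL) {
  if (!inherits(drives, "drive_scheme")) drives <- drive_scheme(drives)
  dm <- dim(stack)
  if (length(dm) != 4L)
    stop("stack must be a 4-D array [x, y, channel, drive]")
  if (dm[4] != length(drives))
    stop("drive dimension (", dm[4], ") does not match the drive scheme (",
         length(drives), ")")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(dm[3]))
  if (length(channel_ids) != dm[3])
    stop("channel_ids length does not match the channel dimension")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (c_i in seq_len(dm[3])) for (j in seq_len(dm[4])) {
    base <- file.path(dir, sprintf("%s_%s_d%02d", prefix,
                                   channel_ids[c_i], j))
    RNifti::writeNifti(Re(stack[, , c_i, j]), paste0(base, "_real.nii.gz"))
    RNifti::writeNifti(Im(stack[, , c_i, j]), paste0(base, "_imag.nii.gz"))
  }
  sidecar <- list(prefix = prefix,
                  drives = as.numeric(drives),
                  scheme_kind = attr(drives, "kind"),
                  sigma = sigma,
                  channel_ids = as.list(channel_ids),
                  dim = dm,
                  seed = seed,
                  package_version =
                    as.character(utils::packageVersion("relb1map")),
                  created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, paste0(prefix, "_sidecar.json"))
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a complex image stack written by [write_stack()]
#'
#' @param sidecar Path to the sidecar JSON (or to the directory containing
#'   exactly one `*_sidecar.json`).
#' @return A list with `stack` (complex array `[x, y, channel, drive]`),
#'   `drives` (a [drive_scheme()]), `sigma` (may be `NULL`) and
#'   `channel_ids`.
#' @export
read_stack <- function(sidecar) {
  if (dir.exists(sidecar)) {
    hits <- list.files(sidecar, pattern = "_sidecar\\.json$",
                       full.names = TRUE)
    if (length(hits) != 1L)
      stop("expected exactly one *_sidecar.json in ", sidecar,
           " (found ", length(hits), ")")
    sidecar <- hits
  }
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  drives <- drive_scheme(meta$drives,
                         kind = if (is.null(meta$scheme_kind)) "explicit"
                                else meta$scheme_kind)
  channel_ids <- as.character(meta$channel_ids)
  nd <- length(drives); nch <- length(channel_ids)
  stack <- NULL
  for (c_i in seq_len(nch)) for (j in seq_len(nd)) {
    base <- file.path(dir, sprintf("%s_%s_d%02d", meta$prefix,
                                   channel_ids[c_i], j))
    re_p <- paste0(base, "_real.nii.gz")
    im_p <- paste0(base, "_imag.nii.gz")
    if (!file.exists(re_p) || !file.exists(im_p))
      stop("missing real/imaginary pair for channel ", channel_ids[c_i],
           ", drive ", j, ": ", base, "_{real,imag}.nii.gz")
    re <- as.array(RNifti::readNifti(re_p))
    im <- as.array(RNifti::readNifti(im_p))
    if (!identical(dim(re), dim(im)))
      stop("real/imaginary dimensions differ for ", base)
    if (is.null(stack)) stack <- array(0 + 0i, c(dim(re), nch, nd))
    if (!identical(dim(re), dim(stack)[1:2]))
      stop("image dimensions inconsistent across the stack at ", base)
    stack[, , c_i, j] <- complex(real = re, imaginary = im)
  }
  list(stack = stack, drives = drives,
       sigma = if (is.null(meta$sigma)) NULL else as.numeric(meta$sigma),
       channel_ids = channel_ids)
}

#' Write reconstruction outputs to NIfTI + JSON
#'
#' Writes, per channel: real/imaginary pairs of the reconstructed complex
#' image, the relative-map magnitude and phase volumes; plus the integer
#' `k_max` volume, the zero-denominator flag mask and a JSON run log of the
#' settings.
#'
#' @param recon A [reconstruct_stack()] result.
#' @param maps A [relative_map()] result on `recon$gamma`.
#' @param dir Output directory (created if missing).
#' @param phase_reference Optional channel id/index used for phase
#'   referencing (recorded in the log; `NULL` for raw phase).
#' @return Invisibly, the path of the run log JSON.
#' @export
write_outputs <- function(recon, maps, dir, phase_reference = NULL) {
  stopifnot(is.list(recon), !is.null(recon$gamma), !is.null(recon$k_max),
            inherits(maps, "relative_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nch <- dim(recon$gamma)[3]
  ph <- relative_phase(maps, reference = phase_reference)
  for (c_i in seq_len(nch)) {
    id <- maps$channel_ids[c_i]
    RNifti::writeNifti(Re(recon$gamma[, , c_i]),
                       file.path(dir, sprintf("gamma_%s_real.nii.gz", id)))
    RNifti::writeNifti(Im(recon$gamma[, , c_i]),
                       file.path(dir, sprintf("gamma_%s_imag.nii.gz", id)))
    RNifti::writeNifti(Mod(maps$rT[, , c_i]),
                       file.path(dir, sprintf("rT_%s_mag.nii.gz", id)))
    RNifti::writeNifti(ph[, , c_i],
                       file.path(dir, sprintf("rT_%s_phase.nii.gz", id)))
    RNifti::writeNifti(recon$k_max[, , c_i] + 0L,
                       file.path(dir, sprintf("kmax_%s.nii.gz", id)),
                       datatype = "int16")
  }
  RNifti::writeNifti(maps$valid + 0L, file.path(dir, "valid_mask.nii.gz"),
                     datatype = "uint8")
  log <- list(drives = as.numeric(recon$drives),
              sigma = recon$sigma,
              channel_ids = as.list(maps$channel_ids),
              phase_reference = phase_reference,
              n_invalid_voxels = sum(!maps$valid),
              package_version =
                as.character(utils::packageVersion("relb1map")),
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "run_log.json")
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
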