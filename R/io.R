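#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti preserving data (32-bit float for quantitative
#' maps, unsigned 8-bit for masks), voxel size and axis order.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_nifti()` returns a list with `data` (array, attributes
#'   stripped) and `voxel_size` (mm per spatial axis).
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  data <- array(as.numeric(img), dim(img))
  list(data = data, voxel_size = as.double(pd[seq_len(min(3, length(pd)))]))
}

#' @rdname read_nifti
#' @param volume Numeric or logical array (3-D or 4-D).
#' @param voxel_size Numeric, mm per spatial axis.
#' @param mask Write as unsigned 8-bit (for binary masks) instead of 32-bit
#'   float.
#' @export
write_nifti <- function(volume, path, voxel_size = c(1, 1, 2),
                        mask = is.logical(volume)) {
  v <- volume * 1
  img <- RNifti::asNifti(v)
  nd <- length(dim(v))
  pd <- rep_len(as.double(voxel_size), min(3, nd))
  RNifti::pixdim(img) <- c(pd, rep(1, nd - length(pd)))
  RNifti::writeNifti(img, path,
                     datatype = if (mask) "uint8" else "float")
  invisible(path)
}

#' Write / read a phantom as NIfTI maps with a YAML sidecar
#'
#' One NIfTI file per map (quantitative maps as 32-bit float, masks as
#' uint8) plus `phantom.yaml` recording the seed, configuration and units.
#'
#' @param phantom A `phantom_volume`.
#' @param dir Output directory (created if needed).
#' @return `write_phantom()` returns `dir` invisibly; `read_phantom()`
#'   returns a `phantom_volume`.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- phantom$voxel_size
  quant <- c("t1_map", "t2s_map", "m0_map", "b1_map",
             "prob_nawm", "prob_gm", "prob_csf")
  for (nm in quant) {
    write_nifti(phantom[[nm]], file.path(dir, paste0(nm, ".nii.gz")), vs)
  }
  for (nm in c("lesion_mask", "brain_mask")) {
    write_nifti(phantom[[nm]] != 0, file.path(dir, paste0(nm, ".nii.gz")),
                vs, mask = TRUE)
  }
  side <- list(seed = phantom$seed,
               voxel_size_mm = as.numeric(vs),
               units = list(t1_map = "ms", t2s_map = "ms", m0_map = "a.u.",
                            b1_map = "scale"),
               config = unclass(phantom$config))
  side$config$t1_ms <- as.list(side$config$t1_ms)
  side$config$t2s_ms <- as.list(side$config$t2s_ms)
  side$config$m0 <- as.list(side$config$m0)
  yaml::write_yaml(side, file.path(dir, "phantom.yaml"))
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  side <- yaml::read_yaml(file.path(dir, "phantom.yaml"))
  maps <- list()
  for (nm in c("t1_map", "t2s_map", "m0_map", "b1_map", "prob_nawm",
               "prob_gm", "prob_csf", "lesion_mask", "brain_mask")) {
    maps[[nm]] <- read_nifti(file.path(dir, paste0(nm, ".nii.gz")))$data
  }
  maps$lesion_mask <- maps$lesion_mask != 0
  maps$brain_mask <- maps$brain_mask != 0
  cfg <- lapply(side$config, function(x) if (is.list(x)) unlist(x) else x)
  maps$voxel_size <- as.double(side$voxel_size_mm)
  maps$seed <- side$seed
  maps$config <- do.call(phantom_config, cfg)
  structure(maps, class = "phantom_volume")
}

#' Persist / load a fingerprint dictionary
#'
#' The dictionary (atoms, parameter index, schedule and grid metadata) is
#' stored as a single serialized container.
#'
#' @param dictionary An `mrf_dictionary`.
#' @param path File path (conventionally `.rds`).
#' @export
save_dictionary <- function(dictionary, path) {
  saveRDS(dictionary, path)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  d <- readRDS(path)
  if (!inherits(d, "mrf_dictionary")) stop("not a dictionary container")
  d
}

#' Write / read a baseline stack as 4-D NIfTI
#'
#' @param stack A [baseline_stack()].
#' @param path File path.
#' @param schedule Schedule attached on read (frame timing is not stored in
#'   the NIfTI header).
#' @export
write_stack <- function(stack, path) {
  write_nifti(stack$data, path, stack$voxel_size)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, schedule = default_schedule()) {
  nii <- read_nifti(path)
  baseline_stack(nii$data, schedule, nii$voxel_size)
}
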