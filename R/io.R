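# NIfTI input/output, model checkpoints, and run configuration files.

#' Read a NIfTI volume
#'
#' Reads a 2D or 3D single-channel NIfTI file; a 3D volume with a singleton
#' third axis is loaded as 2D. Vector fields written by [write_volume()]
#' (component axis last) are restored when `type` is `"velocity"` or
#' `"deformation"`.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param type `"image"`, `"labelmap"`, `"velocity"` or `"deformation"`.
#' @return The corresponding hyperreg object with spacing preserved.
#' @export
read_volume <- function(path, type = "image") {
  type <- match.arg(type, c("image", "labelmap", "velocity", "deformation"))
  if (!file.exists(path))
    hr_stop("data", paste("no such file:", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    hr_stop("data", paste0("malformed NIfTI file '", path,
                                           "': ", conditionMessage(e))))
  a <- as.array(img)
  pd <- RNifti::pixdim(img)
  if (type %in% c("velocity", "deformation")) {
    # stored as (H, W, D, ncomp); D == 1 means a 2D field
    if (length(dim(a)) != 4L)
      hr_stop("data", paste("expected a 4D multi-component field in", path))
    if (dim(a)[3] == 1L)
      a <- array(a, dim = c(dim(a)[1], dim(a)[2], dim(a)[4]))
    return(if (type == "velocity") as_velocity(a) else as_deformation(a))
  }
  if (length(dim(a)) == 3L && dim(a)[3] == 1L)
    a <- array(a, dim = dim(a)[1:2])
  nd <- length(dim(a))
  spacing <- rep_len(pd, max(nd, length(pd)))[seq_len(nd)]
  spacing[spacing <= 0] <- 1
  if (type == "labelmap") as_labelmap(a, spacing) else as_image(a, spacing)
}

#' Write a NIfTI volume
#'
#' 2D data are stored with a singleton third axis; vector fields are stored
#' as 4D volumes with the component axis last. Label maps are written with
#' an integer datatype so labels round-trip exactly.
#'
#' @param obj An [as_image()], [as_labelmap()], [as_velocity()] or
#'   [as_deformation()] object.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(obj, path) {
  if (inherits(obj, c("hr_velocity", "hr_deformation"))) {
    dm <- dim(obj)
    a <- if (length(dm) == 3L)
      array(obj, dim = c(dm[1], dm[2], 1L, dm[3]))
    else array(obj, dim = dm)
    nif <- RNifti::asNifti(a)
    RNifti::writeNifti(nif, path)
    return(invisible(path))
  }
  spacing <- spacing_of(obj)
  a <- as_grid_array(obj)
  if (length(dim(a)) == 2L) {
    a <- array(a, dim = c(dim(a), 1L))
    spacing <- c(spacing, 1)
  }
  if (inherits(obj, "hr_labelmap")) {
    a <- array(as.integer(a), dim = dim(a))
    attr(a, "pixdim") <- spacing
    nif <- RNifti::asNifti(a, datatype = "int32")
  } else {
    attr(a, "pixdim") <- spacing
    nif <- RNifti::asNifti(a)
  }
  RNifti::writeNifti(nif, path)
  invisible(path)
}

#' Save a trained model checkpoint
#'
#' A single archive holding the hypernetwork parameters, both
#' configurations, the registration weight manifest, and any hyperparameter
#' normalization metadata; version-stamped.
#'
#' @param model A [hyper_model()].
#' @param path Output path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "hyper_model"))
    hr_stop("value", "model must be a hyper_model")
  saveRDS(list(format = "hyperreg_model", version = model$version,
               model = model), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Validates the format version and that the stored weight manifest matches
#' the stored registration configuration; forward outputs reproduce the
#' saved model bit-identically.
#'
#' @param path Path written by [save_model()].
#' @return A [hyper_model()].
#' @export
load_model <- function(path) {
  x <- tryCatch(readRDS(path),
                error = function(e) hr_stop("data", paste("unreadable checkpoint:", path)))
  if (!identical(x$format, "hyperreg_model"))
    hr_stop("data", "not a hyperreg model checkpoint")
  if (!identical(x$version, "1"))
    hr_stop("data", paste("unsupported checkpoint version:", x$version))
  model <- x$model
  expect_spec <- build_weight_spec(model$unet_config)
  if (!identical(expect_spec$total_count, model$spec$total_count))
    hr_stop("spec", "checkpoint weight manifest does not match its configuration")
  out_dim <- ncol(model$theta[[length(model$theta)]]$W)
  if (out_dim != model$spec$total_count)
    hr_stop("spec", "hypernetwork output dimension does not match the weight manifest")
  model
}

# -- run configuration ------------------------------------------------------

run_config_keys <- c("unet", "hypernet", "train", "prior", "synth",
                     "outdir", "verbosity")

#' Read a run configuration file
#'
#' YAML document with top-level sections `unet`, `hypernet`, `train`,
#' `prior`, `synth`, `outdir`, `verbosity`; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return Named list of configuration sections.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) hr_stop("config", paste("no such config:", path))
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown))
    hr_stop("config", paste("unknown config keys:",
                            paste(unknown, collapse = ", ")))
  cfg
}

#' Write a run configuration file
#'
#' @param cfg Named list with a subset of the known sections.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown))
    hr_stop("config", paste("unknown config keys:",
                            paste(unknown, collapse = ", ")))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
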