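#' Write a cohort to disk in standard neuroimaging formats
#'
#' Per subject: structural channels as 3D NIfTI, diffusion data as a 4D NIfTI
#' with FSL-dialect plain-text `.bval`/`.bvec` files, and activation maps as
#' a 4D NIfTI (map order = atlas order). The surface template is written as
#' tab-delimited text (vertex_id, hemi, x/y/z mm, sampling locus) plus a JSON
#' homologue map, and a JSON manifest describes the cohort.
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vox <- cohort$spec$voxel_size_mm
  for (s in cohort$subjects) {
    sdir <- file.path(dir, s$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    RNifti::writeNifti(RNifti::asNifti(s$structural$t1, pixdim = rep(vox, 3)),
                       file.path(sdir, "t1.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(s$structural$t2, pixdim = rep(vox, 3)),
                       file.path(sdir, "t2.nii.gz"))
    write_dwi(s$dwi, file.path(sdir, "dwi"), voxel_size_mm = vox)
    acts <- array(unlist(s$activations, use.names = FALSE),
                  dim = c(s$grid_shape, length(s$activations)))
    RNifti::writeNifti(RNifti::asNifti(acts, pixdim = rep(vox, 3)),
                       file.path(sdir, "activations.nii.gz"))
  }
  write_surface_template(cohort$template, dir)
  manifest <- list(
    n_subjects = cohort$spec$n_subjects,
    subject_ids = names(cohort$subjects),
    grid_shape = cohort$spec$grid_shape,
    voxel_size_mm = vox,
    maps = cohort$atlas$maps,
    sessions = cohort$spec$sessions,
    seed = cohort$spec$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Write a diffusion sample as 4D NIfTI + FSL bval/bvec
#'
#' Volume order: b0 volumes first, then each shell's directions in protocol
#' order. `basename.bval` holds one row of b-values, `basename.bvec` three
#' rows (x, y, z components).
#'
#' @param dwi a `dwi_sample`.
#' @param basename output path without extension.
#' @param voxel_size_mm voxel size for the NIfTI header.
#' @return `basename`, invisibly.
#' @export
write_dwi <- function(dwi, basename, voxel_size_mm = 2) {
  vols <- c(dwi$b0_volumes, unlist(lapply(dwi$shells, `[[`, "signals"),
                                   recursive = FALSE))
  dm <- dim(vols[[1]])
  arr <- array(unlist(vols, use.names = FALSE), dim = c(dm, length(vols)))
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = rep(voxel_size_mm, 3)),
                     paste0(basename, ".nii.gz"))
  bvals <- c(rep(0, length(dwi$b0_volumes)),
             unlist(lapply(dwi$shells, function(sh)
               rep(sh$b_value, nrow(sh$directions)))))
  bvecs <- cbind(matrix(0, 3, length(dwi$b0_volumes)),
                 t(do.call(rbind, lapply(dwi$shells, `[[`, "directions"))))
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "),
             paste0(basename, ".bval"))
  writeLines(apply(format(bvecs, trim = TRUE), 1, paste, collapse = " "),
             paste0(basename, ".bvec"))
  invisible(basename)
}

#' Read a diffusion sample written by [write_dwi()]
#'
#' @param basename path without extension.
#' @param b0_threshold b-values at or below this count as b0.
#' @return a `dwi_sample`.
#' @export
read_dwi <- function(basename, b0_threshold = 10) {
  arr <- as.array(RNifti::readNifti(paste0(basename, ".nii.gz")))
  bvals <- scan(paste0(basename, ".bval"), quiet = TRUE)
  bv <- matrix(scan(paste0(basename, ".bvec"), quiet = TRUE), nrow = 3,
               byrow = TRUE)
  is_b0 <- bvals <= b0_threshold
  b0s <- lapply(which(is_b0), function(i) arr[, , , i])
  shells <- lapply(unique(bvals[!is_b0]), function(b) {
    idx <- which(!is_b0 & bvals == b)
    list(b_value = b, directions = t(bv[, idx, drop = FALSE]),
         signals = lapply(idx, function(i) arr[, , , i]))
  })
  structure(list(b0_volumes = b0s, shells = shells), class = "dwi_sample")
}

#' Write the surface template as delimited text + JSON homologue map
#'
#' @param template a [surface_template()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_surface_template <- function(template, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(template$vertices,
                     file.path(dir, "surface_template.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(homologue = template$homologue,
         grid_shape = template$grid_shape,
         voxel_size_mm = template$voxel_size_mm),
    file.path(dir, "surface_homologues.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a surface template written by [write_surface_template()]
#'
#' @param dir directory containing the template files.
#' @return a [surface_template()].
#' @export
read_surface_template <- function(dir) {
  v <- utils::read.table(file.path(dir, "surface_template.tsv"),
                         header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(file.path(dir, "surface_homologues.json"),
                              simplifyVector = TRUE)
  structure(list(vertices = v, homologue = as.integer(meta$homologue),
                 grid_shape = as.integer(meta$grid_shape),
                 voxel_size_mm = meta$voxel_size_mm),
            class = "surface_template")
}

#' Write predicted activation volumes as 4D NIfTI
#'
#' @param vols named list of 3D volumes (atlas order).
#' @param path output `.nii.gz` path.
#' @param voxel_size_mm voxel size for the header.
#' @return `path`, invisibly.
#' @export
write_activations <- function(vols, path, voxel_size_mm = 2) {
  arr <- array(unlist(vols, use.names = FALSE),
               dim = c(dim(vols[[1]]), length(vols)))
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = rep(voxel_size_mm, 3)), path)
  invisible(path)
}
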