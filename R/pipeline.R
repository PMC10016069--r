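#' Read a run manifest
#'
#' A manifest is a JSON file (or an equivalent named list) describing a
#' cohort run: a `subjects` map from subject id to per-subject file paths
#' (`dwi`, `bval`, `bvec`, `white`, `pial`, optional `transform` 4x4 text
#' file, optional `correspondence` CSV), the model parameter (`"odi"` or
#' `"fa"`), the threshold direction, a `threshold` (number or `"sweep"`),
#' an optional `restriction` label file, sampling/smoothing settings, an
#' `output_dir` and a `seed`.
#'
#' @param manifest path to a JSON manifest, or a named list.
#' @return the manifest as a named list, validated.
#' @export
read_manifest <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  if (is.null(manifest$param)) manifest$param <- "odi"
  if (is.null(manifest$direction))
    manifest$direction <- if (manifest$param == "odi") "below" else "above"
  expected <- if (manifest$param == "odi") "below" else "above"
  if (manifest$direction != expected)
    stop(sprintf("parameter %s requires direction '%s'",
                 manifest$param, expected))
  if (is.null(manifest$seed)) manifest$seed <- 1L
  if (is.null(manifest$threshold)) manifest$threshold <- 0.375
  manifest
}

#' Run the full per-subject mapping pipeline
#'
#' Executes model fit (NODDI for ODI, free-water DTI for FA), optional
#' rigid resampling into structural space, depth-weighted cortical
#' sampling, optional atlas resampling, morphometry, and parcellation;
#' writes the per-vertex map (curv + CSV), the parcel label, a metrics row
#' and a provenance JSON to `output_dir/<subject_id>/`.
#'
#' @param manifest a manifest list or JSON path (see [read_manifest()]).
#' @param subject_id subject key into `manifest$subjects`.
#' @return a `parcel_result` with attached `vertex_map`.
#' @export
run_subject <- function(manifest, subject_id) {
  manifest <- read_manifest(manifest)
  sub <- manifest$subjects[[subject_id]]
  if (is.null(sub)) stop("unknown subject: ", subject_id)
  protocol <- read_bvals_bvecs(sub$bval, sub$bvec)
  if (!any(protocol$b0)) stop("missing b=0 measurement")
  dwi <- RNifti::readNifti(sub$dwi)
  aff <- unclass(RNifti::xform(dwi)); attributes(aff) <- list(dim = c(4L, 4L))
  sig <- array(as.numeric(dwi), dim = dim(dwi))
  w <- read_surface(sub$white); p <- read_surface(sub$pial)
  if (!identical(dim(w$vertices), dim(p$vertices)) ||
      !identical(w$triangles, p$triangles))
    stop("white/pial topology mismatch for subject ", subject_id)
  surfaces <- surface_pair(w$vertices, p$vertices, w$triangles)

  mask <- if (!is.null(sub$mask)) read_volume(sub$mask)$data > 0 else NULL
  if (manifest$param == "odi") {
    fitopt <- manifest$fit %||% list()
    fit <- fit_noddi(sig, protocol, mask = mask,
                     n_theta = fitopt$n_theta %||% 48L,
                     n_phi = fitopt$n_phi %||% 32L)
    pvol <- scalar_volume(fit$odi, aff)
  } else {
    fit <- fit_fwdti(sig, protocol, mask = mask)
    pvol <- scalar_volume(fit$fa, aff)
  }
  if (!is.null(sub$transform) && !is.null(sub$reference)) {
    ref <- read_volume(sub$reference)
    tr <- as.matrix(read.table(sub$transform))
    pvol <- resample_volume(pvol, tr, ref$affine, dim(ref$data))
  }
  scfg <- do.call(sampling_config, as.list(manifest$sampling %||% list()))
  vmap <- sample_cortex(pvol, surfaces, scfg)
  values <- if (!is.null(sub$correspondence))
    resample_to_atlas(vmap, read_correspondence(sub$correspondence))
  else vmap$mean
  adjacency <- mesh_adjacency(surfaces)
  morph <- vertex_morphometry(surfaces)
  restriction <- if (!is.null(manifest$restriction))
    read_label(manifest$restriction) else rep(TRUE, nrow(surfaces$white))
  smcfg <- do.call(smoothing_config, as.list(manifest$smoothing %||% list()))
  res <- parcellate(values, adjacency, morph, restriction,
                    threshold = as.numeric(manifest$threshold),
                    direction = manifest$direction, smoothing = smcfg)
  if (!is.null(manifest$output_dir)) {
    out <- file.path(manifest$output_dir, subject_id)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_curv(values, file.path(out, paste0(manifest$param, ".curv")))
    write_vertex_map(vmap, file.path(out, paste0(manifest$param, "_map.csv")))
    write_label(which(res$mask), file.path(out, "parcel.label"),
                vertices = surfaces$white)
    met <- res[c("area", "mean_thickness", "volume", "percent_area",
                 "percent_volume", "n_vertices")]
    write.csv(cbind(subject_id = subject_id, as.data.frame(met)),
              file.path(out, "metrics.csv"), row.names = FALSE)
    prov <- list(package = "ficmap",
                 version = as.character(utils::packageVersion("ficmap")),
                 subject = subject_id, param = manifest$param,
                 direction = manifest$direction,
                 threshold = manifest$threshold,
                 sampling = unclass(scfg), smoothing = unclass(smcfg),
                 seed = manifest$seed)
    jsonlite::write_json(prov, file.path(out, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  attr(res, "vertex_map") <- values
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a cohort: per-subject pipelines plus cohort statistics
#'
#' Runs every subject in the manifest (failures are recorded and skipped),
#' optionally performs the threshold sweep when `manifest$threshold ==
#' "sweep"`, and writes the cohort metrics CSV and the population
#' probability map.
#'
#' @param manifest a manifest list or JSON path.
#' @return list with `metrics` (one row per subject), `failures`,
#'   `probability` (per-vertex fraction), and when sweeping also `sweep`
#'   and `threshold`.
#' @export
run_cohort <- function(manifest) {
  manifest <- read_manifest(manifest)
  ids <- names(manifest$subjects)
  if (length(ids) < 3L) stop("cohort run needs at least 3 subjects")
  sweeping <- identical(manifest$threshold, "sweep")
  if (sweeping) manifest$threshold <- 0.5  # placeholder for the first pass
  results <- list(); failures <- character()
  for (id in ids) {
    r <- tryCatch(run_subject(manifest, id), error = function(e) e)
    if (inherits(r, "error")) {
      failures <- c(failures, setNames(conditionMessage(r), id))
    } else results[[id]] <- r
  }
  if (length(results) == 0L) stop("all subjects failed")
  maps <- vapply(results, function(r) attr(r, "vertex_map"),
                 numeric(length(attr(results[[1L]], "vertex_map"))))
  out <- list(failures = failures)
  if (sweeping) {
    first <- manifest$subjects[[names(results)[1L]]]
    w <- read_surface(first$white); p <- read_surface(first$pial)
    surfaces <- surface_pair(w$vertices, p$vertices, w$triangles)
    adjacency <- mesh_adjacency(surfaces)
    morph <- vertex_morphometry(surfaces)
    restriction <- if (!is.null(manifest$restriction))
      read_label(manifest$restriction) else rep(TRUE, nrow(surfaces$white))
    sw <- sweep_thresholds(maps, adjacency, morph, restriction,
                           direction = manifest$direction)
    thr <- select_threshold(sw)
    manifest$threshold <- thr
    results <- lapply(names(results), function(id) run_subject(manifest, id))
    names(results) <- colnames(maps)
    out$sweep <- sw; out$threshold <- thr
  }
  met <- do.call(rbind, lapply(names(results), function(id) {
    r <- results[[id]]
    data.frame(subject_id = id, area = r$area,
               mean_thickness = r$mean_thickness, volume = r$volume,
               percent_area = r$percent_area,
               percent_volume = r$percent_volume,
               n_vertices = r$n_vertices)
  }))
  out$metrics <- met
  out$probability <- probability_map(vapply(results, function(r) r$mask,
                                            logical(nrow(maps))))
  if (!is.null(manifest$output_dir)) {
    write.csv(met, file.path(manifest$output_dir, "cohort_metrics.csv"),
              row.names = FALSE)
    write_curv(out$probability,
               file.path(manifest$output_dir, "probability.curv"))
  }
  out
}

#' Write a complete synthetic subject to disk
#'
#' Generates the phantom surfaces, parameter volumes and multi-shell DWI
#' signals for one synthetic subject and writes them in the standard
#' formats consumed by [run_subject()] (NIfTI volumes, FreeSurfer binary
#' surfaces, FSL bval/bvec) together with a JSON ground-truth sidecar (true
#' patch vertex indices and true parameter values).
#'
#' @param dir output directory.
#' @param spec a `phantom_spec`.
#' @param protocol a `diffusion_protocol` (default [multishell_protocol()]).
#' @param dwi logical; also simulate and write the 4D DWI volume (slow for
#'   large grids; default FALSE writes parameter volumes only).
#' @return named list of written file paths.
#' @export
simulate_subject <- function(dir, spec = phantom_spec(),
                             protocol = multishell_protocol(), dwi = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  surfaces <- make_phantom_surfaces(spec)
  vols <- make_microstructure_phantom(spec, surfaces)
  paths <- list(
    white = file.path(dir, "lh.white"), pial = file.path(dir, "lh.pial"),
    odi = file.path(dir, "odi.nii.gz"), fa = file.path(dir, "fa.nii.gz"),
    bval = file.path(dir, "dwi.bval"), bvec = file.path(dir, "dwi.bvec"),
    truth = file.path(dir, "ground_truth.json"))
  write_surface(surfaces$white, surfaces$triangles, paths$white)
  write_surface(surfaces$pial, surfaces$triangles, paths$pial)
  write_volume(vols$odi, paths$odi)
  write_volume(vols$fa, paths$fa)
  write_bvals_bvecs(protocol, paths$bval, paths$bvec)
  if (dwi) {
    paths$dwi <- file.path(dir, "dwi.nii.gz")
    paths$mask <- file.path(dir, "mask.nii.gz")
    # ribbon mask with one-voxel margin: only these voxels are simulated/fit
    d <- dim(vols$odi$data)
    ijk <- arrayInd(seq_len(prod(d)), d) - 1L
    world <- cbind(ijk, 1) %*% t(vols$odi$affine)
    r <- sqrt(rowSums(world[, 1:3]^2))
    mask <- array(r >= spec$white_radius - spec$voxel_size &
                    r <= spec$pial_radius + spec$voxel_size, d)
    sig <- make_dwi_phantom(
      list(ndi = array(0.6, d), odi = vols$odi, viso = array(0.05, d)),
      protocol, noise_sd = spec$noise_sd, seed = spec$seed, mask = mask)
    img <- RNifti::asNifti(sig)
    img <- RNifti::`sform<-`(img, structure(vols$odi$affine, code = 2L))
    RNifti::writeNifti(img, paths$dwi)
    write_volume(scalar_volume(array(as.numeric(mask), d), vols$odi$affine),
                 paths$mask)
  }
  truth <- list(patch_vertices = patch_vertices(surfaces, spec),
                odi_patch = spec$odi_patch,
                odi_background = spec$odi_background,
                fa_patch = spec$fa_patch, fa_background = spec$fa_background,
                patch_angular_radius = spec$patch_angular_radius)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE)
  invisible(paths)
}
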