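#' Bundle a default synthetic LA case
#'
#' One-stop generator for the package's default verification case: LA
#' anatomy with orifices, cyclic radial ground-truth motion, the ED image
#' and blood-pool segmentation, coordinates, regions and mapped fibres.
#'
#' @param seed case seed
#' @param s_peak peak radial scale (default 1.08)
#' @param t_peak frame of peak expansion
#' @param n_frames frames per cycle
#' @param dims,spacing image grid (default 64^3 at 1.5 mm)
#' @param noise_sd image noise (default 5 intensity units)
#' @return list with `anatomy`, `motion`, `ed_image`, `segmentation`,
#'   `uac`, `regions`, `fibres`
#' @export
synth_la_case <- function(seed = 1, s_peak = 1.08, t_peak = 4, n_frames = 10,
                          dims = c(64, 64, 64), spacing = 1.5, noise_sd = 5) {
  anatomy <- synth_anatomy("la", seed = seed)
  motion <- synth_motion(centre = colMeans(anatomy$mesh$vertices),
                         s_peak = s_peak, t_peak = t_peak,
                         n_frames = n_frames)
  ed_image <- rasterize_mesh(anatomy$mesh, dims, spacing, inside = 300,
                             outside = 50, blur_sigma = 1,
                             noise_sd = noise_sd, seed = seed)
  seg <- rasterize_mesh(anatomy$mesh, dims, spacing,
                        origin = attr(ed_image, "origin"), inside = 1,
                        outside = 0, blur_sigma = 0, noise_sd = 0)
  seg <- array((seg >= 0.5) * 1L, dims)
  attr(seg, "spacing") <- attr(ed_image, "spacing")
  attr(seg, "origin") <- attr(ed_image, "origin")
  uacr <- compute_uac(anatomy$mesh, anatomy$landmarks)
  fibres <- map_fibres(anatomy$mesh, uacr$uac)
  list(anatomy = anatomy, motion = motion, ed_image = ed_image,
       segmentation = seg, uac = uacr$uac, regions = uacr$regions,
       fibres = fibres, seed = seed)
}

#' Pipeline configuration
#'
#' Inputs may be in-memory objects or file paths (NIfTI volumes, VTK
#' meshes, JSON landmarks/atlas/regions); paths are checked up front.
#'
#' @param images an [image_series()], or a character vector of per-frame
#'   NIfTI paths
#' @param mesh [surface_mesh()] or VTK path (ED endocardium)
#' @param landmarks landmark list or JSON path
#' @param segmentation optional ED mask (array or NIfTI path)
#' @param atlas [fibre_atlas()] or JSON path (default: bundled synthetic)
#' @param regions region spec tibble or JSON path (default: bundled)
#' @param registration a [registration_config()]
#' @param out_dir output directory for persisted artefacts (`NULL` = none)
#' @param frame_schedule `"default10"` keeps 10 frames (subsampling a
#'   20-frame series); `"all"` keeps every frame
#' @param gls compute planar 2D GLS as well
#' @param seed recorded in all outputs
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(images, mesh, landmarks, segmentation = NULL,
                            atlas = NULL, regions = NULL,
                            registration = registration_config(),
                            out_dir = NULL, frame_schedule = "default10",
                            gls = FALSE, seed = 1) {
  for (p in list(images, mesh, landmarks, segmentation, atlas, regions))
    if (is.character(p) && !all(file.exists(p)))
      abort(paste("missing input file(s):",
                  paste(p[!file.exists(p)], collapse = ", ")))
  structure(list(images = images, mesh = mesh, landmarks = landmarks,
                 segmentation = segmentation, atlas = atlas,
                 regions = regions, registration = registration,
                 out_dir = out_dir, frame_schedule = frame_schedule,
                 gls = gls, seed = seed),
            class = "pipeline_config")
}

resolve_input <- function(x, reader) if (is.character(x)) reader(x) else x

#' Run the end-to-end strain pipeline
#'
#' register -> propagate -> coordinates/regions/fibres -> strain
#' (-> planar GLS) -> report.  Each stage's outputs are persisted under
#' `out_dir` when given; re-running with identical inputs and configuration
#' reproduces identical reports.
#'
#' @param config a [pipeline_config()]
#' @return a [strain_report()] with the fitted motion field attached as
#'   attribute `motion`
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e))))
  }
  images <- stage("load_images", {
    im <- config$images
    if (is.character(im)) {
      frames <- lapply(im, read_image_nifti)
      im <- image_series(frames, attr(frames[[1]], "spacing"),
                         attr(frames[[1]], "origin"))
    }
    im
  })
  if (config$frame_schedule == "default10" && length(images$frames) >= 20) {
    keep <- seq(1, length(images$frames), by = 2)
    images <- image_series(images$frames[keep], images$spacing, images$origin,
                           images$frame_fraction[keep])
  }
  mesh <- stage("load_mesh", resolve_input(config$mesh, read_mesh_vtk))
  landmarks <- stage("load_landmarks",
                     resolve_input(config$landmarks, read_landmarks))
  spec <- stage("load_regions", {
    r <- config$regions
    if (is.null(r)) region_spec() else resolve_input(r, region_spec)
  })
  atlas <- stage("load_atlas", {
    a <- config$atlas
    if (is.null(a)) read_fibre_atlas() else resolve_input(a, read_fibre_atlas)
  })

  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  motion <- stage("register", register_series(images, config$registration))
  if (!is.null(out)) write_motion_field(motion, file.path(out, "motion.json"))

  meshes <- stage("propagate", propagate_mesh(mesh, motion))
  uacr <- stage("coordinates", compute_uac(mesh, landmarks, spec))
  fibres <- stage("fibres", map_fibres(mesh, uacr$uac, atlas))
  transients <- stage("strain",
                      strain_transients(meshes, fibres, uacr$regions))
  gls <- NULL
  if (isTRUE(config$gls)) gls <- stage("gls_2d", {
    v2 <- extract_view(images, mesh, landmarks, "2ch")
    v4 <- extract_view(images, mesh, landmarks, "4ch")
    gls_2d(v2, v4, config$registration)
  })
  report <- stage("report", strain_report(transients, meshes, gls))
  if (!is.null(out)) {
    write_strain_report(report, out, seed = config$seed)
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("lastrain")),
           r_version = R.version.string,
           seed = config$seed,
           config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
           frames = length(images$frames)),
      file.path(out, "run_log.json"), auto_unbox = TRUE)
  }
  attr(report, "motion") <- motion
  report
}

#' Run the synthetic-image verification loop on the default case
#'
#' Generates the default synthetic LA case, projects its analytic motion
#' onto a control-point lattice (so the truth lies in the registration's
#' representation space), builds synthetic frames by warping the ED image
#' through that field, re-registers, and reports vertex-position and
#' reservoir-strain recovery errors.
#'
#' @param seed case seed (drives anatomy bumps and image noise)
#' @param config a [registration_config()] for the re-registration
#' @param case optional pre-built [synth_la_case()] result
#' @param lattice_factor spacing of the ground-truth lattice as a fraction
#'   of the image extent
#' @return the [verify_synthetic()] result, plus elements
#'   `median_rmse_peak_mm` and `reservoir_error_pct` (named per metric),
#'   `case` and `truth_field`
#' @export
run_verification <- function(seed = 1, config = registration_config(),
                             case = NULL, lattice_factor = 1 / 8) {
  if (is.null(case)) case <- synth_la_case(seed = seed)
  org <- attr(case$ed_image, "origin")
  sp <- attr(case$ed_image, "spacing")
  d <- dim(case$ed_image)
  upper <- org + (d - 1) * sp
  lv <- level_covering(org, upper, d * sp * lattice_factor,
                       config$n_temporal)
  truth <- fit_motion_field(case$motion, list(lv), org, upper,
                            case$motion$n_frames)
  res <- verify_synthetic(case$ed_image, case$anatomy$mesh, truth, config,
                          case$fibres, case$regions)
  peak <- res$rmse[res$rmse$frame == case$motion$t_peak, ]
  res$median_rmse_peak_mm <- peak$median_mm
  res$reservoir_error_pct <- setNames(res$strain_error$abs_error,
                                      res$strain_error$metric)
  res$case <- case
  res$truth_field <- truth
  res
}
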