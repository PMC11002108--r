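#' Propagate the end-diastolic mesh through a motion field
#'
#' Each frame's mesh is `vertex + u(vertex, t)` with topology and labels
#' unchanged; frame 0 is the input mesh itself.
#'
#' @param ed_mesh reference [surface_mesh()] at end-diastole
#' @param motion a [motion_field()] or [synth_motion()] ground truth
#' @param frames frame times to evaluate (default `0:(n_frames - 1)`)
#' @return list of per-frame `surface_mesh` objects
#' @export
propagate_mesh <- function(ed_mesh, motion, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(motion$n_frames) - 1
  lapply(frames, function(t) {
    m <- ed_mesh
    if (inherits(motion, "ground_truth_motion")) {
      m$vertices <- apply_motion(motion, ed_mesh$vertices, t)
    } else {
      u <- evaluate_displacement(motion, ed_mesh$vertices, t)
      attr(u, "outside") <- NULL
      m$vertices <- ed_mesh$vertices + u
    }
    m
  })
}

#' Dice score coefficient of two binary masks
#'
#' @param a,b binary arrays on a common grid
#' @return `2 |A & B| / (|A| + |B|)`
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) abort("masks must share a grid")
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na == 0 || nb == 0) abort("empty mask")
  2 * sum(a != 0 & b != 0) / (na + nb)
}

#' Surface distances between two meshes
#'
#' `asd` is the symmetrised average surface distance (mean of the two
#' directed mean vertex-to-surface distances); `dhd` is the directed
#' Hausdorff distance from the first mesh's vertices to the second mesh's
#' surface.
#'
#' @param mesh_a,mesh_b [surface_mesh()] objects (`mesh_a` = tracked,
#'   `mesh_b` = truth for the directed Hausdorff)
#' @return list with `asd` and `dhd` (mm)
#' @export
surface_distances <- function(mesh_a, mesh_b) {
  dab <- point_mesh_distance_cpp(mesh_a$vertices, mesh_b$vertices,
                                 mesh_b$triangles - 1L)
  dba <- point_mesh_distance_cpp(mesh_b$vertices, mesh_a$vertices,
                                 mesh_a$triangles - 1L)
  list(asd = (mean(dab) + mean(dba)) / 2, dhd = max(dab))
}

#' Tracking-accuracy metrics
#'
#' Dice score coefficient between tracked and ground-truth segmentations,
#' average surface distance and directed Hausdorff distance (tracked to
#' truth) between the meshes.
#'
#' @param tracked_mesh,truth_mesh meshes at the comparison frame
#' @param tracked_seg,truth_seg binary masks on a common grid
#' @param case case identifier
#' @param frame frame compared
#' @return one-row tibble with `case`, `frame`, `dsc`, `asd`, `dhd`
#' @export
accuracy_metrics <- function(tracked_mesh, truth_mesh, tracked_seg, truth_seg,
                             case = NA_character_, frame = NA_integer_) {
  sd <- surface_distances(tracked_mesh, truth_mesh)
  tibble(case = case, frame = frame,
         dsc = dice_coefficient(tracked_seg, truth_seg),
         asd = sd$asd, dhd = sd$dhd)
}

#' Warp a binary segmentation through a motion field
#'
#' Nearest-neighbour resampling of the ED mask through the fitted motion,
#' giving the tracked segmentation at frame `t`.
#'
#' @param seg binary 3D array with `spacing`/`origin` attributes (or pass
#'   them explicitly)
#' @param motion a [motion_field()]
#' @param t frame
#' @param spacing,origin grid geometry
#' @return binary array
#' @export
warp_segmentation <- function(seg, motion, t, spacing = attr(seg, "spacing"),
                              origin = attr(seg, "origin")) {
  w <- warp_image(array(as.numeric(seg), dim(seg)), motion, t,
                  spacing = spacing, origin = origin)
  out <- array((w >= 0.5) * 1L, dim(seg))
  attr(out, "spacing") <- spacing
  attr(out, "origin") <- origin
  out
}

#' Seeded k-fold partition
#'
#' @param n number of cases, or a vector of group labels to stratify by
#' @param k folds
#' @param seed seed
#' @return integer fold assignment of length `n`
#' @export
make_folds <- function(n, k, seed = 1) {
  labels <- if (length(n) > 1) n else rep(1, n)
  n <- length(labels)
  if (n < k) abort("need at least k cases")
  set.seed(seed)
  fold <- integer(n)
  for (g in unique(labels)) {
    idx <- sample(which(labels == g))
    fold[idx] <- rep_len(seq_len(k), length(idx))[order(seq_along(idx))]
  }
  fold
}

#' Hyperparameter grid search with cross-validated selection
#'
#' Evaluates every (SW, BE) combination on every case, min-max normalises
#' each metric across the grid (Dice inverted to an error so that lower is
#' better for all three), combines them with equal weights, and selects the
#' optimum by k-fold cross-validation: per fold the best combination on the
#' training cases is scored on the held-out cases; the reported optimum
#' minimises the mean test error.  Ties resolve to the lowest SW, then BE.
#'
#' @param metrics either a tibble with columns `case`, `sw`, `be`, `dsc`,
#'   `asd`, `dhd` (one row per case per combination), or a function
#'   `(case, sw, be)` returning a named list/row with those three metrics
#' @param cases case identifiers (required when `metrics` is a function)
#' @param sw_values,be_values grid values
#' @param k_folds folds for cross-validation
#' @param seed fold-assignment seed
#' @param stratify optional per-case group labels for stratified folds
#' @return object of class `grid_search_result`: list with `grid`
#'   (per-combination mean combined error), `folds`, `per_fold` (train
#'   optimum and its test error per fold) and `optimum`
#' @export
hyperparameter_search <- function(metrics, cases = NULL, sw_values = NULL,
                                  be_values = NULL, k_folds = 5, seed = 1,
                                  stratify = NULL) {
  if (is.function(metrics)) {
    if (is.null(cases) || is.null(sw_values) || is.null(be_values))
      abort("supply cases and grid values when metrics is a function")
    rows <- list()
    for (cs in cases)
      for (sw in sw_values)
        for (be in be_values) {
          m <- metrics(cs, sw, be)
          rows[[length(rows) + 1L]] <-
            tibble(case = cs, sw = sw, be = be,
                   dsc = m$dsc, asd = m$asd, dhd = m$dhd)
        }
    metrics <- dplyr::bind_rows(rows)
  }
  metrics <- dplyr::arrange(as_tibble(metrics), .data$case, .data$sw, .data$be)
  if (is.null(sw_values)) sw_values <- sort(unique(metrics$sw))
  if (is.null(be_values)) be_values <- sort(unique(metrics$be))
  n_comb <- length(sw_values) * length(be_values)
  if (nrow(dplyr::distinct(metrics, .data$sw, .data$be)) != n_comb)
    abort("metrics must cover the full SW x BE grid")

  # min-max normalise each metric over the grid; Dice becomes an error
  rng <- function(x) if (diff(range(x)) < 1e-15) rep(0, length(x)) else
    (x - min(x)) / (max(x) - min(x))
  metrics <- dplyr::mutate(metrics,
                           err_dsc = rng(1 - .data$dsc),
                           err_asd = rng(.data$asd),
                           err_dhd = rng(.data$dhd),
                           combined = (.data$err_dsc + .data$err_asd +
                                         .data$err_dhd) / 3)

  grid <- dplyr::summarise(dplyr::group_by(metrics, .data$sw, .data$be),
                           combined = mean(.data$combined), .groups = "drop")

  case_ids <- sort(unique(metrics$case))
  if (length(case_ids) < k_folds) abort("need at least k_folds cases")
  strat <- if (is.null(stratify)) length(case_ids) else stratify
  fold <- make_folds(strat, k_folds, seed)
  folds <- tibble(case = case_ids, fold = fold)
  met <- dplyr::left_join(metrics, folds, by = "case")

  pick <- function(tab) {
    tab <- dplyr::arrange(tab, .data$combined, .data$sw, .data$be)
    tab[1, c("sw", "be", "combined")]
  }
  per_fold <- dplyr::bind_rows(lapply(seq_len(k_folds), function(f) {
    train <- dplyr::summarise(
      dplyr::group_by(met[met$fold != f, ], .data$sw, .data$be),
      combined = mean(.data$combined), .groups = "drop")
    best <- pick(train)
    test <- met[met$fold == f & met$sw == best$sw & met$be == best$be, ]
    tibble(fold = f, sw = best$sw, be = best$be,
           train_error = best$combined, test_error = mean(test$combined))
  }))
  # overall optimum: combination minimising mean test error over folds in
  # which it can be evaluated (scored on each fold's test cases)
  test_err <- dplyr::bind_rows(lapply(seq_len(k_folds), function(f) {
    dplyr::summarise(dplyr::group_by(met[met$fold == f, ], .data$sw, .data$be),
                     combined = mean(.data$combined), .groups = "drop")
  }))
  overall <- dplyr::summarise(dplyr::group_by(test_err, .data$sw, .data$be),
                              combined = mean(.data$combined), .groups = "drop")
  structure(list(grid = grid, folds = folds, per_fold = per_fold,
                 optimum = pick(overall), n_combinations = n_comb),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat("<grid_search_result> ", x$n_combinations, " (SW, BE) combinations\n",
      sep = "")
  cat(sprintf("  optimum: SW = %g, BE = %g (mean test error %.4f)\n",
              x$optimum$sw, x$optimum$be, x$optimum$combined))
  invisible(x)
}

#' @export
tidy.grid_search_result <- function(x, ...) x$grid

#' @export
glance.grid_search_result <- function(x, ...) {
  tibble(sw = x$optimum$sw, be = x$optimum$be,
         mean_test_error = x$optimum$combined,
         n_combinations = x$n_combinations)
}

#' Synthetic-image verification loop
#'
#' Builds synthetic frames by warping the ED image through a known motion
#' field, re-registers the synthetic series, propagates the ED mesh through
#' both the generating and the re-registered fields, and reports per-frame
#' vertex position errors plus the absolute reservoir-strain errors for the
#' area and fibre metrics.
#'
#' @param ed_image 3D array (frame 0) with `spacing`/`origin` attributes
#' @param ed_mesh reference mesh
#' @param motion generating [motion_field()] (the known truth)
#' @param config [registration_config()] for the re-registration
#' @param fibres per-element fibre matrix (for fibre strain)
#' @param regions per-element region labels (`NA` outside the body)
#' @param reregister set `FALSE` to compare the generating motion with
#'   itself (self-consistency check)
#' @return list with `rmse` (tibble frame/median/mean/q90 vertex error, body
#'   vertices), `strain_error` (tibble metric/abs error in percentage
#'   points), `recovered` motion field and both strain transient sets
#' @export
verify_synthetic <- function(ed_image, ed_mesh, motion, config, fibres,
                             regions, reregister = TRUE) {
  F <- motion$n_frames
  frames <- vector("list", F)
  frames[[1]] <- ed_image
  for (t in seq_len(F - 1)) frames[[t + 1]] <- warp_image(ed_image, motion, t)
  ser <- image_series(frames, attr(ed_image, "spacing"),
                      attr(ed_image, "origin"))
  recovered <- if (reregister) register_series(ser, config) else motion

  body_v <- sort(unique(as.vector(
    ed_mesh$triangles[ed_mesh$element_labels == "body", ])))
  V <- ed_mesh$vertices
  rmse <- dplyr::bind_rows(lapply(seq_len(F) - 1, function(t) {
    e <- sqrt(rowSums((evaluate_displacement(recovered, V, t) -
                         evaluate_displacement(motion, V, t))^2))
    tibble(frame = t, median_mm = median(e[body_v]),
           mean_mm = mean(e[body_v]),
           q90_mm = as.numeric(stats::quantile(e[body_v], 0.9)))
  }))

  st_true <- strain_transients(propagate_mesh(ed_mesh, motion), fibres, regions)
  st_rec <- strain_transients(propagate_mesh(ed_mesh, recovered), fibres, regions)
  gl <- function(st, m) st$value[st$scope == "global" & st$metric == m]
  strain_error <- tibble(
    metric = c("area", "fibre"),
    truth = c(reservoir_strain(gl(st_true, "area")),
              reservoir_strain(gl(st_true, "fibre"))),
    recovered = c(reservoir_strain(gl(st_rec, "area")),
                  reservoir_strain(gl(st_rec, "fibre"))))
  strain_error$abs_error <- abs(strain_error$recovered - strain_error$truth)

  list(rmse = rmse, strain_error = strain_error, recovered = recovered,
       transients_truth = st_true, transients_recovered = st_rec)
}
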