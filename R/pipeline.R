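## End-to-end orchestration: phantom -> (optional) acquisition round
## trip -> registration -> preprocessing -> tiling -> adversarial
## training -> colorization -> CIELAB evaluation, with per-stage file
## artifacts, plus the two seeded benchmark protocols used throughout
## the documentation and tests.

#' Build paired training tiles
#'
#' Cuts aligned tiles from a prepared stack and its registered H&E
#' target on a common grid.
#'
#' @param prepared a `normalized_stack` from [prepare_input()].
#' @param target a [stained_image()] aligned with `prepared`.
#' @param grid a [plan_tiles()] grid (e.g. non-overlapping for
#'   training).
#' @return List of `list(x, y)` pairs in anchor order.
#' @export
tile_pairs <- function(prepared, target, grid) {
  xs <- extract_tiles(prepared$channels, grid)
  ys <- extract_tiles(if (inherits(target, "stained_image")) target$rgb else target,
                      grid)
  Map(function(x, y) list(x = x, y = y), xs, ys)
}

## Mean Lab SSIM over a list of (prediction, truth) RGB tile pairs.
tile_lab_ssim <- function(pred_tiles, true_tiles, window_px = 7) {
  dr <- c(100, 255, 255)
  vapply(seq_along(pred_tiles), function(i) {
    lp <- rgb_to_lab(clip01(pred_tiles[[i]]))
    lt <- rgb_to_lab(true_tiles[[i]])
    mean(vapply(1:3, function(k) ssim(lp[, , k], lt[, , k],
                                      window_px = window_px,
                                      dynamic_range = dr[k]), 0))
  }, 0)
}

## Generator inference on a list of input tiles.
predict_tiles <- function(bundle, tiles, batch_size = 16) {
  preds <- vector("list", length(tiles))
  for (start in seq(1, length(tiles), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, length(tiles))
    yb <- net_forward(bundle$generator, tiles_to_tensor(tiles[idx]))$out
    for (j in seq_along(idx)) preds[[idx[j]]] <- yb[, , , j, drop = FALSE][, , , 1]
  }
  preds
}

#' Overfit-colorization benchmark on a phantom
#'
#' Desk-scale analogue of bracketing model performance by overfitting:
#' the same seeded phantom provides training and test material, setting
#' an upper bound on what the colorizer can achieve. Non-overlapping
#' tiles are cut from the prepared stack and the perfectly registered
#' H&E ground truth; training uses a subset of them, and generalization
#' is measured on tiles of an independent phantom draw (same spec,
#' different seed) that the model has never seen. Reports the mean Lab
#' SSIM of generator predictions on the training tiles (the overfit
#' bound) and on the unseen tiles.
#'
#' @param seed integer seed driving the phantoms, the tile subset and
#'   training.
#' @param size phantom side length in pixels (default 512).
#' @param tile_px training tile size (default 64).
#' @param n_train tiles used for training (default 48, of the 64 the
#'   default geometry yields).
#' @param n_heldout unseen-phantom tiles evaluated (default 16).
#' @param config a [train_config()]; the default is a miniature
#'   generator sized for a single CPU.
#' @return List with `ssim_train`, `ssim_heldout`, `bundle`, `phantom`,
#'   and the evaluated tile indices.
#' @export
run_overfit_demo <- function(seed = 1L, size = 512L, tile_px = 64L,
                             n_train = 48L, n_heldout = 16L,
                             config = train_config(max_epochs = 100,
                                                   patience_epochs = 15,
                                                   lr = 2e-3, batch_size = 8,
                                                   base_width = 8, depth = 3,
                                                   seed = seed,
                                                   val_fraction = 0)) {
  ph <- sample_phantom(phantom_spec(size, size, seed = seed),
                       include_stream = FALSE)
  prepared <- prepare_input(ph$contrast)
  grid <- plan_tiles(c(size, size), tile_px, overlap_frac = 0)
  pairs <- tile_pairs(prepared, ph$he_true, grid)
  train_idx <- with_seed(seed + 7L,
                         sample.int(length(pairs),
                                    min(n_train, length(pairs))))
  bundle <- train_colorizer(pairs[train_idx], config = config,
                            provenance = prepared$provenance)
  ## unseen material: an independent draw from the same specimen model
  ph2 <- sample_phantom(phantom_spec(size, size, seed = seed + 911L),
                        include_stream = FALSE)
  pairs2 <- tile_pairs(prepare_input(ph2$contrast), ph2$he_true, grid)
  heldout_idx <- with_seed(seed + 13L,
                           sample.int(length(pairs2),
                                      min(n_heldout, length(pairs2))))
  eval_tiles <- function(pp, idx) {
    preds <- predict_tiles(bundle, lapply(pp[idx], `[[`, "x"))
    mean(tile_lab_ssim(preds, lapply(pp[idx], `[[`, "y")))
  }
  list(ssim_train = eval_tiles(pairs, train_idx),
       ssim_heldout = eval_tiles(pairs2, heldout_idx),
       bundle = bundle, phantom = ph, grid = grid,
       train_idx = train_idx, heldout_idx = heldout_idx)
}

#' Registration-recovery benchmark on a phantom
#'
#' A phantom's H&E copy is displaced by a known smooth thin-plate warp;
#' automated landmark proposal, normalized-cross-correlation refinement
#' and thin-plate-spline fitting then recover the alignment. Reports
#' the mean distance between refined landmarks and the true warp, and
#' the interior mean absolute error between the re-warped H&E and the
#' ground truth as a percentage of the dynamic range.
#'
#' @param seed phantom seed.
#' @param size phantom side, pixels.
#' @param warp_amplitude_px true warp amplitude (<= 8 px is the
#'   supported regime).
#' @param search_px,window_px NCC refinement parameters; the search
#'   radius must cover the warp amplitude.
#' @return List with `landmark_residual_px`, `interior_mae_pct`,
#'   `transform` and the refined `landmarks`.
#' @export
run_registration_demo <- function(seed = 1L, size = 512L,
                                  warp_amplitude_px = 6,
                                  search_px = ceiling(warp_amplitude_px) + 3,
                                  window_px = 14) {
  ph <- sample_phantom(phantom_spec(size, size,
                                    warp_amplitude_px = warp_amplitude_px,
                                    seed = seed),
                       include_stream = FALSE)
  reg <- register_he(ph$contrast, ph$he_moving,
                     search_px = search_px, window_px = window_px)
  lm <- reg$landmarks
  truth <- transform_points(ph$true_warp, cbind(lm$x_ref, lm$y_ref))
  residual <- mean(sqrt((lm$x_mov - truth[, 1])^2 + (lm$y_mov - truth[, 2])^2))
  margin <- ceiling(warp_amplitude_px) + 8
  rows <- (margin + 1):(size - margin)
  mae <- mean(abs(reg$warped$rgb[rows, rows, ] - ph$he_true$rgb[rows, rows, ]))
  list(landmark_residual_px = residual, interior_mae_pct = 100 * mae,
       transform = reg$transform, landmarks = lm, warped = reg$warped,
       phantom = ph)
}

#' Run the full pipeline
#'
#' Executes phantom generation, an optional acquisition round trip
#' (scan-stream emission and grid reconstruction), H&E registration,
#' preprocessing, tiling, adversarial training, whole-image
#' colorization and CIELAB evaluation, writing per-stage artifacts into
#' `out_dir`.
#'
#' @param out_dir run directory (created).
#' @param seed global seed propagated to every stochastic stage.
#' @param phantom a [phantom_spec()] (its seed is overridden by
#'   `seed`).
#' @param use_acquisition reconstruct the stack from an emitted pulse
#'   stream instead of using the phantom stack directly.
#' @param tile_px training/inference tile size.
#' @param train a [train_config()].
#' @param eval_n_patches,eval_patch_px evaluation sampling parameters.
#' @param evaluate_against `"registered"` (the warped-and-recovered
#'   H&E, as in a real study) or `"ground_truth"` (the phantom's
#'   perfectly aligned H&E).
#' @param verbose print stage progress.
#' @return List with the [evaluate_pair()] `report`, the `bundle`, the
#'   `virtual` stained image and the artifact paths.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         phantom = phantom_spec(256, 256),
                         use_acquisition = FALSE,
                         tile_px = 64,
                         train = train_config(max_epochs = 40,
                                              patience_epochs = 10,
                                              base_width = 12, depth = 3,
                                              seed = seed),
                         eval_n_patches = 100, eval_patch_px = 64,
                         evaluate_against = c("registered", "ground_truth"),
                         verbose = FALSE) {
  evaluate_against <- match.arg(evaluate_against)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  phantom$seed <- as.integer(seed)
  say("[phantom] sampling %d x %d", phantom$height_px, phantom$width_px)
  ph <- sample_phantom(phantom, include_stream = use_acquisition)
  write_contrast_stack(ph$contrast, file.path(out_dir, "contrast.tiff"))
  write_stained_image(ph$he_true, file.path(out_dir, "he_true.tiff"))
  write_stained_image(ph$he_moving, file.path(out_dir, "he_moving.tiff"))
  write_landmarks(ph$landmarks_true, file.path(out_dir, "landmarks_true.csv"))
  stack <- ph$contrast
  if (use_acquisition) {
    say("[acquisition] stream round trip")
    write_pulse_stream(ph$pulse_stream, file.path(out_dir, "stream.csv"))
    stack <- reconstruct_grid(ph$pulse_stream)
  }
  say("[registration] landmark recovery")
  reg <- register_he(stack, ph$he_moving,
                     search_px = ceiling(phantom$warp_amplitude_px) + 3)
  write_stained_image(reg$warped, file.path(out_dir, "he_registered.tiff"))
  write_transform(reg$transform, file.path(out_dir, "transform.yaml"))
  write_landmarks(reg$landmarks, file.path(out_dir, "landmarks_refined.csv"))
  target <- if (evaluate_against == "ground_truth") ph$he_true else reg$warped
  say("[preprocess] contrast stretch + reversal")
  prepared <- prepare_input(stack)
  grid_train <- plan_tiles(dim(prepared$channels)[1:2], tile_px, 0)
  pairs <- tile_pairs(prepared, target, grid_train)
  say("[train] %d tiles of %d px", length(pairs), tile_px)
  bundle <- train_colorizer(pairs, config = train,
                            provenance = prepared$provenance)
  save_bundle(bundle, file.path(out_dir, "bundle"))
  say("[colorize] stitched inference")
  virtual <- colorize(bundle, prepared)
  write_stained_image(virtual, file.path(out_dir, "virtual_he.tiff"))
  say("[evaluate] %d patches of %d px", eval_n_patches, eval_patch_px)
  report <- evaluate_pair(virtual, target, n_patches = eval_n_patches,
                          patch_px = eval_patch_px, seed = seed)
  jsonlite::write_json(unclass(report)[c("ssim_mean", "ssim_sd", "rmse_mean",
                                         "rmse_sd", "n_patches", "patch_px",
                                         "color_space", "rmse_units")],
                       file.path(out_dir, "metrics.json"), auto_unbox = TRUE,
                       digits = NA)
  list(report = report, bundle = bundle, virtual = virtual, out_dir = out_dir)
}

#' Write canonical test fixtures
#'
#' Deterministically regenerates the small inputs used across the test
#' suite and documentation; writing the same fixture twice produces
#' byte-identical files.
#'
#' @param name one of `"ramp200"` (a 10 x 20 raster holding 200
#'   distinct ramp values), `"checker16"` (16 x 16 binary
#'   checkerboard), `"phantom-s1"` (seeded 512 px phantom: contrast
#'   stack, true/moving H&E, true landmarks).
#' @param dir output directory.
#' @return Character vector of the written paths.
#' @export
make_fixture <- function(name, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  known <- c("ramp200", "checker16", "phantom-s1")
  if (!name %in% known) {
    stopf("unknown fixture '%s'; available: %s", name,
          paste(known, collapse = ", "))
  }
  if (name == "ramp200") {
    m <- matrix(seq(0, 1, length.out = 200), 10, 20)
    p <- file.path(dir, "ramp200.tiff")
    tiff::writeTIFF(m, p, bits.per.sample = 16)
    return(p)
  }
  if (name == "checker16") {
    m <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
    p <- file.path(dir, "checker16.tiff")
    tiff::writeTIFF(m, p, bits.per.sample = 8)
    return(p)
  }
  ph <- sample_phantom(phantom_spec(512, 512, seed = 1L), include_stream = FALSE)
  paths <- c(
    write_contrast_stack(ph$contrast, file.path(dir, "phantom-s1_contrast.tiff")),
    write_stained_image(ph$he_true, file.path(dir, "phantom-s1_he_true.tiff")),
    write_stained_image(ph$he_moving, file.path(dir, "phantom-s1_he_moving.tiff")),
    write_landmarks(ph$landmarks_true, file.path(dir, "phantom-s1_landmarks.csv")))
  unname(paths)
}
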