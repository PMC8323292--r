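#' Default run configuration
#'
#' One nested list drives an end-to-end run; unknown keys are rejected by
#' [validate_config()], and every stochastic step derives its seed from
#' the single `seed` entry.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    scene = scene_params(),
    overview = list(px_per_um = 2.96, tiles = NULL),
    preprocess = list(p_low = 0.005, p_high = 0.995, sigma_blur = 1.5,
                      laplacian_sign = "positive",
                      min_area = 100, close_size = 5, sigma_basin = 1.5),
    detection = detection_params(),
    rois = list(n = 1L, anchor_section = 1L),
    focus = list(anchors_per_ribbon = 3L),
    navigation = list(mags = c("20x", "100x"), start_section = 1L,
                      n_sections = NULL, settle_s = 2.0,
                      axis_signs = c(1, 1), order_by = "roi"),
    microscope = list(fov_px = 200L, jitter_um = 0),
    registration = list(mode = "translation"))
}

#' Validate a run configuration
#'
#' Checks the configuration against the schema of [default_config()]:
#' unknown keys (at any nesting level) raise an error naming the key, and
#' missing keys are filled in from the defaults.
#'
#' @param config nested list, or path to a YAML file.
#' @return the completed configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config error: configuration must be a list")
  ref <- default_config()
  check <- function(cfg, ref, path) {
    extra <- setdiff(names(cfg), names(ref))
    if (length(extra))
      stop(sprintf("config error: unknown key '%s'",
                   paste0(path, extra[1])))
    for (k in names(cfg)) {
      if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(cfg[[k]]))
        check(cfg[[k]], ref[[k]], paste0(path, k, "."))
    }
  }
  check(config, ref, "")
  out <- utils::modifyList(ref, config)
  stopifnot(out$overview$px_per_um > 0, out$microscope$fov_px >= 32)
  out
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf("[%s] INFO %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  if (!is.null(con)) writeLines(msg, con)
  invisible(msg)
}

# nearest detected section (ribbon, index) for a pixel position
locate_section <- function(det, p_px) {
  best <- c(Inf, NA, NA)
  for (r in seq_along(det$ribbons)) {
    cen <- t(vapply(det$ribbons[[r]]$sections, quad_centroid, numeric(2)))
    d <- sqrt((cen[, 1] - p_px[1])^2 + (cen[, 2] - p_px[2])^2)
    k <- which.min(d)
    if (d[k] < best[1]) best <- c(d[k], r, k)
  }
  list(ribbon = as.integer(best[2]), section = as.integer(best[3]),
       dist = best[1])
}

#' Match detected sections to ground-truth sections
#'
#' Greedy one-to-one assignment of detected sections to true sections by
#' centroid distance.  A detected section counts as correct when its
#' matched true centroid is within `tol_px`.
#'
#' @param det a `detection_result`.
#' @param truth_px list of ribbons, each a list of true quads (px).
#' @param tol_px match tolerance in pixels.
#' @return data frame (ribbon, det_index, truth_ribbon, truth_index,
#'   centroid_dist_px, matched).
#' @export
match_detection <- function(det, truth_px, tol_px = 40) {
  tc <- NULL
  for (r in seq_along(truth_px))
    for (k in seq_along(truth_px[[r]]))
      tc <- rbind(tc, c(r, k, quad_centroid(truth_px[[r]][[k]])))
  used <- rep(FALSE, nrow(tc))
  out <- NULL
  for (r in seq_along(det$ribbons)) for (k in seq_along(det$ribbons[[r]]$sections)) {
    cen <- quad_centroid(det$ribbons[[r]]$sections[[k]])
    d <- sqrt((tc[, 3] - cen[1])^2 + (tc[, 4] - cen[2])^2)
    d[used] <- Inf
    j <- which.min(d)
    ok <- is.finite(d[j]) && d[j] <= tol_px
    if (ok) used[j] <- TRUE
    out <- rbind(out, data.frame(ribbon = r, det_index = k,
                                 truth_ribbon = if (ok) tc[j, 1] else NA,
                                 truth_index = if (ok) tc[j, 2] else NA,
                                 centroid_dist_px = if (is.finite(d[j])) d[j] else NA,
                                 matched = ok))
  }
  out
}

#' Run the full synthetic navigation pipeline
#'
#' Executes the complete workflow against the synthetic scene and
#' simulated microscope: render (optionally tile + stitch) the overview,
#' preprocess, detect all sections from per-ribbon seeds, calibrate the
#' stage on a section corner, define ROIs, build the focus map and the
#' navigation plan, then walk the magnification ladder - acquire, register,
#' refine - persisting the plan after every entry.  All artefacts (overview
#' TIFF, detection and plan JSON, per-transition correction CSVs, error
#' table, log) are written to `out_dir`; a rerun on a directory whose plan
#' has no pending entries acquires nothing.
#'
#' @param config configuration list or YAML path (see [default_config()]).
#' @param out_dir run directory (created if missing).
#' @return invisible list: scene, detection, match, calibration, plan,
#'   stacks, corrections (per transition), and the per-section `errors`
#'   table (stage-target error vs ground truth at each ladder step).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("atnav_run_")) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out_dir, "log.txt"), open = "a")
  on.exit(close(logf))
  t_start <- Sys.time()
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  cfg_hash <- sum(utf8ToInt(paste(deparse(cfg), collapse = "")))
  log_line(logf, "run start; config hash %d; seed %d", cfg_hash, cfg$seed)

  scene <- generate_scene(cfg$scene, cfg$seed)
  log_line(logf, "scene: %d ribbons, %d sections",
           length(scene$ribbons), sum(scene$section_counts))
  ppu <- cfg$overview$px_per_um
  ov <- render_overview(scene, ppu, tiles = cfg$overview$tiles)
  truth_px <- attr(ov, "truth_px")
  origin_um <- attr(ov, "origin_um")
  if (!is.null(cfg$overview$tiles)) {
    st <- grid_stitch(attr(ov, "tile_grid"), pixel_size = 1 / ppu)
    log_line(logf, "stitched %d tiles", nrow(attr(st, "offsets")))
    ov$pixels <- st$pixels
  }
  write_overview(ov, file.path(out_dir, "overview.tif"))

  edge <- preprocess_overview(ov, cfg$preprocess)
  log_line(logf, "preprocess: stages %s",
           paste(names(attr(edge, "stages")), collapse = ","))

  seeds <- with_seed(cfg$seed + 101L, lapply(truth_px, function(rb) {
    k <- ceiling(length(rb) / 2)
    section_quad(unclass(rb[[k]]) + matrix(stats::runif(8, -3, 3), 4, 2),
                 check = FALSE)
  }))
  det <- detect_all_sections(edge, seeds, cfg$detection)
  mm <- match_detection(det, truth_px)
  log_line(logf, "detection: %d sections (%d matched to truth)",
           n_sections(det), sum(mm$matched))
  write_detection(det, file.path(out_dir, "detection.json"))

  # stage calibration: zero the stage on corner 1 of the first section
  origin_px <- unclass(det$ribbons[[1]]$sections[[1]])[1, ]
  cal <- calibrate_stage(origin_px, 1 / ppu, cfg$navigation$axis_signs)
  stage_origin_um <- origin_um + (origin_px - 0.5) / ppu
  log_line(logf, "calibration: origin px (%.1f, %.1f)", origin_px[1], origin_px[2])

  # focus map: the user focuses at a few section centroids per ribbon
  fx <- c(); fy <- c(); fz <- c()
  for (r in seq_along(det$ribbons)) {
    nq <- length(det$ribbons[[r]]$sections)
    ks <- unique(round(seq(1, nq, length.out = min(cfg$focus$anchors_per_ribbon, nq))))
    for (k in ks) {
      cen_px <- quad_centroid(det$ribbons[[r]]$sections[[k]])
      cen_st <- px_to_stage(cal, cen_px)
      fx <- c(fx, cen_st[1]); fy <- c(fy, cen_st[2])
      fz <- c(fz, scene_focus_at(scene, stage_origin_um[1] + cen_st[1],
                                 stage_origin_um[2] + cen_st[2]))
    }
  }
  focus <- focus_map(fx, fy, fz)

  # ROIs: the user clicks the dark structure in the anchor section
  roi_px_all <- attr(ov, "roi_px")
  n_roi <- min(cfg$rois$n, length(scene$rois))
  rois <- list(); roi_sections <- list()
  for (i in seq_len(n_roi)) {
    a_truth <- cfg$rois$anchor_section
    click <- roi_px_all[[i]][a_truth, ]
    loc <- locate_section(det, click)
    rois[[i]] <- define_roi(scene$rois[[i]]$id, det, loc$ribbon, loc$section,
                            click)
    roi_sections[[i]] <- c(loc, list(truth_anchor = a_truth))
  }

  mags <- cfg$navigation$mags
  n_sec_ribbon <- length(det$ribbons[[rois[[1]]$ribbon]]$sections)
  n_sections <- if (is.null(cfg$navigation$n_sections)) n_sec_ribbon else
    min(cfg$navigation$n_sections, n_sec_ribbon)
  plan_path <- file.path(out_dir, "plan.json")
  if (file.exists(plan_path)) {
    plan <- read_plan(plan_path)
    log_line(logf, "resuming existing plan (%d pending)",
             sum(plan$entries$status == "pending"))
  } else {
    plan <- build_plan(rois, det, cal, focus, mags,
                       start_section = cfg$navigation$start_section,
                       n_sections = n_sections,
                       order_by = cfg$navigation$order_by)
    write_plan(plan, plan_path)
  }
  plan0 <- plan

  scope <- simulated_microscope(scene, stage_origin_um,
                                fov_px = cfg$microscope$fov_px,
                                jitter_um = cfg$microscope$jitter_um,
                                seed = cfg$seed + 202L)

  # truth in the calibrated stage frame, per ROI
  truth_stage <- lapply(seq_len(n_roi), function(i)
    sweep(scene$rois[[i]]$trajectory, 2, stage_origin_um))

  corrections <- list(); stacks_all <- list(); errors <- NULL
  for (mi in seq_along(mags)) {
    m <- mags[mi]
    res <- acquire_stack(plan, scope, settle_s = cfg$navigation$settle_s,
                         mag = m, path = plan_path)
    plan <- res$plan
    log_line(logf, "acquired %d stack(s) at %s", length(res$stacks), m)
    stacks_all <- c(stacks_all, res$stacks)
    for (key in names(res$stacks)) {
      stk <- res$stacks[[key]]
      if (length(stk$frames) < 2) next
      ri <- which(vapply(rois, function(r) r$id, "") == stk$entries$roi_id[1])
      ref_frame <- which(stk$entries$section == rois[[ri]]$anchor_section)
      if (!length(ref_frame)) ref_frame <- 1L
      reg <- register_stack(stk, mode = cfg$registration$mode,
                            reference = ref_frame[1])
      if (mi < length(mags)) {
        nxt <- mags[mi + 1]
        plan <- refine_plan(plan, reg, stk, next_mag = nxt)
        corr <- attr(plan, "corrections")
        tag <- sprintf("%s_to_%s", m, nxt)
      } else {
        # final ladder step: record the fully corrected targets
        corr <- local({
          signs <- cal$axis_signs
          dx <- running_mean(signs[1] * reg$dx_px * stk$pixel_size, 3L)
          dy <- running_mean(signs[2] * reg$dy_px * stk$pixel_size, 3L)
          data.frame(section = stk$entries$section, dx_um = dx, dy_um = dy,
                     magnitude_um = sqrt(dx^2 + dy^2))
        })
        tag <- sprintf("%s_final", m)
      }
      corrections[[tag]] <- corr
      write_corrections(corr, file.path(out_dir, sprintf("corrections_%s.csv", tag)))
      write_plan(plan, plan_path)
      log_line(logf, "refined after %s: median correction %.2f um",
               m, stats::median(corr$magnitude_um))
      # error bookkeeping against ground truth
      ri_truth <- truth_stage[[ri]]
      secs <- stk$entries$section
      tr_idx <- roi_truth_index(roi_sections[[ri]], rois[[ri]], secs)
      tru <- ri_truth[tr_idx, , drop = FALSE]
      cur <- plan$entries[plan$entries$roi_id == stk$entries$roi_id[1] &
                          plan$entries$mag == mags[min(mi + 1, length(mags))], ]
      cur <- cur[match(secs, cur$section), ]
      tgt <- cbind(cur$x_um, cur$y_um)
      if (mi == length(mags))
        tgt <- tgt + cbind(corr$dx_um, corr$dy_um)
      err_now <- sqrt(rowSums((tgt - tru)^2))
      p0 <- plan0$entries[plan0$entries$roi_id == stk$entries$roi_id[1] &
                          plan0$entries$mag == m, ]
      p0 <- p0[match(secs, p0$section), ]
      err_plan <- sqrt(rowSums((cbind(p0$x_um, p0$y_um) - tru)^2))
      errors <- rbind(errors, data.frame(
        roi_id = stk$entries$roi_id[1], stage = sprintf("after_%s", m),
        section = secs, error_plan_um = err_plan, error_um = err_now))
    }
  }
  if (!is.null(errors))
    utils::write.csv(errors, file.path(out_dir, "errors.csv"), row.names = FALSE)
  log_line(logf, "run complete in %.1f s",
           as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  invisible(list(out_dir = out_dir, scene = scene, overview = ov, det = det,
                 match = mm, calibration = cal, stage_origin_um = stage_origin_um,
                 focus = focus, rois = rois, plan = plan, plan_initial = plan0,
                 stacks = stacks_all, corrections = corrections, errors = errors))
}

# map plan section indices (detected ribbon order) to scene trajectory rows:
# the detected ribbon may start mid-ribbon, so align via the anchor section,
# whose true index is known from the user click
roi_truth_index <- function(loc, roi, sections) {
  sections + (loc$truth_anchor - loc$section)
}

#' Read a navigation plan back from disk
#'
#' Thin wrapper over [read_plan()] fulfilling the serialization contract:
#' `roundtrip_plan(write_plan(plan, path))` equals the plan field for
#' field, and a truncated or malformed file raises a parse error without
#' returning a partial plan.
#'
#' @param path plan JSON path.
#' @export
roundtrip_plan <- function(path) {
  if (!file.exists(path)) stop(sprintf("plan file '%s' does not exist", path))
  read_plan(path)
}
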