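#' Pixel-to-stage calibration
#'
#' The stage is zeroed on a section corner near the centre of the field of
#' view; the calibration then converts overview pixel coordinates to
#' absolute stage micrometres: `stage = axis_signs * (p - origin_px) *
#' pixel_size`.
#'
#' @param origin_px overview pixel coordinates `c(x, y)` of the stage
#'   origin (the zeroed corner).
#' @param pixel_size micrometres per overview pixel.
#' @param axis_signs `c(+-1, +-1)`: stage-axis directions relative to image
#'   x-right / y-down.
#' @return a `stage_calibration`.
#' @export
calibrate_stage <- function(origin_px, pixel_size, axis_signs = c(1, 1)) {
  stopifnot(pixel_size > 0, all(axis_signs %in% c(-1, 1)), length(origin_px) == 2)
  structure(list(origin_px = as.numeric(origin_px),
                 pixel_size = pixel_size,
                 axis_signs = as.numeric(axis_signs)),
            class = "stage_calibration")
}

#' Convert overview pixels to stage micrometres (and back)
#' @param cal a `stage_calibration`.
#' @param p point `c(x, y)` or n x 2 matrix.
#' @export
px_to_stage <- function(cal, p) {
  pm <- if (is.matrix(p)) p else matrix(p, ncol = 2)
  out <- sweep(sweep(pm, 2, cal$origin_px), 2, cal$axis_signs, "*") * cal$pixel_size
  colnames(out) <- c("x", "y")
  if (is.matrix(p)) out else drop(out)
}

#' @rdname px_to_stage
#' @export
stage_to_px <- function(cal, p) {
  pm <- if (is.matrix(p)) p else matrix(p, ncol = 2)
  out <- sweep(sweep(pm / cal$pixel_size, 2, cal$axis_signs, "*"),
               2, cal$origin_px, "+")
  colnames(out) <- c("x", "y")
  if (is.matrix(p)) out else drop(out)
}

#' Define a region of interest on the overview image
#'
#' An ROI is selected by one click in one section; its natural-coordinate
#' address (the inverse transfinite map of the click in the anchor
#' section) is what gets propagated to every other section.
#'
#' @param id ROI identifier.
#' @param detection a `detection_result`.
#' @param ribbon index of the ribbon containing the anchor section.
#' @param anchor_section index of the anchor section within that ribbon.
#' @param anchor_point_px overview pixel coordinates of the selected point.
#' @return an `at_roi` with the derived natural coordinates.
#' @export
define_roi <- function(id, detection, ribbon, anchor_section, anchor_point_px) {
  quads <- detection$ribbons[[ribbon]]$sections
  stopifnot(anchor_section >= 1, anchor_section <= length(quads))
  nat <- inverse_map(quads[[anchor_section]], anchor_point_px)
  if (any(attr(nat, "outside")))
    warning(sprintf("ROI '%s' anchor point lies outside its section", id))
  structure(list(id = id, ribbon = ribbon, anchor_section = anchor_section,
                 anchor_point_px = as.numeric(anchor_point_px),
                 natural = as.numeric(unclass_nat(nat))),
            class = "at_roi")
}

#' Build a navigation plan across sections and magnifications
#'
#' For every ROI and every requested section the ROI position is
#' propagated through the transfinite map from the anchor section, the
#' result converted to stage micrometres, and the focus surface queried at
#' the target.  Plans for several ROIs are the concatenation of the
#' independent single-ROI plans (predictions are fully independent), so
#' several regions can be multiplexed in one run.
#'
#' @param rois an `at_roi` or list of them.
#' @param detection a `detection_result`.
#' @param cal a `stage_calibration`.
#' @param focus a `focus_map` (stage micrometres), or NULL for focus 0.
#' @param mags character vector of magnification labels (ladder order).
#' @param start_section first section index (within the ROI's ribbon).
#' @param n_sections number of consecutive sections to include.
#' @param order_by `"roi"` (all sections of one ROI first) or `"section"`.
#' @return a `navigation_plan`: calibration, focus anchors, ROIs and an
#'   `entries` data frame (roi_id, section, mag, x_um, y_um, z_um, status).
#' @export
build_plan <- function(rois, detection, cal, focus, mags = c("20x", "100x"),
                       start_section = 1L, n_sections = NULL,
                       order_by = c("roi", "section")) {
  order_by <- match.arg(order_by)
  if (inherits(rois, "at_roi")) rois <- list(rois)
  entries <- NULL
  for (roi in rois) {
    quads <- detection$ribbons[[roi$ribbon]]$sections
    n_av <- length(quads)
    ns <- if (is.null(n_sections)) n_av - start_section + 1L else n_sections
    last <- start_section + ns - 1L
    if (start_section < 1 || last > n_av)
      stop(sprintf("range error: sections %d..%d requested, %d detected",
                   start_section, last, n_av))
    anchor <- quads[[roi$anchor_section]]
    for (k in start_section:last) {
      tgt_px <- forward_map(quads[[k]], roi$natural)
      tgt <- px_to_stage(cal, tgt_px)
      z <- if (is.null(focus)) 0 else
        as.numeric(interpolate_focus(focus, tgt[1], tgt[2]))
      for (m in mags)
        entries <- rbind(entries, data.frame(
          roi_id = roi$id, section = k, mag = m,
          x_um = tgt[[1]], y_um = tgt[[2]], z_um = z,
          status = "pending", stringsAsFactors = FALSE))
    }
  }
  if (order_by == "section")
    entries <- entries[order(entries$section, entries$roi_id, entries$mag), ]
  rownames(entries) <- NULL
  structure(list(calibration = cal,
                 focus = focus,
                 rois = rois,
                 mag_table = mag_pixel_sizes(),
                 entries = entries),
            class = "navigation_plan")
}

#' @export
print.navigation_plan <- function(x, ...) {
  cat(sprintf("navigation_plan: %d entries (%d pending), %d ROI(s), mags: %s\n",
              nrow(x$entries), sum(x$entries$status == "pending"),
              length(x$rois), paste(unique(x$entries$mag), collapse = ", ")))
  invisible(x)
}

#' Execute the pending entries of a navigation plan
#'
#' Drives the microscope to each pending target in section order, waits
#' for the stage to settle, sets focus, and acquires.  The plan is
#' persisted after every entry when `path` is given, so an interrupted run
#' resumes with only the remaining pending entries.  A failing entry is
#' marked `failed` and the loop continues; failures are summarised in a
#' warning at the end.
#'
#' @param plan a `navigation_plan`.
#' @param scope a microscope interface: list with `move_to(c(x,y))`,
#'   `set_focus(z)`, `acquire(mag)` (see [simulated_microscope()]).
#' @param settle_s settle wait between stage movement and acquisition in
#'   seconds (recorded in the stack metadata; the simulator does not sleep).
#' @param mag restrict acquisition to one magnification label (optional).
#' @param roi_id restrict to one ROI (optional).
#' @param path plan JSON file to persist after every entry (optional).
#' @param sleep actually sleep `settle_s` between moves (real hardware).
#' @return list with the updated `plan` and `stacks`: one `image_stack`
#'   per (roi, mag) combination acquired.
#' @export
acquire_stack <- function(plan, scope, settle_s = 2.0, mag = NULL,
                          roi_id = NULL, path = NULL, sleep = FALSE) {
  e <- plan$entries
  sel <- e$status == "pending"
  if (!is.null(mag)) sel <- sel & e$mag == mag
  if (!is.null(roi_id)) sel <- sel & e$roi_id == roi_id
  idx <- which(sel)
  idx <- idx[order(e$section[idx])]
  stacks <- list()
  failures <- 0L
  for (i in idx) {
    row <- e[i, ]
    ok <- tryCatch({
      scope$move_to(c(row$x_um, row$y_um))
      if (sleep && settle_s > 0) Sys.sleep(settle_s)
      scope$set_focus(row$z_um)
      frame <- scope$acquire(row$mag)
      key <- paste(row$roi_id, row$mag, sep = "/")
      if (is.null(stacks[[key]]))
        stacks[[key]] <- list(frames = list(), entries = NULL,
                              pixel_size = attr(frame, "pixel_size"),
                              settle_s = settle_s)
      stacks[[key]]$frames[[length(stacks[[key]]$frames) + 1]] <- frame
      stacks[[key]]$entries <- rbind(stacks[[key]]$entries, row)
      TRUE
    }, error = function(err) { failures <<- failures + 1L; FALSE })
    e$status[i] <- if (ok) "done" else "failed"
    plan$entries <- e
    if (!is.null(path)) write_plan(plan, path)
  }
  stacks <- lapply(stacks, function(s) {
    rownames(s$entries) <- NULL
    structure(s, class = "image_stack")
  })
  if (failures > 0)
    warning(sprintf("%d plan entr%s failed during acquisition",
                    failures, if (failures == 1) "y" else "ies"))
  list(plan = plan, stacks = stacks)
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %d frames, %.4f um/px, ROI %s at %s\n",
              length(x$frames), x$pixel_size,
              x$entries$roi_id[1], x$entries$mag[1]))
  invisible(x)
}

#' Write / read a navigation plan as JSON
#'
#' The plan file is the single source of truth for a run: calibration,
#' focus anchors, ROI definitions and per-entry stage targets with status.
#' `read_plan(write_plan(plan))` reproduces the plan field for field.
#'
#' @param plan a `navigation_plan`.
#' @param path JSON file path.
#' @export
write_plan <- function(plan, path) {
  obj <- list(
    calibration = list(origin_px = plan$calibration$origin_px,
                       pixel_size_um = plan$calibration$pixel_size,
                       axis_signs = plan$calibration$axis_signs),
    focus_anchors = if (is.null(plan$focus)) list() else
      list(x = plan$focus$x, y = plan$focus$y, z = plan$focus$z),
    mag_table = as.list(plan$mag_table),
    rois = lapply(plan$rois, function(r)
      list(id = r$id, ribbon = r$ribbon, anchor_section = r$anchor_section,
           anchor_point_px = r$anchor_point_px, natural = r$natural)),
    entries = plan$entries)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop(sprintf("parse error in plan file '%s': %s",
                                 path, conditionMessage(e))))
  need <- c("calibration", "focus_anchors", "mag_table", "rois", "entries")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop(sprintf("parse error in plan file '%s': missing field '%s'",
                 path, miss[1]))
  cal <- calibrate_stage(unlist(obj$calibration$origin_px),
                         obj$calibration$pixel_size_um,
                         unlist(obj$calibration$axis_signs))
  focus <- if (length(obj$focus_anchors))
    focus_map(unlist(obj$focus_anchors$x), unlist(obj$focus_anchors$y),
              unlist(obj$focus_anchors$z)) else NULL
  rois <- obj$rois
  roi_list <- if (is.data.frame(rois)) {
    lapply(seq_len(nrow(rois)), function(i)
      structure(list(id = rois$id[i], ribbon = rois$ribbon[i],
                     anchor_section = rois$anchor_section[i],
                     anchor_point_px = unlist(rois$anchor_point_px[i]),
                     natural = unlist(rois$natural[i])), class = "at_roi"))
  } else {
    lapply(rois, function(r)
      structure(list(id = r$id, ribbon = r$ribbon,
                     anchor_section = r$anchor_section,
                     anchor_point_px = unlist(r$anchor_point_px),
                     natural = unlist(r$natural)), class = "at_roi"))
  }
  entries <- as.data.frame(obj$entries, stringsAsFactors = FALSE)
  if (!all(c("roi_id", "section", "mag", "x_um", "y_um", "z_um", "status")
           %in% names(entries)))
    stop(sprintf("parse error in plan file '%s': malformed entries", path))
  structure(list(calibration = cal, focus = focus, rois = roi_list,
                 mag_table = unlist(obj$mag_table), entries = entries),
            class = "navigation_plan")
}
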