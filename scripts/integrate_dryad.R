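#!/usr/bin/env Rscript
# Optional integration with the deposited tracking data (Dryad
# doi:10.5061/dryad.2z34tmpnc). Given a directory of per-session CSV exports
# (head rotation series, eye rotation series, mouse/cricket trajectories),
# recomputes the whole-session statistics that the synthetic acceptance
# checks cover only in property form: functional-focus contour centers,
# pitch/roll compensation gains with and without frozen eye axes, and
# per-trial capture-time medians.
#
#   Rscript scripts/integrate_dryad.R --data <dir> --out <dir>
#
# Expected layout per session <id>:
#   <id>_head.csv       timestamp + r11..r33          (head -> world)
#   <id>_left_eye.csv   timestamp + phi/theta/psi deg (eye in head)
#   <id>_right_eye.csv  timestamp + phi/theta/psi deg
#   <id>_trajectory.csv t, mouse_*, cricket_*, bearing_deg
#   <id>_capture.txt    manual capture-end timestamp (s)

suppressMessages(library(mousegaze))

args <- commandArgs(trailingOnly = TRUE)
get_opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 0) return(default)
  args[i + 1]
}
data_dir <- get_opt("--data")
out_dir <- get_opt("--out", "results/dryad")
if (is.null(data_dir) || !dir.exists(data_dir)) {
  stop("no --data directory given (the deposited tracking data are not ",
       "bundled with this package); download the Dryad archive and export ",
       "sessions to the layout described in the header comment", call. = FALSE)
}
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

sessions <- unique(sub("_head\\.csv$", "",
                       list.files(data_dir, pattern = "_head\\.csv$")))
if (length(sessions) == 0) stop("no '<id>_head.csv' files found in --data")

summary_rows <- list()
for (id in sessions) {
  fp <- function(sfx) file.path(data_dir, paste0(id, sfx))
  head_ser <- horizon_align(read_rotation_series_csv(fp("_head.csv"), "head"))
  left <- read_rotation_series_csv(fp("_left_eye.csv"), "left_eye")
  left <- resample_rotation_series(left, head_ser$timestamps)
  gains <- list(
    control_x = compensation_gain(head_ser, left, "X")$slope,
    control_y = compensation_gain(head_ser, left, "Y")$slope,
    torsion_frozen_x = compensation_gain(
      head_ser, freeze_eye_rotations(left, "torsion"), "X")$slope,
    vertical_frozen_y = compensation_gain(
      head_ser, freeze_eye_rotations(left, "vertical"), "Y")$slope)

  traj <- read_trajectory_csv(fp("_trajectory.csv"))
  cap_end <- as.numeric(readLines(fp("_capture.txt"))[1])
  seg <- classify_epochs(traj, cap_end)
  tr <- seg$epochs[seg$epochs$kind == "track" & !seg$epochs$excluded, ]
  focus <- NULL
  if (nrow(tr) > 0) {
    sel <- which(traj$timestamps >= tr$t_start[1] &
                   traj$timestamps <= tr$t_end[1])
    poses <- resample_rotation_series(left, traj$timestamps[sel])
    cc <- t(vapply(seq_along(sel), function(k) {
      i <- sel[k]
      project_point_to_cornea(traj$cricket[i, ], traj$mouse[i, ],
                              poses$rotations[, , k])
    }, numeric(2)))
    cc <- cc[stats::complete.cases(cc), , drop = FALSE]
    if (nrow(cc) > 10) {
      dm <- prey_density_map(cc, spherical_grid(129), smooth_px = 2)
      focus <- hdr_contours(dm, 50)[[1]]$center
    }
  }
  capture_time <- if (nrow(tr) > 0) cap_end - tr$t_start[1] else NA_real_
  summary_rows[[id]] <- data.frame(
    session = id, gain_x = gains$control_x, gain_y = gains$control_y,
    gain_x_torsion_frozen = gains$torsion_frozen_x,
    gain_y_vertical_frozen = gains$vertical_frozen_y,
    focus_radial_deg = if (is.null(focus)) NA else focus[["radial"]],
    focus_rotation_deg = if (is.null(focus)) NA else focus[["rotation"]],
    capture_time_s = capture_time)
}
out <- do.call(rbind, summary_rows)
utils::write.csv(out, file.path(out_dir, "session_summary.csv"),
                 row.names = FALSE)
cat(sprintf("wrote %s (%d sessions)\n",
            file.path(out_dir, "session_summary.csv"), nrow(out)))
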