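motion_cols <- c("trans_x_mm", "trans_y_mm", "trans_z_mm",
                 "rot_x_deg", "rot_y_deg", "rot_z_deg")

as_motion_matrix <- function(motion) {
  m <- as.matrix(as.data.frame(motion))
  if (ncol(m) != 6) abort("motion trace must have 6 columns (3 translations mm, 3 rotations deg).")
  if (!is.null(colnames(m)) && all(motion_cols %in% colnames(m))) {
    m <- m[, motion_cols, drop = FALSE]
  }
  if (any(!is.finite(m))) abort("motion parameters must be finite.")
  m
}

rot_matrix <- function(deg) {
  th <- deg * pi / 180
  cx <- cos(th[1]); sx <- sin(th[1])
  cy <- cos(th[2]); sy <- sin(th[2])
  cz <- cos(th[3]); sz <- sin(th[3])
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  rx %*% ry %*% rz
}

#' Framewise displacement (Jenkinson)
#'
#' Per-volume head-motion summary: the root-mean-square displacement, over a
#' ball of radius `head_radius_mm`, induced by the relative rigid-body
#' transform between consecutive volumes,
#' \deqn{FD_t = \sqrt{\tfrac{1}{5}R^2\,\mathrm{tr}(\Delta A^\top \Delta A) +
#'   \|\Delta b\|^2}}
#' with \eqn{\Delta A = R_t R_{t-1}^\top - I} and
#' \eqn{\Delta b = b_t - R_t R_{t-1}^\top b_{t-1}} (the relative transform's
#' translation). Rotations are read in degrees (applied as Rx Ry Rz).
#' `FD[1] = 0` by convention.
#'
#' @param motion T x 6 motion trace: columns `trans_x_mm, trans_y_mm,
#'   trans_z_mm, rot_x_deg, rot_y_deg, rot_z_deg` (or any 6 columns in that
#'   order).
#' @param head_radius_mm Ball radius, default 80 mm.
#' @return Numeric vector of length T (mm).
#' @export
framewise_displacement <- function(motion, head_radius_mm = 80) {
  m <- as_motion_matrix(motion)
  tt <- nrow(m)
  if (tt < 2) abort("need at least 2 timepoints.")
  fd <- numeric(tt)
  r_prev <- rot_matrix(m[1, 4:6])
  b_prev <- m[1, 1:3]
  for (t in 2:tt) {
    r_cur <- rot_matrix(m[t, 4:6])
    b_cur <- m[t, 1:3]
    dr <- r_cur %*% t(r_prev)
    da <- dr - diag(3)
    db <- b_cur - as.vector(dr %*% b_prev)
    fd[t] <- sqrt(head_radius_mm^2 / 5 * sum(da^2) + sum(db^2))
    r_prev <- r_cur
    b_prev <- b_cur
  }
  fd
}

#' Friston 24-parameter motion design
#'
#' The six rigid-body parameters, their one-volume backshift (first row zero),
#' and the squares of both sets: a T x 24 design for nuisance regression.
#'
#' @inheritParams framewise_displacement
#' @return T x 24 numeric matrix.
#' @export
friston24 <- function(motion) {
  m <- as_motion_matrix(motion)
  if (nrow(m) < 2) abort("need at least 2 timepoints.")
  lag <- rbind(0, m[-nrow(m), , drop = FALSE])
  out <- cbind(m, lag, m^2, lag^2)
  colnames(out) <- c(paste0("p", 1:6), paste0("p", 1:6, "_lag"),
                     paste0("p", 1:6, "_sq"), paste0("p", 1:6, "_lag_sq"))
  out
}

#' Motion-based subject exclusion
#'
#' A subject is excluded if (1) any translation exceeds `max_trans_mm` in
#' absolute value, or (2) any rotation exceeds `max_rot_deg`, or (3) their
#' mean framewise displacement exceeds the group mean plus `fd_sd_mult`
#' standard deviations of mean FD. The FD rule's group statistics are computed
#' within each diagnostic group over the subjects passing the first two rules
#' (subjects already excluded by gross motion do not contaminate them).
#'
#' @param motion_tbl Tibble with columns `subject_id`, `group`, and a
#'   list-column `motion` of T x 6 traces.
#' @param max_trans_mm,max_rot_deg Hard thresholds (defaults 2.5).
#' @param fd_sd_mult Multiplier on the group SD of mean FD (default 2).
#' @param head_radius_mm Passed to [framewise_displacement()].
#' @return QC report tibble: per subject `included`, `max_translation_mm`,
#'   `max_rotation_deg`, `mean_fd`, `fd_limit`, `reason` (NA when included).
#' @export
motion_exclusion <- function(motion_tbl, max_trans_mm = 2.5, max_rot_deg = 2.5,
                             fd_sd_mult = 2, head_radius_mm = 80) {
  stopifnot(all(c("subject_id", "group", "motion") %in% names(motion_tbl)))
  per <- purrr::map(motion_tbl$motion, function(mo) {
    m <- as_motion_matrix(mo)
    tibble(
      max_translation_mm = max(abs(m[, 1:3])),
      max_rotation_deg = max(abs(m[, 4:6])),
      mean_fd = mean(framewise_displacement(m, head_radius_mm))
    )
  })
  rep_tbl <- dplyr::bind_cols(
    motion_tbl[, c("subject_id", "group")],
    dplyr::bind_rows(per)
  )
  rep_tbl$gross_fail <- rep_tbl$max_translation_mm > max_trans_mm |
    rep_tbl$max_rotation_deg > max_rot_deg
  rep_tbl <- rep_tbl |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(
      fd_limit = {
        ok <- !.data$gross_fail
        if (!any(ok)) abort("a group has no subjects passing the gross-motion rules.")
        mean(.data$mean_fd[ok]) + fd_sd_mult * sd(.data$mean_fd[ok])
      }
    ) |>
    dplyr::ungroup()
  rep_tbl$fd_fail <- !rep_tbl$gross_fail & !is.na(rep_tbl$fd_limit) &
    rep_tbl$mean_fd > rep_tbl$fd_limit
  rep_tbl |>
    dplyr::mutate(
      included = !.data$gross_fail & !.data$fd_fail,
      reason = dplyr::case_when(
        .data$max_translation_mm > max_trans_mm &
          .data$max_rotation_deg > max_rot_deg ~ "translation,rotation",
        .data$max_translation_mm > max_trans_mm ~ "translation",
        .data$max_rotation_deg > max_rot_deg ~ "rotation",
        .data$fd_fail ~ "mean_fd",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::select("subject_id", "group", "included", "max_translation_mm",
                  "max_rotation_deg", "mean_fd", "fd_limit", "reason")
}
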