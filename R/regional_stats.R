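# Regional (per-segment) inFAT distribution: relative inFAT percentage and
# regional volume percentage.

#' Relative inFAT percentage per segment
#'
#' Fat volume in each segment divided by the total inFAT volume in the LA
#' wall, as a percentage. When the total inFAT volume is zero all values are
#' reported missing (with a warning), never a division error.
#'
#' @param classes `fat_classes` array from [classify_fat()].
#' @param labels voxel segment labels from [label_wall_voxels()].
#' @param by_class also return per-class (dense/admixture) percentages.
#' @return data.frame with `label`, `name`, `infat_ml`, `rel_infat_pct` (and
#'   optional per-class columns).
#' @export
relative_infat_percentage <- function(classes, labels, by_class = TRUE) {
  vv <- attr(classes, "voxel_volume_ml")
  nm <- la_segment_names()
  vol_of <- function(sel) vapply(nm$label, function(l)
    sum(sel & labels == l) * vv, numeric(1))
  v_dense <- vol_of(classes == 1L)
  v_admix <- vol_of(classes == 2L)
  v_fat <- v_dense + v_admix
  tot <- sum(v_fat)
  if (tot > 0) {
    pct <- 100 * v_fat / tot
  } else {
    warning("total inFAT volume is zero; relative percentages undefined")
    pct <- rep(NA_real_, nrow(nm))
  }
  out <- data.frame(label = nm$label, name = nm$name,
                    infat_ml = v_fat, rel_infat_pct = pct)
  if (by_class) {
    out$dense_ml <- v_dense
    out$admix_ml <- v_admix
    out$rel_dense_pct <- if (sum(v_dense) > 0) 100 * v_dense / sum(v_dense) else NA_real_
    out$rel_admix_pct <- if (sum(v_admix) > 0) 100 * v_admix / sum(v_admix) else NA_real_
  }
  out
}

#' Regional volume percentage per segment
#'
#' Wall volume of each segment divided by the total segmented wall volume,
#' as a percentage.
#'
#' @param labels voxel segment labels from [label_wall_voxels()].
#' @param wall the `wall_mask`.
#' @return data.frame with `label`, `name`, `wall_ml`, `regional_vol_pct`.
#' @export
regional_volume_percentage <- function(labels, wall) {
  if (!any(wall$mask)) stop("empty wall mask")
  vv <- wall$voxel_volume_ml
  nm <- la_segment_names()
  v_wall <- vapply(nm$label, function(l) sum(labels == l) * vv, numeric(1))
  zero <- v_wall == 0
  if (any(zero))
    message("segments with zero wall volume: ",
            paste(nm$label[zero], collapse = ", "))
  data.frame(label = nm$label, name = nm$name, wall_ml = v_wall,
             regional_vol_pct = 100 * v_wall / sum(v_wall))
}

#' Full per-segment regional distribution table
#'
#' Joins [relative_infat_percentage()] and [regional_volume_percentage()]
#' into the 19-row per-patient regional report.
#'
#' @inheritParams relative_infat_percentage
#' @inheritParams regional_volume_percentage
#' @return 19-row data.frame: label, name, infat_ml, rel_infat_pct, wall_ml,
#'   regional_vol_pct (+ per-class extras).
#' @export
regional_distribution <- function(classes, labels, wall) {
  fat <- relative_infat_percentage(classes, labels)
  vol <- regional_volume_percentage(labels, wall)
  cbind(fat[c("label", "name", "infat_ml", "rel_infat_pct")],
        vol[c("wall_ml", "regional_vol_pct")],
        fat[c("dense_ml", "admix_ml", "rel_dense_pct", "rel_admix_pct")])
}
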