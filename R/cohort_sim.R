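# Synthetic cohort generator: per-patient metric tables with group-level
# location shifts emulating a three-arm AF imaging study.

#' Default cohort effect specification
#'
#' Per-metric, per-group sampling distributions for a three-arm cohort
#' (control / paroxysmal AF / persistent AF). Volumes are log-normal
#' parameterised by median and interquartile range; radiodensities and
#' clinical covariates are Gaussian. Values encode the group conditions of a
#' cohort of 80 patients (30/30/20) with persistent AF showing the highest
#' fat burden and controls the lowest, controls having lower BMI.
#'
#' @return named list: each metric maps to a list with `dist`
#'   (`"lognormal"`/`"normal"`) and per-group parameters.
#' @export
default_effect_spec <- function() {
  ln <- function(med, iqr) list(dist = "lognormal", median = med, iqr = iqr)
  nr <- function(mean, sd) list(dist = "normal", mean = mean, sd = sd)
  g <- function(ctrl, parox, pers) list(control = ctrl, paroxysmal = parox,
                                        persistent = pers)
  list(
    infat_ml = ln(g(0.275, 0.415, 0.460),
                  g(c(0.198, 0.375), c(0.252, 0.593), c(0.350, 1.045))),
    dense_ml = ln(g(0.050, 0.130, 0.195),
                  g(c(0.028, 0.118), c(0.090, 0.215), c(0.110, 0.397))),
    admix_ml = ln(g(0.210, 0.280, 0.335),
                  g(c(0.165, 0.290), c(0.150, 0.432), c(0.233, 0.505))),
    infat_hu = nr(g(-34.9, -38.6, -43.1), g(8.4, 8.7, 7.6)),
    dense_hu = nr(g(-73.7, -76.3, -78.7), g(5.7, 8.6, 4.3)),
    admix_hu = nr(g(-23.0, -23.2, -23.7), g(2.1, 0.8, 0.9)),
    la_vol_ml = nr(g(89, 106, 102), g(22, 21, 14)),
    lawt_mm = nr(g(1.13, 1.25, 1.33), g(0.21, 0.22, 0.20)),
    wall_vol_ml = nr(g(9.7, 11.3, 11.9), g(2.7, 4.6, 4.3)),
    bmi = nr(g(24.8, 26.7, 27.8), g(3.3, 3.9, 3.9)),
    age = nr(g(62.7, 64.9, 64.1), g(9.0, 10.2, 10.4)),
    male_frac = list(dist = "binary", p = g(0.65, 0.50, 0.567)))
}

#' Null cohort effect specification
#'
#' All three groups share the control-group distributions: used for type-I
#' error calibration of the statistics stage.
#'
#' @return an effect spec as in [default_effect_spec()].
#' @export
null_effect_spec <- function() {
  spec <- default_effect_spec()
  lapply(spec, function(m) {
    for (fld in intersect(c("median", "iqr", "mean", "sd", "p"), names(m)))
      m[[fld]] <- lapply(m[[fld]], function(...) m[[fld]]$control)
    m
  })
}

# log-normal (meanlog, sdlog) from median and IQR
lnorm_params <- function(med, iqr) {
  sdlog <- log(iqr[2] / iqr[1]) / (2 * qnorm(0.75))
  list(meanlog = log(med), sdlog = sdlog)
}

#' Generate a synthetic cohort table
#'
#' Per-patient metrics drawn independently from per-group distributions; the
#' normalised metrics are computed from the drawn volumes. Deterministic
#' given the seed.
#'
#' @param n_per_group named counts, e.g. `c(paroxysmal = 30, persistent = 30,
#'   control = 20)`.
#' @param effect_spec per-group distributions, see [default_effect_spec()].
#' @param seed integer seed.
#' @return data.frame of class `cohort_table`: patient_id, group (factor
#'   control/paroxysmal/persistent), sex, age, bmi, and the metric columns.
#' @export
make_cohort <- function(n_per_group = c(paroxysmal = 30, persistent = 30,
                                        control = 20),
                        effect_spec = default_effect_spec(),
                        seed = 1L) {
  if (any(n_per_group <= 0)) stop("group sizes must be positive")
  groups <- names(n_per_group)
  if (!all(groups %in% c("control", "paroxysmal", "persistent")))
    stop("group labels must be control/paroxysmal/persistent")
  set.seed(as.integer(seed))
  rows <- lapply(groups, function(gr) {
    n <- n_per_group[[gr]]
    draw <- function(m) {
      switch(m$dist,
        lognormal = {
          p <- lnorm_params(m$median[[gr]], m$iqr[[gr]])
          rlnorm(n, p$meanlog, p$sdlog)
        },
        normal = rnorm(n, m$mean[[gr]], m$sd[[gr]]),
        binary = rbinom(n, 1, m$p[[gr]]))
    }
    vals <- lapply(effect_spec, draw)
    df <- data.frame(group = gr,
                     sex = ifelse(vals$male_frac == 1, "male", "female"),
                     age = vals$age, bmi = vals$bmi)
    for (nm in setdiff(names(vals), c("male_frac", "age", "bmi")))
      df[[nm]] <- vals[[nm]]
    df
  })
  out <- do.call(rbind, rows)
  out$patient_id <- sprintf("P%03d", seq_len(nrow(out)))
  out$group <- factor(out$group, levels = c("control", "paroxysmal", "persistent"))
  out$sex <- factor(out$sex, levels = c("female", "male"))
  for (cl in c("infat", "dense", "admix")) {
    out[[paste0(cl, "_lavol_au")]] <- out[[paste0(cl, "_ml")]] / out$la_vol_ml
    out[[paste0(cl, "_wallvol_au")]] <- out[[paste0(cl, "_ml")]] / out$wall_vol_ml
  }
  out <- out[c("patient_id", setdiff(names(out), "patient_id"))]
  class(out) <- c("cohort_table", "data.frame")
  out
}
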