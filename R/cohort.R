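#' Default two-arm longitudinal trajectory anchors
#'
#' Per-arm mean parameter trajectories at days 0/3/6/9 for a simulated
#' GL261-like glioma cohort: a control arm with monotone tumour growth and a
#' treated arm responding to Temozolomide-like chemotherapy. Anchors follow
#' the measured study values where these exist: common baselines of sphere
#' fraction 0.54 (SD 0.05), ball fraction 0.39 (SD 0.06), stick fraction
#' 0.07 (SD 0.02), radius 10.6 um (SD 0.6), stick diffusivity 10.8e-9 m^2/s
#' (SD 4e-9), ADC 0.99e-9 m^2/s, kurtosis 0.85, volume 8 mm^3; a control
#' radius decrease of 9% by day 9 against a treated decrease of 54%
#' (0.46 x baseline); control volumes 8/47/89 mm^3 at days 0/6/9 against
#' treated 8/48/61 mm^3. Remaining anchors are plausible interpolating
#' shapes consistent with the qualitative trends (ball fraction and ADC
#' rising, kurtosis and sphere fraction falling faster under treatment,
#' stick diffusivity dipping then recovering in the treated arm).
#'
#' @return nested list: `trajectories[[arm]][[parameter]]` = mean at each of
#'   days 0, 3, 6, 9; `sds[[parameter]]` = per-timepoint SD.
#' @export
defaultCohortTrajectories <- function() {
  list(
    days = c(0, 3, 6, 9),
    trajectories = list(
      control = list(
        volume  = c(8, 22, 47, 89),
        ADC     = c(0.99e-9, 1.07e-9, 1.14e-9, 1.22e-9),
        K       = c(0.85, 0.83, 0.80, 0.77),
        dStick  = c(10.8e-9, 9.5e-9, 8.5e-9, 7.5e-9),
        fSphere = c(0.54, 0.53, 0.50, 0.47),
        fBall   = c(0.39, 0.40, 0.43, 0.46),
        fStick  = c(0.07, 0.07, 0.07, 0.07),
        R       = c(10.6, 10.9, 10.2, 10.6 * 0.91)
      ),
      treated = list(
        volume  = c(8, 21, 48, 61),
        ADC     = c(0.99e-9, 1.11e-9, 1.28e-9, 1.42e-9),
        K       = c(0.85, 0.80, 0.70, 0.60),
        dStick  = c(10.8e-9, 8.0e-9, 10.0e-9, 12.0e-9),
        fSphere = c(0.54, 0.47, 0.31, 0.17),
        fBall   = c(0.39, 0.46, 0.62, 0.76),
        fStick  = c(0.07, 0.07, 0.07, 0.07),
        R       = c(10.6, 8.5, 6.5, 10.6 * 0.46)
      )
    ),
    sds = list(
      volume = c(3, 5, 11, 22), ADC = rep(0.06e-9, 4), K = rep(0.03, 4),
      dStick = rep(4e-9, 4), fSphere = rep(0.05, 4), fBall = rep(0.06, 4),
      fStick = rep(0.02, 4), R = rep(0.6, 4)
    )
  )
}

#' Specify a synthetic two-arm longitudinal cohort
#'
#' @param nPerArm subjects per arm (default 12).
#' @param days imaging timepoints (days).
#' @param trajectories,sds trajectory anchors as produced by
#'   [defaultCohortTrajectories()] (means per arm/parameter/timepoint and
#'   SDs per parameter/timepoint).
#' @param snr b0 signal-to-noise ratio for optional voxel-level synthesis.
#' @param voxelsPerTumour voxels per synthetic tumour when DWI data are
#'   requested.
#' @param seed integer seed.
#' @return a `CohortSpec` list (class "CohortSpec").
#' @export
cohortSpec <- function(nPerArm = 12L, days = c(0, 3, 6, 9),
                       trajectories = NULL, sds = NULL,
                       snr = 50, voxelsPerTumour = 20L, seed = 1L) {
  def <- defaultCohortTrajectories()
  if (is.null(trajectories)) trajectories <- def$trajectories
  if (is.null(sds)) sds <- def$sds
  for (arm in names(trajectories))
    for (p in names(trajectories[[arm]]))
      if (length(trajectories[[arm]][[p]]) != length(days))
        stop("trajectory for ", arm, "/", p, " must give a mean per timepoint",
             call. = FALSE)
  if (any(unlist(sds) < 0)) stop("SDs must be non-negative", call. = FALSE)
  structure(list(nPerArm = as.integer(nPerArm), days = days,
                 trajectories = trajectories, sds = sds, snr = snr,
                 voxelsPerTumour = as.integer(voxelsPerTumour),
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws per-subject per-timepoint parameter means from normal distributions
#' around the arm trajectory anchors (truncated to valid ranges; fractions
#' renormalised to sum to one) and returns them as a long-format cohort
#' table. When `withDwi = TRUE`, a set of voxel-level diffusion-weighted
#' signals is also synthesised per subject and timepoint from the subject's
#' VERDICT parameters under the given scheme and SNR.
#'
#' @param spec a `CohortSpec` from [cohortSpec()].
#' @param withDwi also synthesise voxel-level DWI signal sets (slower).
#' @param scheme scheme used when `withDwi = TRUE` (default mouse protocol).
#' @return list with `table` (data.frame: subject, arm, day, parameter,
#'   value) and, if requested, `dwi` (nested list of per-subject,
#'   per-timepoint normalised signal matrices with rows = voxels).
#' @examples
#' coh <- generateCohort(cohortSpec(nPerArm = 4, seed = 7))
#' head(coh$table)
#' @export
generateCohort <- function(spec, withDwi = FALSE, scheme = NULL) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  arms <- names(spec$trajectories)
  params <- names(spec$trajectories[[1]])
  rows <- list()
  subjParams <- list()
  for (arm in arms) {
    for (s in seq_len(spec$nPerArm)) {
      id <- sprintf("%s%02d", substr(arm, 1, 1), s)
      for (ti in seq_along(spec$days)) {
        vals <- vapply(params, function(p) {
          stats::rnorm(1, spec$trajectories[[arm]][[p]][ti], spec$sds[[p]][ti])
        }, numeric(1))
        ## truncation to physical ranges
        for (p in intersect(c("fSphere", "fBall", "fStick"), params))
          vals[p] <- min(max(vals[p], 0.005), 0.98)
        frac <- intersect(c("fSphere", "fBall", "fStick"), params)
        if (length(frac) == 3L) vals[frac] <- vals[frac] / sum(vals[frac])
        if ("R" %in% params) vals["R"] <- min(max(vals["R"], 0.2), 19.9)
        if ("dStick" %in% params) vals["dStick"] <- max(vals["dStick"], 3.05e-9)
        if ("volume" %in% params) vals["volume"] <- max(vals["volume"], 0.5)
        if ("K" %in% params) vals["K"] <- max(vals["K"], 0)
        if ("ADC" %in% params) vals["ADC"] <- max(vals["ADC"], 1e-11)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = id, arm = arm, day = spec$days[ti],
          parameter = params, value = unname(vals))
        subjParams[[id]][[as.character(spec$days[ti])]] <- as.list(vals)
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  out <- list(table = tab, spec = spec)
  if (withDwi) {
    if (is.null(scheme)) scheme <- buildMouseProtocol()
    dwb0 <- !isB0(scheme)
    out$dwi <- lapply(subjParams, function(tp) {
      lapply(tp, function(v) {
        pars <- list(fSphere = v$fSphere, fBall = v$fBall, fStick = v$fStick,
                     R = v$R, dStick = v$dStick, theta = 1.0, phi = 0.8,
                     dSphere = 1e-9, dBall = 2e-9)
        clean <- verdictSignal(scheme, pars)[dwb0]
        t(replicate(spec$voxelsPerTumour,
                    addRicianNoise(clean, 1 / spec$snr)))
      })
    })
  }
  out
}
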