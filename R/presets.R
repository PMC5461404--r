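#' Named study presets (best-fit parameter sets per condition)
#'
#' Two-state parameter sets for the measured conditions: wild-type EF-P
#' in normal growth (exchange lifetimes 16/7 ms), ribosomes (30S label),
#' EF-P after chloramphenicol (lifetimes 9/7 ms; the stationary bound
#' fraction 7/16 = 0.4375 follows from the lifetimes), EF-P after
#' rifampin, and the non-binding mutant EF-P K34A. Static presets carry
#' no lifetimes. Only conditions with a ribosome-bound slow state
#' (D_slow = 0.2 um^2/s) have ribosome-zone axial structure.
#'
#' @param name one of "efp", "ribosome", "efp_cam", "efp_rif", "k34a".
#' @param nCells cells in the study (default 120).
#' @param cellLengthRange tip-to-tip length range, um.
#' @param trajectoriesPerCell mean trajectories recorded per cell.
#' @return list of class "StudyPreset" with the model, cell statistics
#'   and a `ribosomeZones` flag.
#' @export
studyPreset <- function(name = c("efp", "ribosome", "efp_cam", "efp_rif",
                                 "k34a"),
                        nCells = 120L, cellLengthRange = c(3.2, 8.4),
                        trajectoriesPerCell = 15L) {
  name <- match.arg(name)
  model <- switch(name,
    efp = TwoStateModel(Dslow = 0.2, Dfast = 4.3, tauFree = 16,
                        tauBound = 7, sigmaSlow = 50, sigmaFast = 75),
    ribosome = TwoStateModel(Dslow = 0.2, Dfast = 0.8, fSlow = 0.65,
                             sigmaSlow = 40, sigmaFast = 75),
    efp_cam = TwoStateModel(Dslow = 0.2, Dfast = 1.2, tauFree = 9,
                            tauBound = 7, sigmaSlow = 50, sigmaFast = 90),
    efp_rif = TwoStateModel(Dslow = 4.6, Dfast = 8, fSlow = 0.55,
                            sigmaSlow = 75, sigmaFast = 150),
    k34a = TwoStateModel(Dslow = 3.2, Dfast = 9.7, fSlow = 0.65,
                         sigmaSlow = 50, sigmaFast = 90))
  structure(list(name = name, model = model, nCells = as.integer(nCells),
                 cellLengthRange = cellLengthRange,
                 trajectoriesPerCell = as.integer(trajectoriesPerCell),
                 ribosomeZones = model@Dslow <= 0.25),
            class = "StudyPreset")
}

# three-zone axial weighting for ribosome-bound molecules: two polar
# zones plus mid-cell, emulating nucleoid-excluded ribosome-rich regions
.sampleBoundAxial <- function(n, L, centers = c(-0.3, 0, 0.3),
                              weights = c(0.4, 0.2, 0.4), sd = 0.07) {
  zone <- sample.int(3L, n, replace = TRUE, prob = weights)
  x <- stats::rnorm(n, mean = centers[zone] * L, sd = sd * L)
  # reject outside the cell body, redraw
  bad <- abs(x) > L / 2 * 0.98
  while (any(bad)) {
    zone <- sample.int(3L, sum(bad), replace = TRUE, prob = weights)
    x[bad] <- stats::rnorm(sum(bad), centers[zone] * L, sd * L)
    bad <- abs(x) > L / 2 * 0.98
  }
  x
}

#' Generate a full synthetic study bundle
#'
#' Emits cells (lengths drawn log-normally within the preset range,
#' diameter 0.9 um), and per cell a set of trajectories simulated from
#' the preset model in that cell's geometry. Trajectory lengths follow a
#' geometric law with mean 9 frames (a photobleaching stand-in, capped
#' at 30) so that after the >= 7-frame filter the six-step yield matches
#' the scale of a real study (~860 six-step trajectories for the efp
#' preset defaults). For presets with a ribosome-bound state, initial
#' positions of bound-starting trajectories are drawn from a three-zone
#' axial weighting (two polar + mid-cell), giving the pooled axial
#' distribution the ribosome-like three-peak structure; free-state
#' molecules start uniformly.
#'
#' @param preset a [studyPreset()].
#' @param seed integer master seed.
#' @param diameter cell diameter, um.
#' @return list of class "StudyBundle": `cells` (data.frame cell_id,
#'   length_um, diameter_um), `trajectories` (a [TrajectorySet-class]).
#' @export
generateStudy <- function(preset, seed, diameter = 0.9) {
  stopifnot(inherits(preset, "StudyPreset"))
  model <- preset$model
  withSeed(seed, {
    rng <- preset$cellLengthRange
    lens <- numeric(0)
    while (length(lens) < preset$nCells) {
      cand <- stats::rlnorm(preset$nCells, log(4.3), 0.3)
      lens <- c(lens, cand[cand >= rng[1] & cand <= rng[2]])
    }
    lens <- lens[seq_len(preset$nCells)]
    cells <- data.frame(cell_id = sprintf("cell%03d", seq_len(preset$nCells)),
                        length_um = lens, diameter_um = diameter)
    allRec <- vector("list", preset$nCells)
    trajOffset <- 0L
    for (ci in seq_len(preset$nCells)) {
      nT <- preset$trajectoriesPerCell
      trajLens <- pmin(stats::rgeom(nT, 1 / 9) + 1L, 30L)
      cell <- Spherocylinder(lens[ci], diameter)
      cfg <- SimConfig(nFrames = max(trajLens), cell = cell)
      # zone-weighted starts for bound-state molecules
      startState <- if (model@exchange || preset$ribosomeZones)
        stats::rbinom(nT, 1L, model@fSlow) else rep.int(-1L, nT)
      initX <- rep(NA_real_, nT)
      if (preset$ribosomeZones) {
        nb <- sum(startState == 1L)
        if (nb > 0)
          initX[startState == 1L] <- .sampleBoundAxial(nb, lens[ci])
      }
      fixedState <- if (model@exchange) NULL else startState
      initState <- if (model@exchange) startState else NULL
      ts <- simulateEnsemble(model, cfg, nT, seed = seed + 7919L * ci,
                             static = !model@exchange,
                             fixedState = fixedState, initX = initX,
                             initState = initState,
                             cellIds = rep(cells$cell_id[ci], nT))
      rec <- ts@records
      # truncate each trajectory to its drawn length
      keep <- rec$frame < trajLens[rec$traj_id]
      rec <- rec[keep, , drop = FALSE]
      rec$traj_id <- rec$traj_id + trajOffset
      trajOffset <- trajOffset + nT
      allRec[[ci]] <- rec
    }
    rec <- do.call(rbind, allRec)
    structure(list(cells = cells,
                   trajectories = new("TrajectorySet", records = rec,
                                      frameInterval = 2)),
              class = "StudyBundle")
  })
}
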