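# Orchestration of the full in-silico plate experiment: simulated
# acquisition -> (optional render/track) -> MSD -> classification -> DA
# filter -> tau-reference summaries -> stratified statistics, with a
# machine-readable manifest.

#' Plate traversal order
#'
#' The stage visits the 96-well plate in a fixed number of translation
#' steps, imaging one group of wells (one well per objective) per step;
#' with 12 objectives, 8 steps cover all 96 wells.
#'
#' @param layout a \linkS4class{PlateLayout}
#' @param nSteps number of translation steps, default 8
#' @return list of character vectors: well ids visited at each step
#' @export
wellVisitOrder <- function(layout, nSteps = 8) {
  wells <- names(layout@wells)
  split(wells, rep(seq_len(nSteps), length.out = length(wells)))
}

#' Build a run configuration
#'
#' Collects every tunable of the in-silico experiment. Defaults follow
#' the acquisition conditions: 33 fps for 60 s, ~3 beads per FOV,
#' reference lag 1 s, DA posterior threshold 0.5, 8 traversal steps.
#'
#' @param layout a \linkS4class{PlateLayout}
#' @param conditionParams named list of \linkS4class{MotionModelParams}
#' @param spec a \linkS4class{FrameSpec}
#' @param seed integer seed for the whole run
#' @param control control condition label (comparisons are each
#'   condition vs control)
#' @param beadsPerFov mean beads per field of view
#' @param tauRef reference lag (s)
#' @param daThreshold DA posterior retention threshold
#' @param bonferroniFamily Bonferroni family size; NULL = number of
#'   comparisons
#' @param nSteps plate traversal steps
#' @param render render each FOV to video and re-track it instead of
#'   using the generated positions directly (slow; exercises the full
#'   imaging path)
#' @return a RunConfig list
#' @export
runConfig <- function(layout, conditionParams, spec = frameSpec(),
                      seed = 1L, control = NULL, beadsPerFov = 3,
                      tauRef = 1, daThreshold = 0.5, bonferroniFamily = NULL,
                      nSteps = 8, render = FALSE) {
  conds <- unique(layout@wells)
  missing <- setdiff(conds, names(conditionParams))
  if (length(missing))
    stop("unparameterized condition(s): ", paste(missing, collapse = ", "))
  if (is.null(control)) control <- conds[1]
  structure(list(layout = layout, conditionParams = conditionParams,
                 spec = spec, seed = as.integer(seed), control = control,
                 beadsPerFov = beadsPerFov, tauRef = tauRef,
                 daThreshold = daThreshold,
                 bonferroniFamily = bonferroniFamily, nSteps = nSteps,
                 render = render),
            class = "RunConfig")
}

#' Run the full in-silico experiment
#'
#' Deterministic given the config seed. Stages: simulate the plate
#' (trajectories per FOV, visiting wells in the configured traversal
#' order), optionally render + re-track each FOV, compute per-bead MSD
#' curves, classify each trajectory, retain DA beads, summarize each
#' condition at the reference lag, and compare every condition to the
#' control with van Elteren's test (strata = plate/objective pairing)
#' with Bonferroni correction. When \code{outDir} is given, each stage's
#' artifact is written (trajectories.csv, msd.csv, posteriors.csv,
#' summary.csv, stats.csv, sigtable.csv, manifest.json).
#'
#' @param config a RunConfig from \code{\link{runConfig}}
#' @param outDir optional output directory
#' @param verbose log stage progress to stderr
#' @return list: trajectories, msd, posteriors, retained, modelFrequency,
#'   summary, stats, sigtable, manifest
#' @export
runExperiment <- function(config, outDir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  log <- function(...) if (verbose) message("[beadRheo] ", sprintf(...))
  set.seed(config$seed)
  order <- wellVisitOrder(config$layout, config$nSteps)

  log("simulating plate (%d wells, %d FOV/well)",
      length(config$layout@wells), config$layout@fovsPerWell)
  traj <- simulatePlate(config$layout, config$conditionParams, config$spec,
                        beadsPerFov = config$beadsPerFov, seed = NULL)
  if (!nrow(traj)) stop("stage simulate: no beads generated")

  if (config$render) {
    log("rendering and re-tracking each FOV")
    traj <- .retrackPlate(traj, config$spec)
    if (!nrow(traj)) stop("stage track: no trajectories recovered")
  }

  log("computing MSD curves for %d beads", length(unique(traj$bead_id)))
  msd <- computeMsdAll(traj)

  log("classifying trajectories")
  post <- classifyTrajectories(msd)
  flt <- filterDa(post, config$daThreshold)
  retained <- flt$retained
  if (!nrow(retained)) stop("stage filter: no DA trajectories retained")
  msdDa <- msd[msd$bead_id %in% retained$bead_id, ]

  log("summarizing at tau = %g s", config$tauRef)
  summary <- summarizeAtTau(msdDa, config$tauRef, by = "condition")

  vals <- msdAtTau(msdDa, config$tauRef)
  stats <- tryCatch(
    compareToControl(vals$msd_um2, vals$condition, vals$stratum,
                     control = config$control,
                     family = config$bonferroniFamily,
                     assay = "MSD"),
    error = function(e) stop("stage stats: ", conditionMessage(e),
                             call. = FALSE))
  sig <- significanceTable(stats)

  manifest <- list(
    package = "beadRheo",
    version = as.character(utils::packageVersion("beadRheo")),
    seed = config$seed, control = config$control,
    tauRef = config$tauRef, daThreshold = config$daThreshold,
    beadsPerFov = config$beadsPerFov, render = config$render,
    nSteps = config$nSteps, traversal = order,
    nBeads = length(unique(traj$bead_id)), nBeadsRetained = nrow(retained),
    fps = 1 / config$spec@dt, durationS = config$spec@nFrames * config$spec@dt,
    conditions = unique(config$layout@wells))

  res <- list(trajectories = traj, msd = msd, posteriors = post,
              retained = retained, modelFrequency = flt$modelFrequency,
              summary = summary, stats = stats, sigtable = sig,
              manifest = manifest)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTrajectories(traj, file.path(outDir, "trajectories.csv"))
    utils::write.csv(msd, file.path(outDir, "msd.csv"), row.names = FALSE)
    utils::write.csv(post, file.path(outDir, "posteriors.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(outDir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(stats, file.path(outDir, "stats.csv"), row.names = FALSE)
    utils::write.csv(sig, file.path(outDir, "sigtable.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

# render each FOV's beads to video, track, and re-tag provenance;
# bead ids are re-assigned per FOV by the tracker
.retrackPlate <- function(traj, spec) {
  keys <- interaction(traj$well, traj$fov, drop = TRUE)
  out <- list()
  counter <- 0L
  for (k in levels(keys)) {
    sub <- traj[keys == k, ]
    video <- renderVideo(sub, spec, seed = NULL)
    tr <- trackVideo(video)
    if (!nrow(tr)) next
    tr$bead_id <- tr$bead_id + counter
    counter <- counter + max(tr$bead_id)
    tr$well <- sub$well[1]; tr$fov <- sub$fov[1]
    tr$condition <- sub$condition[1]; tr$stratum <- sub$stratum[1]
    out[[length(out) + 1L]] <- tr
  }
  if (!length(out)) return(traj[0, ])
  do.call(rbind, out)
}
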