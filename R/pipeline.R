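## End-to-end orchestration: generate the stimulus battery, simulate both cell
## types under control/TTX/knockout conditions, run the analysis stack, and
## validate the resulting bundle.

#' Build a run configuration
#'
#' A fully serializable description of one pipeline run: stimulus geometry,
#' circuit-parameter overrides, the battery switches, and the master seed from
#' which every stage derives its own child seed (see [childSeed()]), so stages
#' can be rerun in isolation.
#'
#' @param seed master seed.
#' @param circuit named list of [circuitParams()] overrides.
#' @param stimulus list with `fieldSize`, `pixelPitch`, `frameRate`.
#' @param spots list: `enabled`, `radii` (um), `nPeriods`.
#' @param split list: `enabled` (even, biased and linear-diagnostic runs).
#' @param texture list: `enabled`, `conditions` (subset of
#'   `control`, `ttx`, `ko`).
#' @param bars list: `enabled`, `heights`, `speeds`, `conditions`.
#' @param noise list: `enabled`, `duration_s` (temporal-filter recovery).
#' @return a list of class `omsRunConfig`.
#' @export
runConfig <- function(seed = 1L,
                      circuit = list(),
                      stimulus = list(fieldSize = 800, pixelPitch = 4,
                                      frameRate = 30),
                      spots = list(enabled = TRUE,
                                   radii = c(25, 50, 100, 150, 225, 300),
                                   nPeriods = 1),
                      split = list(enabled = TRUE),
                      texture = list(enabled = TRUE,
                                     conditions = c("control", "ttx", "ko")),
                      bars = list(enabled = TRUE, heights = c(200, 600),
                                  speeds = 400, conditions = c("control", "ttx")),
                      noise = list(enabled = FALSE, duration_s = 120)) {
  cfg <- list(seed = as.integer(seed), circuit = circuit, stimulus = stimulus,
              spots = spots, split = split, texture = texture, bars = bars,
              noise = noise)
  class(cfg) <- c("omsRunConfig", "list")
  cfg
}

#' @rdname runConfig
#' @param file YAML path.
#' @export
saveConfig <- function(cfg, file) {
  yaml::write_yaml(unclass(cfg), file)
  invisible(file)
}

#' @rdname runConfig
#' @export
loadConfig <- function(file) do.call(runConfig, yaml::read_yaml(file))

#' Derive a stage seed from the master seed
#'
#' Deterministic fan-out: `(seed * 1009 + hash(stage)) mod (2^31 - 1)`, where
#' `hash` is a small polynomial over the stage name's bytes.  Stages can
#' therefore be rerun in isolation with reproducible randomness.
#'
#' @param seed master seed.
#' @param stage stage name.
#' @return integer child seed.
#' @export
childSeed <- function(seed, stage) {
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 1000003
  as.integer((as.numeric(seed) * 1009 + h) %% (2^31 - 1))
}

.condParams <- function(cfg, condition, stage) {
  ov <- cfg$circuit
  ov$seed <- childSeed(cfg$seed, stage)
  if (condition == "ttx") ov$ttx <- TRUE
  if (condition == "ko") ov$vglut3Ko <- TRUE
  do.call(circuitParams, ov)
}

#' Generate the synthetic experiment battery
#'
#' Simulates every enabled stimulus x cell x condition combination of the
#' configuration and writes one RDS trace bundle per combination under
#' `outDir/traces/<cell>/<stimulus>/<condition>.rds`, plus `manifest.csv`
#' (cell_id, cell_type, stimulus, condition, seed, path).  Partial output is
#' removed if any stage fails.
#'
#' @param cfg a [runConfig()].
#' @param outDir output directory (created).
#' @return the manifest data.frame, invisibly.
#' @export
generateExperiment <- function(cfg, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  created <- file.path(outDir, c("traces", "manifest.csv"))
  rows <- list()
  stimGeom <- cfg$stimulus

  emit <- function(cell, cellType, stimulus, condition, sim) {
    dir <- file.path(outDir, "traces", cell, stimulus)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(dir, paste0(condition, ".rds"))
    writeTrace(sim, path)
    rows[[length(rows) + 1L]] <<- data.frame(
      cell_id = cell, cell_type = cellType, stimulus = stimulus,
      condition = condition,
      seed = childSeed(cfg$seed, paste(cell, stimulus, sep = "/")),
      path = file.path("traces", cell, stimulus, paste0(condition, ".rds")))
  }

  ok <- FALSE
  on.exit(if (!ok) unlink(created, recursive = TRUE))

  geomArgs <- list(fieldSize = stimGeom$fieldSize,
                   pixelPitch = stimGeom$pixelPitch,
                   frameRate = stimGeom$frameRate)
  if (isTRUE(cfg$spots$enabled)) {
    clips <- do.call(makeSpotSeries,
                     c(list(radii = cfg$spots$radii,
                            nPeriods = cfg$spots$nPeriods %||% 1,
                            orderSeed = childSeed(cfg$seed, "spot_order")),
                       geomArgs))
    pars <- .condParams(cfg, "control", "vg3/spots")
    for (cl in clips[-length(clips)])   # drop the repeated stability clip
      emit("vg3_01", "VG3-AC", paste0("spot_r", cl@params$radius), "control",
           simulateVG3(cl, pars))
  }
  if (isTRUE(cfg$split$enabled)) {
    pars <- .condParams(cfg, "control", "vg3/split")
    even <- do.call(makeSplitField, c(list(biasFraction = 0.5), geomArgs))
    biased <- do.call(makeSplitField, c(list(biasFraction = 0.75), geomArgs))
    emit("vg3_01", "VG3-AC", "split_even", "control", simulateVG3(even, pars))
    emit("vg3_01", "VG3-AC", "split_biased", "control",
         simulateVG3(biased, pars))
    lin <- .condParams(cfg, "control", "vg3/split")
    lin@rectifySubunits <- FALSE
    emit("vg3_01", "VG3-AC", "split_even", "linear", simulateVG3(even, lin))
  }
  if (isTRUE(cfg$texture$enabled)) {
    segs <- c("global", "diff_center", "diff_surround")
    clips <- lapply(segs, function(s)
      do.call(makeTextureMotion, c(list(segment = s), geomArgs)))
    names(clips) <- segs
    for (cond in intersect(cfg$texture$conditions, c("control", "ttx"))) {
      pars <- .condParams(cfg, cond, "vg3/texture")
      for (s in segs)
        emit("vg3_01", "VG3-AC", paste0("texture_", s), cond,
             simulateVG3(clips[[s]], pars))
    }
    for (cond in intersect(cfg$texture$conditions, c("control", "ko"))) {
      pars <- .condParams(cfg, cond, "w3/texture")
      for (s in segs)
        emit("w3_01", "W3-RGC", paste0("texture_", s), cond,
             simulateW3(clips[[s]], pars))
    }
  }
  if (isTRUE(cfg$bars$enabled)) {
    for (cond in cfg$bars$conditions) {
      pars <- .condParams(cfg, cond, "vg3/bars")
      for (h in cfg$bars$heights) for (sp in cfg$bars$speeds) {
        cl <- do.call(makeMovingBar,
                      c(list(height = h, speed = sp), geomArgs))
        emit("vg3_01", "VG3-AC", sprintf("bar_h%d_s%d", h, sp), cond,
             simulateVG3(cl, pars))
      }
    }
  }
  if (isTRUE(cfg$noise$enabled)) {
    cl <- makeWhiteNoise(duration_s = cfg$noise$duration_s,
                         seed = childSeed(cfg$seed, "noise_stim"))
    pars <- .condParams(cfg, "control", "vg3/noise")
    emit("vg3_01", "VG3-AC", "white_noise", "control", simulateVG3(cl, pars))
    writeClip(cl, file.path(outDir, "traces", "white_noise_stim.rds"))
  }

  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  ok <- TRUE
  invisible(manifest)
}

.readSim <- function(outDir, manifest, cell, stimulus, condition) {
  row <- manifest[manifest$cell_id == cell & manifest$stimulus == stimulus &
                    manifest$condition == condition, , drop = FALSE]
  if (nrow(row) == 0) return(NULL)
  readTrace(file.path(outDir, row$path[1]))
}

#' Run the full pipeline
#'
#' [generateExperiment()] followed by the analysis stack; writes tidy CSV
#' result tables (`motion_selectivity.csv`, `harmonics.csv`,
#' `size_tuning.csv`, `area_response_fits.csv`, and `filters.csv` when the
#' noise battery is enabled) plus `run_manifest.csv` with the MD5 checksum of
#' every artifact.  Deterministic given the configuration.
#'
#' @param cfg a [runConfig()].
#' @param outDir output directory.
#' @return list with the result tables, invisibly.
#' @export
runPipeline <- function(cfg, outDir) {
  manifest <- generateExperiment(cfg, outDir)
  res <- list()

  if (isTRUE(cfg$texture$enabled)) {
    ms <- list()
    grab <- function(cell, field, cond) {
      trs <- lapply(c("global", "diff_center", "diff_surround"), function(s)
        .readSim(outDir, manifest, cell, paste0("texture_", s), cond)[[field]])
      names(trs) <- c("global", "diff_center", "diff_surround")
      if (any(vapply(trs, is.null, logical(1)))) NULL else trs
    }
    for (cond in intersect(cfg$texture$conditions, c("control", "ttx"))) {
      trs <- grab("vg3_01", "voltage", cond)
      if (!is.null(trs)) {
        m <- motionSelectivity(trs)
        m$cell_id <- "vg3_01"; m$condition <- cond
        ms[[length(ms) + 1L]] <- m
      }
    }
    for (cond in intersect(cfg$texture$conditions, c("control", "ko"))) {
      trs <- grab("w3_01", "gExc", cond)
      if (!is.null(trs)) {
        m <- motionSelectivity(trs)
        m$cell_id <- "w3_01"; m$condition <- cond
        ms[[length(ms) + 1L]] <- m
      }
    }
    res$motion_selectivity <- do.call(rbind, ms)
  }

  if (isTRUE(cfg$split$enabled)) {
    hrows <- list()
    for (case in list(c("split_even", "control"), c("split_biased", "control"),
                      c("split_even", "linear"))) {
      sim <- .readSim(outDir, manifest, "vg3_01", case[1], case[2])
      if (is.null(sim)) next
      tr <- sim$epsc
      ev <- events(tr)
      h <- harmonicAmplitudes(tr, fundamentalHz = 2,
                              window = c(ev$start_s[1], ev$end_s[1]))
      hrows[[length(hrows) + 1L]] <- data.frame(
        stimulus = case[1], condition = case[2],
        f1 = h$f1Amplitude, f2 = h$f2Amplitude)
    }
    res$harmonics <- do.call(rbind, hrows)
  }

  if (isTRUE(cfg$bars$enabled)) {
    st <- list()
    for (cond in cfg$bars$conditions) {
      hs <- cfg$bars$heights
      sims <- lapply(hs, function(h)
        .readSim(outDir, manifest, "vg3_01",
                 sprintf("bar_h%d_s%d", h, cfg$bars$speeds[1]), cond))
      if (any(vapply(sims, is.null, logical(1)))) next
      for (field in c("voltage", "gInh")) {
        t <- sizeTuning(lapply(sims, `[[`, field), hs)
        tt <- t$table
        tt$condition <- cond; tt$signal <- field
        tt$suppression_index <- t$suppressionIndex
        st[[length(st) + 1L]] <- tt
      }
    }
    res$size_tuning <- do.call(rbind, st)
  }

  if (isTRUE(cfg$spots$enabled) && length(cfg$spots$radii) >= 5) {
    radii <- sort(cfg$spots$radii)
    sims <- lapply(radii, function(r)
      .readSim(outDir, manifest, "vg3_01", paste0("spot_r", r), "control"))
    if (!any(vapply(sims, is.null, logical(1)))) {
      curve <- measureAreaResponse(lapply(sims, `[[`, "voltage"), radii,
                                   modality = "voltage_mV")
      fits <- lapply(c("on", "off"), function(p) fitDoG(curve, p))
      res$area_response_fits <- do.call(rbind, lapply(seq_along(fits),
        function(i) data.frame(
          polarity = c("on", "off")[i], k_center = fits[[i]]@kCenter,
          sigma_center = fits[[i]]@sigmaCenter,
          k_surround = fits[[i]]@kSurround,
          sigma_surround = fits[[i]]@sigmaSurround,
          diameter_center = rfDiameter(fits[[i]], "center"),
          diameter_surround = rfDiameter(fits[[i]], "surround"),
          rss = fits[[i]]@rss)))
    }
  }

  if (isTRUE(cfg$noise$enabled)) {
    cl <- readClip(file.path(outDir, "traces", "white_noise_stim.rds"))
    sim <- .readSim(outDir, manifest, "vg3_01", "white_noise", "control")
    if (!is.null(sim)) {
      fp <- recoverFilters(cl, sim$voltage)
      met <- filterMetrics(fp)
      res$filters <- data.frame(lag_s = (seq_along(onFilter(fp)) - 1) /
                                  frameRate(fp),
                                on = onFilter(fp), off = offFilter(fp))
      res$filter_metrics <- data.frame(
        pathway = c("on", "off"),
        peak_time_s = met$peakTime_s, biphasic_index = met$biphasicIndex)
    }
  }

  for (nm in names(res))
    utils::write.csv(res[[nm]], file.path(outDir, paste0(nm, ".csv")),
                     row.names = FALSE)
  files <- c(file.path(outDir, manifest$path), file.path(outDir, "manifest.csv"),
             file.path(outDir, paste0(names(res), ".csv")))
  rm <- data.frame(path = sub(paste0("^", outDir, "/?"), "", files),
                   md5 = unname(tools::md5sum(files)))
  utils::write.csv(rm, file.path(outDir, "run_manifest.csv"),
                   row.names = FALSE)
  invisible(res)
}

#' Validate a pipeline results bundle
#'
#' Evaluates the qualitative circuit contracts on a results bundle written by
#' [runPipeline()]: the texture-motion sign pattern (depolarization only for
#' differential center motion; suppression abolished by TTX), F2-dominance of
#' even split-field excitation (and its collapse in the linear diagnostic),
#' size suppression of edge responses (absent under TTX; inhibition
#' non-decreasing), the knockout reduction of W3 excitation confined to
#' differential center motion, and convergence of the receptive-field fits.
#' Missing artifacts are enumerated as failed checks with `value = NA`.
#'
#' @param outDir a directory written by [runPipeline()].
#' @return data.frame with columns `check`, `value`, `pass`.
#' @export
validateRun <- function(outDir) {
  checks <- list()
  add <- function(name, value, pass)
    checks[[length(checks) + 1L]] <<- data.frame(check = name, value = value,
                                                 pass = pass)
  tryRead <- function(f) {
    p <- file.path(outDir, f)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }

  ms <- tryRead("motion_selectivity.csv")
  if (is.null(ms)) add("motion_selectivity_present", NA_real_, FALSE)
  else {
    g <- function(cell, cond, seg)
      ms$amplitude[ms$cell_id == cell & ms$condition == cond &
                     ms$segment == seg][1]
    add("vg3_diff_center_depolarizes", g("vg3_01", "control", "diff_center"),
        isTRUE(g("vg3_01", "control", "diff_center") > 0))
    add("vg3_global_hyperpolarizes", g("vg3_01", "control", "global"),
        isTRUE(g("vg3_01", "control", "global") < 0))
    add("vg3_diff_surround_hyperpolarizes",
        g("vg3_01", "control", "diff_surround"),
        isTRUE(g("vg3_01", "control", "diff_surround") < 0))
    if ("ttx" %in% ms$condition)
      add("ttx_global_depolarizes", g("vg3_01", "ttx", "global"),
          isTRUE(g("vg3_01", "ttx", "global") > 0))
    if ("ko" %in% ms$condition) {
      red <- 1 - g("w3_01", "ko", "diff_center") /
        g("w3_01", "control", "diff_center")
      add("ko_diff_center_reduction", red, isTRUE(red > 0.25))
      chg <- abs(g("w3_01", "ko", "global") /
                   g("w3_01", "control", "global") - 1)
      add("ko_global_unchanged", chg, isTRUE(chg < 0.25))
    }
  }

  h <- tryRead("harmonics.csv")
  if (is.null(h)) add("harmonics_present", NA_real_, FALSE)
  else {
    pick <- function(st, cond) h[h$stimulus == st & h$condition == cond, ]
    ev <- pick("split_even", "control"); bi <- pick("split_biased", "control")
    if (nrow(ev)) add("even_split_f2_dominant", ev$f2 / ev$f1,
                      isTRUE(ev$f2 / ev$f1 >= 3))
    if (nrow(bi)) add("biased_split_f1_dominant", bi$f1 / bi$f2,
                      isTRUE(bi$f1 > bi$f2))
    lin <- pick("split_even", "linear")
    if (nrow(ev) && nrow(lin))
      add("linear_f2_collapse", ev$f2 / lin$f2,
          isTRUE(ev$f2 / lin$f2 >= 10))
  }

  st <- tryRead("size_tuning.csv")
  if (is.null(st)) add("size_tuning_present", NA_real_, FALSE)
  else {
    si <- function(cond, sig)
      st$suppression_index[st$condition == cond & st$signal == sig][1]
    add("size_suppression_control", si("control", "voltage"),
        isTRUE(si("control", "voltage") >= 0.5))
    if ("ttx" %in% st$condition)
      add("size_suppression_abolished_ttx", si("ttx", "voltage"),
          isTRUE(si("ttx", "voltage") <= 0.2))
    amp <- function(hh) st$amplitude[st$condition == "control" &
                                       st$signal == "gInh" &
                                       st$edge == "leading" &
                                       st$height == hh][1]
    hs <- sort(unique(st$height))
    if (length(hs) >= 2)
      add("inhibition_non_decreasing", amp(max(hs)) / amp(min(hs)),
          isTRUE(amp(max(hs)) >= 0.9 * amp(min(hs))))
  }

  fits <- tryRead("area_response_fits.csv")
  if (is.null(fits)) add("area_response_fits_present", NA_real_, FALSE)
  else add("dog_fit_converged", min(fits$sigma_surround - fits$sigma_center),
           isTRUE(all(fits$sigma_surround > fits$sigma_center)))

  do.call(rbind, checks)
}
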