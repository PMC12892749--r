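#' Default pipeline configuration
#'
#' Nested list mirroring the stages. `scenario` drives the synthetic
#' generator; replace it with `input` (paths to an EDF/TSV recording) to
#' run on recorded data. Unknown keys anywhere are rejected by
#' [validate_config].
#'
#' @param seed global seed; per-stage seeds are derived from it
#'   deterministically.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    scenario = list(n_regions = 68L, driver = 1L, n_targets = 5L,
                    coupling_strength = 0.35, delta_gain = 8,
                    duration = 600, rate = 256, sensor_snr = 5),
    preprocess = list(bandpass = c(0.5, 80), notch = c(48, 52),
                      preictal_minutes = NULL, epoch_seconds = 2,
                      common_average = FALSE),
    inverse = list(alpha = "auto", snr = 3, avg_ref = TRUE,
                   source_radius = 0.75),
    psd = list(window_s = 2, overlap = 0.5),
    network = list(order = "auto", max_order = 6L, ridge = 1e-3,
                   densities = c(0.05, 0.5, 0.05), hub_cutoff = 0.95,
                   bands = "delta"),
    si = list(band = "delta", realizations = 200L, t_max = 100, dt = 0.01,
              coupling_gain = 0.5, d0 = 0.1, threshold = 0.5,
              cutoff = 0.95),
    evaluate = NULL,
    input = NULL,
    out_dir = NULL)
}

config_schema <- list(
  seed = NA, out_dir = NA,
  scenario = c("n_regions", "driver", "n_targets", "coupling_strength",
               "delta_gain", "duration", "rate", "sensor_snr"),
  input = c("eeg", "format", "rate", "onset_sample", "lead_field"),
  preprocess = c("bandpass", "notch", "preictal_minutes", "epoch_seconds",
                 "common_average"),
  inverse = c("alpha", "snr", "avg_ref", "source_radius"),
  psd = c("window_s", "overlap"),
  network = c("order", "max_order", "ridge", "densities", "hub_cutoff",
              "bands"),
  si = c("band", "realizations", "t_max", "dt", "coupling_gain", "d0",
         "threshold", "cutoff"),
  evaluate = c("clinical", "metric"))

#' Validate a pipeline configuration
#'
#' Checks the config against the key schema (unknown keys are errors) and
#' the basic value constraints, before any computation or I/O.
#'
#' @param cfg nested configuration list (see [default_config]).
#' @return `cfg`, invisibly, merged over the defaults.
#' @export
validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (blk in names(cfg)) {
    allowed <- config_schema[[blk]]
    if (length(allowed) > 1 || !is.na(allowed[1])) {
      bad <- setdiff(names(cfg[[blk]]), allowed)
      if (length(bad))
        stop("unknown keys in config block '", blk, "': ",
             paste(bad, collapse = ", "))
    }
  }
  base <- default_config(seed = if (!is.null(cfg$seed)) cfg$seed else 1L)
  for (blk in names(cfg)) {
    if (is.list(cfg[[blk]]) && is.list(base[[blk]]))
      base[[blk]] <- utils::modifyList(base[[blk]], cfg[[blk]])
    else base[[blk]] <- cfg[[blk]]
  }
  cfg <- base
  with(cfg$preprocess, {
    if (!is.null(epoch_seconds) && epoch_seconds <= 0)
      stop("config: epoch_seconds must be > 0")
    if (bandpass[1] <= 0 || bandpass[1] >= bandpass[2])
      stop("config: bandpass edges must satisfy 0 < lo < hi")
  })
  if (cfg$psd$overlap < 0 || cfg$psd$overlap >= 1)
    stop("config: psd overlap must be in [0, 1)")
  if (cfg$si$dt <= 0 || cfg$si$t_max <= cfg$si$dt)
    stop("config: si needs dt > 0 and t_max > dt")
  d <- cfg$network$densities
  if (length(d) == 3 && d[3] < d[2] - d[1]) # [from, to, by] shorthand
    cfg$network$densities <- seq(d[1], d[2], by = d[3])
  invisible(cfg)
}

#' Read a pipeline configuration from JSON
#' @param path JSON file.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

# Rolling polynomial hash of a character string, as 8 hex digits; used only
# to fingerprint configs in run manifests.
fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full localization pipeline
#'
#' Stage order: simulate (or load) -> preprocess -> sLORETA -> region
#' extraction -> PSD -> MVAR/DTF band networks -> degree metrics -> seizure
#' index -> (optional) evaluation. Rerunning with the same config is
#' bit-identical. Stage outputs are returned in one list and optionally
#' persisted under `cfg$out_dir`.
#'
#' @param cfg configuration list (validated first; see [default_config]).
#' @param verbose print one line per stage (default FALSE).
#' @return list with elements `recording`, `regions`, `psd_bands`,
#'   `networks`, `metrics`, `si`, `report` (or NULL), `truth` (scenario
#'   ground truth or NULL) and `manifest`.
#' @export
run_pipeline <- function(cfg = default_config(), verbose = FALSE) {
  cfg <- validate_config(cfg)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  # --- acquire -----------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$input)) {
    rec <- read_eeg(cfg$input$eeg,
                    format = if (is.null(cfg$input$format)) "auto"
                             else cfg$input$format,
                    rate = cfg$input$rate,
                    onset_marker = cfg$input$onset_sample)
    n_regions <- NULL
    say("loaded %d x %d recording", nrow(rec$samples), ncol(rec$samples))
  } else {
    sc <- cfg$scenario
    scn <- scenario_preictal(n_regions = sc$n_regions, driver = sc$driver,
                             n_targets = sc$n_targets,
                             coupling_strength = sc$coupling_strength,
                             delta_gain = sc$delta_gain,
                             duration = sc$duration, rate = sc$rate,
                             sensor_snr = sc$sensor_snr,
                             seed = cfg$seed)
    src <- simulate_sources(scn)
    head_mod <- default_head(sc$n_regions,
                             source_radius = cfg$inverse$source_radius)
    lf_true <- make_lead_field(head_mod)
    rec <- project_to_scalp(src, lf_true, snr = sc$sensor_snr,
                            seed = cfg$seed + 7919L)
    truth <- list(scenario = scn, sources = src)
    n_regions <- sc$n_regions
    say("simulated scenario: driver %s, %d regions",
        paste(scn$driver_regions, collapse = ","), sc$n_regions)
  }
  tick("acquire")

  # --- preprocess --------------------------------------------------------
  pp <- cfg$preprocess
  rec <- bandpass(rec, pp$bandpass[1], pp$bandpass[2])
  rec <- notch(rec, freq = mean(pp$notch),
               halfwidth = diff(pp$notch) / 2)
  if (!is.null(pp$preictal_minutes))
    rec <- select_preictal(rec, pp$preictal_minutes)
  if (isTRUE(pp$common_average)) rec <- common_average(rec)
  tick("preprocess")

  # --- inverse imaging ---------------------------------------------------
  if (is.null(n_regions)) n_regions <- 68L
  head_mod <- default_head(n_regions,
                           source_radius = cfg$inverse$source_radius)
  lf <- if (!is.null(cfg$input$lead_field)) read_lead_field(cfg$input$lead_field)
        else make_lead_field(head_mod)
  inv <- build_inverse(lf, alpha = cfg$inverse$alpha, snr = cfg$inverse$snr,
                       avg_ref = cfg$inverse$avg_ref)
  est <- apply_sloreta(inv, rec)
  parc <- centroid_parcellation(n_regions)
  regions <- extract_regions(est, parc)
  say("sLORETA: %d sources, alpha = %.4g", nrow(est$s_hat), inv$alpha)
  tick("inverse")

  # --- spectra -----------------------------------------------------------
  scheme <- band_scheme()
  psd <- welch_psd(regions, window_s = cfg$psd$window_s,
                   overlap = cfg$psd$overlap)
  psd_bands <- band_aggregate(psd, scheme)
  tick("psd")

  # --- directed networks -------------------------------------------------
  reg_rec <- eeg_recording(regions$x, regions$rate,
                           sprintf("R%03d", seq_len(nrow(regions$x))))
  eps <- epoch_recording(reg_rec, pp$epoch_seconds)
  mvar <- fit_mvar(eps, p = cfg$network$order, ridge = cfg$network$ridge,
                   max_order = cfg$network$max_order)
  dtf <- compute_dtf(mvar)
  networks <- list(); metrics <- list()
  for (band in cfg$network$bands) {
    adj <- band_network(dtf, scheme, band)
    networks[[band]] <- adj
    metrics[[band]] <- node_metrics(adj, densities = cfg$network$densities,
                                    cutoff = cfg$network$hub_cutoff)
  }
  say("MVAR order %d, %d band network(s)", mvar$p, length(networks))
  tick("network")

  # --- seizure index -----------------------------------------------------
  si_band <- cfg$si$band
  si_adj <- if (si_band %in% names(networks)) networks[[si_band]]
            else band_network(dtf, scheme, si_band)
  si_cfg <- si_config(coupling_gain = cfg$si$coupling_gain,
                      n_realizations = cfg$si$realizations,
                      t_max = cfg$si$t_max, dt = cfg$si$dt,
                      seed = cfg$seed + 104729L, d0 = cfg$si$d0,
                      threshold = cfg$si$threshold, cutoff = cfg$si$cutoff)
  si <- si_pipeline(regions, si_adj, band = si_band, scheme = scheme,
                    cfg = si_cfg)
  tick("si")

  # --- evaluation --------------------------------------------------------
  report <- NULL
  if (!is.null(cfg$evaluate)) {
    records <- read_clinical(cfg$evaluate$clinical, n_regions = n_regions)
    metric <- if (is.null(cfg$evaluate$metric)) "dc_out"
              else cfg$evaluate$metric
    predicted <- if (metric == "si") si$epileptogenic
                 else metrics[[si_band]]$hubs[[metric]]
    labels <- vapply(records, function(r) classify_patient(predicted, r), "")
    report <- diagnostics(tally_classifications(labels))
    tick("evaluate")
  }

  manifest <- list(
    config_hash = fnv1a(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                         null = "null")),
    package_version = as.character(utils::packageVersion("eznetsi")),
    seed = cfg$seed, timings_s = as.list(timings))

  out <- list(recording = rec, regions = regions, psd_bands = psd_bands,
              networks = networks, metrics = metrics, si = si,
              report = report, truth = truth, manifest = manifest)
  if (!is.null(cfg$out_dir)) {
    write_results(metrics, report, cfg$out_dir)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
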