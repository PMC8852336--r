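# Report assembly and orchestration: paper-style duration tables,
# on-disk array container, run manifest, and the end-to-end pipeline.

#' Write a band-power array to the long-format container
#'
#' The on-disk container is a plain-text long-format CSV with named
#' dimension columns (`region`, `band`, `participant`, `epoch`, `value`)
#' plus a JSON sidecar (`<path>.json`) holding the epoch length, dimension
#' sizes, labels, and any generative ground-truth record.
#'
#' @param x a [band_power_array()].
#' @param path CSV path to write.
#' @return `path`, invisibly.
#' @export
write_band_power <- function(x, path) {
  if (!inherits(x, "band_power_array")) stop("`x` must be a band_power_array", call. = FALSE)
  d <- dim(x$values)
  df <- data.frame(
    region = rep(x$regions, times = prod(d[2:4])),
    band = rep(rep(x$bands, each = d[1]), times = prod(d[3:4])),
    participant = rep(rep(seq_len(d[3]), each = prod(d[1:2])), times = d[4]),
    epoch = rep(seq_len(d[4]), each = prod(d[1:3])),
    value = as.vector(x$values),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(dims = as.list(stats::setNames(d, c("region", "band", "participant", "epoch"))),
               epoch_length_s = x$epoch_length_s,
               regions = x$regions, bands = x$bands,
               ground_truth = x$ground_truth)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a band-power array from the long-format container
#'
#' @param path CSV path written by [write_band_power()]; the JSON sidecar
#'   `<path>.json` must sit alongside.
#' @return a [band_power_array()].
#' @export
read_band_power <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- unname(unlist(side$dims))
  vals <- array(NA_real_, dim = d)
  ri <- match(df$region, side$regions)
  bi <- match(df$band, side$bands)
  vals[cbind(ri, bi, df$participant, df$epoch)] <- df$value
  out <- band_power_array(vals, region_labels = side$regions,
                          epoch_length_s = side$epoch_length_s,
                          ground_truth = side$ground_truth)
  out$bands <- side$bands
  out
}

#' Format threshold durations as a paper-style table
#'
#' Assembles one or more threshold-duration analyses (e.g. the
#' band-power family, the parameterized-periodic family, and the
#' aperiodic slope/offset family) into a single wide table: one row per
#' feature, columns excellent/good/moderate x median/min/max plus the
#' most and least stable region, DNS coded as the literal string `"DNS"`.
#'
#' @param tables a named list of [threshold_durations()] results; names
#'   are the feature-family row group labels. A single `threshold_table`
#'   is also accepted.
#' @return a data.frame with columns `family`, `feature`,
#'   `excellent_median`, `excellent_min`, `excellent_max`, `good_*`,
#'   `moderate_*`, `most_stable_region`, `least_stable_region`.
#' @export
make_duration_table <- function(tables) {
  if (inherits(tables, "threshold_table")) tables <- list(features = tables)
  lvl <- function(th) if (th >= 0.9) "excellent" else if (th >= 0.75) "good" else "moderate"
  rows <- list()
  for (fam in names(tables)) {
    tt <- tables[[fam]]
    agg <- tt$aggregates
    for (f in unique(agg$band)) {
      sub <- agg[agg$band == f, ]
      row <- list(family = fam, feature = f)
      for (i in seq_len(nrow(sub))) {
        pre <- lvl(sub$threshold[i])
        row[[paste0(pre, "_median")]] <- sub$median[i]
        row[[paste0(pre, "_min")]] <- sub$min[i]
        row[[paste0(pre, "_max")]] <- sub$max[i]
      }
      row$most_stable_region <- sub$most_stable_region[1]
      row$least_stable_region <- sub$least_stable_region[1]
      rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  cols <- c("family", "feature",
            paste0(rep(c("excellent", "good", "moderate"), each = 3),
                   c("_median", "_min", "_max")),
            "most_stable_region", "least_stable_region")
  out <- do.call(rbind, lapply(rows, function(r) r[cols]))
  rownames(out) <- NULL
  out
}

#' Write / read a threshold-duration table
#'
#' Round-trip safe CSV serialization of the per-region duration table:
#' durations are written as integers (multiples of the epoch length) and
#' DNS cells as the literal string `"DNS"`.
#'
#' @param tt a [threshold_durations()] result.
#' @param path CSV path.
#' @return `path` invisibly (write); a data.frame equal to
#'   `tt$durations` (read).
#' @export
write_threshold_durations <- function(tt, path) {
  if (!inherits(tt, "threshold_table")) stop("`tt` must be a threshold_table", call. = FALSE)
  df <- tt$durations
  df$duration_s <- ifelse(is.na(df$duration_s), "DNS",
                          format(df$duration_s, trim = TRUE, scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_threshold_durations
#' @export
read_threshold_durations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(duration_s = "character"))
  dur <- rep(NA_real_, nrow(df))
  keep <- df$duration_s != "DNS"
  dur[keep] <- as.numeric(df$duration_s[keep])
  df$duration_s <- dur
  df
}

#' Run the full stability pipeline from a configuration
#'
#' Executes synthesis (or ingest) -> epoching -> Welch PSD -> band
#' averaging -> stability curves -> threshold tables, with optional
#' spectral parameterization and contribution stages, writing CSV outputs
#' and a JSON run manifest to `out_dir`. Identical configuration + seed
#' reproduce byte-identical CSVs.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{seed}{root seed (default 1).}
#'     \item{n_participants, n_regions}{cohort size and region count.}
#'     \item{duration_s, epoch_length_s, fs_hz}{session geometry.}
#'     \item{offset, exponent, peaks, participant_sd, epoch_sd}{spectral
#'       ground truth for synthesis (see [spectral_ground_truth()]).}
#'     \item{window_length_s, overlap}{Welch settings.}
#'     \item{bands}{`"canonical"` (default) or `"tensteps"`.}
#'     \item{n_permutations}{epoch permutations (default 1000).}
#'     \item{thresholds}{ICC thresholds (default 0.50/0.75/0.90).}
#'     \item{parameterize}{logical: run spectral parameterization of the
#'       epoch-bin-averaged spectra and its stability (default FALSE).}
#'     \item{contribution}{logical: run the leave-one-out contribution
#'       analysis with generated demographics (default FALSE).}
#'     \item{input_csv}{optional: read a band-power array from this
#'       container instead of synthesizing time series.}
#'   }
#' @param out_dir output directory, created if missing.
#' @return invisibly, a list with the main in-memory results (`band_power`,
#'   `curves`, `thresholds`, optionally `specparam`, `contribution`) and
#'   the manifest.
#' @export
run_pipeline <- function(config, out_dir = "results") {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    seed = 1L, n_participants = 20L, n_regions = 4L,
    duration_s = 240, epoch_length_s = 6, fs_hz = 250,
    offset = 1, exponent = 1,
    peaks = data.frame(cf = 10, height = 0.6, sd = 1.5),
    participant_sd = 0.08, epoch_sd = 0.04,
    window_length_s = 3, overlap = 0.5, bands = "canonical",
    n_permutations = 1000L, thresholds = c(0.50, 0.75, 0.90),
    parameterize = FALSE, contribution = FALSE, input_csv = NULL
  ), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stages <- list()
  tick <- function(name, expr) {
    s <- Sys.time()
    v <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
    stages[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    v
  }

  band_defs <- switch(cfg$bands, canonical = canonical_bands(),
                      tensteps = tenstep_bands(),
                      stop("config `bands` must be 'canonical' or 'tensteps'", call. = FALSE))

  if (!is.null(cfg$input_csv)) {
    bp <- tick("ingest", read_band_power(cfg$input_csv))
    psd_bins <- NULL
  } else {
    truth <- spectral_ground_truth(
      offset = cfg$offset, exponent = cfg$exponent, peaks = cfg$peaks,
      participant_sd = cfg$participant_sd, epoch_sd = cfg$epoch_sd,
      fs_hz = cfg$fs_hz, duration_s = cfg$duration_s,
      epoch_length_s = cfg$epoch_length_s, seed = cfg$seed
    )
    series <- tick("synthgen",
                   gen_region_timeseries(truth, cfg$n_participants, cfg$n_regions))
    psd <- tick("welch", welch_psd(series, cfg$window_length_s, cfg$overlap))
    bp <- tick("band_average", band_average(psd, band_defs))
    psd_bins <- psd
  }

  sched <- permutation_schedule(dim(bp$values)[4], cfg$n_permutations,
                                seed = child_seed(cfg$seed, 1))
  curves <- tick("stability", stability_curves(bp, sched))
  tt <- tick("thresholds", threshold_durations(curves, cfg$thresholds))

  write_band_power(bp, file.path(out_dir, "band_power.csv"))
  utils::write.csv(curves$region_summary, file.path(out_dir, "stability_summary.csv"),
                   row.names = FALSE)
  write_threshold_durations(tt, file.path(out_dir, "threshold_durations.csv"))
  utils::write.csv(make_duration_table(list(`power spectral density` = tt)),
                   file.path(out_dir, "duration_table.csv"), row.names = FALSE)

  out <- list(band_power = bp, curves = curves, thresholds = tt, schedule = sched)

  if (isTRUE(cfg$parameterize) && !is.null(psd_bins)) {
    out$specparam <- tick("specparam", {
      mean_psd <- apply(psd_bins$values, c(1, 2, 3), mean)  # R x freq x S
      st <- param_settings()
      fits <- apply(mean_psd, c(1, 3), function(v) {
        ft <- fit_spectrum(v, psd_bins$freqs_hz, st)
        c(offset = ft$offset, exponent = ft$exponent, r2 = ft$r2,
          n_peaks = nrow(ft$peaks))
      })
      df <- as.data.frame.table(fits, responseName = "value",
                                stringsAsFactors = FALSE)
      names(df) <- c("parameter", "region", "participant", "value")
      utils::write.csv(df, file.path(out_dir, "specparam_fits.csv"), row.names = FALSE)
      df
    })
  }

  if (isTRUE(cfg$contribution)) {
    out$contribution <- tick("contribution", {
      demo <- gen_demographics(dim(bp$values)[3], seed = child_seed(cfg$seed, 2))
      scores <- loo_stability_auc(bp, sched)
      tests <- covariate_regression(scores, demo)
      utils::write.csv(cbind(demo, scores$delta_auc),
                       file.path(out_dir, "contribution_scores.csv"), row.names = FALSE)
      utils::write.csv(tests, file.path(out_dir, "covariate_tests.csv"), row.names = FALSE)
      list(scores = scores, tests = tests, demographics = demo)
    })
  }

  manifest <- list(
    package = "specstab",
    version = as.character(utils::packageVersion("specstab")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    settings = cfg[setdiff(names(cfg), "input_csv")],
    stage_seconds = stages,
    input_digest = list(
      band_power_sum = sum(bp$values),
      band_power_dims = dim(bp$values)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  out$manifest <- manifest
  invisible(out)
}
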