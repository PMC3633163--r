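#' Write / read a spike table as TSV
#'
#' Columns: layer, neuron, time_ms.
#'
#' @param spikes spikes data.frame (e.g. \code{sim$spikes}).
#' @param path target file.
#' @return \code{read_spikes} returns the spikes data.frame.
#' @export
write_spikes <- function(spikes, path) {
  utils::write.table(spikes, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a response trace as TSV
#'
#' @param trace a \code{response_trace} (or any data.frame).
#' @param path target file.
#' @return \code{read_trace} returns a \code{response_trace}.
#' @export
write_trace <- function(trace, path) {
  hdr <- sprintf("# T_bin=%g step=%g layer=%s", attr(trace, "T_bin"),
                 attr(trace, "step"), attr(trace, "layer"))
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.table(trace, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, gregexpr("[A-Za-z_]+=[^ ]+", hdr))[[1]]
  kv <- strsplit(m, "=")
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1)
  vals <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  structure(df, class = c("response_trace", "data.frame"),
            T_bin = as.numeric(vals$T_bin), step = as.numeric(vals$step),
            layer = vals$layer)
}

#' Write a sweep result as tidy TSV plus a JSON summary
#'
#' @param sweep a \code{sweep_result}.
#' @param path TSV target; the JSON summary goes to \code{<path>.json}.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.table(sweep$data, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(param_name = sweep$param_name,
                            measure = sweep$measure, summary = sweep$summary),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

params_hash <- function(params) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(params), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, params, seeds, files, extra = list()) {
  man <- c(list(package_version = as.character(utils::packageVersion("saccstd")),
                params = unclass(params), params_md5 = params_hash(params),
                seeds = seeds, files = files,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           extra)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  man
}

#' Run a named experiment bundle
#'
#' Maps the four canonical experiment settings onto protocol + analysis
#' bundles and writes their outputs (spike tables, traces, sweep TSVs, a
#' JSON summary and a reproducibility manifest) to a directory:
#' \describe{
#'   \item{fading}{single microsaccade after a stationary warm-up
#'     (g = 0.15, A = 50, sigma = 1.5, Delta_M = 2.0): onset and saccade
#'     response peaks and the fading time.}
#'   \item{frequency}{average-activity and sensitivity sweep over Poisson
#'     microsaccade frequency.}
#'   \item{flashing}{flashing versus stationary stimulus comparison
#'     (T_on = T_off = 1 s, Delta_M = 1.0, 1.5 Hz Poisson saccades) and the
#'     interval analysis versus t_m - t_on.}
#'   \item{saturation}{magnitude and velocity sweeps of the response peak
#'     (g = 0.2, A = 100).}
#' }
#'
#' @param name one of "fading", "frequency", "flashing", "saturation".
#' @param out_dir output directory (created if missing).
#' @param seeds replicate seeds.
#' @param overrides named list of \code{\link{model_parameters}} overrides.
#' @param ... further arguments passed to the underlying sweep functions
#'   (e.g. \code{duration}, grids) to scale the experiment.
#' @return the manifest, invisibly; results as an attribute
#'   \code{"results"}.
#' @export
run_experiment <- function(name = c("fading", "frequency", "flashing", "saturation"),
                           out_dir, seeds = 1:20, overrides = list(), ...) {
  name <- match.arg(name)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- switch(name,
                 saturation = list(g = 0.2, A = 100),
                 list(g = 0.15, A = 50))
  params <- do.call(model_parameters, utils::modifyList(base, overrides))
  files <- character(0)
  results <- list()

  if (name == "fading") {
    net <- build_network(params)
    pr <- add_saccades(stationary_protocol(3000, params$A),
                       single_saccade(2000, 2.0))
    sim <- run_simulation(params, pr, seed = derive_seed(seeds[1], 2),
                          sample_every = 1, network = net)
    tr <- moving_bin_counts(sim, T_bin = params$T_bin)
    results$sim <- sim
    results$trace <- tr
    results$onset_peak <- response_peak(tr, 0)
    results$saccade_peak <- response_peak(tr, 2000)
    results$fading_ms <- as.numeric(fading_time(tr, 2000))
    write_spikes(sim$spikes, f1 <- file.path(out_dir, "spikes.tsv"))
    write_trace(tr, f2 <- file.path(out_dir, "response_trace.tsv"))
    jsonlite::write_json(results[c("onset_peak", "saccade_peak", "fading_ms")],
                         f3 <- file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(f1, f2, f3)
  } else if (name == "frequency") {
    sw <- frequency_sweep(params, F_grid = seq(0.5, 8, by = 0.5),
                          seeds = seeds, ...)
    results$sweep <- sw
    write_sweep(sw, f1 <- file.path(out_dir, "frequency_sweep.tsv"))
    utils::write.table(sw$sensitivity,
                       f2 <- file.path(out_dir, "sensitivity.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(f1, f2)
  } else if (name == "flashing") {
    fvs <- flashing_vs_stationary(params, seeds = seeds, ...)
    fia <- flash_interval_analysis(params,
                                   t_grid = seq(0, 1000, by = 250),
                                   seeds = seeds)
    results$flashing_vs_stationary <- fvs
    results$interval_analysis <- fia
    utils::write.table(fvs, f1 <- file.path(out_dir, "flash_vs_stationary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_sweep(fia, f2 <- file.path(out_dir, "interval_analysis.tsv"))
    files <- c(f1, f2)
  } else if (name == "saturation") {
    msw <- magnitude_sweep(params, seeds = seeds, ...)
    vsw <- velocity_sweep(params, seeds = seeds)
    results$magnitude <- msw
    results$velocity <- vsw
    write_sweep(msw, f1 <- file.path(out_dir, "magnitude_sweep.tsv"))
    write_sweep(vsw, f2 <- file.path(out_dir, "velocity_sweep.tsv"))
    files <- c(f1, f2)
  }
  man <- write_manifest(out_dir, params, seeds, basename(files),
                        extra = list(experiment = name))
  invisible(structure(man, results = results))
}
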