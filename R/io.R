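#' Write / read an output trace as CSV
#'
#' Columns `time_s`, `out`; metadata goes to a JSON sidecar
#' (`<path>.json`) so runs are fully reconstructable.
#'
#' @param trace An [sbf_trace()].
#' @param path CSV file path.
#' @param meta_sidecar Also write `<path>.json` with the trace metadata.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, meta_sidecar = TRUE) {
  stopifnot(inherits(trace, "sbf_trace"))
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  if (meta_sidecar) {
    jsonlite::write_json(trace$meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- read.csv(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  sbf_trace(d$time_s, d$out, meta)
}

#' Write / read a reference memory as CSV
#'
#' Columns `oscillator_id`, `f_hz`, `weight`; scalar fields (criterion,
#' trial count, norm constant) go to the JSON sidecar.
#'
#' @param memory An [encode_reference()] result.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_memory_csv <- function(memory, path) {
  stopifnot(inherits(memory, "sbf_memory"))
  d <- data.frame(oscillator_id = seq_along(memory$weights),
                  f_hz = memory$freqs, weight = memory$weights)
  write.csv(d, path, row.names = FALSE)
  jsonlite::write_json(
    list(criterion = memory$criterion, n_trials = memory$n_trials,
         norm_constant = memory$norm_constant, positive = memory$positive,
         noise = memory$noise[c("distribution", "sigma", "seed")]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_memory_csv
#' @export
read_memory_csv <- function(path) {
  d <- read.csv(path)
  m <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ns <- noise_spec(m$noise$distribution, m$noise$sigma,
                   seed = if (is.null(m$noise$seed)) NULL else m$noise$seed)
  structure(
    list(weights = d$weight, criterion = m$criterion, n_trials = m$n_trials,
         norm_constant = m$norm_constant, freqs = d$f_hz,
         positive = isTRUE(m$positive), noise = ns, criteria = NULL),
    class = "sbf_memory"
  )
}

#' Generate deterministic test fixtures
#'
#' Writes a small, fully reproducible fixture set: a 16-oscillator bank
#' (frequencies CSV), one reference memory, one noiseless trace, one
#' criterion-noise trace and one frequency-noise trace, each with a JSON
#' metadata sidecar.  Files are byte-identical across runs with the same
#' seed.
#'
#' @param dir Output directory (created if missing).
#' @param seed Master seed.
#' @return Character vector of the files written.
#' @export
generate_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- osc_bank_spec(16, 8, 12)
  freqs <- make_frequencies(spec)
  T_crit <- 2
  grid <- probe_grid(spec, T_crit)

  paths <- character(0)
  p <- file.path(dir, "bank.csv")
  write.csv(data.frame(oscillator_id = seq_along(freqs), f_hz = freqs), p,
            row.names = FALSE)
  jsonlite::write_json(unclass(spec), paste0(p, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, p)

  mem_noisy <- encode_reference(freqs, T_crit, n_trials = 200,
                                noise_spec("gaussian", 0.1,
                                           seed = derive_seed(seed, 1)))
  p <- file.path(dir, "memory.csv")
  write_memory_csv(mem_noisy, p)
  paths <- c(paths, p)

  mem0 <- encode_reference(freqs, T_crit, 1, noise_spec("none"))
  p <- file.path(dir, "trace_noiseless.csv")
  write_trace_csv(probe_output(mem0, grid = grid), p)
  paths <- c(paths, p)

  p <- file.path(dir, "trace_criterion_noise.csv")
  write_trace_csv(probe_output(mem_noisy, grid = grid), p)
  paths <- c(paths, p)

  p <- file.path(dir, "trace_frequency_noise.csv")
  write_trace_csv(
    probe_output(mem0, grid = grid,
                 freq_noise = noise_spec("gaussian", 0.1,
                                         seed = derive_seed(seed, 2)),
                 n_probe_trials = 50, average = "rectified"), p)
  paths <- c(paths, p)
  paths
}
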