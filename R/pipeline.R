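# Pipeline plumbing: image IO, sampling presets, YAML configuration, run
# manifests, and the programmatic entry points behind the command-line
# wrapper (inst/cli/neurogabor.R).

usage_error <- function(msg) {
  stop(structure(class = c("neurogabor_usage_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Read / write grayscale images
#'
#' PNG and TIFF files are converted to a real matrix in `[0, 1]`, indexed
#' `[x, y]` (x rightward, y downward); color channels are averaged. Writing
#' clips to `[0, 1]`.
#'
#' @param path Image file; format chosen by extension (`.png`, `.tif(f)`).
#' @return `read_image()`: a numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) usage_error(sprintf("input image not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                usage_error(sprintf("unsupported image format: .%s", ext)))
  if (length(dim(arr)) == 3) arr <- apply(arr[, , 1:min(3, dim(arr)[3])], c(1, 2), mean)
  # stored row-major [y, x]; internal convention is [x, y]
  t(arr)
}

#' @rdname read_image
#' @param image Numeric matrix, internal `[x, y]` convention.
#' @param bits Bit depth for PNG (8 or 16).
#' @export
write_image <- function(image, path, bits = 8) {
  stopifnot(is.matrix(image))
  out <- t(pmin(pmax(image, 0), 1))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(out, path),
         tif = ,
         tiff = tiff::writeTIFF(out, path, bits.per.sample = bits),
         usage_error(sprintf("unsupported image format: .%s", ext)))
  invisible(path)
}

#' Sampling and flow presets
#'
#' Named protocol presets bundling a [bank_spec()] and [flow_config()]
#' arguments:
#' \describe{
#'   \item{`"transform-dense"`}{Dense transform-quality sampling: scale 2,
#'     K = 32 orientations, the 29-value frequency grid from 0.25 to 3.25,
#'     16 phases. For round-trip studies.}
#'   \item{`"enhance-64"`}{The 64 x 64 enhancement protocol: K = 16,
#'     frequencies 0.25..2.25, dt = 0.1, 15 iterations, c1 = 1,
#'     c2 = (K/64)^2.}
#'   \item{`"enhance-256"`}{The 256 x 256 protocol: 48-pixel filters
#'     (trunc_factor 12 at scale 2), K = 16, ten frequencies 1.45..2.19,
#'     75 iterations.}
#' }
#'
#' @param name Preset name.
#' @return A list with elements `bank` (a `bank_spec`) and `flow` (a
#'   `flow_config`).
#' @export
preset <- function(name = c("enhance-64", "transform-dense", "enhance-256")) {
  name <- match.arg(name)
  switch(name,
    "transform-dense" = list(
      bank = bank_spec(sigma = 2, trunc_factor = 6, K = 32,
                       omegas = c(seq(0.25, 1.25, by = 0.25),
                                  seq(1.375, 2.25, by = 0.125),
                                  seq(2.3125, 3.25, by = 0.0625)),
                       M = 16),
      flow = flow_config(iterations = 0)),
    "enhance-64" = list(
      bank = bank_spec(sigma = 2, trunc_factor = 6, K = 16,
                       omegas = c(seq(0.25, 1, by = 0.25),
                                  seq(1.125, 2.25, by = 0.125)),
                       M = 5),
      flow = flow_config(c1 = 1, beta = 16 / 64, dt = 0.1, iterations = 15)),
    "enhance-256" = list(
      bank = bank_spec(sigma = 2, trunc_factor = 12, K = 16,
                       omegas = c(1.45, 1.51, 1.58, 1.66, 1.74, 1.82,
                                  1.91, 2, 2.09, 2.19),
                       M = 5),
      flow = flow_config(c1 = 1, beta = 16 / 256, dt = 0.1,
                         iterations = 75)))
}

#' Read a YAML run configuration
#'
#' Recognized top-level blocks: `bank` (fields of [bank_spec()]), `flow`
#' (fields of [flow_config()]) and `preset`. Explicit fields override the
#' preset; flags passed to [run_enhance()] override both.
#'
#' @param path YAML file.
#' @return A list with `bank`, `flow` and the raw values.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    usage_error(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  base <- if (!is.null(raw$preset)) preset(raw$preset) else
    list(bank = bank_spec(), flow = flow_config())
  bank_args <- unclass(base$bank)
  flow_args <- unclass(base$flow)
  for (nm in names(raw$bank)) bank_args[[nm]] <- raw$bank[[nm]]
  for (nm in names(raw$flow)) flow_args[[nm]] <- raw$flow[[nm]]
  list(bank = do.call(bank_spec, bank_args),
       flow = do.call(flow_config, flow_args),
       raw = raw)
}

resolve_run_config <- function(config_file = NULL, preset_name = NULL,
                               bank_overrides = list(),
                               flow_overrides = list()) {
  if (!is.null(config_file)) {
    cfg <- read_config(config_file)
  } else if (!is.null(preset_name)) {
    cfg <- preset(preset_name)
  } else {
    cfg <- list(bank = bank_spec(), flow = flow_config())
  }
  bank_args <- unclass(cfg$bank)
  flow_args <- unclass(cfg$flow)
  for (nm in names(bank_overrides)) bank_args[[nm]] <- bank_overrides[[nm]]
  for (nm in names(flow_overrides)) flow_args[[nm]] <- flow_overrides[[nm]]
  list(bank = do.call(bank_spec, bank_args),
       flow = do.call(flow_config, flow_args))
}

#' Run the enhancement pipeline on an image file
#'
#' Reads an image, runs [enhance()], writes the result and a JSON manifest
#' recording the fully resolved bank/flow configuration, the seed, and the
#' per-iteration diagnostics -- enough to reproduce the run bit for bit.
#'
#' @param input Path to the input image (PNG/TIFF).
#' @param output Path for the enhanced image.
#' @param manifest Path for the JSON manifest (default `<output>.manifest.json`).
#' @param config_file Optional YAML configuration.
#' @param preset_name Optional preset name (see [preset()]).
#' @param bank_overrides,flow_overrides Named lists overriding individual
#'   [bank_spec()] / [flow_config()] fields; highest precedence.
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return Invisibly, a list with the enhanced image, the manifest, and the
#'   resolved configuration.
#' @export
run_enhance <- function(input, output, manifest = NULL, config_file = NULL,
                        preset_name = NULL, bank_overrides = list(),
                        flow_overrides = list(), seed = 1L) {
  if (missing(input) || is.null(input)) usage_error("no input image given")
  if (missing(output) || is.null(output)) usage_error("no output path given")
  cfg <- resolve_run_config(config_file, preset_name, bank_overrides,
                            flow_overrides)
  image <- read_image(input)
  set.seed(as.integer(seed))
  bank <- build_bank(cfg$bank)
  out <- enhance(image, bank, cfg$flow)
  write_image(out, output)
  if (is.null(manifest)) manifest <- paste0(output, ".manifest.json")
  resolved_flow <- attr(out, "flow_config")
  man <- list(
    input = input, output = output, seed = as.integer(seed),
    bank = unclass(cfg$bank), flow = unclass(resolved_flow),
    image_shape = dim(image),
    diagnostics = attr(out, "diagnostics"),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, manifest, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(image = out, manifest = man, config = cfg))
}

#' Diagnostic subcommands
#'
#' Surfaces the model's diagnostic quantities:
#' \describe{
#'   \item{`"stability-bound"`}{Prints and returns [max_timestep()] for the
#'     given `K, c1, c2`.}
#'   \item{`"coverage"`}{Computes [spectral_coverage()] for the bank on the
#'     given shape; reports the minimum and optionally writes a heat map.}
#'   \item{`"curves"`}{Generates a [curve_fan()] and writes it as CSV.}
#' }
#'
#' @param what One of `"stability-bound"`, `"coverage"`, `"curves"`.
#' @param K,c1,c2 Stability-bound parameters.
#' @param bank_spec_obj A [bank_spec()] for `"coverage"`.
#' @param shape Fourier grid shape for `"coverage"`.
#' @param output Optional output file (PNG heat map, or curves CSV).
#' @param init,coeffs,vary,values Curve-fan parameters (see [curve_fan()]).
#' @param quiet Suppress console output.
#' @return The computed diagnostic, invisibly for file outputs.
#' @export
run_diagnostics <- function(what = c("stability-bound", "coverage", "curves"),
                            K = 16, c1 = 1, c2 = 0.0625,
                            bank_spec_obj = bank_spec(), shape = c(64, 64),
                            output = NULL,
                            init = feature_point(omega = 1),
                            coeffs = curve_coefficients(c1 = 1),
                            vary = "c2", values = seq(-2, 2, by = 0.5),
                            quiet = FALSE) {
  what <- match.arg(what)
  if (what == "stability-bound") {
    bound <- max_timestep(K, c1, c2)
    if (!quiet) cat(sprintf("%.2f\n", bound))
    return(invisible(bound))
  }
  if (what == "coverage") {
    bank <- build_bank(bank_spec_obj)
    cov <- spectral_coverage(bank, shape)
    if (!quiet)
      cat(sprintf("coverage: min %.6g, max %.6g, min/max %.3e\n",
                  min(cov), max(cov), min(cov) / max(cov)))
    if (!is.null(output)) write_image(cov / max(cov), output)
    return(invisible(cov))
  }
  fan <- curve_fan(init, coeffs, vary = vary, values = values)
  if (!is.null(output)) {
    write_curves_csv(fan, output)
    if (!quiet) cat(sprintf("wrote %d curves to %s\n", length(fan), output))
  }
  invisible(fan)
}
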