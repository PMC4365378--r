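#' Paired input/output record of one mechanical test
#'
#' The identification currency: sampled time `t` (s), signed true strain
#' `strain` \eqn{= (e - e_0)/e} and measured load `load` (N), plus metadata
#' (sample label, geometry, protocol, noise descriptor, seed and generating
#' model for synthetic data). The extension is recoverable as
#' `e = e0 / (1 - strain)`, so the record is complete for every model
#' convention.
#'
#' @param t numeric time grid, s, strictly increasing.
#' @param strain signed true strain on `t`.
#' @param load measured load on `t`, N.
#' @param e0 reference extension, mm.
#' @param A0 cross-section, mm^2.
#' @param label sample label (identification/validation bookkeeping).
#' @param meta optional named list of extra provenance fields (protocol,
#'   generating model, noise level, seed, ...).
#' @return Object of class `ts_dataset`.
#' @export
ts_dataset <- function(t, strain, load, e0 = 5, A0 = 700,
                       label = "sample", meta = list()) {
  t <- as.numeric(t); strain <- as.numeric(strain); load <- as.numeric(load)
  if (length(t) != length(strain) || length(t) != length(load))
    stop("'t', 'strain' and 'load' must have equal length")
  if (any(diff(t) <= 0)) stop("'t' must be strictly increasing")
  if (any(strain >= 1)) stop("true strain must be < 1")
  structure(list(t = t, strain = strain, load = load,
                 e0 = e0, A0 = A0, label = label, meta = meta),
            class = "ts_dataset")
}

#' @export
print.ts_dataset <- function(x, ...) {
  cat(sprintf("Test record '%s': %d samples over %g s\n",
              x$label, length(x$t), diff(range(x$t))))
  cat(sprintf("  strain in [%.4g, %.4g], load in [%.4g, %.4g] N; e0 = %g mm, A0 = %g mm^2\n",
              min(x$strain), max(x$strain), min(x$load), max(x$load),
              x$e0, x$A0))
  if (!is.null(x$meta$model))
    cat("  synthetic, generated by:", x$meta$model, "\n")
  invisible(x)
}

#' @export
as.data.frame.ts_dataset <- function(x, ...) {
  data.frame(time_s = x$t, strain = x$strain, load_N = x$load)
}

# kinematic signal of a dataset (e = e0/(1 - eps))
dataset_kinematics <- function(ds) {
  kinematic_signal(ds$t, ds$e0 / (1 - ds$strain), ds$e0)
}

#' Generate a synthetic test record from a model and a protocol
#'
#' Builds the protocol's kinematic signal, simulates the chosen model on
#' it, and adds i.i.d. zero-mean Gaussian measurement noise to the load
#' only (the strain is machine-commanded). The default noise level is 1%
#' of the peak absolute noise-free load. Full provenance (model,
#' parameters, protocol, noise level, seed) is stored in `meta`, so the
#' same seed regenerates the identical dataset.
#'
#' @param structure one of `"linear"`, `"model1"`, `"model1_neohookean"`,
#'   `"hammerstein"`.
#' @param params the matching parameter object: a [linear_tf] (or a list
#'   `g1, g2, tau1, tau2`) for `"linear"`; a [model1_params] for the
#'   model-1 variants; a [model2_params] for `"hammerstein"`.
#' @param spec a [protocol_spec].
#' @param noise_sd standard deviation of the load noise, N; `NULL` for the
#'   default 1% of peak.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param label sample label.
#' @return A [ts_dataset]; `meta$load_clean` holds the noise-free load.
#' @export
generate_dataset <- function(structure, params, spec, noise_sd = NULL,
                             seed = NULL, label = "sample") {
  kin <- make_protocol_signal(spec)
  y <- simulate_structure(structure, params, kin)$y
  if (is.null(noise_sd)) noise_sd <- 0.01 * max(abs(y))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  noise <- if (noise_sd > 0) stats::rnorm(length(y), 0, noise_sd) else 0
  ts_dataset(kin$t, kin$eps, y + noise, e0 = spec$e0, A0 = spec$A0,
             label = label,
             meta = list(model = structure, params = unclass(params),
                         protocol = unclass(spec), noise_sd = noise_sd,
                         seed = seed, load_clean = y))
}

# forward simulation dispatcher shared by generation, fitting and validation
simulate_structure <- function(structure, params, kin) {
  switch(structure,
    linear = {
      tf <- if (inherits(params, "linear_tf")) params
            else maxwell_to_tf(params$g1, params$g2, params$tau1, params$tau2)
      simulate_lti(tf, kin$eps, kin$t)
    },
    model1 = ,
    model1_neohookean = simulate_model1(params, kin),
    hammerstein = simulate_hammerstein(params, kin),
    stop("unknown model structure: ", structure)
  )
}

#' Read and write test records as annotated CSV
#'
#' Plain-text CSV with columns `time_s`, `strain`, `load_N` and a commented
#' metadata header of `# key = value` lines (`label`, `e0_mm`, `A0_mm2`).
#' The round trip `write_dataset()` then `read_dataset()` is lossless for
#' the three columns and the geometric metadata; LF and CRLF files are both
#' accepted.
#'
#' @param ds a [ts_dataset].
#' @param path file path.
#' @return `read_dataset` returns a [ts_dataset]; `write_dataset` returns
#'   `path` invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "ts_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# label = %s", ds$label),
               sprintf("# e0_mm = %.15g", ds$e0),
               sprintf("# A0_mm2 = %.15g", ds$A0),
               "time_s,strain,load_N"), con)
  utils::write.table(
    data.frame(format(ds$t, digits = 15, trim = TRUE, scientific = FALSE),
               format(ds$strain, digits = 17, trim = TRUE),
               format(ds$load, digits = 17, trim = TRUE)),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("^#\\s*([^=\\s]+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- trimws(kv[3])
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) < 2) stop("malformed dataset file '", path, "': no data rows")
  cols <- strsplit(body[1], ",")[[1]]
  need <- c("time_s", "strain", "load_N")
  if (!all(need %in% trimws(cols)))
    stop("malformed dataset file '", path, "' at line ",
         which(lines == body[1]), ": header must contain columns ",
         paste(need, collapse = ", "))
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  for (nm in need) {
    bad <- which(!is.finite(df[[nm]]))
    if (length(bad))
      stop("malformed dataset file '", path, "' at line ", bad[1] + 1,
           ", column '", nm, "': non-numeric value")
  }
  ts_dataset(df$time_s, df$strain, df$load_N,
             e0 = as.numeric(meta$e0_mm %||% 5),
             A0 = as.numeric(meta$A0_mm2 %||% 700),
             label = meta$label %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
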