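#' Write a synthetic SERDS dataset to disk
#'
#' One columnar numeric table per sample (first column the wavenumber axis,
#' remaining columns the measurements, named `g<grid>_l<laser>_r<rep>`), a
#' JSON metadata sidecar per sample, and a dataset-level `manifest.json`
#' listing all samples together with the generator config and seed.
#'
#' @param dataset A `serds_dataset` from [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "serds_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(dataset$samples, function(s) {
    d <- dim(s$measurements)
    idx <- expand.grid(rep = seq_len(d[3]), laser = seq_len(d[2]),
                       grid = seq_len(d[1]))
    idx <- idx[order(idx$grid, idx$laser, idx$rep), , drop = FALSE]
    cols <- lapply(seq_len(nrow(idx)), function(k) {
      s$measurements[idx$grid[k], idx$laser[k], idx$rep[k], ]
    })
    names(cols) <- sprintf("g%d_l%d_r%d", idx$grid, idx$laser, idx$rep)
    tab <- data.frame(wavenumber = s$axis, cols, check.names = FALSE)
    csv <- file.path(dir, paste0(s$sample_id, ".csv"))
    utils::write.csv(tab, csv, row.names = FALSE)
    meta <- list(sample_id = s$sample_id, true_soc = s$true_soc,
                 soc_latent = s$soc_latent,
                 integration_time = s$integration_time,
                 index_map = names(cols))
    jsonlite::write_json(meta, file.path(dir, paste0(s$sample_id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    list(sample_id = s$sample_id, spectra = basename(csv),
         metadata = paste0(s$sample_id, ".json"))
  })
  manifest <- list(n_samples = length(dataset$samples),
                   config = unclass(dataset$config), samples = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic SERDS dataset written by [write_dataset()]
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @return A `serds_dataset`.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  cfg <- manifest$config
  config <- synthetic_config(
    n_samples = cfg$n_samples, soc_range = cfg$soc_range,
    grid_shape = cfg$grid_shape, n_replicates = cfg$n_replicates,
    laser_shift = cfg$laser_shift,
    fluorescence_amplitude_ratio = cfg$fluorescence_amplitude_ratio,
    heteroscedastic_coeffs = cfg$heteroscedastic_coeffs,
    albedo_sd = cfg$albedo_sd, noise_sd = cfg$noise_sd,
    dark_offset = cfg$dark_offset, integration_time = cfg$integration_time,
    native_range = cfg$native_range, native_step = cfg$native_step,
    seed = cfg$seed)
  samples <- lapply(seq_len(nrow(manifest$samples)), function(i) {
    entry <- manifest$samples[i, ]
    tab <- utils::read.csv(file.path(dir, entry$spectra), check.names = FALSE)
    meta <- jsonlite::read_json(file.path(dir, entry$metadata),
                                simplifyVector = TRUE)
    axis <- tab$wavenumber
    cols <- meta$index_map
    ids <- do.call(rbind, regmatches(cols, regexec("g(\\d+)_l(\\d+)_r(\\d+)", cols)))
    g <- as.integer(ids[, 2]); l <- as.integer(ids[, 3]); r <- as.integer(ids[, 4])
    meas <- array(NA_real_, dim = c(max(g), max(l), max(r), length(axis)))
    for (k in seq_along(cols)) meas[g[k], l[k], r[k], ] <- tab[[cols[k]]]
    structure(list(sample_id = meta$sample_id, true_soc = meta$true_soc,
                   soc_latent = meta$soc_latent, measurements = meas,
                   axis = axis, integration_time = meta$integration_time),
              class = "raw_sample")
  })
  structure(list(samples = samples, config = config,
                 axis = samples[[1]]$axis), class = "serds_dataset")
}

#' Write a processed spectrum as two-column text
#'
#' @param s A [spectrum()].
#' @param path Output file; a `.json` sidecar with the metadata is written
#'   next to it.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  utils::write.csv(data.frame(wavenumber = s$axis, intensity = s$intensity),
                   path, row.names = FALSE)
  if (length(s$meta)) {
    jsonlite::write_json(s$meta, paste0(tools::file_path_sans_ext(path), ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a model-ready dataset matrix
#'
#' Samples-by-channels matrix with the SOC label as last column, as CSV.
#'
#' @param x Numeric matrix (samples x channels).
#' @param y SOC labels (%).
#' @param path Output CSV path.
#' @export
write_matrix <- function(x, y, path) {
  stopifnot(nrow(x) == length(y))
  tab <- as.data.frame(x)
  names(tab) <- sprintf("ch%04d", seq_len(ncol(x)))
  tab$soc <- y
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset matrix written by [write_matrix()]
#' @param path CSV path.
#' @return List with `x` (matrix) and `y` (labels).
#' @export
read_matrix <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  y <- tab$soc
  x <- as.matrix(tab[, setdiff(names(tab), "soc"), drop = FALSE])
  list(x = x, y = y)
}
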