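# File formats: multi-structure XYZ, line/grid spectrum CSV, feature
# configuration (YAML/JSON), synthetic-ensemble fixture sets, model
# persistence and run manifests. CSV dialect is pinned: comma separator,
# '.' decimal, UTF-8, required headers.

#' Read a multi-structure XYZ file
#'
#' Parses repeated blocks of "natoms / comment / element x y z". The comment
#' line may carry a conformer identifier (first token) and an energy as an
#' `E=<kcal/mol>` token. Atom counts must be consistent across frames.
#'
#' @param path Path to the XYZ file.
#' @return List of [conformer_geometry()] objects; each carries attributes
#'   `id` and (when present) `energy`.
#' @export
read_multi_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  geoms <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1)
      stop(sprintf("frame %d (line %d): invalid atom count '%s'",
                   frame, i, trimws(lines[i])))
    if (i + 1L + nat > length(lines))
      stop(sprintf("frame %d (line %d): declared %d atoms but file ends early",
                   frame, i, nat))
    comment <- trimws(lines[i + 1L])
    tokens <- strsplit(comment, "\\s+")[[1]]
    id <- if (length(tokens) && nzchar(tokens[1])) tokens[1]
          else sprintf("frame%d", frame)
    etok <- grep("^E=", tokens, value = TRUE)
    energy <- if (length(etok))
      suppressWarnings(as.numeric(sub("^E=", "", etok[1]))) else NA_real_
    elements <- character(nat)
    coords <- matrix(NA_real_, nat, 3)
    for (a in seq_len(nat)) {
      ln <- i + 1L + a
      parts <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(parts) < 4)
        stop(sprintf("frame %d (line %d): expected 'element x y z', got '%s'",
                     frame, ln, lines[ln]))
      xyz <- suppressWarnings(as.numeric(parts[2:4]))
      if (any(is.na(xyz)))
        stop(sprintf("frame %d (line %d): non-numeric coordinate in '%s'",
                     frame, ln, lines[ln]))
      elements[a] <- parts[1]
      coords[a, ] <- xyz
    }
    g <- conformer_geometry(elements, coords)
    attr(g, "id") <- id
    attr(g, "energy") <- energy
    geoms[[frame]] <- g
    i <- i + 2L + nat
  }
  if (length(geoms) == 0) stop("no XYZ frames found in ", path)
  nat <- vapply(geoms, function(g) length(g$elements), integer(1))
  if (length(unique(nat)) != 1)
    stop("inconsistent atom counts across frames: ",
         paste(unique(nat), collapse = ", "))
  geoms
}

#' Write geometries as a multi-structure XYZ file
#'
#' @param geometries List of [conformer_geometry()] objects.
#' @param path Output path.
#' @param ids Optional conformer identifiers (defaults to stored `id`
#'   attributes or frame numbers).
#' @param energies Optional energies written as `E=` tokens.
#' @return `path`, invisibly.
#' @export
write_multi_xyz <- function(geometries, path, ids = NULL, energies = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in seq_along(geometries)) {
    g <- geometries[[k]]
    stopifnot(inherits(g, "conformer_geometry"))
    id <- if (!is.null(ids)) ids[k]
          else if (!is.null(attr(g, "id"))) attr(g, "id")
          else sprintf("frame%d", k)
    en <- if (!is.null(energies)) energies[k] else attr(g, "energy")
    comment <- if (!is.null(en) && is.finite(en))
      sprintf("%s E=%.10g", id, en) else id
    writeLines(as.character(length(g$elements)), con)
    writeLines(comment, con)
    writeLines(sprintf("%s %.10f %.10f %.10f", g$elements,
                       g$coords[, 1], g$coords[, 2], g$coords[, 3]), con)
  }
  invisible(path)
}

read_numeric_csv <- function(path, headers) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(df), headers))
    stop(path, ": expected header '", paste(headers, collapse = ","),
         "', got '", paste(names(df), collapse = ","), "'")
  out <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  for (nm in headers) {
    bad <- which(is.na(out[[nm]]) & nzchar(df[[nm]]))
    allbad <- which(is.na(out[[nm]]))
    if (length(allbad))
      stop(path, ": non-numeric value in column '", nm, "' at row ",
           allbad[1])
  }
  as.data.frame(out)
}

#' Read a line spectrum from CSV
#'
#' Expects header `wavenumber,intensity`, one mode per row; an empty body is
#' a valid zero-mode spectrum.
#'
#' @param path CSV path.
#' @return A [vcd_lines()] spectrum.
#' @export
read_line_spectrum_csv <- function(path) {
  df <- read_numeric_csv(path, c("wavenumber", "intensity"))
  vcd_lines(df$wavenumber, df$intensity)
}

#' Write a line spectrum to CSV
#'
#' @param lines A [vcd_lines()] spectrum.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_line_spectrum_csv <- function(lines, path) {
  stopifnot(inherits(lines, "vcd_lines"))
  df <- data.frame(wavenumber = sprintf("%.17g", lines$wavenumber),
                   intensity = sprintf("%.17g", lines$intensity))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a grid spectrum to CSV
#'
#' Emits header `wavenumber,delta_epsilon` and exactly one row per grid
#' point, at full double precision so a write/read round trip is lossless.
#'
#' @param spectrum A [vcd_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "vcd_spectrum"))
  df <- data.frame(wavenumber = sprintf("%.17g", spectrum$grid$wavenumbers),
                   delta_epsilon = sprintf("%.17g", spectrum$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a grid spectrum from CSV
#'
#' Expects header `wavenumber,delta_epsilon` with evenly spaced wavenumbers;
#' the grid is reconstructed from the node positions.
#'
#' @param path CSV path.
#' @return A [vcd_spectrum()].
#' @export
read_grid_csv <- function(path) {
  df <- read_numeric_csv(path, c("wavenumber", "delta_epsilon"))
  w <- df$wavenumber
  if (length(w) < 2) stop(path, ": a grid spectrum needs at least 2 rows")
  steps <- diff(w)
  if (max(abs(steps - steps[1])) > 1e-6 * abs(steps[1]))
    stop(path, ": wavenumbers are not evenly spaced")
  grid <- vcd_grid(w[1], w[length(w)], steps[1])
  vcd_spectrum(grid, df$delta_epsilon)
}

#' Read a feature configuration from YAML or JSON
#'
#' The file lists 0-based atom-index quadruples under `dihedrals`, bisector
#' pairs (two quadruples each) under `bisectors`, index pairs under
#' `hbond_pairs`, and optionally `angle_encoding`.
#'
#' @param path Path ending in `.yaml`/`.yml` or `.json`.
#' @return A [feature_config()].
#' @export
read_feature_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyMatrix = FALSE,
                          simplifyDataFrame = FALSE)
  as_idx_list <- function(x) lapply(x, function(v) as.integer(unlist(v)))
  feature_config(
    dihedrals = as_idx_list(raw$dihedrals %||% list()),
    bisectors = lapply(raw$bisectors %||% list(), function(b)
      lapply(b, function(v) as.integer(unlist(v)))),
    hbond_pairs = as_idx_list(raw$hbond_pairs %||% list()),
    angle_encoding = raw$angle_encoding %||% "sincos")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic ensemble as a plain-text fixture set
#'
#' Writes `dihedrals.csv` (conformer id, theta columns in degrees, energy),
#' one line-spectrum CSV per conformer under `spectra/`, and
#' `manifest.json` recording the generator configuration and seed.
#'
#' @param e A `synthetic_ensemble`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(e, dir) {
  stopifnot(inherits(e, "synthetic_ensemble"))
  dir.create(file.path(dir, "spectra"), recursive = TRUE,
             showWarnings = FALSE)
  d <- ncol(e$dihedrals)
  tab <- data.frame(conformer = e$ids)
  for (j in seq_len(d))
    tab[[sprintf("theta%d", j)]] <- sprintf("%.10f", e$dihedrals[, j])
  tab$energy <- sprintf("%.10f", e$energies)
  utils::write.csv(tab, file.path(dir, "dihedrals.csv"), row.names = FALSE,
                   quote = FALSE)
  for (i in seq_along(e$ids))
    write_line_spectrum_csv(e$line_spectra[[i]],
                            file.path(dir, "spectra",
                                      paste0(e$ids[i], ".csv")))
  cfg <- unclass(e$map_cfg)
  jsonlite::write_json(
    list(map_config = cfg, sampling = e$sampling,
         n_conformers = length(e$ids),
         degenerate_pairs = !is.null(e$pair_map),
         energy_params = e$energy_params),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dihedral-table fixture
#'
#' Reads the `dihedrals.csv` written by [write_ensemble()] (and, when
#' present, the per-conformer line spectra) back into a record-building
#' friendly form.
#'
#' @param dir Fixture directory.
#' @param grid Grid for broadening the stored line spectra; `NULL` skips
#'   spectra.
#' @param fwhm Lorentzian FWHM for broadening.
#' @return List with `ids`, `dihedrals` (matrix, degrees), `energies`, and
#'   (when read) `records` as for [ensemble_records()].
#' @export
read_ensemble_dir <- function(dir, grid = vcd_grid(), fwhm = 10) {
  tab <- utils::read.csv(file.path(dir, "dihedrals.csv"),
                         check.names = FALSE)
  theta_cols <- grep("^theta", names(tab), value = TRUE)
  dihedrals <- as.matrix(tab[, theta_cols, drop = FALSE])
  ids <- as.character(tab$conformer)
  rownames(dihedrals) <- ids
  energies <- as.numeric(tab$energy)
  out <- list(ids = ids, dihedrals = dihedrals, energies = energies)
  spectra_dir <- file.path(dir, "spectra")
  if (!is.null(grid) && dir.exists(spectra_dir)) {
    out$records <- lapply(seq_along(ids), function(i) {
      lines <- read_line_spectrum_csv(file.path(spectra_dir,
                                                paste0(ids[i], ".csv")))
      list(id = ids[i],
           features = encode_dihedrals(dihedrals[i, ]),
           energy = energies[i],
           spectrum = broaden(lines, grid, fwhm),
           source = "reference")
    })
  }
  out
}

#' Persist a trained surrogate
#'
#' Writes a model directory holding `metadata.json` (architecture, feature
#' layout, grid, preprocessing statistics, training log) and the learned
#' parameters in R's native serialized form; [load_surrogate()] restores
#' bitwise-identical predictions.
#'
#' @param model A `vcd_surrogate`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_surrogate <- function(model, dir) {
  stopifnot(inherits(model, "vcd_surrogate"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(config = unclass(model$config),
               input_layout = model$input_layout,
               slot_type = model$slot_type,
               grid = list(start = model$grid$start, stop = model$grid$stop,
                           step = model$grid$step),
               best_epoch = model$best_epoch, val_mse = model$val_mse,
               seed = model$seed, control = model$control,
               log = model$log)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  saveRDS(list(params = model$params, x_scale = model$x_scale,
               y_center = model$y_center, y_scale = model$y_scale),
          file.path(dir, "parameters.rds"))
  invisible(dir)
}

#' Load a persisted surrogate
#'
#' @param dir Directory written by [save_surrogate()].
#' @return A `vcd_surrogate`.
#' @export
load_surrogate <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "metadata.json"),
                             simplifyDataFrame = TRUE)
  pars <- readRDS(file.path(dir, "parameters.rds"))
  cfg <- do.call(trial_config, meta$config)
  structure(list(config = cfg, params = pars$params,
                 input_layout = meta$input_layout,
                 slot_type = meta$slot_type,
                 grid = vcd_grid(meta$grid$start, meta$grid$stop,
                                 meta$grid$step),
                 x_scale = pars$x_scale, y_center = pars$y_center,
                 y_scale = pars$y_scale,
                 log = as.data.frame(meta$log),
                 best_epoch = meta$best_epoch, val_mse = meta$val_mse,
                 seed = meta$seed, control = meta$control),
            class = "vcd_surrogate")
}

#' Write a run manifest
#'
#' Records the command, configuration, seeds and software versions of a
#' pipeline step so the run can be reproduced.
#'
#' @param dir Output directory.
#' @param command Subcommand name.
#' @param config Named list of the options used.
#' @param seed Integer seed (or NULL).
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, command, config, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(
    list(command = command, config = config, seed = seed,
         package_version = tryCatch(
           as.character(utils::packageVersion("vcdml")),
           error = function(e) "dev"),
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
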