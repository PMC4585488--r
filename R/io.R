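#' Read and write cell tables as CSV
#'
#' The cell-table interchange format is UTF-8 CSV with a header and '.'
#' decimal separator. Required columns: `cell_id, x_um, y_um, layer` and at
#' least one intensity column `ch1..chK`; optional columns (`z_um`, `section`,
#' `clone_id`, `code`, ...) are preserved. Intensities are validated to
#' [0, 255]; a header-only file is an empty table, not an error. On writing,
#' coordinates are rounded to 0.01 um.
#'
#' @param path CSV file path.
#' @return `read_cell_table` returns a data.frame; `write_cell_table` returns
#'   `path` invisibly.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "x_um", "y_um", "layer")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  ch <- channel_columns(tab)
  if (length(ch) == 0L) {
    stop("cell table is missing required column(s): ch1..chK intensities")
  }
  for (k in ch) {
    bad <- which(is.na(tab[[k]]) | tab[[k]] < 0 | tab[[k]] > 255)
    if (length(bad)) {
      stop("intensity out of range [0,255] in column ", k, " at row ", bad[1L])
    }
  }
  tab
}

#' @rdname read_cell_table
#' @param cells Cell table to write.
#' @export
write_cell_table <- function(cells, path) {
  out <- cells
  for (cc in intersect(c("x_um", "y_um", "z_um"), names(out))) {
    out[[cc]] <- round(out[[cc]], 2)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' Plain-text YAML with one block per stage (`simulate`, `segment`, `decode`,
#' `stats`) plus top-level `seed` and `out_dir`. Unknown top-level keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return Named list usable as [run_pipeline()] config.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "out_dir", "simulate", "model", "segment", "decode",
             "stats", "input")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg
}

#' Run the full clonal-analysis pipeline
#'
#' Chains simulate (optional) -> render + segment -> decode -> stats on one
#' seeded configuration, writing all artifacts and a run manifest into
#' `out_dir`. Identical config + seed produce identical outputs; each stage
#' re-seeds from the master seed plus a fixed offset, so stages are
#' individually reproducible. Instead of simulating, a pre-extracted cell
#' table can be supplied via `config$input$cell_table` (CSV), in which case
#' the segment stage is skipped.
#'
#' Artifacts: ground-truth cell table (`truth_cells.csv`), parameter echo
#' (`params.yaml`), rendered image (`image.tif`), detected cells
#' (`detected_cells.csv`), PSNR curves (`psnr_curves.json`), decoded cells
#' (`decoded_cells.csv`), clone summary (`clones.csv`), clone-size histogram
#' (`clone_sizes.json`), dispersion summary (`dispersion.csv` /
#' `dispersion_tests.csv`), and `manifest.json`.
#'
#' @param config Named list (or path to a YAML file, see
#'   [read_pipeline_config()]) with optional blocks `model` (arguments to
#'   [cortical_model()]), `simulate` (arguments to [sim_params()]), `segment`
#'   (arguments to [render_config()] plus `min_area`, `n_range`, `epsilon_db`,
#'   `core_frac`), `decode` (`levels`, `max_link_distance_um`), `stats`
#'   (`sampling_policy`, `alternative`), and `input$cell_table`.
#' @param out_dir Output directory (created if needed); overrides
#'   `config$out_dir`.
#' @param seed Master seed; overrides `config$seed`.
#' @return The run manifest (list), invisibly; also written as JSON.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("an output directory is required")
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = paste0("clonecortex ", as.character(utils::packageVersion("clonecortex"))),
    seed = seed,
    config = config,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list(),
    outputs = list()
  )
  done <- function(stage, files) {
    m <- manifest
    m$stages[[stage]] <- "complete"
    for (f in files) m$outputs[[basename(f)]] <- unname(tools::md5sum(f))
    manifest <<- m
  }
  in_stage <- function(stage, offset, expr) {
    set.seed((seed + offset) %% .Machine$integer.max)
    tryCatch(expr, error = function(e) {
      manifest$stages[[stage]] <<- "failed"
      manifest$finished <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      write_manifest(manifest, out_dir)
      stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  path <- function(f) file.path(out_dir, f)

  model <- do.call(cortical_model,
                   config$model %||% list(boundaries = c(0, 100, 350, 500, 700, 950, 1000),
                                          layer_names = c("L1", "L2/3", "L4", "L5", "L6", "SP")))
  seg_cfg <- config$segment %||% list()
  dec_cfg <- config$decode %||% list()
  stat_cfg <- config$stats %||% list()

  if (!is.null(config$input$cell_table)) {
    cells <- in_stage("segment", 1L, read_cell_table(config$input$cell_table))
    done("segment", character(0))
    sim <- NULL
  } else {
    sim <- in_stage("simulate", 0L, {
      sp <- do.call(sim_params, c(config$simulate %||% list(), list(seed = seed)))
      s <- simulate_clones(model, sp)
      write_cell_table(s$cells, path("truth_cells.csv"))
      yaml::write_yaml(sim_params_echo(sp), path("params.yaml"))
      s
    })
    done("simulate", c(path("truth_cells.csv"), path("params.yaml")))

    cells <- in_stage("segment", 1L, {
      rc <- do.call(render_config,
                    seg_cfg[intersect(names(seg_cfg),
                                      names(formals(render_config)))])
      img <- render_image(sim$cells, rc)
      write_image_tiff(img, path("image.tif"))
      det <- detect_cells(img,
                          pixel_size_um = rc$pixel_size_um,
                          min_area = seg_cfg$min_area %||% 5L,
                          n_range = seg_cfg$n_range %||% 2:15,
                          epsilon_db = seg_cfg$epsilon_db %||% 0.5,
                          core_frac = seg_cfg$core_frac %||% 0.95)
      det$layer <- layer_of(model, det$y_um)
      write_cell_table(det, path("detected_cells.csv"))
      curves <- lapply(attr(det, "thresholds"), function(ts) {
        list(n = ts$n, thresholds = ts$thresholds,
             psnr_db = ts$psnr_db,
             curve = attr(ts, "psnr_curve"))
      })
      jsonlite::write_json(curves, path("psnr_curves.json"),
                           auto_unbox = TRUE, digits = NA, na = "string")
      det
    })
    done("segment", c(path("image.tif"), path("detected_cells.csv"),
                      path("psnr_curves.json")))
  }

  partition <- in_stage("decode", 2L, {
    enc <- encode_cells(cells, levels = dec_cfg$levels %||% 5L)
    part <- group_clones(enc, max_link_distance_um = dec_cfg$max_link_distance_um)
    write_cell_table(part$cells, path("decoded_cells.csv"))
    utils::write.csv(part$groups, path("clones.csv"), row.names = FALSE)
    h <- clone_size_histogram(part)
    jsonlite::write_json(
      list(breaks = h$breaks, labels = h$labels, counts = h$counts,
           n_clones = h$n_clones, missing_sizes = h$missing_sizes),
      path("clone_sizes.json"), auto_unbox = TRUE, digits = NA)
    part
  })
  done("decode", c(path("decoded_cells.csv"), path("clones.csv"),
                   path("clone_sizes.json")))

  in_stage("stats", 3L, {
    pairs <- pair_distances(partition$cells,
                            sampling_policy = stat_cfg$sampling_policy %||% "all")
    if (nrow(pairs)) {
      disp <- summarize_dispersion(pairs,
                                   alternative = stat_cfg$alternative %||% "two.sided")
      utils::write.csv(disp$summary, path("dispersion.csv"), row.names = FALSE)
      utils::write.csv(disp$tests, path("dispersion_tests.csv"), row.names = FALSE)
    } else {
      utils::write.csv(data.frame(), path("dispersion.csv"), row.names = FALSE)
      utils::write.csv(data.frame(), path("dispersion_tests.csv"), row.names = FALSE)
    }
  })
  done("stats", c(path("dispersion.csv"), path("dispersion_tests.csv")))

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  write_manifest(manifest, out_dir)
  invisible(manifest)
}

#' @keywords internal
write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
}

#' @keywords internal
sim_params_echo <- function(sp) {
  echo <- unclass(sp)
  echo$clone_sizes <- if (is.function(echo$clone_sizes)) "sampler(default)"
                      else echo$clone_sizes
  echo
}
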