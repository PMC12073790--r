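# Pipeline orchestration: build -> simulate -> analyze with a YAML-style
# config, per-run JSON manifest and cross-system comparison report.  The
# manifest records the config hash, seed and per-stage outputs so that
# every output file is traceable to the run that produced it.

.default_analyze <- function() {
  list(window_ns = NULL, slice_width = 0.15, contact_cutoff = 0.5,
       qualify_cutoff = 0.7, threshold_density = 200, r0 = 0.6,
       probes = c(0.15, 1.5), grid_resolution = 0.2, depth_threshold = 1.5)
}

.read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config$stages <- config$stages %||% c("build", "simulate", "analyze")
  order <- c("build", "simulate", "analyze")
  bad <- setdiff(config$stages, order)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  config$stages <- order[order %in% config$stages]
  config$seed <- config$seed %||% 1L
  config$system <- config$system %||% "custom"
  an <- .default_analyze()
  an[names(config$analyze %||% list())] <- config$analyze
  config$analyze <- an
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run a build/simulate/analyze pipeline
#'
#' Executes the requested stages and writes every product plus a JSON
#' manifest under `output_dir`.  `build` constructs the gold layer and
#' grafted monolayer of the named system preset (or a custom
#' [monolayer_spec()]) and writes it as GRO; `simulate` runs
#' [simulate_brush()] with the `simulate` parameter block (plus an
#' optional `tensile` block that repeats the run under constant pulling);
#' `analyze` computes the standard observable set -- normalised S score,
#' per-peptide SASA at both probe radii, close and active-spot contacts
#' and persistence totals when a protein/probe is present, the
#' threshold-density distance, the density centroid and the tensile
#' centroid shift -- and writes them as CSV/JSON.
#'
#' Existing outputs are reused (stage skipped) unless `force = TRUE`.
#'
#' @param config path to a YAML config or an equivalent named list.
#'   Recognised top-level fields: `system` (preset name or "custom"),
#'   `stages`, `seed`, `output_dir`, and per-stage blocks `build`,
#'   `simulate` (a [synthetic_params()] argument list; `probe:` a
#'   [probe_spec()] argument list; `tensile:` with `pull_acceleration`),
#'   `analyze` (window/cutoff overrides).
#' @param output_dir overrides `config$output_dir`.
#' @param seed overrides `config$seed`.
#' @param force re-run stages whose outputs already exist.
#' @return the manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, output_dir = NULL, seed = NULL,
                         force = FALSE) {
  cfg <- .read_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  outdir <- output_dir %||% cfg$output_dir %||% stop("no output_dir given")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(system = cfg$system, seed = cfg$seed,
                   config_hash = .config_hash(cfg[setdiff(names(cfg),
                                                          "output_dir")]),
                   package_version = as.character(utils::packageVersion("goldsam")),
                   stages = list())
  paths <- list(build = file.path(outdir, "monolayer.gro"),
                traj = file.path(outdir, "trajectory.gro"),
                tensile = file.path(outdir, "trajectory_pulled.gro"),
                metrics = file.path(outdir, "metrics.json"))

  if ("build" %in% cfg$stages) {
    if (force || !file.exists(paths$build)) {
      spec <- if (cfg$system == "custom") {
        do.call(monolayer_spec, cfg$build)
      } else monolayer_preset(cfg$system)
      nx <- ceiling(spec$box[1] / spec$lattice_spacing)
      ny <- ceiling(spec$box[2] / (spec$lattice_spacing * sqrt(3) / 2))
      gold <- build_gold_layer(spec$lattice_spacing, nx, ny)
      built <- graft_conjugates(gold, spec, seed = cfg$seed)
      write_coordinates(built, paths$build)
    }
    manifest$stages$build <- list(output = paths$build,
                                  n_peptides = if (cfg$system != "custom")
                                    monolayer_preset(cfg$system)$n_peptides
                                  else cfg$build$n_peptides)
  }

  params <- NULL
  if ("simulate" %in% cfg$stages) {
    sim_args <- cfg$simulate %||% list()
    if (!is.null(sim_args$probe)) {
      sim_args$probe <- do.call(probe_spec, sim_args$probe)
    }
    sim_args$seed <- cfg$seed
    tensile <- sim_args$tensile
    sim_args$tensile <- NULL
    params <- do.call(synthetic_params, sim_args)
    if (force || !file.exists(paths$traj)) {
      write_coordinates(simulate_brush(params), paths$traj)
    }
    manifest$stages$simulate <- list(output = paths$traj,
                                     n_chains = params$n_chains,
                                     n_steps = params$n_steps,
                                     duration_ps = params$n_steps * params$timestep,
                                     interchain_attraction = params$interchain_attraction)
    if (!is.null(tensile)) {
      pp <- params
      pp$pull_acceleration <- tensile$pull_acceleration %||% 0.01
      if (force || !file.exists(paths$tensile)) {
        write_coordinates(simulate_brush(pp), paths$tensile)
      }
      manifest$stages$simulate$tensile_output <- paths$tensile
      manifest$stages$simulate$pull_acceleration <- pp$pull_acceleration
    }
  }

  if ("analyze" %in% cfg$stages) {
    an <- cfg$analyze
    traj_path <- cfg$trajectory %||% paths$traj
    if (!file.exists(traj_path)) {
      stop("analyze stage: no trajectory at ", traj_path,
           " (run the simulate stage or set config$trajectory)")
    }
    traj <- read_coordinates(traj_path)
    window <- if (!is.null(an$window_ns)) last_window(traj, an$window_ns)
    metrics <- .analyze_trajectory(traj, an, window)
    if (file.exists(paths$tensile)) {
      pulled <- read_coordinates(paths$tensile)
      pw <- if (!is.null(an$window_ns)) last_window(pulled, an$window_ns)
      pep <- select_atoms(traj$topology, moiety = "peptide")
      before <- density_profile(traj, pep, window, an$slice_width)
      after <- density_profile(pulled, select_atoms(pulled$topology,
                                                    moiety = "peptide"),
                               pw, an$slice_width)
      metrics$tensile_shift_nm <- density_centroid_shift(before, after)
    }
    jsonlite::write_json(metrics, paths$metrics, auto_unbox = TRUE,
                         digits = NA)
    profile <- density_profile(traj, window = window,
                               slice_width = an$slice_width,
                               group_by = "moiety")
    write.csv(as.data.frame(profile),
              file.path(outdir, "density_profile.csv"), row.names = FALSE)
    manifest$stages$analyze <- list(metrics = paths$metrics,
                                    profile = file.path(outdir,
                                                        "density_profile.csv"),
                                    window = window %||% "all")
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

# observable set for one trajectory
.analyze_trajectory <- function(traj, an, window) {
  top <- traj$topology
  m <- list()
  sw <- switch_params(r0 = an$r0)
  n_pep <- length(unique(top$peptide_index[top$peptide_index > 0]))
  if (n_pep >= 2) {
    s <- s_function(traj, p = sw, window = window)
    m$s_norm_mean <- mean(s)
    m$s_norm_sd <- if (length(s) > 1) sd(s) else 0
  }
  idxs <- frames_in_window(traj, window)
  mid_frames <- idxs[unique(round(seq(1, length(idxs),
                                      length.out = min(5, length(idxs)))))]
  pep_heavy <- select_atoms(top, moiety = "peptide", heavy_only = TRUE)
  for (pr in an$probes) {
    key <- sprintf("sasa_per_peptide_probe%s", gsub("\\.", "p", pr))
    vals <- vapply(mid_frames, function(k) {
      mean(sasa(traj$frames[[k]], top, pep_heavy, pr)$per_peptide)
    }, numeric(1))
    m[[key]] <- mean(vals)
  }
  prot <- select_atoms(top, moiety = "protein", heavy_only = TRUE)
  if (length(prot)) {
    mono <- select_atoms(top, moiety = c("linker", "peptide"),
                         heavy_only = TRUE)
    cc <- close_contacts(traj, mono, prot, an$contact_cutoff, window)
    m$close_contacts_mean <- cc$mean
    m$close_contacts_sd <- cc$sd
    m$close_contacts_per_peptide <- cc$mean / max(1, n_pep)
    spots <- active_spots()
    spot_atoms <- prot[top$residue_name[prot] %in% spots$name]
    if (length(spot_atoms)) {
      asc <- close_contacts(traj, pep_heavy, spot_atoms,
                            an$contact_cutoff, window)
      m$active_spot_contacts_mean <- asc$mean
      m$active_spot_contacts_sd <- asc$sd
      pm <- persistence_map(traj, spots, an$contact_cutoff, window)
      m$persistence_total_ns <- sum(pm$values)
    }
  }
  profile <- density_profile(traj, select_atoms(top, moiety = "peptide"),
                             window, an$slice_width)
  m$threshold_distance_nm <- suppressWarnings(
    threshold_distance(profile, an$threshold_density))
  m$centroid_z_nm <- sum(profile$z_centers * profile$density[, 1]) /
    sum(profile$density[, 1])
  hm <- height_map(traj$frames[[idxs[length(idxs)]]], top,
                   grid_resolution = an$grid_resolution,
                   depth_threshold = an$depth_threshold)
  m$max_pocket_depth_nm <- if (nrow(hm$pockets)) max(hm$pockets$depth) else 0
  m
}

#' Compare several pipeline runs
#'
#' Merges the metrics of a set of run manifests into one table, one row
#' per system, for side-by-side comparison (S score, SASA, contacts,
#' persistence, profile descriptors).
#'
#' @param manifests character vector of `manifest.json` paths, or a list
#'   of manifests as returned by [run_pipeline()].
#' @return data.frame, one row per run.
#' @export
pipeline_report <- function(manifests) {
  if (!length(manifests)) stop("need at least one manifest")
  rows <- lapply(manifests, function(mf) {
    if (is.character(mf)) mf <- jsonlite::read_json(mf, simplifyVector = TRUE)
    mpath <- mf$stages$analyze$metrics
    if (is.null(mpath) || !file.exists(mpath)) {
      stop("manifest for system '", mf$system, "' has no analyze metrics")
    }
    met <- jsonlite::read_json(mpath, simplifyVector = TRUE)
    data.frame(system = mf$system, seed = mf$seed,
               as.data.frame(met[vapply(met, is.numeric, logical(1))]),
               stringsAsFactors = FALSE)
  })
  wins <- lapply(manifests, function(mf) {
    if (is.character(mf)) mf <- jsonlite::read_json(mf, simplifyVector = TRUE)
    mf$stages$analyze$window
  })
  lens <- vapply(wins, function(w) {
    if (is.character(w) || is.null(w)) -1 else diff(as.numeric(w))
  }, numeric(1))
  if (length(unique(lens)) > 1L) {
    stop("runs use analysis windows of different lengths; re-analyze with ",
         "a common window before comparing")
  }
  cols <- Reduce(union, lapply(rows, names))
  do.call(rbind, lapply(rows, function(r) {
    r[setdiff(cols, names(r))] <- NA
    r[cols]
  }))
}

#' Export a persistence map as a CSV matrix
#'
#' @param map a [persistence_map()].
#' @param path output CSV.
#' @return the path, invisibly.
#' @export
write_persistence_csv <- function(map, path) {
  write.csv(as.data.frame(map$values), path, row.names = TRUE)
  invisible(path)
}
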