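#' Deterministic per-stage seed derivation
#'
#' Splits one master seed into independent stage seeds so that every
#' pipeline stage draws from its own reproducible stream. Stays below
#' 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param stage Stage name (character).
#' @return Integer seed.
#' @export
split_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((abs(as.numeric(seed)) %% 1e6 * 20011 + h) %% 2147483647)
}

#' Default pipeline configuration
#'
#' All tunables of the synthetic -> detect -> geometry -> quantify -> fit
#' -> expression pipeline in one explicit list; any element can be
#' overridden, and the whole list round-trips through YAML.
#'
#' @param seed Master seed.
#' @return A \code{pipeline_config} list.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    profile = list(sigma = 4, half_width = 9),
    activation = list(p_mid = 1 / 15, T_min = 15, n_nuclei_per_column = 6,
                      alleles_per_nucleus = 2),
    render = list(shape = c(256, 96, 16), psf_sigma = c(1.3, 1.3, 1.6),
                  unit_intensity = 400, ratio_ts = 70, spacing = 12,
                  nucleus_radius = 4.5, n_nuclei_per_column = 6,
                  mrna_per_column = 10, shot_noise = TRUE,
                  read_noise_sd = 1, background = 2, packing_limit = 4),
    detection = list(radius = 5, size_2d = 15, sigma_2d = 2.5, size_3d = 9,
                     sigma_3d = c(1.3, 1.3, 1.6)),
    model = list(T_min = 15),
    genes = list(v_kb_per_min = 2)
  ), class = "pipeline_config")
}

validate_config <- function(config) {
  known <- names(default_config())
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  if (is.null(config$seed)) stop("config must carry a seed")
  config
}

write_atomic_csv <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  path
}

log_event <- function(log_path, stage, seed, files) {
  rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stage = stage, seed = seed,
              package_version = as.character(utils::packageVersion("gradedTS")),
              files = as.list(files))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE, sep = "")
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate-embryo} (synthetic profile, activation table and
#' rendered stacks + ground truth), \code{detect-spots} (3D detection on
#' the rendered smFISH channel), \code{geometry} (midline, column spacing,
#' column/nucleus assignment), \code{quantify} (classification, column
#' summaries), \code{fit-activation}, \code{simulate-expression}
#' (accumulation + probe patterns). Outputs are CSV/TIFF/YAML files
#' written atomically into \code{out_dir}; a JSON-lines log records stage,
#' seed and files. Dependent stages read their upstream files and fail
#' with the missing path named.
#'
#' @param stage Stage name (see above).
#' @param config A \code{pipeline_config} (see [default_config()]).
#' @param out_dir Output directory.
#' @return Named vector of written file paths, invisibly.
#' @export
run_stage <- function(stage, config = default_config(), out_dir = ".") {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log.jsonl")
  need <- function(path) {
    if (!file.exists(path))
      stop("missing upstream output: ", path,
           " (run the earlier stage first)")
    path
  }
  files <- c()

  if (stage == "simulate-embryo") {
    prof <- make_dorsal_profile(config$profile$sigma,
                                config$profile$half_width)
    acfg <- activation_config(config$activation$p_mid,
                              config$activation$T_min,
                              config$activation$n_nuclei_per_column,
                              config$activation$alleles_per_nucleus,
                              seed = split_seed(config$seed, "activation"))
    act <- simulate_activation(prof, acfg)
    rc <- do.call(render_config,
                  c(config$render, list(seed = split_seed(config$seed,
                                                          "render"))))
    emb <- render_embryo(act, prof, rc)
    files <- write_fixture(emb, out_dir)
    files["profile"] <- write_atomic_csv(prof,
                                         file.path(out_dir, "profile.csv"))
    files["activation"] <- write_atomic_csv(act,
                                            file.path(out_dir,
                                                      "activation.csv"))
    files["nuclei"] <- write_atomic_csv(emb$nuclei,
                                        file.path(out_dir, "nuclei.csv"))
    geom <- data.frame(midline_px = emb$geometry$midline_y,
                       spacing_px = emb$geometry$spacing, axis = "y")
    files["geometry"] <- write_atomic_csv(geom,
                                          file.path(out_dir,
                                                    "geometry_true.csv"))
  } else if (stage == "detect-spots") {
    need(file.path(out_dir, "fish.tif"))
    stack <- read_fixture(out_dir)$stacks$fish
    det <- detect_spots_3d(stack, radius = config$detection$radius,
                           size = config$detection$size_3d,
                           sigma = config$detection$sigma_3d)
    files["spots"] <- write_atomic_csv(det$spots,
                                       file.path(out_dir, "spots.csv"))
    files["scan"] <- write_atomic_csv(det$scan$scan,
                                      file.path(out_dir,
                                                "threshold_scan.csv"))
  } else if (stage == "geometry") {
    spots <- read.csv(need(file.path(out_dir, "spots.csv")))
    need(file.path(out_dir, "dapi.tif"))
    fx <- read_fixture(out_dir)
    dapi <- fx$stacks$dapi
    fish <- fx$stacks$fish
    mid <- find_midline(project_max(fish))
    sp <- estimate_column_spacing(project_max(dapi))
    geom <- embryo_geometry(mid, sp$spacing)
    spots <- assign_columns(spots, geom)
    files["spots"] <- write_atomic_csv(spots,
                                       file.path(out_dir, "spots.csv"))
    files["geometry"] <- write_atomic_csv(
      data.frame(midline_px = mid, spacing_px = sp$spacing, axis = "y"),
      file.path(out_dir, "geometry.csv"))
  } else if (stage == "quantify") {
    spots <- read.csv(need(file.path(out_dir, "spots.csv")))
    cls <- classify_spots(spots)
    files["classified"] <- write_atomic_csv(
      cls$spots, file.path(out_dir, "spots_classified.csv"))
    nuc <- read.csv(need(file.path(out_dir, "nuclei.csv")))
    ts <- cls$spots[cls$spots$class == "TS", ]
    asg <- assign_nuclei(ts, nuc)
    summ <- summarize_columns(asg$spots, nuc)
    files["summary"] <- write_atomic_csv(summ,
                                         file.path(out_dir, "columns.csv"))
    files["classification"] <- {
      p <- file.path(out_dir, "classification.json")
      jsonlite::write_json(list(cutoff = cls$cutoff, ratio = cls$ratio,
                                polII = cls$polII,
                                median_mrna = cls$median_mrna,
                                median_ts = cls$median_ts),
                           p, auto_unbox = TRUE, digits = NA)
      p
    }
  } else if (stage == "fit-activation") {
    summ <- read.csv(need(file.path(out_dir, "columns.csv")))
    prof <- read.csv(need(file.path(out_dir, "profile.csv")))
    class(prof) <- c("dorsal_profile", "data.frame")
    fit <- fit_activation(summ, prof, config$model$T_min)
    files["fit"] <- write_atomic_csv(fit$table,
                                     file.path(out_dir, "activation_fit.csv"))
    files["fit_summary"] <- {
      p <- file.path(out_dir, "activation_fit.json")
      jsonlite::write_json(list(T_min = fit$T_min,
                                r_fraction = fit$r_fraction,
                                r_probability = fit$r_probability),
                           p, auto_unbox = TRUE, digits = NA)
      p
    }
  } else if (stage == "simulate-expression") {
    prof <- read.csv(need(file.path(out_dir, "profile.csv")))
    class(prof) <- c("dorsal_profile", "data.frame")
    sims <- rbind(
      simulate_accumulation(prof, config$activation$p_mid,
                            config$model$T_min, loading = "constant"),
      simulate_accumulation(prof, config$activation$p_mid,
                            config$model$T_min, loading = "graded"))
    files["expression"] <- write_atomic_csv(
      sims, file.path(out_dir, "expression_sim.csv"))
    pat <- simulate_probe_pattern(prof, config$activation$p_mid,
                                  seed = split_seed(config$seed, "probes"))
    files["probes"] <- write_atomic_csv(
      pat, file.path(out_dir, "probe_pattern.csv"))
  } else if (stage == "report") {
    summ <- read.csv(need(file.path(out_dir, "columns.csv")))
    prof <- read.csv(need(file.path(out_dir, "profile.csv")))
    spots <- read.csv(need(file.path(out_dir, "spots_classified.csv")))
    sims <- read.csv(need(file.path(out_dir, "expression_sim.csv")))
    p <- file.path(out_dir, "report.png")
    grDevices::png(p, width = 1400, height = 1000, res = 120)
    graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    # TS counts and active fraction along the mesoderm vs Dorsal
    graphics::plot(summ$column, summ$f_hat, type = "b", pch = 16,
                   xlab = "nuclear column", ylab = "active allele fraction",
                   main = "TS activation along the DV axis", ylim = c(0, 1))
    graphics::lines(prof$column, prof$level, lty = 2)
    # per-nucleus TS count histogram stacked by column
    graphics::matplot(summ$column, cbind(summ$n0, summ$n1, summ$n2),
                      type = "b", pch = 1:3, lty = 1,
                      xlab = "nuclear column", ylab = "nuclei",
                      main = "TS per nucleus (0/1/2)")
    # spot intensity histogram (TS vs mRNA)
    graphics::hist(log10(spots$cum_int[spots$cum_int > 0]), breaks = 40,
                   xlab = "log10 cumulative intensity", main =
                     "spot intensities: single mRNAs vs TSs")
    # simulated accumulation, constant vs graded loading
    fin <- sims[sims$t == max(sims$t), ]
    graphics::plot(fin$column[fin$loading == "constant"],
                   fin$M[fin$loading == "constant"], type = "b", pch = 16,
                   xlab = "nuclear column", ylab = "accumulated mRNA",
                   main = "simulated mRNA accumulation")
    graphics::lines(fin$column[fin$loading == "graded"],
                    fin$M[fin$loading == "graded"], type = "b", pch = 1)
    grDevices::dev.off()
    files["report"] <- p
  } else {
    stop("unknown stage: ", stage)
  }
  log_event(log_path, stage, config$seed, files)
  invisible(files)
}

#' Run the full pipeline end to end
#'
#' @param config A \code{pipeline_config}.
#' @param out_dir Output directory.
#' @param stages Stages to run, in order.
#' @return Named vector of all written files, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir = ".",
                         stages = c("simulate-embryo", "detect-spots",
                                    "geometry", "quantify",
                                    "fit-activation",
                                    "simulate-expression")) {
  all_files <- c()
  for (s in stages) all_files <- c(all_files, run_stage(s, config, out_dir))
  invisible(all_files)
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file written by [yaml::write_yaml()] of a config list.
#' @return A validated \code{pipeline_config}.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config(seed = if (!is.null(cfg$seed)) cfg$seed else 1L)
  for (k in names(cfg)) base[[k]] <- utils::modifyList(
    if (is.list(base[[k]])) base[[k]] else list(), as.list(cfg[[k]]))
  base$seed <- as.integer(cfg$seed %||% 1L)
  validate_config(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
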