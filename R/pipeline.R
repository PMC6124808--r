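log_line <- function(msg, logfile = NULL) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " | ", msg)
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
  invisible(line)
}

config_hash <- function(config) {
  raw <- charToRaw(paste(deparse(config), collapse = ""))
  sprintf("%08x", sum(as.integer(raw) * seq_along(raw)) %% .Machine$integer.max)
}

#' Run the analysis pipeline
#'
#' Executes the stages in dependency order on a synthetic experiment (or
#' previously synthesised data in `out_dir`): `synth` (generate and write
#' the experiment), `features` (sliding spectra, delay-delay matrix,
#' windowed MAR cross-spectra), `baseline` (factorial architecture
#' comparison; requires the full 5-pair region set), `invert` (windowed
#' DCM inversions, archived to HDF5), `peb` (second-level model and family
#' comparisons), `map` (PCA projection and band-power surfaces for the hub
#' region).  Every stage logs its seed, the config hash and resulting free
#' energies; deterministic stages reproduce F bitwise on identical config.
#'
#' @param design An [experiment_design()].
#' @param out_dir Output directory (created).
#' @param config Package configuration.
#' @param stages Character subset of
#'   `c("synth", "features", "baseline", "invert", "peb", "map")`.
#' @param map_grid_n Score-grid resolution for the `map` stage.
#' @return Named list of per-stage outputs (invisibly written to
#'   `out_dir`).
#' @export
run_pipeline <- function(design, out_dir,
                         config = default_config(),
                         stages = c("synth", "features", "baseline",
                                    "invert", "peb", "map"),
                         map_grid_n = 15) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  gmax <- config$features$grid
  if (gmax$hi_hz > design$fs_hz / 2)
    stop("config invalid: empirical frequency grid exceeds the data Nyquist")
  write_config(config, file.path(out_dir, "config.yaml"))
  log_line(paste0("config hash ", config_hash(config), ", seed ", design$seed),
           logfile)
  out <- list()
  done <- character(0)
  run_stage <- function(name, fun) {
    log_line(paste("stage", name, "start"), logfile)
    res <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (completed stages: ", paste(done, collapse = ", "), ")",
           call. = FALSE)
    })
    done <<- c(done, name)
    log_line(paste("stage", name, "done"), logfile)
    res
  }

  if ("synth" %in% stages) {
    out$synth <- run_stage("synth", function() {
      ex <- generate_experiment(design, config)
      for (fi in seq_along(ex$fish)) {
        write_timeseries(ex$fish[[fi]]$data, design$fs_hz,
                         file.path(out_dir, sprintf("fish%02d.tsv", fi)),
                         time_s = ex$fish[[fi]]$time_s)
        gt <- ex$fish[[fi]]$ground_truth
        yaml::write_yaml(list(seed = design$seed,
                              segment_times = gt$segment_times,
                              clip = gt$clip,
                              offsets = as.list(gt$offsets),
                              true_beta = apply(ex$true_beta, 1, as.list)),
                         file.path(out_dir,
                                   sprintf("fish%02d_truth.yaml", fi)))
      }
      ex
    })
  }
  series <- if (!is.null(out$synth)) {
    lapply(out$synth$fish, function(f) {
      x <- f$data
      attr(x, "fs") <- design$fs_hz
      x
    })
  } else {
    paths <- sort(list.files(out_dir, "^fish[0-9]+\\.tsv$", full.names = TRUE))
    if (length(paths) == 0) stop("no synthesised data found in ", out_dir)
    lapply(paths, read_timeseries)
  }

  grid <- frequency_grid(gmax$lo_hz, gmax$hi_hz, gmax$by_hz)
  if ("features" %in% stages) {
    out$features <- run_stage("features", function() {
      lapply(seq_along(series), function(fi) {
        x <- series[[fi]]
        ss <- sliding_spectra(x, design$fs_hz,
                              windowing_scheme(config$features$spectra_window$length_s,
                                               config$features$spectra_window$step_s))
        R <- power_corr_matrix(ss, config$features$band_hz)
        write_table_meta(
          as.data.frame(round(R, 6)),
          file.path(out_dir, sprintf("fish%02d_delaydelay.tsv", fi)),
          meta = c(fish = fi,
                   band_hz = paste(config$features$band_hz, collapse = "-"),
                   window_length_s = config$features$spectra_window$length_s,
                   window_step_s = config$features$spectra_window$step_s))
        wsch <- windowing_scheme(config$features$dcm_window$length_s,
                                 config$features$dcm_window$step_s)
        starts <- window_starts(ncol(x), design$fs_hz, wsch)
        len <- round(wsch$length_s * design$fs_hz)
        csds <- lapply(starts, function(s)
          mar_csd(x[, s:(s + len - 1), drop = FALSE], design$fs_hz,
                  config$features$mar_order, grid))
        attr(csds, "window_times") <- (starts - 1) / design$fs_hz +
          wsch$length_s / 2
        list(spectra = ss, delay_delay = R, csds = csds)
      })
    })
  }
  if ("baseline" %in% stages) {
    if (length(design$regions$pairs) != 5) {
      log_line("stage baseline skipped (needs the 5-pair region set)", logfile)
    } else {
      out$baseline <- run_stage("baseline", function() {
        # average CSD over pre-onset windows and fish
        pre <- lapply(out$features, function(f) {
          wt <- attr(f$csds, "window_times")
          f$csds[wt + config$features$dcm_window$length_s / 2 <=
                   design$ptz_onset_s]
        })
        pre <- unlist(pre, recursive = FALSE)
        if (length(pre) == 0) stop("no pre-onset windows for baseline stage")
        avg <- Reduce(`+`, lapply(pre, function(cs) cs$csd)) / length(pre)
        data <- cross_spectrum(grid, avg, validate = FALSE)
        ba <- baseline_architecture(data, design$regions, config,
                                    a_value = design$baseline_coupling)
        tab <- data.frame(
          id = vapply(ba$models, `[[`, integer(1), "id"),
          hub = vapply(ba$models, `[[`, character(1), "hub"),
          neighbouring = vapply(ba$models, `[[`, logical(1), "neighbouring"),
          homotopic = vapply(ba$models, `[[`, logical(1), "homotopic"),
          F = ba$F)
        write_table_meta(tab, file.path(out_dir, "baseline_models.tsv"),
                         meta = c(config = config_hash(config)))
        log_line(paste("baseline best architecture id",
                       tab$id[which.max(tab$F)]), logfile)
        ba
      })
    }
  }
  if ("invert" %in% stages) {
    out$invert <- run_stage("invert", function() {
      m0 <- design_network(design, config)
      prior <- network_priors(m0, config)
      lapply(seq_along(out$features), function(fi) {
        wi <- invert_windows(m0, out$features[[fi]]$csds, prior, config)
        save_inversions(wi, file.path(out_dir,
                                      sprintf("fish%02d_inversions.h5", fi)))
        log_line(sprintf("fish %d: aggregate variance explained %.3f", fi,
                         wi$variance_explained), logfile)
        wi
      })
    })
  }
  if ("peb" %in% stages) {
    out$peb <- run_stage("peb", function() {
      all_results <- unlist(lapply(out$invert, `[[`, "results"),
                            recursive = FALSE)
      times <- unlist(lapply(out$invert, `[[`, "window_times"))
      fish_ids <- rep(seq_along(out$invert),
                      vapply(out$invert, function(w) length(w$results),
                             integer(1)))
      basis <- build_basis(times, design$ptz_onset_s, fish_ids, config)
      regions <- design$regions
      intrinsic <- as.character(outer(regions$names,
                                      c(paste0("h", 1:5), "t_e", "t_i"),
                                      paste, sep = "."))
      m0 <- design_network(design, config)
      prior_names <- names(network_priors(m0, config)$mean)
      fwd <- grep("^fwd\\.", prior_names, value = TRUE)
      bwd <- grep("^bwd\\.", prior_names, value = TRUE)
      gp <- peb_fit(all_results, basis, c(intrinsic, fwd, bwd), config)
      fams_ext <- list(`0` = character(0), F = fwd, B = bwd, FB = c(fwd, bwd))
      cmp_ext <- list(F = vapply(fams_ext, function(fam)
        peb_reduce(gp, effect_mask(gp, c(intrinsic, fam))), numeric(1)))
      cmp_ext$probabilities <- exp(cmp_ext$F - log_sum_exp(cmp_ext$F))
      fams_int <- c(list(`0` = character(0)),
                    stats::setNames(lapply(regions$pairs, function(p) {
                      rn <- regions$names[regions$pair_index ==
                                            match(p, regions$pairs)]
                      as.character(outer(rn, c(paste0("h", 1:5), "t_e", "t_i"),
                                         paste, sep = "."))
                    }), regions$pairs),
                    list(all = intrinsic))
      cmp_int <- list(F = vapply(fams_int, function(fam)
        peb_reduce(gp, effect_mask(gp, fam)), numeric(1)))
      cmp_int$probabilities <- exp(cmp_int$F - log_sum_exp(cmp_int$F))
      eff <- data.frame(
        parameter = rep(colnames(gp$beta), each = nrow(gp$beta)),
        regressor = rep(rownames(gp$beta), ncol(gp$beta)),
        effect = as.vector(gp$beta),
        sd = sqrt(diag(robust_inv(gp$pieces$A + diag(1 / gp$vb,
                                                     length(gp$vb))))))
      write_table_meta(eff, file.path(out_dir, "peb_effects.tsv"),
                       meta = c(F_group = gp$F_group, gamma = gp$gamma))
      log_line(sprintf("PEB F_group %.2f; extrinsic winner %s; intrinsic winner %s",
                       gp$F_group, names(which.max(cmp_ext$F)),
                       names(which.max(cmp_int$F))), logfile)
      list(fit = gp, basis = basis, extrinsic = cmp_ext, intrinsic = cmp_int)
    })
  }
  if ("map" %in% stages) {
    out$map <- run_stage("map", function() {
      gp <- out$peb$fit
      hub_region <- design$regions$names[1]
      pn <- paste0(hub_region, ".", c(paste0("h", 1:5), "t_e", "t_i"))
      means <- t(vapply(gp$updated, function(u) u$mean[pn],
                        numeric(length(pn))))
      colnames(means) <- c(paste0("h", 1:5), "t_e", "t_i")
      wt <- unlist(lapply(out$invert, `[[`, "window_times"))
      ok <- vapply(unlist(lapply(out$invert, `[[`, "results"),
                          recursive = FALSE),
                   function(r) is.null(r$failed), logical(1))
      traj <- parameter_trajectory(wt[ok], means)
      pca <- pca_project(traj)
      base <- source_params(h = pca$gains$center,
                            t_e = pca$time_constants$center[["t_e"]],
                            t_i = pca$time_constants$center[["t_i"]])
      sd1 <- max(stats::sd(pca$gains$scores[, 1]), 0.05)
      sd2 <- max(stats::sd(pca$time_constants$scores[, 1]), 0.05)
      ng <- map_grid_n
      k <- config$mapping$score_grid_sd
      map <- band_power_map(base, pca$gains$loadings[, 1],
                            pca$time_constants$loadings[, 1],
                            seq(-k * sd1, k * sd1, length.out = ng),
                            seq(-k * sd2, k * sd2, length.out = ng),
                            config = config)
      path <- trajectory_overlay(cbind(pca$gains$scores[, 1],
                                       pca$time_constants$scores[, 1]),
                                 traj$window_times, map)
      utils::write.table(path, file.path(out_dir, "trajectory.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      for (b in names(map$surfaces))
        utils::write.table(round(map$surfaces[[b]], 6),
                           file.path(out_dir, paste0("map_", b, ".tsv")),
                           sep = "\t", row.names = FALSE, col.names = FALSE)
      grDevices::png(file.path(out_dir, "band_map.png"), 700, 600)
      plot_band_map(map, path)
      grDevices::dev.off()
      list(pca = pca, map = map, path = path)
    })
  }
  log_line(paste("pipeline complete:", paste(done, collapse = " -> ")),
           logfile)
  invisible(out)
}
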