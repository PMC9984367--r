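#' Default pipeline configuration
#'
#' Flat list of the keys understood by [run_simulate()] and [run_analyze()],
#' with the package defaults. Pass a modified copy, or a YAML file with the
#' same keys, to the entry points.
#'
#' @return Named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "graintex-demo",
    pixel_scale_um = 0.5,
    texture_size_px = 256L,
    texture_hurst = c(0.3, 0.5, 0.7),
    anisotropy_lengths = list(c(8, 8), c(4, 16)),
    packing_counts = list(c(A = 2, B = 10, C = 50), c(A = 1, B = 8, C = 30)),
    packing_size_px = 384L,
    psd_modes = list(c(25, 1.6, 0.45), c(130, 1.4, 0.55)),
    binarize.method = "otsu",
    binarize.threshold = NA,
    binarize.polarity = "bright",
    fractal.fit_min_px = 2,
    acf.window = "none",
    str.threshold = 0.2,
    stats.alpha = 0.05,
    stats.enabled = TRUE
  )
}

load_config <- function(config) {
  base <- default_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  base[names(config)] <- config
  base
}

config_stamp <- function(cfg) {
  sprintf("# graintex seed=%d config_hash=%s", cfg$seed,
          substr(digest_config(cfg), 1, 12))
}

digest_config <- function(cfg) {
  cfg$out_dir <- NULL   # hash the scientific settings, not the location
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(cfg[order(names(cfg))], file = tf)
  unname(tools::md5sum(tf))
}

write_csv_stamped <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_stamp(cfg), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Generate the demo synthetic dataset
#'
#' Writes a reproducible synthetic dataset to disk: self-affine and
#' anisotropic texture fields (16-bit PNG plus a YAML sidecar carrying pixel
#' scale and generator ground truth), granule packings with exact
#' ground-truth tables, one bimodal particle-size histogram, a kernel
#' silhouette, and a manifest listing every artifact with its generator
#' parameters. Deterministic for a fixed config (including seed).
#'
#' @param config a config list (see [default_config()]) or path to a YAML
#'   file; missing keys take the defaults.
#' @return The manifest data frame, invisibly; files under `config$out_dir`.
#' @export
run_simulate <- function(config = NULL) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  add <- function(file, kind, params) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      file = file, kind = kind, params = params,
      md5 = unname(tools::md5sum(file.path(cfg$out_dir, file))))
  }
  sidecar <- function(file, meta) {
    yaml::write_yaml(meta, file.path(cfg$out_dir, paste0(file, ".meta.yml")))
  }
  norm01 <- function(v) (v - min(v)) / (max(v) - min(v))

  i <- 0
  for (h in cfg$texture_hurst) {
    i <- i + 1
    hf <- fbm_surface(cfg$texture_size_px, h, cfg$pixel_scale_um,
                      seed = cfg$seed + i)
    f <- sprintf("texture_fbm_H%02.0f.tif", 100 * h)
    write_image(height_field(norm01(hf$values), hf$pixel_scale),
                file.path(cfg$out_dir, f))
    sidecar(f, c(list(pixel_scale_um = cfg$pixel_scale_um, seed = cfg$seed + i),
                 attr(hf, "ground_truth")))
    add(f, "texture_fbm", sprintf("hurst=%g seed=%d", h, cfg$seed + i))
  }
  for (len in cfg$anisotropy_lengths) {
    i <- i + 1
    hf <- anisotropic_field(cfg$texture_size_px, len, cfg$pixel_scale_um,
                            seed = cfg$seed + i)
    f <- sprintf("texture_aniso_%g_%g.tif", len[1], len[2])
    write_image(height_field(norm01(hf$values), hf$pixel_scale),
                file.path(cfg$out_dir, f))
    gt <- attr(hf, "ground_truth")
    sidecar(f, list(pixel_scale_um = cfg$pixel_scale_um, seed = cfg$seed + i,
                    lengths = as.numeric(len), Str_true = gt$Str_true))
    add(f, "texture_aniso",
        sprintf("lengths=%g,%g seed=%d", len[1], len[2], cfg$seed + i))
  }
  for (k in seq_along(cfg$packing_counts)) {
    i <- i + 1
    cts <- unlist(cfg$packing_counts[[k]])
    if (is.null(names(cts))) names(cts) <- c("A", "B", "C")
    pk <- granule_packing(cts, cfg$packing_size_px, cfg$pixel_scale_um,
                          seed = cfg$seed + i)
    f <- sprintf("packing_%d.png", k)
    write_image(height_field(pk$image$mask * 1, cfg$pixel_scale_um),
                file.path(cfg$out_dir, f))
    gt_file <- sprintf("packing_%d_truth.csv", k)
    write_csv_stamped(pk$granules, file.path(cfg$out_dir, gt_file), cfg)
    sidecar(f, list(pixel_scale_um = cfg$pixel_scale_um, seed = cfg$seed + i,
                    counts = as.list(cts), solid_fraction = pk$solid_fraction))
    add(f, "packing", sprintf("A=%d B=%d C=%d seed=%d",
                              cts[["A"]], cts[["B"]], cts[["C"]],
                              cfg$seed + i))
    add(gt_file, "packing_truth", sprintf("packing=%d", k))
  }
  psd <- psd_mixture(cfg$psd_modes)
  write_csv_stamped(psd, file.path(cfg$out_dir, "psd.csv"), cfg)
  gt <- attr(psd, "ground_truth")
  sidecar("psd.csv", gt)
  add("psd.csv", "psd", sprintf("modes=%d", length(cfg$psd_modes)))

  sil <- kernel_silhouette(8, 4, pixel_scale_mm = 0.02)
  write_image(height_field(sil$mask * 1, 0.02),
              file.path(cfg$out_dir, "kernel_silhouette.png"))
  sidecar("kernel_silhouette.png",
          c(list(pixel_scale_mm = 0.02), attr(sil, "ground_truth")))
  add("kernel_silhouette.png", "silhouette", "L=8 W=4 mm")

  man <- do.call(rbind, manifest)
  write_csv_stamped(man, file.path(cfg$out_dir, "manifest.csv"), cfg)
  invisible(man)
}

#' Analyze a simulated (or configured) dataset
#'
#' Runs the full analysis chain on the dataset written by [run_simulate()]:
#' texture metrics (Str, D, K, tau_c, Sq) for every texture field, watershed +
#' classification + Minkowski summary for every packing, shape descriptors
#' for the kernel silhouette, and the particle-size summary; optionally a
#' statistics block comparing recovered granule areas across packings. Each
#' stage writes its own CSV; a failure aborts with the stage name while
#' earlier outputs are preserved.
#'
#' @param config the config used for [run_simulate()] (list or YAML path).
#' @return Named list of the per-stage result data frames, invisibly; CSVs
#'   under `file.path(config$out_dir, "results")`.
#' @export
run_analyze <- function(config = NULL) {
  cfg <- load_config(config)
  res_dir <- file.path(cfg$out_dir, "results")
  dir.create(res_dir, showWarnings = FALSE, recursive = TRUE)
  man <- read.csv(file.path(cfg$out_dir, "manifest.csv"), comment.char = "#")
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  tex_files <- man$file[man$kind %in% c("texture_fbm", "texture_aniso")]
  results$texture <- stage("fractal", {
    rows <- lapply(tex_files, function(f) {
      hf <- read_image(file.path(cfg$out_dir, f), cfg$pixel_scale_um)
      tm <- texture_metrics(hf, window = cfg$acf.window,
                            threshold = cfg$str.threshold,
                            fit_min_px = cfg$fractal.fit_min_px)
      data.frame(file = f, Str = tm$Str, D = tm$D, K = tm$K,
                 tau_c_um = tm$tau_c_um, Sq = tm$Sq,
                 r_squared = tm$r_squared, monofractal = tm$monofractal)
    })
    do.call(rbind, rows)
  })
  write_csv_stamped(results$texture, file.path(res_dir, "texture_metrics.csv"),
                    cfg)

  pack_files <- man$file[man$kind == "packing"]
  results$morphology <- stage("morphology", {
    rows <- lapply(seq_along(pack_files), function(k) {
      hf <- read_image(file.path(cfg$out_dir, pack_files[k]),
                       cfg$pixel_scale_um)
      bi <- binary_image(hf$values > 0.5, cfg$pixel_scale_um)
      em <- endosperm_morphology(bi)
      ts <- em$type_summary
      write_csv_stamped(em$granules,
                        file.path(res_dir, sprintf("granules_%d.csv", k)), cfg)
      data.frame(file = pack_files[k],
                 n_granules = nrow(em$granules),
                 count_A = ts$count[1], count_B = ts$count[2],
                 count_C = ts$count[3],
                 V = em$minkowski$V, S = em$minkowski$S,
                 chi_e3 = em$minkowski$chi_e3,
                 coverage_rate_um2 = em$coverage_rate_um2,
                 area_mean_um2 = em$area_mean_um2)
    })
    do.call(rbind, rows)
  })
  write_csv_stamped(results$morphology,
                    file.path(res_dir, "morphology_summary.csv"), cfg)

  results$geometry <- stage("geometry", {
    hf <- read_image(file.path(cfg$out_dir, "kernel_silhouette.png"), 1)
    sm <- silhouette_measure(binary_image(hf$values > 0.5, 0.02))
    data.frame(A_mm2 = sm$A, P_mm = sm$P, L_mm = sm$L, W_mm = sm$W,
               Rs = sm$Rs, Rc = sm$Rc)
  })
  write_csv_stamped(results$geometry,
                    file.path(res_dir, "shape_descriptors.csv"), cfg)

  results$flour <- stage("flour", {
    psd <- read.csv(file.path(cfg$out_dir, "psd.csv"), comment.char = "#")
    ps <- psd_summary(psd$size_um, psd$volume_fraction)
    data.frame(d10 = ps$d10, d50 = ps$d50, d90 = ps$d90,
               d_avg = ps$d_avg, span = ps$span)
  })
  write_csv_stamped(results$flour, file.path(res_dir, "psd_summary.csv"), cfg)

  if (isTRUE(cfg$stats.enabled) && length(pack_files) >= 2) {
    results$stats <- stage("stats", {
      gr <- lapply(seq_along(pack_files), function(k)
        read.csv(file.path(res_dir, sprintf("granules_%d.csv", k)),
                 comment.char = "#"))
      value <- unlist(lapply(gr, function(g) g$area_um2))
      group <- rep(seq_along(gr), vapply(gr, nrow, integer(1)))
      cmp <- compare_groups(value, group, alpha = cfg$stats.alpha)
      if (attr(cmp, "test") == "anova_duncan") {
        cbind(test = "anova_duncan", cmp$groups)
      } else {
        data.frame(test = "kruskal_wallis", H = cmp$H, p_value = cmp$p_value)
      }
    })
    write_csv_stamped(results$stats, file.path(res_dir, "stats.csv"), cfg)
  }
  invisible(results)
}
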