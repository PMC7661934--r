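#' The five two-electrode fractionalizations, ring mode and single-electrode
#' settings
#'
#' Standard pulse-amplitude distributions for radial steering between two
#' adjacent segments (E2 dominant, E3 secondary), in 12-degree expected
#' rotation steps, plus the ring-mode (-34/-33/-33%) and single-electrode
#' (-100%) settings.
#'
#' @return Named list of distributions (named percent vectors).
#' @export
standard_distributions <- function() {
  list(
    "ring"      = c("2" = -34, "3" = -33, "4" = -33),
    "-50/-50"   = c("2" = -50, "3" = -50),
    "-60/-40"   = c("2" = -60, "3" = -40),
    "-70/-30"   = c("2" = -70, "3" = -30),
    "-80/-20"   = c("2" = -80, "3" = -20),
    "-90/-10"   = c("2" = -90, "3" = -10),
    "single"    = c("2" = -100, "3" = 0)
  )
}

#' Experiment grid configuration
#'
#' @param target_radii Target VTA radii in mm.
#' @param fractionalizations Named list of two-electrode distributions to
#'   steer with.
#' @param include_ring,include_single Include the ring-mode and
#'   single-electrode reference settings.
#' @param geometry A [lead_geometry()].
#' @param tissue A [tissue_model()].
#' @param grid An [axon_grid_spec()].
#' @param model An [activation_model()], or `NULL` to calibrate at run
#'   time.
#' @param voxel_resolution Voxel edge length in mm.
#' @param impedance_kohm Equal-impedance scenario value in kOhm.
#' @param energy An [energy_params()].
#' @param n_per_axis Contact surface discretization.
#' @return List of class `grid_config`.
#' @export
grid_config <- function(target_radii = seq(2, 4, by = 0.25),
                        fractionalizations = standard_distributions()[
                          c("-50/-50", "-60/-40", "-70/-30", "-80/-20", "-90/-10")],
                        include_ring = TRUE,
                        include_single = TRUE,
                        geometry = lead_geometry(),
                        tissue = tissue_model(),
                        grid = axon_grid_spec(),
                        model = NULL,
                        voxel_resolution = 0.1,
                        impedance_kohm = 3,
                        energy = energy_params(),
                        n_per_axis = 4) {
  structure(as.list(environment()), class = "grid_config")
}

#' Run the full steering / energy experiment grid
#'
#' For every target radius and setting: titrates the total amplitude,
#' builds the VTA(s), and computes steering metrics (rotation angle,
#' deviation from the linear-proportion expectation, radius), volumes,
#' overlap with the same-radius ring-mode VTA, and battery current draw
#' in the equal-impedance scenario. MICC builds one summed-field VTA per
#' cell; Interleaving/MSS builds the two single-electrode VTAs, their
#' union (the Interleaving/MSS VTA, whose radius is the titration
#' control) and intersection. Coactivation rows (identical field to MICC
#' at equal impedances, different current draw) are added for the
#' uniform settings. Deterministic: no randomness is involved.
#'
#' @param config A [grid_config()].
#' @param progress Emit per-cell progress messages.
#' @return Data frame of class `results_table`, one row per (paradigm,
#'   setting, radius) cell; absent interleaved VTA-2 cells are flagged
#'   (`vta2_absent`), not dropped.
#' @export
run_grid <- function(config = grid_config(), progress = FALSE) {
  stopifnot(inherits(config, "grid_config"))
  cfg <- config
  model <- cfg$model
  if (is.null(model)) {
    model <- calibrate_threshold(cfg$geometry, cfg$tissue, cfg$grid,
                                 voxel_resolution = cfg$voxel_resolution,
                                 n_per_axis = cfg$n_per_axis)
  }
  z0 <- level_z(cfg$geometry, "1")
  zq <- cfg$impedance_kohm
  dists <- standard_distributions()
  say <- function(...) if (progress) message(sprintf(...))

  rows <- list()
  add <- function(row) rows[[length(rows) + 1]] <<- row
  blank <- function() data.frame(
    paradigm = NA_character_, setting = NA_character_, target_radius = NA_real_,
    total_amplitude_mA = NA_real_, achieved_radius_mm = NA_real_,
    titration_converged = NA, rotation_deg = NA_real_, expected_deg = NA_real_,
    deviation_deg = NA_real_, volume_mm3 = NA_real_,
    intersection_volume_mm3 = NA_real_, vta2_absent = NA,
    overlap_ring_pct = NA_real_, intersection_pct = NA_real_,
    current_uA = NA_real_, stringsAsFactors = FALSE)

  titrate1 <- function(distribution, radius, paradigm) {
    titrate_amplitude(distribution, radius, paradigm, model, cfg$geometry,
                      cfg$grid, cfg$tissue, cfg$voxel_resolution,
                      cfg$n_per_axis)
  }
  build1 <- function(distribution, amplitude) {
    build_vta(make_sources(cfg$geometry, distribution, amplitude, cfg$n_per_axis),
              model, cfg$grid, cfg$voxel_resolution, cfg$tissue)
  }
  amps_of <- function(distribution, total) {
    fr <- normalize_distribution(distribution)
    abs(fr[fr != 0]) / 100 * total
  }

  # ring-mode reference VTAs (also the overlap denominators)
  ring_vtas <- list()
  if (cfg$include_ring) {
    for (r in cfg$target_radii) {
      say("ring mode, radius %.2f", r)
      ti <- titrate1(dists$ring, r, "micc")
      v <- build1(dists$ring, ti$total_amplitude)
      ring_vtas[[as.character(r)]] <- v
      m <- steering_metrics(v, z0)
      amps <- amps_of(dists$ring, ti$total_amplitude)
      row <- blank()
      row$paradigm <- "micc"; row$setting <- "ring"; row$target_radius <- r
      row$total_amplitude_mA <- ti$total_amplitude
      row$achieved_radius_mm <- ti$achieved_radius
      row$titration_converged <- ti$converged
      row$rotation_deg <- m$rotation_deg
      row$volume_mm3 <- m$volume_mm3
      row$overlap_ring_pct <- 100
      row$current_uA <- current_draw_micc(amps, rep(zq, 3), cfg$energy)
      add(row)
      row$paradigm <- "coactivation"
      row$current_uA <- current_draw_coactivation(ti$total_amplitude,
                                                  rep(zq, 3), cfg$energy)
      add(row)
    }
  }

  if (cfg$include_single) {
    for (r in cfg$target_radii) {
      say("single electrode, radius %.2f", r)
      ti <- titrate1(dists$single, r, "micc")
      v <- build1(dists$single, ti$total_amplitude)
      m <- steering_metrics(v, z0, expected = 0)
      row <- blank()
      row$paradigm <- "micc"; row$setting <- "single"; row$target_radius <- r
      row$total_amplitude_mA <- ti$total_amplitude
      row$achieved_radius_mm <- ti$achieved_radius
      row$titration_converged <- ti$converged
      row$rotation_deg <- m$rotation_deg
      row$expected_deg <- 0; row$deviation_deg <- m$deviation_deg
      row$volume_mm3 <- m$volume_mm3
      if (cfg$include_ring) {
        row$overlap_ring_pct <- overlap_percent(v, ring_vtas[[as.character(r)]])
      }
      row$current_uA <- current_draw_micc(ti$total_amplitude, zq, cfg$energy)
      add(row)
    }
  }

  for (nm in names(cfg$fractionalizations)) {
    d <- cfg$fractionalizations[[nm]]
    expct <- expected_rotation_angle(d)
    for (r in cfg$target_radii) {
      say("fractionalization %s, radius %.2f", nm, r)
      amps2 <- function(total) amps_of(d, total)

      # --- MICC: summed fields, one VTA
      ti <- titrate1(d, r, "micc")
      v <- build1(d, ti$total_amplitude)
      m <- steering_metrics(v, z0, expected = expct)
      row <- blank()
      row$paradigm <- "micc"; row$setting <- nm; row$target_radius <- r
      row$total_amplitude_mA <- ti$total_amplitude
      row$achieved_radius_mm <- ti$achieved_radius
      row$titration_converged <- ti$converged
      row$rotation_deg <- m$rotation_deg; row$expected_deg <- expct
      row$deviation_deg <- m$deviation_deg; row$volume_mm3 <- m$volume_mm3
      if (cfg$include_ring) {
        row$overlap_ring_pct <- overlap_percent(v, ring_vtas[[as.character(r)]])
      }
      row$current_uA <- current_draw_micc(amps2(ti$total_amplitude),
                                          rep(zq, sum(d != 0)), cfg$energy)
      add(row)
      if (identical(unname(abs(d[1])), unname(abs(d[2])))) {
        row$paradigm <- "coactivation"
        row$current_uA <- current_draw_coactivation(
          ti$total_amplitude, rep(zq, sum(d != 0)), cfg$energy)
        add(row)
      }

      # --- Interleaving/MSS: independent fields, union + intersection
      ti <- titrate1(d, r, "interleaving")
      pair <- build_interleaving_vtas(d, ti$total_amplitude, model,
                                      cfg$geometry, cfg$grid, cfg$tissue,
                                      cfg$voxel_resolution, cfg$n_per_axis)
      row <- blank()
      row$paradigm <- "interleaving"; row$setting <- nm; row$target_radius <- r
      row$total_amplitude_mA <- ti$total_amplitude
      row$achieved_radius_mm <- ti$achieved_radius
      row$titration_converged <- ti$converged
      row$expected_deg <- expct
      row$vta2_absent <- is.null(pair$vta2)
      if (!is.null(pair$vta1)) {
        u <- if (is.null(pair$vta2)) pair$vta1 else vta_union(pair$vta1, pair$vta2)
        m <- steering_metrics(u, z0, expected = expct)
        row$rotation_deg <- m$rotation_deg; row$deviation_deg <- m$deviation_deg
        row$volume_mm3 <- m$volume_mm3
        if (!is.null(pair$vta2)) {
          ix <- vta_intersection(pair$vta1, pair$vta2)
          row$intersection_volume_mm3 <- vta_volume(ix)
          row$intersection_pct <- if (u$n_voxels > 0)
            100 * ix$n_voxels / u$n_voxels else NA_real_
        }
        if (cfg$include_ring) {
          row$overlap_ring_pct <- overlap_percent(u, ring_vtas[[as.character(r)]])
        }
      }
      # both programs run regardless of whether VTA 2 forms
      row$current_uA <- current_draw_interleaving(amps2(ti$total_amplitude),
                                                  rep(zq, 2), cfg$energy)
      add(row)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("results_table", "data.frame")
  attr(out, "model") <- model
  out
}

#' Median and interquartile range
#'
#' Quartiles by linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param values Numeric vector (>= 1 non-missing value).
#' @param na.rm Drop missing values first.
#' @return List with `median`, `q25`, `q75`.
#' @export
summarize_median_iqr <- function(values, na.rm = FALSE) {
  if (na.rm) values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values to summarize")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q25 = q[1], q75 = q[3])
}

#' Wilcoxon signed-rank test
#'
#' Paired signed-rank test with zero differences dropped, the exact null
#' distribution for n <= 25 remaining pairs and the normal approximation
#' beyond. When every difference is zero the test is degenerate and
#' p = 1 is returned with a warning.
#'
#' @param x Numeric vector (or differences if `y` is `NULL`).
#' @param y Optional paired sample.
#' @param alternative `"two_sided"`, `"less"` or `"greater"` (alternative
#'   hypothesis about the location of `x - y`).
#' @return List with `statistic` (V), `p`, and `n` (non-zero
#'   differences).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  stopifnot(is.null(y) || length(x) == length(y))
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all differences are zero; degenerate test")
    return(list(statistic = NA_real_, p = 1, n = 0L))
  }
  alt <- c(two_sided = "two.sided", less = "less", greater = "greater")[alternative]
  ht <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = alt,
                       exact = length(d) <= 25, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p = ht$p.value, n = length(d))
}

#' Paired t-test
#'
#' @param x,y Paired numeric vectors (n >= 2); the differences must have
#'   non-zero variance.
#' @param alternative `"two_sided"`, `"less"` or `"greater"`.
#' @return List with `t`, `df`, `p`.
#' @export
paired_t_test <- function(x, y, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::var(x - y) == 0) stop("zero-variance differences")
  alt <- c(two_sided = "two.sided", less = "less", greater = "greater")[alternative]
  ht <- stats::t.test(x, y, paired = TRUE, alternative = alt)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Kolmogorov-Smirnov normality test (estimated parameters)
#'
#' One-sample KS statistic against a normal distribution with the sample
#' mean and standard deviation, using Lilliefors critical values (the
#' appropriate reference when the parameters are estimated from the
#' data).
#'
#' @param values Numeric vector (n >= 5, non-constant).
#' @return List with `D` and `p`.
#' @export
ks_normality <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 5) stop("need at least 5 values")
  if (stats::sd(values) == 0) stop("constant sample; test degenerate")
  ht <- nortest::lillie.test(values)
  list(D = unname(ht$statistic), p = ht$p.value)
}

fmt_miqr <- function(x, digits = 1) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return("---")
  s <- summarize_median_iqr(x)
  sprintf("%.*f (%.*f-%.*f)", digits, s$median, digits, s$q25, digits, s$q75)
}

#' Write report tables from a results table
#'
#' Emits CSV analogues of the standard report tables: per-fractionalization
#' steering deviations and ring-overlap percentages (median and IQR
#' across radii), and per-radius volumes, pulse amplitudes and currents
#' (median and IQR across fractionalizations), plus the raw per-cell
#' grid. Cells without a value (e.g. intersection VTAs where VTA 2 never
#' formed) are rendered as `---`.
#'
#' @param results A [run_grid()] results table.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
report_tables <- function(results, dir) {
  stopifnot(inherits(results, "data.frame"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  w(as.data.frame(results), "grid_results.csv")

  fracs <- setdiff(unique(results$setting), c("ring", "single"))
  radii <- sort(unique(results$target_radius))
  pick <- function(paradigm, setting, col) {
    results[[col]][results$paradigm == paradigm & results$setting == setting]
  }

  # deviations: paradigm rows x fractionalization columns
  dev <- data.frame(paradigm = c("micc", "interleaving"))
  for (f in fracs) {
    dev[[f]] <- c(fmt_miqr(pick("micc", f, "deviation_deg")),
                  fmt_miqr(pick("interleaving", f, "deviation_deg")))
  }
  w(dev, "table_deviation.csv")

  ov <- data.frame(paradigm = c("micc", "interleaving", "intersection"))
  for (f in fracs) {
    ov[[f]] <- c(fmt_miqr(pick("micc", f, "overlap_ring_pct")),
                 fmt_miqr(pick("interleaving", f, "overlap_ring_pct")),
                 fmt_miqr(pick("interleaving", f, "intersection_pct")))
  }
  w(ov, "table_overlap.csv")

  radius_table <- function(col, digits = 1) {
    tb <- data.frame(setting = c("ring", "single", "micc", "interleaving",
                                 "intersection"))
    for (r in radii) {
      sub <- results[results$target_radius == r, ]
      cell <- function(paradigm, setting, column = col) {
        v <- sub[[column]][sub$paradigm == paradigm &
                             (is.null(setting) | sub$setting %in% setting)]
        fmt_miqr(v, digits)
      }
      tb[[sprintf("%.2f", r)]] <- c(
        cell("micc", "ring"), cell("micc", "single"),
        cell("micc", fracs), cell("interleaving", fracs),
        fmt_miqr(sub$intersection_volume_mm3[sub$paradigm == "interleaving" &
                                               sub$setting %in% fracs], digits))
    }
    tb
  }
  w(radius_table("volume_mm3"), "table_volume.csv")
  amp <- radius_table("total_amplitude_mA", digits = 2)
  amp <- amp[amp$setting != "intersection", ]
  w(amp, "table_amplitude.csv")
  cur <- radius_table("current_uA")
  cur <- cur[cur$setting != "intersection", ]
  w(cur, "table_current.csv")
  invisible(paths)
}
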