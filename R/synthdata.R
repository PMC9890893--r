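## Synthetic-data generators. Every generator returns the dataset together
## with a `ground_truth` record of the planted parameters, and is a pure
## function of (params, seed).

# fEPSP waveform primitives ---------------------------------------------------

## Difference-of-exponentials synaptic kernel, zero at t = 0, peak at
## t_p = log(tau_d/tau_r) / (1/tau_r - 1/tau_d). The fEPSP is the downward
## deflection -A * g(t); its descending domain is [0, t_p].
fepsp_kernel <- function(t, tau_r = 0.8, tau_d = 4.0) {
  ifelse(t < 0, 0, exp(-t / tau_d) - exp(-t / tau_r))
}

## Least-squares slope of y on x.
ls_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc * xc)
}

## Mean descent rate of the unit kernel over its first 1 ms, computed on a
## dense grid (1 ns steps would be overkill; 1 us is far below any recording
## grid). Used to scale the kernel so the planted slope is exact in the
## continuum limit.
fepsp_unit_descent_slope <- function(tau_r = 0.8, tau_d = 4.0, win_ms = 1.0) {
  tt <- seq(0, win_ms, by = 0.001)
  ls_slope(tt, -fepsp_kernel(tt, tau_r, tau_d))
}

## Assemble one noise-free evoked trace on a uniform grid.
##  - biphasic stimulus artifact: +/- art_mV over 2 x 0.1 ms at stim onset
##  - fiber volley: brief triangular downward deflection, apex-normalised on
##    the grid so the measured peak-to-baseline magnitude equals the planted
##    amplitude exactly
##  - fEPSP: scaled difference-of-exponentials starting fepsp_delay_ms after
##    the stimulus
fepsp_trace <- function(time_ms, stim_onset_ms, slope_mV_per_ms,
                        fv_amplitude_mV, tau_r = 0.8, tau_d = 4.0,
                        fv_apex_ms = 1.2, fv_halfwidth_ms = 0.4,
                        fepsp_delay_ms = 2.0, art_mV = 4.0) {
  v <- numeric(length(time_ms))
  tr <- time_ms - stim_onset_ms
  # artifact
  v[tr >= 0 & tr < 0.1] <- art_mV
  v[tr >= 0.1 & tr < 0.2] <- -art_mV
  # fiber volley
  if (fv_amplitude_mV > 0) {
    tri <- pmax(0, 1 - abs(tr - fv_apex_ms) / fv_halfwidth_ms)
    if (max(tri) > 0) tri <- tri / max(tri)
    v <- v - fv_amplitude_mV * tri
  }
  # synaptic component, scaled so the first-1-ms descent rate is exact
  if (slope_mV_per_ms != 0) {
    unit <- fepsp_unit_descent_slope(tau_r, tau_d)
    amp <- slope_mV_per_ms / unit   # negative planted slope / negative unit
    v <- v - amp * fepsp_kernel(tr - fepsp_delay_ms, tau_r, tau_d)
  }
  v
}

new_sweep <- function(time_ms, voltage_mV, stim_onset_ms, stim_level = NA_real_,
                      epoch = "baseline", slice_id = "s1", animal_id = "a1") {
  stopifnot(length(time_ms) == length(voltage_mV), all(is.finite(voltage_mV)))
  dt <- diff(time_ms)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * max(dt)) {
    stop("time grid must be strictly increasing with constant step", call. = FALSE)
  }
  structure(
    list(time_ms = time_ms, voltage_mV = voltage_mV,
         stim_onset_ms = stim_onset_ms, stim_level = stim_level,
         epoch = epoch, slice_id = slice_id, animal_id = animal_id),
    class = "sweep"
  )
}

#' Generate a synthetic evoked field-potential sweep
#'
#' Builds one fEPSP trace with a biphasic stimulus artifact, a fiber-volley
#' deflection of known amplitude, and a difference-of-exponentials synaptic
#' deflection whose mean descent rate over the first 1 ms of the descending
#' domain equals the planted slope (exact up to grid quantisation when
#' \code{noise_sd_mV = 0}).
#'
#' @param slope_mV_per_ms planted fEPSP slope (negative for the usual
#'   downward deflection), mV/ms.
#' @param fv_amplitude_mV planted fiber-volley amplitude (peak-to-baseline
#'   magnitude), mV.
#' @param noise_sd_mV standard deviation of additive Gaussian sensor noise.
#' @param dt_ms sample interval in ms.
#' @param duration_ms total trace duration.
#' @param stim_onset_ms time of the stimulus within the trace.
#' @param seed RNG seed.
#' @param ... passed to the waveform builder (time constants, delays).
#' @return list with elements \code{sweep} (a \code{sweep} object) and
#'   \code{truth} (a \code{ground_truth}).
#' @export
gen_fepsp_sweep <- function(slope_mV_per_ms, fv_amplitude_mV = 0.3,
                            noise_sd_mV = 0, dt_ms = 0.05, duration_ms = 30,
                            stim_onset_ms = 5, seed = 1, ...) {
  stop_if_not_scalar_pos(dt_ms, "dt_ms")
  if (noise_sd_mV < 0) stop("noise_sd_mV must be >= 0", call. = FALSE)
  time_ms <- seq(0, duration_ms, by = dt_ms)
  v <- fepsp_trace(time_ms, stim_onset_ms, slope_mV_per_ms, fv_amplitude_mV, ...)
  if (noise_sd_mV > 0) {
    v <- v + with_seed(seed, rnorm(length(v), 0, noise_sd_mV))
  }
  truth <- ground_truth("fepsp_sweep",
                        list(slope_mV_per_ms = slope_mV_per_ms,
                             fv_amplitude_mV = fv_amplitude_mV,
                             noise_sd_mV = noise_sd_mV, dt_ms = dt_ms),
                        seed)
  list(sweep = new_sweep(time_ms, v, stim_onset_ms), truth = truth)
}

#' Generate a synthetic LTP session
#'
#' Sweeps are delivered every 20 s (3 per minute) for \code{n_baseline_min}
#' minutes before and \code{n_post_min} minutes after a theta-burst event at
#' minute 0. Post-TBS sweeps carry slope \code{baseline_slope *
#' potentiation_factor}; per-sweep multiplicative slope noise has standard
#' deviation \code{noise}.
#'
#' @param baseline_slope planted baseline fEPSP slope, mV/ms (negative).
#' @param potentiation_factor ratio of post-TBS to baseline slope (> 0).
#' @param n_baseline_min,n_post_min minutes of baseline / post-TBS recording.
#' @param sweeps_per_min sweeps per minute (20 s inter-stimulus interval = 3).
#' @param noise multiplicative slope noise SD (fraction of the target slope).
#' @param seed RNG seed.
#' @param dt_ms sample interval of each sweep.
#' @return list with \code{session} (class \code{ephys_session}: sweeps plus
#'   per-sweep minute labels, TBS at minute 0) and \code{truth}.
#' @export
gen_ltp_session <- function(baseline_slope = -1.5, potentiation_factor = 1.4,
                            n_baseline_min = 20, n_post_min = 60,
                            sweeps_per_min = 3, noise = 0, seed = 1,
                            dt_ms = 0.05) {
  if (potentiation_factor <= 0) stop("potentiation_factor must be > 0", call. = FALSE)
  if (n_baseline_min < 1 || n_post_min < 1 || sweeps_per_min < 1) {
    stop("minute and sweep counts must be positive", call. = FALSE)
  }
  minutes <- c(seq(-n_baseline_min, -1), seq(1, n_post_min))
  minute_of <- rep(minutes, each = sweeps_per_min)
  target <- ifelse(minute_of > 0, baseline_slope * potentiation_factor, baseline_slope)
  mult <- if (noise > 0) with_seed(seed, rnorm(length(target), 1, noise)) else rep(1, length(target))
  sweeps <- vector("list", length(target))
  for (i in seq_along(target)) {
    sweeps[[i]] <- gen_fepsp_sweep(target[i] * mult[i], noise_sd_mV = 0,
                                   dt_ms = dt_ms, seed = seed)$sweep
    sweeps[[i]]$epoch <- if (minute_of[i] > 0) "post_tbs" else "baseline"
  }
  session <- structure(list(sweeps = sweeps, minute = minute_of, tbs_minute = 0),
                       class = "ephys_session")
  truth <- ground_truth("ltp_session",
                        list(baseline_slope = baseline_slope,
                             potentiation_factor = potentiation_factor,
                             n_baseline_min = n_baseline_min,
                             n_post_min = n_post_min, noise = noise),
                        seed)
  list(session = session, truth = truth)
}

#' Generate a synthetic paired-pulse facilitation session
#'
#' One sweep pair per inter-pulse interval; the second response's slope is
#' \code{first_slope * facilitation_curve(interval)}.
#'
#' @param first_slope slope of the first response, mV/ms.
#' @param facilitation_curve function mapping interval (ms) to the planted
#'   PPF ratio.
#' @param intervals_ms inter-pulse intervals; default 20 to 400 ms in 20 ms
#'   steps.
#' @param noise multiplicative slope noise SD.
#' @param seed RNG seed.
#' @return list with \code{pairs} (list of \code{list(sweep1, sweep2,
#'   interval_ms)}) and \code{truth}.
#' @export
gen_ppf_session <- function(first_slope = -1.5,
                            facilitation_curve = function(i) 1.6 - 0.0015 * i,
                            intervals_ms = seq(20, 400, by = 20),
                            noise = 0, seed = 1, dt_ms = 0.05) {
  if (length(intervals_ms) == 0) stop("interval list is empty", call. = FALSE)
  ratios <- vapply(intervals_ms, facilitation_curve, numeric(1))
  if (any(!is.finite(ratios))) stop("facilitation_curve undefined on some interval", call. = FALSE)
  mult <- if (noise > 0) {
    with_seed(seed, matrix(rnorm(2 * length(intervals_ms), 1, noise), ncol = 2))
  } else matrix(1, length(intervals_ms), 2)
  pairs <- vector("list", length(intervals_ms))
  for (i in seq_along(intervals_ms)) {
    s1 <- gen_fepsp_sweep(first_slope * mult[i, 1], dt_ms = dt_ms, seed = seed)$sweep
    s2 <- gen_fepsp_sweep(first_slope * ratios[i] * mult[i, 2], dt_ms = dt_ms, seed = seed)$sweep
    s1$epoch <- s2$epoch <- "ppf"
    pairs[[i]] <- list(sweep1 = s1, sweep2 = s2, interval_ms = intervals_ms[i])
  }
  truth <- ground_truth("ppf_session",
                        list(first_slope = first_slope, intervals_ms = intervals_ms,
                             ratios = ratios, noise = noise),
                        seed)
  list(pairs = pairs, truth = truth)
}

# Microdialysis ---------------------------------------------------------------

#' Generate a synthetic hourly microdialysis series
#'
#' Baseline fractions at hours -n_baseline_h .. -1 sit at
#' \code{baseline_conc}; after the production inhibitor at t = 0 the
#' concentration follows first-order elimination
#' \code{baseline_conc * exp(-Ke * t)}. Noise is multiplicative log-normal
#' with the given coefficient of variation and unit mean, so concentrations
#' stay positive for the semi-log fit.
#'
#' @param baseline_conc baseline concentration, pg/mL.
#' @param Ke_per_h planted elimination rate constant, per hour.
#' @param n_baseline_h,n_post_h number of baseline / post-inhibitor hourly
#'   fractions (defaults give the usual 14-fraction series).
#' @param noise_cv coefficient of variation of the log-normal noise.
#' @param seed RNG seed.
#' @return list with \code{series} (class \code{dialysate_series}) and
#'   \code{truth}.
#' @export
gen_dialysis_series <- function(baseline_conc = 100, Ke_per_h = 0.5,
                                n_baseline_h = 10, n_post_h = 4,
                                noise_cv = 0, seed = 1, animal_id = "a1") {
  stop_if_not_scalar_pos(baseline_conc, "baseline_conc")
  stop_if_not_scalar_pos(Ke_per_h, "Ke_per_h")
  t_h <- c(seq(-n_baseline_h, -1), seq(1, n_post_h))
  conc <- ifelse(t_h < 0, baseline_conc, baseline_conc * exp(-Ke_per_h * t_h))
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    conc <- conc * with_seed(seed, exp(rnorm(length(conc), -sdlog^2 / 2, sdlog)))
  }
  series <- new_dialysate_series(t_h, conc, animal_id)
  truth <- ground_truth("dialysis_series",
                        list(baseline_conc = baseline_conc, Ke_per_h = Ke_per_h,
                             n_baseline_h = n_baseline_h, n_post_h = n_post_h,
                             noise_cv = noise_cv),
                        seed)
  list(series = series, truth = truth)
}

# Imaging scenes --------------------------------------------------------------

## Anti-aliased disk coverage: 1 inside, 0 outside, linear ramp across one
## pixel at the rim.
render_disk <- function(xg, yg, cx, cy, radius_um, px_um) {
  d <- sqrt(outer((yg - cy)^2, (xg - cx)^2, "+"))
  pmin(1, pmax(0, (radius_um - d) / px_um + 0.5))
}

## Anti-aliased thick polyline: distance to nearest segment.
render_polyline <- function(xg, yg, poly, width_um, px_um) {
  ny <- length(yg); nx <- length(xg)
  dmin <- matrix(Inf, ny, nx)
  X <- matrix(xg, ny, nx, byrow = TRUE)
  Y <- matrix(yg, ny, nx)
  for (k in seq_len(nrow(poly) - 1)) {
    p <- poly[k, ]; q <- poly[k + 1, ]
    vx <- q[1] - p[1]; vy <- q[2] - p[2]
    L2 <- vx * vx + vy * vy
    if (L2 == 0) next
    tt <- pmin(1, pmax(0, ((X - p[1]) * vx + (Y - p[2]) * vy) / L2))
    dx <- X - (p[1] + tt * vx); dy <- Y - (p[2] + tt * vy)
    dmin <- pmin(dmin, sqrt(dx * dx + dy * dy))
  }
  pmin(1, pmax(0, (width_um / 2 - dmin) / px_um + 0.5))
}

new_image_plane <- function(intensity, pixel_size_um, channel) {
  stopifnot(is.matrix(intensity), all(is.finite(intensity)), all(intensity >= 0),
            pixel_size_um > 0)
  structure(list(intensity = intensity, pixel_size_um = pixel_size_um,
                 channel = channel),
            class = "image_plane")
}

#' Generate a synthetic stained-section scene
#'
#' Renders one fluorescence channel per stain class on a calibrated pixel
#' grid: plaques as anti-aliased disks, microglia as a bright soma disk plus
#' thick branch polylines. Optional Poisson + Gaussian noise emulates
#' photon/readout noise. All ground truth is recorded in physical microns.
#'
#' @param roi_size_um scene side length, um (square field).
#' @param pixel_size_um pixel pitch, um.
#' @param plaques data.frame with columns \code{x_um, y_um, diameter_um} and
#'   optional \code{intensity} (default 1).
#' @param microglia list of cells, each \code{list(soma = c(x, y),
#'   soma_diameter_um =, branches = list(2-column matrices of um
#'   coordinates))}.
#' @param background constant background intensity added to every channel.
#' @param noise if > 0, Gaussian read-noise SD added after Poisson resampling
#'   scaled by \code{photons} (set \code{photons = 0} to skip the Poisson
#'   step).
#' @param photons photons per unit intensity for the Poisson step.
#' @param branch_width_um rendered branch thickness.
#' @param branch_intensity branch intensity relative to the soma (somata are
#'   rendered at 1 so a high threshold isolates cell bodies).
#' @param seed RNG seed.
#' @return list with \code{planes} (named list of \code{image_plane}:
#'   \code{plaque}, \code{microglia}), \code{roi} (full-field mask), and
#'   \code{truth} whose params hold the plaque table, soma table, per-cell
#'   skeleton geometry (branch count, junctions, total branch length) and
#'   the plaque-soma distance matrix.
#' @export
gen_scene <- function(roi_size_um = 200, pixel_size_um = 0.5,
                      plaques = NULL, microglia = NULL,
                      background = 0, noise = 0, photons = 50,
                      branch_width_um = 1.5, branch_intensity = 0.5,
                      seed = 1) {
  stop_if_not_scalar_pos(pixel_size_um, "pixel_size_um")
  n <- max(1L, round(roi_size_um / pixel_size_um))
  ## pixel-center coordinates in um (0-based indexing, origin top-left)
  xg <- (seq_len(n) - 0.5) * pixel_size_um
  yg <- xg
  plaque_img <- matrix(0, n, n)
  mg_img <- matrix(0, n, n)

  if (!is.null(plaques) && nrow(plaques) > 0) {
    if (is.null(plaques$intensity)) plaques$intensity <- 1
    for (i in seq_len(nrow(plaques))) {
      plaque_img <- pmax(plaque_img, plaques$intensity[i] *
        render_disk(xg, yg, plaques$x_um[i], plaques$y_um[i],
                    plaques$diameter_um[i] / 2, pixel_size_um))
    }
  }

  soma_tab <- NULL
  skel_truth <- NULL
  if (!is.null(microglia) && length(microglia) > 0) {
    soma_tab <- do.call(rbind, lapply(seq_along(microglia), function(i) {
      cell <- microglia[[i]]
      data.frame(cell = i, x_um = cell$soma[1], y_um = cell$soma[2],
                 soma_diameter_um = cell$soma_diameter_um)
    }))
    skel_truth <- do.call(rbind, lapply(seq_along(microglia), function(i) {
      cell <- microglia[[i]]
      br <- cell$branches %||% list()
      len <- sum(vapply(br, function(p) {
        sum(sqrt(rowSums(diff(p)^2)))
      }, numeric(1)))
      data.frame(cell = i, n_branches = length(br),
                 n_junctions = if (length(br) >= 3) 1L else 0L,
                 total_length_um = len)
    }))
    for (cell in microglia) {
      mg_img <- pmax(mg_img, render_disk(xg, yg, cell$soma[1], cell$soma[2],
                                         cell$soma_diameter_um / 2, pixel_size_um))
      for (p in cell$branches %||% list()) {
        mg_img <- pmax(mg_img, branch_intensity *
          render_polyline(xg, yg, p, branch_width_um, pixel_size_um))
      }
    }
  }

  if (background > 0) {
    plaque_img <- plaque_img + background
    mg_img <- mg_img + background
  }
  if (noise > 0) {
    imgs <- with_seed(seed, {
      lapply(list(plaque_img, mg_img), function(img) {
        if (photons > 0) img <- matrix(rpois(length(img), img * photons) / photons,
                                       nrow(img), ncol(img))
        pmax(img + matrix(rnorm(length(img), 0, noise), nrow(img), ncol(img)), 0)
      })
    })
    plaque_img <- imgs[[1]]; mg_img <- imgs[[2]]
  }

  dist_mat <- NULL
  if (!is.null(plaques) && nrow(plaques) > 0 && !is.null(soma_tab)) {
    dist_mat <- sqrt(outer(plaques$x_um, soma_tab$x_um, "-")^2 +
                     outer(plaques$y_um, soma_tab$y_um, "-")^2)
  }
  truth <- ground_truth("scene",
                        list(roi_size_um = roi_size_um,
                             pixel_size_um = pixel_size_um,
                             plaques = plaques, somata = soma_tab,
                             skeleton = skel_truth,
                             plaque_soma_dist_um = dist_mat,
                             overlap_flag = scene_has_overlap(plaques, soma_tab)),
                        seed)
  list(planes = list(plaque = new_image_plane(plaque_img, pixel_size_um, "X34"),
                     microglia = new_image_plane(mg_img, pixel_size_um, "IBA1")),
       roi = matrix(TRUE, n, n),
       truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scene_has_overlap <- function(plaques, somata) {
  overlap <- FALSE
  if (!is.null(plaques) && nrow(plaques) > 1) {
    d <- as.matrix(dist(plaques[, c("x_um", "y_um")]))
    r <- outer(plaques$diameter_um, plaques$diameter_um, "+") / 2
    diag(d) <- Inf
    overlap <- overlap || any(d < r)
  }
  if (!is.null(somata) && nrow(somata) > 1) {
    d <- as.matrix(dist(somata[, c("x_um", "y_um")]))
    r <- outer(somata$soma_diameter_um, somata$soma_diameter_um, "+") / 2
    diag(d) <- Inf
    overlap <- overlap || any(d < r)
  }
  overlap
}

#' Star-shaped microglial cell for synthetic scenes
#'
#' Soma disk with \code{n_arms} straight branches of the given lengths at the
#' given angles; the analytic skeleton is \code{n_arms} branches, one
#' junction (for >= 3 arms) and total length \code{sum(lengths_um)}.
#' @export
microglion_star <- function(center, n_arms = 4, lengths_um = 20,
                            angles = NULL, soma_diameter_um = 6) {
  if (is.null(angles)) angles <- seq(0, 2 * pi, length.out = n_arms + 1)[-(n_arms + 1)]
  lengths_um <- rep_len(lengths_um, n_arms)
  branches <- lapply(seq_len(n_arms), function(i) {
    rbind(center,
          center + lengths_um[i] * c(cos(angles[i]), sin(angles[i])))
  })
  list(soma = center, soma_diameter_um = soma_diameter_um, branches = branches)
}

# PRM -------------------------------------------------------------------------

#' Generate a synthetic PRM run
#'
#' For each peptide species the native chromatographic peak area is
#' \code{true_fmol * area_per_fmol} and the internal-standard area is
#' \code{spike_fmol * area_per_fmol}, each perturbed by independent unit-mean
#' log-normal noise of the stated CV.
#'
#' @param true_fmol named numeric vector of planted amounts per peptide
#'   species (names become the \code{species} column).
#' @param spike_fmol stable-isotope internal-standard spike per peptide.
#' @param area_per_fmol detector response, area units per fmol.
#' @param noise_cv coefficient of variation of the multiplicative area noise.
#' @param sample_id,genotype sample annotation.
#' @param seed RNG seed.
#' @return list with \code{measurements} (data.frame: sample_id, genotype,
#'   species, native_area, sil_area, spike_fmol) and \code{truth}.
#' @export
gen_prm_run <- function(true_fmol, spike_fmol = 5, area_per_fmol = 1e5,
                        noise_cv = 0, sample_id = "s1", genotype = "WT",
                        seed = 1) {
  stop_if_not_scalar_pos(spike_fmol, "spike_fmol")
  k <- length(true_fmol)
  species <- names(true_fmol) %||% paste0("pep", seq_len(k))
  mult <- if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    with_seed(seed, exp(rnorm(2 * k, -sdlog^2 / 2, sdlog)))
  } else rep(1, 2 * k)
  meas <- data.frame(
    sample_id = sample_id, genotype = genotype, species = species,
    native_area = unname(true_fmol) * area_per_fmol * mult[seq_len(k)],
    sil_area = spike_fmol * area_per_fmol * mult[k + seq_len(k)],
    spike_fmol = spike_fmol,
    stringsAsFactors = FALSE
  )
  truth <- ground_truth("prm_run",
                        list(true_fmol = true_fmol, spike_fmol = spike_fmol,
                             area_per_fmol = area_per_fmol, noise_cv = noise_cv),
                        seed)
  list(measurements = meas, truth = truth)
}

# RNA-seq counts --------------------------------------------------------------

#' Generate a synthetic gene x sample count matrix
#'
#' Negative-binomial counts with log-normal gene-wise dispersions. DE genes
#' have their second-group mean multiplied by \code{2^log2FC}. Module genes
#' share a latent factor partially determined by group label: for sample j,
#' \code{f_j = sqrt(r2)*z(group_j) + sqrt(1-r2)*e_j}, and member gene g gets
#' a log2-scale shift \code{loading * f_j * 0.5}.
#'
#' @param n_genes total genes.
#' @param groups character/factor of length n_samples with two levels; the
#'   second level carries the DE shift.
#' @param lib_sizes expected library sizes per sample.
#' @param nb_dispersion median NB dispersion; gene-wise values are log-normal
#'   around it (sdlog 0.3).
#' @param de_genes named numeric vector: planted log2 fold-changes keyed by
#'   gene index (or NULL).
#' @param module_genes integer indices of planted co-expression module
#'   members (or NULL).
#' @param module_loading latent-factor loading of module genes.
#' @param module_trait_r2 fraction of latent-factor variance explained by
#'   group label.
#' @param seed RNG seed.
#' @return list with \code{counts} (matrix), \code{meta} (data.frame:
#'   sample, group, sex, qc covariates) and \code{truth}.
#' @export
gen_counts <- function(n_genes = 2000, groups = rep(c("WT", "Hom"), each = 6),
                       lib_sizes = NULL, nb_dispersion = 0.05,
                       de_genes = NULL, module_genes = NULL,
                       module_loading = 1.5, module_trait_r2 = 0.5,
                       seed = 1) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2 || any(table(groups) < 2)) {
    stop("need two groups with >= 2 samples each", call. = FALSE)
  }
  ns <- length(groups)
  if (is.null(lib_sizes)) lib_sizes <- rep(2e6, ns)
  with_seed(seed, {
    base_mu <- exp(rnorm(n_genes, log(50), 1.2))      # per-2M-reads expected count
    prop <- base_mu / sum(base_mu)
    disp <- exp(rnorm(n_genes, log(nb_dispersion), 0.3))
    log2shift <- matrix(0, n_genes, ns)
    grp2 <- groups == levels(groups)[2]
    if (!is.null(de_genes) && length(de_genes)) {
      idx <- as.integer(names(de_genes))
      log2shift[idx, grp2] <- log2shift[idx, grp2] + rep(de_genes, sum(grp2))
    }
    f <- NULL
    if (!is.null(module_genes) && length(module_genes)) {
      z <- scale(as.numeric(grp2))[, 1]
      f <- sqrt(module_trait_r2) * z + sqrt(1 - module_trait_r2) * rnorm(ns)
      load_g <- rep(module_loading, length(module_genes))
      log2shift[module_genes, ] <- log2shift[module_genes, ] +
        outer(load_g, f) * 0.5
    }
    mu <- (prop %o% lib_sizes) * 2^log2shift
    counts <- matrix(rnbinom(n_genes * ns, mu = mu, size = 1 / disp), n_genes, ns)
    rownames(counts) <- sprintf("g%04d", seq_len(n_genes))
    colnames(counts) <- sprintf("s%02d", seq_len(ns))
    meta <- data.frame(
      sample = colnames(counts), group = groups,
      sex = factor(rep_len(c("F", "M"), ns)),
      gene_count_pct = runif(ns, 70, 90),
      strandness = runif(ns, 0.95, 1.0),
      exonic_rate = runif(ns, 0.6, 0.8)
    )
    truth <- ground_truth("counts",
                          list(n_genes = n_genes, groups = as.character(groups),
                               lib_sizes = lib_sizes, nb_dispersion = nb_dispersion,
                               de_genes = de_genes, module_genes = module_genes,
                               module_loading = module_loading,
                               module_trait_r2 = module_trait_r2,
                               latent_factor = f),
                          seed)
    list(counts = counts, meta = meta, truth = truth)
  })
}
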