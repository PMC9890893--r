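test_that("generators are deterministic in (seed, params)", {
  a <- gen_fepsp_sweep(-1.5, noise_sd_mV = 0.05, seed = 7)
  b <- gen_fepsp_sweep(-1.5, noise_sd_mV = 0.05, seed = 7)
  expect_identical(a$sweep$voltage_mV, b$sweep$voltage_mV)
  expect_false(identical(a$sweep$voltage_mV,
                         gen_fepsp_sweep(-1.5, noise_sd_mV = 0.05, seed = 8)$sweep$voltage_mV))

  d1 <- gen_dialysis_series(noise_cv = 0.1, seed = 3)
  d2 <- gen_dialysis_series(noise_cv = 0.1, seed = 3)
  expect_identical(d1$series$conc, d2$series$conc)

  c1 <- gen_counts(n_genes = 100, seed = 5)
  c2 <- gen_counts(n_genes = 100, seed = 5)
  expect_identical(c1$counts, c2$counts)

  p1 <- gen_prm_run(c(a = 2), noise_cv = 0.1, seed = 4)
  p2 <- gen_prm_run(c(a = 2), noise_cv = 0.1, seed = 4)
  expect_identical(p1$measurements$native_area, p2$measurements$native_area)

  s1 <- gen_scene(50, 1, plaques = data.frame(x_um = 25, y_um = 25, diameter_um = 10),
                  noise = 0.02, seed = 9)
  s2 <- gen_scene(50, 1, plaques = data.frame(x_um = 25, y_um = 25, diameter_um = 10),
                  noise = 0.02, seed = 9)
  expect_identical(s1$planes$plaque$intensity, s2$planes$plaque$intensity)
})

test_that("every generated dataset carries its ground truth", {
  g <- gen_ltp_session(-1.5, 1.4, noise = 0.02, seed = 2)
  expect_s3_class(g$truth, "ground_truth")
  expect_equal(g$truth$params$potentiation_factor, 1.4)
  expect_equal(g$truth$seed, 2)
})

test_that("fEPSP sweep generation plants exact slope and fiber volley", {
  g <- gen_fepsp_sweep(-2.0, fv_amplitude_mV = 0.3, noise_sd_mV = 0)
  f <- extract_sweep_features(g$sweep)
  expect_lt(abs(f$fepsp_slope_mV_per_ms / -2.0 - 1), 0.02)
  expect_equal(f$fv_amplitude_mV, 0.3, tolerance = 1e-9)
  expect_error(gen_fepsp_sweep(-1, dt_ms = 0), "dt_ms")
  expect_error(gen_fepsp_sweep(-1, noise_sd_mV = -1), "noise")
})

test_that("LTP session plants the potentiation profile", {
  flat <- ltp_profile(gen_ltp_session(-1.5, 1.0, noise = 0)$session)
  expect_true(all(abs(flat$pct - 100) < 1e-6))
  up <- ltp_profile(gen_ltp_session(-1.5, 1.5, noise = 0)$session)
  expect_equal(attr(up, "last5_mean"), 150, tolerance = 1e-6)
  expect_error(gen_ltp_session(-1.5, 0), "potentiation_factor")
  expect_error(gen_ltp_session(-1.5, 1.2, n_post_min = 0), "positive")
})

test_that("PPF session follows the 20-400 ms schedule and planted curve", {
  g <- gen_ppf_session(-1.5, noise = 0)
  expect_length(g$pairs, 20)
  expect_equal(vapply(g$pairs, `[[`, numeric(1), "interval_ms"), seq(20, 400, 20))
  const <- gen_ppf_session(-1.5, facilitation_curve = function(i) 1, noise = 0)
  prof <- ppf_profile(const$pairs)
  expect_true(all(abs(prof$ratio - 1) < 1e-9))
  spike <- gen_ppf_session(-1.5, facilitation_curve = function(i) ifelse(i == 20, 1.6, 1),
                           noise = 0)
  expect_equal(ppf_profile(spike$pairs)$ratio[1], 1.6, tolerance = 1e-9)
  expect_error(gen_ppf_session(-1.5, intervals_ms = numeric(0)), "empty")
})

test_that("dialysate series has 14 fractions and plants half-life", {
  g <- gen_dialysis_series(baseline_conc = 100, Ke_per_h = 0.693, noise_cv = 0)
  expect_length(g$series$t_h, 14)
  conc1 <- g$series$conc[g$series$t_h == 1]
  expect_equal(conc1, 50, tolerance = 1e-3)
  expect_error(gen_dialysis_series(baseline_conc = 0), "baseline_conc")
  expect_error(gen_dialysis_series(Ke_per_h = -1), "Ke_per_h")
})

test_that("dialysate noise is positive-concentration log-normal with unit mean", {
  concs <- vapply(1:500, function(s)
    baseline_mean(gen_dialysis_series(baseline_conc = 50, noise_cv = 0.1,
                                      seed = s)$series), numeric(1))
  expect_true(all(concs > 0))
  expect_lt(abs(mean(concs) / 50 - 1), 0.01)
})

test_that("scene ground-truth tables mirror the requested objects", {
  pl <- data.frame(x_um = c(seq(15, 135, length.out = 10), seq(20, 120, length.out = 5)),
                   y_um = c(rep(40, 10), rep(110, 5)),
                   diameter_um = c(rep(12, 10), rep(5, 5)))
  sc <- gen_scene(150, 0.5, plaques = pl)
  expect_equal(nrow(sc$truth$params$plaques), 15)
  empty <- gen_scene(60, 1)
  expect_equal(area_fraction(empty$planes$plaque, empty$roi, 0.5), 0)
  cross <- microglion_star(c(40, 40), 4, 20, angles = c(0, pi / 2, pi, 3 * pi / 2))
  scx <- gen_scene(80, 0.5, microglia = list(cross))
  expect_equal(scx$truth$params$skeleton$n_branches, 4L)
  expect_equal(scx$truth$params$skeleton$n_junctions, 1L)
  expect_equal(scx$truth$params$skeleton$total_length_um, 80)
})

test_that("PRM generation plants the area ratios", {
  g <- gen_prm_run(c(pep = 5), spike_fmol = 5, noise_cv = 0)
  expect_equal(g$measurements$native_area, g$measurements$sil_area)
  g0 <- gen_prm_run(c(pep = 0), noise_cv = 0)
  expect_equal(g0$measurements$native_area, 0)
  expect_error(gen_prm_run(c(pep = 1), spike_fmol = 0), "spike_fmol")
})

test_that("count generation: equal libraries with no DE give TMM factors near 1", {
  g <- gen_counts(n_genes = 800, groups = rep(c("A", "B"), each = 5), seed = 11)
  f <- tmm_factors(filter_genes(g$counts))
  expect_true(all(abs(f - 1) < 0.05))
  expect_error(gen_counts(groups = c("A", "B")), "2 samples")
})

test_that("null count matrices produce few DEGs at FDR 0.05", {
  n_deg <- vapply(1:20, function(s) {
    g <- gen_counts(n_genes = 400, groups = rep(c("A", "B"), each = 5), seed = s)
    filt <- filter_genes(g$counts)
    de <- genewise_de_test(filt, tmm_factors(filt), g$meta$group)
    de$fdr <- bh_adjust(de$p_value)
    sum(classify_deg(de)$status != "ns")
  }, numeric(1))
  expect_lte(mean(n_deg), 0.05 * 400)
})

test_that("generator outputs pass the analysis modules' input validation", {
  expect_s3_class(gen_fepsp_sweep(-1)$sweep, "sweep")
  expect_s3_class(gen_dialysis_series()$series, "dialysate_series")
  sc <- gen_scene(40, 1, plaques = data.frame(x_um = 20, y_um = 20, diameter_um = 10))
  expect_s3_class(sc$planes$plaque, "image_plane")
  expect_no_error(validate_manifest(
    data.frame(animal_id = "a", genotype = "WT", modality = "x", file = "f"),
    check_files = FALSE))
})
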