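binary_plane <- function(mask, px = 1) {
  new_image_plane(matrix(as.numeric(mask), nrow(mask), ncol(mask)), px, "test")
}

test_that("area fraction counts above-threshold ROI pixels", {
  m <- matrix(0.2, 10, 10)
  p <- binary_plane(m > 1)          # all zero
  expect_equal(area_fraction(new_image_plane(m, 1, "x"), threshold = 0.5), 0)
  m2 <- matrix(c(rep(1, 50), rep(0, 50)), 10, 10)
  expect_equal(area_fraction(new_image_plane(m2, 1, "x"), threshold = 0.5), 50)
  roi <- matrix(FALSE, 10, 10)
  expect_error(area_fraction(new_image_plane(m2, 1, "x"), roi, 0.5), "empty ROI")
})

test_that("synthetic plaque scenes reproduce the planted area fraction", {
  pl <- data.frame(x_um = c(30, 70, 110), y_um = c(40, 90, 40),
                   diameter_um = c(20, 24, 16))
  sc <- gen_scene(150, 0.5, plaques = pl)
  truth <- 100 * sum(pi * (pl$diameter_um / 2)^2) / 150^2
  expect_lt(abs(area_fraction(sc$planes$plaque, sc$roi, 0.5) - truth), 0.2)
})

test_that("the diameter filter keeps only plaques above 8 um", {
  pl <- data.frame(x_um = c(seq(15, 135, length.out = 10), seq(20, 120, length.out = 5)),
                   y_um = c(rep(40, 10), rep(110, 5)),
                   diameter_um = c(rep(12, 10), rep(5, 5)))
  sc <- gen_scene(150, 0.5, plaques = pl)
  d <- detect_particles(sc$planes$plaque, sc$roi, 0.5, min_diameter_um = 8)
  expect_equal(d$count, 10)
  expect_equal(detect_particles(sc$planes$plaque, sc$roi, 0.5, min_diameter_um = 13)$count, 0)
  ## density x ROI area = count, exactly
  expect_equal(d$density_per_mm2 * d$roi_area_um2 / 1e6, d$count, tolerance = 1e-12)
})

test_that("raising threshold or diameter never increases fraction or count", {
  set.seed(31)
  for (rep in 1:5) {
    pl <- random_separated_plaques(6, 4)
    sc <- gen_scene(150, 0.5, plaques = pl, noise = 0.05, photons = 100,
                    seed = rep)
    af <- vapply(c(0.3, 0.5, 0.7), function(th)
      area_fraction(sc$planes$plaque, sc$roi, th), numeric(1))
    expect_true(all(diff(af) <= 0))
    cnt <- vapply(c(4, 8, 12), function(d)
      detect_particles(sc$planes$plaque, sc$roi, 0.5, d)$count, numeric(1))
    expect_true(all(diff(cnt) <= 0))
  }
})

test_that("outputs are invariant to translation and 90-degree rotation", {
  pl <- data.frame(x_um = c(40, 80), y_um = c(40, 90), diameter_um = c(14, 10))
  sc <- gen_scene(130, 0.5, plaques = pl)
  base <- detect_particles(sc$planes$plaque, sc$roi, 0.5)
  shifted <- data.frame(x_um = pl$x_um + 10, y_um = pl$y_um - 15,
                        diameter_um = pl$diameter_um)
  sc2 <- gen_scene(130, 0.5, plaques = shifted)
  mv <- detect_particles(sc2$planes$plaque, sc2$roi, 0.5)
  expect_equal(mv$count, base$count)
  expect_equal(sort(mv$particles$area_um2), sort(base$particles$area_um2),
               tolerance = 1e-9)
  rot <- new_image_plane(t(sc$planes$plaque$intensity)[ncol(sc$planes$plaque$intensity):1, ],
                         0.5, "rot")
  rr <- detect_particles(rot, threshold = 0.5)
  expect_equal(rr$count, base$count)
  expect_equal(sort(rr$particles$area_um2), sort(base$particles$area_um2),
               tolerance = 1e-9)
  expect_equal(area_fraction(rot, threshold = 0.5),
               area_fraction(sc$planes$plaque, sc$roi, 0.5), tolerance = 1e-12)
})

test_that("random separated scenes are counted exactly (generator truth)", {
  set.seed(77)
  for (rep in 1:50) {
    n_large <- sample(3:8, 1); n_small <- sample(0:4, 1)
    pl <- random_separated_plaques(n_large, n_small)
    sc <- gen_scene(150, 0.5, plaques = pl, seed = rep)
    got <- detect_particles(sc$planes$plaque, sc$roi, 0.5, 8)$count
    expect_equal(got, n_large)
  }
})

test_that("microglial soma density and size are recovered", {
  cells <- lapply(1:5, function(i)
    microglion_star(c(30 + i * 25, 100), 4, 10, soma_diameter_um = 8))
  sc <- gen_scene(200, 0.5, microglia = cells)
  ms <- microglia_somata(sc$planes$microglia, threshold = 0.55)
  expect_equal(nrow(ms$somata), 5)
  expect_equal(ms$density_per_mm2, 5 / 0.04, tolerance = 1e-9)   # 200 um square = 0.04 mm2
  expect_lt(abs(ms$mean_soma_area_um2 / (pi * 16) - 1), 0.05)
  empty <- gen_scene(100, 1)
  expect_equal(microglia_somata(empty$planes$microglia, threshold = 0.5)$density_per_mm2, 0)
})

test_that("soma sizes match planted areas across random scenes", {
  set.seed(5)
  rel <- vapply(1:50, function(i) {
    d <- runif(1, 8, 12)
    sc <- gen_scene(60, 0.5, microglia = list(
      list(soma = c(30, 30), soma_diameter_um = d, branches = list())))
    microglia_somata(sc$planes$microglia, threshold = 0.5)$mean_soma_area_um2 /
      (pi * (d / 2)^2) - 1
  }, numeric(1))
  expect_lt(max(abs(rel)), 0.05)
})

test_that("skeletons of bars and crosses match analytic geometry", {
  bar <- list(soma = c(100, 100), soma_diameter_um = 0.1,
              branches = list(rbind(c(90, 100), c(110, 100))))
  mb <- skeleton_morphometry(gen_scene(200, 0.5, microglia = list(bar))$planes$microglia,
                             threshold = 0.3)
  expect_equal(mb$branch_count, 1L)
  expect_equal(mb$junction_count, 0L)
  expect_lt(abs(mb$total_branch_length_um - 20), 1)
  cross <- microglion_star(c(100, 100), 4, 20, angles = c(0, pi / 2, pi, 3 * pi / 2))
  mc <- skeleton_morphometry(gen_scene(200, 0.5, microglia = list(cross))$planes$microglia,
                             threshold = 0.3)
  expect_equal(mc$branch_count, 4L)
  expect_equal(mc$junction_count, 1L)
  ## tolerance: one pixel (0.5 um) per arm
  expect_lt(abs(mc$total_branch_length_um - 80), 4 * 0.5)
  expect_equal(nrow(skeleton_morphometry(gen_scene(50, 1)$planes$microglia,
                                         threshold = 0.5)), 0L)
})

test_that("30 random planted trees: branch counts exact, lengths within 5%", {
  set.seed(11)
  for (i in 1:30) {
    st <- random_clean_star()
    m <- skeleton_morphometry(gen_scene(100, 0.5, microglia = list(st$cell))$planes$microglia,
                              threshold = 0.3)
    expect_equal(m$branch_count[1], st$n_arms)
    expect_equal(m$junction_count[1], 1L)
    expect_lt(abs(m$total_branch_length_um[1] / st$total_len - 1), 0.05)
  }
})

test_that("plaque neighborhoods count somata within the 30 um radius", {
  pl <- data.frame(x_um = 100, y_um = 100, diameter_um = 12)
  mg <- lapply(c(10, 20, 40), function(r)
    microglion_star(c(100 + r, 100), 3, 6, soma_diameter_um = 6))
  sc <- gen_scene(200, 0.5, plaques = pl, microglia = mg)
  nb <- plaque_neighborhood(sc$planes$plaque, sc$planes$microglia, 0.5, 0.8)
  expect_equal(nb$microglia_count, 2L)
  expect_false(nb$coverage_flagged)
  sc0 <- gen_scene(200, 0.5, plaques = pl)
  nb0 <- plaque_neighborhood(sc0$planes$plaque, sc0$planes$microglia, 0.5, 0.8)
  expect_equal(nb0$microglia_count, 0L)
  expect_true(nb0$coverage_flagged)
  expect_true(is.na(nb0$coverage_um2_per_mg))
})

test_that("neighborhood counts agree with a brute-force distance oracle", {
  set.seed(19)
  for (rep in 1:50) {
    n_pl <- sample(1:3, 1); n_mg <- sample(2:6, 1)
    repeat {
      pl <- data.frame(x_um = runif(n_pl, 30, 170), y_um = runif(n_pl, 30, 170),
                       diameter_um = runif(n_pl, 10, 14))
      if (n_pl < 2 || min(dist(pl[, 1:2])) > 30) break
    }
    centers <- matrix(numeric(0), 0, 2)
    mg <- lapply(seq_len(n_mg), function(i) {
      repeat {
        ctr <- runif(2, 15, 185)
        d_pl <- sqrt((ctr[1] - pl$x_um)^2 + (ctr[2] - pl$y_um)^2)
        ## keep somata off plaques, away from each other, and clear of the
        ## 30 um decision boundary so centroid jitter cannot flip a count
        ok <- all(d_pl > 12) && all(abs(d_pl - 30) > 3) &&
          (nrow(centers) == 0 || min(sqrt(rowSums(sweep(centers, 2, ctr)^2))) > 15)
        if (ok) break
      }
      centers <<- rbind(centers, ctr)
      microglion_star(ctr, 3, 5, soma_diameter_um = 6)
    })
    sc <- gen_scene(200, 0.5, plaques = pl, microglia = mg, seed = rep)
    nb <- plaque_neighborhood(sc$planes$plaque, sc$planes$microglia, 0.5, 0.8)
    truth <- sc$truth$params
    expect_equal(nrow(nb), n_pl)
    ord <- order(nb$x_um)
    oracle <- vapply(order(truth$plaques$x_um), function(i)
      sum(truth$plaque_soma_dist_um[i, ] <= 30), integer(1))
    expect_equal(nb$microglia_count[ord], oracle)
  }
})

test_that("colocalized area matches planted overlap and handles edge cases", {
  a <- matrix(0, 40, 40); a[11:20, 1:13] <- 1
  b <- matrix(0, 40, 40); b[11:20, 8:20] <- 1
  pa <- new_image_plane(a, 1, "A"); pb <- new_image_plane(b, 1, "B")
  r <- colocalized_area(pa, pb, 0.5, 0.5)
  expect_equal(r$area_um2, 60)                  # 10 x 6 pixel overlap
  expect_equal(r$fraction, 0.3, tolerance = 1e-12)  # 60 / (130 + 130 - 60)
  expect_equal(colocalized_area(pa, pa, 0.5, 0.5)$fraction, 1)
  disj <- new_image_plane(1 - a, 1, "B")
  expect_equal(colocalized_area(pa, disj, 0.5, 0.5)$fraction, 0)
  flat <- new_image_plane(matrix(1, 40, 40), 1, "C")
  expect_error(colocalized_area(pa, flat), "constant channel")
})

test_that("automated threshold search recovers fixed-threshold overlap", {
  set.seed(3)
  ## uncorrelated backgrounds, one co-bright block: the automated search
  ## should place the threshold between background and block
  a <- matrix(runif(1600, 0, 0.2), 40, 40); a[11:25, 11:25] <- runif(225, 0.8, 1)
  b <- matrix(runif(1600, 0, 0.2), 40, 40); b[11:25, 11:25] <- runif(225, 0.7, 0.9)
  pa <- new_image_plane(a, 1, "A"); pb <- new_image_plane(b, 1, "B")
  r <- colocalized_area(pa, pb)
  expect_gt(r$fraction, 0.8)      # the bright block colocalizes in both
  expect_true(r$threshold_a > 0.2 & r$threshold_a < 0.8)
})
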