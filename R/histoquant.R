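## Quantification of calibrated stained-section images: thresholded area
## fractions, particle (plaque) detection with a physical diameter filter,
## microglial soma density, skeleton morphometry, plaque-centered
## neighborhoods and channel colocalization.
##
## Conventions: pixel indices are 0-based with origin top-left; all reported
## geometry is in physical microns; objects are 8-connected components;
## "diameter" of an irregular object is the equivalent circular diameter
## 2*sqrt(area/pi).

check_plane <- function(plane) {
  stopifnot(inherits(plane, "image_plane"))
  invisible(plane)
}

check_roi <- function(plane, roi) {
  if (!is.matrix(roi) || !all(dim(roi) == dim(plane$intensity))) {
    stop("ROI mask must be a logical matrix congruent with the plane", call. = FALSE)
  }
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  invisible(roi)
}

## 8-connected labeling. EBImage::bwlabel is 4-connected; labels touching
## diagonally are merged afterwards with a union-find over the label graph.
label8 <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(EBImage::bwlabel(m)), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab > 1) {
    parent <- seq_len(nlab)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    for (d in list(c(1, 1), c(1, -1))) {
      sh <- shift_mat(lab, d[1], d[2])
      sel <- lab > 0L & sh > 0L & lab != sh
      if (any(sel)) {
        pairs <- unique(cbind(lab[sel], sh[sel]))
        for (i in seq_len(nrow(pairs))) {
          ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
          if (ra != rb) parent[rb] <- ra
        }
      }
    }
    roots <- vapply(seq_len(nlab), find, integer(1))
    lab[lab > 0L] <- match(roots, sort(unique(roots)))[lab[lab > 0L]]
  }
  lab
}

## Per-label area (pixels) and centroid in um (pixel centers at
## (index - 0.5) * pixel size, 0-based convention).
particle_stats <- function(lab, px_um) {
  u <- seq_len(max(lab))
  if (max(lab) == 0) {
    return(data.frame(label = integer(0), area_um2 = numeric(0),
                      equivalent_diameter_um = numeric(0),
                      x_um = numeric(0), y_um = numeric(0)))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  npx <- tabulate(l, nbins = max(lab))
  ## arr.ind: row = y index, col = x index (1-based)
  cx <- tapply((idx[, 2] - 0.5) * px_um, l, mean)
  cy <- tapply((idx[, 1] - 0.5) * px_um, l, mean)
  area <- npx * px_um^2
  data.frame(label = u, area_um2 = area,
             equivalent_diameter_um = 2 * sqrt(area / pi),
             x_um = as.numeric(cx), y_um = as.numeric(cy))
}

#' Thresholded area fraction within an ROI
#'
#' Percentage of ROI pixels whose intensity exceeds the threshold.
#'
#' @param plane an \code{image_plane}.
#' @param roi logical mask congruent with the plane (default: whole field).
#' @param threshold intensity threshold (strictly above counts as positive).
#' @return percent, in [0, 100].
#' @export
area_fraction <- function(plane, roi = NULL, threshold) {
  check_plane(plane)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(plane$intensity), ncol(plane$intensity))
  check_roi(plane, roi)
  100 * sum(plane$intensity[roi] > threshold) / sum(roi)
}

#' Detect particles (plaques) above a threshold with a diameter filter
#'
#' 8-connected components of above-threshold pixels within the ROI;
#' components with equivalent circular diameter exceeding
#' \code{min_diameter_um} are retained (the conventional plaque filter is
#' > 8 um). Density is reported in objects per mm^2 of ROI.
#'
#' @inheritParams area_fraction
#' @param min_diameter_um minimum equivalent diameter (strict inequality);
#'   set to 0 to keep all components.
#' @return list of class \code{particle_result}: \code{particles}
#'   (data.frame: area_um2, equivalent_diameter_um, centroid x_um/y_um),
#'   \code{count}, \code{density_per_mm2}, \code{mean_size_um2},
#'   \code{roi_area_um2}.
#' @export
detect_particles <- function(plane, roi = NULL, threshold, min_diameter_um = 8) {
  check_plane(plane)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(plane$intensity), ncol(plane$intensity))
  check_roi(plane, roi)
  px <- plane$pixel_size_um
  mask <- plane$intensity > threshold & roi
  tab <- particle_stats(label8(mask), px)
  tab <- tab[tab$equivalent_diameter_um > min_diameter_um, , drop = FALSE]
  rownames(tab) <- NULL
  roi_area_um2 <- sum(roi) * px^2
  structure(
    list(particles = tab, count = nrow(tab),
         density_per_mm2 = nrow(tab) / (roi_area_um2 / 1e6),
         mean_size_um2 = if (nrow(tab)) mean(tab$area_um2) else NA_real_,
         roi_area_um2 = roi_area_um2),
    class = "particle_result"
  )
}

#' @export
print.particle_result <- function(x, ...) {
  cat(sprintf("%d particles, %.2f /mm^2, mean size %.1f um^2 (ROI %.3g um^2)\n",
              x$count, x$density_per_mm2, x$mean_size_um2, x$roi_area_um2))
  invisible(x)
}

#' Microglial soma density and size
#'
#' Particle analysis with a soma-scale size gate: components with equivalent
#' diameter inside \code{[min_diameter_um, max_diameter_um]} count as cell
#' bodies. The threshold should isolate the bright somata from the dimmer
#' processes.
#'
#' @inheritParams area_fraction
#' @param min_diameter_um,max_diameter_um soma size gate (equivalent
#'   diameter, um).
#' @return list: \code{somata} (centroid table), \code{density_per_mm2},
#'   \code{mean_soma_area_um2}.
#' @export
microglia_somata <- function(plane, roi = NULL, threshold,
                             min_diameter_um = 3, max_diameter_um = 15) {
  res <- detect_particles(plane, roi, threshold, min_diameter_um = min_diameter_um)
  tab <- res$particles
  tab <- tab[tab$equivalent_diameter_um <= max_diameter_um, , drop = FALSE]
  list(somata = tab,
       density_per_mm2 = nrow(tab) / (res$roi_area_um2 / 1e6),
       mean_soma_area_um2 = if (nrow(tab)) mean(tab$area_um2) else NA_real_)
}

# Skeletonization -------------------------------------------------------------

shift_mat <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(0L, n, p)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(p, p + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

## Zhang-Suen-style thinning of a binary matrix to a (near) 1-pixel-wide
## skeleton. The neighbor-count condition is tightened from B >= 2 to
## B >= 3 so that 2-neighbor stroke tips are never deleted: the classic
## B = 2 rule progressively unravels oblique stroke ends while wide regions
## elsewhere keep the iteration alive. The price is an occasional extra
## corner pixel on staircases, which the skeleton-graph stage (redundant
## diagonal removal + chord lengths) absorbs.
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      ## neighbors in Zhang-Suen order P2..P9 = N, NE, E, SE, S, SW, W, NW
      ## (rows increase downward, so N = row - 1)
      p2 <- shift_mat(m, 1, 0);  p3 <- shift_mat(m, 1, -1)
      p4 <- shift_mat(m, 0, -1); p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1, 0); p7 <- shift_mat(m, -1, 1)
      p8 <- shift_mat(m, 0, 1);  p9 <- shift_mat(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- m == 1 & b >= 3 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & b >= 3 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

## Skeleton graph: nodes are skeleton pixels, edges connect 8-neighbors,
## except that a diagonal edge is dropped when the two pixels share an
## orthogonal skeleton neighbor (the staircase shortcut), so clean paths
## have degree 2. Returns an edge list (linear indices, weight in pixel
## units) for the TRUE pixels of `sk`.
skeleton_edges <- function(sk) {
  nr <- nrow(sk)
  idx <- which(sk)
  if (length(idx) == 0) {
    return(data.frame(a = integer(0), b = integer(0), w = numeric(0)))
  }
  at <- function(r, c) r >= 1 & r <= nr & c >= 1 & c <= ncol(sk) &
    sk[cbind(pmax(1, pmin(nr, r)), pmax(1, pmin(ncol(sk), c)))]
  rr <- ((idx - 1) %% nr) + 1
  cc <- ((idx - 1) %/% nr) + 1
  edges <- list()
  add_edges <- function(dr, dc, w, diag_check) {
    r2 <- rr + dr; c2 <- cc + dc
    ok <- at(r2, c2)
    if (diag_check) {
      ## drop diagonal edges with a shared orthogonal neighbor
      red <- at(rr, cc + dc) | at(rr + dr, cc)
      ok <- ok & !red
    }
    if (any(ok)) {
      edges[[length(edges) + 1]] <<- data.frame(
        a = idx[ok], b = (c2[ok] - 1) * nr + r2[ok], w = w)
    }
  }
  add_edges(0, 1, 1, FALSE)          # E
  add_edges(1, 0, 1, FALSE)          # S
  add_edges(1, 1, sqrt(2), TRUE)     # SE
  add_edges(-1, 1, sqrt(2), TRUE)    # NE
  if (length(edges) == 0) {
    return(data.frame(a = integer(0), b = integer(0), w = numeric(0)))
  }
  do.call(rbind, edges)
}

## Union-find connected components over an edge list restricted to `nodes`.
edge_components <- function(nodes, edges) {
  comp <- seq_along(nodes)
  names(comp) <- as.character(nodes)
  find <- function(x) {
    while (comp[x] != x) {
      comp[x] <<- comp[comp[x]]
      x <- comp[x]
    }
    x
  }
  keep <- edges$a %in% nodes & edges$b %in% nodes
  ia <- match(edges$a[keep], nodes); ib <- match(edges$b[keep], nodes)
  for (k in seq_along(ia)) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) comp[rb] <- ra
  }
  roots <- vapply(seq_along(nodes), find, numeric(1))
  match(roots, unique(roots))
}

## Euclidean chord length of one branch component: order the pixels along
## the path and sum straight chords of a few pixels' stride, which removes
## the staircase overestimate of stepwise (1 / sqrt 2) length on oblique
## segments. Falls back to the edge-weight sum for loops.
path_chord_length <- function(members, edges, nr, stride = 4) {
  n <- length(members)
  if (n <= 1) return(0)
  keep <- edges$a %in% members & edges$b %in% members
  ia <- match(edges$a[keep], members); ib <- match(edges$b[keep], members)
  adj <- vector("list", n)
  for (k in seq_along(ia)) {
    adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
    adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
  }
  degs <- lengths(adj)
  start <- which(degs <= 1)[1]
  if (is.na(start)) return(sum(edges$w[keep]))
  order_idx <- integer(n)
  visited <- rep(FALSE, n)
  cur <- start
  for (i in seq_len(n)) {
    order_idx[i] <- cur
    visited[cur] <- TRUE
    nxt <- adj[[cur]][!visited[adj[[cur]]]]
    if (length(nxt) == 0) {
      order_idx <- order_idx[seq_len(i)]
      break
    }
    cur <- nxt[1]
  }
  m <- members[order_idx]
  rr <- ((m - 1) %% nr) + 1
  cc <- ((m - 1) %/% nr) + 1
  pick <- unique(c(seq(1, length(m), by = stride), length(m)))
  sum(sqrt(diff(rr[pick])^2 + diff(cc[pick])^2))
}

## Branch/junction/length analysis of one cell's skeleton. Junction pixels
## (graph degree >= 3) cluster by adjacency; clusters linked by connector
## segments shorter than `merge_px` merge into one junction (thinning often
## splits an n-way crossing into nearby 3-way nodes). Dead-end spurs shorter
## than `prune_px` hanging off a junction are pruned. Branches are the
## remaining components after junction removal; lengths are Euclidean chord
## sums along each path plus the steps joining them to their junctions.
analyze_skeleton <- function(sk, prune_px = 4, merge_px = 5) {
  nr <- nrow(sk)
  edges <- NULL; nodes <- NULL; deg <- NULL
  junction_nodes <- NULL; branch_nodes <- NULL; bcomp <- NULL
  recompute <- function() {
    edges <<- skeleton_edges(sk)
    nodes <<- which(sk)
    deg <<- table(factor(c(edges$a, edges$b), levels = nodes))
    junction_nodes <<- nodes[deg >= 3]
    branch_nodes <<- setdiff(nodes, junction_nodes)
    bcomp <<- if (length(branch_nodes)) edge_components(branch_nodes, edges)
              else integer(0)
  }
  recompute()
  if (length(nodes) == 0) {
    return(list(n_branches = 0L, n_junctions = 0L, length_px = 0))
  }
  ## prune short dead-end spurs attached to a junction
  if (length(junction_nodes)) {
    pruned <- FALSE
    for (cid in unique(bcomp)) {
      members <- branch_nodes[bcomp == cid]
      if (length(members) > prune_px) next
      touches_j <- any((edges$a %in% members & edges$b %in% junction_nodes) |
                       (edges$b %in% members & edges$a %in% junction_nodes))
      has_end <- any(deg[as.character(members)] == 1)
      if (touches_j && has_end) {
        sk[members] <- FALSE
        pruned <- TRUE
      }
    }
    if (pruned) recompute()
  }
  ## initial junction clusters by adjacency
  n_clust <- 0L; jclust <- integer(0)
  if (length(junction_nodes)) {
    jclust <- edge_components(junction_nodes, skeleton_edges_full(sk, junction_nodes))
    n_clust <- max(jclust)
  }
  ## branch components: touched clusters and path lengths
  comp_ids <- if (length(bcomp)) unique(bcomp) else integer(0)
  touched <- list(); plen <- numeric(0); join_len <- numeric(0)
  for (cid in comp_ids) {
    members <- branch_nodes[bcomp == cid]
    tc <- integer(0); jl <- 0
    if (n_clust > 0) {
      sel <- (edges$a %in% members & edges$b %in% junction_nodes) |
             (edges$b %in% members & edges$a %in% junction_nodes)
      if (any(sel)) {
        jn <- ifelse(edges$a[sel] %in% junction_nodes, edges$a[sel], edges$b[sel])
        cl <- jclust[match(jn, junction_nodes)]
        for (cc in unique(cl)) {
          tc <- c(tc, cc)
          jl <- jl + min(edges$w[sel][cl == cc])
        }
      }
    }
    touched[[as.character(cid)]] <- tc
    plen[as.character(cid)] <- path_chord_length(members, edges, nr)
    join_len[as.character(cid)] <- jl
  }
  ## merge clusters linked by short connectors; connectors are not branches
  parent <- seq_len(max(1L, n_clust))
  findc <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  is_connector <- setNames(rep(FALSE, length(comp_ids)), as.character(comp_ids))
  for (cid in comp_ids) {
    key <- as.character(cid)
    tc <- unique(touched[[key]])
    if (length(tc) >= 2 && plen[key] + join_len[key] <= merge_px) {
      is_connector[key] <- TRUE
      for (k in seq_along(tc)[-1]) {
        ra <- findc(tc[1]); rb <- findc(tc[k])
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  n_junctions <- if (n_clust > 0) {
    length(unique(vapply(seq_len(n_clust), findc, numeric(1))))
  } else 0L
  n_branches <- sum(!is_connector)
  if (n_branches == 0L && length(nodes) > 0) n_branches <- 1L
  total <- sum(plen) + sum(join_len)
  list(n_branches = as.integer(n_branches),
       n_junctions = as.integer(n_junctions),
       length_px = total)
}

## Full 8-adjacency edges among a subset of pixels (for junction clustering,
## where staircase pruning must not split a cluster).
skeleton_edges_full <- function(sk, subset_nodes) {
  sub <- matrix(FALSE, nrow(sk), ncol(sk))
  sub[subset_nodes] <- TRUE
  nr <- nrow(sub)
  idx <- which(sub)
  rr <- ((idx - 1) %% nr) + 1
  cc <- ((idx - 1) %/% nr) + 1
  edges <- list()
  for (d in list(c(0, 1), c(1, 0), c(1, 1), c(-1, 1))) {
    r2 <- rr + d[1]; c2 <- cc + d[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(sub)
    ok[ok] <- sub[cbind(r2[ok], c2[ok])]
    if (any(ok)) {
      edges[[length(edges) + 1]] <- data.frame(
        a = idx[ok], b = (c2[ok] - 1) * nr + r2[ok], w = 1)
    }
  }
  if (length(edges) == 0) {
    return(data.frame(a = integer(0), b = integer(0), w = numeric(0)))
  }
  do.call(rbind, edges)
}

#' Skeleton morphometry of microglia-like cells
#'
#' Each 8-connected above-threshold component is thinned to a medial-axis
#' skeleton (Zhang-Suen). Skeleton pixels with three or more skeleton
#' neighbors form junctions (adjacent junction pixels cluster into one
#' junction); removing them splits the skeleton into branches. Branch length
#' sums pixel-step distances (1 or sqrt(2) pixel units, scaled to um) along
#' each branch path, plus the step connecting each branch end to its
#' junction.
#'
#' @inheritParams area_fraction
#' @param min_area_um2 components smaller than this are ignored (debris).
#' @return data.frame of class \code{morphometry_record}, one row per cell:
#'   \code{cell, branch_count, junction_count, total_branch_length_um}; empty
#'   (zero rows) when there is no foreground.
#' @export
skeleton_morphometry <- function(plane, roi = NULL, threshold, min_area_um2 = 10) {
  check_plane(plane)
  px <- plane$pixel_size_um
  mask <- plane$intensity > threshold
  if (!is.null(roi)) mask <- mask & roi
  lab <- label8(mask)
  ncell <- max(lab)
  rows <- list()
  for (cell in seq_len(ncell)) {
    cm <- lab == cell
    if (sum(cm) * px^2 < min_area_um2) next
    sk <- skeletonize(cm)
    if (!any(sk)) next
    an <- analyze_skeleton(sk)
    rows[[length(rows) + 1]] <- data.frame(
      cell = cell, branch_count = an$n_branches,
      junction_count = an$n_junctions,
      total_branch_length_um = an$length_px * px
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = integer(0), branch_count = integer(0),
               junction_count = integer(0), total_branch_length_um = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("morphometry_record", "data.frame")
  out
}

# Neighborhoods and colocalization --------------------------------------------

#' Plaque-centered microglial neighborhoods
#'
#' For each detected plaque, counts microglia whose soma centroid lies within
#' \code{radius_um} of the plaque centroid, and reports the plaque-microglia
#' colocalized area inside that disk divided by the count (coverage per
#' microglion, the automated surrogate for manual plaque-associated
#' microglia counting).
#'
#' @param plaque_plane,microglia_plane congruent calibrated planes.
#' @param plaque_threshold,soma_threshold,microglia_threshold intensity
#'   thresholds for plaque detection, soma detection, and the microglial
#'   signal used for coverage.
#' @param radius_um neighborhood radius (the conventional 30 um).
#' @param min_plaque_diameter_um plaque diameter filter.
#' @return data.frame, one row per plaque: centroid, \code{microglia_count},
#'   \code{coverage_um2_per_mg} (NA with \code{coverage_flagged = TRUE} when
#'   no microglia are within the radius).
#' @export
plaque_neighborhood <- function(plaque_plane, microglia_plane,
                                plaque_threshold, soma_threshold,
                                microglia_threshold = soma_threshold / 2,
                                radius_um = 30, min_plaque_diameter_um = 8) {
  check_plane(plaque_plane); check_plane(microglia_plane)
  if (!all(dim(plaque_plane$intensity) == dim(microglia_plane$intensity)) ||
      plaque_plane$pixel_size_um != microglia_plane$pixel_size_um) {
    stop("planes must be congruent and share calibration", call. = FALSE)
  }
  px <- plaque_plane$pixel_size_um
  plaques <- detect_particles(plaque_plane, threshold = plaque_threshold,
                              min_diameter_um = min_plaque_diameter_um)$particles
  if (nrow(plaques) == 0) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      microglia_count = integer(0),
                      coverage_um2_per_mg = numeric(0),
                      coverage_flagged = logical(0)))
  }
  somata <- microglia_somata(microglia_plane, threshold = soma_threshold)$somata
  colocal <- plaque_plane$intensity > plaque_threshold &
    microglia_plane$intensity > microglia_threshold
  nr <- nrow(colocal); nc <- ncol(colocal)
  xs <- (seq_len(nc) - 0.5) * px
  ys <- (seq_len(nr) - 0.5) * px
  out <- plaques[, c("x_um", "y_um")]
  out$microglia_count <- vapply(seq_len(nrow(plaques)), function(i) {
    if (nrow(somata) == 0) return(0L)
    d <- sqrt((somata$x_um - plaques$x_um[i])^2 + (somata$y_um - plaques$y_um[i])^2)
    sum(d <= radius_um)
  }, integer(1))
  out$coverage_um2_per_mg <- NA_real_
  for (i in seq_len(nrow(plaques))) {
    if (out$microglia_count[i] == 0) next
    disk <- outer((ys - plaques$y_um[i])^2, (xs - plaques$x_um[i])^2, "+") <= radius_um^2
    out$coverage_um2_per_mg[i] <- sum(colocal & disk) * px^2 / out$microglia_count[i]
  }
  out$coverage_flagged <- out$microglia_count == 0
  rownames(out) <- NULL
  out
}

#' Colocalized area of two channels
#'
#' Area (um^2) where both channels exceed their thresholds, plus the
#' colocalized fraction (intersection over union of the positive areas).
#' When thresholds are not supplied they are chosen by a Costes-style
#' bisection along channel A's intensity range that drives the correlation
#' of the below-threshold pixels to zero.
#'
#' @param planeA,planeB congruent planes.
#' @param threshold_a,threshold_b fixed thresholds; leave NULL for the
#'   automated search.
#' @return list: \code{area_um2}, \code{fraction}, thresholds used.
#' @export
colocalized_area <- function(planeA, planeB, threshold_a = NULL, threshold_b = NULL) {
  check_plane(planeA); check_plane(planeB)
  if (!all(dim(planeA$intensity) == dim(planeB$intensity))) {
    stop("planes must be congruent", call. = FALSE)
  }
  a <- planeA$intensity; b <- planeB$intensity
  if (is.null(threshold_a) || is.null(threshold_b)) {
    if (sd(a) == 0 || sd(b) == 0) {
      stop("constant channel: automated colocalization threshold undefined", call. = FALSE)
    }
    ## Costes-style search: walk the threshold down channel A's range (with
    ## B coupled through the A-B regression) and stop at the highest
    ## threshold where the below-threshold pixels are uncorrelated; below
    ## that point the correlation is dominated by noise and no longer
    ## monotone, so a scan is used rather than bisection
    fit <- lm(as.vector(b) ~ as.vector(a))
    below_cor <- function(ta) {
      tb <- coef(fit)[1] + coef(fit)[2] * ta
      sel <- a < ta | b < tb
      if (sum(sel) < 10 || sd(a[sel]) == 0 || sd(b[sel]) == 0) return(c(1, 10))
      c(cor(a[sel], b[sel]), sum(sel))
    }
    grid <- seq(max(a), min(a), length.out = 100)
    threshold_a <- min(a)
    for (ta in grid) {
      cc <- below_cor(ta)
      ## stop where the below-threshold correlation is statistically
      ## indistinguishable from zero (|r| within its sampling error)
      if (cc[1] <= 1.96 / sqrt(cc[2])) {
        threshold_a <- ta
        break
      }
    }
    threshold_b <- unname(coef(fit)[1] + coef(fit)[2] * threshold_a)
  }
  pos_a <- a > threshold_a; pos_b <- b > threshold_b
  inter <- sum(pos_a & pos_b)
  uni <- sum(pos_a | pos_b)
  px <- planeA$pixel_size_um
  list(area_um2 = inter * px^2,
       fraction = if (uni > 0) inter / uni else 0,
       threshold_a = threshold_a, threshold_b = threshold_b)
}
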