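#' Configuration of a synthetic multi-round brightfield scene
#'
#' Defines the ground-truthed phantom the generator renders: a field of
#' microglia/macrophage cells with known phenotypes (soma disk plus thin
#' processes), hematoxylin-counterstained nuclei, amyloid-plaque blobs
#' (with sub-exclusion diffuse speckles), tangle cell bodies with
#' neurites, vessel masks, per-round rigid misalignment, optional residual
#' chromogen carry-over between rounds, and additive Gaussian
#' optical-density noise. All randomness is fixed by `seed`.
#'
#' @param field_um side length of the square field, microns.
#' @param microns_per_pixel pixel size, microns.
#' @param n_cells number of microglia/macrophage cells.
#' @param phenotype_proportions named proportions over the five phenotype
#'   labels (must sum to 1 with `gfap_conflict_fraction`'s complement).
#' @param gfap_conflict_fraction fraction of cells rendered IBA1+GFAP+
#'   (QC class).
#' @param panel staining order of the marker rounds.
#' @param n_plaques,plaque_radius_um plaque count and nominal radius range
#'   (blobs are unions of jittered disks around the nominal radius).
#' @param n_diffuse_speckles,speckle_radius_um small diffuse amyloid
#'   deposits below the pathology size exclusion.
#' @param n_tangles,tangle_radius_um PHF1+ cell-body count and radius.
#' @param n_vessels,vessel_halfwidth_um vessel segment count and
#'   half-width (masks only; vessels are not a stained channel).
#' @param n_other_nuclei hematoxylin-only nuclei (non-microglial cells).
#' @param n_astrocytes GFAP+ astrocytes (star-shaped, IBA1-negative).
#' @param n_process_fragments sub-exclusion IBA1+ process cuts.
#' @param attraction named per-phenotype plaque-attraction coefficients
#'   `a`: placement density is weighted `1 + a * exp(-d / attraction_scale_um)`
#'   with `d` the distance to the nearest plaque edge.
#' @param attraction_scale_um attraction length scale, microns.
#' @param contact_fraction optional named per-phenotype fraction of cells
#'   placed in direct contact with a plaque (the rest are kept clear of
#'   plaques); overrides `attraction` for those phenotypes.
#' @param max_shift_px,max_rotation_deg per-round rigid misalignment
#'   ranges (round 1 is the reference and is never misaligned).
#' @param retention_fraction chromogen carry-over per de-staining step:
#'   the fraction of stained *pixels* whose chromogen survives one
#'   de-staining (0 = complete removal). Retention is realized through a
#'   smooth spatial survival field fixed by the seed (blocking failures
#'   are patchy, not pixel salt), cut at the exact retention quantile over
#'   the stained region, so raising the fraction with the same seed only
#'   ever adds retained pixels; stain survives k de-stainings where the
#'   field lies below the `retention_fraction^k` quantile.
#' @param od_sigma additive Gaussian noise in OD space, per RGB sample.
#' @param cell_od,hema_od,background_od,plaque_od rendered stain densities
#'   (OD units).
#' @param soma_radius_um,nucleus_radius_um,n_processes,process_length_um,
#'   process_halfwidth_um cell geometry.
#' @param min_separation_um minimum centre-to-centre cell separation; the
#'   generator fails with a config error when cells cannot be packed.
#' @param white_point,quantize rendered intensity scale; `quantize` rounds
#'   to integer (8-bit) levels.
#' @param stains a [stain_matrix()] with the chromogen first and
#'   hematoxylin second.
#' @param seed RNG seed fixing all randomness.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(field_um = 512, microns_per_pixel = 1, n_cells = 120,
                         phenotype_proportions = c(
                           "IBA1+P2Y12+" = 0.45, "IBA1-only" = 0.25,
                           "IBA1+Ferritin+" = 0.10, "IBA1+Ferritin+CD68+" = 0.12,
                           "IBA1+CD68+" = 0.08),
                         gfap_conflict_fraction = 0,
                         panel = c("P2Y12", "TMEM119", "Ferritin", "CD45",
                                   "CD68", "IBA1", "GFAP", "PHF1", "Abeta"),
                         n_plaques = 3, plaque_radius_um = c(12, 22),
                         n_diffuse_speckles = 20, speckle_radius_um = c(0.8, 2),
                         n_tangles = 3, tangle_radius_um = c(6, 8),
                         n_vessels = 2, vessel_halfwidth_um = 4,
                         n_other_nuclei = round(0.8 * n_cells),
                         n_astrocytes = 10, n_process_fragments = 15,
                         attraction = c("IBA1+P2Y12+" = 0, "IBA1-only" = 0,
                                        "IBA1+Ferritin+" = 2,
                                        "IBA1+Ferritin+CD68+" = 8,
                                        "IBA1+CD68+" = 2),
                         attraction_scale_um = 25,
                         contact_fraction = NULL,
                         max_shift_px = 8, max_rotation_deg = 2,
                         retention_fraction = 0, od_sigma = 0.01,
                         cell_od = 0.9, hema_od = 0.75, background_od = 0.06,
                         plaque_od = 1.1,
                         soma_radius_um = c(3.6, 4.8), nucleus_radius_um = 2.6,
                         n_processes = 2:4, process_length_um = c(7, 12),
                         process_halfwidth_um = 0.6,
                         min_separation_um = 30,
                         white_point = 255, quantize = TRUE,
                         stains = default_stain_matrix(), seed = 1) {
  pp <- phenotype_proportions
  if (is.null(names(pp)) || !setequal(names(pp), phenotype_labels()))
    stop("phenotype_proportions must be named with the five phenotype labels",
         call. = FALSE)
  if (abs(sum(pp) - 1) > 1e-9)
    stop("phenotype_proportions must sum to 1", call. = FALSE)
  if (gfap_conflict_fraction < 0 || gfap_conflict_fraction >= 1)
    stop("gfap_conflict_fraction must be in [0, 1)", call. = FALSE)
  stopifnot(field_um > 0, microns_per_pixel > 0, n_cells >= 0,
            retention_fraction >= 0, retention_fraction <= 1, od_sigma >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "scene_config"
  cfg
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(
    "<scene_config> %g um field @ %g um/px, %d cells, %d-round panel, %d plaques, seed %d\n",
    x$field_um, x$microns_per_pixel, x$n_cells, length(x$panel),
    x$n_plaques, x$seed))
  invisible(x)
}

## ---- rasterization primitives (pixel units, 0-based centres) ----------

soft_cov <- function(r, d, soft) pmin(pmax((r - d) / soft + 0.5, 0), 1)

draw_disk <- function(canvas, cx, cy, r, amp, soft = 0.7) {
  ny <- nrow(canvas); nx <- ncol(canvas)
  x1 <- max(floor(cx - r - soft), 0); x2 <- min(ceiling(cx + r + soft), nx - 1)
  y1 <- max(floor(cy - r - soft), 0); y2 <- min(ceiling(cy + r + soft), ny - 1)
  if (x1 > x2 || y1 > y2) return(canvas)
  xs <- x1:x2; ys <- y1:y2
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  sub <- canvas[ys + 1, xs + 1, drop = FALSE]
  canvas[ys + 1, xs + 1] <- pmax(sub, amp * soft_cov(r, d, soft))
  canvas
}

draw_capsule <- function(canvas, x0, y0, x1, y1, hw, amp, soft = 0.7) {
  ny <- nrow(canvas); nx <- ncol(canvas)
  pad <- hw + soft
  xa <- max(floor(min(x0, x1) - pad), 0); xb <- min(ceiling(max(x0, x1) + pad), nx - 1)
  ya <- max(floor(min(y0, y1) - pad), 0); yb <- min(ceiling(max(y0, y1) + pad), ny - 1)
  if (xa > xb || ya > yb) return(canvas)
  xs <- xa:xb; ys <- ya:yb
  vx <- x1 - x0; vy <- y1 - y0
  L2 <- max(vx^2 + vy^2, 1e-12)
  PX <- base::matrix(rep(xs, each = length(ys)), length(ys))
  PY <- base::matrix(rep(ys, length(xs)), length(ys))
  t <- pmin(pmax(((PX - x0) * vx + (PY - y0) * vy) / L2, 0), 1)
  d <- sqrt((PX - (x0 + t * vx))^2 + (PY - (y0 + t * vy))^2)
  sub <- canvas[ys + 1, xs + 1, drop = FALSE]
  canvas[ys + 1, xs + 1] <- pmax(sub, amp * soft_cov(hw, d, soft))
  canvas
}

## ---- geometry sampling -------------------------------------------------

# run expr with a private RNG stream
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

sample_marker_vector <- function(label) {
  mk <- c(IBA1 = TRUE, P2Y12 = FALSE, TMEM119 = FALSE, CD45 = FALSE,
          CD68 = FALSE, Ferritin = FALSE, GFAP = FALSE)
  switch(label,
    "IBA1+P2Y12+" = { mk["P2Y12"] <- TRUE
                      mk["TMEM119"] <- runif(1) < 0.7
                      mk["CD45"] <- runif(1) < 0.8 },
    "IBA1-only" = { mk["CD45"] <- runif(1) < 0.5 },
    "IBA1+Ferritin+" = { mk["Ferritin"] <- TRUE; mk["CD45"] <- runif(1) < 0.8 },
    "IBA1+Ferritin+CD68+" = { mk[c("Ferritin", "CD68")] <- TRUE
                              mk["CD45"] <- runif(1) < 0.9 },
    "IBA1+CD68+" = { mk["CD68"] <- TRUE; mk["CD45"] <- runif(1) < 0.8 },
    "gfap_conflict" = { mk["GFAP"] <- TRUE },
    stop("unknown phenotype label: ", label))
  mk
}

# distance from a point to the nearest nominal plaque edge (um); Inf if no
# plaques
plaque_edge_distance <- function(x, y, plaques) {
  if (length(plaques) == 0L) return(Inf)
  min(vapply(plaques, function(p)
    sqrt((x - p$x)^2 + (y - p$y)^2) - p$radius, numeric(1)))
}

sample_scene_truth <- function(cfg) {
  L <- cfg$field_um
  margin <- 18
  runit <- function(lo, hi) runif(1, lo, hi)

  plaques <- lapply(seq_len(cfg$n_plaques), function(i) {
    R <- runit(cfg$plaque_radius_um[1], cfg$plaque_radius_um[2])
    x <- runit(margin + R, L - margin - R); y <- runit(margin + R, L - margin - R)
    k <- 5L
    ang <- runif(k, 0, 2 * pi); off <- runif(k, 0.15 * R, 0.5 * R)
    disks <- rbind(
      data.frame(dx = 0, dy = 0, r = 0.65 * R),
      data.frame(dx = off * cos(ang), dy = off * sin(ang),
                 r = runif(k, 0.35 * R, 0.6 * R)))
    list(id = i, x = x, y = y, radius = R, disks = disks)
  })
  speckles <- if (cfg$n_diffuse_speckles > 0)
    data.frame(x = runif(cfg$n_diffuse_speckles, 2, L - 2),
               y = runif(cfg$n_diffuse_speckles, 2, L - 2),
               r = runif(cfg$n_diffuse_speckles, cfg$speckle_radius_um[1],
                         cfg$speckle_radius_um[2]))
    else data.frame(x = numeric(), y = numeric(), r = numeric())
  tangles <- lapply(seq_len(cfg$n_tangles), function(i) {
    r <- runit(cfg$tangle_radius_um[1], cfg$tangle_radius_um[2])
    x <- runit(margin, L - margin); y <- runit(margin, L - margin)
    nn <- sample(1:2, 1)
    ang <- runif(nn, 0, 2 * pi); len <- runif(nn, 18, 30)
    list(id = i, x = x, y = y, radius = r,
         neurites = data.frame(angle = ang, len = len, hw = 0.8))
  })
  vessels <- lapply(seq_len(cfg$n_vessels), function(i) {
    side <- sample(1:2, 1)
    if (side == 1) { x0 <- 0; x1 <- L; y0 <- runit(margin, L - margin); y1 <- runit(margin, L - margin) }
    else { y0 <- 0; y1 <- L; x0 <- runit(margin, L - margin); x1 <- runit(margin, L - margin) }
    list(id = i, x0 = x0, y0 = y0, x1 = x1, y1 = y1,
         hw = cfg$vessel_halfwidth_um)
  })

  # phenotype labels
  labs5 <- names(cfg$phenotype_proportions)
  gcf <- cfg$gfap_conflict_fraction
  labels <- if (cfg$n_cells > 0)
    sample(c(labs5, "gfap_conflict"), cfg$n_cells, replace = TRUE,
           prob = c(cfg$phenotype_proportions * (1 - gcf), gcf))
    else character()

  # positions: sequential rejection with plaque attraction / contact rule
  xs <- ys <- numeric(cfg$n_cells)
  cf <- cfg$contact_fraction
  a_max <- function(a) 1 + a
  clearance <- cfg$soma_radius_um[2] + cfg$process_length_um[2] + 3
  for (i in seq_len(cfg$n_cells)) {
    lab <- labels[i]
    a <- if (!is.null(cfg$attraction) && lab %in% names(cfg$attraction))
      cfg$attraction[[lab]] else 0
    in_contact_mode <- !is.null(cf) && lab %in% names(cf) && length(plaques) > 0
    want_contact <- in_contact_mode && runif(1) < cf[[lab]]
    placed <- FALSE
    for (try in 1:5000) {
      if (want_contact) {
        p <- plaques[[sample.int(length(plaques), 1)]]
        th <- runif(1, 0, 2 * pi)
        rad <- runif(1, 0.2, 0.7) * p$radius  # inside the blob's core disk
        x <- p$x + rad * cos(th); y <- p$y + rad * sin(th)
        if (x < margin || x > L - margin || y < margin || y > L - margin) next
      } else {
        x <- runit(margin, L - margin); y <- runit(margin, L - margin)
      }
      if (i > 1) {
        d2 <- (xs[seq_len(i - 1)] - x)^2 + (ys[seq_len(i - 1)] - y)^2
        if (min(d2) < cfg$min_separation_um^2) next
      }
      if (!want_contact && in_contact_mode) {
        # non-contact cells of a contact-fraction phenotype stay clear
        if (plaque_edge_distance(x, y, plaques) < clearance) next
      } else if (!want_contact && a > 0) {
        d <- max(plaque_edge_distance(x, y, plaques), 0)
        w <- 1 + a * exp(-d / cfg$attraction_scale_um)
        if (runif(1) > w / a_max(a)) next
      }
      xs[i] <- x; ys[i] <- y; placed <- TRUE; break
    }
    if (!placed)
      stop("scene config error: cells denser than packable under min_separation_um",
           call. = FALSE)
  }

  markers <- if (cfg$n_cells > 0)
    t(vapply(labels, sample_marker_vector,
             c(IBA1 = TRUE, P2Y12 = TRUE, TMEM119 = TRUE, CD45 = TRUE,
               CD68 = TRUE, Ferritin = TRUE, GFAP = TRUE)))
    else base::matrix(logical(), 0, 7,
                      dimnames = list(NULL, c("IBA1", "P2Y12", "TMEM119",
                                              "CD45", "CD68", "Ferritin", "GFAP")))
  geom <- lapply(seq_len(cfg$n_cells), function(i) {
    r <- runit(cfg$soma_radius_um[1], cfg$soma_radius_um[2])
    np <- sample(cfg$n_processes, 1)
    list(x = xs[i], y = ys[i], r = r,
         proc = data.frame(angle = runif(np, 0, 2 * pi),
                           len = runif(np, cfg$process_length_um[1],
                                       cfg$process_length_um[2]),
                           hw = cfg$process_halfwidth_um))
  })
  cells <- data.frame(id = seq_len(cfg$n_cells), x_um = xs, y_um = ys,
                      phenotype = labels,
                      soma_radius_um = vapply(geom, `[[`, numeric(1), "r"))
  cells <- cbind(cells, as.data.frame(markers))
  rownames(cells) <- NULL

  other_nuclei <- if (cfg$n_other_nuclei > 0)
    data.frame(x = runif(cfg$n_other_nuclei, 4, L - 4),
               y = runif(cfg$n_other_nuclei, 4, L - 4))
    else data.frame(x = numeric(), y = numeric())
  astro <- lapply(seq_len(cfg$n_astrocytes), function(i) {
    np <- sample(5:7, 1)
    list(x = runit(margin, L - margin), y = runit(margin, L - margin), r = 3.2,
         proc = data.frame(angle = runif(np, 0, 2 * pi),
                           len = runif(np, 9, 14), hw = 0.8))
  })
  fragments <- if (cfg$n_process_fragments > 0)
    data.frame(x = runif(cfg$n_process_fragments, 4, L - 4),
               y = runif(cfg$n_process_fragments, 4, L - 4),
               r = runif(cfg$n_process_fragments, 1.2, 2.6))
    else data.frame(x = numeric(), y = numeric(), r = numeric())

  # smooth chromogen-survival field (reference frame): Gaussian-blurred
  # white noise; stain survives k de-stainings where the field is below
  # its retention^k quantile over the stained region
  n_px <- round(cfg$field_um / cfg$microns_per_pixel)
  retention_field <- smooth_field(n_px, sigma = 2.5 / cfg$microns_per_pixel)

  # per-round true transforms (fixed -> moving, pixels); round 1 = reference
  ctr <- c((n_px - 1) / 2, (n_px - 1) / 2)
  transforms <- lapply(seq_along(cfg$panel), function(r) {
    if (r == 1) identity_transform(fixed_round = 1, moving_round = r)
    else rigid_transform(runif(1, -cfg$max_rotation_deg, cfg$max_rotation_deg),
                         runif(1, -cfg$max_shift_px, cfg$max_shift_px),
                         runif(1, -cfg$max_shift_px, cfg$max_shift_px),
                         center = ctr, fixed_round = 1, moving_round = r)
  })
  destain_transforms <- lapply(seq_along(cfg$panel), function(r)
    rigid_transform(runif(1, -cfg$max_rotation_deg, cfg$max_rotation_deg),
                    runif(1, -cfg$max_shift_px, cfg$max_shift_px),
                    runif(1, -cfg$max_shift_px, cfg$max_shift_px),
                    center = ctr, fixed_round = 1, moving_round = paste0(r, "-destained")))

  list(cells = cells, geom = geom, plaques = plaques, speckles = speckles,
       tangles = tangles, vessels = vessels, other_nuclei = other_nuclei,
       astrocytes = astro, fragments = fragments,
       transforms = transforms, destain_transforms = destain_transforms,
       retention_field = retention_field,
       retained = data.frame(round = seq_along(cfg$panel),
                             fraction = cfg$retention_fraction),
       config = cfg)
}

## ---- rendering ---------------------------------------------------------

# chromogen density for one marker round, geometry pushed through `tr`
# (reference -> moving)
render_chromogen <- function(truth, marker, tr) {
  cfg <- truth$config
  mpp <- cfg$microns_per_pixel
  n_px <- round(cfg$field_um / mpp)
  C <- base::matrix(0, n_px, n_px)
  p <- decompose_transform(tr)
  th <- p["angle_deg"] * pi / 180
  tp <- function(x, y) {              # um -> moving-frame px
    q <- apply_transform(tr, cbind(x / mpp, y / mpp))
    list(x = q[, 1], y = q[, 2])
  }
  amp <- cfg$cell_od
  draw_cell <- function(g) {
    q <- tp(g$x, g$y)
    C <<- draw_disk(C, q$x, q$y, g$r / mpp, amp)
    for (j in seq_len(nrow(g$proc))) {
      a <- g$proc$angle[j] + th
      x1 <- g$x + g$proc$len[j] * cos(g$proc$angle[j])
      y1 <- g$y + g$proc$len[j] * sin(g$proc$angle[j])
      q1 <- tp(x1, y1)
      C <<- draw_capsule(C, q$x, q$y, q1$x, q1$y, g$proc$hw[j] / mpp, amp)
    }
  }
  if (marker %in% colnames(truth$cells)[-(1:5)] || marker %in%
      c("IBA1", "P2Y12", "TMEM119", "CD45", "CD68", "Ferritin", "GFAP")) {
    pos <- which(truth$cells[[marker]])
    for (i in pos) draw_cell(truth$geom[[i]])
  }
  if (marker == "GFAP") {
    for (g in truth$astrocytes) draw_cell(g)
  }
  if (marker == "IBA1" && nrow(truth$fragments)) {
    for (j in seq_len(nrow(truth$fragments))) {
      q <- tp(truth$fragments$x[j], truth$fragments$y[j])
      C <- draw_disk(C, q$x, q$y, truth$fragments$r[j] / mpp, amp)
    }
  }
  if (marker == "Abeta") {
    pamp <- cfg$plaque_od
    for (p2 in truth$plaques) {
      for (j in seq_len(nrow(p2$disks))) {
        q <- tp(p2$x + p2$disks$dx[j], p2$y + p2$disks$dy[j])
        C <- draw_disk(C, q$x, q$y, p2$disks$r[j] / mpp, pamp, soft = 1.5)
      }
    }
    if (nrow(truth$speckles)) for (j in seq_len(nrow(truth$speckles))) {
      q <- tp(truth$speckles$x[j], truth$speckles$y[j])
      C <- draw_disk(C, q$x, q$y, truth$speckles$r[j] / mpp, 0.9)
    }
  }
  if (marker == "PHF1") {
    for (tg in truth$tangles) {
      q <- tp(tg$x, tg$y)
      C <- draw_disk(C, q$x, q$y, tg$radius / mpp, amp)
      for (j in seq_len(nrow(tg$neurites))) {
        x1 <- tg$x + tg$neurites$len[j] * cos(tg$neurites$angle[j])
        y1 <- tg$y + tg$neurites$len[j] * sin(tg$neurites$angle[j])
        q1 <- tp(x1, y1)
        C <- draw_capsule(C, q$x, q$y, q1$x, q1$y, tg$neurites$hw[j] / mpp, amp)
      }
    }
  }
  C
}

render_hematoxylin <- function(truth, tr) {
  cfg <- truth$config
  mpp <- cfg$microns_per_pixel
  n_px <- round(cfg$field_um / mpp)
  H <- base::matrix(cfg$background_od, n_px, n_px)
  tp <- function(x, y) {
    q <- apply_transform(tr, cbind(x / mpp, y / mpp))
    list(x = q[, 1], y = q[, 2])
  }
  nr <- cfg$nucleus_radius_um / mpp
  put <- function(x, y, r = nr) {
    q <- tp(x, y)
    H <<- draw_disk(H, q$x, q$y, r, cfg$hema_od)
  }
  for (g in truth$geom) put(g$x, g$y)
  if (nrow(truth$other_nuclei))
    for (j in seq_len(nrow(truth$other_nuclei)))
      put(truth$other_nuclei$x[j], truth$other_nuclei$y[j])
  for (g in truth$astrocytes) put(g$x, g$y)
  for (tg in truth$tangles) put(tg$x, tg$y)
  H
}

# periodic Gaussian-blurred white noise field, sd-normalized
smooth_field <- function(n, sigma) {
  z <- base::matrix(rnorm(n * n), n, n)
  fr <- c(0:(n %/% 2), -((ceiling(n / 2) - 1):1)) / n
  g <- exp(-2 * pi^2 * sigma^2 * outer(fr^2, fr^2, `+`))
  f <- Re(stats::fft(stats::fft(z) * g, inverse = TRUE)) / n^2
  (f - mean(f)) / stats::sd(f)
}

# binary chromogen-survival mask after k de-stainings of the
# round whose reference-frame chromogen field is `C_ref`, expressed in the
# moving frame of `tr`; the quantile cut makes the retained fraction of
# stained pixels equal retention^k
survival_mask <- function(truth, k, tr, C_ref) {
  cfg <- truth$config
  stained <- C_ref > 0.5 * cfg$cell_od
  if (!any(stained))
    return(base::matrix(0, nrow(C_ref), ncol(C_ref)))
  q <- stats::quantile(truth$retention_field[stained],
                       cfg$retention_fraction^k, names = FALSE)
  M <- (truth$retention_field < q) * 1
  p <- decompose_transform(tr)
  if (abs(p["angle_deg"]) < 1e-12 && abs(p["tx"]) < 1e-12 &&
      abs(p["ty"]) < 1e-12) return(M)
  # re-binarize at the 0.5 level so interpolation neither erodes nor
  # dilates the retained area
  (warp(M, invert_transform(tr)) >= 0.5) * 1
}

# densities -> noisy brightfield RGB calibrated_image
develop_rgb <- function(C, H, cfg, round_id) {
  basis <- cfg$stains$basis
  od <- array(0, c(nrow(C), ncol(C), 3))
  for (k in 1:3) od[, , k] <- C * basis[k, 1] + H * basis[k, 2]
  if (cfg$od_sigma > 0)
    od <- od + array(rnorm(length(od), 0, cfg$od_sigma), dim(od))
  od[od < 0] <- 0
  I <- cfg$white_point * 10^(-od)
  if (cfg$quantize) I <- round(I)
  I[I < 0] <- 0; I[I > cfg$white_point] <- cfg$white_point
  calibrated_image(I, cfg$microns_per_pixel, round_id = round_id,
                   modality = "brightfield_rgb", white_point = cfg$white_point)
}

#' Generate a ground-truthed multi-round brightfield scene
#'
#' Renders each staining round as a brightfield RGB image via the
#' Beer-Lambert forward model: hematoxylin-stained nuclei and tissue
#' background (present every round) plus that round's chromogen-stained
#' structures (cells positive for the round's marker, plaques, tangles),
#' mixed through the configured stain vectors, misaligned by the true
#' per-round transforms, with additive OD noise. When
#' `retention_fraction > 0`, a fraction of each earlier round's chromogen
#' carries over into later images (residual staining). With
#' `destain = TRUE`, a post-de-staining check image (hematoxylin plus
#' retained chromogen only, on its own misalignment) is rendered for each
#' round, as used by the residual-stain QC.
#'
#' @param cfg a [scene_config()].
#' @param render render the round images (otherwise ground truth only).
#' @param destain also render per-round de-stained check images.
#' @return An object of class `ihc_scene`: `truth` (cell table with
#'   positions/phenotypes/marker vectors, pathology geometry, true
#'   transforms, retention), `images` (per-round `calibrated_image`s) and
#'   `destain_images`.
#' @export
generate_scene <- function(cfg, render = TRUE, destain = FALSE) {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(cfg$seed, {
    truth <- sample_scene_truth(cfg)
    images <- NULL; destain_images <- NULL
    if (render) {
      images <- vector("list", length(cfg$panel))
      names(images) <- cfg$panel
      ref_chrom <- vector("list", length(cfg$panel))   # reference-frame cache
      get_ref <- function(r) {
        if (is.null(ref_chrom[[r]]))
          ref_chrom[[r]] <<- render_chromogen(truth, cfg$panel[r],
                                              identity_transform())
        ref_chrom[[r]]
      }
      for (r in seq_along(cfg$panel)) {
        tr <- truth$transforms[[r]]
        C <- render_chromogen(truth, cfg$panel[r], tr)
        if (cfg$retention_fraction > 0 && r > 1) {
          for (s in seq_len(r - 1)) {
            if (cfg$retention_fraction^(r - s) > 1e-4)
              C <- C + render_chromogen(truth, cfg$panel[s], tr) *
                survival_mask(truth, r - s, tr, get_ref(s))
          }
        }
        H <- render_hematoxylin(truth, tr)
        images[[r]] <- develop_rgb(C, H, cfg, round_id = r)
      }
      if (destain) {
        destain_images <- vector("list", length(cfg$panel))
        names(destain_images) <- cfg$panel
        for (r in seq_along(cfg$panel)) {
          tr <- truth$destain_transforms[[r]]
          Cd <- if (cfg$retention_fraction > 0)
            render_chromogen(truth, cfg$panel[r], tr) *
              survival_mask(truth, 1, tr, get_ref(r))
            else base::matrix(0, round(cfg$field_um / cfg$microns_per_pixel),
                              round(cfg$field_um / cfg$microns_per_pixel))
          H <- render_hematoxylin(truth, tr)
          destain_images[[r]] <- develop_rgb(Cd, H, cfg,
                                             round_id = paste0(r, "-destained"))
        }
      }
    }
    structure(list(truth = truth, images = images,
                   destain_images = destain_images),
              class = "ihc_scene")
  })
}

#' @export
print.ihc_scene <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("<ihc_scene> %d cells, %d plaques, %d tangles; %s round images%s\n",
              nrow(x$truth$cells), length(x$truth$plaques),
              length(x$truth$tangles),
              if (is.null(x$images)) "no" else length(x$images),
              if (is.null(x$destain_images)) "" else " + de-stain checks"))
  invisible(x)
}

#' Render a conventional single-round stain of the same scene
#'
#' The same ground-truth scene rendered as a single-stain positive
#' control: no misalignment, no residual contamination, fresh acquisition
#' noise. Used to compare multiplex-extracted channels against the
#' single-stain reference.
#'
#' @param scene an `ihc_scene` (or a [scene_config()], in which case the
#'   truth is generated first).
#' @param marker a marker in the panel.
#' @return A `calibrated_image` (brightfield RGB).
#' @export
render_single_stain <- function(scene, marker) {
  if (inherits(scene, "scene_config")) scene <- generate_scene(scene, render = FALSE)
  stopifnot(inherits(scene, "ihc_scene"))
  cfg <- scene$truth$config
  if (!marker %in% cfg$panel)
    stop(sprintf("marker '%s' is not in the panel", marker), call. = FALSE)
  ri <- match(marker, cfg$panel)
  with_seed((cfg$seed %% 1000003L) * 1000L + 777L + ri, {
    tr <- identity_transform()
    C <- render_chromogen(scene$truth, marker, tr)
    H <- render_hematoxylin(scene$truth, tr)
    develop_rgb(C, H, cfg, round_id = paste0(marker, "-single"))
  })
}

#' Ground-truth pathology and vessel masks of a scene
#'
#' Rasterizes the scene's true plaque, tangle-body or vessel geometry in
#' the reference frame into an `object_set`, for use as the truth side of
#' proximity and association checks (vessel masks are supplied this way,
#' never detected from a stain).
#'
#' @param scene an `ihc_scene`.
#' @param kind `"abeta_plaque"`, `"phf1_tangle"` or `"vessel"`.
#' @return An `object_set` with `kind` set.
#' @export
scene_truth_objects <- function(scene, kind = c("abeta_plaque", "phf1_tangle",
                                                "vessel")) {
  kind <- match.arg(kind)
  truth <- scene$truth
  cfg <- truth$config
  mpp <- cfg$microns_per_pixel
  n_px <- round(cfg$field_um / mpp)
  M <- base::matrix(0, n_px, n_px)
  if (kind == "abeta_plaque") {
    for (p in truth$plaques)
      for (j in seq_len(nrow(p$disks)))
        M <- draw_disk(M, (p$x + p$disks$dx[j]) / mpp, (p$y + p$disks$dy[j]) / mpp,
                       p$disks$r[j] / mpp, 1, soft = 1e-6)
  } else if (kind == "phf1_tangle") {
    for (tg in truth$tangles)
      M <- draw_disk(M, tg$x / mpp, tg$y / mpp, tg$radius / mpp, 1, soft = 1e-6)
  } else {
    for (v in truth$vessels)
      M <- draw_capsule(M, v$x0 / mpp, v$y0 / mpp, v$x1 / mpp, v$y1 / mpp,
                        v$hw / mpp, 1, soft = 1e-6)
  }
  objs <- detect_objects(density_map(M, mpp, stain = kind), threshold = 0.5,
                         min_area = 0)
  objs$kind <- kind
  if (nrow(objs$table)) objs$table$kind <- kind
  objs
}

#' Ground-truth cell masks of a scene
#'
#' Rasterizes every ground-truth cell (soma plus processes) in the
#' reference frame into an `object_set` whose labels are the true
#' phenotypes, for truth-side spatial measurements that must not depend
#' on detection (overlapping cells are rasterized independently).
#'
#' @param scene an `ihc_scene`.
#' @return An `object_set` with a `label` column holding true phenotypes.
#' @export
scene_truth_cell_objects <- function(scene) {
  truth <- scene$truth
  cfg <- truth$config
  mpp <- cfg$microns_per_pixel
  n_px <- round(cfg$field_um / mpp)
  n <- nrow(truth$cells)
  labels <- base::matrix(0L, n_px, n_px)
  pixels <- vector("list", n)
  boundary <- vector("list", n)
  for (i in seq_len(n)) {
    g <- truth$geom[[i]]
    ext <- (g$r + max(c(0, g$proc$len))) / mpp + 2
    x0 <- max(floor(g$x / mpp - ext), 0)
    y0 <- max(floor(g$y / mpp - ext), 0)
    x1 <- min(ceiling(g$x / mpp + ext), n_px - 1)
    y1 <- min(ceiling(g$y / mpp + ext), n_px - 1)
    loc <- base::matrix(0, y1 - y0 + 1, x1 - x0 + 1)
    cx <- g$x / mpp - x0; cy <- g$y / mpp - y0
    loc <- draw_disk(loc, cx, cy, g$r / mpp, 1, soft = 1e-6)
    for (j in seq_len(nrow(g$proc))) {
      ex <- (g$x + g$proc$len[j] * cos(g$proc$angle[j])) / mpp - x0
      ey <- (g$y + g$proc$len[j] * sin(g$proc$angle[j])) / mpp - y0
      loc <- draw_capsule(loc, cx, cy, ex, ey, g$proc$hw[j] / mpp, 1,
                          soft = 1e-6)
    }
    mask <- loc >= 0.5
    ii <- which(mask)
    ly <- nrow(loc)
    py <- (ii - 1L) %% ly + y0
    px <- (ii - 1L) %/% ly + x0
    lin <- px * n_px + py + 1L
    pixels[[i]] <- sort(lin)
    labels[lin] <- i
    oc <- EBImage::ocontour(EBImage::Image(mask * 1))[[1]]
    boundary[[i]] <- cbind(x_um = (oc[, 2] + x0) * mpp,
                           y_um = (oc[, 1] + y0) * mpp)
  }
  tab <- data.frame(id = seq_len(n), x_um = truth$cells$x_um,
                    y_um = truth$cells$y_um,
                    area_um2 = vapply(pixels, length, integer(1)) * mpp^2,
                    equiv_diameter_um = 2 * sqrt(
                      vapply(pixels, length, integer(1)) * mpp^2 / pi),
                    n_px = vapply(pixels, length, integer(1)),
                    label = truth$cells$phenotype)
  structure(list(table = tab, pixels = pixels, boundary = boundary,
                 labels = labels, microns_per_pixel = mpp,
                 dim = c(n_px, n_px), threshold = NA_real_),
            class = "object_set")
}
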