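#' Voxelized tissue scene
#'
#' A 2D slice described by per-voxel relaxation/diffusion maps and an
#' integer ROI label map. Labels index into `label_names`; label 0 is
#' background.
#'
#' @param t1,t2,m0,adc Numeric matrices (ms, ms, a.u., mm^2/s) sharing one
#'   grid.
#' @param label_map Integer matrix of ROI labels on the same grid.
#' @param label_names Named integer vector mapping region names to labels
#'   (must include all non-zero labels present in `label_map`).
#' @param pixel_mm In-plane pixel size, mm.
#' @return An object of class `tissue_scene`.
#' @export
tissue_scene <- function(t1, t2, m0, adc, label_map, label_names,
                         pixel_mm = 3) {
  dm <- dim(t1)
  for (m in list(t2, m0, adc, label_map))
    if (!identical(dim(m), dm)) .stopf("all maps must share one grid")
  if (any(t1 <= 0) || any(t2 <= 0)) .stopf("t1 and t2 maps must be > 0")
  if (any(m0 < 0) || any(adc < 0)) .stopf("m0 and adc maps must be >= 0")
  present <- setdiff(unique(as.integer(label_map)), 0L)
  if (!all(present %in% label_names))
    .stopf("label map contains labels missing from label_names")
  structure(list(t1 = t1, t2 = t2, m0 = m0, adc = adc,
                 label_map = label_map, label_names = label_names,
                 pixel_mm = pixel_mm, dim = dm),
            class = "tissue_scene")
}

#' @export
print.tissue_scene <- function(x, ...) {
  cat(sprintf("tissue scene %d x %d (%g mm pixels), %d labelled regions\n",
              x$dim[1], x$dim[2], x$pixel_mm, length(x$label_names)))
  invisible(x)
}

# Logical mask of an ellipse; angle_deg rotates the first semi-axis from the
# column (left-right) direction.
.ellipse_mask <- function(nrow, ncol, center, semi_axes, angle_deg = 0) {
  r <- matrix(seq_len(nrow), nrow, ncol) - center[1]
  c <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE) - center[2]
  th <- angle_deg * pi / 180
  u <- c * cos(th) + r * sin(th)
  v <- -c * sin(th) + r * cos(th)
  (u / semi_axes[1])^2 + (v / semi_axes[2])^2 <= 1
}

# Normalized elliptical radius (0 at centre, 1 on the rim) for a voxel set.
.ellipse_radius <- function(rows, cols, center, semi_axes, angle_deg = 0) {
  r <- rows - center[1]; c <- cols - center[2]
  th <- angle_deg * pi / 180
  u <- c * cos(th) + r * sin(th)
  v <- -c * sin(th) + r * cos(th)
  sqrt((u / semi_axes[1])^2 + (v / semi_axes[2])^2)
}

#' Default geometry of the digital incoherent-motion phantom
#'
#' Two "intra-slice" tubes (water thickened with cellulose, housing the
#' motion bead) run horizontally through the slice; four "inter-slice" tubes
#' filled to T1 values of 800, 1000, 1300 and 1600 ms mimic different
#' tissues and probe the T1 dependence of the flip-angle compensation.
#'
#' @param nrow,ncol Grid size.
#' @param pixel_mm Pixel size, mm.
#' @return A config list for [build_phantom_scene()].
#' @export
phantom_config <- function(nrow = 64, ncol = 64, pixel_mm = 3) {
  list(
    nrow = nrow, ncol = ncol, pixel_mm = pixel_mm,
    bath = list(t1 = 2500, t2 = 200, m0 = 1, adc = 2.0e-3),
    intra_tubes = list(
      list(name = "intra_slice_1", row = 26, cols = c(14, 50), half_height = 2,
           t1 = 1300, t2 = 120, m0 = 1, adc = 2.0e-3),
      list(name = "intra_slice_2", row = 38, cols = c(14, 50), half_height = 2,
           t1 = 1300, t2 = 120, m0 = 1, adc = 2.0e-3)
    ),
    inter_tubes = list(
      list(name = "inter_t1_800", center = c(12, 12), radius = 5, t1 = 800),
      list(name = "inter_t1_1000", center = c(12, 52), radius = 5, t1 = 1000),
      list(name = "inter_t1_1300", center = c(52, 12), radius = 5, t1 = 1300),
      list(name = "inter_t1_1600", center = c(52, 52), radius = 5, t1 = 1600)
    )
  )
}

#' Digital twin of the incoherent-motion phantom
#'
#' Builds the [tissue_scene()] of the phantom slice: a water bath, two
#' intra-slice motion-bead tubes and four inter-slice tubes whose T1 values
#' (800/1000/1300/1600 ms) span the relaxation times of different tissues.
#' Deterministic given the config.
#'
#' @param config Geometry list as produced by [phantom_config()]. An empty
#'   tube list yields a background-only scene.
#' @return A `tissue_scene` with 7 regions under the default config
#'   (background bath, 2 intra-slice and 4 inter-slice tubes).
#' @export
build_phantom_scene <- function(config = phantom_config()) {
  cfg <- utils::modifyList(phantom_config(), config)
  if (!length(config)) { cfg$intra_tubes <- list(); cfg$inter_tubes <- list() }
  else {
    if (!is.null(config$intra_tubes)) cfg$intra_tubes <- config$intra_tubes
    if (!is.null(config$inter_tubes)) cfg$inter_tubes <- config$inter_tubes
  }
  nr <- cfg$nrow; nc <- cfg$ncol
  t1 <- matrix(cfg$bath$t1, nr, nc); t2 <- matrix(cfg$bath$t2, nr, nc)
  m0 <- matrix(cfg$bath$m0, nr, nc); adc <- matrix(cfg$bath$adc, nr, nc)
  lab <- matrix(0L, nr, nc)
  names <- integer(0)
  next_label <- 1L
  paint <- function(mask, name, props) {
    if (any(lab[mask] != 0L)) .stopf("overlapping tubes in phantom config")
    lab[mask] <<- next_label
    names[name] <<- next_label
    next_label <<- next_label + 1L
    for (f in intersect(names(props), c("t1", "t2", "m0", "adc"))) {
      map <- get(f); map[mask] <- props[[f]]; assign(f, map, inherits = TRUE)
    }
  }
  for (tube in cfg$intra_tubes) {
    mask <- matrix(FALSE, nr, nc)
    rows <- (tube$row - tube$half_height):(tube$row + tube$half_height)
    mask[rows, tube$cols[1]:tube$cols[2]] <- TRUE
    paint(mask, tube$name, tube)
  }
  for (tube in cfg$inter_tubes) {
    mask <- .ellipse_mask(nr, nc, tube$center, rep(tube$radius, 2))
    paint(mask, tube$name, utils::modifyList(list(t2 = 150, adc = 2.0e-3),
                                             tube))
  }
  tissue_scene(t1, t2, m0, adc, lab, names, cfg$pixel_mm)
}

#' Synthetic calf-muscle slice
#'
#' A 64 x 64 slice (192 mm field of view, 3 mm pixels) with convex labelled
#' regions for the soleus, gastrocnemius medialis, gastrocnemius lateralis
#' and tibialis anterior muscles, embedded in a lower-magnetization
#' surround. Muscle defaults: T1 = 1300 ms, T2 = 35 ms, ADC = 1.5e-3 mm^2/s.
#' Deterministic given the config.
#'
#' @param config Optional overrides: `nrow`, `ncol`, `pixel_mm`, `muscle`
#'   (list of tissue values applied to all muscles).
#' @return A `tissue_scene` with labels
#'   `soleus`, `gastrocnemius_medialis`, `gastrocnemius_lateralis`,
#'   `tibialis_anterior`.
#' @export
build_leg_scene <- function(config = list()) {
  cfg <- utils::modifyList(
    list(nrow = 64, ncol = 64, pixel_mm = 3,
         muscle = list(t1 = 1300, t2 = 35, m0 = 1, adc = 1.5e-3)),
    config)
  nr <- cfg$nrow; nc <- cfg$ncol
  leg <- .ellipse_mask(nr, nc, c(nr / 2, nc / 2), c(nc * 0.44, nr * 0.44))
  t1 <- matrix(1300, nr, nc); t2 <- matrix(45, nr, nc)
  m0 <- matrix(0, nr, nc); adc <- matrix(1.5e-3, nr, nc)
  m0[leg] <- 0.6  # connective tissue / unlabelled muscle surround
  lab <- matrix(0L, nr, nc)
  mus <- cfg$muscle
  regions <- list(
    soleus = .ellipse_mask(nr, nc, c(nr * 0.62, nc * 0.50),
                           c(nc * 0.26, nr * 0.12)),
    gastrocnemius_medialis = .ellipse_mask(nr, nc, c(nr * 0.36, nc * 0.33),
                                           c(nc * 0.13, nr * 0.11), 20),
    gastrocnemius_lateralis = .ellipse_mask(nr, nc, c(nr * 0.36, nc * 0.67),
                                            c(nc * 0.13, nr * 0.11), -20),
    tibialis_anterior = .ellipse_mask(nr, nc, c(nr * 0.84, nc * 0.40),
                                      c(nc * 0.11, nr * 0.07))
  )
  names <- integer(0)
  for (i in seq_along(regions)) {
    mask <- regions[[i]] & leg & lab == 0L
    lab[mask] <- i
    names[names(regions)[i]] <- i
    t1[mask] <- mus$t1; t2[mask] <- mus$t2
    m0[mask] <- mus$m0; adc[mask] <- mus$adc
  }
  tissue_scene(t1, t2, m0, adc, lab, names, cfg$pixel_mm)
}
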