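#' Reducing sugars from DNSA absorbance
#'
#' Converts the 546 nm absorbance of the dinitrosalicylic-acid assay to
#' reducing-sugar content in percent of fresh weight via the calibration line
#' `%RS = (absorbance - 0.00385) * 1.07893`. `absorbance_from_rs()` is the
#' inverse.
#'
#' @param absorbance Non-negative absorbance value(s).
#' @param rs_pct Reducing-sugar content (% fresh weight).
#' @return Numeric vector.
#' @examples
#' rs_from_absorbance(0.00385) # 0
#' @export
rs_from_absorbance <- function(absorbance) {
  if (any(absorbance < 0)) {
    stop_ts("`absorbance` must be non-negative.", "tuberspec_input_error")
  }
  (absorbance - 0.00385) * 1.07893
}

#' @rdname rs_from_absorbance
#' @export
absorbance_from_rs <- function(rs_pct) {
  rs_pct / 1.07893 + 0.00385
}

#' Default cultivar panel
#'
#' Ten cultivars (five with cooking aptitude, five with crisping aptitude)
#' with the dry-matter, starch and reducing-sugar characterization used to
#' parameterize the synthetic chemistry tables. Cooking cultivars sit in the
#' 17--19% dry-matter window, crisping cultivars in 20--23.2%, and reducing
#' sugars stay below 0.2% for all.
#'
#' @return A tibble with columns `cultivar`, `class`, `dm_mean`, `dm_sd`,
#'   `starch_mean`, `starch_sd`, `rs_mean`, `rs_sd`.
#' @export
default_cultivars <- function() {
  tibble(
    cultivar = c("Ambition", "Laudine", "Levantina", "Madeleine", "Rudolph",
                 "Agria", "Corsica", "Hermes", "Lady Amarilla", "Lyoness"),
    class = rep(c("cooking", "frying"), each = 5),
    dm_mean = c(18.56, 18.57, 18.63, 17.77, 18.87,
                21.00, 20.93, 22.81, 20.47, 23.14),
    dm_sd = c(0.18, 0.19, 0.22, 0.23, 0.14, 0.23, 0.15, 0.17, 0.21, 0.14),
    starch_mean = c(11.47, 11.49, 11.55, 10.66, 11.79,
                    13.95, 13.91, 15.84, 13.44, 16.18),
    starch_sd = c(0.09, 0.11, 0.07, 0.10, 0.12, 0.11, 0.14, 0.09, 0.16, 0.10),
    rs_mean = c(0.145, 0.116, 0.150, 0.162, 0.076,
                0.140, 0.065, 0.099, 0.103, 0.061),
    rs_sd = c(0.008, 0.006, 0.010, 0.012, 0.007,
              0.012, 0.009, 0.010, 0.011, 0.007)
  )
}

#' Synthetic slice generator settings
#'
#' Parameters of the synthetic line-scan acquisition. Defaults emulate the
#' emulated instrument and sample: 320-column frames, elliptical slices of
#' roughly 4,000--5,000 foreground pixels on a dark holder, a smooth
#' reflectance baseline (about 0.55 falling to 0.35 across the axis) with
#' absorption valleys at 1,015, 1,200 and 1,450 nm, a darker central pith, a
#' small positive reflectance offset over 1,200--1,400 nm for the frying
#' class, per-pixel multiplicative/additive scatter, sensor noise and
#' per-column stripes.
#'
#' @param shape Image shape `c(rows, cols)`.
#' @param semi_axes Range (min, max) the ellipse semi-axes are drawn from, px.
#' @param center_jitter Max uniform displacement of the ellipse centre, px.
#' @param baseline Reflectance baseline at the first and last band.
#' @param valley_centers,valley_depths,valley_widths Gaussian absorption-valley
#'   parameters (centres and widths in nm).
#' @param depth_jitter_sd Per-tuber lognormal-ish jitter (relative sd) of the
#'   valley depths — the main between-tuber spectral variability.
#' @param pixel_depth_sd Per-pixel relative jitter of the valley depths,
#'   emulating local compositional texture (water/starch granularity). Unlike
#'   scatter, this shape variation survives SNV/MSC and is what makes
#'   pixel-wise classification genuinely harder than mean-spectrum
#'   classification.
#' @param pith_frac Normalized elliptical radius of the pith core.
#' @param pith_factor Multiplicative reflectance attenuation at the pith
#'   centre (1 = none).
#' @param delta Class reflectance offset added over `delta_band` for the
#'   frying class.
#' @param delta_band Wavelength window (nm) carrying the class offset.
#' @param delta_pith_factor Attenuation of the class offset at the pith centre
#'   (pith tissue carries a weaker class signal).
#' @param delta_pixel_sd Per-pixel spread of the class-marker band amplitude
#'   (reflectance units over `delta_band`). The constituents that separate the
#'   classes (sugars/starch) also vary within a slice, so pixel populations of
#'   the two classes overlap along the very direction that separates them;
#'   this is what keeps pixel-wise accuracy below mean-spectrum accuracy.
#'   Independent across pixels, so it averages out of mean spectra.
#' @param scatter_a_sd,scatter_b_sd Per-pixel multiplicative/additive scatter
#'   spread.
#' @param noise_sd Per-pixel, per-band Gaussian noise (reflectance units).
#' @param stripe_sd Per-column stripe amplitude (reflectance units).
#' @param background_refl Reflectance of the sample holder.
#' @param white_level White-tile reflectance (0.99 for a ceramic standard).
#' @param dark_level Dark-current offset, camera counts.
#' @param gain_peak Peak of the smooth illumination/gain curve, camera counts.
#' @return A list of settings for [generate_slice()].
#' @export
slice_spec <- function(shape = c(112, 320),
                       semi_axes = c(30, 40),
                       center_jitter = 6,
                       baseline = c(0.55, 0.35),
                       valley_centers = c(1015, 1200, 1450),
                       valley_depths = c(0.05, 0.07, 0.25),
                       valley_widths = c(20, 35, 45),
                       depth_jitter_sd = 0.04,
                       pixel_depth_sd = 0.3,
                       pith_frac = 0.35,
                       pith_factor = 0.75,
                       delta = 0.02,
                       delta_band = c(1200, 1400),
                       delta_pith_factor = 0.4,
                       delta_pixel_sd = 0.01,
                       scatter_a_sd = 0.05,
                       scatter_b_sd = 0.01,
                       noise_sd = 0.005,
                       stripe_sd = 0.003,
                       background_refl = 0.03,
                       white_level = 0.99,
                       dark_level = 100,
                       gain_peak = 18000) {
  as.list(environment())
}

# smooth band weight for the class offset (sigmoid flanks, ~10 nm scale)
delta_profile <- function(w, band) {
  1 / (1 + exp(-(w - band[1]) / 10)) * 1 / (1 + exp((w - band[2]) / 10))
}

# smooth illumination/gain curve over the axis, camera counts per unit
# reflectance
gain_curve <- function(w, peak) {
  peak * exp(-((w - 1300) / 500)^2) + 0.1 * peak
}

#' Generate one synthetic slice acquisition
#'
#' Simulates a raw line-scan hypercube of a single potato slice plus its
#' white/dark references and ground-truth mask. The reflectance image is built
#' as `radial(u) * base(lambda) + delta * g(lambda) * atten(u)` for foreground
#' pixels (elliptical radius `u`), where `radial` darkens the pith, `base` is
#' the valley-carved baseline (with per-tuber depth jitter), and the class
#' offset `delta` (frying only) acts over 1,200--1,400 nm with its own pith
#' attenuation; per-pixel scatter (`a*s + b`), Gaussian noise and per-column
#' stripes are added, and the result is inverted through the reflectance
#' calibration equation against the generated references to obtain raw camera
#' counts. With `noise_sd = 0`, scatter off and no jitter, calibrating the raw
#' cube returns the deterministic construction exactly.
#'
#' @param class_label `"cooking"` or `"frying"`.
#' @param axis Wavelength axis (default 256 bands over 900--1,700 nm).
#' @param spec Settings from [slice_spec()].
#' @param sample_id Identifier stored in the cube.
#' @param seed Optional integer seed for this slice.
#' @return A list: `raw` ([hypercube], camera counts), `refs`
#'   ([reference_pair]), `truth_mask` (logical matrix), `reflectance`
#'   (noiseless foreground reflectance cube, for diagnostics), `geometry`
#'   (ellipse centre/axes), `class_label`.
#' @export
generate_slice <- function(class_label = c("cooking", "frying"),
                           axis = build_wavelength_axis(900, 1700, 256),
                           spec = slice_spec(),
                           sample_id = NA_character_,
                           seed = NULL) {
  class_label <- match.arg(class_label)
  if (!is.null(seed)) set.seed(seed)
  w <- as.numeric(axis)
  nb <- length(w)
  rows <- spec$shape[1]; cols <- spec$shape[2]

  # geometry
  ax_r <- runif(1, spec$semi_axes[1], spec$semi_axes[2])
  ax_c <- runif(1, spec$semi_axes[1], spec$semi_axes[2])
  cr <- rows / 2 + runif(1, -spec$center_jitter, spec$center_jitter)
  cc <- cols / 2 + runif(1, -spec$center_jitter, spec$center_jitter)
  if (cr - ax_r < 1 || cr + ax_r > rows || cc - ax_c < 1 || cc + ax_c > cols) {
    stop_ts("Ellipse exceeds the image bounds; enlarge `shape` or shrink axes.",
            "tuberspec_spec_error")
  }
  rr <- matrix(seq_len(rows), rows, cols)
  cm <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  u <- sqrt(((rr - cr) / ax_r)^2 + ((cm - cc) / ax_c)^2)
  mask <- u <= 1

  # per-tuber spectral base
  depths <- spec$valley_depths *
    exp(rnorm(3, 0, spec$depth_jitter_sd) - spec$depth_jitter_sd^2 / 2)
  base <- seq(spec$baseline[1], spec$baseline[2], length.out = nb)
  for (k in 1:3) {
    base <- base - depths[k] *
      exp(-((w - spec$valley_centers[k])^2) / (2 * spec$valley_widths[k]^2))
  }
  delta_cls <- if (class_label == "frying") spec$delta else 0
  g <- delta_profile(w, spec$delta_band)

  # per-pixel radial factors
  radial <- 1 - (1 - spec$pith_factor) * exp(-(u / spec$pith_frac)^2)
  atten <- 1 - (1 - spec$delta_pith_factor) * exp(-(u / spec$pith_frac)^2)

  n_px <- rows * cols
  fg <- as.vector(mask)
  refl <- matrix(spec$background_refl, n_px, nb)
  refl[fg, ] <- outer(radial[mask], base) + delta_cls * outer(atten[mask], g)
  clean <- refl # noiseless construction, foreground + background

  # per-pixel compositional texture: class-marker amplitude and local
  # valley-depth variation
  n_fg <- sum(fg)
  if (spec$delta_pixel_sd > 0) {
    refl[fg, ] <- refl[fg, , drop = FALSE] +
      outer(rnorm(n_fg, 0, spec$delta_pixel_sd), g)
  }
  if (spec$pixel_depth_sd > 0) {
    for (k in 1:3) {
      gk <- exp(-((w - spec$valley_centers[k])^2) /
                  (2 * spec$valley_widths[k]^2))
      ek <- rnorm(n_fg, 0, spec$pixel_depth_sd) * depths[k]
      refl[fg, ] <- refl[fg, , drop = FALSE] - outer(radial[mask] * ek, gk)
    }
  }

  # per-pixel scatter on foreground
  if (spec$scatter_a_sd > 0 || spec$scatter_b_sd > 0) {
    a_px <- rnorm(sum(fg), 1, spec$scatter_a_sd)
    b_px <- rnorm(sum(fg), 0, spec$scatter_b_sd)
    refl[fg, ] <- refl[fg, , drop = FALSE] * a_px + b_px
  }
  if (spec$noise_sd > 0) refl <- refl + rnorm(n_px * nb, 0, spec$noise_sd)
  if (spec$stripe_sd > 0) {
    stripe <- rnorm(cols, 0, spec$stripe_sd)
    refl <- refl + stripe[as.vector(cm)]
  }

  # references and inversion of the calibration equation
  gain <- gain_curve(w, spec$gain_peak)
  white <- matrix(spec$dark_level, cols, nb) +
    outer(rep(spec$white_level, cols), gain)
  dark <- matrix(spec$dark_level, cols, nb)
  refs <- reference_pair(white, dark)
  denom <- refs$white - refs$dark # cols x bands
  col_of_px <- as.vector(cm)
  raw_flat <- refs$dark[col_of_px, ] + refl * denom[col_of_px, ]
  raw_flat <- pmax(raw_flat, 0) # detector counts cannot go negative

  list(
    raw = hypercube(array(raw_flat, c(rows, cols, nb)), axis, kind = "raw",
                    sample_id = sample_id, class_label = class_label),
    refs = refs,
    truth_mask = mask,
    reflectance = hypercube(array(clean, c(rows, cols, nb)), axis,
                            kind = "reflectance", sample_id = sample_id,
                            class_label = class_label),
    geometry = list(center = c(cr, cc), semi_axes = c(ax_r, ax_c)),
    class_label = class_label
  )
}

#' Generate a full synthetic dataset on disk
#'
#' Writes a reproducible synthetic acquisition campaign: one raw ENVI cube and
#' truth-mask PNG per tuber, a shared white/dark reference pair, a manifest
#' CSV (`sample_id`, `cultivar`, `class`, geometry, paths) and a
#' Table-1-style chemistry CSV (per-cultivar dry matter, starch, reducing
#' sugars and the DNSA absorbance consistent with them). Defaults produce the
#' emulated campaign: 10 cultivars x 8 tubers = 80 cubes, 40 per class.
#'
#' @param dir Output directory (created if missing).
#' @param n_cultivars Number of cultivars drawn from `cultivars`.
#' @param tubers_per_cultivar Tubers per cultivar.
#' @param cultivars Cultivar panel, see [default_cultivars()].
#' @param axis Wavelength axis.
#' @param spec [slice_spec()] settings.
#' @param seed Integer seed; the whole dataset is reproducible from it
#'   (per-slice substreams are derived by counter so slices are independent
#'   of generation order).
#' @param data_type ENVI data type for the raw cubes (`"uint16"` matches a
#'   line-scan camera; quantization is negligible at the default gain).
#' @return The manifest tibble (also written to `<dir>/manifest.csv`),
#'   with attribute `chemistry`.
#' @export
generate_dataset <- function(dir,
                             n_cultivars = 10,
                             tubers_per_cultivar = 8,
                             cultivars = default_cultivars(),
                             axis = build_wavelength_axis(900, 1700, 256),
                             spec = slice_spec(),
                             seed = 1,
                             data_type = "uint16") {
  if (n_cultivars < 1 || tubers_per_cultivar < 1) {
    stop_ts("Counts must be >= 1.", "tuberspec_parameter_error")
  }
  if (n_cultivars > nrow(cultivars)) {
    stop_ts("Not enough cultivars in the panel.", "tuberspec_parameter_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- cultivars[seq_len(n_cultivars), ]
  seed <- as.integer(seed)

  # shared references (a short scan of the tile / closed cap)
  w <- as.numeric(axis)
  gain <- gain_curve(w, spec$gain_peak)
  cols <- spec$shape[2]
  white <- matrix(spec$dark_level, cols, length(w)) +
    outer(rep(spec$white_level, cols), gain)
  dark <- matrix(spec$dark_level, cols, length(w))
  ref_lines <- 8
  white_cube <- hypercube(
    aperm(array(t(white), c(length(w), cols, ref_lines)), c(3, 2, 1)),
    axis, kind = "raw", sample_id = "white_reference")
  dark_cube <- hypercube(
    aperm(array(t(dark), c(length(w), cols, ref_lines)), c(3, 2, 1)),
    axis, kind = "raw", sample_id = "dark_reference")
  write_envi(white_cube, file.path(dir, "white"), data_type = data_type)
  write_envi(dark_cube, file.path(dir, "dark"), data_type = data_type)

  rows_list <- list()
  idx <- 0L
  for (ci in seq_len(nrow(panel))) {
    for (ti in seq_len(tubers_per_cultivar)) {
      idx <- idx + 1L
      sid <- sprintf("%s_t%02d", gsub("[^A-Za-z0-9]", "", panel$cultivar[ci]), ti)
      sl <- generate_slice(panel$class[ci], axis = axis, spec = spec,
                           sample_id = sid,
                           seed = (seed * 1000L + idx) %% 2147483647L)
      base <- file.path(dir, sid)
      write_envi(sl$raw, base, data_type = data_type)
      png::writePNG(sl$truth_mask * 1, paste0(base, "_mask.png"))
      rows_list[[idx]] <- tibble(
        sample_id = sid, cultivar = panel$cultivar[ci],
        class = panel$class[ci],
        center_row = sl$geometry$center[1], center_col = sl$geometry$center[2],
        semi_row = sl$geometry$semi_axes[1], semi_col = sl$geometry$semi_axes[2],
        path_raw = paste0(sid, ".hdr"),
        path_mask = paste0(sid, "_mask.png"),
        path_white = "white.hdr", path_dark = "dark.hdr"
      )
    }
  }
  manifest <- dplyr::bind_rows(rows_list)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))

  set.seed((seed * 1000L + 999983L) %% 2147483647L)
  chem <- dplyr::mutate(
    panel,
    dm_pct = rnorm(nrow(panel), .data$dm_mean, .data$dm_sd),
    starch_pct = rnorm(nrow(panel), .data$starch_mean, .data$starch_sd),
    rs_pct = pmax(rnorm(nrow(panel), .data$rs_mean, .data$rs_sd), 0.01),
    absorbance = absorbance_from_rs(.data$rs_pct)
  )
  chem <- dplyr::select(chem, "cultivar", "class", "dm_pct", "starch_pct",
                        "rs_pct", "absorbance")
  readr::write_csv(chem, file.path(dir, "chemistry.csv"))
  attr(manifest, "chemistry") <- chem
  manifest
}

#' Split a dataset into calibration and validation
#'
#' Two splitting modes: `"mean_spectra_75_25"` draws a class-stratified random
#' 75/25 split over all tubers (80 tubers -> 60 calibration, 20 validation);
#' `"pixelwise_2_1_per_cultivar"` first selects 3 tubers per cultivar, then
#' assigns 2 to calibration and 1 to validation (10 cultivars -> 20/10
#' tubers), the remaining tubers are marked `"unused"`.
#'
#' @param manifest Manifest tibble (or path to a manifest CSV).
#' @param mode Split mode, see above.
#' @param seed Integer seed for the random draws.
#' @return The manifest with an added `split` column
#'   (`"calibration"`/`"validation"`/`"unused"`).
#' @export
split_dataset <- function(manifest,
                          mode = c("mean_spectra_75_25",
                                   "pixelwise_2_1_per_cultivar"),
                          seed = 1) {
  mode <- match.arg(mode)
  if (is.character(manifest)) {
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  }
  set.seed(as.integer(seed))
  n <- nrow(manifest)
  split <- rep("unused", n)
  if (mode == "mean_spectra_75_25") {
    for (cl in unique(manifest$class)) {
      i <- which(manifest$class == cl)
      n_cal <- round(0.75 * length(i))
      cal <- sample(i, n_cal)
      split[cal] <- "calibration"
      split[setdiff(i, cal)] <- "validation"
    }
  } else {
    for (cu in unique(manifest$cultivar)) {
      i <- which(manifest$cultivar == cu)
      if (length(i) < 3) {
        stop_ts(sprintf("Cultivar %s has %d tubers; pixel-wise mode needs 3.",
                        cu, length(i)), "tuberspec_parameter_error")
      }
      three <- if (length(i) == 3) i else sample(i, 3)
      cal <- sample(three, 2)
      split[cal] <- "calibration"
      split[setdiff(three, cal)] <- "validation"
    }
  }
  dplyr::mutate(manifest, split = split)
}
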