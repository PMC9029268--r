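#' Construct a voxel volume
#'
#' A 3-D grid of PET values with millimetre spacing and a unit tag
#' (`"activity"` for kBq/mL activity concentration, `"SUV"` or `"SUL"`).
#'
#' @param values 3-D numeric array.
#' @param spacing numeric length-3, mm per axis; all > 0.
#' @param unit `"activity"`, `"SUV"` or `"SUL"`.
#' @return object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, unit = c("activity", "SUV", "SUL")) {
  unit <- match.arg(unit)
  if (length(dim(values)) != 3) stop("values must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (any(!is.finite(values))) stop("voxel values must be finite")
  structure(list(values = values, spacing = spacing, unit = unit),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, unit ", x$unit, "\n", sep = "")
  invisible(x)
}

#' Patient attributes used for SUV/SUL normalization
#'
#' @param weight_kg body weight in kg (> 0).
#' @param height_cm height in cm (> 0).
#' @param sex `"male"` or `"female"`.
#' @param injected_activity_mbq injected FDG activity in MBq (> 0).
#' @return object of class `patient_attributes`.
#' @export
patient_attributes <- function(weight_kg, height_cm = NA_real_,
                               sex = NA_character_,
                               injected_activity_mbq = NA_real_) {
  if (!is.finite(weight_kg) || weight_kg <= 0) stop("weight_kg must be > 0")
  structure(list(weight_kg = weight_kg, height_cm = height_cm, sex = sex,
                 injected_activity_mbq = injected_activity_mbq),
            class = "patient_attributes")
}

#' Convert activity concentration to SUV
#'
#' SUV = concentration (kBq/mL) / (injected activity (kBq) / body weight (g)),
#' i.e. the ratio of local to whole-body-average tracer concentration.
#'
#' @param volume a [voxel_volume()] in activity units.
#' @param attrs a [patient_attributes()] with weight and injected activity.
#' @return a [voxel_volume()] tagged `"SUV"`.  An already-SUV input is
#'   returned unchanged with a warning.
#' @export
#' @examples
#' v <- voxel_volume(array(5, c(2, 2, 2)), c(2, 2, 2), "activity")
#' a <- patient_attributes(70, injected_activity_mbq = 350)
#' to_suv(v, a)$values[1]  # 5 / (350000/70000) = 1
to_suv <- function(volume, attrs) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(attrs, "patient_attributes"))
  if (volume$unit != "activity") {
    warning("volume is already in ", volume$unit, " units; returning unchanged")
    return(volume)
  }
  act <- attrs$injected_activity_mbq
  if (!is.finite(act) || act <= 0) stop("injected_activity_mbq must be > 0")
  suv <- volume$values / ((act * 1000) / (attrs$weight_kg * 1000))
  voxel_volume(suv, volume$spacing, "SUV")
}

#' Lean body mass and body-surface-area normalizers
#'
#' Returns the normalizer mass (kg) used to rescale SUV to SUL:
#' `"lbm_janmahasatian"` (fat-free mass from weight and BMI),
#' `"lbm_james"` (the classic James formula), or `"bsa"` (Du Bois body
#' surface area converted to a mass equivalent via the 70 kg / 1.73 m^2
#' reference adult, so SUL stays on the SUV scale).
#'
#' @param attrs a [patient_attributes()] with weight, height and sex.
#' @param method normalization method.
#' @return normalizer in kg.
#' @export
sul_normalizer <- function(attrs, method = c("lbm_janmahasatian", "lbm_james",
                                             "bsa")) {
  method <- match.arg(method)
  w <- attrs$weight_kg
  h <- attrs$height_cm
  if (!is.finite(h) || h <= 0) stop("patient attribute 'height_cm' is required")
  if (!isTRUE(attrs$sex %in% c("male", "female")))
    stop("patient attribute 'sex' is required ('male' or 'female')")
  male <- attrs$sex == "male"
  switch(method,
    lbm_james = if (male) 1.10 * w - 128 * (w / h)^2
                else 1.07 * w - 148 * (w / h)^2,
    lbm_janmahasatian = {
      bmi <- w / (h / 100)^2
      if (male) 9270 * w / (6680 + 216 * bmi)
      else 9270 * w / (8780 + 244 * bmi)
    },
    bsa = {
      bsa_m2 <- 0.007184 * w^0.425 * h^0.725
      bsa_m2 * 70 / 1.73
    })
}

#' Rescale SUV to SUL
#'
#' SUL = SUV x normalizer / weight, where the normalizer is a lean body
#' mass (Janmahasatian by default, James as an option) or a
#' body-surface-area mass equivalent.  Accepts a [voxel_volume()] or a
#' bare numeric vector of SUVs.
#'
#' @param suv a `"SUV"` [voxel_volume()] or numeric vector.
#' @param attrs a [patient_attributes()] with weight, height and sex.
#' @param method see [sul_normalizer()].
#' @return same shape as the input, rescaled; volumes are tagged `"SUL"`
#'   and carry the method in attribute `"sul_method"`.
#' @export
suv_to_sul <- function(suv, attrs, method = c("lbm_janmahasatian", "lbm_james",
                                              "bsa")) {
  method <- match.arg(method)
  factor <- sul_normalizer(attrs, method) / attrs$weight_kg
  if (inherits(suv, "voxel_volume")) {
    out <- voxel_volume(suv$values * factor, suv$spacing, "SUL")
    attr(out, "sul_method") <- method
    out
  } else {
    out <- suv * factor
    attr(out, "sul_method") <- method
    out
  }
}

# voxel center coordinates (mm) along one axis: (i - 0.5) * spacing
axis_centers <- function(n, sp) (seq_len(n) - 0.5) * sp

# integer offsets (rows: di,dj,dk) whose center displacement is within
# radius_mm for the given spacing
sphere_offsets <- function(radius_mm, spacing) {
  r <- floor(radius_mm / spacing)
  g <- expand.grid(di = -r[1]:r[1], dj = -r[2]:r[2], dk = -r[3]:r[3])
  d2 <- (g$di * spacing[1])^2 + (g$dj * spacing[2])^2 + (g$dk * spacing[3])^2
  as.matrix(g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
}

#' Sphere-constrained peak uptake (SUVpeak)
#'
#' The maximum, over candidate sphere centers placed at voxel centers
#' inside the lesion mask, of the mean of all grid voxels whose centers lie
#' within a sphere of `sphere_diameter_mm` (default 12 mm, ~1 cm^3).  The
#' sphere may extend beyond the mask; voxels falling outside the grid are
#' excluded from the mean.
#'
#' @param suv_volume a [voxel_volume()].
#' @param lesion_mask logical/0-1 array of the same dimensions; non-empty.
#' @param sphere_diameter_mm averaging sphere diameter in mm.
#' @return the peak value (scalar), with the maximizing center index (1-based
#'   voxel coordinates) in attribute `"center"`.
#' @export
suv_peak <- function(suv_volume, lesion_mask, sphere_diameter_mm = 12) {
  stopifnot(inherits(suv_volume, "voxel_volume"))
  vals <- suv_volume$values
  dims <- dim(vals)
  if (!identical(dim(lesion_mask), dims))
    stop("lesion_mask dimensions must match the volume")
  idx <- which(lesion_mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("lesion mask is empty")
  radius <- sphere_diameter_mm / 2
  if (any(2 * radius > dims * suv_volume$spacing))
    stop("averaging sphere is larger than the grid")
  off <- sphere_offsets(radius, suv_volume$spacing)
  sums <- numeric(nrow(idx))
  cnts <- numeric(nrow(idx))
  for (o in seq_len(nrow(off))) {
    i <- idx[, 1] + off[o, 1]
    j <- idx[, 2] + off[o, 2]
    k <- idx[, 3] + off[o, 3]
    ok <- i >= 1 & i <= dims[1] & j >= 1 & j <= dims[2] & k >= 1 & k <= dims[3]
    lin <- i[ok] + (j[ok] - 1) * dims[1] + (k[ok] - 1) * dims[1] * dims[2]
    sums[ok] <- sums[ok] + vals[lin]
    cnts[ok] <- cnts[ok] + 1
  }
  means <- sums / cnts
  best <- which.max(means)
  structure(means[best], center = idx[best, ])
}

#' Metabolic tumor volume by threshold delineation
#'
#' Grows the delineation from the hottest voxel of the seed mask over
#' face-adjacent voxels whose value reaches the threshold
#' `max(relative_pct/100 x lesion SUVmax, absolute_floor)`.  MTV is the
#' delineated voxel count times the voxel volume, in cm^3.
#'
#' @param suv_volume a [voxel_volume()].
#' @param seed_mask logical/0-1 array marking the lesion; non-empty.
#' @param relative_pct threshold as percent of the lesion SUVmax
#'   (default 42).
#' @param absolute_floor optional absolute SUV floor.
#' @return list with `mtv_cm3` and the logical delineation `mask`
#'   (empty mask and `mtv_cm3 = 0` when no voxel reaches the threshold).
#' @export
mtv <- function(suv_volume, seed_mask, relative_pct = 42,
                absolute_floor = NULL) {
  stopifnot(inherits(suv_volume, "voxel_volume"))
  vals <- suv_volume$values
  dims <- dim(vals)
  if (!identical(dim(seed_mask), dims))
    stop("seed_mask dimensions must match the volume")
  seed_idx <- which(seed_mask != 0)
  if (length(seed_idx) == 0) stop("seed mask is empty")
  suvmax <- max(vals[seed_idx])
  thr <- relative_pct / 100 * suvmax
  if (!is.null(absolute_floor)) thr <- max(thr, absolute_floor)
  above <- vals >= thr
  start <- seed_idx[which.max(vals[seed_idx])]
  if (!above[start]) {
    return(list(mtv_cm3 = 0, mask = array(FALSE, dims)))
  }
  mask <- flood_fill3d(above, start, dims)
  list(mtv_cm3 = sum(mask) * prod(suv_volume$spacing) / 1000, mask = mask)
}

# 6-connected (face-adjacent) flood fill from linear index `start` over
# TRUE voxels of `above`
flood_fill3d <- function(above, start, dims) {
  nxy <- dims[1] * dims[2]
  visited <- array(FALSE, dims)
  visited[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nb <- c(frontier - 1, frontier + 1, frontier - dims[1], frontier + dims[1],
            frontier - nxy, frontier + nxy)
    # guard axis wrap-around for the +/-1 and +/-dims[1] moves
    i0 <- ((frontier - 1) %% dims[1]) + 1
    j0 <- (((frontier - 1) %/% dims[1]) %% dims[2]) + 1
    valid <- c(i0 > 1, i0 < dims[1], j0 > 1, j0 < dims[2],
               frontier > nxy, frontier <= length(above) - nxy)
    nb <- nb[valid]
    nb <- unique(nb[nb >= 1 & nb <= length(above)])
    nb <- nb[above[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

#' Total lesion glycolysis
#'
#' TLG = MTV x SUVmean (exact product).
#'
#' @param mtv_cm3 metabolic tumor volume, cm^3 (>= 0).
#' @param suvmean mean SUV over the delineated volume (>= 0).
#' @return TLG in cm^3 x SUV.
#' @export
#' @examples
#' tlg(10, 4)  # 40
tlg <- function(mtv_cm3, suvmean) {
  if (any(mtv_cm3 < 0) || any(suvmean < 0))
    stop("mtv_cm3 and suvmean must be >= 0")
  mtv_cm3 * suvmean
}

#' Liver reference statistics from a spherical ROI
#'
#' Mean and population standard deviation of SUL and SUV over the voxels
#' whose centers lie within a sphere (default 3 cm diameter) centered at
#' `center_mm` in the liver.
#'
#' @param sul_volume,suv_volume [voxel_volume()]s on the same grid (either
#'   may be `NULL`, in which case its statistics are `NA`).
#' @param center_mm sphere center in mm (length 3).
#' @param sphere_diameter_mm sphere diameter in mm, default 30.
#' @return a [liver_ref()] object.
#' @export
liver_reference <- function(sul_volume, suv_volume, center_mm,
                            sphere_diameter_mm = 30) {
  ref_vol <- if (!is.null(sul_volume)) sul_volume else suv_volume
  stopifnot(inherits(ref_vol, "voxel_volume"))
  dims <- dim(ref_vol$values)
  sp <- ref_vol$spacing
  r <- sphere_diameter_mm / 2
  if (any(center_mm - r < 0) || any(center_mm + r > dims * sp))
    stop("liver reference sphere is clipped by the grid boundary")
  cx <- axis_centers(dims[1], sp[1]); cy <- axis_centers(dims[2], sp[2])
  cz <- axis_centers(dims[3], sp[3])
  d2 <- outer(outer((cx - center_mm[1])^2, (cy - center_mm[2])^2, "+"),
              (cz - center_mm[3])^2, "+")
  inside <- d2 <= r^2
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  stat <- function(vol) {
    if (is.null(vol)) return(c(NA_real_, NA_real_))
    x <- vol$values[inside]
    c(mean(x), pop_sd(x))
  }
  s_sul <- stat(sul_volume); s_suv <- stat(suv_volume)
  liver_ref(sulmean = s_sul[1], sul_sd = s_sul[2],
            suvmean = s_suv[1], suv_sd = s_suv[2],
            sphere_diameter_mm = sphere_diameter_mm)
}

#' Longest diameter of a delineated lesion
#'
#' Maximum Euclidean distance (mm) between any two voxel centers in the
#' mask.  Large masks are reduced to their boundary voxels first (interior
#' voxels cannot realize the maximum).
#'
#' @param mask logical/0-1 3-D array; non-empty.
#' @param spacing mm per axis (length 3).
#' @return longest diameter in mm (0 for a single voxel).
#' @export
longest_diameter <- function(mask, spacing) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty")
  if (nrow(idx) == 1) return(0)
  if (nrow(idx) > 400) {
    dims <- dim(mask)
    on_boundary <- logical(nrow(idx))
    m <- mask != 0
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
      on_boundary[r] <- i == 1 || i == dims[1] || j == 1 || j == dims[2] ||
        k == 1 || k == dims[3] ||
        !(m[i - 1, j, k] && m[i + 1, j, k] && m[i, j - 1, k] &&
          m[i, j + 1, k] && m[i, j, k - 1] && m[i, j, k + 1])
    }
    idx <- idx[on_boundary, , drop = FALSE]
  }
  xyz <- sweep(idx - 0.5, 2, spacing, "*")
  max(stats::dist(xyz))
}

#' Quantify all lesions of one scan
#'
#' Runs the full per-lesion quantification on a SUV volume and an integer
#' label mask (0 = background, 1 = liver, >= 2 = lesions): SUVmax, SUVmean
#' over the threshold delineation, sphere-constrained SUVpeak, SULpeak,
#' MTV, TLG and longest diameter, plus the 3-cm liver reference sphere.
#'
#' @param suv_volume a `"SUV"` [voxel_volume()].
#' @param label_mask integer array (same dims): 0 background, 1 liver,
#'   lesion labels from 2 upward (stable across scans).
#' @param attrs optional [patient_attributes()]; required for SUL.
#' @param sul_method see [sul_normalizer()].
#' @param relative_pct MTV delineation threshold, percent of lesion SUVmax.
#' @param liver_center_mm optional liver sphere center; defaults to the
#'   liver label's centroid.
#' @return list with `lesions` (data.frame: `lesion_id`, `suvmax`,
#'   `suvmean`, `suvpeak`, `sulpeak`, `mtv_cm3`, `tlg`,
#'   `longest_diameter_mm`) and `liver` (a [liver_ref()] or `NULL`).
#' @export
quantify_scan <- function(suv_volume, label_mask, attrs = NULL,
                          sul_method = "lbm_janmahasatian",
                          relative_pct = 42, liver_center_mm = NULL) {
  stopifnot(inherits(suv_volume, "voxel_volume"))
  sul_factor <- if (!is.null(attrs)) {
    sul_normalizer(attrs, sul_method) / attrs$weight_kg
  } else NA_real_
  labels <- sort(setdiff(unique(as.integer(label_mask)), c(0L, 1L)))
  rows <- lapply(labels, function(lab) {
    lm <- label_mask == lab
    delin <- mtv(suv_volume, lm, relative_pct)
    smax <- max(suv_volume$values[lm])
    smean <- if (any(delin$mask)) mean(suv_volume$values[delin$mask]) else
      mean(suv_volume$values[lm])
    speak <- as.numeric(suv_peak(suv_volume, lm))
    diam <- if (any(delin$mask))
      longest_diameter(delin$mask, suv_volume$spacing) else 0
    data.frame(lesion_id = paste0("L", lab), suvmax = smax, suvmean = smean,
               suvpeak = speak, sulpeak = speak * sul_factor,
               mtv_cm3 = delin$mtv_cm3, tlg = tlg(delin$mtv_cm3, smean),
               longest_diameter_mm = diam, stringsAsFactors = FALSE)
  })
  liver <- NULL
  if (any(label_mask == 1)) {
    if (is.null(liver_center_mm)) {
      li <- which(label_mask == 1, arr.ind = TRUE)
      liver_center_mm <- colMeans(sweep(li - 0.5, 2, suv_volume$spacing, "*"))
    }
    sul_vol <- if (!is.na(sul_factor))
      voxel_volume(suv_volume$values * sul_factor, suv_volume$spacing, "SUL")
    else NULL
    liver <- liver_reference(sul_vol, suv_volume, liver_center_mm)
  }
  list(lesions = do.call(rbind, rows), liver = liver)
}

#' Read / write a PET volume as NIfTI
#'
#' Thin wrappers over RNifti keeping the mm spacing and unit tag.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param unit unit tag to attach on read.
#' @return [voxel_volume()] (read) or the path, invisibly (write).
#' @export
read_pet_volume <- function(path, unit = "SUV") {
  img <- RNifti::readNifti(path)
  voxel_volume(array(as.numeric(img), dim = dim(img)),
               RNifti::pixdim(img)[seq_len(3)], unit)
}

#' @rdname read_pet_volume
#' @param volume a [voxel_volume()] (or integer label array with `spacing`
#'   attribute semantics supplied via a volume wrapper).
#' @export
write_pet_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
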