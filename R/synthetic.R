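#' Phantom specification
#'
#' Describes a synthetic chest-CT phantom: two ellipsoidal low-HU lungs
#' inside a soft-tissue body cylinder surrounded by exterior air, with
#' lesion blobs whose voxels follow the GGO and consolidation HU
#' distributions, vessel-like distractor structures whose HU also falls in
#' the lesion interval (the realistic noise source for HU-threshold
#' pseudo-labels), and additive Gaussian noise.
#'
#' HU distributions are truncated so noiseless lesion voxels always stay
#' inside their nominal intervals: GGO ~ N(-550, 80) on [-750, -301],
#' consolidation ~ N(-150, 60) on [-300, 50].
#'
#' @param shape volume dimensions in voxels.
#' @param spacing voxel spacing in mm.
#' @param body_hu,body_sd soft-tissue HU mean and spatial sd.
#' @param lung_hu,lung_sd aerated-lung HU mean and spatial sd.
#' @param lesion_count integer range (min, max) of lesions per phantom.
#' @param lesion_radius in-plane radius range in voxels.
#' @param ggo_fraction target fraction of lesion voxels that are GGO (rim)
#'   rather than consolidation (core).
#' @param distractor_count number of vessel-mimicking structures placed at
#'   lung boundaries, HU in the consolidation range.
#' @param noise_sd additive Gaussian noise sd in HU.
#' @param seed RNG seed making the phantom deterministic.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 8L), spacing = c(1, 1, 5),
                         body_hu = 40, body_sd = 15,
                         lung_hu = -850, lung_sd = 40,
                         lesion_count = c(1L, 3L), lesion_radius = c(3, 8),
                         ggo_fraction = 0.5, distractor_count = 3L,
                         noise_sd = 20, seed = 1L) {
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 body_hu = body_hu, body_sd = body_sd,
                 lung_hu = lung_hu, lung_sd = lung_sd,
                 lesion_count = as.integer(lesion_count),
                 lesion_radius = as.numeric(lesion_radius),
                 ggo_fraction = ggo_fraction,
                 distractor_count = as.integer(distractor_count),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate one CT phantom
#'
#' Deterministic under `spec$seed`. Returns the HU volume together with the
#' exact ground-truth lung mask, lesion mask and lesion subtype mask
#' (1 = GGO rim, 2 = consolidation core). Distractor structures are part of
#' the volume but not of the lesion truth, so an HU-threshold pseudo-label
#' derived from the phantom is a strict superset of the truth whenever
#' `distractor_count > 0`.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` ([hu_volume()]), `lung`, `lesion`
#'   ([label_mask()]s) and `subtypes` (`subtype_mask`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  xi <- (seq_len(nx) - 0.5) / nx
  yi <- (seq_len(ny) - 0.5) / ny
  X <- array(rep(xi, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(yi, each = nx), times = nz), c(nx, ny, nz))

  # body: in-plane ellipse cylinder; outside is exterior air touching border
  body <- ((X - 0.5) / 0.46)^2 + ((Y - 0.5) / 0.42)^2 <= 1
  vol <- array(stats::rnorm(nx * ny * nz, spec$body_hu, spec$body_sd),
               c(nx, ny, nz))
  vol[!body] <- -1000

  # two lung ellipsoids
  lung <- array(FALSE, c(nx, ny, nz))
  centers <- list(c(0.32, 0.5), c(0.68, 0.5))
  ax <- 0.13; ay <- 0.26
  for (ctr in centers) {
    ell <- ((X - ctr[1]) / ax)^2 + ((Y - ctr[2]) / ay)^2 <= 1
    lung <- lung | ell
  }
  lung <- lung & body
  vol[lung] <- stats::rnorm(sum(lung), spec$lung_hu, spec$lung_sd)

  lesion <- array(FALSE, c(nx, ny, nz))
  subt <- array(0L, c(nx, ny, nz))
  n_les <- if (spec$lesion_count[1] == spec$lesion_count[2]) spec$lesion_count[1]
           else sample(spec$lesion_count[1]:spec$lesion_count[2], 1)
  ix <- array(rep(seq_len(nx), times = ny * nz), c(nx, ny, nz))
  iy <- array(rep(rep(seq_len(ny), each = nx), times = nz), c(nx, ny, nz))
  iz <- array(rep(seq_len(nz), each = nx * ny), c(nx, ny, nz))
  lung_idx <- which(lung)
  for (k in seq_len(n_les)) {
    placed <- FALSE
    for (attempt in 1:50) {
      r <- stats::runif(1, spec$lesion_radius[1], spec$lesion_radius[2])
      r <- r * 0.9^max(0, attempt - 10)  # shrink if placement keeps failing
      rz <- max(1, round(r / 3))
      ctr_i <- lung_idx[sample(length(lung_idx), 1)]
      cx <- ix[ctr_i]; cy <- iy[ctr_i]; cz <- iz[ctr_i]
      dist2 <- ((ix - cx) / r)^2 + ((iy - cy) / r)^2 + ((iz - cz) / rz)^2
      blob <- dist2 <= 1
      if (any(blob & !lung)) next  # lesions must lie strictly inside the lungs
      if (!any(blob)) next
      core <- dist2 <= (1 - spec$ggo_fraction)  # consolidation core, GGO rim
      nb <- sum(blob)
      hu_ggo <- rtruncnorm1(nb, -550, 80, -750, -301)
      hu_con <- rtruncnorm1(nb, -150, 60, -300, 50)
      v <- ifelse(core[blob], hu_con, hu_ggo)
      vol[blob] <- v
      lesion <- lesion | blob
      subt[blob & !core] <- 1L
      subt[blob & core] <- 2L
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place lesion ", k, " inside the lungs")
  }

  # distractors: small vessel-like discs at the lung boundary, HU in the
  # consolidation range -> captured by the HU rule but not true lesion
  if (spec$distractor_count > 0) {
    interior <- lung & !lesion
    shell_idx <- which(interior)
    bd <- .binary_dilate_3d(as.logical(!lung), as.integer(spec$shape), 2L)
    dim(bd) <- spec$shape
    shell <- interior & bd   # within 2 voxels of the lung boundary
    shell_idx <- which(shell)
    if (length(shell_idx)) {
      for (k in seq_len(spec$distractor_count)) {
        ci <- shell_idx[sample(length(shell_idx), 1)]
        cx <- ix[ci]; cy <- iy[ci]; cz <- iz[ci]
        rr <- stats::runif(1, 1, 2.2)
        disc <- ((ix - cx) / rr)^2 + ((iy - cy) / rr)^2 <= 1 &
          abs(iz - cz) <= sample(0:1, 1)
        disc <- disc & lung & !lesion
        if (!any(disc)) next
        vol[disc] <- rtruncnorm1(sum(disc), -150, 60, -300, 50)
      }
    }
  }

  if (spec$noise_sd > 0)
    vol <- vol + stats::rnorm(length(vol), 0, spec$noise_sd)

  list(volume = hu_volume(vol, spec$spacing),
       lung = label_mask(lung, spec$spacing, role = "lung"),
       lesion = label_mask(lesion, spec$spacing, role = "lesion"),
       subtypes = structure(list(voxels = subt, spacing = spec$spacing,
                                 n_outside = 0L),
                            class = "subtype_mask"))
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_cases` phantoms as NIfTI volumes and masks plus a JSON manifest,
#' split into labeled / pseudo / test subsets. Labeled and test cases carry
#' their true lesion masks; pseudo cases additionally carry the HU-derived
#' pseudo-label, mirroring a study design where a small expert-annotated set
#' is supplemented by a larger automatically labelled set.
#'
#' @param n_cases number of phantoms (>= 1).
#' @param spec a [phantom_spec()]; case `i` uses seed `spec$seed + i`.
#' @param out_dir output directory (created if needed).
#' @param fractions named fractions for the labeled/pseudo/test split
#'   (pseudo defaults to twice the labeled fraction).
#' @return the manifest as a data.frame, invisibly; written as
#'   `manifest.json`.
#' @export
generate_dataset <- function(n_cases, spec, out_dir,
                             fractions = c(labeled = 0.25, pseudo = 0.5,
                                           test = 0.25)) {
  if (n_cases < 1) stop("n_cases must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_lab <- max(1, round(fractions[["labeled"]] * n_cases))
  n_test <- max(0, round(fractions[["test"]] * n_cases))
  subset <- rep("pseudo", n_cases)
  subset[seq_len(n_lab)] <- "labeled"
  if (n_test > 0) subset[(n_cases - n_test + 1):n_cases] <- "test"
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    sp <- spec; sp$seed <- spec$seed + i
    ph <- generate_phantom(sp)
    id <- sprintf("case%03d", i)
    write_volume(ph$volume, file.path(out_dir, paste0(id, "_ct.nii.gz")))
    write_mask(ph$lung, file.path(out_dir, paste0(id, "_lung.nii.gz")))
    write_mask(ph$lesion, file.path(out_dir, paste0(id, "_lesion.nii.gz")))
    if (subset[i] == "pseudo") {
      pl <- generate_pseudolabel(ph$volume, ph$lung)
      write_mask(pl, file.path(out_dir, paste0(id, "_pseudo.nii.gz")))
    }
    rows[[i]] <- data.frame(case = id, subset = subset[i], seed = sp$seed)
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}

#' Pseudo-label noise rates
#'
#' False-positive fraction `|pseudo \ true| / |pseudo|` and false-negative
#' fraction `|true \ pseudo| / |true|` of a pseudo-label against the truth.
#' Empty denominators yield `NA`.
#'
#' @param true_mask,pseudo_mask [label_mask()]s (or 0/1 arrays) of identical
#'   shape.
#' @return named numeric vector `c(fp = ..., fn = ...)`.
#' @export
pseudo_label_noise_rate <- function(true_mask, pseudo_mask) {
  tv <- mask_voxels(true_mask); pv <- mask_voxels(pseudo_mask)
  if (!identical(dim(tv), dim(pv))) stop("mask shapes differ")
  np <- sum(pv); nt <- sum(tv)
  c(fp = if (np == 0) NA_real_ else sum(pv & !tv) / np,
    fn = if (nt == 0) NA_real_ else sum(tv & !pv) / nt)
}
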