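#' Synthetic mammogram-like fixtures
#'
#' Seeded generators for (a) mammogram-like single-channel images with an
#' elliptical breast region, band-limited fibroglandular texture, and
#' class-dependent lesions (bright spiculated mass or a microcalcification
#' cluster for malignant, an optional low-contrast smooth blob for benign),
#' and (b) two-Gaussian fused-embedding samples. These make every module
#' testable without external data. They emulate coarse statistical structure
#' only, not radiographic realism.
#'
#' @name fixtures
NULL

# separable Gaussian blur, sigma in pixels (band-limits white noise)
gauss_blur <- function(x, sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma); k <- k / sum(k)
  H <- nrow(x); W <- ncol(x)
  pad <- function(idx, n) pmin(pmax(idx, 1), n)
  out <- matrix(0, H, W)
  for (d in seq(-r, r)) out <- out + k[d + r + 1] * x[pad(seq_len(H) + d, H), ]
  out2 <- matrix(0, H, W)
  for (d in seq(-r, r)) out2 <- out2 + k[d + r + 1] * out[, pad(seq_len(W) + d, W)]
  out2
}

#' Generate one synthetic breast image with a lesion mask
#'
#' Dark background, bright elliptical breast region with smooth texture;
#' malignant lesions are either a bright Gaussian blob with radial spicule
#' strokes (`"mass"`) or a cluster of 5-15 small high-intensity dots
#' (`"microcalcification_cluster"`); benign images carry a faint smooth blob
#' (`"mass"`) or nothing (`"none"`). Intensities lie in [0, 1]; the mask
#' marks lesion pixels. Deterministic given the RNG state; pass `seed` for
#' a self-contained draw.
#'
#' @param size image side length (default 96).
#' @param class `"benign"` or `"malignant"`.
#' @param lesion_kind `"mass"`, `"microcalcification_cluster"`, or `"none"`
#'   (`"none"` is only valid for benign images).
#' @param texture_amp amplitude of the fibroglandular texture.
#' @param lesion_contrast lesion brightness above local tissue.
#' @param seed optional integer seed.
#' @return list with `image` (matrix in [0,1]) and `mask` (logical matrix).
#' @export
generate_breast_image <- function(size = 96L, class = c("benign", "malignant"),
                                  lesion_kind = NULL, texture_amp = 0.1,
                                  lesion_contrast = 0.45, seed = NULL) {
  class <- match.arg(class)
  with_seed(seed, {
    if (is.null(lesion_kind)) {
      lesion_kind <- if (class == "malignant") {
        sample(c("mass", "microcalcification_cluster"), 1)
      } else {
        sample(c("mass", "none"), 1, prob = c(0.6, 0.4))
      }
    }
    if (class == "malignant" && lesion_kind == "none")
      stop("malignant images always carry a lesion")
    H <- as.integer(size); W <- as.integer(size)
    rg <- expand.grid(r = seq_len(H), c = seq_len(W))
    # elliptical breast region, slightly off-center
    cy <- H * stats::runif(1, 0.45, 0.55); cx <- W * stats::runif(1, 0.4, 0.5)
    ay <- H * stats::runif(1, 0.36, 0.44); ax <- W * stats::runif(1, 0.30, 0.40)
    ell <- ((rg$r - cy) / ay)^2 + ((rg$c - cx) / ax)^2
    breast <- matrix(ell <= 1, H, W)
    edge <- matrix(pmax(0, 1 - ell), H, W)            # soft falloff to the skin line
    base <- 0.35 + 0.25 * edge^0.5
    tex <- gauss_blur(matrix(stats::rnorm(H * W), H, W), sigma = max(1.5, size / 48))
    tex <- tex / stats::sd(tex) * texture_amp
    img <- (base + tex) * breast + 0.02
    mask <- matrix(FALSE, H, W)

    if (lesion_kind != "none") {
      # lesion center well inside the breast; radius 1-15% of breast area
      repeat {
        lr <- cy + stats::runif(1, -0.5, 0.5) * ay
        lc <- cx + stats::runif(1, -0.5, 0.5) * ax
        rad <- size * stats::runif(1, 0.05, 0.1)
        d2 <- (matrix(rg$r, H, W) - lr)^2 + (matrix(rg$c, H, W) - lc)^2
        cand <- d2 <= rad^2
        if (all(breast[cand])) break
        rad <- rad * 0.8                               # shrink until inside
      }
      if (class == "malignant" && lesion_kind == "microcalcification_cluster") {
        n_dots <- sample(5:15, 1)
        for (i in seq_len(n_dots)) {
          ang <- stats::runif(1, 0, 2 * pi); rr <- stats::runif(1, 0, rad)
          dy <- lr + rr * sin(ang); dx <- lc + rr * cos(ang)
          dot_r <- stats::runif(1, 0.8, 1.6)
          dd <- (matrix(rg$r, H, W) - dy)^2 + (matrix(rg$c, H, W) - dx)^2
          bump <- exp(-dd / (2 * dot_r^2))
          img <- img + lesion_contrast * bump * breast
          mask <- mask | (bump > 0.3 & breast)
        }
      } else {
        sharp <- if (class == "malignant") 2.2 else 1.0
        contrast <- if (class == "malignant") lesion_contrast else 0.3 * lesion_contrast
        bump <- exp(-(d2 / (2 * (rad / sharp)^2))^(if (class == "malignant") 1 else 0.7))
        img <- img + contrast * bump * breast
        mask <- mask | (cand & breast)
        if (class == "malignant") {                   # radial spicule strokes
          n_sp <- sample(6:10, 1)
          for (k in seq_len(n_sp)) {
            ang <- stats::runif(1, 0, 2 * pi)
            len <- rad * stats::runif(1, 1.2, 2.0)
            ts <- seq(0, 1, length.out = ceiling(len) * 2)
            pr <- round(lr + ts * len * sin(ang)); pc <- round(lc + ts * len * cos(ang))
            ok <- pr >= 1 & pr <= H & pc >= 1 & pc <= W
            idx <- cbind(pr[ok], pc[ok])
            inb <- breast[idx]
            idx <- idx[inb, , drop = FALSE]
            img[idx] <- img[idx] + 0.5 * lesion_contrast * (1 - ts[ok][inb])
            mask[idx] <- TRUE
          }
        }
      }
    }
    list(image = clip01(img), mask = mask, lesion_kind = lesion_kind)
  })
}

#' Generate a synthetic patient cohort
#'
#' Draws `n_patients` patients with 1-3 images each (mean about 1.5), a
#' patient-consistent class (malignant with probability `malignant_frac`),
#' and one synthetic image plus lesion mask per row. With `dir` set, images
#' and masks are written as PNGs and the patient table as CSV; otherwise
#' everything stays in memory. Deterministic under `seed`.
#'
#' @param n_patients number of patients (>= 4).
#' @param malignant_frac probability a patient is malignant (default 0.3).
#' @param size image side length (default 96).
#' @param seed integer seed.
#' @param dir optional output directory.
#' @return list with `table` (data.frame: patient_id, image_id, path, label),
#'   `images`, `masks` (lists keyed by image_id), and the generation
#'   parameters in `params`.
#' @export
generate_cohort <- function(n_patients = 100L, malignant_frac = 0.3,
                            size = 96L, seed = 1L, dir = NULL) {
  stopifnot(n_patients >= 4)
  with_seed(seed, {
    counts <- sample(1:3, n_patients, replace = TRUE, prob = c(0.55, 0.4, 0.05))
    classes <- ifelse(stats::runif(n_patients) < malignant_frac, "malignant", "benign")
    rows <- list(); images <- list(); masks <- list()
    for (p in seq_len(n_patients)) {
      pid <- sprintf("P%04d", p)
      for (j in seq_len(counts[p])) {
        iid <- sprintf("%s_img%d", pid, j)
        gen <- generate_breast_image(size = size, class = classes[p])
        images[[iid]] <- gen$image
        masks[[iid]] <- gen$mask
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = pid, image_id = iid,
          path = if (is.null(dir)) NA_character_ else file.path(dir, paste0(iid, ".png")),
          label = classes[p], stringsAsFactors = FALSE)
      }
    }
    table <- do.call(rbind, rows)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      for (iid in names(images)) {
        png::writePNG(images[[iid]], file.path(dir, paste0(iid, ".png")))
        png::writePNG(masks[[iid]] * 1, file.path(dir, paste0(iid, "_mask.png")))
      }
      utils::write.csv(table, file.path(dir, "patients.csv"), row.names = FALSE)
    }
    list(table = table, images = images, masks = masks,
         params = list(n_patients = n_patients, malignant_frac = malignant_frac,
                       size = size, seed = seed))
  })
}

#' Two-Gaussian embedding fixture
#'
#' Samples `n` points per class from isotropic Gaussians whose means are
#' `separation * sigma` apart along a random unit direction, mimicking
#' well-separated fused embeddings. Used to test prototype learning in
#' isolation.
#'
#' @param n samples per class.
#' @param D embedding dimension.
#' @param separation distance between class means in units of `sigma`.
#' @param sigma isotropic standard deviation.
#' @param seed integer seed.
#' @return list with `X` (2n x D matrix), `y` (0 = benign, 1 = malignant),
#'   `means` (2 x D), `sigma`.
#' @export
embedding_fixture <- function(n = 500L, D = 16L, separation = 6, sigma = 1,
                              seed = 1L) {
  stopifnot(separation >= 0, sigma > 0, n >= 1, D >= 1)
  with_seed(seed, {
    dir <- stats::rnorm(D); dir <- dir / sqrt(sum(dir^2))
    mu0 <- -dir * separation * sigma / 2
    mu1 <- +dir * separation * sigma / 2
    X0 <- matrix(stats::rnorm(n * D, sd = sigma), n, D) +
      matrix(mu0, n, D, byrow = TRUE)
    X1 <- matrix(stats::rnorm(n * D, sd = sigma), n, D) +
      matrix(mu1, n, D, byrow = TRUE)
    list(X = rbind(X0, X1), y = rep(c(0L, 1L), each = n),
         means = rbind(mu0, mu1), sigma = sigma)
  })
}

#' Read a grayscale image (PNG or TIFF)
#'
#' 8- or 16-bit grayscale; RGB(A) input is converted by channel averaging.
#' @param path file path ending in .png, .tif or .tiff.
#' @return numeric matrix in [0, 1].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(x)) == 3) x <- apply(x[, , 1:min(3, dim(x)[3]), drop = FALSE], c(1, 2), mean)
  x
}
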