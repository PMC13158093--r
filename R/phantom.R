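# Synthetic 5-sequence tumor phantoms. The generator encodes the contrast
# physiology the grading task rests on: high-grade lesions get lower ADC
# (restricted diffusion from high cell density), heterogeneous T2 signal with
# a necrotic core, stronger rim enhancement and blurrier borders; low-grade
# lesions are uniform with sharp borders.

# separable Gaussian smoothing of a 3D array via per-axis kernel matrices
gauss_axis_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- (i - r):(i + r)
    ok <- idx >= 1L & idx <= n
    m[i, idx[ok]] <- k[ok]
    m[i, ] <- m[i, ] / sum(m[i, ])
  }
  m
}

smooth_gauss3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  m1 <- gauss_axis_matrix(d[1], sigma)
  m2 <- gauss_axis_matrix(d[2], sigma)
  m3 <- gauss_axis_matrix(d[3], sigma)
  x <- m1 %*% matrix(a, d[1], d[2] * d[3])
  dim(x) <- d
  x <- aperm(x, c(2, 1, 3))
  x <- m2 %*% matrix(x, d[2], d[1] * d[3])
  dim(x) <- d[c(2, 1, 3)]
  x <- aperm(x, c(2, 1, 3))
  x <- aperm(x, c(3, 2, 1))
  x <- m3 %*% matrix(x, d[3], d[2] * d[1])
  dim(x) <- d[c(3, 2, 1)]
  aperm(x, c(3, 2, 1))
}

ellipsoid_mask <- function(grid, center, radii) {
  d <- seq_len(grid[1]); h <- seq_len(grid[2]); w <- seq_len(grid[3])
  dd <- ((d - center[1]) / radii[1])^2
  hh <- ((h - center[2]) / radii[2])^2
  ww <- ((w - center[3]) / radii[3])^2
  arr <- outer(outer(dd, hh, `+`), ww, `+`)
  array(as.numeric(arr <= 1), dim = grid)
}

#' Specification of one synthetic tumor phantom
#'
#' @param grid Integer `(D, H, W)` voxel grid.
#' @param spacing Voxel spacing in mm, `(D, H, W)` order (default the
#'   0.5 x 0.5 mm in-plane, 5 mm slice protocol).
#' @param center Tumor center in voxels (default grid center).
#' @param radii Ellipsoid radii in voxels.
#' @param grade `"LG"` or `"HG"`.
#' @param necrosis Add a necrotic core (default: high grade only).
#' @param edema Add a peritumoral edema band (default: high grade only).
#' @param sigma_boundary Gaussian boundary blur in voxels (default 1.5 for
#'   high grade — blurred infiltrative borders — and 0.5 for low grade).
#' @param sigma_noise Additive Gaussian noise SD in normalized intensity
#'   units.
#' @param adc_gap ADC contrast between grades, in units of `sigma_noise`
#'   (high-grade in-tumor ADC sits this many noise SDs below low-grade).
#' @param seed Seed making the phantom a pure function of its spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid = c(16L, 64L, 64L),
                         spacing = c(5, 0.5, 0.5),
                         center = (grid + 1) / 2,
                         radii = c(4, 16, 16),
                         grade = c("LG", "HG"),
                         necrosis = NULL,
                         edema = NULL,
                         sigma_boundary = NULL,
                         sigma_noise = 0.1,
                         adc_gap = 1.0,
                         seed = 1L) {
  grade <- match.arg(grade)
  hg <- grade == "HG"
  spec <- list(grid = as.integer(grid), spacing = spacing, center = center,
               radii = radii, grade = grade,
               necrosis = if (is.null(necrosis)) hg else necrosis,
               edema = if (is.null(edema)) hg else edema,
               sigma_boundary = if (is.null(sigma_boundary)) {
                 if (hg) 1.5 else 0.5
               } else sigma_boundary,
               sigma_noise = sigma_noise, adc_gap = adc_gap,
               seed = as.integer(seed))
  stopifnot(spec$sigma_noise >= 0, all(spec$radii > 0))
  if (any(spec$center - spec$radii < 1) ||
      any(spec$center + spec$radii > spec$grid)) {
    stop("tumor ellipsoid exceeds the voxel grid", call. = FALSE)
  }
  structure(spec, class = "phantom_spec")
}

#' Generate one 5-sequence tumor phantom
#'
#' Builds the five MRI contrasts from a shared ellipsoidal tumor: CE-T1WI
#' with rim enhancement (stronger for high grade), mildly hypointense T1WI,
#' hyperintense T2WI (plus heterogeneity texture and a necrotic core for high
#' grade), FLAIR with an optional peritumoral edema band, and ADC whose
#' in-tumor mean is lower for high grade by `adc_gap * sigma_noise`.
#' Boundaries are blurred with `sigma_boundary`; the returned mask is the
#' exact (unblurred) ellipsoid indicator. Deterministic given the spec.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (`(D, H, W, 5)` array, canonical sequence
#'   order), `mask` (`(D, H, W)` binary array), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  g <- spec$grid
  hg <- spec$grade == "HG"
  e_full <- ellipsoid_mask(g, spec$center, spec$radii)
  s <- smooth_gauss3(e_full, spec$sigma_boundary)
  s_inner <- smooth_gauss3(ellipsoid_mask(g, spec$center, spec$radii * 0.7),
                           spec$sigma_boundary)
  rim <- pmax(s - s_inner, 0)
  core <- if (spec$necrosis) {
    smooth_gauss3(ellipsoid_mask(g, spec$center, spec$radii * 0.4),
                  spec$sigma_boundary)
  } else {
    array(0, dim = g)
  }
  band <- if (spec$edema) {
    pmax(smooth_gauss3(ellipsoid_mask(g, spec$center,
                                      pmin(spec$radii * 1.3,
                                           spec$grid / 2 - 0.5)),
                       spec$sigma_boundary) - s, 0)
  } else {
    array(0, dim = g)
  }

  rim_amp <- if (hg) 1.2 else 0.6
  ce <- rim_amp * rim + 0.2 * s
  t1 <- -0.4 * s
  t2 <- 0.8 * s
  if (hg) {
    tex <- smooth_gauss3(array(stats::rnorm(prod(g)), dim = g), 1.0)
    t2 <- t2 + 3 * spec$sigma_noise * tex * s + 0.6 * core
  }
  flair <- 0.5 * s + 0.6 * band
  adc_drop <- if (hg) 0.15 + spec$adc_gap * spec$sigma_noise else 0.15
  adc <- 1 - adc_drop * s

  vol <- array(0, dim = c(g, 5L))
  vol[, , , 1] <- ce
  vol[, , , 2] <- t1
  vol[, , , 3] <- t2
  vol[, , , 4] <- flair
  vol[, , , 5] <- adc
  vol <- vol + array(stats::rnorm(prod(g) * 5, sd = spec$sigma_noise),
                     dim = c(g, 5L))
  list(volume = vol, mask = e_full, spec = spec)
}

#' Generate a labelled phantom dataset
#'
#' Draws `n` phantoms with per-subject jitter in tumor center and radii and
#' grade-dependent defaults, giving two well-separated but non-degenerate
#' classes for training and evaluation exercises.
#'
#' @param n Number of subjects.
#' @param prevalence Probability of high grade (default the 198/340 of the
#'   cohort structure the generator mirrors).
#' @param grid Voxel grid of every phantom.
#' @param seed Master seed; each phantom derives its own sub-seed.
#' @param ... Passed on to [phantom_spec()] (e.g. `sigma_noise`).
#' @return A [volume_batch()] with labels (1 = HG) and masks.
#' @export
generate_phantom_dataset <- function(n, prevalence = 198 / 340,
                                     grid = c(16L, 64L, 64L), seed = 1L, ...) {
  set.seed(seed)
  labels <- stats::rbinom(n, 1L, prevalence)
  subseeds <- sample.int(.Machine$integer.max, n)
  jitter_c <- matrix(stats::runif(3 * n, -0.05, 0.05), ncol = 3)
  jitter_r <- matrix(stats::runif(3 * n, 0.8, 1.1), ncol = 3)
  base_radii <- grid * c(0.25, 0.25, 0.25)
  vols <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- phantom_spec(
      grid = grid,
      center = (grid + 1) / 2 + jitter_c[i, ] * grid,
      radii = base_radii * jitter_r[i, ],
      grade = if (labels[i] == 1L) "HG" else "LG",
      seed = subseeds[i], ...)
    ph <- generate_phantom(spec)
    vols[[i]] <- ph$volume
    masks[[i]] <- ph$mask
  }
  volume_batch(vols, labels = labels, masks = masks)
}

#' Specification of a synthetic clinical cohort
#'
#' Grade-conditional category probabilities default to the structure of a
#' 340-subject pediatric brain-tumor cohort (142 low grade / 198 high grade):
#' gender, tumor location, tumor type (ependymoma / medulloblastoma /
#' pilocytic astrocytoma), necrosis, edema, and a near-deterministic Ki-67
#' coupling (>15% in essentially all high-grade subjects), plus per-grade
#' normal age distributions.
#'
#' @param n Number of subjects.
#' @param prevalence Probability of high grade.
#' @param seed Seed.
#' @return A `cohort_spec` list with the conditional probability tables.
#' @export
cohort_spec <- function(n, prevalence = 198 / 340, seed = 1L) {
  probs <- list(
    gender = list(levels = c("male", "female"),
                  LG = c(76, 66) / 142, HG = c(130, 68) / 198),
    location = list(
      levels = c("fourth_ventricle", "vermis_midline", "brainstem",
                 "cerebellum_hemisphere", "occipital_lobe", "frontal_lobe"),
      LG = c(56, 15, 6, 64, 0, 1) / 142,
      HG = c(144, 23, 4, 22, 4, 1) / 198),
    type = list(levels = c("EP", "MB", "PA"),
                LG = c(33, 0, 109) / 142, HG = c(39, 159, 0) / 198),
    necrosis = list(levels = c("necrotic", "non_necrotic"),
                    LG = c(30, 112) / 142, HG = c(159, 39) / 198),
    edema = list(levels = c("edematous", "non_edematous"),
                 LG = c(62, 80) / 142, HG = c(135, 63) / 198),
    ki67 = list(levels = c(">15%", "<=15%"),
                LG = c(4, 138) / 142, HG = c(198, 0) / 198)
  )
  age <- list(LG = c(mean = 6.5, sd = 3.2), HG = c(mean = 8.3, sd = 3.2))
  structure(list(n = as.integer(n), prevalence = prevalence, probs = probs,
                 age = age, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic clinical cohort table
#'
#' Draws per-subject grade, then each covariate from its grade-conditional
#' distribution; ages are normal per grade, truncated to \[0.5, 18\] years.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject: `id`, `grade` (`"LG"`/`"HG"`),
#'   `label` (1 = HG), `age`, and one column per covariate. `n = 0` yields an
#'   empty table with the full schema.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  label <- if (n > 0) stats::rbinom(n, 1L, spec$prevalence) else integer(0)
  grade <- ifelse(label == 1L, "HG", "LG")
  draw <- function(cov) {
    out <- character(n)
    for (g in c("LG", "HG")) {
      idx <- grade == g
      if (any(idx)) {
        out[idx] <- sample(cov$levels, sum(idx), replace = TRUE,
                           prob = cov[[g]])
      }
    }
    out
  }
  age <- numeric(n)
  for (g in c("LG", "HG")) {
    idx <- grade == g
    if (any(idx)) {
      a <- stats::rnorm(sum(idx), spec$age[[g]]["mean"], spec$age[[g]]["sd"])
      age[idx] <- pmin(pmax(a, 0.5), 18)
    }
  }
  out <- tibble::tibble(
    id = if (n > 0) sprintf("S%04d", seq_len(n)) else character(0),
    grade = grade, label = label, age = age)
  for (v in names(spec$probs)) out[[v]] <- draw(spec$probs[[v]])
  out
}

#' Stratified train/validation/test split
#'
#' Samples without replacement within each class. Validation and test totals
#' are `round(ratio * n)` overall; each class contributes its proportional
#' quota, fractional seats going to the classes with the largest remainders
#' (ties broken by class order), so class prevalence in every split stays
#' within one subject of the global prevalence. The remainder trains. The
#' three index sets are disjoint and their union covers all ids.
#'
#' @param ids Vector of subject identifiers.
#' @param labels Class labels, same length.
#' @param ratios Numeric `(train, val, test)`, summing to 1.
#' @param seed Seed.
#' @return List of id vectors `train`, `val`, `test`.
#' @export
stratified_split <- function(ids, labels, ratios = c(0.7, 0.15, 0.15),
                             seed = 1L) {
  stopifnot(length(ids) == length(labels),
            abs(sum(ratios) - 1) < 1e-8, length(ratios) == 3L)
  set.seed(seed)
  classes <- unique(labels)
  n_class <- vapply(classes, function(g) sum(labels == g), integer(1))
  if (any(n_class < 3L)) {
    stop("class '", classes[which(n_class < 3L)[1]],
         "' has fewer than 3 subjects; cannot split", call. = FALSE)
  }
  # largest-remainder allocation of the per-split totals across classes
  allocate <- function(ratio) {
    total <- round(ratio * length(labels))
    quota <- ratio * n_class
    base <- floor(quota)
    extra <- total - sum(base)
    if (extra > 0) {
      take <- order(quota - base, decreasing = TRUE)[seq_len(extra)]
      base[take] <- base[take] + 1L
    } else if (extra < 0) {
      drop_i <- order(quota - base)[seq_len(-extra)]
      base[drop_i] <- base[drop_i] - 1L
    }
    base
  }
  n_val <- allocate(ratios[2])
  n_test <- allocate(ratios[3])
  train <- val <- test <- c()
  for (i in seq_along(classes)) {
    cls <- sample(ids[labels == classes[i]])
    val <- c(val, cls[seq_len(n_val[i])])
    test <- c(test, cls[n_val[i] + seq_len(n_test[i])])
    train <- c(train, cls[-seq_len(n_val[i] + n_test[i])])
  }
  list(train = train, val = val, test = test)
}
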