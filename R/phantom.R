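## Synthetic sagittal-spine phantom.
##
## Emulates the statistical structure the segmentation/classification
## pipeline assumes: a vertical stack of bright, rounded-rectangular
## vertebral bodies (L1 superior .. L5 inferior) on a dark background, with
## anterior (left) wedge-compression deformation for fractured levels, a
## smooth multiplicative intensity bias field, and additive Gaussian noise.
## Ground-truth masks and labels are exact by construction.

#' Phantom specification
#'
#' @param image_height,image_width image size in pixels.
#' @param n_vertebrae number of stacked vertebral bodies (default 5,
#'   labelled L1 top to L5 bottom).
#' @param vb_height,vb_width vertebral body size in pixels.
#' @param disc_gap intervertebral gap in pixels.
#' @param corner_radius rounding radius of the vertebral corners, pixels.
#' @param fracture_levels integer indices (1 = L1) of fractured levels.
#' @param height_loss_fraction anterior height loss of fractured levels, in
#'   `[0, 1)`: the left column keeps `1 - height_loss_fraction` of its
#'   height, scaling linearly to full height at the posterior (right) edge.
#' @param boundary_irregularity amplitude (pixels) of the random perturbation
#'   of the collapsed superior boundary.
#' @param foreground_mean,background_mean mean intensities (0-255 scale).
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0).
#' @param bias_amplitude multiplicative bias-field half-range `a`: the field
#'   lies in `[1 - a, 1 + a]` (two low-frequency separable cosine terms with
#'   random phases).
#' @param seed integer seed; identical spec + seed gives bit-identical cases.
#' @return validated list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(image_height = 256L, image_width = 256L,
                         n_vertebrae = 5L,
                         vb_height = 28L, vb_width = 44L,
                         disc_gap = 10L, corner_radius = 5L,
                         fracture_levels = integer(0),
                         height_loss_fraction = 0.4,
                         boundary_irregularity = 1,
                         foreground_mean = 180, background_mean = 40,
                         noise_sd = 5, bias_amplitude = 0.1,
                         seed = 1L) {
  spec <- list(image_height = as.integer(image_height),
               image_width = as.integer(image_width),
               n_vertebrae = as.integer(n_vertebrae),
               vb_height = as.integer(vb_height),
               vb_width = as.integer(vb_width),
               disc_gap = as.integer(disc_gap),
               corner_radius = as.integer(corner_radius),
               fracture_levels = as.integer(fracture_levels),
               height_loss_fraction = height_loss_fraction,
               boundary_irregularity = boundary_irregularity,
               foreground_mean = foreground_mean,
               background_mean = background_mean,
               noise_sd = noise_sd,
               bias_amplitude = bias_amplitude,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$n_vertebrae < 1) stop_field("n_vertebrae", "must be >= 1")
  if (spec$height_loss_fraction < 0 || spec$height_loss_fraction >= 1) {
    stop_field("height_loss_fraction", "must lie in [0, 1)")
  }
  if (spec$noise_sd < 0) stop_field("noise_sd", "must be >= 0")
  if (spec$bias_amplitude < 0) stop_field("bias_amplitude", "must be >= 0")
  if (spec$boundary_irregularity < 0) stop_field("boundary_irregularity", "must be >= 0")
  if (length(spec$fracture_levels) &&
      (min(spec$fracture_levels) < 1 || max(spec$fracture_levels) > spec$n_vertebrae)) {
    stop_field("fracture_levels", "indices must lie in 1..n_vertebrae")
  }
  total_h <- spec$n_vertebrae * spec$vb_height + (spec$n_vertebrae - 1) * spec$disc_gap
  if (total_h > spec$image_height - 8L) {
    stop_field("vb_height", "stacked extent does not fit inside the image (8 px margin)")
  }
  if (spec$vb_width > spec$image_width - 8L) {
    stop_field("vb_width", "vertebra wider than the image (8 px margin)")
  }
  invisible(spec)
}

# Column heights of the rounded-rectangle template: full height except near
# the left/right ends where quarter-circle corners shave both the top and
# bottom rows.
rounded_template_heights <- function(h, w, r) {
  heights <- rep(h, w)
  if (r > 0) {
    for (c0 in seq_len(w)) {
      dl <- r - (c0 - 1); dr <- r - (w - c0)
      d <- max(dl, dr, 0)
      if (d > 0) {
        cut <- r - floor(sqrt(max(0, r^2 - d^2)))
        heights[c0] <- max(0, h - 2 * cut)
      }
    }
  }
  heights
}

# Build one vertebra mask inside an h x w box. Fractured: column heights are
# scaled by (1 - hlf) at the left edge, linearly up to 1 at the right; the
# inferior boundary stays fixed, the superior boundary drops (plus an
# irregular perturbation), giving the anterior wedge morphology.
vb_mask_box <- function(spec, fractured) {
  h <- spec$vb_height; w <- spec$vb_width
  heights <- rounded_template_heights(h, w, spec$corner_radius)
  tops <- (h - heights) %/% 2          # rows cut from the top (template)
  if (fractured) {
    f <- (1 - spec$height_loss_fraction) +
      spec$height_loss_fraction * (seq_len(w) - 1) / (w - 1)
    new_heights <- round(heights * f)
    if (spec$boundary_irregularity > 0) {
      jitter <- stats::rnorm(w, 0, spec$boundary_irregularity)
      jitter <- round(stats::filter(c(jitter[1], jitter, jitter[w]),
                                    rep(1 / 3, 3))[2:(w + 1)])
      new_heights <- pmax(1, pmin(heights, new_heights + jitter))
    }
    # keep the bottom (inferior) edge; the cut comes off the top
    tops <- tops + (heights - new_heights)
    heights <- new_heights
  }
  box <- matrix(0L, h, w)
  for (c0 in seq_len(w)) {
    if (heights[c0] > 0) {
      box[(tops[c0] + 1):(tops[c0] + heights[c0]), c0] <- 1L
    }
  }
  box
}

#' Generate one phantom case
#'
#' @param spec a [phantom_spec()].
#' @return object of class `"phantom_case"`: list with
#'   * `image`: integer gray matrix in `[0, 255]`,
#'   * `truth_masks`: named list (`L1`, `L2`, ...) of pairwise-disjoint 0/1
#'     ground-truth masks,
#'   * `labels`: named integer vector, 0 = normal, 1 = fractured,
#'   * `spec`: the input spec.
#' @examples
#' case <- generate_case(phantom_spec(fracture_levels = 3, seed = 7))
#' sapply(case$truth_masks, sum)
#' @export
generate_case <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  with_seed(spec$seed, {
    H <- spec$image_height; W <- spec$image_width
    n <- spec$n_vertebrae
    total_h <- n * spec$vb_height + (n - 1) * spec$disc_gap
    y0 <- (H - total_h) %/% 2
    x0 <- (W - spec$vb_width) %/% 2
    masks <- vector("list", n)
    labels <- integer(n)
    names(masks) <- names(labels) <- paste0("L", seq_len(n))
    for (i in seq_len(n)) {
      fractured <- i %in% spec$fracture_levels
      labels[i] <- as.integer(fractured)
      box <- vb_mask_box(spec, fractured)
      m <- matrix(0L, H, W)
      top <- y0 + (i - 1) * (spec$vb_height + spec$disc_gap)
      m[(top + 1):(top + spec$vb_height), (x0 + 1):(x0 + spec$vb_width)] <- box
      masks[[i]] <- m
    }
    img <- matrix(spec$background_mean, H, W)
    for (i in seq_len(n)) img[masks[[i]] == 1L] <- spec$foreground_mean
    if (spec$bias_amplitude > 0) {
      ph <- stats::runif(4, 0, 2 * pi)
      xs <- (seq_len(W) - 1) / W; ys <- (seq_len(H) - 1) / H
      b1 <- outer(cos(2 * pi * ys + ph[1]), cos(2 * pi * xs + ph[2]))
      b2 <- outer(cos(4 * pi * ys + ph[3]), cos(4 * pi * xs + ph[4]))
      img <- img * (1 + spec$bias_amplitude * (b1 + b2) / 2)
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
    }
    img <- as_gray(pmin(pmax(round_half_up(img), 0), 255))
    structure(list(image = img, truth_masks = masks, labels = labels, spec = spec),
              class = "phantom_case")
  })
}

#' Generate a phantom dataset
#'
#' Draws per-vertebra fracture indicators i.i.d. Bernoulli(prevalence) and
#' generates one case per subject, each with its own deterministic sub-seed.
#'
#' @param spec_template a [phantom_spec()] whose `fracture_levels` and `seed`
#'   are overridden per case.
#' @param n_cases number of cases (default 63 subjects, mirroring the scale
#'   of a 63-patient / 315-vertebra clinical study).
#' @param fracture_prevalence probability that any given vertebra is
#'   fractured, in `[0, 1]`.
#' @param seed master seed for the label draw and case sub-seeds.
#' @return list with `cases` (list of `"phantom_case"`) and `manifest`
#'   (data.frame: `case_id`, `level`, `label`).
#' @export
generate_dataset <- function(spec_template = phantom_spec(),
                             n_cases = 63L,
                             fracture_prevalence = 0.3,
                             seed = 1L) {
  stopifnot(inherits(spec_template, "phantom_spec"))
  if (n_cases < 1) stop_field("n_cases", "must be >= 1")
  if (fracture_prevalence < 0 || fracture_prevalence > 1) {
    stop_field("fracture_prevalence", "must lie in [0, 1]")
  }
  n <- spec_template$n_vertebrae
  lab_mat <- with_seed(derive_seed(seed, "labels"), {
    matrix(stats::rbinom(n_cases * n, 1, fracture_prevalence), n_cases, n)
  })
  cases <- vector("list", n_cases)
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    spec_i <- spec_template
    spec_i$fracture_levels <- which(lab_mat[i, ] == 1L)
    spec_i$seed <- derive_seed(seed, paste0("case", i))
    cases[[i]] <- generate_case(spec_i)
    rows[[i]] <- data.frame(case_id = sprintf("case%03d", i),
                            level = paste0("L", seq_len(n)),
                            label = lab_mat[i, ])
  }
  names(cases) <- sprintf("case%03d", seq_len(n_cases))
  list(cases = cases, manifest = do.call(rbind, rows))
}
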