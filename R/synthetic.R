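# Synthetic-data generators.  These stand in for the clinical inputs the
# pipeline was designed around -- frozen-section whole-slide images with
# pathologist ROI annotations and slide-level labels -- so that every
# downstream stage can be exercised and tested without any slide archive.
#
# Three generators, three levels of abstraction:
#   * simulate_slide():            a tiled two-texture RGB raster with a
#                                  planted malignant region (tests tiling,
#                                  labeling, the patch model, heatmaps)
#   * simulate_likelihood_corpus(): per-slide Beta-mixture patch
#                                  likelihoods (tests aggregation/selection/
#                                  slide models without any imaging)
#   * simulate_feature_bags():     Gaussian instance bags with planted
#                                  witness instances (tests the MIL head)

default_texture_params <- function() {
  list(
    benign    = list(mean = c(0.85, 0.68, 0.78), sd = 0.04,
                     freq = 4,  amp = 0.05),
    malignant = list(mean = c(0.55, 0.40, 0.65), sd = 0.04,
                     freq = 12, amp = 0.08),
    blank_value = 0.97
  )
}

#' Configuration for one synthetic tiled slide
#'
#' Describes a slide as a grid of tiles drawn from two texture/color
#' classes: a benign background texture (pale pink, low spatial
#' frequency) and a malignant texture (darker purple, higher "nuclear
#' speckle" frequency), plus near-white blank tiles emulating glass.
#' A malignant slide plants a contiguous region of malignant tiles
#' covering a fraction `malignant_fraction` of the tissue tiles,
#' mirroring that ROI annotations delineate lesional tissue.
#'
#' @param grid_rows,grid_cols Tile-grid extent (positive integers).
#' @param tile_size Tile side in pixels (default 512, the standard patch
#'   size for 20x WSI pipelines).
#' @param malignant_fraction Fraction rho of tissue tiles inside the
#'   planted malignant region; 0 defines a benign slide.
#' @param blank_fraction Fraction of tiles that are blank glass.
#' @param texture_params Per-class color mean/sd, speckle frequency and
#'   amplitude; see `default_texture_params()`.
#' @param seed Integer seed; identical config + seed reproduce the slide
#'   byte for byte.
#' @return Object of class `slide_sim_config`.
#' @export
slide_sim_config <- function(grid_rows, grid_cols, tile_size = 512L,
                             malignant_fraction = 0,
                             blank_fraction = 0,
                             texture_params = default_texture_params(),
                             seed = 1L) {
  if (grid_rows < 1 || grid_cols < 1) {
    stop_config("grid dimensions must be positive")
  }
  if (tile_size < 4) stop_config("tile_size too small")
  assert_scalar_number(malignant_fraction, "malignant_fraction", 0, 1)
  assert_scalar_number(blank_fraction, "blank_fraction", 0, 1)
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 tile_size = as.integer(tile_size),
                 malignant_fraction = malignant_fraction,
                 blank_fraction = blank_fraction,
                 texture_params = texture_params,
                 seed = as.integer(seed)),
            class = "slide_sim_config")
}

# grow a contiguous tile region of size n from a random start among the
# candidate (tissue) tiles; BFS over 4-neighbours, restarting at the
# nearest unused candidate if the component is exhausted
grow_region <- function(candidates, n, grid_rows, grid_cols) {
  if (n == 0L) return(integer(0))
  cand_set <- rep(FALSE, grid_rows * grid_cols)
  cand_set[candidates] <- TRUE
  start <- candidates[sample.int(length(candidates), 1L)]
  region <- integer(0)
  frontier <- start
  while (length(region) < n) {
    if (!length(frontier)) {
      left <- setdiff(candidates, region)
      frontier <- left[sample.int(length(left), 1L)]
    }
    cur <- frontier[1L]
    frontier <- frontier[-1L]
    if (cur %in% region) next
    region <- c(region, cur)
    r <- (cur - 1L) %/% grid_cols
    c <- (cur - 1L) %% grid_cols
    nb <- c(if (r > 0L) cur - grid_cols,
            if (r < grid_rows - 1L) cur + grid_cols,
            if (c > 0L) cur - 1L,
            if (c < grid_cols - 1L) cur + 1L)
    nb <- nb[cand_set[nb] & !(nb %in% region) & !(nb %in% frontier)]
    frontier <- c(frontier, nb)
  }
  region
}

render_tile <- function(par, tile_size) {
  xy <- outer(seq_len(tile_size), seq_len(tile_size), `+`) / tile_size
  phase <- stats::runif(1, 0, 2 * pi)
  speckle <- par$amp * sin(2 * pi * par$freq * xy + phase)
  tile <- array(0, dim = c(tile_size, tile_size, 3L))
  for (ch in 1:3) {
    tile[, , ch] <- par$mean[ch] + speckle +
      stats::rnorm(tile_size^2, sd = par$sd)
  }
  pmin(pmax(tile, 0), 1)
}

#' Generate one synthetic tiled slide
#'
#' @param cfg A [slide_sim_config()].
#' @return List with `raster` (H x W x 3 array in \[0,1\]), `roi_mask`
#'   (H x W binary matrix covering exactly the planted malignant tiles),
#'   `label` (1 iff `malignant_fraction > 0`), and `tiles`, a data frame
#'   of per-tile ground truth (`row`, `col`, 0-based; `blank`;
#'   `in_roi`).
#' @export
simulate_slide <- function(cfg) {
  stopifnot(inherits(cfg, "slide_sim_config"))
  with_seed(cfg$seed, {
    nr <- cfg$grid_rows; nc <- cfg$grid_cols; ts <- cfg$tile_size
    n_tiles <- nr * nc
    idx <- seq_len(n_tiles)
    n_blank <- round(cfg$blank_fraction * n_tiles)
    blank <- rep(FALSE, n_tiles)
    if (n_blank > 0) blank[sample(idx, n_blank)] <- TRUE
    tissue_idx <- idx[!blank]
    if (!length(tissue_idx)) stop_config("no tissue tiles on slide")
    n_roi <- round(cfg$malignant_fraction * length(tissue_idx))
    if (cfg$malignant_fraction > 0 && n_roi == 0L) n_roi <- 1L
    roi_idx <- grow_region(tissue_idx, n_roi, nr, nc)

    raster <- array(0, dim = c(nr * ts, nc * ts, 3L))
    roi_mask <- matrix(0L, nr * ts, nc * ts)
    tp <- cfg$texture_params
    in_roi <- rep(FALSE, n_tiles)
    in_roi[roi_idx] <- TRUE
    for (i in idx) {
      r <- (i - 1L) %/% nc
      c <- (i - 1L) %% nc
      rows <- (r * ts + 1L):((r + 1L) * ts)
      cols <- (c * ts + 1L):((c + 1L) * ts)
      if (blank[i]) {
        raster[rows, cols, ] <- tp$blank_value +
          stats::rnorm(ts^2 * 3, sd = 0.005)
      } else if (in_roi[i]) {
        raster[rows, cols, ] <- render_tile(tp$malignant, ts)
        roi_mask[rows, cols] <- 1L
      } else {
        raster[rows, cols, ] <- render_tile(tp$benign, ts)
      }
    }
    raster <- pmin(pmax(raster, 0), 1)
    tiles <- data.frame(row = (idx - 1L) %/% nc, col = (idx - 1L) %% nc,
                        blank = blank, in_roi = in_roi)
    list(raster = raster, roi_mask = roi_mask,
         label = as.integer(cfg$malignant_fraction > 0), tiles = tiles)
  })
}

#' Configuration for a Beta-mixture patch-likelihood corpus
#'
#' An imaging-free stand-in for the output of a trained patch
#' classifier: benign slides draw every patch likelihood from
#' `Beta(a0, b0)` (mass near 0), malignant slides draw a per-slide
#' fraction rho ~ Uniform(`rho_range`) of patches from `Beta(a1, b1)`
#' (mass near 1) and the rest from the benign component.  The defaults
#' -- Beta(2, 8) vs Beta(8, 2) with rho in \[0.2, 0.6\] -- encode a
#' moderately confident patch classifier on slides whose lesion covers
#' a fifth to three fifths of the tissue.
#'
#' @param n_slides Number of slides.
#' @param n_patches Patches per slide: a scalar or a `c(lo, hi)` range
#'   sampled uniformly per slide.
#' @param benign_beta,malignant_beta Length-2 positive shape vectors.
#' @param rho_range Interval for the malignant-patch fraction of
#'   positive slides.
#' @param class_prior Fraction of slides that are positive (allocated
#'   deterministically via rounding, then order shuffled).
#' @param label_scheme Which slide endpoint the labels represent
#'   (`"malignancy"`, `"braf"`, `"lnm"`); bookkeeping only.
#' @param seed Integer seed.
#' @return Object of class `likelihood_sim_config`.
#' @export
likelihood_sim_config <- function(n_slides, n_patches = c(50L, 200L),
                                  benign_beta = c(2, 8),
                                  malignant_beta = c(8, 2),
                                  rho_range = c(0.2, 0.6),
                                  class_prior = 0.5,
                                  label_scheme = c("malignancy", "braf",
                                                   "lnm"),
                                  seed = 1L) {
  label_scheme <- match.arg(label_scheme)
  if (n_slides < 0) stop_config("n_slides must be >= 0")
  if (any(c(benign_beta, malignant_beta) <= 0)) {
    stop_config("Beta shape parameters must be positive")
  }
  assert_scalar_number(class_prior, "class_prior", 0, 1)
  if (class_prior > 0 && n_slides > 0 &&
      (length(rho_range) != 2L || any(!is.finite(rho_range)))) {
    stop_config("rho_range must be a finite interval for positive slides")
  }
  if (length(rho_range) == 2L &&
      (rho_range[1] > rho_range[2] || rho_range[1] < 0 ||
       rho_range[2] > 1)) {
    stop_config("rho_range must be an ordered sub-interval of [0, 1]")
  }
  structure(list(n_slides = as.integer(n_slides),
                 n_patches = as.integer(n_patches),
                 benign_beta = benign_beta,
                 malignant_beta = malignant_beta,
                 rho_range = rho_range, class_prior = class_prior,
                 label_scheme = label_scheme, seed = as.integer(seed)),
            class = "likelihood_sim_config")
}

#' Generate a corpus of patch-likelihood bags
#'
#' @param cfg A [likelihood_sim_config()].
#' @return List with `bags` (list of [likelihood_bag()]), `labels`
#'   (named 0/1 integer vector), `rho` (per-slide malignant fraction, 0
#'   for negatives) and `components` (per-slide 0/1 vector marking which
#'   patches came from the malignant Beta component).
#' @export
simulate_likelihood_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "likelihood_sim_config"))
  n <- cfg$n_slides
  if (n == 0L) {
    return(list(bags = list(), labels = integer(0), rho = numeric(0),
                components = list()))
  }
  with_seed(cfg$seed, {
    n_pos <- round(cfg$class_prior * n)
    labels <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
    names(labels) <- sprintf("slide_%03d", seq_len(n))
    a0 <- cfg$benign_beta[1]; b0 <- cfg$benign_beta[2]
    a1 <- cfg$malignant_beta[1]; b1 <- cfg$malignant_beta[2]
    bags <- vector("list", n)
    components <- vector("list", n)
    rho <- numeric(n)
    for (i in seq_len(n)) {
      m <- if (length(cfg$n_patches) == 2L) {
        sample(cfg$n_patches[1]:cfg$n_patches[2], 1L)
      } else cfg$n_patches[1]
      if (labels[i] == 1L) {
        rho[i] <- stats::runif(1, cfg$rho_range[1], cfg$rho_range[2])
        n_mal <- round(rho[i] * m)
        comp <- sample(rep(c(1L, 0L), c(n_mal, m - n_mal)))
      } else {
        comp <- rep(0L, m)
      }
      p <- numeric(m)
      p[comp == 0L] <- stats::rbeta(sum(comp == 0L), a0, b0)
      p[comp == 1L] <- stats::rbeta(sum(comp == 1L), a1, b1)
      bags[[i]] <- likelihood_bag(names(labels)[i], p)
      components[[i]] <- comp
    }
    list(bags = bags, labels = labels, rho = rho,
         components = components)
  })
}

#' Generate planted-signal multiple-instance feature bags
#'
#' Negative bags hold i.i.d. standard Gaussian instances in `dim`
#' dimensions; positive bags replace a `witness_rate` fraction of
#' instances with witnesses whose mean is shifted by `signal_shift`
#' along the first coordinate axis.  The mean-pooled embedding of a
#' positive bag is therefore displaced by `signal_shift * witness_rate`
#' along that axis -- the closed-form separation the MIL head must
#' recover.
#'
#' @param n_bags Total number of bags (half positive by rounding).
#' @param n_instances Instances per bag.
#' @param dim Instance dimension (default 768, the ViT-style contract).
#' @param signal_shift Mean shift of witness instances (0 = null case).
#' @param witness_rate Fraction of instances that are witnesses in a
#'   positive bag; must be in (0, 1].
#' @param seed Integer seed.
#' @return List with `bags` (list of [feature_bag()]), `labels` (named
#'   0/1 vector) and `witness` (per-bag logical vector marking witness
#'   instances).
#' @export
simulate_feature_bags <- function(n_bags, n_instances, dim = 768L,
                                  signal_shift = 3, witness_rate = 0.3,
                                  seed = 1L) {
  if (dim < 1) stop_config("dim must be >= 1")
  if (!(witness_rate > 0 && witness_rate <= 1)) {
    stop_config("witness_rate must lie in (0, 1]")
  }
  with_seed(seed, {
    n_pos <- round(n_bags / 2)
    labels <- sample(rep(c(1L, 0L), c(n_pos, n_bags - n_pos)))
    names(labels) <- sprintf("bag_%03d", seq_len(n_bags))
    bags <- vector("list", n_bags)
    witness <- vector("list", n_bags)
    for (i in seq_len(n_bags)) {
      x <- matrix(stats::rnorm(n_instances * dim), n_instances, dim)
      w <- rep(FALSE, n_instances)
      if (labels[i] == 1L) {
        n_wit <- max(1L, round(witness_rate * n_instances))
        w[sample.int(n_instances, n_wit)] <- TRUE
        x[w, 1L] <- x[w, 1L] + signal_shift
      }
      bags[[i]] <- feature_bag(names(labels)[i], x)
      witness[[i]] <- w
    }
    list(bags = bags, labels = labels, witness = witness)
  })
}
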