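# Stain normalization by sparse stain separation, in the style of
# Vahadane et al.'s sparse non-negative matrix factorization: RGB is
# mapped to optical density (Beer-Lambert), factored into a 3 x 2
# non-negative stain basis W times non-negative concentrations H with an
# L1 penalty on H, and a source image is re-rendered with a target
# image's basis after robust concentration rescaling.

CANONICAL_HE <- cbind(hematoxylin = c(0.650, 0.704, 0.286),
                      eosin       = c(0.072, 0.990, 0.105))

#' RGB to optical density (Beer-Lambert transform)
#'
#' @param pixels Intensities on the 0..`I0` scale (values in \[0,1\]
#'   are interpreted as fractions of `I0`); zeros are clipped to 1
#'   before the log.
#' @param I0 Background (white) intensity, default 255.
#' @return Optical densities, same shape: `-log(I / I0)`, >= 0.
#' @export
rgb_to_od <- function(pixels, I0 = 255) {
  p <- pixels
  if (max(p) <= 1) p <- p * I0
  p <- pmin(pmax(p, 1), I0)
  -log(p / I0)
}

#' Optical density back to RGB intensity
#'
#' @param od Non-negative optical densities.
#' @param I0 Background intensity.
#' @return Intensities in `[0, I0]`.
#' @export
od_to_rgb <- function(od, I0 = 255) {
  pmin(pmax(I0 * exp(-od), 0), I0)
}

# image (H x W x 3, [0,1] or 0..255) -> 3 x n OD matrix
image_to_od_matrix <- function(image, I0 = 255) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop_input("image must be H x W x 3")
  od <- rgb_to_od(image, I0)
  t(matrix(od, ncol = 3L))
}

# exact per-pixel 2-stain non-negative least squares with fixed basis:
# unconstrained normal-equation solve, then clamp-and-resolve (valid for
# two variables)
stain_concentrations <- function(od, W) {
  A <- crossprod(W)            # 2 x 2
  b <- crossprod(W, od)        # 2 x n
  det_a <- A[1, 1] * A[2, 2] - A[1, 2]^2
  h1 <- (A[2, 2] * b[1, ] - A[1, 2] * b[2, ]) / det_a
  h2 <- (A[1, 1] * b[2, ] - A[1, 2] * b[1, ]) / det_a
  neg1 <- h1 < 0; neg2 <- h2 < 0
  h1[neg1] <- 0
  h2[neg1] <- pmax(b[2, neg1] / A[2, 2], 0)
  h2[neg2 & !neg1] <- 0
  h1[neg2 & !neg1] <- pmax(b[1, neg2 & !neg1] / A[1, 1], 0)
  rbind(h1, h2)
}

#' Fit a two-stain model by sparse non-negative factorization
#'
#' Factorizes the optical-density matrix of the image's tissue pixels
#' as `V ~ W H` with `W >= 0` (3 x 2, unit-norm columns) and `H >= 0`,
#' penalizing `lambda * sum(H)` to encourage each pixel to load on few
#' stains.  Solved by multiplicative updates from a deterministic
#' perturbation of canonical hematoxylin/eosin vectors; columns are
#' ordered so the first stain is the one most aligned with canonical
#' hematoxylin.
#'
#' @param image H x W x 3 array.
#' @param sparsity_lambda L1 weight on concentrations (default 0.1).
#' @param od_floor Pixels whose OD norm is below this are background and
#'   excluded from fitting (default 0.15).
#' @param I0 Background intensity (default 255).
#' @param max_iter,tol Update budget and relative-objective stopping
#'   tolerance (defaults 200 and 1e-4).
#' @param seed Seed for the deterministic initialization jitter.
#' @return Object of class `stain_model`: `W` (3 x 2), `conc_scale`
#'   (99th-percentile concentration per stain), `I0`, `lambda`.
#' @export
fit_stain_model <- function(image, sparsity_lambda = 0.1,
                            od_floor = 0.15, I0 = 255,
                            max_iter = 200L, tol = 1e-4, seed = 1L) {
  V <- image_to_od_matrix(image, I0)
  keep <- sqrt(colSums(V^2)) > od_floor
  V <- V[, keep, drop = FALSE]
  n_stains <- 2L
  if (ncol(V) < n_stains * 50L) {
    stop_input("too few tissue pixels above the OD floor to fit stains")
  }
  sv <- svd(V, nu = 0, nv = 0)$d
  if (sv[2] / sv[1] < 0.02) {
    warning("degenerate stain basis: optical density is numerically ",
            "rank one (monochrome input?); the second stain is ",
            "unidentifiable")
  }
  W <- with_seed(seed, {
    CANONICAL_HE * matrix(stats::runif(6, 0.9, 1.1), 3L)
  })
  W <- sweep(W, 2L, sqrt(colSums(W^2)), `/`)
  H <- pmax(stain_concentrations(V, W), 1e-8)
  eps <- 1e-10
  obj_prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H +
                                    sparsity_lambda + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    nrm <- sqrt(colSums(W^2))
    W <- sweep(W, 2L, nrm, `/`)
    H <- H * nrm
    obj <- sum((V - W %*% H)^2) + sparsity_lambda * sum(H)
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) < tol * max(obj_prev, eps)) break
    obj_prev <- obj
  }
  cos_sim <- abs(crossprod(W, CANONICAL_HE))
  if (abs(sum(W[, 1] * W[, 2])) > 0.999) {
    warning("degenerate stain basis: the two stain vectors coincide")
  }
  if (cos_sim[2, 1] > cos_sim[1, 1]) W <- W[, 2:1, drop = FALSE]
  H <- stain_concentrations(V, W)
  conc_scale <- as.numeric(apply(H, 1L, stats::quantile, probs = 0.99,
                                 names = FALSE))
  conc_scale <- pmax(conc_scale, 1e-6)
  structure(list(W = unname(W), conc_scale = conc_scale, I0 = I0,
                 lambda = sparsity_lambda),
            class = "stain_model")
}

#' @export
print.stain_model <- function(x, ...) {
  cat("<stain_model> basis (columns = stains):\n")
  print(round(x$W, 3))
  cat("conc_scale:", round(x$conc_scale, 3), "\n")
  invisible(x)
}

#' Map a source image's stains onto a target stain model
#'
#' Decomposes the image against the source basis, rescales each stain's
#' concentrations by the ratio of target to source robust maxima, and
#' re-renders with the target basis.  Pure-background images (no pixel
#' above the OD floor) are returned unchanged.
#'
#' @param image H x W x 3 array in \[0,1\] (or 0..255; returned on the
#'   input scale).
#' @param source,target Fitted [fit_stain_model()] objects.
#' @param od_floor Background detection floor.
#' @return Normalized image, same shape and scale as the input.
#' @export
normalize_stains <- function(image, source, target, od_floor = 0.15) {
  stopifnot(inherits(source, "stain_model"),
            inherits(target, "stain_model"))
  if (ncol(source$W) != ncol(target$W)) {
    stop_input("source and target models use different stain counts")
  }
  scale01 <- max(image) <= 1
  V <- image_to_od_matrix(image, source$I0)
  if (!any(sqrt(colSums(V^2)) > od_floor)) return(image)
  H <- stain_concentrations(V, source$W)
  H <- H * (target$conc_scale / source$conc_scale)
  od_new <- target$W %*% H
  out <- od_to_rgb(od_new, target$I0)
  out <- array(t(out), dim = dim(image))
  if (scale01) out / target$I0 else out
}

#' Serialize / deserialize a stain model as JSON
#'
#' @param model A `stain_model`.
#' @param path File path.
#' @return `read_stain_model()` returns the model; `write_stain_model()`
#'   its path, invisibly.
#' @export
write_stain_model <- function(model, path) {
  stopifnot(inherits(model, "stain_model"))
  jsonlite::write_json(list(W = model$W, conc_scale = model$conc_scale,
                            I0 = model$I0, lambda = model$lambda),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stain_model
#' @export
read_stain_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(W = matrix(unlist(x$W), nrow = 3L),
                 conc_scale = as.numeric(x$conc_scale),
                 I0 = as.numeric(x$I0), lambda = as.numeric(x$lambda)),
            class = "stain_model")
}
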