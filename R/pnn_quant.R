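# Perineuronal-net quantification: top-half maximum-intensity projection,
# IsoData ("Default") binarization within a traced ROI, largest-connected-
# component surface contiguity, and density per mm^2.

#' Construct a calibrated image stack
#'
#' @param voxels 3D numeric array indexed `[y, x, z]`.
#' @param um_per_px lateral pixel size (micrometres).
#' @param z_step_um z-step between planes (micrometres); default 0.37.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(voxels, um_per_px, z_step_um = 0.37) {
  if (length(dim(voxels)) != 3L || any(dim(voxels) < 1L)) {
    stop("image_stack: voxels must be a non-empty 3D array", call. = FALSE)
  }
  check_positive_scalar(um_per_px, "um_per_px")
  check_positive_scalar(z_step_um, "z_step_um")
  structure(list(voxels = voxels, um_per_px = um_per_px, z_step_um = z_step_um),
            class = "image_stack")
}

#' Maximum-intensity projection over the top half of a stack
#'
#' Projects planes `1 .. ceiling(Z/2)` (plane 1 = top). Restricting the
#' projection to the top half of each net avoids out-of-focus signal from
#' the far surface dominating the projected ring.
#'
#' @param stack an [image_stack()].
#' @return 2D numeric matrix (a single-plane stack is returned unchanged
#'   with a warning).
#' @export
project_top_half <- function(stack) {
  d <- dim(stack$voxels)
  if (d[3] == 1L) {
    warning("project_top_half: single-plane stack returned unchanged")
    return(stack$voxels[, , 1])
  }
  planes <- seq_len(ceiling(d[3] / 2))
  out <- stack$voxels[, , planes[1]]
  for (z in planes[-1]) out <- pmax(out, stack$voxels[, , z])
  out
}

#' IsoData (iterative intermeans) threshold
#'
#' The classic iterative scheme behind FIJI's "Default" method: starting
#' from the mid-range, the threshold is repeatedly set to the average of the
#' mean intensity below and the mean above it until it stabilizes.
#'
#' @param values numeric vector of intensities.
#' @return the threshold; pixels strictly above it are foreground.
#' @export
isodata_threshold <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L || max(values) == min(values)) {
    stop("isodata_threshold: uniform or empty intensity set", call. = FALSE)
  }
  t <- mean(range(values))
  for (iter in 1:200) {
    lo <- values[values <= t]
    hi <- values[values > t]
    if (!length(hi) || !length(lo)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < 1e-9) break
    t <- t_new
  }
  t
}

# Otsu's method on a 256-bin histogram; alternative to IsoData.
otsu_threshold <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L || max(values) == min(values)) {
    stop("otsu_threshold: uniform or empty intensity set", call. = FALSE)
  }
  breaks <- seq(min(values), max(values), length.out = 257)
  h <- tabulate(findInterval(values, breaks, all.inside = TRUE), nbins = 256)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# Logical matrix marking pixels whose centers fall inside a polygon
# (even-odd ray casting; vertices given as columns x, y in pixel units).
in_polygon_mask <- function(ny, nx, poly) {
  px <- poly[, 1]
  py <- poly[, 2]
  n <- length(px)
  xs <- rep(seq_len(nx), each = ny)
  ys <- rep(seq_len(ny), times = nx)
  inside <- rep(FALSE, length(xs))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > ys) != (py[j] > ys)) &
      (xs < (px[j] - px[i]) * (ys - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, ny, nx)
}

#' Construct a binary PNN mask
#'
#' @param mask logical matrix (TRUE = WFA-positive pixel).
#' @param roi_outline optional polygon (matrix of x, y columns) of the
#'   traced net.
#' @param threshold_value intensity threshold that produced the mask.
#' @return object of class `pnn_mask`.
#' @export
pnn_mask <- function(mask, roi_outline = NULL, threshold_value = NA_real_) {
  if (!is.matrix(mask)) stop("pnn_mask: mask must be a matrix", call. = FALSE)
  structure(list(mask = mask != 0, roi_outline = roi_outline,
                 threshold_value = threshold_value),
            class = "pnn_mask")
}

#' Binarize WFA signal with default (IsoData) thresholding
#'
#' Computes the threshold from the intensities inside the traced ROI (so a
#' large dark background cannot drag the threshold down) and marks
#' above-threshold pixels inside the ROI as foreground; everything outside
#' the ROI is background.
#'
#' @param image 2D numeric matrix (typically a [project_top_half()] result).
#' @param roi optional polygon (matrix with columns x, y, pixel units);
#'   `NULL` uses the whole image.
#' @param method `"isodata"` (FIJI's "Default") or `"otsu"`.
#' @return a [pnn_mask()].
#' @export
binarize_default <- function(image, roi = NULL, method = c("isodata", "otsu")) {
  method <- match.arg(method)
  inroi <- if (is.null(roi)) matrix(TRUE, nrow(image), ncol(image)) else
    in_polygon_mask(nrow(image), ncol(image), roi)
  vals <- image[inroi]
  if (length(vals) == 0L) stop("binarize_default: ROI contains no pixels", call. = FALSE)
  if (max(vals) == min(vals)) {
    stop("binarize_default: uniform-intensity ROI, cannot threshold", call. = FALSE)
  }
  thr <- if (method == "isodata") isodata_threshold(vals) else otsu_threshold(vals)
  pnn_mask(inroi & image > thr, roi_outline = roi, threshold_value = thr)
}

# Connected-component labelling by breadth-first search.
label_components <- function(mask, connectivity = 8) {
  ny <- nrow(mask)
  nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  offs <- if (connectivity == 8) {
    cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1), dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dy = c(-1, 1, 0, 0), dx = c(0, 0, -1, 1))
  }
  cur <- 0L
  fg <- which(mask)
  queue <- integer(length(fg))
  for (start in fg) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    head <- 1L
    tail <- 1L
    queue[1L] <- start
    while (head <= tail) {
      p <- queue[head]
      head <- head + 1L
      y <- ((p - 1L) %% ny) + 1L
      x <- ((p - 1L) %/% ny) + 1L
      for (k in seq_len(nrow(offs))) {
        yy <- y + offs[k, 1L]
        xx <- x + offs[k, 2L]
        if (yy >= 1L && yy <= ny && xx >= 1L && xx <= nx) {
          q <- (xx - 1L) * ny + yy
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            tail <- tail + 1L
            queue[tail] <- q
          }
        }
      }
    }
  }
  lab
}

#' Surface contiguity of a binarized PNN
#'
#' Fraction of the WFA-positive pixels that reside within the largest
#' connected component of the mask. A fully intact net surface scores 1;
#' fragmentation into disconnected arcs lowers the score.
#'
#' @param mask a [pnn_mask()] (or logical matrix) with at least one
#'   foreground pixel.
#' @param connectivity 8 (default; diagonally touching arcs connect) or 4.
#' @return object of class `contiguity_result`: `fraction`, `n_components`,
#'   `largest_component_px`, `total_px`.
#' @export
contiguity <- function(mask, connectivity = 8) {
  m <- if (inherits(mask, "pnn_mask")) mask$mask else mask != 0
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  total <- sum(m)
  if (total == 0L) stop("contiguity: empty mask", call. = FALSE)
  lab <- label_components(m, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  structure(list(fraction = max(sizes) / total,
                 n_components = length(sizes),
                 largest_component_px = max(sizes),
                 total_px = total),
            class = "contiguity_result")
}

#' Perineuronal-net density
#'
#' @param cell_count number of counted nets.
#' @param area_mm2 traced region area in mm^2 (must be positive).
#' @return object of class `density_result`: `cell_count`, `area_mm2`,
#'   `density` (cells per mm^2).
#' @export
pnn_density <- function(cell_count, area_mm2) {
  if (!is.numeric(area_mm2) || length(area_mm2) != 1L || !is.finite(area_mm2) ||
      area_mm2 <= 0) {
    stop("pnn_density: area_mm2 must be positive", call. = FALSE)
  }
  check_nonneg_scalar(cell_count, "cell_count")
  structure(list(cell_count = cell_count, area_mm2 = area_mm2,
                 density = cell_count / area_mm2),
            class = "density_result")
}

#' Area of a traced polygon in mm^2
#'
#' Shoelace formula on pixel coordinates, converted with the pixel size.
#'
#' @param poly polygon matrix with columns x, y (pixel units).
#' @param um_per_px pixel size (micrometres).
#' @return area in mm^2.
#' @export
polygon_area_mm2 <- function(poly, um_per_px) {
  x <- poly[, 1]
  y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  area_px2 <- abs(sum(x[j] * y - x * y[j])) / 2
  area_px2 * um_per_px^2 / 1e6
}
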