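#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer replace_na
#' @importFrom purrr map map_dfr map2 pmap imap list_rbind
NULL

# Deterministic 31-bit child seed from a master seed plus arbitrary key parts.
# Counter-based splitting so any (plate, well, site) regenerates identically
# regardless of iteration order. Plain polynomial string hash; R integers are
# 32-bit so everything is kept below 2^31 - 1.
derive_seed <- function(master, ...) {
  key <- paste(c(format(master, scientific = FALSE), ...), collapse = "/")
  bytes <- utf8ToInt(key)
  h <- as.double(master %% 2147483647L)
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Run code under a temporary RNG state; restores .Random.seed afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Linear indices and values of a patch placed at (cy, cx) in an h x w image,
# clipped at the borders. The caller accumulates `img[idx] <- img[idx] + vals`
# in its own frame so the image matrix is modified in place (no full copy).
patch_at <- function(patch, cy, cx, h, w) {
  ph <- nrow(patch); pw <- ncol(patch)
  ry <- round(cy) - (ph - 1L) %/% 2L; rx <- round(cx) - (pw - 1L) %/% 2L
  y0 <- max(1L, ry); y1 <- min(h, ry + ph - 1L)
  x0 <- max(1L, rx); x1 <- min(w, rx + pw - 1L)
  if (y0 > y1 || x0 > x1) return(list(idx = integer(0), vals = double(0)))
  ys <- y0:y1; xs <- x0:x1
  idx <- rep((xs - 1L) * h, each = length(ys)) + ys
  vals <- patch[(y0 - ry + 1L):(y1 - ry + 1L), (x0 - rx + 1L):(x1 - rx + 1L)]
  list(idx = idx, vals = as.vector(vals))
}

# 2-D Gaussian patch with given sigma and peak amplitude.
gaussian_patch <- function(sigma, amplitude, radius = ceiling(4 * sigma)) {
  ax <- seq(-radius, radius)
  g <- exp(-ax^2 / (2 * sigma^2))
  amplitude * outer(g, g)
}

# Soft-edged ellipse: amplitude inside, sigmoid roll-off of width edge px.
ellipse_patch <- function(ry, rx, theta, amplitude, edge = 1) {
  r <- ceiling(max(ry, rx) + 4 * edge)
  ax <- seq(-r, r)
  yy <- matrix(ax, length(ax), length(ax))
  xx <- t(yy)
  u <- yy * cos(theta) - xx * sin(theta)
  v <- yy * sin(theta) + xx * cos(theta)
  d <- sqrt((u / ry)^2 + (v / rx)^2)
  # distance-to-boundary in approximate pixel units
  amplitude / (1 + exp((d - 1) * max(ry, rx) / edge))
}

# Soft-edged disk.
disk_patch <- function(radius, amplitude, edge = 1) {
  ellipse_patch(radius, radius, 0, amplitude, edge)
}

as_matrix <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  as.matrix(x)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}
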