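#' Parameters of the synthetic chromatin intensity generator
#'
#' @param correlation_length spatial correlation scale of the field, um.
#'   Default 0.15 um, on the order of chromatin domain foci resolved by
#'   structured-illumination imaging of a ~1 um nuclear region.
#' @param contrast standard deviation of the log-intensity (dynamic
#'   range); 0 gives a uniform field.
#' @param blocked_fraction_target fraction of voxels pinned to the grid
#'   maximum (within 1% of max), forming fully blocked heterochromatin-like
#'   foci after normalisation.
#' @param seed integer RNG seed.
#' @return Object of class `field_params`.
#' @export
field_params <- function(correlation_length = 0.15, contrast = 1.5,
                         blocked_fraction_target = 0.002, seed = 1L) {
  if (correlation_length <= 0)
    stop("`correlation_length` must be positive", call. = FALSE)
  if (contrast < 0) stop("`contrast` must be >= 0", call. = FALSE)
  if (blocked_fraction_target < 0 || blocked_fraction_target >= 1)
    stop("`blocked_fraction_target` must be in [0, 1)", call. = FALSE)
  structure(list(correlation_length = correlation_length,
                 contrast = contrast,
                 blocked_fraction_target = blocked_fraction_target,
                 seed = as.integer(seed)),
            class = "field_params")
}

# per-axis discrete FFT frequencies (cycles per sample)
fft_freqs <- function(n) {
  j <- 0:(n - 1)
  ifelse(j <= n %/% 2, j, j - n) / n
}

#' Generate a DAPI-like synthetic chromatin intensity grid
#'
#' Smoothed log-normal noise: white Gaussian noise on the lattice is
#' low-pass filtered in Fourier space with a Gaussian kernel of physical
#' scale `correlation_length`, standardised, and exponentiated with the
#' requested log-contrast.  The result is a non-negative field with
#' spatial autocorrelation decaying at the correlation scale and a
#' heavy-tailed intensity distribution (a few dense foci over a sparse
#' background), qualitatively emulating a voxelised DAPI stack.
#' Optionally the top `blocked_fraction_target` of voxels is pinned to the
#' maximum so the normalised field contains fully blocked voxels.
#' Deterministic given the seed; the global RNG state is left untouched.
#'
#' @param lattice a `lattice_spec`.
#' @param params a `field_params`.
#' @return Numeric array of dim `c(nx, ny, nz)` with non-negative
#'   intensities (feed to [normalize_chromatin()]).
#' @export
generate_field <- function(lattice, params = field_params()) {
  stopifnot(inherits(lattice, "lattice_spec"),
            inherits(params, "field_params"))
  nx <- lattice$nx; ny <- lattice$ny; nz <- lattice$nz
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(params$seed)
  z <- array(stats::rnorm(lattice$N), dim = c(nx, ny, nz))
  if (params$contrast == 0)
    return(array(1, dim = c(nx, ny, nz)))
  # Gaussian low-pass with per-axis physical frequencies (1/um)
  kx <- 2 * pi * fft_freqs(nx) / lattice$hx
  ky <- 2 * pi * fft_freqs(ny) / lattice$hy
  kz <- 2 * pi * fft_freqs(nz) / lattice$hz
  k2 <- outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  filt <- exp(-0.5 * params$correlation_length^2 * k2)
  zs <- Re(stats::fft(stats::fft(z) * filt, inverse = TRUE)) / lattice$N
  sdz <- stats::sd(as.numeric(zs))
  if (sdz > 0) zs <- (zs - mean(zs)) / sdz
  v <- exp(params$contrast * zs)
  if (params$blocked_fraction_target > 0) {
    thr <- stats::quantile(v, 1 - params$blocked_fraction_target,
                           names = FALSE)
    v[v >= thr] <- max(v)
  }
  v
}

# map input index r (1..n_in) onto output bins 1..n_out by footprint;
# returns per-input bin assignment
pool_bins <- function(n_in, n_out) {
  pmin(n_out, 1L + floor((seq_len(n_in) - 1L) * n_out / n_in))
}

# mean-pool one 2D plane onto nx x ny (ImageJ-style region mean); if the
# input is coarser than the output along an axis, nearest-index sampling
# fills the extra bins
pool_plane <- function(plane, nx, ny) {
  n_in_x <- nrow(plane); n_in_y <- ncol(plane)
  if (n_in_x >= nx) {
    bx <- pool_bins(n_in_x, nx)
    plane <- apply(plane, 2, function(col) tapply(col, bx, mean))
    if (nx == 1L) plane <- matrix(plane, nrow = 1L)
  } else {
    src <- pmin(n_in_x, pmax(1L, round((seq_len(nx) - 0.5) * n_in_x / nx + 0.5)))
    plane <- plane[src, , drop = FALSE]
  }
  if (n_in_y >= ny) {
    by <- pool_bins(n_in_y, ny)
    plane <- t(apply(plane, 1, function(row) tapply(row, by, mean)))
    if (ny == 1L) plane <- matrix(plane, ncol = 1L)
  } else {
    src <- pmin(n_in_y, pmax(1L, round((seq_len(ny) - 0.5) * n_in_y / ny + 0.5)))
    plane <- plane[, src, drop = FALSE]
  }
  plane
}

#' Import a chromatin intensity stack from CSV plane files
#'
#' Reads one comma-separated intensity matrix per z-plane, mean-pools each
#' plane onto the `nx x ny` in-plane mesh, and maps the planes onto the
#' `nz` lattice layers by nearest index (duplicating planes when the
#' lattice has more layers than the stack, e.g. 9 imaging planes onto 11
#' layers).  Values must be non-negative; the absolute intensity scale is
#' irrelevant after [normalize_chromatin()].
#'
#' TIFF stacks are not read directly (no TIFF reader in the supported
#' dependency set); convert stacks to per-plane CSV first.
#'
#' @param paths character vector of CSV file paths, one per z-plane, in
#'   z order.  Each file holds a numeric matrix, no header.
#' @param lattice a `lattice_spec`.
#' @return Numeric array of dim `c(nx, ny, nz)` (feed to
#'   [normalize_chromatin()]).
#' @export
import_intensity_stack <- function(paths, lattice) {
  stopifnot(inherits(lattice, "lattice_spec"))
  if (length(paths) == 0L) stop("no input planes given", call. = FALSE)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("unreadable input plane(s): ", paste(paths[missing], collapse = ", "),
         call. = FALSE)
  planes <- lapply(paths, function(p) {
    m <- as.matrix(utils::read.csv(p, header = FALSE))
    storage.mode(m) <- "double"
    if (any(!is.finite(m)) || any(m < 0))
      stop("negative or non-finite intensity in ", p, call. = FALSE)
    pool_plane(m, lattice$nx, lattice$ny)
  })
  np <- length(planes)
  src_z <- pmin(np, pmax(1L, round((seq_len(lattice$nz) - 0.5) * np /
                                     lattice$nz + 0.5)))
  out <- array(0, dim = c(lattice$nx, lattice$ny, lattice$nz))
  for (k in seq_len(lattice$nz)) out[, , k] <- planes[[src_z[k]]]
  out
}
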