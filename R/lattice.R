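#' Build a Cartesian voxel lattice
#'
#' Discretises a rectangular box into `nx * ny * nz` uniform voxels.  The
#' default geometry is the 50 x 50 x 11 mesh over a 1 um cube used for the
#' nuclear simulation domain; note that with these defaults the voxels are
#' anisotropic (`hz != hx`), and all per-axis jump rates use the per-axis
#' voxel edge length.
#'
#' Voxels are addressed by a single 1-based linear index with the x axis
#' fastest, i.e. `i = x + nx * (y - 1 + ny * (z - 1))`.
#'
#' @param dims integer vector of length 3: voxel counts `(nx, ny, nz)`.
#' @param box numeric vector of length 3: box edge lengths in um.
#' @return An object of class `lattice_spec`: a list with `nx, ny, nz`,
#'   `Lx, Ly, Lz`, per-axis voxel edges `hx, hy, hz` (um) and the total
#'   voxel count `N`.
#' @examples
#' lat <- build_lattice(c(50, 50, 11), c(1, 1, 1))
#' lat$hx  # 0.02 um
#' lat$N   # 27500
#' @export
build_lattice <- function(dims = c(50L, 50L, 11L), box = c(1, 1, 1)) {
  if (length(dims) != 3L || any(!is.finite(dims)) || any(dims < 1) ||
      any(dims != round(dims)))
    stop("`dims` must be three positive integers", call. = FALSE)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("`box` must be three positive lengths (um)", call. = FALSE)
  dims <- as.integer(dims)
  h <- box / dims
  structure(list(
    nx = dims[1L], ny = dims[2L], nz = dims[3L],
    Lx = box[1L], Ly = box[2L], Lz = box[3L],
    hx = h[1L], hy = h[2L], hz = h[3L],
    N = as.integer(prod(dims))
  ), class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec> %d x %d x %d voxels over %g x %g x %g um (N = %d)\n",
              x$nx, x$ny, x$nz, x$Lx, x$Ly, x$Lz, x$N))
  cat(sprintf("  voxel edges: hx = %g, hy = %g, hz = %g um\n", x$hx, x$hy, x$hz))
  invisible(x)
}

# linear index <-> (x, y, z), all 1-based
voxel_index <- function(lattice, x, y, z) {
  x + lattice$nx * (y - 1L + lattice$ny * (z - 1L))
}

voxel_coords <- function(lattice, i) {
  i0 <- i - 1L
  x <- i0 %% lattice$nx
  y <- (i0 %/% lattice$nx) %% lattice$ny
  z <- i0 %/% (lattice$nx * lattice$ny)
  cbind(x = x + 1L, y = y + 1L, z = z + 1L)
}

# 6-neighbourhood with reflective boundaries: absent neighbours are NA
voxel_neighbors <- function(lattice, i) {
  co <- voxel_coords(lattice, i)
  x <- co[1L, "x"]; y <- co[1L, "y"]; z <- co[1L, "z"]
  nb <- c(
    "-x" = if (x > 1L)          voxel_index(lattice, x - 1L, y, z) else NA_integer_,
    "+x" = if (x < lattice$nx)  voxel_index(lattice, x + 1L, y, z) else NA_integer_,
    "-y" = if (y > 1L)          voxel_index(lattice, x, y - 1L, z) else NA_integer_,
    "+y" = if (y < lattice$ny)  voxel_index(lattice, x, y + 1L, z) else NA_integer_,
    "-z" = if (z > 1L)          voxel_index(lattice, x, y, z - 1L) else NA_integer_,
    "+z" = if (z < lattice$nz)  voxel_index(lattice, x, y, z + 1L) else NA_integer_
  )
  nb
}

#' Normalise a chromatin intensity grid to per-voxel densities
#'
#' Converts a non-negative stain-intensity grid (e.g. voxelised DAPI
#' intensities) into the dimensionless per-voxel chromatin density
#' `c_i = I_i / max_j I_j`.  The voxel(s) carrying the maximal intensity
#' have density 1 and are fully blocked to transcription-factor diffusion;
#' ties at the maximum are allowed.  The field is static: chromatin does
#' not diffuse or remodel during a simulation.
#'
#' @param intensity numeric vector or array of non-negative intensities,
#'   one value per voxel.
#' @param lattice a `lattice_spec`; the grid must have `lattice$N` values
#'   (an array must have dim `c(nx, ny, nz)`).
#' @return An object of class `chromatin_field`: list with numeric `c`
#'   (length `N`, values in `[0, 1]`) and the `lattice`.
#' @export
normalize_chromatin <- function(intensity, lattice) {
  if (!inherits(lattice, "lattice_spec"))
    stop("`lattice` must be a lattice_spec", call. = FALSE)
  if (is.array(intensity)) {
    d <- dim(intensity)
    if (length(d) == 2L) d <- c(d, 1L)
    if (!identical(as.integer(d), c(lattice$nx, lattice$ny, lattice$nz)))
      stop("intensity grid shape does not match the lattice", call. = FALSE)
    intensity <- as.numeric(intensity)
  }
  intensity <- as.numeric(intensity)
  if (length(intensity) != lattice$N)
    stop("intensity grid shape does not match the lattice", call. = FALSE)
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and non-negative", call. = FALSE)
  mx <- max(intensity)
  cc <- if (mx > 0) intensity / mx else intensity  # all-zero grid -> c = 0
  structure(list(c = cc, lattice = lattice), class = "chromatin_field")
}

#' Uniform (empty) chromatin field
#'
#' Convenience constructor for the crowding-free limit `c_i = 0`.
#' @param lattice a `lattice_spec`.
#' @return A `chromatin_field` with zero density everywhere.
#' @export
empty_chromatin <- function(lattice) {
  structure(list(c = numeric(lattice$N), lattice = lattice),
            class = "chromatin_field")
}

#' Crowding configuration
#'
#' @param theta occupancy probability in `[0, 1]`: each voxel independently
#'   holds one artificial crowding agent with probability `theta`.
#' @param size_class `"big"` (diffusion factor delta = 0.1, i.e. 90%
#'   reduction) or `"small"` (delta = 0.6, 40% reduction).
#' @param seed integer RNG seed for the placement.
#' @return An object of class `crowding_config`.
#' @export
crowding_config <- function(theta = 0, size_class = c("big", "small"),
                            seed = 1L) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta < 0 || theta > 1)
    stop("`theta` must be a single value in [0, 1]", call. = FALSE)
  size_class <- match.arg(size_class)
  structure(list(theta = theta, size_class = size_class,
                 seed = as.integer(seed)),
            class = "crowding_config")
}

# diffusion attenuation factors per crowder size class
crowder_delta <- c(empty = 1, small = 0.6, big = 0.1)

#' Place artificial crowding agents on the lattice
#'
#' Each voxel is independently occupied by a single crowding agent of the
#' configured size class with probability `theta` (Bernoulli placement; the
#' expected occupied count is `theta * N`).  The placement is static for
#' the whole simulation and deterministic given the configuration seed.
#'
#' @param lattice a `lattice_spec`.
#' @param cfg a `crowding_config`.
#' @return An object of class `crowder_field`: list with character
#'   `occupancy` (per voxel, one of `"empty"`, `"small"`, `"big"`), numeric
#'   `delta` (1, 0.6 or 0.1), plus `theta`, `size_class`, `seed`.
#' @export
place_crowders <- function(lattice, cfg = crowding_config()) {
  if (!inherits(lattice, "lattice_spec"))
    stop("`lattice` must be a lattice_spec", call. = FALSE)
  if (!inherits(cfg, "crowding_config"))
    stop("`cfg` must be a crowding_config", call. = FALSE)
  occ <- rep("empty", lattice$N)
  if (cfg$theta > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(cfg$seed)
    hit <- stats::runif(lattice$N) < cfg$theta
    occ[hit] <- cfg$size_class
  }
  structure(list(
    occupancy = occ,
    delta = unname(crowder_delta[occ]),
    theta = cfg$theta, size_class = cfg$size_class, seed = cfg$seed,
    lattice = lattice
  ), class = "crowder_field")
}

#' Empty crowder field (theta = 0)
#' @param lattice a `lattice_spec`.
#' @return A `crowder_field` with every voxel empty (`delta = 1`).
#' @export
empty_crowders <- function(lattice) {
  structure(list(occupancy = rep("empty", lattice$N),
                 delta = rep(1, lattice$N),
                 theta = 0, size_class = "big", seed = NA_integer_,
                 lattice = lattice),
            class = "crowder_field")
}

#' Crowding-attenuated diffusion jump rate into a voxel
#'
#' Mesoscopic rate (per minute) for a molecule with free diffusion
#' coefficient `D0` to hop into `dest_voxel` along `axis`:
#' `D0 * (1 - c_dest) * delta_dest / h_axis^2`.  The attenuation depends
#' only on the destination voxel's chromatin density and crowder occupancy
#' (origin-voxel crowding and lock-in effects are deliberately ignored).
#' A destination with `c = 1` is fully blocked (rate 0).
#'
#' @param lattice a `lattice_spec`.
#' @param chromatin a `chromatin_field`.
#' @param crowders a `crowder_field`.
#' @param D0 free diffusion coefficient, um^2 min^-1.
#' @param dest_voxel destination voxel linear index (1-based).
#' @param axis `"x"`, `"y"` or `"z"` (selects the voxel edge length).
#' @return Jump rate in min^-1.
#' @export
jump_rate <- function(lattice, chromatin, crowders, D0, dest_voxel,
                      axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  if (dest_voxel < 1L || dest_voxel > lattice$N)
    stop("`dest_voxel` out of lattice bounds", call. = FALSE)
  h <- switch(axis, x = lattice$hx, y = lattice$hy, z = lattice$hz)
  D0 * (1 - chromatin$c[dest_voxel]) * crowders$delta[dest_voxel] / h^2
}

#' Effective diffusion ratio of a crowder field
#'
#' The voxel-average attenuation `D*/D = sum_i delta_i / N`: multiplying a
#' free diffusion coefficient `D` by this factor gives the effective
#' coefficient `D*` under the artificial crowding agents alone.
#'
#' @param crowders a `crowder_field`.
#' @return Dimensionless factor in `[0.1, 1]`.
#' @export
effective_diffusion_ratio <- function(crowders) {
  if (!inherits(crowders, "crowder_field"))
    stop("`crowders` must be a crowder_field", call. = FALSE)
  sum(crowders$delta) / length(crowders$delta)
}

#' Select a gene voxel by local chromatin-density regime
#'
#' Places the gene in a super-dense, dense or sparse chromatin area.
#' Regimes are quantile bands of the chromatin density over the eligible
#' voxels (those with `c < 1`; a fully blocked voxel can never be reached
#' by the transcription factor and is always excluded):
#' sparse = quantiles `[0, 0.2)`, dense = `[0.5, 0.8)`, super-dense =
#' `[0.8, 1]`.  Within the band the voxel whose density is closest to the
#' band's midpoint quantile is returned (lowest index on ties), making the
#' choice deterministic.  On a uniform field all regimes coincide and the
#' first eligible voxel is returned.
#'
#' @param chromatin a `chromatin_field`.
#' @param regime `"sparse"`, `"dense"` or `"superdense"`.
#' @param bands named list of quantile bands, overridable.
#' @return Voxel linear index (1-based).
#' @export
place_gene <- function(chromatin,
                       regime = c("sparse", "dense", "superdense"),
                       bands = list(sparse = c(0, 0.2),
                                    dense = c(0.5, 0.8),
                                    superdense = c(0.8, 1))) {
  regime <- match.arg(regime)
  cc <- chromatin$c
  eligible <- which(cc < 1)
  if (length(eligible) == 0L)
    stop("no eligible gene voxel: the whole field is fully blocked (c = 1)",
         call. = FALSE)
  ce <- cc[eligible]
  if (diff(range(ce)) == 0) return(eligible[1L])  # uniform field: any voxel
  band <- bands[[regime]]
  q <- stats::quantile(ce, probs = band, names = FALSE, type = 7)
  inband <- if (band[2L] >= 1) ce >= q[1L] & ce <= q[2L]
            else ce >= q[1L] & ce < q[2L]
  if (!any(inband))
    stop(sprintf("no voxel found in the '%s' chromatin-density band", regime),
         call. = FALSE)
  target <- stats::quantile(ce, probs = mean(band), names = FALSE, type = 7)
  cand <- eligible[inband]
  cand[which.min(abs(cc[cand] - target))]
}

#' Voxels reachable from a start voxel through unblocked chromatin
#'
#' Breadth-first search over the 6-neighbour lattice graph restricted to
#' voxels with `c < 1` (crowders attenuate but never block, so they do not
#' affect connectivity).
#'
#' @param lattice a `lattice_spec`.
#' @param chromatin a `chromatin_field`.
#' @param from starting voxel index.
#' @return Integer vector of reachable voxel indices (including `from`).
#' @export
reachable_voxels <- function(lattice, chromatin, from) {
  if (chromatin$c[from] >= 1)
    stop("start voxel is fully blocked (c = 1)", call. = FALSE)
  open <- chromatin$c < 1
  seen <- logical(lattice$N)
  seen[from] <- TRUE
  queue <- from
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    nb <- voxel_neighbors(lattice, v)
    nb <- nb[!is.na(nb)]
    nb <- nb[open[nb] & !seen[nb]]
    if (length(nb)) {
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  which(seen)
}
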