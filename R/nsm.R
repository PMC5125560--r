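# Trajectory container shared by the spatial and well-mixed simulators.
new_trajectory <- function(out, t_end, sample_dt, seed, initial_active,
                           spatial = TRUE, gene_voxel = NA_integer_,
                           config_digest = NA_character_) {
  tf <- out$tf_voxel
  if (spatial) tf <- tf + 1L  # engine is 0-based
  structure(list(
    time = out$time,
    M = out$M,
    P = out$P,
    promoter = out$promoter,          # 1 = active, 0 = repressed
    tf_voxel = tf,
    switch_log = data.frame(time = out$switch_time,
                            state = out$switch_state),
    initial_active = initial_active,
    t_end = t_end, sample_dt = sample_dt,
    seed = seed, n_events = out$n_events,
    gene_voxel = gene_voxel,
    config_digest = config_digest
  ), class = "crowdsim_trajectory")
}

#' @export
print.crowdsim_trajectory <- function(x, ...) {
  cat(sprintf("<crowdsim_trajectory> t_end = %g min, %d samples, %d promoter switches, %.3g events\n",
              x$t_end, length(x$time), nrow(x$switch_log), x$n_events))
  cat(sprintf("  final state: M = %d, P = %d, promoter %s\n",
              x$M[length(x$M)], x$P[length(x$P)],
              if (x$promoter[length(x$promoter)] == 1) "active" else "repressed"))
  invisible(x)
}

#' Simulate one cell with the crowding-modified next subvolume method
#'
#' Statistically exact event-driven sampling of the reaction-diffusion
#' master equation on the voxel lattice.  The transcription factor hops
#' between adjacent voxels with rates attenuated by the destination
#' voxel's chromatin density and crowder occupancy (see [jump_rate()]);
#' all chemistry is local to the gene voxel, with mRNA and protein kept as
#' global counters.  Boundaries are reflective and fully blocked voxels
#' (`c = 1`) are never entered.
#'
#' @param lattice a `lattice_spec`.
#' @param chromatin a `chromatin_field`.
#' @param crowders a `crowder_field`.  The gene voxel takes part in the
#'   crowder placement like any other voxel: crowders attenuate but never
#'   block (`delta >= 0.1`), and exempting the gene voxel would make it an
#'   entropic trap for the TF at high crowding (the stationary occupancy
#'   of the hop process is proportional to `(1 - c_i) * delta_i`),
#'   inverting the crowding effect on the activation rate.
#' @param rates a `rate_constants`.
#' @param gene_voxel gene locus index (1-based); must have `c < 1`.
#' @param t_end simulated time, min (default 1000).
#' @param sample_dt sampling interval for the recorded series, min.
#'   Switch statistics always come from the event-exact `switch_log`, so a
#'   coarse `sample_dt` (even `t_end`) is fine for end-point population
#'   runs.
#' @param seed integer seed; fully determines the trajectory (TF start
#'   position and the event stream).
#' @param tf_start optional TF start voxel; default: uniform over the
#'   voxels connected to the gene through unblocked chromatin.
#' @param initial_bound start with the TF bound (promoter active).
#' @param kon_domain_scaled binding propensity convention, see
#'   [reaction_propensities()].
#' @param max_events guard against runaway event counts.
#' @return An object of class `crowdsim_trajectory`: sampled `time`, `M`,
#'   `P`, `promoter` (1 = active), `tf_voxel` series, the event-exact
#'   `switch_log` (`time`, `state` after the switch), and run metadata.
#' @export
simulate_cell <- function(lattice, chromatin, crowders, rates,
                          gene_voxel, t_end = 1000, sample_dt = 1,
                          seed = 1L, tf_start = NULL,
                          initial_bound = FALSE,
                          kon_domain_scaled = TRUE,
                          max_events = 5e9) {
  stopifnot(inherits(lattice, "lattice_spec"),
            inherits(chromatin, "chromatin_field"),
            inherits(crowders, "crowder_field"),
            inherits(rates, "rate_constants"))
  if (t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
  if (chromatin$c[gene_voxel] >= 1)
    stop("gene voxel is fully blocked (c = 1): transcription impossible",
         call. = FALSE)

  if (is.null(tf_start) && !initial_bound) {
    reach <- reachable_voxels(lattice, chromatin, gene_voxel)
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    tf_start <- if (length(reach) == 1L) reach else sample(reach, 1L)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  if (initial_bound) tf_start <- gene_voxel

  out <- cpp_nsm_run(
    dims = c(lattice$nx, lattice$ny, lattice$nz),
    hvec = c(lattice$hx, lattice$hy, lattice$hz),
    cfield = chromatin$c, delta = crowders$delta,
    D0 = rates$D_TF,
    k_on = rates$k_on, k_off = rates$k_off,
    s_A = rates$s_A, s_R = rates$s_R, s_P = rates$s_P,
    d_M = rates$delta_M, d_P = rates$delta_P,
    gene = gene_voxel - 1L, tf0 = tf_start - 1L,
    bound0 = initial_bound, kon_scaled = kon_domain_scaled,
    t_end = t_end, sample_dt = sample_dt,
    seed = as.numeric(seed), max_events = max_events)

  new_trajectory(out, t_end = t_end, sample_dt = sample_dt, seed = seed,
                 initial_active = initial_bound, spatial = TRUE,
                 gene_voxel = gene_voxel)
}

#' One diffusive hop of a free transcription factor
#'
#' Samples the destination of a single TF jump from `origin` among the up
#' to six lattice neighbours, with probabilities proportional to the
#' crowding-attenuated per-direction jump rates.  Fully blocked
#' destinations (`c = 1`) have probability zero; at the boundary the
#' missing directions are simply absent (reflective box).  Uses R's global
#' RNG.  Exposed mainly for testing the hop kernel in isolation; the
#' simulation engine integrates the same rates internally.
#'
#' @inheritParams jump_rate
#' @param origin origin voxel index.
#' @return Destination voxel index, or `origin` if every neighbour is
#'   blocked.
#' @export
diffusion_step <- function(lattice, chromatin, crowders, D0, origin) {
  nb <- voxel_neighbors(lattice, origin)
  axes <- c("x", "x", "y", "y", "z", "z")
  ok <- !is.na(nb)
  rates <- numeric(length(nb))
  rates[ok] <- vapply(which(ok), function(d)
    jump_rate(lattice, chromatin, crowders, D0, nb[d], axes[d]), numeric(1))
  tot <- sum(rates)
  if (tot <= 0) return(origin)
  unname(nb[sample.int(6L, 1L, prob = rates / tot)])
}

# Per-cell seed stream: a small counter hash keeping values < 2^31.
derive_seed <- function(base_seed, i) {
  ((as.numeric(base_seed) %% 65536) * 32749 + i * 2654435761) %% 2147483647 + 1
}

#' Simulate an ensemble of isogenic cells
#'
#' Runs `n_cells` independent trajectories sharing one chromatin field and
#' gene locus.  By default the artificial crowder placement is resampled
#' per cell at the same `theta` (independent cytoplasms); set
#' `resample_crowders = FALSE` to share one placement.  Per-cell seeds are
#' derived deterministically from `base_seed` by a counter construction,
#' so the ensemble is reproducible and order-independent.
#'
#' @inheritParams simulate_cell
#' @param theta crowdedness parameter in `[0, 1]`.
#' @param size_class `"big"` or `"small"` crowding agent.
#' @param n_cells number of cells.
#' @param base_seed root seed of the ensemble.
#' @param resample_crowders logical, see above.
#' @return List of `crowdsim_trajectory`, with attributes `gene_voxel`,
#'   `theta`, `size_class`, `base_seed`.
#' @export
run_ensemble <- function(lattice, chromatin, rates, gene_voxel,
                         theta = 0, size_class = "big",
                         n_cells = 16000L, base_seed = 1L,
                         t_end = 1000, sample_dt = 1,
                         resample_crowders = TRUE,
                         kon_domain_scaled = TRUE) {
  if (n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  shared <- if (!resample_crowders || theta == 0)
    place_crowders(lattice, crowding_config(theta, size_class,
                                            seed = derive_seed(base_seed, 0)))
  else NULL
  out <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    s <- derive_seed(base_seed, i)
    crow <- if (is.null(shared))
      place_crowders(lattice, crowding_config(theta, size_class, seed = s))
    else shared
    out[[i]] <- simulate_cell(lattice, chromatin, crow, rates, gene_voxel,
                              t_end = t_end, sample_dt = sample_dt,
                              seed = s, kon_domain_scaled = kon_domain_scaled)
  }
  attr(out, "gene_voxel") <- gene_voxel
  attr(out, "theta") <- theta
  attr(out, "size_class") <- size_class
  attr(out, "base_seed") <- base_seed
  out
}

#' End-point mRNA counts of an ensemble
#' @param ensemble list of trajectories from [run_ensemble()].
#' @return Integer vector of `M` at `t_end`, one per cell.
#' @export
endpoint_M <- function(ensemble) {
  vapply(ensemble, function(tr) tr$M[length(tr$M)], integer(1))
}
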