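#' Assemble an experiment configuration
#'
#' A single JSON-serialisable description of one simulation experiment:
#' rate constants, lattice geometry, crowding, chromatin source, gene
#' placement and run control.  Defaults reproduce the reference setup
#' (50 x 50 x 11 voxels over a 1 um cube, 1000 min runs, 16000-cell
#' populations); scale `n_cells`, `dims` and `t_end` down for interactive
#' use.
#'
#' @param rates named list of [rate_constants()] overrides.
#' @param dims,box lattice voxel counts and box edge lengths (um).
#' @param theta crowdedness parameter in `[0, 1]`.
#' @param size_class `"big"` or `"small"` crowding agent.
#' @param chromatin either `list(source = "none")`, `list(source =
#'   "synthetic", correlation_length =, contrast =, blocked_fraction_target
#'   =, seed =)` (missing fields take [field_params()] defaults), or
#'   `list(source = "csv", paths = <plane files>)`.
#' @param gene either `list(regime = "sparse"|"dense"|"superdense")` or
#'   `list(voxel = <index>)`.
#' @param t_end,sample_dt simulation time and sampling interval, min.
#' @param n_cells population size for population subcommands.
#' @param base_seed root seed.
#' @param kon_domain_scaled binding propensity convention, see
#'   [reaction_propensities()].
#' @param resample_crowders resample the crowder placement per cell.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(rates = list(),
                              dims = c(50L, 50L, 11L), box = c(1, 1, 1),
                              theta = 0, size_class = "big",
                              chromatin = list(source = "synthetic"),
                              gene = list(regime = "dense"),
                              t_end = 1000, sample_dt = 1,
                              n_cells = 16000L, base_seed = 1L,
                              kon_domain_scaled = TRUE,
                              resample_crowders = TRUE) {
  cfg <- list(
    rates = unclass(do.call(rate_constants, rates)),
    dims = as.integer(dims), box = as.numeric(box),
    theta = theta, size_class = size_class,
    chromatin = chromatin, gene = gene,
    t_end = t_end, sample_dt = sample_dt,
    n_cells = as.integer(n_cells), base_seed = as.integer(base_seed),
    kon_domain_scaled = isTRUE(kon_domain_scaled),
    resample_crowders = isTRUE(resample_crowders))
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

validate_config <- function(cfg) {
  if (cfg$theta < 0 || cfg$theta > 1)
    stop("config error: theta must lie in [0, 1]", call. = FALSE)
  if (!cfg$size_class %in% c("big", "small"))
    stop("config error: size_class must be 'big' or 'small'", call. = FALSE)
  if (cfg$t_end <= 0 || cfg$sample_dt <= 0)
    stop("config error: t_end and sample_dt must be positive", call. = FALSE)
  if (!cfg$chromatin$source %in% c("none", "synthetic", "csv"))
    stop("config error: unknown chromatin source", call. = FALSE)
  if (is.null(cfg$gene$regime) && is.null(cfg$gene$voxel))
    stop("config error: gene needs a regime or an explicit voxel",
         call. = FALSE)
  invisible(cfg)
}

#' Read / write an experiment configuration as JSON
#' @param path JSON file path.
#' @rdname config_io
#' @return `read_config` returns an `experiment_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- list(
    rates = as.list(raw$rates %||% list()),
    theta = raw$theta %||% 0,
    size_class = raw$size_class %||% "big",
    chromatin = as.list(raw$chromatin %||% list(source = "synthetic")),
    gene = as.list(raw$gene %||% list(regime = "dense")),
    t_end = raw$t_end %||% 1000,
    sample_dt = raw$sample_dt %||% 1,
    n_cells = raw$n_cells %||% 16000L,
    base_seed = raw$base_seed %||% 1L,
    kon_domain_scaled = raw$kon_domain_scaled %||% TRUE,
    resample_crowders = raw$resample_crowders %||% TRUE)
  if (!is.null(raw$dims)) args$dims <- raw$dims
  if (!is.null(raw$box)) args$box <- raw$box
  do.call(experiment_config, args)
}

#' @param cfg an `experiment_config`.
#' @rdname config_io
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# polynomial hash of the canonical JSON form (exact in doubles); stamps
# outputs so a run directory records exactly which configuration made it
config_digest <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Materialise lattice, chromatin field and gene voxel from a config.
build_world <- function(cfg) {
  lattice <- build_lattice(cfg$dims, cfg$box)
  chrom <- switch(cfg$chromatin$source,
    none = empty_chromatin(lattice),
    synthetic = {
      fp <- field_params(
        correlation_length = cfg$chromatin$correlation_length %||% 0.15,
        contrast = cfg$chromatin$contrast %||% 1.5,
        blocked_fraction_target =
          cfg$chromatin$blocked_fraction_target %||% 0.002,
        seed = cfg$chromatin$seed %||% cfg$base_seed)
      normalize_chromatin(generate_field(lattice, fp), lattice)
    },
    csv = normalize_chromatin(
      import_intensity_stack(cfg$chromatin$paths, lattice), lattice))
  gene_voxel <- if (!is.null(cfg$gene$voxel)) as.integer(cfg$gene$voxel)
                else place_gene(chrom, cfg$gene$regime)
  rates <- do.call(rate_constants, as.list(cfg$rates))
  list(lattice = lattice, chromatin = chrom, gene_voxel = gene_voxel,
       rates = rates)
}

#' Serialise lattice and static fields to a run directory
#'
#' Writes `fields.json` (dims, box, theta, size class, seed) and
#' `voxels.csv` (index, chromatin density, crowder occupancy) so a
#' simulation's spatial substrate can be reconstructed bit-exactly.
#'
#' @param dir output directory (created if needed).
#' @param lattice,chromatin,crowders the fields to store.
#' @return `dir`, invisibly.
#' @export
write_fields <- function(dir, lattice, chromatin, crowders) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- list(dims = c(lattice$nx, lattice$ny, lattice$nz),
                 box = c(lattice$Lx, lattice$Ly, lattice$Lz),
                 theta = crowders$theta, size_class = crowders$size_class,
                 seed = crowders$seed)
  jsonlite::write_json(header, file.path(dir, "fields.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(
    data.frame(index = seq_len(lattice$N), c = chromatin$c,
               occupancy = crowders$occupancy),
    file.path(dir, "voxels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read lattice and static fields back from a run directory
#' @param dir directory written by [write_fields()].
#' @return List with `lattice`, `chromatin`, `crowders`.
#' @export
read_fields <- function(dir) {
  header <- jsonlite::fromJSON(file.path(dir, "fields.json"))
  tab <- utils::read.csv(file.path(dir, "voxels.csv"),
                         stringsAsFactors = FALSE)
  lattice <- build_lattice(header$dims, header$box)
  chrom <- structure(list(c = tab$c, lattice = lattice),
                     class = "chromatin_field")
  crow <- structure(list(occupancy = tab$occupancy,
                         delta = unname(crowder_delta[tab$occupancy]),
                         theta = header$theta,
                         size_class = header$size_class,
                         seed = header$seed, lattice = lattice),
                    class = "crowder_field")
  list(lattice = lattice, chromatin = chrom, crowders = crow)
}
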