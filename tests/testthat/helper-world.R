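# Shared fixture builders.  Everything is generated in code; meshes are
# kept small so the default test run stays within minutes.

# empty (uncrowded, chromatin-free) world on a small lattice
make_empty_world <- function(dims = c(6L, 6L, 3L), box = c(1, 1, 1)) {
  lat <- build_lattice(dims, box)
  list(lattice = lat,
       chromatin = empty_chromatin(lat),
       crowders = empty_crowders(lat))
}

# synthetic-chromatin world with a dense-regime gene, default field params
make_chromatin_world <- function(dims = c(8L, 8L, 4L), seed = 1L,
                                 regime = "dense") {
  lat <- build_lattice(dims)
  ch <- normalize_chromatin(generate_field(lat, field_params(seed = seed)),
                            lat)
  list(lattice = lat, chromatin = ch,
       gene_voxel = place_gene(ch, regime))
}

# crowder field with every voxel occupied by the given class
make_full_crowders <- function(lattice, size_class) {
  place_crowders(lattice, crowding_config(theta = 1, size_class = size_class,
                                          seed = 1L))
}

# per-event switch durations (t_on, t_off) from an event-exact log
switch_durations <- function(tr) {
  log <- tr$switch_log
  if (nrow(log) < 2L) return(list(on = numeric(0), off = numeric(0)))
  dur <- diff(log$time)
  state_during <- log$state[-nrow(log)]  # state after each switch
  list(on = dur[state_during == 1L], off = dur[state_during == 0L])
}
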