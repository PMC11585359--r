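# Shared fixtures: chamber-like crown geometry and short synthetic periods.

chamber_crown <- function(LAI = 3.3, radius = 0.6, depth = 3,
                          crown_base = 0.45, x = 0, y = 0) {
  crown_geometry(height = crown_base + depth, radius = radius,
                 leaf_area = LAI * pi * radius^2, crown_base = crown_base,
                 x = x, y = y)
}

# wide flat cylinder whose interior approximates a horizontally homogeneous
# canopy slab (gridpoints sit far from the edge)
slab_crown <- function(LAI = 3.3, depth = 3, radius = 50) {
  crown_geometry(height = depth, radius = radius,
                 leaf_area = LAI * pi * radius^2)
}

short_met <- function(seed = 1, start = "2013-12-15", end = "2014-01-05",
                      cadence_min = 60) {
  synth_met(synth_met_config(start = start, end = end,
                             cadence_min = cadence_min, seed = seed))
}

short_trees <- function(seed = 1, start = "2013-12-15", end = "2014-01-05") {
  synth_trees(tree_growth_config(seed = seed), start = start, end = end)
}

sweep_argmax <- function(sweep) sweep$Tair[which.max(sweep$Anet)]
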