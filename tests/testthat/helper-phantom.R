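# Shared fixtures. Phantom bundles are deterministic under their seed and
# moderately expensive, so they are built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# the standard study phantom
std_phantom <- function() cached("std", make_phantom(phantom_spec()))

# a reduced phantom for unit tests of the expensive stages
small_spec <- function(seed = 1L) phantom_spec(dim = c(36L, 44L, 32L), seed = seed)
small_phantom <- function() cached("small", make_phantom(small_spec()))

# a tiny structure graph: root -> A -> B chain
chain_graph <- function() {
  structure_graph(data.frame(id = c(1L, 2L, 3L),
                             parent_id = c(NA, 1L, 2L)))
}

# a minimal annotation volume from a label array
tiny_ann <- function(arr, voxel = 25) {
  labeled_volume(array(as.integer(arr), dim(arr)), grid_meta(voxel))
}
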