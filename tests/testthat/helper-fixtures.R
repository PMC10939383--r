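# Shared fixtures built in code: a hand-written minimal PDB and a small
# voxel configuration that keeps CNN tests fast.

pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     element = substr(name, 1, 1), altloc = " ",
                     record = "ATOM") {
  sprintf("%-6s%5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          altloc, resname, chain, resno, x, y, z, element)
}

# one alanine with a real side-chain CB (to be discarded on read)
single_ala_pdb <- function() {
  paste(c(
    pdb_line(1, "N", "ALA", "A", 1, 0.000, 0.000, 0.000),
    pdb_line(2, "CA", "ALA", "A", 1, 1.458, 0.000, 0.000, element = "C"),
    pdb_line(3, "C", "ALA", "A", 1, 2.009, 1.420, 0.000),
    pdb_line(4, "O", "ALA", "A", 1, 1.251, 2.390, 0.000),
    pdb_line(5, "CB", "ALA", "A", 1, 2.000, -0.800, -1.200, element = "C"),
    "TER", "END"), collapse = "\n")
}

small_config <- function(...) {
  voxel_config(voxels_per_side = 9, ...)
}

tiny_timed_spec <- function(channels = 5) {
  model_spec("timed", input_shape = c(9, 9, 9, channels),
             conv_blocks = list(8), spatial_dropout_rate = 0.05)
}

# small synthetic dataset cached per test run
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- synthetic_labelled_dataset(
        n_structures = 10, length = 30, seed = 7, config = small_config())
    }
    cache
  }
})
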