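# Hand-written graphs and molfiles reused across test files.

water_graph <- function() {
  molecule_graph("water", c("O", "H", "H"),
                 bonds = rbind(c(1L, 2L, 1L), c(1L, 3L, 1L)))
}

methane_graph <- function() {
  molecule_graph("methane", c("C", "H", "H", "H", "H"),
                 bonds = cbind(1L, 2:5, 1L))
}

# CH3-CH2-OH with explicit hydrogens
ethanol_graph <- function() {
  molecule_graph("ethanol", c("C", "C", "O", rep("H", 6L)),
                 bonds = rbind(c(1L, 2L, 1L), c(2L, 3L, 1L),
                               c(1L, 4L, 1L), c(1L, 5L, 1L), c(1L, 6L, 1L),
                               c(2L, 7L, 1L), c(2L, 8L, 1L), c(3L, 9L, 1L)))
}

# C6 ring with aromatic (order 4) bonds
benzene_graph <- function() {
  molecule_graph("benzene", rep("C", 6L),
                 bonds = cbind(1:6, c(2:6, 1L), 4L))
}

# glucose heavy-atom skeleton plus explicit hydrogens: C6H12O6
glucose_graph <- function() {
  molecule_graph("glucose", c(rep("C", 6L), rep("O", 6L), rep("H", 12L)),
                 bonds = rbind(cbind(1:5, 2:6, 1L),       # carbon chain
                               cbind(1:6, 7:12, 1L),      # one O per C
                               cbind(c(1:6, 7:12), 13:24, 1L)))
}

# Minimal hand-written molfiles
minimal_molfile <- function() {
  paste("one carbon", "", "",
        "  1  0  0  0  0  0  0  0  0  0999 V2000",
        "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
        "M  END", sep = "\n")
}

water_molfile <- function() {
  paste("water", "", "",
        "  3  2  0  0  0  0  0  0  0  0999 V2000",
        "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
        "    0.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
        "    0.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
        "  1  2  1  0", "  1  3  1  0",
        "M  END", sep = "\n")
}

# A small random corpus of parsed synthetic molecules.
synth_corpus <- function(n = 50L, seed = 7L) {
  cfg <- synth_config(n_compounds = n, n_pathways = min(10L, n),
                      hierarchy_depth = 3L, seed = seed)
  mols <- gen_molecules(cfg)
  lapply(names(mols), function(id) parse_molfile(mols[[id]], compound_id = id))
}

# Apply a random atom permutation to a graph (same molecule, new atom order).
permute_graph <- function(graph, seed) {
  set.seed(seed)
  n <- length(graph$elements)
  perm <- sample.int(n)          # perm[i] = new position of old atom i
  b <- graph$bonds
  if (nrow(b)) {
    b[, 1L] <- perm[b[, 1L]]
    b[, 2L] <- perm[b[, 2L]]
  }
  inv <- order(perm)
  molecule_graph(graph$compound_id, graph$elements[inv], graph$charges[inv], b)
}

# Tiny study + dataset for bookkeeping-level CV tests.
tiny_dataset <- function(seed = 11L, n_compounds = 20L, n_pathways = 3L) {
  cfg <- synth_config(n_compounds = n_compounds, n_pathways = n_pathways,
                      hierarchy_depth = 2L, seed = seed)
  st <- synth_study(cfg)
  pd <- suppressMessages(
    build_pathway_dataset(st$graphs, st$annotations, st$hierarchy,
                          max_radius = 1L))
  list(study = st, pd = pd)
}

# Fast MLP settings for tests that only exercise bookkeeping.
fast_mlp <- function(...) {
  mlp_config(hidden_sizes = c(8L, 4L), max_epochs = 5L, batch_size = 64L,
             val_fraction = 0, ...)
}
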