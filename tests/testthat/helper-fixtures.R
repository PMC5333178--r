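# Shared fixtures. Scenarios are generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# the full default validation scenario (seed 42, 2000 steps)
default_scenario <- function() cached("default_scenario", generate_scenario())

default_attributes <- function() {
  cached("default_attributes", suppressMessages(
    derive_attributes(default_scenario()$frames, default_scenario()$ligand,
                      default_scenario()$active_site,
                      ligand_atoms = default_scenario()$ligand_atoms)))
}

# a short scenario for oracle-equality tests (same geometry, fewer steps)
small_scenario <- function() {
  cached("small_scenario",
         generate_scenario(scenario_spec(seed = 11, n_steps = 240)))
}

small_attributes <- function() {
  cached("small_attributes", suppressMessages(
    derive_attributes(small_scenario()$frames, small_scenario()$ligand,
                      small_scenario()$active_site,
                      ligand_atoms = small_scenario()$ligand_atoms)))
}

# right-angle unit elbow polyline
elbow_traj <- function() {
  ligand_trajectory(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
}

# collinear equally spaced points along +x
line_traj <- function(n = 10, spacing = 1) {
  ligand_trajectory(cbind(spacing * (0:(n - 1)), 0, 0))
}

# hand-written 3-model PDB: 4 protein atoms + 1-atom ligand LIG
write_tiny_pdb <- function(path) {
  atom_line <- function(serial, name, resname, chain, resid, x, y, z) {
    sprintf("ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, name, resname, chain, resid, x, y, z)
  }
  lig_xyz <- rbind(c(5, 0, 0), c(5, 1, 0), c(5, 2, 0))
  lines <- character(0)
  for (f in 1:3) {
    lines <- c(lines, sprintf("MODEL     %4d", f),
               atom_line(1, "N1", "ALA", "A", 1, 0, 0, f - 1),
               atom_line(2, "C1", "ALA", "A", 1, 1, 0, f - 1),
               atom_line(3, "C2", "ALA", "A", 2, 2, 0, f - 1),
               atom_line(4, "O1", "ALA", "A", 2, 3, 0, f - 1),
               atom_line(5, "C1", "LIG", "A", 3,
                         lig_xyz[f, 1], lig_xyz[f, 2], lig_xyz[f, 3]),
               "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  list(path = path, lig_xyz = lig_xyz)
}

# rigid rotation matrix about an arbitrary fixed axis
fixed_rotation <- function() {
  ax <- c(1, 2, 3) / sqrt(14)
  th <- 0.83
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

traj_mat <- function(traj) unname(as.matrix(traj[, c("x", "y", "z")]))
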