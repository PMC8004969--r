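# Small fixtures built in code.

# minimal cofactor + substrate-fragment topology with explicit coordinates;
# returns a one-frame trajectory.  Layout mirrors the reactive-frame
# generator but with hand-placed atoms for exact arithmetic.
tiny_reactive_traj <- function(C = c(3.7, 0, 0),
                               HS = c(2.61, 0, 0),
                               HR = c(3.7 + 1.09, 0, 0)) {
  atoms <- data.frame(
    serial = 1:4,
    name = c("OH", "C13", "H3S", "H3R"),
    element = c("O", "C", "H", "H"),
    resname = c("FEO", "SUB", "SUB", "SUB"),
    resnum = c(1L, 2L, 2L, 2L),
    monomer = c("A", "B", "B", "B"))
  top <- topology_spec(atoms,
                       cofactor_oxygen = "A:1:OH",
                       reactive_carbon = "B:2:C13",
                       h_proS = "B:2:H3S", h_proR = "B:2:H3R")
  xyz <- matrix(c(0, 0, 0, C, HS, HR), nrow = 1L)
  trajectory(top, xyz)
}

# tetra-coordinated carbon with two carbon and two hydrogen neighbours at
# ideal tetrahedral directions, bonds declared, prochiral set to AUTO
auto_prochiral_traj <- function(swap_h = FALSE, mirror = FALSE) {
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    sqrt(3)
  cc <- c(5, 5, 5)
  hs <- cc + 1.09 * dirs[3, ]
  hr <- cc + 1.09 * dirs[4, ]
  if (swap_h) { tmp <- hs; hs <- hr; hr <- tmp }
  coords <- rbind(cc,
                  cc + 1.5 * dirs[1, ],   # C14 (high priority branch)
                  cc + 1.5 * dirs[2, ],   # C12
                  hs, hr)
  if (mirror) coords[, 1] <- -coords[, 1]
  atoms <- data.frame(
    serial = 1:5,
    name = c("C13", "C14", "C12", "HA", "HB"),
    element = c("C", "C", "C", "H", "H"),
    resname = "SUB", resnum = 2L, monomer = "B")
  top <- topology_spec(
    atoms,
    reactive_carbon = "B:2:C13",
    h_proS = "AUTO", h_proR = "AUTO",
    bonds = list(c("B:2:C13", "B:2:C14"), c("B:2:C13", "B:2:C12"),
                 c("B:2:C13", "B:2:HA"), c("B:2:C13", "B:2:HB")),
    branch_priority = "B:2:C14")
  trajectory(top, matrix(as.vector(t(coords)), nrow = 1L))
}

# write a 2-model PDB of the given coordinate list to a temp file
write_tiny_pdb <- function(frames, atoms, path = tempfile(fileext = ".pdb")) {
  lines <- character()
  for (m in seq_along(frames)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    co <- frames[[m]]
    for (i in seq_len(nrow(atoms))) {
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        atoms$serial[i], atoms$name[i], atoms$resname[i], atoms$monomer[i],
        atoms$resnum[i], co[i, 1], co[i, 2], co[i, 3], atoms$element[i]))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}
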