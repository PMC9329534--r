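# Multi-model PDB I/O for toy trajectories. Reading delegates to bio3d;
# writing emits fixed-width MODEL/ATOM/ENDMDL records (one model per frame).

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traj_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  topo <- traj$topology
  resname <- if ("resname" %in% names(topo)) topo$resname else "GLY"
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(traj$frames)) {
    xyz <- traj$frames[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(topo)),
      ifelse(nchar(topo$atom) < 4, paste0(" ", topo$atom), topo$atom),
      resname, topo$resid, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
      toupper(topo$element)
    )
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Parses with bio3d (`multi = TRUE`); each MODEL becomes one frame. vdW
#' radii are assigned from the packaged Bondi-type table by element.
#'
#' @param path PDB file path.
#' @return A [trajectory()].
#' @export
read_traj_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(trimws(at$elety), 1, 1)
  }
  topo <- tibble::tibble(
    atom = trimws(at$elety),
    element = trimws(elem),
    resid = at$resno,
    resname = trimws(at$resid)
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(m) {
    matrix(xyz[m, ], ncol = 3, byrow = TRUE)
  })
  trajectory(topo, frames)
}
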