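## Multi-model PDB round trip for coordinate ensembles. Reading goes
## through bio3d (multi = TRUE); writing emits fixed-width MODEL/ATOM/
## HETATM/ENDMDL records directly because per-model water counts vary
## and ensembles need MODEL blocks.

subunit_chains <- c(LETTERS[1:22], "W")  # waters use chain W

#' Write a coordinate ensemble as a multi-model PDB file
#'
#' Calpha atoms are written as ATOM records (residue name ALA, one chain
#' per subunit), water oxygens as HETATM `HOH O` records on chain W, one
#' MODEL/ENDMDL block per snapshot.
#'
#' @param ensemble A [coord_ensemble()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "coord_ensemble"))
  m <- dim(ensemble$coords)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(m)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    snap <- ensemble$coords[i, , , drop = TRUE]
    snap <- matrix(snap, ncol = 3)
    serial <- 0L
    for (j in seq_len(nrow(snap))) {
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, subunit_chains[ensemble$subunit[j]], ensemble$residue[j],
        snap[j, 1], snap[j, 2], snap[j, 3]), con)
    }
    w <- if (is.null(ensemble$waters)) NULL else ensemble$waters[[i]]
    if (!is.null(w) && nrow(w) > 0) {
      for (j in seq_len(nrow(w))) {
        serial <- serial + 1L
        writeLines(sprintf(
          "HETATM%5d  O   HOH W%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
          serial, j, w[j, 1], w[j, 2], w[j, 3]), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file into a coordinate ensemble
#'
#' Calpha atoms (any residue name except HOH) become the ensemble
#' coordinates; `HOH` oxygen records become the per-snapshot water sets.
#' Chains map to subunits in order of appearance. The first model is the
#' reference.
#'
#' @param path PDB file with MODEL/ENDMDL records.
#' @param axis Channel axis (default z).
#' @return A [coord_ensemble()].
#' @export
read_ensemble_pdb <- function(path, axis = c(0, 0, 1)) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  is_ca <- pdb$atom$elety == "CA" & pdb$atom$resid != "HOH"
  is_wat <- pdb$atom$resid == "HOH" & pdb$atom$elety == "O"
  xyz <- pdb$xyz                      # models x 3*atoms
  m <- nrow(xyz)
  ca_idx <- which(is_ca)
  n <- length(ca_idx)
  coords <- array(NA_real_, c(m, n, 3))
  for (i in seq_len(m)) {
    mat <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    coords[i, , ] <- mat[ca_idx, , drop = FALSE]
  }
  chains <- pdb$atom$chain[ca_idx]
  subunit <- match(chains, unique(chains))
  residue <- pdb$atom$resno[ca_idx]
  waters <- NULL
  if (any(is_wat)) {
    w_idx <- which(is_wat)
    waters <- lapply(seq_len(m), function(i) {
      mat <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
      w <- mat[w_idx, , drop = FALSE]
      w[stats::complete.cases(w), , drop = FALSE]
    })
  }
  coord_ensemble(coords, residue, subunit, waters = waters, axis = axis)
}
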