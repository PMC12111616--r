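# SMILES templates for the synthetic annotation table.
#
# Each chemical class is a homologous series on a fixed head group. Acyl
# chains vary in length, unsaturation and hydroxylation so that path-based
# fingerprints see real within-class structure (pure chain-length homologues
# can hash to identical path sets), while head groups keep classes apart.

acyl_chain <- function(len, n_db = 0, hydroxyl = FALSE) {
  len <- max(len, 4L)
  atoms <- rep("C", len)
  if (n_db > 0) {
    # spread double bonds along the chain, never at the carbonyl end
    at <- unique(pmin(len - 1L, floor(seq(3, len - 1, length.out = n_db))))
    for (k in at) atoms[k] <- "C="
  }
  if (hydroxyl) atoms[max(2L, len %/% 2L)] <- "C(O)"
  paste(atoms, collapse = "")
}

class_smiles <- function(class, i) {
  # Homologous series on a fixed head group per class, acyl chains of
  # varying length (>= 8 carbons). Path fingerprints saturate on long
  # linear chains, so each class forms one tight group in Tanimoto space
  # while head groups keep classes apart - the structure the chemical
  # clustering stage is meant to recover.
  r1 <- acyl_chain(8L + (i - 1L) %% 12L)
  r2 <- acyl_chain(8L + (i * 3L) %% 8L)
  switch(
    class,
    fatty_acid = paste0("OC(=O)", acyl_chain(8L + (i - 1L) %% 12L)),
    glycerolipid = paste0("OCC(COC(=O)", r1, ")OC(=O)", r2),
    phospholipid_pc = paste0("C[N+](C)(C)CCOP([O-])(=O)OCC(COC(=O)",
                             r1, ")OC(=O)", r2),
    # ether-linked sn-1 chain, ethanolamine head
    phospholipid_pe = paste0("NCCOP(O)(=O)OCC(CO", r1, ")OC(=O)", r2),
    sphingolipid = paste0("CCCCCCCCCCCCCC=CC(O)C(CO)NC(=O)", r1),
    cyclic = paste0("OC(=O)", acyl_chain(8L + (i - 1L) %% 8L), "c1ccccc1"),
    abort(paste0("unknown chemical class: ", class))
  )
}

# crude but monotone-in-size mass/formula surrogates for the annotation table
smiles_composition <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  n_c <- sum(chars %in% c("C", "c"))
  n_o <- sum(chars %in% c("O", "o"))
  n_n <- sum(chars %in% c("N", "n"))
  n_p <- sum(chars == "P")
  n_h <- max(0L, 2L * n_c - 2L * sum(chars == "=") - 6L * sum(chars == "1") %/% 2L)
  list(n_c = n_c, n_h = n_h, n_o = n_o, n_n = n_n, n_p = n_p)
}

smiles_mass <- function(smiles) {
  k <- smiles_composition(smiles)
  12.000 * k$n_c + 1.00783 * k$n_h + 15.99491 * k$n_o +
    14.00307 * k$n_n + 30.97376 * k$n_p
}

smiles_formula <- function(smiles) {
  k <- smiles_composition(smiles)
  paste0("C", k$n_c, "H", k$n_h,
         if (k$n_n > 0) paste0("N", k$n_n) else "",
         "O", k$n_o,
         if (k$n_p > 0) paste0("P", k$n_p) else "")
}
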