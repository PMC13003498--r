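# Regenerates inst/extdata/guest_templates.sdf, the curated heavy-atom
# template geometries for the ten-guest screening panel. Geometries are
# built from SMILES with OpenBabel's rule-based builder, hydrogens are
# stripped, all acyclic single-bond torsions are set to anti, and the pose
# is canonicalized to principal axes. Run from the repository root:
#   Rscript tools/generate_guest_templates.R
for (f in list.files("R", full.names = TRUE)) source(f)
smis <- guest_smiles()
mols <- list()
for (nm in names(smis)) {
  mol <- strip_hydrogens(smiles_to_3d(smis[[nm]], nm))
  rot <- rotatable_bonds(mol$elements, mol$bonds)
  base <- build_conformer_ensemble(mol$xyz, mol$elements, mol$bonds, rot,
                                   1L, 1L)[[1]]
  mols[[nm]] <- list(xyz = base, elements = mol$elements, bonds = mol$bonds)
}
write_sdf_library(mols, "inst/extdata/guest_templates.sdf")
cat("wrote", length(mols), "templates\n")
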