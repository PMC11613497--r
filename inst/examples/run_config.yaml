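# Example run configuration for mfccmbe.
# Either give a fixture recipe (synthetic complex, below) or PDB inputs:
#   protein_pdb: path/to/protein.pdb
#   ligand_pdb: path/to/ligand.pdb
fixture:
  sequence: AGSDKA      # one-letter amino acid sequence
  ligand: zwitterion    # point | zwitterion | water
  distance: 3           # minimum anchor-residue / ligand distance, Angstrom
  conformation: extended
ligand_charge: 0        # formal charge of the ligand (never inferred)
backend: pairwise       # pairwise | threebody (analytic test potentials)
lambdas: [1, 2, 3, 4, 6, Inf]   # trimer screen cutoffs, Angstrom
methods: [mfcc, mfcc-mbe2]
reference: supermolecular
proline_policy: error   # error | strip
seed: 1                 # seeds fixture jitter; runs are reproducible
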