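"""Build a seeded 3D structure from a SMILES string.

Called by protomeR::parse_smiles_to_3d. Prints a JSON object with
elements, coordinates (Angstrom), bonds (1-based, with orders) and the
net formal charge. Exits non-zero with a message on stderr on failure.
"""
import json
import sys


def main():
    smiles, seed, steps_per_atom = sys.argv[1], int(sys.argv[2]), int(sys.argv[3])
    from rdkit import Chem, RDLogger
    from rdkit.Chem import AllChem
    RDLogger.DisableLog("rdApp.*")

    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        sys.stderr.write("unparsable SMILES: %s\n" % smiles)
        sys.exit(2)
    mol = Chem.AddHs(mol)

    params = AllChem.ETKDGv3()
    params.randomSeed = seed
    params.useRandomCoords = False
    if AllChem.EmbedMolecule(mol, params) != 0:
        params.useRandomCoords = True
        if AllChem.EmbedMolecule(mol, params) != 0:
            sys.stderr.write("3D embedding failed for: %s\n" % smiles)
            sys.exit(3)

    # MMFF94 relaxation; UFF fallback for atom types MMFF cannot assign.
    # Step count scales with size, with a floor so tiny molecules relax fully.
    total_steps = max(200, steps_per_atom * mol.GetNumAtoms())
    try:
        if AllChem.MMFFHasAllMoleculeParams(mol):
            AllChem.MMFFOptimizeMolecule(mol, maxIters=total_steps)
        else:
            AllChem.UFFOptimizeMolecule(mol, maxIters=total_steps)
    except Exception as exc:  # pragma: no cover - RDKit internal failures
        sys.stderr.write("force-field relaxation failed: %s\n" % exc)
        sys.exit(4)

    conf = mol.GetConformer()
    out = {
        "elements": [a.GetSymbol() for a in mol.GetAtoms()],
        "coords": [[conf.GetAtomPosition(i).x,
                    conf.GetAtomPosition(i).y,
                    conf.GetAtomPosition(i).z]
                   for i in range(mol.GetNumAtoms())],
        "bonds": [[b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1,
                   b.GetBondTypeAsDouble()] for b in mol.GetBonds()],
        "formal_charge": Chem.GetFormalCharge(mol),
    }
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
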