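"""Seeded conformer embedding for one molecule.

Distance-geometry (ETKDGv3) embedding with a fixed random seed, force-field
minimisation (MMFF94, UFF fallback when parameters are missing), per-conformer
energies in kcal/mol and Gasteiger partial charges. Writes one SDF record per
conformer with `energy_kcal`, `forcefield` and `gasteiger_charges` properties.
Called by the R package as a subprocess; deterministic for a fixed seed.
"""

import argparse
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def main() -> int:
    ap = argparse.ArgumentParser()
    ap.add_argument("--smiles", required=True)
    ap.add_argument("--label", default="molecule")
    ap.add_argument("--n-embed", type=int, default=200)
    ap.add_argument("--seed", type=int, default=42)
    ap.add_argument("--max-iters", type=int, default=500)
    ap.add_argument("--out", required=True)
    args = ap.parse_args()

    mol = Chem.MolFromSmiles(args.smiles)
    if mol is None:
        sys.stderr.write(f"unparsable SMILES for '{args.label}'\n")
        return 2
    mol = Chem.AddHs(mol)

    params = AllChem.ETKDGv3()
    params.randomSeed = args.seed
    ids = AllChem.EmbedMultipleConfs(mol, numConfs=args.n_embed, params=params)
    if len(ids) == 0:
        sys.stderr.write(f"embedding failed for '{args.label}'\n")
        return 3

    forcefield = "MMFF94"
    if AllChem.MMFFHasAllMoleculeParams(mol):
        res = AllChem.MMFFOptimizeMoleculeConfs(mol, maxIters=args.max_iters)
    else:
        forcefield = "UFF"
        res = AllChem.UFFOptimizeMoleculeConfs(mol, maxIters=args.max_iters)
    energies = [e for _converged, e in res]

    AllChem.ComputeGasteigerCharges(mol)
    charges = " ".join(
        f"{a.GetDoubleProp('_GasteigerCharge'):.6f}" for a in mol.GetAtoms()
    )

    mol.SetProp("_Name", args.label)
    mol.SetProp("forcefield", forcefield)
    mol.SetProp("gasteiger_charges", charges)
    writer = Chem.SDWriter(args.out)
    for cid, energy in zip(ids, energies):
        mol.SetProp("energy_kcal", f"{energy:.8f}")
        writer.write(mol, confId=cid)
    writer.close()
    return 0


if __name__ == "__main__":
    sys.exit(main())
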