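"""RDKit descriptor helper for the ctpairs R package.

Reads one SMILES per line from argv[1], writes a CSV of descriptors to
argv[2]. Unparseable SMILES produce an all-empty row with parse_error=1.
"""
import csv
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdMolDescriptors as rd
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

COLS = [
    "canonical_smiles", "fraction_csp3", "n_heteroatoms", "n_stereocenters",
    "n_aliphatic_rings", "n_aliphatic_carbocycles", "n_aliphatic_heterocycles",
    "n_aromatic_rings", "n_aromatic_carbocycles", "n_aromatic_heterocycles",
    "n_saturated_rings", "n_saturated_carbocycles", "n_saturated_heterocycles",
    "n_aromatic_atoms", "n_aromatic_c", "n_aromatic_n", "n_aromatic_hetero",
    "scaffold_w_stereo", "scaffold_wo_stereo", "parse_error",
]


def aromatic_counts(mol):
    """Total aromatic atoms plus aromatic C / N / hetero counts."""
    total = c = n = hetero = 0
    for atom in mol.GetAtoms():
        if not atom.GetIsAromatic():
            continue
        total += 1
        num = atom.GetAtomicNum()
        if num == 6:
            c += 1
        else:
            hetero += 1
            if num == 7:
                n += 1
    return total, c, n, hetero


def describe(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return [smiles] + [""] * (len(COLS) - 2) + [1]
    total, arc, arn, arh = aromatic_counts(mol)
    scaffold = MurckoScaffold.GetScaffoldForMol(mol)
    return [
        smiles,
        rd.CalcFractionCSP3(mol),
        rd.CalcNumHeteroatoms(mol),
        rd.CalcNumAtomStereoCenters(mol)
        + rd.CalcNumUnspecifiedAtomStereoCenters(mol),
        rd.CalcNumAliphaticRings(mol),
        rd.CalcNumAliphaticCarbocycles(mol),
        rd.CalcNumAliphaticHeterocycles(mol),
        rd.CalcNumAromaticRings(mol),
        rd.CalcNumAromaticCarbocycles(mol),
        rd.CalcNumAromaticHeterocycles(mol),
        rd.CalcNumSaturatedRings(mol),
        rd.CalcNumSaturatedCarbocycles(mol),
        rd.CalcNumSaturatedHeterocycles(mol),
        total, arc, arn, arh,
        Chem.MolToSmiles(scaffold, isomericSmiles=True),
        Chem.MolToSmiles(scaffold, isomericSmiles=False),
        0,
    ]


def main():
    infile, outfile = sys.argv[1], sys.argv[2]
    with open(infile) as fh:
        smiles = [line.rstrip("\n") for line in fh if line.strip()]
    with open(outfile, "w", newline="") as fh:
        writer = csv.writer(fh)
        writer.writerow(COLS)
        for smi in smiles:
            writer.writerow(describe(smi))


if __name__ == "__main__":
    main()
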