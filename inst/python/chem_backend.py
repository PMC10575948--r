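"""RDKit backend for qsareval.

Reads newline-delimited SMILES from an input file and writes CSV to an
output file. Invoked once per batch from R; never interactively.

Usage:
  python chem_backend.py canon  <in> <out>
  python chem_backend.py feat   <in> <out> <name> <params_json>

`canon` emits: canonical,valid,scaffold (scaffold of the canonical form,
empty for acyclic or invalid input).
`feat` emits a numeric matrix with a header row; failed rows are all "NA"
(imputation is the caller's policy). Names: PhysChem, RDKit2D, MACCS,
MorganBits, MorganCounts, AtomPairs.
"""

import csv
import json
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors, MACCSkeys, rdFingerprintGenerator, rdMolDescriptors
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

PHYSCHEM = [
    "MolWt", "MolLogP", "NumHDonors", "NumHAcceptors", "NumRotatableBonds",
    "NumAtoms", "NumHeavyAtoms", "MolMR", "PSA", "FormalCharge", "NumRings",
]


def read_smiles(path):
    with open(path) as fh:
        return [line.rstrip("\n") for line in fh]


def cmd_canon(inp, out):
    rows = []
    for smi in read_smiles(inp):
        mol = Chem.MolFromSmiles(smi) if smi else None
        if mol is None:
            rows.append(("", 0, ""))
            continue
        can = Chem.MolToSmiles(mol)
        try:
            scaf = MurckoScaffold.MurckoScaffoldSmiles(can)
        except Exception:
            scaf = ""
        rows.append((can, 1, scaf))
    with open(out, "w", newline="") as fh:
        w = csv.writer(fh)
        w.writerow(["canonical", "valid", "scaffold"])
        w.writerows(rows)


def physchem_row(mol):
    return [
        Descriptors.MolWt(mol),
        Descriptors.MolLogP(mol),
        rdMolDescriptors.CalcNumHBD(mol),
        rdMolDescriptors.CalcNumHBA(mol),
        rdMolDescriptors.CalcNumRotatableBonds(mol),
        mol.GetNumAtoms() + sum(a.GetTotalNumHs() for a in mol.GetAtoms()),
        mol.GetNumHeavyAtoms(),
        Descriptors.MolMR(mol),
        rdMolDescriptors.CalcTPSA(mol),
        Chem.GetFormalCharge(mol),
        rdMolDescriptors.CalcNumRings(mol),
    ]


def cmd_feat(inp, out, name, params):
    radius = int(params.get("radius", 2))
    n_bits = int(params.get("n_bits", 2048))

    if name == "PhysChem":
        header = PHYSCHEM
        func = physchem_row
    elif name == "RDKit2D":
        desc = Descriptors.descList
        header = [d[0] for d in desc]

        def func(mol):
            vals = []
            for _, f in desc:
                try:
                    v = f(mol)
                    vals.append(v if isinstance(v, (int, float)) and math.isfinite(v) else None)
                except Exception:
                    vals.append(None)
            return vals
    elif name == "MACCS":
        # RDKit emits 167 slots with key 0 unused; it is dropped here.
        header = ["maccs_%d" % i for i in range(1, 167)]

        def func(mol):
            return list(MACCSkeys.GenMACCSKeys(mol))[1:]
    elif name in ("MorganBits", "MorganCounts"):
        gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=n_bits)
        header = ["bit_%d" % i for i in range(n_bits)]
        if name == "MorganBits":
            def func(mol):
                return list(gen.GetFingerprint(mol))
        else:
            def func(mol):
                vec = [0] * n_bits
                for k, v in gen.GetCountFingerprint(mol).GetNonzeroElements().items():
                    vec[k] = v
                return vec
    elif name == "AtomPairs":
        gen = rdFingerprintGenerator.GetAtomPairGenerator(fpSize=n_bits)
        header = ["bit_%d" % i for i in range(n_bits)]

        def func(mol):
            return list(gen.GetFingerprint(mol))
    else:
        sys.exit("unknown representation: %s" % name)

    with open(out, "w", newline="") as fh:
        w = csv.writer(fh)
        w.writerow(header)
        for smi in read_smiles(inp):
            mol = Chem.MolFromSmiles(smi) if smi else None
            if mol is None:
                w.writerow(["NA"] * len(header))
                continue
            try:
                row = func(mol)
            except Exception:
                row = [None] * len(header)
            w.writerow(["NA" if v is None else v for v in row])


def main():
    cmd = sys.argv[1]
    if cmd == "canon":
        cmd_canon(sys.argv[2], sys.argv[3])
    elif cmd == "feat":
        params = json.loads(sys.argv[5]) if len(sys.argv) > 5 else {}
        if not isinstance(params, dict):  # empty R list serializes as []
            params = {}
        cmd_feat(sys.argv[2], sys.argv[3], sys.argv[4], params)
    elif cmd == "version":
        import rdkit
        print(rdkit.__version__)
    else:
        sys.exit("unknown command: %s" % cmd)


if __name__ == "__main__":
    main()
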