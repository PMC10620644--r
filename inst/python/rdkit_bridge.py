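"""Small-molecule descriptor bridge.

Reads tab-separated requests on stdin (one per line) and emits a JSON array
on stdout. Modes:
  descriptors  -- line: SMILES           -> physicochemical descriptors
  canonical    -- line: SMILES           -> canonical SMILES
  substruct    -- line: SMILES \t SMARTS -> boolean match
Unparseable input is reported per-record with an "error" field rather than
aborting the batch.
"""
import sys
import json

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors, Crippen, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")


def main():
    mode = sys.argv[1] if len(sys.argv) > 1 else "descriptors"
    out = []
    for line in sys.stdin:
        line = line.rstrip("\n")
        if not line.strip():
            continue
        fields = line.split("\t")
        smi = fields[0]
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"smiles": smi, "error": "parse"})
            continue
        if mode == "canonical":
            out.append({"smiles": smi, "canonical": Chem.MolToSmiles(mol)})
        elif mode == "substruct":
            patt = Chem.MolFromSmarts(fields[1])
            if patt is None:
                out.append({"smiles": smi, "error": "bad pattern"})
            else:
                out.append({"smiles": smi,
                            "match": bool(mol.HasSubstructMatch(patt))})
        else:
            out.append({
                "smiles": smi,
                "canonical": Chem.MolToSmiles(mol),
                "mw": Descriptors.MolWt(mol),
                "hbd": rdMolDescriptors.CalcNumHBD(mol),
                "hba": rdMolDescriptors.CalcNumHBA(mol),
                "rotatable_bonds": rdMolDescriptors.CalcNumRotatableBonds(mol),
                "clogp": Crippen.MolLogP(mol),
                "psa": rdMolDescriptors.CalcTPSA(mol),
                "heavy_atoms": mol.GetNumHeavyAtoms(),
            })
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
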