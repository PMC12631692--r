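"""Batched RDKit worker for the molgat R package.

Reads a JSON request {"smiles": [...], "gen3d": bool, "seed": int} from
argv[1] and writes a JSON response to argv[2]: a list with one entry per
input SMILES, either null (parse failure) or a molecule record. The record's
atom arrays follow the input SMILES atom-token order (RDKit does not
renumber atoms on parsing). Geometry is optional and may fail independently
of parsing; a failed geometry is reported as {"error": ...} so the caller
can apply its drop policy.

Conformers are generated with ETKDG using the request seed, relaxed with
MMFF94 (UFF when MMFF parameters are missing), and charged with MMFF94
partial charges (Gasteiger fallback). All of this is deterministic for a
fixed seed.
"""

import json
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors, Lipinski, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")


def atom_record(mol):
    return {
        "element": [a.GetSymbol() for a in mol.GetAtoms()],
        "atomic_number": [a.GetAtomicNum() for a in mol.GetAtoms()],
        "aromatic": [bool(a.GetIsAromatic()) for a in mol.GetAtoms()],
        "degree": [a.GetDegree() for a in mol.GetAtoms()],
        "n_h": [a.GetTotalNumHs() for a in mol.GetAtoms()],
        "valence": [a.GetTotalValence() for a in mol.GetAtoms()],
        "radical_electrons": [a.GetNumRadicalElectrons()
                              for a in mol.GetAtoms()],
        "formal_charge": [a.GetFormalCharge() for a in mol.GetAtoms()],
        "has_implicit_h": [a.GetNumImplicitHs() > 0 for a in mol.GetAtoms()],
        "hybridization": [str(a.GetHybridization()) for a in mol.GetAtoms()],
    }


def descriptor_record(mol):
    return {
        "tpsa": rdMolDescriptors.CalcTPSA(mol),
        "mw": Descriptors.MolWt(mol),
        "hba": rdMolDescriptors.CalcNumHBA(mol),
        "hbd": rdMolDescriptors.CalcNumHBD(mol),
        "num_hbond_donors": Lipinski.NumHDonors(mol),
        "num_rotatable_bonds": rdMolDescriptors.CalcNumRotatableBonds(mol),
        "num_rings": rdMolDescriptors.CalcNumRings(mol),
        "net_formal_charge": Chem.GetFormalCharge(mol),
    }


def geometry_record(mol, seed):
    try:
        mh = Chem.AddHs(mol)
        params = AllChem.ETKDGv3()
        params.randomSeed = int(seed)
        if AllChem.EmbedMolecule(mh, params) != 0:
            return {"error": "conformer embedding failed"}
        try:
            AllChem.MMFFOptimizeMolecule(mh)
            ff = "MMFF94"
        except Exception:
            AllChem.UFFOptimizeMolecule(mh)
            ff = "UFF"
        charges = None
        charge_model = "MMFF94"
        try:
            props = AllChem.MMFFGetMoleculeProperties(mh)
            if props is not None:
                charges = [props.GetMMFFPartialCharge(i)
                           for i in range(mh.GetNumAtoms())]
        except Exception:
            charges = None
        if charges is None:
            AllChem.ComputeGasteigerCharges(mh)
            charges = [float(a.GetProp("_GasteigerCharge"))
                       for a in mh.GetAtoms()]
            charge_model = "Gasteiger"
        if any(not math.isfinite(q) for q in charges):
            return {"error": "non-finite partial charges"}
        conf = mh.GetConformer()
        coords = [[conf.GetAtomPosition(i).x,
                   conf.GetAtomPosition(i).y,
                   conf.GetAtomPosition(i).z]
                  for i in range(mh.GetNumAtoms())]
        volume = AllChem.ComputeMolVolume(mh)
        return {
            "n_heavy": mol.GetNumAtoms(),
            "coords": coords,
            "charges": charges,
            "volume": volume,
            "force_field": ff,
            "charge_model": charge_model,
        }
    except Exception as exc:  # embedding can throw on odd valences
        return {"error": str(exc)}


def process(smiles, gen3d, seed):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None or mol.GetNumAtoms() == 0:
        return None
    rec = {
        "smiles": smiles,
        "atoms": atom_record(mol),
        "bonds": [[b.GetBeginAtomIdx(), b.GetEndAtomIdx()]
                  for b in mol.GetBonds()],
        "descriptors": descriptor_record(mol),
    }
    if gen3d:
        rec["geometry"] = geometry_record(mol, seed)
    return rec


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    gen3d = bool(req.get("gen3d", False))
    seed = int(req.get("seed", 0))
    out = [process(s, gen3d, seed) for s in req["smiles"]]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
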