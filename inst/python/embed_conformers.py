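"""Deterministic seeded 3D embedding of SMILES via RDKit ETKDGv3.

Reads {"smiles": [...], "seed": int} as JSON on stdin, writes a JSON list of
V2000 molblocks (null where embedding failed) on stdout.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


N_CONFS = 8  # small seeded ensemble; the lowest-energy member is kept


def embed(smi, seed):
    m = Chem.MolFromSmiles(smi)
    if m is None:
        return None
    m = Chem.AddHs(m)
    ps = AllChem.ETKDGv3()
    ps.randomSeed = seed
    cids = list(AllChem.EmbedMultipleConfs(m, numConfs=N_CONFS, params=ps))
    if not cids:
        ps.useRandomCoords = True
        cids = list(AllChem.EmbedMultipleConfs(m, numConfs=N_CONFS, params=ps))
        if not cids:
            return None
    best, best_e = cids[0], None
    for cid in cids:
        try:
            if AllChem.MMFFHasAllMoleculeParams(m):
                ff = AllChem.MMFFGetMoleculeForceField(
                    m, AllChem.MMFFGetMoleculeProperties(m), confId=cid)
            else:
                ff = AllChem.UFFGetMoleculeForceField(m, confId=cid)
            ff.Minimize(maxIts=2000)
            e = ff.CalcEnergy()
        except Exception:
            e = None
        if e is not None and (best_e is None or e < best_e):
            best, best_e = cid, e
    return Chem.MolToMolBlock(m, confId=best)


def main():
    inp = json.load(sys.stdin)
    seed = int(inp.get("seed", 1))
    out = [embed(s, seed) for s in inp["smiles"]]
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
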