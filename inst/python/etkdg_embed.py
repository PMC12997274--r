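"""Batch conformer generation: seeded ETKDGv3 embedding + MMFF94s relaxation.

Reads a multi-record SDF (hydrogen-free heavy-atom blocks are fine), embeds
`n_conf` conformers per record with a fixed random seed, optimises them with
the MMFF94s force field, and writes one SDF entry per conformer carrying
`mol_index`, `conf_index` and `energy_kcal` properties. Heavy-atom order of
the input is preserved (added hydrogens are appended, then stripped).
"""
import sys

from rdkit import Chem
from rdkit.Chem import AllChem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def main(inp, out, n_conf, seed):
    writer = Chem.SDWriter(out)
    supplier = Chem.SDMolSupplier(inp, removeHs=False, sanitize=True)
    for idx, mol in enumerate(supplier, start=1):
        if mol is None:
            sys.stderr.write("FAIL %d parse\n" % idx)
            continue
        try:
            molh = Chem.AddHs(mol)
            params = AllChem.ETKDGv3()
            params.randomSeed = seed
            params.clearConfs = True
            conf_ids = AllChem.EmbedMultipleConfs(molh, numConfs=n_conf, params=params)
            if not conf_ids:
                sys.stderr.write("FAIL %d embed\n" % idx)
                continue
            res = AllChem.MMFFOptimizeMoleculeConfs(molh, mmffVariant="MMFF94s")
            stripped = Chem.RemoveHs(molh)
            for k, cid in enumerate(conf_ids):
                stripped.SetProp("mol_index", str(idx))
                stripped.SetProp("conf_index", str(k + 1))
                energy = res[k][1] if k < len(res) and res[k][0] != -1 else float("nan")
                stripped.SetProp("energy_kcal", "%.6f" % energy)
                writer.write(stripped, confId=cid)
        except Exception as exc:  # noqa: BLE001 - report and keep going
            sys.stderr.write("FAIL %d %s\n" % (idx, exc))
    writer.close()


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2], int(sys.argv[3]), int(sys.argv[4]))
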