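"""RDKit helper invoked by the scaffoldspace R package.

Usage: python chem_bridge.py <op> <input.json> <outdir>

Each op reads a JSON payload and writes one or more TSV files into <outdir>.
All SMILES emitted are RDKit canonical SMILES. The bridge performs only
standard toolkit operations (parsing, largest-fragment standardization,
Bemis-Murcko scaffold extraction, InChI-Key generation, Morgan fingerprints,
molecular-graph export, SDF reading, deterministic decoration of scaffolds);
all method logic lives on the R side.
"""

import json
import random
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem
from rdkit.Chem import inchi
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")


def largest_fragment(mol):
    """Fragment with the most heavy atoms; ties broken by canonical SMILES."""
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=True)
    if len(frags) == 1:
        return frags[0]
    keyed = sorted(
        frags, key=lambda f: (-f.GetNumHeavyAtoms(), Chem.MolToSmiles(f))
    )
    return keyed[0]


def murcko(mol):
    """Canonical Bemis-Murcko scaffold SMILES, or '' for acyclic input."""
    if mol.GetRingInfo().NumRings() == 0:
        return ""
    scaf = MurckoScaffold.GetScaffoldForMol(mol)
    if scaf is None or scaf.GetNumHeavyAtoms() == 0:
        return ""
    return Chem.MolToSmiles(scaf)


def op_process(payload, outdir):
    ids = payload["ids"]
    smiles = payload["smiles"]
    rows = []
    for rid, smi in zip(ids, smiles):
        rec = {
            "id": rid, "ok": 0, "error": "", "n_frags": 0,
            "smiles_std": "", "inchikey": "", "bms": "", "bms_inchikey": "",
        }
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            rec["error"] = "unparseable SMILES"
            rows.append(rec)
            continue
        rec["n_frags"] = len(Chem.GetMolFrags(mol))
        std = largest_fragment(mol)
        rec["smiles_std"] = Chem.MolToSmiles(std)
        try:
            rec["inchikey"] = inchi.MolToInchiKey(std)
        except Exception:
            rec["error"] = "inchi failure"
            rows.append(rec)
            continue
        bms = murcko(std)
        rec["bms"] = bms
        if bms:
            try:
                rec["bms_inchikey"] = inchi.MolToInchiKey(Chem.MolFromSmiles(bms))
            except Exception:
                rec["error"] = "inchi failure on scaffold"
                rows.append(rec)
                continue
        rec["ok"] = 1
        rows.append(rec)
    write_tsv(
        outdir, "mols.tsv",
        ["id", "ok", "error", "n_frags", "smiles_std", "inchikey", "bms",
         "bms_inchikey"],
        rows,
    )


def op_graphs(payload, outdir):
    """Molecular graph tables (atoms, bonds, SSSR rings) for valid SMILES."""
    atoms, bonds, rings = [], [], []
    for i, smi in enumerate(payload["smiles"]):
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            raise ValueError("graphs op received unparseable SMILES: %s" % smi)
        ri = mol.GetRingInfo()
        for a in mol.GetAtoms():
            atoms.append({
                "mol": i, "atom": a.GetIdx(), "symbol": a.GetSymbol(),
                "anum": a.GetAtomicNum(),
                "aromatic": int(a.GetIsAromatic()),
                "charge": a.GetFormalCharge(),
                "in_ring": int(a.IsInRing()),
                "degree": a.GetDegree(),
            })
        for b in mol.GetBonds():
            bonds.append({
                "mol": i, "a": b.GetBeginAtomIdx(), "b": b.GetEndAtomIdx(),
                "order": b.GetBondTypeAsDouble(),
                "aromatic": int(b.GetIsAromatic()),
                "in_ring": int(b.IsInRing()),
            })
        for ridx, ring in enumerate(ri.AtomRings()):
            for a in ring:
                rings.append({"mol": i, "ring": ridx, "atom": a})
    write_tsv(outdir, "atoms.tsv",
              ["mol", "atom", "symbol", "anum", "aromatic", "charge",
               "in_ring", "degree"], atoms)
    write_tsv(outdir, "bonds.tsv",
              ["mol", "a", "b", "order", "aromatic", "in_ring"], bonds)
    write_tsv(outdir, "rings.tsv", ["mol", "ring", "atom"], rings)


def op_fp(payload, outdir):
    radius = int(payload.get("radius", 3))
    nbits = int(payload.get("nbits", 2048))
    rows = []
    for rid, smi in zip(payload["ids"], payload["smiles"]):
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            rows.append({"id": rid, "ok": 0, "bits": ""})
            continue
        fp = AllChem.GetMorganFingerprintAsBitVect(mol, radius, nBits=nbits)
        on = list(fp.GetOnBits())
        rows.append({"id": rid, "ok": 1, "bits": " ".join(str(b) for b in on)})
    write_tsv(outdir, "fps.tsv", ["id", "ok", "bits"], rows)


def op_read_sdf(payload, outdir):
    path = payload["path"]
    id_prop = payload.get("id_prop") or None
    rows = []
    supplier = Chem.SDMolSupplier(path, sanitize=True)
    for i, mol in enumerate(supplier):
        if mol is None:
            rows.append({"id": "SDF%05d" % (i + 1), "ok": 0, "smiles": ""})
            continue
        if id_prop and mol.HasProp(id_prop):
            rid = mol.GetProp(id_prop)
        elif mol.HasProp("_Name") and mol.GetProp("_Name").strip():
            rid = mol.GetProp("_Name").strip()
        else:
            rid = "SDF%05d" % (i + 1)
        rows.append({"id": rid, "ok": 1, "smiles": Chem.MolToSmiles(mol)})
    write_tsv(outdir, "sdf.tsv", ["id", "ok", "smiles"], rows)


def op_decorate(payload, outdir):
    """Decorate scaffolds with 0..max_sub substituents at ring carbons.

    Deterministic for a given seed. Substituent SMILES are attached by a
    single bond from their first atom to a randomly chosen ring carbon that
    still carries at least one implicit hydrogen. Invalid decorations are
    retried a bounded number of times.
    """
    rng = random.Random(int(payload["seed"]))
    scaffolds = payload["scaffolds"]
    pool = payload.get("pool") or ["C", "CC", "O", "N", "F", "Cl", "OC",
                                   "C#N", "C(C)C", "C(=O)C"]
    n = int(payload["n"])
    max_sub = int(payload.get("max_sub", 3))
    mols = [Chem.MolFromSmiles(s) for s in scaffolds]
    if any(m is None for m in mols):
        raise ValueError("decorate op received unparseable scaffold SMILES")
    frag_mols = {s: Chem.MolFromSmiles(s) for s in pool}
    rows = []
    for i in range(n):
        parent_idx = rng.randrange(len(mols))
        base = mols[parent_idx]
        n_sub = rng.randint(0, max_sub)
        out = None
        for _attempt in range(8):
            work = Chem.RWMol(base)
            ok = True
            for _s in range(n_sub):
                sites = [a.GetIdx() for a in work.GetAtoms()
                         if a.IsInRing() and a.GetSymbol() == "C"
                         and a.GetTotalNumHs() > 0]
                if not sites:
                    ok = False
                    break
                site = rng.choice(sites)
                frag = frag_mols[pool[rng.randrange(len(pool))]]
                offset = work.GetNumAtoms()
                combo = Chem.RWMol(Chem.CombineMols(work.GetMol(), frag))
                combo.AddBond(site, offset, Chem.BondType.SINGLE)
                try:
                    Chem.SanitizeMol(combo)
                except Exception:
                    ok = False
                    break
                work = combo
            if ok:
                try:
                    out = Chem.MolToSmiles(work.GetMol())
                except Exception:
                    out = None
            if out:
                break
        if out is None:  # fall back to the bare scaffold
            out = Chem.MolToSmiles(base)
            n_sub = 0
        rows.append({"i": i + 1, "smiles": out, "parent": parent_idx + 1,
                     "n_sub": n_sub})
    write_tsv(outdir, "compounds.tsv", ["i", "smiles", "parent", "n_sub"], rows)


def write_tsv(outdir, name, cols, rows):
    with open("%s/%s" % (outdir, name), "w") as fh:
        fh.write("\t".join(cols) + "\n")
        for r in rows:
            fh.write("\t".join(str(r[c]) for c in cols) + "\n")


OPS = {
    "process": op_process,
    "graphs": op_graphs,
    "fp": op_fp,
    "read_sdf": op_read_sdf,
    "decorate": op_decorate,
}


def main(argv):
    if len(argv) != 4 or argv[1] not in OPS:
        sys.stderr.write("usage: chem_bridge.py <%s> <input.json> <outdir>\n"
                         % "|".join(sorted(OPS)))
        return 2
    with open(argv[2]) as fh:
        payload = json.load(fh)
    OPS[argv[1]](payload, argv[3])
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
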